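# Fixture builders shared across test files. All randomness is seeded by
# the caller.

# random normalized differential DVH on a uniform grid
rand_ddvh <- function(n_bins = 200, bin_width = 0.05, start = bin_width / 2) {
  v <- stats::runif(n_bins)
  dvh_differential(start + (0:(n_bins - 1)) * bin_width, v / sum(v),
                   bin_width = bin_width)
}

# differential DVH with specified point masses, embedded in a uniform grid
mass_ddvh <- function(doses, masses, bin_width = 0.05) {
  lo <- min(doses); hi <- max(doses)
  centers <- seq(lo, hi, by = bin_width)
  v <- numeric(length(centers))
  for (i in seq_along(doses)) {
    j <- which.min(abs(centers - doses[i]))
    v[j] <- v[j] + masses[i]
  }
  dvh_differential(centers, v, bin_width = bin_width)
}

linear_cdvh <- function(dmax = 50) dvh_cumulative(c(0, dmax), c(1, 0))

# even-odd point-in-polygon test (for the dense-sampling MHD oracle)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# brute-force MHD: sample the polygon bounding box on a fine lattice, keep
# interior points inside the field bounds, maximize the signed distance
mhd_sampling_oracle <- function(scene, resolution = 0.002) {
  poly <- scene$heart_contour
  xs <- seq(min(poly[, 1]), max(poly[, 1]), by = resolution)
  ys <- seq(min(poly[, 2]), max(poly[, 2]), by = resolution)
  grid <- expand.grid(x = xs, y = ys)
  keep <- point_in_polygon(grid$x, grid$y, poly)
  if (!is.null(scene$field_bounds)) {
    b <- scene$field_bounds
    keep <- keep & grid$x >= b[1] & grid$x <= b[2] &
      grid$y >= b[3] & grid$y <= b[4]
  }
  if (!any(keep)) return(0)
  d <- (grid$x[keep] - scene$edge_point[1]) * scene$edge_normal[1] +
    (grid$y[keep] - scene$edge_point[2]) * scene$edge_normal[2]
  max(0, max(d))
}

# exact two-sided signed-rank p by enumeration of all 2^m sign patterns
signed_rank_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  patterns <- 0:(2^m - 1)
  bits <- vapply(seq_len(m) - 1L,
                 function(b) (patterns %/% 2^b) %% 2, numeric(length(patterns)))
  w_all <- as.vector(bits %*% r)
  min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
}

# exact two-sided rank-sum p by enumeration of all rank assignments
rank_sum_enum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(rank(c(x, y))[combos], nrow = n)) - n * (n + 1) / 2
  min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
}

# minimal hand-built paired cohort: uniform-dose organs so every metric is
# checkable by hand
toy_pair <- function(id, heart_fb_dose, heart_eig_dose, plan_type = "tangential") {
  mk <- function(dose, tech) {
    structure_plan("heart", tech, plan_type,
                   dvh_differential(dose, 1, bin_width = 0.05,
                                    total_volume = 600,
                                    structure_label = "heart"))
  }
  patient_plan_pair(id, plan_type,
                    fb = list(heart = mk(heart_fb_dose, "FB")),
                    eig = list(heart = mk(heart_eig_dose, "EIG")))
}
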