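#' Beam's-eye-view scene for the maximum heart distance
#'
#' A 2D abstraction of the beam's-eye view of a tangential field: the heart
#' contour projected into the view as a simple closed polygon (cm), and the
#' posterior field edge as an infinite straight line given by a point on it
#' and the unit normal pointing into the field. An optional axis-aligned
#' rectangle limits the aperture laterally. The jagged per-leaf MLC edge is
#' abstracted to its straight posterior border.
#'
#' @param heart_contour Two-column matrix (x, y in cm) of polygon vertices
#'   in order; at least 3 vertices, simple (non-self-intersecting), with
#'   non-zero area. Do not repeat the first vertex.
#' @param edge_point Length-2 numeric: a point on the posterior field edge.
#' @param edge_normal Length-2 unit vector (|n| = 1 within 1e-9) pointing
#'   from the edge into the treated field.
#' @param field_bounds Optional `c(xmin, xmax, ymin, ymax)` rectangle.
#' @return An object of class `bev_scene`.
#' @export
bev_scene <- function(heart_contour, edge_point, edge_normal,
                      field_bounds = NULL) {
  heart_contour <- as.matrix(heart_contour)
  if (ncol(heart_contour) != 2L)
    stop("heart_contour must be a two-column (x, y) matrix")
  if (nrow(heart_contour) < 3L)
    stop("degenerate polygon: at least 3 vertices required")
  if (any(!is.finite(heart_contour)))
    stop("non-finite polygon coordinates")
  if (abs(polygon_area(heart_contour)) < 1e-12)
    stop("degenerate polygon: zero area")
  if (!polygon_is_simple(heart_contour))
    stop("heart contour must be a simple (non-self-intersecting) polygon")
  edge_point <- as.numeric(edge_point)
  edge_normal <- as.numeric(edge_normal)
  if (length(edge_point) != 2L || length(edge_normal) != 2L)
    stop("edge_point and edge_normal must have length 2")
  if (abs(sqrt(sum(edge_normal^2)) - 1) > 1e-9)
    stop("edge_normal must have unit length")
  if (!is.null(field_bounds)) {
    field_bounds <- as.numeric(field_bounds)
    if (length(field_bounds) != 4L || field_bounds[1] >= field_bounds[2] ||
        field_bounds[3] >= field_bounds[4])
      stop("field_bounds must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  structure(list(heart_contour = heart_contour, edge_point = edge_point,
                 edge_normal = edge_normal, field_bounds = field_bounds),
            class = "bev_scene")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  sum(x * y[j] - x[j] * y) / 2
}

# O(n^2) segment-intersection check; contours here have tens of vertices.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Sutherland-Hodgman clip of polygon p by half-plane dot(x, n) <= c
clip_halfplane <- function(p, n, c) {
  if (nrow(p) == 0L) return(p)
  vals <- p %*% n - c
  out <- matrix(numeric(0), ncol = 2)
  np <- nrow(p)
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    a <- p[i, ]; b <- p[j, ]
    va <- vals[i]; vb <- vals[j]
    if (va <= 1e-12) out <- rbind(out, a)
    if ((va < -1e-12 && vb > 1e-12) || (va > 1e-12 && vb < -1e-12)) {
      t <- va / (va - vb)
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

#' Maximum heart distance (MHD)
#'
#' The maximal perpendicular penetration, in cm, of the heart contour past
#' the posterior field edge into the treated field — the standard
#' beam's-eye-view surrogate for how much heart a tangential field
#' irradiates. Computed as the maximum signed distance
#' `dot(v - edge_point, edge_normal)` over the contour restricted to the
#' field bounds; the maximum of this linear function over a polygon is
#' attained at a vertex of the (clipped) contour. Hearts entirely on the
#' out-of-field side give 0; vertices exactly on the edge count as 0.
#'
#' @param scene A [bev_scene()] object.
#' @return MHD in cm (>= 0). Reported to 1 decimal in plan tables.
#' @export
max_heart_distance <- function(scene) {
  stopifnot(inherits(scene, "bev_scene"))
  poly <- scene$heart_contour
  if (!is.null(scene$field_bounds)) {
    b <- scene$field_bounds
    poly <- clip_halfplane(poly, c(-1, 0), -b[1])
    poly <- clip_halfplane(poly, c(1, 0), b[2])
    poly <- clip_halfplane(poly, c(0, -1), -b[3])
    poly <- clip_halfplane(poly, c(0, 1), b[4])
    if (nrow(poly) == 0L) return(0)
  }
  depths <- (poly[, 1] - scene$edge_point[1]) * scene$edge_normal[1] +
    (poly[, 2] - scene$edge_point[2]) * scene$edge_normal[2]
  max(0, max(depths))
}
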