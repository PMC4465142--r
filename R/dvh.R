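#' Differential dose-volume histogram
#'
#' A differential DVH stores, for a single structure, the fraction of the
#' structure volume receiving a dose inside each bin of a uniform dose grid.
#' Doses are bin centers in Gy; the volume fractions are unitless and sum
#' to one (a normalized DVH). The absolute structure volume, if known, is
#' carried as metadata in cm^3 and never enters the dose metrics.
#'
#' Volume fractions whose sum deviates from one by more than `1e-6` but at
#' most `1e-3` are renormalized with a warning (planning-system exports are
#' often rounded); larger deviations are rejected.
#'
#' @param bin_center Numeric vector of bin-center doses in Gy, strictly
#'   increasing on a uniform grid with spacing `bin_width`.
#' @param volume_fraction Non-negative volume fraction per bin, summing to 1.
#' @param bin_width Dose bin width in Gy. Default 0.05 Gy, the grid planning
#'   systems typically export.
#' @param total_volume Optional absolute structure volume in cm^3.
#' @param structure_label Optional structure name.
#' @return An object of class `dvh_diff`.
#' @seealso [dvh_cumulative()], [as_cumulative()], [mean_dose()]
#' @export
dvh_differential <- function(bin_center, volume_fraction, bin_width = 0.05,
                             total_volume = NULL, structure_label = "") {
  bin_center <- as.numeric(bin_center)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(bin_center) == 0L)
    stop("empty DVH: at least one dose bin is required")
  if (length(bin_center) != length(volume_fraction))
    stop("bin_center and volume_fraction must have equal length")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number (Gy)")
  if (any(!is.finite(bin_center)) || any(!is.finite(volume_fraction)))
    stop("non-finite values in DVH")
  if (any(bin_center < 0))
    stop("doses must be non-negative")
  if (any(volume_fraction < 0))
    stop("volume fractions must be non-negative")
  if (length(bin_center) > 1L) {
    spacing <- diff(bin_center)
    if (any(spacing <= 0))
      stop("bin centers must be strictly increasing")
    if (any(abs(spacing - bin_width) > 1e-9))
      stop("bin centers must lie on a uniform grid with spacing bin_width")
  }
  s <- sum(volume_fraction)
  if (abs(s - 1) > 1e-3)
    stop(sprintf(
      "volume fractions sum to %.6f, not 1: not a normalized differential DVH",
      s))
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("renormalizing volume fractions (sum was %.6f)", s))
    volume_fraction <- volume_fraction / s
  }
  structure(
    list(bin_center = bin_center, bin_width = bin_width,
         volume_fraction = volume_fraction, total_volume = total_volume,
         structure_label = as.character(structure_label)),
    class = "dvh_diff")
}

#' Cumulative dose-volume histogram
#'
#' A cumulative DVH gives, on an ascending dose grid, the fraction of the
#' structure volume receiving at least that dose. The curve is monotone
#' non-increasing and equals 1 at zero dose. Between grid points the curve
#' is evaluated by linear interpolation; below the grid it is 1 and above
#' the grid it is 0.
#'
#' @param dose Ascending numeric dose grid in Gy.
#' @param volume_fraction Fraction of volume receiving at least each dose.
#' @param total_volume Optional absolute structure volume in cm^3.
#' @param structure_label Optional structure name.
#' @return An object of class `dvh_cum`.
#' @export
dvh_cumulative <- function(dose, volume_fraction, total_volume = NULL,
                           structure_label = "") {
  dose <- as.numeric(dose)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose) == 0L)
    stop("empty DVH: at least one grid point is required")
  if (length(dose) != length(volume_fraction))
    stop("dose and volume_fraction must have equal length")
  if (any(!is.finite(dose)) || any(!is.finite(volume_fraction)))
    stop("non-finite values in DVH")
  if (any(dose < 0)) stop("doses must be non-negative")
  if (is.unsorted(dose, strictly = TRUE))
    stop("dose grid must be strictly increasing")
  if (any(diff(volume_fraction) > 1e-9))
    stop("cumulative DVH must be monotone non-increasing in dose")
  # snap away tiny non-monotone noise
  volume_fraction <- rev(cummax(rev(volume_fraction)))
  if (min(volume_fraction) < 0) stop("volume fractions must be non-negative")
  v0 <- if (dose[1] <= 0) volume_fraction[1] else 1
  if (abs(v0 - 1) > 1e-6)
    stop(sprintf("cumulative DVH must equal 1 at zero dose (got %.8f)", v0))
  structure(
    list(dose = dose, volume_fraction = volume_fraction,
         total_volume = total_volume,
         structure_label = as.character(structure_label)),
    class = "dvh_cum")
}

#' @export
print.dvh_diff <- function(x, ...) {
  cat(sprintf("Differential DVH%s: %d bins of %.3g Gy, dose %.2f-%.2f Gy\n",
              if (nzchar(x$structure_label))
                paste0(" [", x$structure_label, "]") else "",
              length(x$bin_center), x$bin_width,
              min(x$bin_center), max(x$bin_center)))
  cat(sprintf("  mean dose %.2f Gy%s\n", mean_dose(x),
              if (!is.null(x$total_volume))
                sprintf(", volume %.1f cm^3", x$total_volume) else ""))
  invisible(x)
}

#' @export
print.dvh_cum <- function(x, ...) {
  cat(sprintf("Cumulative DVH%s: %d grid points, dose %.2f-%.2f Gy\n",
              if (nzchar(x$structure_label))
                paste0(" [", x$structure_label, "]") else "",
              length(x$dose), min(x$dose), max(x$dose)))
  invisible(x)
}

#' Convert a differential DVH to cumulative form
#'
#' The cumulative grid is placed on the left bin edges of the differential
#' histogram; the value at an edge is the total volume fraction of bins
#' whose centers lie at or above it. A final grid point at the right edge
#' of the last bin closes the curve at 0, and a point (0, 1) is prepended
#' when the first edge is positive, so the result evaluates correctly over
#' the whole dose axis.
#'
#' @param ddvh A [dvh_differential()] object.
#' @return A [dvh_cumulative()] object.
#' @export
as_cumulative <- function(ddvh) {
  stopifnot(inherits(ddvh, "dvh_diff"))
  w <- ddvh$bin_width
  edges <- ddvh$bin_center - w / 2
  edges <- pmax(edges, 0)
  vals <- rev(cumsum(rev(ddvh$volume_fraction)))
  # close the curve: nothing receives >= the right edge of the last bin
  edges <- c(edges, max(ddvh$bin_center) + w / 2)
  vals <- c(vals, 0)
  if (edges[1] > 0) {
    edges <- c(0, edges)
    vals <- c(vals[1], vals)
  }
  keep <- !duplicated(edges)
  dvh_cumulative(edges[keep], vals[keep],
                 total_volume = ddvh$total_volume,
                 structure_label = ddvh$structure_label)
}

#' Convert a cumulative DVH to differential form
#'
#' Rebins the cumulative curve onto a uniform grid of width `bin_width`
#' starting at the lowest grid dose: the mass of bin i is the drop of the
#' (linearly interpolated) cumulative curve across the bin. The resulting
#' fractions sum to the cumulative value at the grid start.
#'
#' @param cdvh A [dvh_cumulative()] object.
#' @param bin_width Dose bin width in Gy (default 0.05).
#' @return A [dvh_differential()] object with bin centers at the midpoints
#'   of the rebinning grid.
#' @export
as_differential <- function(cdvh, bin_width = 0.05) {
  stopifnot(inherits(cdvh, "dvh_cum"))
  if (bin_width <= 0) stop("bin_width must be positive")
  d0 <- min(cdvh$dose)
  d1 <- max(cdvh$dose)
  n_bins <- max(1L, as.integer(ceiling((d1 - d0) / bin_width - 1e-9)))
  edges <- d0 + (0:n_bins) * bin_width
  v_edges <- cum_eval(cdvh, edges)
  dv <- -diff(v_edges)
  dv[dv < 0 & dv > -1e-12] <- 0
  if (any(dv < 0)) stop("cumulative DVH is not monotone: negative bin mass")
  dvh_differential(edges[-length(edges)] + bin_width / 2, dv,
                   bin_width = bin_width,
                   total_volume = cdvh$total_volume,
                   structure_label = cdvh$structure_label)
}

# Evaluate the cumulative curve at arbitrary doses: linear interpolation on
# the grid, 1 below the grid, 0 above it.
cum_eval <- function(cdvh, x) {
  d <- cdvh$dose
  v <- cdvh$volume_fraction
  out <- numeric(length(x))
  below <- x < d[1]
  above <- x > d[length(d)] + 1e-12
  inside <- !below & !above
  out[below] <- 1
  out[above] <- 0
  if (any(inside)) {
    if (length(d) == 1L) {
      out[inside] <- v
    } else {
      out[inside] <- stats::approx(d, v, xout = pmin(x[inside], d[length(d)]),
                                   method = "linear", rule = 2)$y
    }
  }
  out
}

#' Mean absorbed dose of a differential DVH
#'
#' The volume-weighted mean dose, `sum(D_i * dV_i)`, in Gy.
#'
#' @param ddvh A [dvh_differential()] object.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(ddvh) {
  stopifnot(inherits(ddvh, "dvh_diff"))
  sum(ddvh$bin_center * ddvh$volume_fraction)
}

#' Fractional volume receiving at least a threshold dose (VxGy)
#'
#' Evaluates the cumulative DVH at `threshold` Gy by linear interpolation
#' (`interp = "linear"`, the default) or at the nearest grid dose at or
#' above the threshold (`interp = "nearest"`). Thresholds below the grid
#' return 1, above the grid 0.
#'
#' @param cdvh A [dvh_cumulative()] object.
#' @param threshold Dose threshold in Gy, non-negative.
#' @param interp `"linear"` or `"nearest"`.
#' @return Volume fraction in `[0, 1]`; multiply by 100 for the percent
#'   values quoted in plan reports.
#' @export
volume_at_dose <- function(cdvh, threshold, interp = c("linear", "nearest")) {
  stopifnot(inherits(cdvh, "dvh_cum"))
  interp <- match.arg(interp)
  if (any(threshold < 0)) stop("threshold must be non-negative")
  if (interp == "linear") return(cum_eval(cdvh, threshold))
  vapply(threshold, function(t) {
    if (t < cdvh$dose[1]) return(1)
    i <- which(cdvh$dose >= t - 1e-12)
    if (length(i) == 0L) return(0)
    cdvh$volume_fraction[i[1]]
  }, numeric(1))
}

#' Volume covered by a percentage of the prescription dose
#'
#' Coverage metrics such as V93% and V95% of targets, or the hot-spot
#' volume V105%: the fraction of the structure receiving at least
#' `percent/100 * prescription` Gy.
#'
#' @param cdvh A [dvh_cumulative()] object.
#' @param percent Percentage of the prescription dose (> 0), e.g. 93.
#' @param prescription Prescription dose in Gy (default 50).
#' @inheritParams volume_at_dose
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_at_relative_dose <- function(cdvh, percent, prescription = 50,
                                    interp = c("linear", "nearest")) {
  if (any(percent <= 0)) stop("percent must be positive")
  if (prescription <= 0) stop("prescription dose must be positive")
  volume_at_dose(cdvh, prescription * percent / 100, interp = match.arg(interp))
}

#' Dose to the hottest fraction of the volume (DxPct)
#'
#' The smallest dose D such that at most `volume_fraction` of the structure
#' receives at least D — e.g. `volume_fraction = 0.02` gives the
#' near-maximum dose D2%. Linear interpolation on the cumulative curve is
#' the default; `interp = "nearest"` returns the smallest grid dose whose
#' cumulative value is at or below the requested fraction.
#'
#' @param cdvh A [dvh_cumulative()] object.
#' @param volume_fraction Fraction in (0, 1].
#' @inheritParams volume_at_dose
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(cdvh, volume_fraction,
                           interp = c("linear", "nearest")) {
  stopifnot(inherits(cdvh, "dvh_cum"))
  interp <- match.arg(interp)
  if (length(volume_fraction) != 1L || volume_fraction <= 0 ||
      volume_fraction > 1)
    stop("volume_fraction must be a single value in (0, 1]")
  d <- cdvh$dose
  v <- cdvh$volume_fraction
  v0 <- cum_eval(cdvh, 0)
  if (volume_fraction > v0 + 1e-12) {
    warning("requested volume fraction exceeds the DVH volume; returning 0 Gy")
    return(0)
  }
  idx <- which(v <= volume_fraction + 1e-15)
  if (length(idx) == 0L) {
    # curve stays above the fraction on the whole grid; it drops to 0 just
    # beyond the last grid dose
    return(d[length(d)])
  }
  i <- idx[1]
  if (interp == "nearest" || i == 1L) return(d[i])
  if (v[i - 1] <= volume_fraction + 1e-15) return(d[i - 1])
  # interpolate the crossing inside (d[i-1], d[i]]
  d[i - 1] + (v[i - 1] - volume_fraction) / (v[i - 1] - v[i]) * (d[i] - d[i - 1])
}

#' Single-structure treatment plan
#'
#' Bundles one structure's differential DVH with the plan context needed by
#' the dose metrics: the treatment technique (free breathing `FB` or
#' enhanced inspiration gating `EIG`), the plan type (tangential or
#' locoregional) and the prescription dose.
#'
#' @param organ One of `"PTV"`, `"CTV-T"`, `"heart"`, `"LAD"`, `"lung"`.
#' @param technique `"FB"` or `"EIG"`.
#' @param plan_type `"tangential"` or `"locoregional"`.
#' @param dvh A [dvh_differential()] object.
#' @param prescription_dose Prescription dose in Gy (default 50, delivered
#'   in 25 fractions of 2 Gy in the standard schedule).
#' @return An object of class `structure_plan`.
#' @export
structure_plan <- function(organ, technique, plan_type, dvh,
                           prescription_dose = 50) {
  organ <- match.arg(organ, c("PTV", "CTV-T", "heart", "LAD", "lung"))
  technique <- match.arg(technique, c("FB", "EIG"))
  plan_type <- match.arg(plan_type, c("tangential", "locoregional"))
  stopifnot(inherits(dvh, "dvh_diff"))
  if (!is.numeric(prescription_dose) || prescription_dose <= 0)
    stop("prescription_dose must be positive")
  structure(list(organ = organ, technique = technique, plan_type = plan_type,
                 dvh = dvh, prescription_dose = prescription_dose),
            class = "structure_plan")
}
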