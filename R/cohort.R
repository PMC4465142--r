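#' Two-sided paired Wilcoxon signed-rank test
#'
#' Tests whether paired per-patient values differ between two techniques.
#' Zero differences are dropped (Wilcoxon's convention). With at most 20
#' nonzero differences and no tied absolute differences the exact null
#' distribution of the signed-rank statistic is used (via
#' [stats::psignrank()]); otherwise a normal approximation with continuity
#' correction and the standard tie correction of the variance.
#'
#' @param x,y Equal-length numeric vectors of paired values (n >= 5).
#' @return A list with `p_value`, `statistic` (rank sum of positive
#'   differences), `n_used` (nonzero differences) and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("paired test requires n >= 5 pairs")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0L
  if (m <= 20L && !has_ties) {
    p <- if (w > m * (m + 1) / 4)
      2 * stats::psignrank(w - 1, m, lower.tail = FALSE)
    else
      2 * stats::psignrank(w, m)
    return(list(p_value = min(1, p), statistic = w, n_used = m,
                method = "exact"))
  }
  mu <- m * (m + 1) / 4
  tie_tab <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(-abs(z))), statistic = w,
       n_used = m, method = "normal_approx")
}

#' Two-sided unpaired Wilcoxon rank-sum test
#'
#' Compares two independent groups (e.g. tangential vs locoregional
#' patients). Exact via [stats::pwilcox()] when the combined sample size is
#' at most 20 and there are no ties; otherwise the tie- and
#' continuity-corrected normal approximation.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A list as in [paired_wilcoxon()]; `statistic` is the
#'   Mann-Whitney U of `x`.
#' @export
unpaired_wilcoxon <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (n + m <= 20L && !has_ties) {
    p <- if (u > n * m / 2)
      2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    else
      2 * stats::pwilcox(u, n, m)
    return(list(p_value = min(1, p), statistic = u, n_used = n + m,
                method = "exact"))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(-abs(z))), statistic = u,
       n_used = n + m, method = "normal_approx")
}

#' Median and range of a metric sample
#'
#' The summary reported per table cell: median (midpoint convention for
#' even n) with the min-max range.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, min, max)`.
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty sample")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Paired FB/EIG plan set for one patient
#'
#' @param patient_id Patient identifier.
#' @param plan_type `"tangential"` or `"locoregional"`.
#' @param fb,eig Named lists of [structure_plan()] objects, keyed by organ.
#' @param scenes Optional named list with [bev_scene()] elements `FB` and
#'   `EIG` for the maximum heart distance.
#' @param amplitude_mm Optional breathing amplitude during gating (mm).
#' @return An object of class `patient_plan_pair`.
#' @export
patient_plan_pair <- function(patient_id, plan_type, fb, eig, scenes = NULL,
                              amplitude_mm = NA_real_) {
  plan_type <- match.arg(plan_type, c("tangential", "locoregional"))
  stopifnot(is.list(fb), is.list(eig))
  structure(list(patient_id = as.character(patient_id),
                 plan_type = plan_type, fb = fb, eig = eig,
                 scenes = scenes, amplitude_mm = amplitude_mm),
            class = "patient_plan_pair")
}

# Metric definitions per organ, in report (table) order. Units: cm^3 for
# structure volumes, Gy for doses, percent for relative volumes, cm for MHD.
organ_metric_names <- function() {
  c("V_PTV (cm3)", "V_93%,PTV (%)",
    "V_CTV-T (cm3)", "V_95%,CTV-T (%)",
    "V_heart (cm3)", "D_mean,heart (Gy)", "D_2%,heart (Gy)",
    "V_25Gy,heart (%)", "MHD (cm)",
    "V_LAD (cm3)", "D_mean,LAD (Gy)", "D_2%,LAD (Gy)", "V_25Gy,LAD (%)",
    "V_lung (cm3)", "D_mean,lung (Gy)", "V_20Gy,lung (%)",
    "NTCP cardiac mortality (%)", "NTCP radiation pneumonitis (%)")
}

# Metrics for one structure plan -> named numeric vector
structure_metrics <- function(plan) {
  dvh <- plan$dvh
  cdvh <- as_cumulative(dvh)
  rx <- plan$prescription_dose
  out <- c()
  vol <- if (is.null(dvh$total_volume)) NA_real_ else dvh$total_volume
  switch(plan$organ,
    "PTV" = {
      out["V_PTV (cm3)"] <- vol
      out["V_93%,PTV (%)"] <- 100 * volume_at_relative_dose(cdvh, 93, rx)
    },
    "CTV-T" = {
      out["V_CTV-T (cm3)"] <- vol
      out["V_95%,CTV-T (%)"] <- 100 * volume_at_relative_dose(cdvh, 95, rx)
    },
    "heart" = {
      out["V_heart (cm3)"] <- vol
      out["D_mean,heart (Gy)"] <- mean_dose(dvh)
      out["D_2%,heart (Gy)"] <- dose_at_volume(cdvh, 0.02)
      out["V_25Gy,heart (%)"] <- 100 * volume_at_dose(cdvh, 25)
    },
    "LAD" = {
      out["V_LAD (cm3)"] <- vol
      out["D_mean,LAD (Gy)"] <- mean_dose(dvh)
      out["D_2%,LAD (Gy)"] <- dose_at_volume(cdvh, 0.02)
      out["V_25Gy,LAD (%)"] <- 100 * volume_at_dose(cdvh, 25)
    },
    "lung" = {
      out["V_lung (cm3)"] <- vol
      out["D_mean,lung (Gy)"] <- mean_dose(dvh)
      out["V_20Gy,lung (%)"] <- 100 * volume_at_dose(cdvh, 20)
    })
  out
}

#' Extract all per-patient metric records from a plan pair
#'
#' Computes every dose/volume metric available from the supplied organs,
#' the maximum heart distance when scenes are present, and the NTCP
#' endpoints (cardiac mortality from the heart DVH, radiation pneumonitis
#' from the lung DVH, both in percent).
#'
#' @param pair A [patient_plan_pair()].
#' @param registry Endpoint registry, see [default_endpoint_registry()].
#' @return Data frame with columns `patient_id`, `metric`, `technique`,
#'   `value` (one row per available metric and technique).
#' @export
extract_metrics <- function(pair, registry = default_endpoint_registry()) {
  stopifnot(inherits(pair, "patient_plan_pair"))
  rows <- list()
  for (tech in c("FB", "EIG")) {
    plans <- if (tech == "FB") pair$fb else pair$eig
    vals <- c()
    for (plan in plans) vals <- c(vals, structure_metrics(plan))
    if (!is.null(pair$scenes) && !is.null(pair$scenes[[tech]]))
      vals["MHD (cm)"] <- max_heart_distance(pair$scenes[[tech]])
    if (!is.null(plans[["heart"]]))
      vals["NTCP cardiac mortality (%)"] <- 100 * ntcp_relative_seriality(
        plans[["heart"]]$dvh,
        lookup_endpoint("cardiac_mortality", pair$plan_type, registry))
    if (!is.null(plans[["lung"]]))
      vals["NTCP radiation pneumonitis (%)"] <- 100 * ntcp_relative_seriality(
        plans[["lung"]]$dvh,
        lookup_endpoint("radiation_pneumonitis", pair$plan_type, registry))
    vals <- vals[!is.na(vals)]
    if (length(vals))
      rows[[tech]] <- data.frame(patient_id = pair$patient_id,
                                 metric = names(vals), technique = tech,
                                 value = unname(vals),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the cohort comparison report
#'
#' For each metric and plan-type stratum: the FB and EIG medians with
#' ranges over patients and the two-sided paired Wilcoxon p-value, flagged
#' significant at `alpha` (default 0.01; no multiple-testing correction is
#' applied, each metric is tested at the fixed level). Patients missing a
#' metric under either technique are dropped from that metric's paired
#' test with a warning.
#'
#' @param cohort List of [patient_plan_pair()] objects.
#' @param registry Endpoint registry.
#' @param alpha Significance level (default 0.01).
#' @return A data frame of class `cohort_report`, one row per metric and
#'   plan type, with full-precision columns `median_fb`, `min_fb`,
#'   `max_fb`, `median_eig`, `min_eig`, `max_eig`, `p_value`,
#'   `significant`, `n_pairs`.
#' @export
build_cohort_report <- function(cohort, registry = default_endpoint_registry(),
                                alpha = 0.01) {
  stopifnot(length(cohort) >= 1L, alpha > 0, alpha < 1)
  recs <- do.call(rbind, lapply(cohort, extract_metrics, registry = registry))
  plan_types <- vapply(cohort, `[[`, character(1), "plan_type")
  pt_by_patient <- stats::setNames(plan_types,
                                   vapply(cohort, `[[`, character(1),
                                          "patient_id"))
  recs$plan_type <- pt_by_patient[recs$patient_id]
  out <- list()
  for (pt in unique(recs$plan_type)) {
    sub <- recs[recs$plan_type == pt, ]
    metrics <- intersect(organ_metric_names(), unique(sub$metric))
    for (met in metrics) {
      fb <- sub[sub$metric == met & sub$technique == "FB", ]
      eig <- sub[sub$metric == met & sub$technique == "EIG", ]
      ids <- intersect(fb$patient_id, eig$patient_id)
      dropped <- setdiff(union(fb$patient_id, eig$patient_id), ids)
      if (length(dropped))
        warning(sprintf("metric '%s' (%s): dropping patient(s) %s from the paired test",
                        met, pt, paste(dropped, collapse = ", ")))
      if (length(ids) == 0L) next
      xf <- fb$value[match(ids, fb$patient_id)]
      xe <- eig$value[match(ids, eig$patient_id)]
      sf <- summarize_metric(xf)
      se <- summarize_metric(xe)
      p <- if (length(ids) >= 5L)
        suppressWarnings(paired_wilcoxon(xf, xe)$p_value) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        plan_type = pt, metric = met,
        median_fb = sf[["median"]], min_fb = sf[["min"]], max_fb = sf[["max"]],
        median_eig = se[["median"]], min_eig = se[["min"]],
        max_eig = se[["max"]],
        p_value = p, significant = !is.na(p) && p < alpha,
        n_pairs = length(ids), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  attr(report, "alpha") <- alpha
  class(report) <- c("cohort_report", class(report))
  report
}

# table-style rounding: 2 decimals for NTCP rows, 1 decimal otherwise
report_round <- function(metric, x) {
  digits <- ifelse(grepl("^NTCP", metric), 2L, 1L)
  sprintf(paste0("%.", digits, "f"), x)
}

#' @export
print.cohort_report <- function(x, ...) {
  alpha <- attr(x, "alpha")
  for (pt in unique(x$plan_type)) {
    sub <- x[x$plan_type == pt, ]
    cat(sprintf("\n%s treatment (n = %d pairs; paired Wilcoxon, alpha = %g)\n",
                paste0(toupper(substring(pt, 1, 1)), substring(pt, 2)),
                max(sub$n_pairs), alpha))
    cells <- data.frame(
      Metric = sub$metric,
      FB = sprintf("%s [%s-%s]", report_round(sub$metric, sub$median_fb),
                   report_round(sub$metric, sub$min_fb),
                   report_round(sub$metric, sub$max_fb)),
      EIG = sprintf("%s [%s-%s]", report_round(sub$metric, sub$median_eig),
                    report_round(sub$metric, sub$min_eig),
                    report_round(sub$metric, sub$max_eig)),
      p = ifelse(is.na(sub$p_value), "-",
                 ifelse(sub$p_value < 0.001, "<0.001",
                        sprintf("%.3f", sub$p_value))),
      sig = ifelse(!is.na(sub$significant) & sub$significant, "*", ""))
    print(cells, row.names = FALSE, right = FALSE)
  }
  invisible(x)
}
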