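#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates paired free-breathing (FB) and enhanced
#' inspiration gating (EIG) treatment plans at the DVH level. Each organ's
#' cumulative DVH is a two-component curve: a low-dose exponential bath,
#' `(1 - f_hi) * exp(-D / lambda)`, plus a high-dose in-field shoulder,
#' `f_hi * logistic((D_hi - D) / w)` — the qualitative shape of planning
#' DVHs for organs partly inside tangential fields. The in-field volume
#' fraction `f_hi` is drawn log-normally per patient; gating multiplies it
#' by an organ-specific effect multiplier (< 1 for the heart and LAD,
#' which move out of the field during inspiration). FB and EIG share the
#' patient's latent draw, so the pairing structure is real; a small
#' per-technique log-normal jitter (`technique_sdlog`) controls how
#' tightly the pair is correlated (smaller = stronger pairing).
#'
#' Default calibration constants reproduce the typical cohort medians of a
#' 16 + 16 patient tangential/locoregional left-breast series (e.g. FB
#' heart V25Gy around 2.2% tangential, breathing amplitude median 7 mm,
#' maximum heart distance 1.3 cm FB vs 0.4 cm EIG); they are stochastic
#' calibration targets at n = 16, not exact claims, and every constant can
#' be overridden.
#'
#' @param n_patients Number of patients (>= 2; default 16).
#' @param plan_type `"tangential"` or `"locoregional"`.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param organs Organs to generate (default all five structures).
#' @param technique_sdlog Per-technique log-normal jitter (default 0.15).
#' @param effect_multipliers Optional named vector overriding the EIG
#'   in-field-fraction multipliers, e.g. `c(heart = 1, LAD = 1, lung = 1)`
#'   for a no-effect null cohort.
#' @param prescription_dose Prescription dose in Gy (default 50).
#' @param bin_width DVH bin width in Gy (default 0.05).
#' @param with_geometry Generate beam's-eye-view scenes for the MHD
#'   (default TRUE).
#' @param organ_params Optional named list overriding entries of
#'   [default_organ_params()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 16L, plan_type = "tangential",
                          seed = 1L,
                          organs = c("PTV", "CTV-T", "heart", "LAD", "lung"),
                          technique_sdlog = 0.15,
                          effect_multipliers = NULL,
                          prescription_dose = 50,
                          bin_width = 0.05,
                          with_geometry = TRUE,
                          organ_params = NULL) {
  plan_type <- match.arg(plan_type, c("tangential", "locoregional"))
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("n_patients must be >= 2")
  if (technique_sdlog < 0) stop("technique_sdlog must be >= 0")
  if (bin_width <= 0) stop("bin_width must be positive")
  organs <- match.arg(organs, c("PTV", "CTV-T", "heart", "LAD", "lung"),
                      several.ok = TRUE)
  params <- default_organ_params(plan_type)
  if (!is.null(organ_params))
    for (org in names(organ_params))
      params[[org]] <- utils::modifyList(params[[org]], organ_params[[org]])
  if (!is.null(effect_multipliers)) {
    if (any(effect_multipliers <= 0) || any(effect_multipliers > 1))
      stop("effect multipliers must lie in (0, 1]")
    for (org in names(effect_multipliers))
      params[[org]]$eig_mult <- unname(effect_multipliers[[org]])
  }
  structure(list(n_patients = as.integer(n_patients), plan_type = plan_type,
                 seed = as.integer(seed), organs = organs,
                 technique_sdlog = technique_sdlog,
                 prescription_dose = prescription_dose,
                 bin_width = bin_width, with_geometry = with_geometry,
                 params = params),
            class = "cohort_config")
}

#' Default generative parameters per organ
#'
#' Location/scale constants of the DVH shape model per organ and plan
#' type: `f_hi_median` and `f_hi_sdlog` (log-normal in-field volume
#' fraction), `lambda` and `lambda_sdlog` (low-dose bath scale, Gy),
#' `d_hi` and `shoulder_w` (shoulder center and width, Gy), `eig_mult`
#' (EIG multiplier on `f_hi`), and per-technique structure volume medians
#' (`vol_fb`, `vol_eig`, cm^3) with `vol_sdlog`. Targets use `sigma`
#' (Gaussian fall-off width of the cumulative curve around the
#' prescription, Gy) instead of the two-component shape. The amplitude and
#' MHD entries parameterize the breathing amplitude (mm) and the scene
#' penetration depths (cm).
#'
#' @param plan_type `"tangential"` or `"locoregional"`.
#' @return Named list of per-organ parameter lists.
#' @export
default_organ_params <- function(plan_type = "tangential") {
  tang <- plan_type == "tangential"
  list(
    PTV = list(sigma = if (tang) 1.57 else 1.67, sigma_sdlog = 0.06,
               vol_fb = if (tang) 891 else 1136,
               vol_eig = if (tang) 888 else 1136, vol_sdlog = 0.55),
    `CTV-T` = list(sigma = 0.55, sigma_sdlog = 0.20,
                   vol_fb = 40, vol_eig = if (tang) 43 else 40,
                   vol_sdlog = 0.60),
    heart = list(f_hi_median = if (tang) 0.022 else 0.033, f_hi_sdlog = 0.60,
                 lambda = if (tang) 1.65 else 1.75, lambda_sdlog = 0.12,
                 d_hi = 40, d_hi_sdlog = 0.12, shoulder_w = 1.5,
                 eig_mult = 0.10,
                 vol_fb = if (tang) 593 else 613,
                 vol_eig = if (tang) 593 else 613, vol_sdlog = 0.12),
    LAD = list(f_hi_median = if (tang) 0.402 else 0.514, f_hi_sdlog = 0.50,
               lambda = if (tang) 2.5 else 3.7, lambda_sdlog = 0.15,
               d_hi = if (tang) 42 else 46, d_hi_sdlog = 0.10,
               shoulder_w = 1.5, eig_mult = 0.10,
               vol_fb = 1.8, vol_eig = 1.8, vol_sdlog = 0.25),
    lung = list(f_hi_median = if (tang) 0.091 else 0.27, f_hi_sdlog = 0.40,
                lambda = if (tang) 1.4 else 2.5, lambda_sdlog = 0.15,
                d_hi = 45, d_hi_sdlog = 0.05, shoulder_w = 2.0,
                eig_mult = if (tang) 1.0 else 0.8,
                vol_fb = if (tang) 1132 else 1047,
                vol_eig = if (tang) 1765 else 1683, vol_sdlog = 0.15),
    amplitude = list(median_mm = if (tang) 7.0 else 6.9, sdlog = 0.22),
    mhd = list(fb_median = if (tang) 1.3 else 1.7, fb_sdlog = 0.32,
               shift_median = if (tang) 0.9 else 1.1, shift_sdlog = 0.30))
}

#' Draw one patient's latent variables
#'
#' All patient-to-patient variability lives in these standard-normal
#' latents; both techniques are generated from the same draw, which is
#' what makes the cohort genuinely paired. Draw order is fixed (amplitude,
#' MHD, then per organ in the configured order: `z_f`, `z_lambda`,
#' `z_vol`, `z_dhi`, `eps_f` FB/EIG, `eps_vol` FB/EIG) so that seeds
#' remain stable across versions.
#'
#' @param config A [cohort_config()].
#' @return Named list of latent draws (consumes the R RNG stream).
#' @export
draw_patient_latents <- function(config) {
  draw <- list(z_amp = stats::rnorm(1), z_mhd_fb = stats::rnorm(1),
               z_mhd_shift = stats::rnorm(1))
  for (org in config$organs) {
    draw[[org]] <- list(z_f = stats::rnorm(1), z_lambda = stats::rnorm(1),
                        z_vol = stats::rnorm(1), z_dhi = stats::rnorm(1),
                        eps_f = stats::setNames(stats::rnorm(2), c("FB", "EIG")),
                        eps_vol = stats::setNames(stats::rnorm(2), c("FB", "EIG")))
  }
  draw
}

# In-field volume fraction for one technique; deterministic in the draw.
# When the organ's multiplier is dose-reducing (< 1), the EIG fraction is
# clamped at the FB value so gating never increases the irradiated volume
# of that organ within a patient.
oar_f_hi <- function(p, technique, lat, tech_sdlog) {
  f_of <- function(tech, mult)
    min(0.95, p$f_hi_median * mult *
          exp(p$f_hi_sdlog * lat$z_f + tech_sdlog * lat$eps_f[[tech]]))
  f <- f_of(technique, if (technique == "EIG") p$eig_mult else 1)
  if (technique == "EIG" && p$eig_mult < 1) f <- min(f, f_of("FB", 1))
  f
}

#' Generate one organ-at-risk differential DVH
#'
#' Builds the two-component cumulative curve for the requested organ and
#' technique from the patient's latent draw, differences it onto the
#' configured uniform dose grid (0 Gy up to past the shoulder) and
#' normalizes. Identical draws with an effect multiplier of 1 give
#' identical FB and EIG DVHs.
#'
#' @param organ `"heart"`, `"LAD"` or `"lung"`.
#' @param technique `"FB"` or `"EIG"`.
#' @param draw A [draw_patient_latents()] result.
#' @param config A [cohort_config()].
#' @return A [dvh_differential()] object with the drawn structure volume
#'   attached.
#' @export
generate_oar_dvh <- function(organ, technique, draw, config) {
  organ <- match.arg(organ, c("heart", "LAD", "lung"))
  technique <- match.arg(technique, c("FB", "EIG"))
  p <- config$params[[organ]]
  lat <- draw[[organ]]
  if (is.null(lat)) stop(sprintf("draw has no latents for organ '%s'", organ))
  f_hi <- oar_f_hi(p, technique, lat, config$technique_sdlog)
  lambda <- p$lambda * exp(p$lambda_sdlog * lat$z_lambda)
  # the in-field shoulder dose varies per patient (how deep the structure
  # sits in the field); FB and EIG share the draw
  d_hi <- min(p$d_hi * exp(p$d_hi_sdlog * lat$z_dhi),
              1.05 * config$prescription_dose)
  vol_med <- if (technique == "FB") p$vol_fb else p$vol_eig
  vol <- vol_med * exp(p$vol_sdlog * lat$z_vol +
                         0.02 * lat$eps_vol[[technique]])
  w <- config$bin_width
  d_max <- d_hi + 10 * p$shoulder_w
  edges <- seq(0, d_max, by = w)
  v <- (1 - f_hi) * exp(-edges / lambda) +
    f_hi * stats::plogis((d_hi - edges) / p$shoulder_w)
  v <- v / v[1]
  dv <- -diff(v)
  dv[length(dv)] <- dv[length(dv)] + v[length(v)]  # residual tail mass
  dvh_differential(edges[-length(edges)] + w / 2, dv, bin_width = w,
                   total_volume = vol, structure_label = organ)
}

#' Generate one target (PTV or CTV-T) differential DVH
#'
#' The target cumulative DVH is a Gaussian fall-off around the
#' prescription dose with a patient-drawn width (narrow widths give full
#' coverage); the differential DVH is then rescaled along the dose axis so
#' that the mean dose equals the prescription exactly, mirroring plan
#' normalization to the PTV mean dose.
#'
#' @param organ `"PTV"` or `"CTV-T"`.
#' @inheritParams generate_oar_dvh
#' @return A [dvh_differential()] object.
#' @export
generate_target_dvh <- function(organ, technique, draw, config) {
  organ <- match.arg(organ, c("PTV", "CTV-T"))
  technique <- match.arg(technique, c("FB", "EIG"))
  p <- config$params[[organ]]
  lat <- draw[[organ]]
  if (is.null(lat)) stop(sprintf("draw has no latents for organ '%s'", organ))
  sigma <- p$sigma * exp(p$sigma_sdlog * lat$z_f +
                           0.03 * lat$eps_f[[technique]])
  vol_med <- if (technique == "FB") p$vol_fb else p$vol_eig
  vol <- vol_med * exp(p$vol_sdlog * lat$z_vol +
                         0.02 * lat$eps_vol[[technique]])
  rx <- config$prescription_dose
  w <- config$bin_width
  edges <- seq(0, rx + 10 * sigma, by = w)
  v <- stats::pnorm((rx - edges) / sigma)
  v <- v / v[1]
  dv <- -diff(v)
  dv[length(dv)] <- dv[length(dv)] + v[length(v)]
  centers <- edges[-length(edges)] + w / 2
  m <- sum(centers * dv) / sum(dv)
  scale <- rx / m                       # normalize mean dose to prescription
  dvh_differential(centers * scale, dv, bin_width = w * scale,
                   total_volume = vol, structure_label = organ)
}

# Regular polygon heart contour penetrating `depth` cm past a vertical
# posterior field edge through the origin (normal +x, into the field).
make_heart_scene <- function(depth, radius = 4, n_vertices = 24) {
  theta <- 2 * pi * (0:(n_vertices - 1)) / n_vertices
  center <- c(depth - radius, 0)
  poly <- cbind(center[1] + radius * cos(theta),
                center[2] + radius * sin(theta))
  bev_scene(poly, edge_point = c(0, 0), edge_normal = c(1, 0),
            field_bounds = c(-60, 60, -60, 60))
}

#' Generate a paired FB/EIG synthetic cohort
#'
#' Seeds the RNG from the config and generates `n_patients` paired plan
#' sets: per patient one latent draw, both techniques' DVHs for every
#' configured organ, the breathing amplitude, and (optionally) a
#' beam's-eye-view scene pair in which the EIG heart penetration is the FB
#' depth reduced by a drawn shift and floored at zero — patients whose
#' heart leaves the field entirely under gating get MHD = 0.
#'
#' @param config A [cohort_config()].
#' @return List of [patient_plan_pair()] objects of length `n_patients`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  amp <- config$params$amplitude
  mhd <- config$params$mhd
  lapply(seq_len(config$n_patients), function(i) {
    draw <- draw_patient_latents(config)
    amplitude <- amp$median_mm * exp(amp$sdlog * draw$z_amp)
    depth_fb <- mhd$fb_median * exp(mhd$fb_sdlog * draw$z_mhd_fb)
    shift <- mhd$shift_median * exp(mhd$shift_sdlog * draw$z_mhd_shift)
    depth_eig <- max(0, depth_fb - shift)
    plans <- function(tech) {
      out <- list()
      for (org in config$organs) {
        dvh <- if (org %in% c("PTV", "CTV-T"))
          generate_target_dvh(org, tech, draw, config)
        else
          generate_oar_dvh(org, tech, draw, config)
        out[[org]] <- structure_plan(org, tech, config$plan_type, dvh,
                                     config$prescription_dose)
      }
      out
    }
    scenes <- if (config$with_geometry)
      list(FB = make_heart_scene(depth_fb),
           EIG = if (depth_eig > 0) make_heart_scene(depth_eig) else
             make_heart_scene(-0.5))  # fully out of field -> MHD 0
    patient_plan_pair(sprintf("P%02d", i), config$plan_type,
                      fb = plans("FB"), eig = plans("EIG"),
                      scenes = scenes, amplitude_mm = amplitude)
  })
}
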