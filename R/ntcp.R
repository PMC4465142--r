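#' Endpoint parameter set for the relative seriality model
#'
#' The model needs three parameters per clinical endpoint: the relative
#' seriality factor `s` in (0, 1] describing tissue architecture (s near 1:
#' serial organ, a small hot subvolume drives the complication; s near 0:
#' parallel organ, the complication follows the whole-organ dose), the
#' maximum normalized slope `gamma` of the dose-response curve, and `D50`,
#' the uniform whole-organ dose giving 50% complication probability.
#'
#' @param endpoint Endpoint label, e.g. `"cardiac_mortality"`.
#' @param s Relative seriality factor in (0, 1].
#' @param gamma Maximum normalized dose-response slope (> 0).
#' @param d50 Dose in Gy giving 50% complication probability (> 0).
#' @param plan_scope `"any"`, `"tangential"` or `"locoregional"`: the plan
#'   type the parameter set was fitted for.
#' @param source_label Free-text provenance note.
#' @return An object of class `endpoint_params`.
#' @export
endpoint_params <- function(endpoint, s, gamma, d50, plan_scope = "any",
                            source_label = "") {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)
    stop("s must be a single value in (0, 1]")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be positive")
  if (!is.numeric(d50) || length(d50) != 1L || d50 <= 0)
    stop("d50 must be positive (Gy)")
  plan_scope <- match.arg(plan_scope, c("any", "tangential", "locoregional"))
  structure(list(endpoint = as.character(endpoint), plan_scope = plan_scope,
                 s = s, gamma = gamma, d50 = d50,
                 source_label = as.character(source_label)),
            class = "endpoint_params")
}

#' @export
print.endpoint_params <- function(x, ...) {
  cat(sprintf("NTCP endpoint '%s' (%s): s = %g, gamma = %g, D50 = %g Gy\n",
              x$endpoint, x$plan_scope, x$s, x$gamma, x$d50))
  invisible(x)
}

#' Default NTCP endpoint registry
#'
#' Published relative-seriality parameter sets for breast radiotherapy
#' organs at risk: excess cardiac mortality for the whole heart
#' (s = 1, gamma = 1.28, D50 = 52.3 Gy) and radiation pneumonitis for the
#' ipsilateral lung with plan-type-specific fits adapted to a type-b dose
#' algorithm (tangential: s = 0.012, gamma = 0.974, D50 = 27.52 Gy;
#' locoregional: s = 0.012, gamma = 0.966, D50 = 29.23 Gy). No parameter
#' set exists for the LAD coronary artery, which therefore gets dose
#' metrics only.
#'
#' @return A data frame with columns `endpoint`, `plan_scope`, `s`,
#'   `gamma`, `d50`, `source_label`; pass extra rows of the same shape to
#'   [lookup_endpoint()] to register custom endpoints.
#' @export
default_endpoint_registry <- function() {
  data.frame(
    endpoint = c("cardiac_mortality", "radiation_pneumonitis",
                 "radiation_pneumonitis"),
    plan_scope = c("any", "tangential", "locoregional"),
    s = c(1, 0.012, 0.012),
    gamma = c(1.28, 0.974, 0.966),
    d50 = c(52.3, 27.52, 29.23),
    source_label = c("whole heart, excess cardiac mortality",
                     "ipsilateral lung, tangential fields",
                     "ipsilateral lung, locoregional fields"),
    stringsAsFactors = FALSE)
}

#' Look up the parameter set for an endpoint and plan type
#'
#' Rows with `plan_scope = "any"` match either plan type; otherwise the
#' scope must equal the requested plan type.
#'
#' @param endpoint Endpoint name.
#' @param plan_type `"tangential"` or `"locoregional"`.
#' @param registry Registry data frame, see [default_endpoint_registry()].
#' @return An [endpoint_params()] object.
#' @export
lookup_endpoint <- function(endpoint, plan_type = "tangential",
                            registry = default_endpoint_registry()) {
  plan_type <- match.arg(plan_type, c("tangential", "locoregional"))
  hit <- registry$endpoint == endpoint &
    (registry$plan_scope == "any" | registry$plan_scope == plan_type)
  if (!any(hit))
    stop(sprintf("unknown endpoint '%s' for plan type '%s'; known endpoints: %s",
                 endpoint, plan_type,
                 paste(unique(registry$endpoint), collapse = ", ")))
  r <- registry[which(hit)[1], ]
  endpoint_params(r$endpoint, s = r$s, gamma = r$gamma, d50 = r$d50,
                  plan_scope = r$plan_scope, source_label = r$source_label)
}

#' Poisson dose-response probability
#'
#' Complication probability of a subvolume uniformly irradiated to `dose`:
#' `P(D) = 2^(-exp(e * gamma * (1 - D/D50)))`, where `e` is Euler's number
#' (the standard parameterization in which `gamma` is the maximum
#' normalized slope of the curve and `P(D50) = 1/2` exactly). Strictly
#' increasing in dose, with P(0) essentially zero and P -> 1 at high dose.
#'
#' @param dose Dose in Gy (vectorized, non-negative).
#' @param params An [endpoint_params()] object, or anything with `gamma`
#'   and `d50` fields.
#' @return Probability in (0, 1).
#' @export
poisson_response <- function(dose, params) {
  if (any(dose < 0)) stop("dose must be non-negative")
  2^(-exp(exp(1) * params$gamma * (1 - dose / params$d50)))
}

#' Relative seriality NTCP of a differential DVH
#'
#' The relative seriality model aggregates the per-bin Poisson response
#' over an inhomogeneous dose distribution:
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^(dV_i))^(1/s)`,
#' with `dV_i` the volume fraction of dose bin `i`. For a uniform dose the
#' expression collapses to `P(D)` for every `s`. The product is accumulated
#' in log space (`sum dV_i * log1p(-P_i^s)`) with the per-bin probabilities
#' clamped to `[1e-300, 1 - 1e-15]`: for small `s` the terms `P^s` approach
#' 1 and a naive product underflows.
#'
#' No fractionation (EQD2) correction is applied; parameter sets are used
#' at their native 2 Gy/fraction reference.
#'
#' @param ddvh A [dvh_differential()] object (normalized).
#' @param params An [endpoint_params()] object.
#' @return NTCP as a probability in `[0, 1]`.
#' @export
ntcp_relative_seriality <- function(ddvh, params) {
  stopifnot(inherits(ddvh, "dvh_diff"))
  s <- params$s
  if (is.null(s) || s <= 0) stop("relative seriality factor s must be > 0")
  p <- poisson_response(ddvh$bin_center, params)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  ps <- exp(s * log(p))
  if (any(ps >= 1)) {
    warning("P(D)^s reached 1; NTCP saturates at 1")
    return(1)
  }
  log_prod <- sum(ddvh$volume_fraction * log1p(-ps))
  inner <- -expm1(log_prod)            # 1 - prod(...)
  if (inner <= 0) return(0)
  min(1, exp(log(inner) / s))
}
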