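# Fitness-based inclusion rule and the Hedges' g moderator quantifying the
# strength of local adaptation of the derived population.

#' Hedges' g between two groups of fitness observations
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean(native) - mean(foreign)) / s_pooled` with pooled SD
#' (denominators `n - 1`) and small-sample correction
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)`. Positive g means the local (native)
#' population is fitter than the transplanted one.
#'
#' @param native,foreign Numeric vectors of fitness observations
#'   (`length >= 2` each), e.g. BinB vs AinB measured in environment B.
#' @return Hedges' g.
#' @export
hedges_g <- function(native, foreign) {
  n1 <- length(native); n2 <- length(foreign)
  if (n1 < 2 || n2 < 2)
    pv_stop("pv_insufficient_data_error",
            "Hedges' g needs at least 2 observations per group")
  if (anyNA(native) || anyNA(foreign))
    pv_stop("pv_validation_error", "fitness observations contain NA")
  sp <- sqrt(((n1 - 1) * stats::var(native) + (n2 - 1) * stats::var(foreign)) /
               (n1 + n2 - 2))
  if (sp <= 0)
    pv_stop("pv_degenerate_error", "zero pooled SD of fitness observations")
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * (mean(native) - mean(foreign)) / sp
}

#' Local adaptation check and moderator for one comparison
#'
#' A comparison demonstrates local adaptation when at least one fitness
#' measure is higher in at least one native-vs-transplant contrast: BinB vs
#' AinB (environment B) or AinA vs BinA (environment A), i.e. the contrast
#' has Hedges' g > 0. The g of the B-environment contrast (the derived
#' population's home) for the primary measure (metadata flag `is_primary`;
#' first listed measure otherwise) is exported as the `local_adaptation_g`
#' moderator.
#'
#' @param comp An [rt_comparison()] with a `fitness` data frame (columns
#'   `population`, `environment`, `measure_name`, optional `is_primary`,
#'   `value`).
#' @return List with `local_adaptation` (logical), `g` (the moderator),
#'   `primary_measure`, and `table` (per-measure g for both contrasts).
#' @export
check_local_adaptation <- function(comp) {
  stopifnot(inherits(comp, "rt_comparison"))
  fit <- comp$fitness
  if (is.null(fit) || !nrow(fit))
    pv_stop("pv_missing_data_error",
            "comparison %s has no fitness data", comp$comparison_id)
  grab <- function(measure, pop, env) {
    fit$value[fit$measure_name == measure & fit$population == pop &
                fit$environment == env]
  }
  measures <- unique(fit$measure_name)
  tab <- do.call(rbind, lapply(measures, function(m) {
    gB <- tryCatch(hedges_g(grab(m, "B", "B"), grab(m, "A", "B")),
                   plastvec_error = function(e) NA_real_)
    gA <- tryCatch(hedges_g(grab(m, "A", "A"), grab(m, "B", "A")),
                   plastvec_error = function(e) NA_real_)
    data.frame(measure_name = m, g_envB = gB, g_envA = gA,
               stringsAsFactors = FALSE)
  }))
  if (all(is.na(tab$g_envB)) && all(is.na(tab$g_envA)))
    pv_stop("pv_missing_data_error",
            "comparison %s: no fitness contrast computable", comp$comparison_id)
  primary <- if ("is_primary" %in% names(fit) && any(fit$is_primary %in%
                                                     c(TRUE, "TRUE", 1))) {
    fit$measure_name[fit$is_primary %in% c(TRUE, "TRUE", 1)][1]
  } else measures[1]
  list(
    local_adaptation = any(c(tab$g_envB, tab$g_envA) > 0, na.rm = TRUE),
    g = tab$g_envB[match(primary, tab$measure_name)],
    primary_measure = primary,
    table = tab
  )
}
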