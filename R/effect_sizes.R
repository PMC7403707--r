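# Monte Carlo sampling distributions for the geometry effect sizes.
#
# The sampling scheme is a parametric bootstrap of individuals: each
# replicate redraws every unit's n individuals from a multivariate normal
# at the unit's observed centroid and P-matrix, then recomputes the
# statistics on the replicate comparison. This respects each population's
# sample size and is valid for any n >= 3, including n - 1 < d. A Wishart
# variant (replicate P drawn directly from the Wishart, replicate mean from
# MVN(centroid, P/n)) is available as a config switch; the two are
# asymptotically equivalent.

#' Parametric bootstrap replicate of an experimental unit
#'
#' Draws `n` new individuals from `MVN(centroid(unit), P(unit))`.
#'
#' @param unit A (standardized) [rt_unit()] with `n >= 3`.
#' @param seed Optional integer seed for a self-contained, reproducible
#'   draw; when `NULL` the current RNG stream is used.
#' @return An [rt_unit()] of identical shape.
#' @export
resample_unit <- function(unit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- centroid(unit)
  P <- p_matrix(unit)
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    pv_stop("pv_numeric_error", "unit P-matrix is not positive semi-definite")
  x <- MASS::mvrnorm(unit$n, mu = mu, Sigma = (P + t(P)) / 2)
  if (unit$n == 1) x <- matrix(x, nrow = 1)
  rt_unit(x, unit$population, unit$environment, unit$study_id,
          unit$comparison_id)
}

# One joint replicate of the 4 units -> named numeric stats vector.
# mus/Ps/ns are precomputed per unit; mech selects bootstrap flavor.
mc_replicate_stats <- function(mus, Ps, ns, names, mechanism = "bootstrap") {
  cen <- list(); Prep <- NULL
  need_P <- any(!(names %in% CENTROID_ONLY_NAMES))
  if (need_P) Prep <- list()
  for (k in names(mus)) {
    if (mechanism == "bootstrap") {
      x <- MASS::mvrnorm(ns[[k]], mu = mus[[k]], Sigma = Ps[[k]])
      cen[[k]] <- colMeans(x)
      if (need_P) Prep[[k]] <- stats::cov(x)
    } else { # wishart: P ~ W_d(P/(n-1), n-1)/(n-1), mean ~ MVN(mu, P/n)
      n <- ns[[k]]
      W <- stats::rWishart(1, df = n - 1, Sigma = Ps[[k]] / (n - 1))[, , 1]
      cen[[k]] <- MASS::mvrnorm(1, mu = mus[[k]], Sigma = Ps[[k]] / n)
      if (need_P) Prep[[k]] <- W
    }
  }
  geometry_stats(cen, Prep, names = names)
}

#' Monte Carlo distributions of all requested effect sizes for a comparison
#'
#' Jointly resamples the four experimental units `n_reps` times and
#' recomputes each named statistic per replicate. The Monte Carlo mean is
#' the point estimate entering the meta-analysis (it matches the per-study
#' means displayed on circular effect-size plots); the plug-in estimate on
#' the observed data is stored alongside, and the Monte Carlo variance is
#' the effect's sampling variance.
#'
#' @param comp A standardized [rt_comparison()].
#' @param names Statistics to compute; default all of `EFFECT_NAMES`.
#' @param n_reps Number of Monte Carlo replicates (default 10000).
#' @param seed Integer seed; when `NULL`, derived per comparison is not
#'   possible, so the current RNG stream is used.
#' @param mechanism `"bootstrap"` (parametric bootstrap of individuals,
#'   default) or `"wishart"` (direct Wishart/MVN draws of P and the mean).
#' @param max_na_frac Maximal tolerated fraction of undefined replicates
#'   per statistic before an unstable-effect error is raised.
#' @return A list of `effect_size` objects (one per statistic): each has
#'   `comparison_id`, `name`, `point_estimate` (MC mean), `observed`
#'   (plug-in), `sampling_variance`, `mc_draws`, `n_reps`, `rng_seed`.
#' @export
mc_effect_sizes <- function(comp, names = EFFECT_NAMES, n_reps = 10000,
                            seed = NULL, mechanism = c("bootstrap", "wishart"),
                            max_na_frac = 0.1) {
  stopifnot(inherits(comp, "rt_comparison"), n_reps >= 2)
  mechanism <- match.arg(mechanism)
  names <- match.arg(names, EFFECT_NAMES, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  mus <- lapply(comp$units, centroid)
  Ps <- lapply(comp$units, function(u) {
    P <- p_matrix(u)
    (P + t(P)) / 2
  })
  ns <- lapply(comp$units, `[[`, "n")
  observed <- geometry_stats(mus, Ps, names = names)
  draws <- matrix(NA_real_, n_reps, length(names),
                  dimnames = list(NULL, names))
  for (r in seq_len(n_reps))
    draws[r, ] <- mc_replicate_stats(mus, Ps, ns, names, mechanism)
  out <- lapply(names, function(nm) {
    d <- draws[, nm]
    na_frac <- mean(is.na(d))
    if (is.na(observed[[nm]]))
      pv_stop("pv_unstable_effect_error",
              "effect %s of %s is undefined on the observed data (zero vector)",
              nm, comp$comparison_id)
    if (na_frac > max_na_frac)
      pv_stop("pv_unstable_effect_error",
              "effect %s of %s undefined in %.0f%% of replicates",
              nm, comp$comparison_id, 100 * na_frac)
    d <- d[!is.na(d)]
    structure(
      list(comparison_id = comp$comparison_id, study_id = comp$study_id,
           species = comp$species, name = nm,
           point_estimate = mean(d), observed = observed[[nm]],
           sampling_variance = stats::var(d), mc_draws = d,
           n_reps = n_reps, rng_seed = seed),
      class = "effect_size"
    )
  })
  stats::setNames(out, names)
}

#' Monte Carlo distribution of one named effect size
#'
#' Convenience wrapper around [mc_effect_sizes()] for a single statistic.
#'
#' @inheritParams mc_effect_sizes
#' @param name One of `EFFECT_NAMES`.
#' @return A single `effect_size` object.
#' @export
effect_size_distribution <- function(comp, name, n_reps = 10000, seed = NULL,
                                     mechanism = c("bootstrap", "wishart")) {
  name <- match.arg(name, EFFECT_NAMES)
  mc_effect_sizes(comp, names = name, n_reps = n_reps, seed = seed,
                  mechanism = match.arg(mechanism))[[name]]
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size %s: %s = %.4f (observed %.4f), var %.5f, %d reps>\n",
              x$comparison_id, x$name, x$point_estimate, x$observed,
              x$sampling_variance, x$n_reps))
  invisible(x)
}

#' Sampling covariance matrix with shared-unit correlation
#'
#' Effect sizes computed from overlapping experimental units are not
#' independent (the shared-control-group problem). The covariance between
#' two effects sharing at least one unit is modeled as
#' `r * sqrt(v_i * v_j)` with a fixed correlation `r` (default 0.5);
#' non-sharing pairs get 0 and the diagonal holds the Monte Carlo sampling
#' variances.
#'
#' @param effects List of `effect_size` objects (or a numeric vector of
#'   sampling variances).
#' @param unit_map List (same length/order) of character vectors naming the
#'   experimental units each effect used; two effects covary iff their unit
#'   sets intersect. Default: all effects from the same `comparison_id`
#'   share all four units.
#' @param r Assumed correlation for sharing pairs.
#' @return Symmetric PSD matrix with attribute `shared_r`. If the raw
#'   matrix is not PSD it is replaced by the nearest PSD matrix (eigenvalue
#'   clipping) with a warning.
#' @export
build_sampling_covariance <- function(effects, unit_map = NULL, r = 0.5) {
  if (is.list(effects) && all(vapply(effects, inherits, TRUE, "effect_size"))) {
    vars <- vapply(effects, `[[`, numeric(1), "sampling_variance")
    ids <- vapply(effects, function(e) paste(e$comparison_id, e$name, sep = ":"),
                  character(1))
    if (is.null(unit_map))
      unit_map <- lapply(effects, function(e)
        paste(e$comparison_id, UNIT_KEYS, sep = ":"))
  } else {
    vars <- as.numeric(effects)
    ids <- names(vars) %||% paste0("e", seq_along(vars))
    if (is.null(unit_map))
      unit_map <- lapply(seq_along(vars), function(i) character(0))
  }
  stopifnot(all(vars >= 0), length(unit_map) == length(vars))
  k <- length(vars)
  V <- diag(vars, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (length(intersect(unit_map[[i]], unit_map[[j]])))
        V[i, j] <- V[j, i] <- r * sqrt(vars[i] * vars[j])
    }
  }
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(ev$values, 1)) {
    warning("sampling covariance not PSD; clipped to nearest PSD matrix")
    V <- ev$vectors %*% diag(pmax(ev$values, 0), k) %*% t(ev$vectors)
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(ids, ids)
  attr(V, "shared_r") <- r
  V
}

#' Correlation of P-matrix shape ratios across paired environments with a
#' Monte Carlo confidence interval
#'
#' For pairs of P-matrices (e.g., each comparison's AinA and AinB), computes
#' the Pearson correlation of the eigenvalue ratios `lambda2/lambda1` and a
#' percentile confidence interval from joint parametric resampling: per
#' replicate, every matrix is re-estimated from `n` fresh MVN individuals
#' and the correlation recomputed.
#'
#' @param pairs List of 2-element lists/pairs of P-matrices; each matrix
#'   needs an `n` attribute (as from [p_matrix()]) or `n` defaults to 20.
#' @param n_reps Monte Carlo replicates for the CI.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return List with `estimate`, `ci` (percentile), `n_pairs`, `reps`.
#' @export
eigen_ratio_correlation <- function(pairs, n_reps = 1000, seed = NULL,
                                    conf = 0.95) {
  if (length(pairs) < 3)
    pv_stop("pv_insufficient_data_error",
            "need at least 3 P-matrix pairs, got %d", length(pairs))
  if (!is.null(seed)) set.seed(seed)
  ratio <- function(P) {
    ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev[2] / ev[1]
  }
  obs <- vapply(pairs, function(pr) c(ratio(pr[[1]]), ratio(pr[[2]])),
                numeric(2))
  est <- stats::cor(obs[1, ], obs[2, ])
  resample_ratio <- function(P) {
    n <- attr(P, "n") %||% 20L
    x <- MASS::mvrnorm(n, mu = rep(0, nrow(P)), Sigma = (P + t(P)) / 2)
    ratio(stats::cov(x))
  }
  reps <- vapply(seq_len(n_reps), function(r) {
    m <- vapply(pairs, function(pr)
      c(resample_ratio(pr[[1]]), resample_ratio(pr[[2]])), numeric(2))
    stats::cor(m[1, ], m[2, ])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_pairs = length(pairs), reps = reps)
}
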