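# Multilevel random-effects meta-analysis of the vector effect sizes.
#
# The model is y = X beta + Z u + e with u ~ N(0, tau2_study * I) over
# studies (or tau2_phylo * Phi over species, Phi a phylogenetic correlation
# matrix), an observation-level random effect e_obs ~ N(0, tau2_obs * I),
# and known sampling (co)variances V from the Monte Carlo simulations.
# Estimation is REML via metafor::rma.mv; candidate random structures are
# compared by AICc with the parameter count p = fixed effects + estimated
# variance components.

#' Assemble a meta-analytic dataset for one effect-size statistic
#'
#' @param effects List of `effect_size` objects (all with the same `name`),
#'   or a data frame with columns `yi`, `vi`, `study_id`, `species`,
#'   `comparison_id`.
#' @param V Optional sampling covariance matrix from
#'   [build_sampling_covariance()]; defaults to `diag(vi)`.
#' @param moderators Optional data frame (one row per effect) with columns
#'   among `n_traits`, `prop_morphology`, `local_adaptation_g`.
#' @param phylo Optional species-level correlation matrix (unit diagonal,
#'   PSD) from [phylo_correlation_matrix()].
#' @return An object of class `meta_dataset`.
#' @export
build_meta_dataset <- function(effects, V = NULL, moderators = NULL,
                               phylo = NULL) {
  if (is.data.frame(effects)) {
    dat <- effects
    stopifnot(all(c("yi", "vi", "study_id", "species") %in% names(dat)))
    if (is.null(dat$comparison_id))
      dat$comparison_id <- paste0("c", seq_len(nrow(dat)))
  } else {
    dat <- do.call(rbind, lapply(effects, function(e)
      data.frame(yi = e$point_estimate, vi = e$sampling_variance,
                 study_id = e$study_id, species = e$species,
                 comparison_id = e$comparison_id, name = e$name,
                 stringsAsFactors = FALSE)))
  }
  dat$obs_id <- paste0("obs", seq_len(nrow(dat)))
  if (is.null(V)) V <- diag(dat$vi, nrow(dat))
  stopifnot(nrow(V) == nrow(dat))
  if (!is.null(moderators)) {
    stopifnot(nrow(moderators) == nrow(dat))
    dat <- cbind(dat, moderators[setdiff(names(moderators), names(dat))])
  }
  if (!is.null(phylo)) {
    if (is.null(dimnames(phylo)) ||
        !all(unique(dat$species) %in% rownames(phylo)))
      pv_stop("pv_lookup_error",
              "phylo matrix lacks entries for some species in the data")
    stopifnot(max(abs(diag(phylo) - 1)) < 1e-8)
  }
  structure(list(data = dat, V = V, phylo = phylo), class = "meta_dataset")
}

#' Phylogenetic correlation matrix from a dated ultrametric tree
#'
#' For an ultrametric tree, the correlation between two species is the
#' shared root-to-MRCA branch length divided by the total tree depth
#' (diagonal 1). The tree must be binary (no polytomies) and ultrametric to
#' tolerance; it is pruned to the requested species.
#'
#' @param tree An `ape::phylo` object or path to a Newick file.
#' @param species Character vector of species to retain (must all be tips).
#' @param tol Ultrametricity tolerance (relative, on root-to-tip depths).
#' @return Correlation matrix in `species` order.
#' @export
phylo_correlation_matrix <- function(tree, species, tol = 1e-6) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    pv_stop("pv_lookup_error", "species missing from tree: %s",
            paste(missing, collapse = ", "))
  if (!ape::is.ultrametric(tree, tol = tol, option = 2))
    pv_stop("pv_validation_error", "tree is not ultrametric (tol %g)", tol)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    pv_stop("pv_validation_error", "tree must be rooted with no polytomies")
  pruned <- ape::keep.tip(tree, species)
  C <- ape::vcv(pruned, corr = TRUE)
  C <- C[species, species, drop = FALSE]
  (C + t(C)) / 2
}

#' Fit a multilevel random-effects meta-analytic model
#'
#' Fits the effect sizes with known sampling covariance `V`, a study-level
#' random effect (or a phylogenetic species-level random effect), and an
#' observation-level random effect, by REML. Optional moderators enter as
#' main effects only; `n_traits` and `prop_morphology` are z-scored before
#' fitting so slopes are per-SD, and predicted means at moderator mean and
#' mean +/- 1 SD are returned for each standardized moderator.
#'
#' @param data A `meta_dataset` from [build_meta_dataset()].
#' @param random `"study"` or `"phylo"` (requires `data$phylo`).
#' @param moderators Character vector of moderator column names (subset of
#'   `n_traits`, `prop_morphology`, `local_adaptation_g`), or `NULL` for an
#'   intercept-only model.
#' @param tau2_fixed Optional numeric length-2 vector fixing the
#'   (study/phylo, observation) variance components; `NA` entries are
#'   estimated (the default estimates both).
#' @return An object of class `plast_meta` with components `mu`, `ci`,
#'   `tau2_study`, `tau2_obs`, `betas`, `loglik_reml`, `aicc`, `k`, `p`,
#'   `predictions` (for moderator models) and the underlying metafor `fit`.
#' @export
fit_random_effects <- function(data, random = c("study", "phylo"),
                               moderators = NULL,
                               tau2_fixed = c(NA_real_, NA_real_)) {
  stopifnot(inherits(data, "meta_dataset"))
  random <- match.arg(random)
  dat <- data$data
  k <- nrow(dat)
  if (k < 3)
    pv_stop("pv_insufficient_data_error", "need k >= 3 effects, got %d", k)
  if (random == "phylo" && is.null(data$phylo))
    pv_stop("pv_validation_error", "no phylogenetic correlation matrix supplied")

  scaled <- list()
  mods_formula <- NULL
  if (!is.null(moderators)) {
    for (m in moderators) {
      if (!m %in% names(dat))
        pv_stop("pv_validation_error", "moderator %s absent from data", m)
      if (m %in% c("n_traits", "prop_morphology")) {
        mu <- mean(dat[[m]]); sdv <- stats::sd(dat[[m]])
        if (sdv == 0)
          pv_stop("pv_rank_deficiency_error", "moderator %s is constant", m)
        dat[[paste0(m, "_z")]] <- (dat[[m]] - mu) / sdv
        scaled[[m]] <- c(mean = mu, sd = sdv)
      }
    }
    terms <- ifelse(moderators %in% names(scaled),
                    paste0(moderators, "_z"), moderators)
    X <- stats::model.matrix(stats::reformulate(terms), dat)
    if (qr(X)$rank < ncol(X))
      pv_stop("pv_rank_deficiency_error", "collinear moderators")
    mods_formula <- stats::reformulate(terms)
  }

  rand <- if (random == "study") {
    list(~ 1 | study_id, ~ 1 | obs_id)
  } else {
    list(~ 1 | species, ~ 1 | obs_id)
  }
  Rlist <- if (random == "phylo") list(species = data$phylo) else NULL

  args <- list(
    yi = dat$yi, V = data$V, data = dat, random = rand,
    sigma2 = tau2_fixed, method = "REML", test = "z", sparse = FALSE,
    control = list(optimizer = "nlminb", iter.max = 1000, rel.tol = 1e-10)
  )
  if (!is.null(mods_formula)) args$mods <- mods_formula
  if (!is.null(Rlist)) {
    args$R <- Rlist
    args$Rscale <- "none"
  }
  fit <- tryCatch(
    do.call(metafor::rma.mv, args),
    error = function(e) {
      # documented restart: switch optimizer before giving up
      args$control <- list(optimizer = "optim", optmethod = "Nelder-Mead")
      tryCatch(
        do.call(metafor::rma.mv, args),
        error = function(e2)
          pv_stop("pv_convergence_error",
                  "REML fit failed to converge: %s", conditionMessage(e2))
      )
    }
  )

  p_fixed <- length(fit$beta)
  p_var <- sum(is.na(tau2_fixed))
  p <- p_fixed + p_var
  ll <- as.numeric(stats::logLik(fit))
  betas <- data.frame(
    term = rownames(fit$beta), estimate = as.numeric(fit$beta),
    se = fit$se, ci_low = fit$ci.lb, ci_high = fit$ci.ub,
    stringsAsFactors = FALSE
  )

  predictions <- NULL
  if (!is.null(moderators) && length(scaled)) {
    base <- colMeans(stats::model.matrix(mods_formula, dat))[-1]
    predictions <- do.call(rbind, lapply(names(scaled), function(m) {
      zcol <- paste0(m, "_z")
      at_z <- c(-1, 0, 1)
      newmods <- matrix(rep(base, each = 3), 3,
                        dimnames = list(NULL, names(base)))
      newmods[, zcol] <- at_z
      pr <- stats::predict(fit, newmods = newmods)
      data.frame(moderator = m, at = c("mean-1sd", "mean", "mean+1sd"),
                 value = scaled[[m]]["mean"] + at_z * scaled[[m]]["sd"],
                 predicted = pr$pred, ci_low = pr$ci.lb, ci_high = pr$ci.ub,
                 stringsAsFactors = FALSE)
    }))
    rownames(predictions) <- NULL
  }

  out <- structure(
    list(
      mu = as.numeric(fit$beta[1]),
      ci = c(fit$ci.lb[1], fit$ci.ub[1]),
      tau2_study = fit$sigma2[1], tau2_obs = fit$sigma2[2],
      betas = betas, loglik_reml = ll,
      k = k, p = p, p_fixed = p_fixed,
      random = random, moderators = moderators, scaled = scaled,
      predictions = predictions, fit = fit
    ),
    class = "plast_meta"
  )
  out$aicc <- aicc(out)
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2p + 2p(p+1) / (k - p - 1)` with `p` counted as
#' fixed effects plus estimated variance components. Returns `Inf` with a
#' warning when `k <= p + 1`.
#'
#' @param fit A `plast_meta` object, or a list with elements `loglik_reml`,
#'   `p`, `k`.
#' @export
aicc <- function(fit) {
  ll <- fit$loglik_reml; p <- fit$p; k <- fit$k
  stopifnot(is.numeric(ll), is.numeric(p), is.numeric(k))
  if (k <= p + 1) {
    warning(sprintf("AICc undefined for k = %d, p = %d (k <= p + 1)", k, p))
    return(Inf)
  }
  -2 * ll + 2 * p + 2 * p * (p + 1) / (k - p - 1)
}

#' Compare study-level and phylogenetic random-effect structures
#'
#' Fits both structures on identical data and ranks them by AICc. A tie
#' within 2 AICc units selects the study structure (the conventional
#' meta-analytic default).
#'
#' @inheritParams fit_random_effects
#' @return List with `table` (structure, aicc, delta), `selected`, and the
#'   two fits.
#' @export
compare_random_structures <- function(data, moderators = NULL) {
  if (is.null(data$phylo))
    pv_stop("pv_validation_error",
            "phylogenetic correlation matrix required for comparison")
  fits <- list(
    study = fit_random_effects(data, "study", moderators),
    phylo = fit_random_effects(data, "phylo", moderators)
  )
  tab <- data.frame(
    structure = names(fits),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE
  )
  tab$delta <- tab$aicc - min(tab$aicc)
  selected <- if (tab$aicc[tab$structure == "study"] -
                  tab$aicc[tab$structure == "phylo"] <= 2) "study" else "phylo"
  list(table = tab[order(tab$aicc), ], selected = selected, fits = fits)
}

#' @export
print.plast_meta <- function(x, digits = 4, ...) {
  cat(sprintf("Multilevel meta-analytic model (REML, %s random effect)\n",
              x$random))
  cat(sprintf("k = %d effects; tau2_%s = %.4f, tau2_obs = %.4f\n",
              x$k, x$random, x$tau2_study, x$tau2_obs))
  if (is.null(x$moderators)) {
    cat(sprintf("Pooled mean: %.*f  [95%% CI %.*f, %.*f]\n",
                digits, x$mu, digits, x$ci[1], digits, x$ci[2]))
  } else {
    cat("Fixed effects:\n")
    print(x$betas, digits = digits, row.names = FALSE)
  }
  cat(sprintf("logLik(REML) = %.4f, p = %d, AICc = %.4f\n",
              x$loglik_reml, x$p, x$aicc))
  invisible(x)
}

#' @export
summary.plast_meta <- function(object, ...) {
  structure(list(fit = object), class = "summary.plast_meta")
}

#' @export
print.summary.plast_meta <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$predictions)) {
    cat("\nPredicted means at moderator mean and +/- 1 SD:\n")
    print(x$fit$predictions, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.plast_meta <- function(object, ...) {
  stats::setNames(object$betas$estimate, object$betas$term)
}

#' Predicted pooled means from a fitted meta-analytic model
#'
#' For intercept-only models, returns the pooled mean with its CI. For
#' moderator models, returns predictions at the moderator values stored at
#' fit time (mean and +/- 1 SD for standardized moderators) or at
#' user-specified `newmods` (on the original moderator scale).
#'
#' @param object A `plast_meta` fit.
#' @param newmods Optional data frame of moderator values.
#' @param ... Unused.
#' @export
predict.plast_meta <- function(object, newmods = NULL, ...) {
  if (is.null(object$moderators)) {
    return(data.frame(predicted = object$mu, ci_low = object$ci[1],
                      ci_high = object$ci[2]))
  }
  if (is.null(newmods)) return(object$predictions)
  X <- newmods
  for (m in names(object$scaled))
    X[[paste0(m, "_z")]] <- (X[[m]] - object$scaled[[m]]["mean"]) /
      object$scaled[[m]]["sd"]
  terms <- rownames(object$fit$beta)[-1]
  mm <- as.matrix(X[terms])
  pr <- stats::predict(object$fit, newmods = mm)
  data.frame(predicted = pr$pred, ci_low = pr$ci.lb, ci_high = pr$ci.ub)
}
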