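# End-to-end orchestration: read -> standardize -> geometry -> Monte Carlo
# effect sizes -> local-adaptation moderator -> sampling covariance ->
# multilevel meta-analytic fits, plus the ancestral-order sensitivity
# analysis. Per-comparison failures are logged and skipped; dataset-level
# failures abort.

#' Build a pipeline configuration
#'
#' @param study,traits,fitness,tree Input file paths (`fitness` and `tree`
#'   optional; without a tree the random-structure comparison is skipped).
#' @param output_dir Directory for the result bundle.
#' @param master_seed Master RNG seed; per-comparison seeds are derived
#'   from it deterministically, so identical configurations reproduce
#'   identical outputs.
#' @param n_reps Monte Carlo replicates per comparison (values below 1000
#'   trigger a warning; sampling variances get noisy).
#' @param shared_r Assumed correlation between effects sharing units.
#' @param random_structure `"study"`, `"phylo"`, or `"compare"` (fit both,
#'   select by AICc).
#' @param effect_names Statistics to analyze.
#' @param moderators Moderator columns for meta-regression models, or
#'   `NULL` to skip them.
#' @param mechanism Monte Carlo mechanism, see [mc_effect_sizes()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study, traits, fitness = NULL, tree = NULL,
                            output_dir = tempfile("plastvec_run_"),
                            master_seed = 1L, n_reps = 10000,
                            shared_r = 0.5,
                            random_structure = c("study", "phylo", "compare"),
                            effect_names = EFFECT_NAMES,
                            moderators = c("n_traits", "prop_morphology",
                                           "local_adaptation_g"),
                            mechanism = "bootstrap") {
  for (p in c(study, traits, fitness, tree))
    if (!file.exists(p)) pv_stop("pv_config_error", "input not found: %s", p)
  if (n_reps < 1000)
    warning("n_reps < 1000: Monte Carlo sampling variances will be noisy")
  structure(
    list(study = study, traits = traits, fitness = fitness, tree = tree,
         output_dir = output_dir, master_seed = as.integer(master_seed),
         n_reps = n_reps, shared_r = shared_r,
         random_structure = match.arg(random_structure),
         effect_names = match.arg(effect_names, EFFECT_NAMES,
                                  several.ok = TRUE),
         moderators = moderators, mechanism = mechanism),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Fields mirror the arguments of [pipeline_config()]; relative input paths
#' are resolved against the config file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param ... Overrides passed on to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("study", "traits", "fitness", "tree"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

# MC effect sizes for one comparison with a seed derived from the master
# seed, the comparison id, and its orientation (baseline/flipped).
comparison_effects <- function(comp, config, flipped = FALSE) {
  seed <- derive_seed(config$master_seed,
                      paste0(comp$comparison_id, if (flipped) ":flipped"))
  mc_effect_sizes(standardize_traits(comp), names = config$effect_names,
                  n_reps = config$n_reps, seed = seed,
                  mechanism = config$mechanism)
}

pipeline_moderators <- function(comps) {
  do.call(rbind, lapply(comps, function(comp) {
    g <- tryCatch(check_local_adaptation(comp),
                  plastvec_error = function(e) list(g = NA_real_,
                                                    local_adaptation = NA))
    data.frame(
      comparison_id = comp$comparison_id,
      n_traits = nrow(comp$traits),
      prop_morphology = mean(comp$traits$trait_type == "morphology"),
      local_adaptation_g = g$g,
      local_adaptation = g$local_adaptation,
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the input files of `config` and writes the
#' result bundle to `config$output_dir`: `effects.csv` (one row per
#' comparison x statistic), `densities/<effect>.csv` (Monte Carlo draws),
#' `meta_summary.csv` (one row per fitted model), `geometry.csv`, and
#' `manifest.json` (seeds, configuration, package version). Comparisons
#' failing a stage are dropped with a warning naming the stage and
#' comparison; an empty validated dataset is a dataset-level error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `comparisons`, `geometry`, `effects`,
#'   `moderators`, `meta_fits`, `structure_comparison`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  comps <- read_study_table(config$study, config$traits, config$fitness)
  if (!length(comps))
    pv_stop("pv_dataset_error", "no valid comparisons in input")
  message(sprintf("run_pipeline: %d comparisons read", length(comps)))

  ok <- list(); effects <- list(); geoms <- list()
  for (comp in comps) {
    res <- tryCatch({
      std <- standardize_traits(comp)
      list(geom = comparison_geometry(std),
           eff = comparison_effects(comp, config))
    }, plastvec_error = function(e) {
      warning(sprintf("comparison %s skipped (%s): %s", comp$comparison_id,
                      class(e)[1], conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      ok[[comp$comparison_id]] <- comp
      geoms[[comp$comparison_id]] <- res$geom
      effects[[comp$comparison_id]] <- res$eff
    }
  }
  if (!length(ok))
    pv_stop("pv_dataset_error", "no comparison survived the analysis stages")

  moderators <- pipeline_moderators(ok)
  phylo <- NULL; tree <- NULL
  if (!is.null(config$tree)) {
    tree <- ape::read.tree(config$tree)
    species <- unique(vapply(ok, `[[`, "", "species"))
    phylo <- phylo_correlation_matrix(tree, species)
  }

  meta_fits <- list(); structure_comparison <- NULL
  for (nm in config$effect_names) {
    eff_nm <- lapply(ok, function(comp) effects[[comp$comparison_id]][[nm]])
    V <- build_sampling_covariance(eff_nm, r = config$shared_r)
    ds <- build_meta_dataset(eff_nm, V = V,
                             moderators = moderators[
                               setdiff(names(moderators),
                                       c("comparison_id", "local_adaptation"))],
                             phylo = phylo)
    structure <- config$random_structure
    if (structure == "compare") {
      cmpres <- compare_random_structures(ds)
      if (is.null(structure_comparison)) structure_comparison <- list()
      structure_comparison[[nm]] <- cmpres
      meta_fits[[nm]] <- list(overall = cmpres$fits[[cmpres$selected]])
    } else {
      meta_fits[[nm]] <- list(overall = fit_random_effects(ds, structure))
    }
    if (!is.null(config$moderators)) {
      usable <- config$moderators[vapply(config$moderators, function(m)
        !anyNA(ds$data[[m]]) && stats::sd(ds$data[[m]]) > 0, logical(1))]
      if (length(usable) && nrow(ds$data) >= length(usable) + 4) {
        meta_fits[[nm]]$moderated <- tryCatch(
          fit_random_effects(ds, meta_fits[[nm]]$overall$random, usable),
          plastvec_error = function(e) NULL)
      }
    }
  }

  files <- write_result_bundle(config, ok, geoms, effects, moderators,
                               meta_fits, structure_comparison)
  invisible(list(comparisons = ok, geometry = geoms, effects = effects,
                 moderators = moderators, meta_fits = meta_fits,
                 structure_comparison = structure_comparison, files = files))
}

effects_table <- function(effects) {
  do.call(rbind, lapply(effects, function(effs) {
    do.call(rbind, lapply(effs, function(e)
      data.frame(comparison_id = e$comparison_id, study_id = e$study_id,
                 species = e$species, name = e$name,
                 point_estimate = e$point_estimate, observed = e$observed,
                 sampling_variance = e$sampling_variance,
                 n_reps = e$n_reps, stringsAsFactors = FALSE)))
  }))
}

write_result_bundle <- function(config, comps, geoms, effects, moderators,
                                meta_fits, structure_comparison) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "densities"), showWarnings = FALSE)
  files <- list(effects = file.path(out, "effects.csv"),
                geometry = file.path(out, "geometry.csv"),
                moderators = file.path(out, "moderators.csv"),
                meta = file.path(out, "meta_summary.csv"),
                manifest = file.path(out, "manifest.json"))
  et <- effects_table(effects)
  rownames(et) <- NULL
  utils::write.csv(et, files$effects, row.names = FALSE)
  gt <- geometry_table(geoms)
  rownames(gt) <- NULL
  utils::write.csv(gt, files$geometry, row.names = FALSE)
  utils::write.csv(moderators, files$moderators, row.names = FALSE)
  for (cid in names(effects)) {
    draws <- do.call(cbind, lapply(effects[[cid]], function(e) {
      v <- rep(NA_real_, e$n_reps); v[seq_along(e$mc_draws)] <- e$mc_draws; v
    }))
    utils::write.csv(as.data.frame(draws),
                     file.path(out, "densities", paste0(cid, ".csv")),
                     row.names = FALSE)
  }
  meta_rows <- list()
  for (nm in names(meta_fits)) for (kind in names(meta_fits[[nm]])) {
    f <- meta_fits[[nm]][[kind]]
    if (is.null(f)) next
    meta_rows[[paste(nm, kind)]] <- data.frame(
      effect = nm, model = kind, random = f$random, k = f$k,
      estimate = f$mu, ci_low = f$ci[1], ci_high = f$ci[2],
      tau2_study = f$tau2_study, tau2_obs = f$tau2_obs,
      loglik_reml = f$loglik_reml, p = f$p, aicc = f$aicc,
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(do.call(rbind, meta_rows), files$meta, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plastvec")),
    master_seed = config$master_seed, n_reps = config$n_reps,
    shared_r = config$shared_r, mechanism = config$mechanism,
    random_structure = config$random_structure,
    effect_names = config$effect_names,
    inputs = list(study = config$study, traits = config$traits,
                  fitness = config$fitness, tree = config$tree),
    selected_structures = if (!is.null(structure_comparison))
      lapply(structure_comparison, `[[`, "selected") else NULL
  )
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  files
}

#' Flip the ancestral-order assignment of a comparison
#'
#' Relabels population/environment A as B and vice versa (AinA becomes
#' BinB, AinB becomes BinA), including the fitness table. Under a flip the
#' two plasticity vectors exchange roles and the total-difference vector
#' reverses sign, so the plasticity-plasticity angle is invariant while
#' directional statistics can change.
#'
#' @param comp An [rt_comparison()].
#' @return The flipped comparison.
#' @export
flip_comparison <- function(comp) {
  swap <- function(x) c(A = "B", B = "A")[[x]]
  units <- lapply(comp$units, function(u) {
    u$population <- swap(u$population)
    u$environment <- swap(u$environment)
    u
  })
  names(units) <- vapply(units, function(u)
    unit_key(u$population, u$environment), character(1))
  comp$units <- units[UNIT_KEYS]
  if (!is.null(comp$fitness)) {
    comp$fitness$population <- vapply(comp$fitness$population, swap, "")
    comp$fitness$environment <- vapply(comp$fitness$environment, swap, "")
  }
  comp
}

#' Ancestral-order sensitivity analysis
#'
#' The assignment of which population is ancestral can be uncertain. For
#' each of `n_randomizations` runs, every comparison flagged
#' `ancestral_ambiguous` is independently flipped with probability 1/2, the
#' Monte Carlo effect sizes of flipped comparisons are recomputed, and the
#' pooled meta-analytic mean of the focal statistic refitted. Results per
#' flip pattern are cached, so with few ambiguous comparisons the possible
#' outcomes are enumerated exactly.
#'
#' @param config A [pipeline_config()].
#' @param n_randomizations Number of randomized reruns.
#' @param effect_name Focal statistic (default `"angle_pt"`).
#' @param seed Seed for the flip randomization (defaults to
#'   `config$master_seed`).
#' @return List with `baseline` (pooled mean), `pooled_means` (length
#'   `n_randomizations`, equal to baseline when nothing is ambiguous),
#'   `n_ambiguous`, `patterns` (flip pattern per run).
#' @export
ancestral_order_sensitivity <- function(config, n_randomizations = 20,
                                        effect_name = "angle_pt",
                                        seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  comps <- read_study_table(config$study, config$traits, config$fitness)
  if (!length(comps)) pv_stop("pv_dataset_error", "no comparisons in input")
  ambiguous <- names(comps)[vapply(comps, `[[`, TRUE, "ancestral_ambiguous")]
  effects0 <- lapply(comps, function(comp) {
    comparison_effects(comp, config)[[effect_name]]
  })
  pooled <- function(effs) {
    V <- build_sampling_covariance(effs, r = config$shared_r)
    ds <- build_meta_dataset(effs, V = V)
    fit_random_effects(ds, "study")$mu
  }
  baseline <- pooled(effects0)
  if (!length(ambiguous)) {
    message("no ancestrally ambiguous comparisons; returning baseline only")
    return(list(baseline = baseline, pooled_means = rep(baseline,
                                                        n_randomizations),
                n_ambiguous = 0L, patterns = NULL))
  }
  flipped_cache <- list()
  flipped_effect <- function(cid) {
    if (is.null(flipped_cache[[cid]]))
      flipped_cache[[cid]] <<- comparison_effects(
        flip_comparison(comps[[cid]]), config, flipped = TRUE)[[effect_name]]
    flipped_cache[[cid]]
  }
  set.seed(seed %||% config$master_seed)
  patterns <- matrix(stats::runif(n_randomizations * length(ambiguous)) < 0.5,
                     n_randomizations, length(ambiguous),
                     dimnames = list(NULL, ambiguous))
  pooled_cache <- new.env(parent = emptyenv())
  pooled_means <- vapply(seq_len(n_randomizations), function(r) {
    key <- paste(as.integer(patterns[r, ]), collapse = "")
    if (!is.null(pooled_cache[[key]])) return(pooled_cache[[key]])
    effs <- effects0
    for (cid in ambiguous[patterns[r, ]]) effs[[cid]] <- flipped_effect(cid)
    val <- pooled(effs)
    pooled_cache[[key]] <- val
    val
  }, numeric(1))
  list(baseline = baseline, pooled_means = pooled_means,
       n_ambiguous = length(ambiguous), patterns = patterns)
}
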