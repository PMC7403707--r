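# Synthetic reciprocal-transplant data with closed-form ground truth.
#
# The generator plays the role of a compiled multi-study dataset: unit
# centroids are placed exactly by the requested plasticity and divergence
# vectors, individuals are drawn from a multivariate normal with a
# controllable P-matrix eigenstructure, fitness observations are drawn to
# hit a target Hedges' g in expectation, and whole meta-datasets add
# study-level and observation-level heterogeneity plus a random ultrametric
# species tree. Every implied angle/length/classification is recorded in
# closed form so that pipeline estimates can be validated against known
# truth.

rotation_from_spec <- function(d, orientation) {
  if (is.null(orientation) || identical(orientation, "identity"))
    return(diag(d))
  if (is.matrix(orientation)) {
    stopifnot(nrow(orientation) == d, ncol(orientation) == d)
    return(orientation)
  }
  if (identical(orientation, "random")) {
    qr_ <- qr(matrix(stats::rnorm(d * d), d))
    Q <- qr.Q(qr_)
    return(Q %*% diag(sign(diag(qr.R(qr_))), d))
  }
  pv_stop("pv_spec_error", "unknown P orientation specification")
}

#' Specification for one synthetic reciprocal transplant comparison
#'
#' Unit centroids are constructed as `AinA = base_centroid`,
#' `AinB = AinA + plasticity_A`, `BinB = AinB + divergence`,
#' `BinA = BinB + plasticity_B`; all true angles and fractions follow in
#' closed form. `plasticity_B = "mirror"` (the default) sets
#' `plasticity_B = -plasticity_A`: perfectly conserved plasticity, true
#' plasticity-plasticity angle 180 degrees, the natural reference point.
#'
#' @param d_traits Number of traits (>= 2).
#' @param n_per_unit Individuals per experimental unit (>= 3).
#' @param base_centroid Centroid of AinA (recycled to length `d_traits`).
#' @param plasticity_A Plastic response of population A (AinA to AinB).
#' @param divergence Evolutionary divergence (AinB to BinB).
#' @param plasticity_B Plastic response of population B (BinB to BinA), or
#'   `"mirror"` for `-plasticity_A`.
#' @param P_eigenvalues Descending positive eigenvalues of the within-unit
#'   P-matrix.
#' @param P_orientation `"identity"`, `"random"`, or a `d x d` rotation.
#' @param fitness_g Target Hedges' g of the home-vs-transplant fitness
#'   contrast in each environment.
#' @param n_fitness Fitness observations per unit.
#' @param trait_types Character vector (`"morphology"`/`"phenology"`),
#'   recycled to `d_traits`.
#' @param species,study_id,comparison_id Labels.
#' @param ancestral_ambiguous Ambiguity flag passed to the comparison.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(d_traits = 2, n_per_unit = 30,
                           base_centroid = 0,
                           plasticity_A = c(1, rep(0, d_traits - 1)),
                           divergence = c(0, 0.5, rep(0, max(0, d_traits - 2))),
                           plasticity_B = "mirror",
                           P_eigenvalues = 0.5 * 0.6^(seq_len(d_traits) - 1),
                           P_orientation = "identity",
                           fitness_g = 0.5, n_fitness = n_per_unit,
                           trait_types = "morphology",
                           species = "sp1", study_id = "S1",
                           comparison_id = "C1",
                           ancestral_ambiguous = FALSE, seed = NULL) {
  stopifnot(d_traits >= 2, n_per_unit >= 3, length(P_eigenvalues) == d_traits,
            all(P_eigenvalues > 0), !is.unsorted(rev(P_eigenvalues)))
  spec <- list(
    d_traits = d_traits, n_per_unit = n_per_unit,
    base_centroid = rep_len(base_centroid, d_traits),
    plasticity_A = plasticity_A, divergence = divergence,
    plasticity_B = plasticity_B, P_eigenvalues = P_eigenvalues,
    P_orientation = P_orientation, fitness_g = fitness_g,
    n_fitness = n_fitness,
    trait_types = rep_len(trait_types, d_traits),
    species = species, study_id = study_id, comparison_id = comparison_id,
    ancestral_ambiguous = ancestral_ambiguous, seed = seed
  )
  for (nm in c("plasticity_A", "divergence"))
    if (length(spec[[nm]]) != d_traits)
      pv_stop("pv_spec_error", "%s must have length d_traits = %d", nm, d_traits)
  if (!identical(spec$plasticity_B, "mirror") &&
      length(spec$plasticity_B) != d_traits)
    pv_stop("pv_spec_error", "plasticity_B must have length d_traits or 'mirror'")
  class(spec) <- "generator_spec"
  spec
}

# Closed-form truth for the noiseless construction. Computed directly from
# the centroid definitions (independently of the geometry module, which the
# tests cross-validate against).
generator_truth <- function(spec, P) {
  cen <- list(AinA = spec$base_centroid)
  cen$AinB <- cen$AinA + spec$plasticity_A
  pB_spec <- if (identical(spec$plasticity_B, "mirror")) -spec$plasticity_A
             else spec$plasticity_B
  cen$BinB <- cen$AinB + spec$divergence
  cen$BinA <- cen$BinB + pB_spec
  pB <- cen$BinA - cen$BinB
  nrm <- function(v) sqrt(sum(v^2))
  ang <- function(u, v) 180 / pi *
    acos(min(1, max(-1, sum(u * v) / (nrm(u) * nrm(v)))))
  # truth refers to the noiseless centroid configuration, so the vectors are
  # reconstructed from the centroids exactly as an analyzer would
  pA <- cen$AinB - cen$AinA
  tot <- cen$BinB - cen$AinA
  ed <- cen$BinB - cen$AinB
  e1 <- eigen(P, symmetric = TRUE)$vectors[, 1]
  uang <- function(a, v) 180 / pi *
    acos(min(1, abs(sum(a * v)) / (nrm(a) * nrm(v))))
  frac <- 100 * sum(pA * tot) / sum(tot^2)
  angle_pt <- ang(pA, tot)
  list(
    centroids = cen,
    P = P,
    stats = c(
      angle_pp = ang(pA, pB),
      angle_pt = angle_pt,
      angle_pe = ang(pA, ed),
      angle_pmax_e = uang(e1, ed),
      angle_pmax_p = uang(e1, pA),
      projection_pct = frac,
      log_length_diff = log(nrm(pB)) - log(nrm(pA)),
      log_var_ratio_A = 0,
      log_var_ratio_B = 0
    ),
    classification = if (angle_pt > 90) "opposite"
                     else if (frac > 100) "overshoot" else "undershoot",
    eigen_ratio = spec$P_eigenvalues[2] / spec$P_eigenvalues[1],
    fitness_g = spec$fitness_g
  )
}

#' Generate one synthetic comparison with its ground truth
#'
#' @param spec A [generator_spec()].
#' @return List with `comparison` (an [rt_comparison()], unstandardized)
#'   and `truth` (noiseless centroids, shared P-matrix, true statistics,
#'   classification and fitness g).
#' @export
generate_comparison <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$d_traits
  Q <- rotation_from_spec(d, spec$P_orientation)
  P <- Q %*% diag(spec$P_eigenvalues, d) %*% t(Q)
  truth <- generator_truth(spec, P)
  units <- list()
  for (key in UNIT_KEYS) {
    pop <- substr(key, 1, 1); env <- substr(key, 4, 4)
    x <- MASS::mvrnorm(spec$n_per_unit, mu = truth$centroids[[key]], Sigma = P)
    colnames(x) <- paste0("trait", seq_len(d))
    rownames(x) <- paste0(key, "_", seq_len(spec$n_per_unit))
    units[[key]] <- rt_unit(x, pop, env, spec$study_id, spec$comparison_id)
  }
  # Fitness: unit-SD normal; home units offset so that the expected
  # standardized difference after the small-sample correction J equals the
  # target g in each environment's native-vs-transplant contrast.
  nf <- spec$n_fitness
  J <- 1 - 3 / (4 * (2 * nf) - 9)
  delta <- spec$fitness_g / J
  fitness <- do.call(rbind, lapply(UNIT_KEYS, function(key) {
    pop <- substr(key, 1, 1); env <- substr(key, 4, 4)
    mu <- if (pop == env) delta else 0
    data.frame(population = pop, environment = env,
               measure_name = "biomass", is_primary = TRUE,
               value = stats::rnorm(nf, mean = mu, sd = 1),
               stringsAsFactors = FALSE)
  }))
  traits <- data.frame(name = paste0("trait", seq_len(d)),
                       trait_type = spec$trait_types,
                       units = "standardized", stringsAsFactors = FALSE)
  comp <- rt_comparison(units, traits, species = spec$species,
                        study_id = spec$study_id,
                        comparison_id = spec$comparison_id,
                        fitness = fitness,
                        ancestral_ambiguous = spec$ancestral_ambiguous)
  list(comparison = comp, truth = truth)
}

#' Specification for a synthetic meta-analytic dataset
#'
#' Defaults are calibrated to the descriptive statistics typical of
#' compiled plant reciprocal-transplant literatures: studies mostly
#' contribute a single comparison (range 1-15), trait counts average about
#' 3.8 with SD about 1.9 (clamped to 2-9), and study and species are
#' confounded (one species per study) with species related through a random
#' ultrametric coalescent tree of depth 1.
#'
#' @param k_studies Number of studies.
#' @param true_mu True overall mean of the focal effect size (degrees for
#'   angles).
#' @param effect_name Which statistic the true means refer to.
#' @param tau2_study Between-study variance of true effects.
#' @param tau2_obs Observation-level (within-study) variance.
#' @param vi_range Range of per-effect sampling variances drawn uniformly
#'   (effect level), in squared effect units.
#' @param comp_probs Probabilities of 1..15 comparisons per study.
#' @param n_traits_mean,n_traits_sd Normal parameters for trait counts,
#'   rounded and clamped to `[2, 9]`.
#' @param n_per_unit_range Per-unit sample sizes drawn uniformly (integer).
#' @param fitness_g_mean,fitness_g_sd Normal parameters for per-comparison
#'   target local-adaptation g.
#' @param seed Integer seed.
#' @return A `meta_generator_spec` list.
#' @export
meta_generator_spec <- function(k_studies = 34, true_mu = 30,
                                effect_name = "angle_pt",
                                tau2_study = 25, tau2_obs = 10,
                                vi_range = c(4, 64),
                                comp_probs = c(0.68, 0.12, 0.07, 0.04, 0.03,
                                               0.02, 0.01, 0.005, 0.005,
                                               0.004, 0.003, 0.002, 0.002,
                                               0.001, 0.001),
                                n_traits_mean = 3.82, n_traits_sd = 1.91,
                                n_per_unit_range = c(10, 40),
                                fitness_g_mean = 0.5, fitness_g_sd = 0.3,
                                seed = NULL) {
  stopifnot(k_studies >= 2, tau2_study >= 0, tau2_obs >= 0,
            all(vi_range > 0), length(comp_probs) == 15)
  structure(
    list(k_studies = k_studies, true_mu = true_mu, effect_name = effect_name,
         tau2_study = tau2_study, tau2_obs = tau2_obs, vi_range = vi_range,
         comp_probs = comp_probs / sum(comp_probs),
         n_traits_mean = n_traits_mean, n_traits_sd = n_traits_sd,
         n_per_unit_range = n_per_unit_range,
         fitness_g_mean = fitness_g_mean, fitness_g_sd = fitness_g_sd,
         seed = seed),
    class = "meta_generator_spec"
  )
}

draw_n_traits <- function(k, mean, sd) {
  pmin(9L, pmax(2L, as.integer(round(stats::rnorm(k, mean, sd)))))
}

#' Generate a synthetic meta-analytic dataset with known ground truth
#'
#' Per-comparison true effects are drawn from the two-level random-effects
#' model `theta_ij = mu + u_i + w_ij` with `u_i ~ N(0, tau2_study)` and
#' `w_ij ~ N(0, tau2_obs)`. At `level = "effect"` the observed effect adds
#' sampling noise `N(0, vi)` with `vi` drawn from `vi_range`, giving a
#' ready-to-fit `meta_dataset` (the standard design for validating the
#' meta-analytic layer). At `level = "individual"` each comparison is built
#' as a full 4-unit design via [generate_comparison()], with the plasticity
#' vector fixed along the first trait axis and the total-difference vector
#' rotated in the first trait plane so the true focal angle equals
#' `theta_ij` (clamped to `[1, 179]` degrees); effect estimates must then
#' be computed by the Monte Carlo pipeline.
#'
#' @param spec A [meta_generator_spec()].
#' @param level `"effect"` or `"individual"`.
#' @return For `"effect"`: list with `dataset` (a `meta_dataset` including
#'   moderators and phylogeny), `tree`, and `truth` (true mu, tau2s, study
#'   effects, per-effect true values). For `"individual"`: additionally
#'   `comparisons` (list of generation results) instead of a fitted-ready
#'   dataset's `yi`.
#' @export
generate_meta_dataset <- function(spec, level = c("effect", "individual")) {
  stopifnot(inherits(spec, "meta_generator_spec"))
  level <- match.arg(level)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  k <- spec$k_studies
  n_comp <- sample.int(15, k, replace = TRUE, prob = spec$comp_probs)
  study_id <- rep(paste0("S", seq_len(k)), n_comp)
  species <- rep(paste0("sp", seq_len(k)), n_comp)  # study/species confounded
  m <- length(study_id)
  comparison_id <- paste0(study_id, "_c",
                          unlist(lapply(n_comp, seq_len), use.names = FALSE))
  u <- stats::rnorm(k, 0, sqrt(spec$tau2_study))
  w <- stats::rnorm(m, 0, sqrt(spec$tau2_obs))
  theta <- spec$true_mu + rep(u, n_comp) + w

  n_traits_study <- draw_n_traits(k, spec$n_traits_mean, spec$n_traits_sd)
  n_traits <- rep(n_traits_study, n_comp)
  # trait-type mix at the study level: mostly all-morphology, a few
  # all-phenology, the rest mixed
  mix_type <- sample(c("morph", "phen", "mixed"), k, replace = TRUE,
                     prob = c(22, 3, 9) / 34)
  prop_morph_study <- ifelse(mix_type == "morph", 1,
                             ifelse(mix_type == "phen", 0,
                                    stats::runif(k, 0.2, 0.8)))
  prop_morphology <- rep(prop_morph_study, n_comp)
  local_g <- stats::rnorm(m, spec$fitness_g_mean, spec$fitness_g_sd)
  tree <- ape::rcoal(k, tip.label = paste0("sp", seq_len(k)))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  phylo <- phylo_correlation_matrix(tree, paste0("sp", seq_len(k)))
  moderators <- data.frame(n_traits = n_traits,
                           prop_morphology = prop_morphology,
                           local_adaptation_g = local_g)
  truth <- list(true_mu = spec$true_mu, tau2_study = spec$tau2_study,
                tau2_obs = spec$tau2_obs, study_effects = u,
                theta = theta, effect_name = spec$effect_name)

  if (level == "effect") {
    vi <- stats::runif(m, spec$vi_range[1], spec$vi_range[2])
    yi <- theta + stats::rnorm(m, 0, sqrt(vi))
    dat <- data.frame(yi = yi, vi = vi, study_id = study_id,
                      species = species, comparison_id = comparison_id,
                      stringsAsFactors = FALSE)
    ds <- build_meta_dataset(dat, moderators = moderators, phylo = phylo)
    return(list(dataset = ds, tree = tree, truth = truth))
  }

  # individual level: realize each comparison as a 4-unit design whose true
  # focal angle equals theta (clamped into the open (0, 180) range)
  theta_cl <- pmin(179, pmax(1, theta))
  comparisons <- vector("list", m)
  for (i in seq_len(m)) {
    d <- n_traits[i]
    ang <- theta_cl[i] * pi / 180
    pA <- c(1, rep(0, d - 1))
    tot <- 1.2 * c(cos(ang), sin(ang), rep(0, d - 2))
    comparisons[[i]] <- generate_comparison(generator_spec(
      d_traits = d,
      n_per_unit = sample(seq(spec$n_per_unit_range[1],
                              spec$n_per_unit_range[2]), 1),
      plasticity_A = pA, divergence = tot - pA,
      # spherical P: per-trait standardization is then isotropic, so the
      # raw-scale true angles survive the standardization step
      P_eigenvalues = rep(0.35, d),
      P_orientation = "identity",
      fitness_g = local_g[i],
      trait_types = c(rep("morphology", round(prop_morphology[i] * d)),
                      rep("phenology", d - round(prop_morphology[i] * d))),
      species = species[i], study_id = study_id[i],
      comparison_id = comparison_id[i]
    ))
  }
  truth$theta_realized <- theta_cl
  list(comparisons = comparisons, tree = tree, phylo = phylo,
       moderators = moderators, truth = truth)
}

#' Write a synthetic dataset to the pipeline's CSV/Newick schema
#'
#' Writes the study table, trait metadata, fitness table, Newick tree and a
#' ground-truth CSV, so the full pipeline can run end-to-end on files alone.
#'
#' @param gen Result of `generate_meta_dataset(..., level = "individual")`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_synthetic_dataset <- function(gen, dir) {
  stopifnot(!is.null(gen$comparisons))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    study = file.path(dir, "study.csv"),
    traits = file.path(dir, "traits.csv"),
    fitness = file.path(dir, "fitness.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "ground_truth.csv")
  )
  comps <- lapply(gen$comparisons, `[[`, "comparison")
  # trait metadata must cover every trait name once; trait names are shared
  # (trait1..trait9) but types differ per comparison, so namespace them
  for (i in seq_along(comps)) {
    cid <- comps[[i]]$comparison_id
    new_names <- paste0(cid, "_", comps[[i]]$traits$name)
    comps[[i]]$traits$name <- new_names
    for (k in seq_along(comps[[i]]$units))
      colnames(comps[[i]]$units[[k]]$individuals) <- new_names
  }
  write_study_table(comps, paths$study, paths$traits, paths$fitness)
  ape::write.tree(gen$tree, paths$tree)
  truth_tab <- do.call(rbind, lapply(seq_along(gen$comparisons), function(i) {
    tr <- gen$comparisons[[i]]$truth
    data.frame(comparison_id = comps[[i]]$comparison_id, t(tr$stats),
               classification = tr$classification,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth_tab, paths$truth, row.names = FALSE)
  invisible(paths)
}
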