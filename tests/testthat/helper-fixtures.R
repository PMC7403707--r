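# Fixtures are built in code; nothing is stored on disk except what a test
# writes to its own tempdir.

toy_traits <- function(d = 2) {
  data.frame(name = paste0("trait", seq_len(d)),
             trait_type = rep(c("morphology", "phenology"), length.out = d),
             units = "cm", stringsAsFactors = FALSE)
}

# Deterministic unit: n individuals at the given centroid plus a fixed
# full-rank jitter pattern (no RNG involved).
fixed_unit <- function(center, pop, env, n = 8, comparison_id = "C1",
                       study_id = "S1") {
  d <- length(center)
  jitter <- outer(seq_len(n), seq_len(d), function(i, j)
    0.15 * i * (-1)^(i + j) + 0.07 * j * sin(i))
  jitter <- sweep(jitter, 2, colMeans(jitter))  # exact centroids
  m <- sweep(jitter, 2, center, `+`)
  colnames(m) <- paste0("trait", seq_len(d))
  rownames(m) <- paste0(pop, env, "_", seq_len(n))
  rt_unit(m, pop, env, study_id, comparison_id)
}

# Comparison with exactly placed centroids (jitter pattern is identical in
# all units, so centroid differences are exact).
toy_comparison <- function(AinA = c(0, 0), AinB = c(1, 0), BinB = c(1, 0.5),
                           BinA = c(0, 0.5), n = 8, comparison_id = "C1",
                           study_id = "S1", species = "sp1",
                           fitness = NULL, ancestral_ambiguous = FALSE) {
  units <- list(
    AinA = fixed_unit(AinA, "A", "A", n, comparison_id, study_id),
    AinB = fixed_unit(AinB, "A", "B", n, comparison_id, study_id),
    BinB = fixed_unit(BinB, "B", "B", n, comparison_id, study_id),
    BinA = fixed_unit(BinA, "B", "A", n, comparison_id, study_id)
  )
  rt_comparison(units, toy_traits(length(AinA)), species = species,
                study_id = study_id, comparison_id = comparison_id,
                fitness = fitness, ancestral_ambiguous = ancestral_ambiguous)
}

toy_fitness <- function(gB_positive = TRUE, n = 10, seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(list(c("A", "A", 1), c("A", "B", 0),
                             c("B", "B", if (gB_positive) 1 else -1),
                             c("B", "A", 0)), function(u)
    data.frame(population = u[1], environment = u[2],
               measure_name = "seeds", is_primary = TRUE,
               value = rnorm(n, as.numeric(u[3]), 1),
               stringsAsFactors = FALSE)))
}

# Random PSD matrix with unit-scale eigenvalues.
random_psd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) / d
  (S + t(S)) / 2
}
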