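# Data model, file I/O, validation and trait standardization for
# two-population reciprocal transplant studies.
#
# A comparison is the classic 2 x 2 design: population A (putatively
# ancestral) and population B (derived), each grown in its home and in the
# other population's environment, giving four experimental units AinA, AinB,
# BinB, BinA. Individuals are rows, traits are columns.

UNIT_KEYS <- c("AinA", "AinB", "BinB", "BinA")

unit_key <- function(population, environment) {
  paste0(population, "in", environment)
}

#' Construct an experimental unit
#'
#' An experimental unit is one population grown in one environment: an
#' `n x d` matrix of individual trait measurements plus its labels.
#'
#' @param individuals Numeric matrix, individuals in rows, traits in columns.
#' @param population,environment `"A"` or `"B"`.
#' @param study_id,comparison_id Identifying labels.
#' @return An object of class `rt_unit`.
#' @export
rt_unit <- function(individuals, population, environment,
                    study_id = "S1", comparison_id = "C1") {
  individuals <- as.matrix(individuals)
  storage.mode(individuals) <- "double"
  population <- match.arg(population, c("A", "B"))
  environment <- match.arg(environment, c("A", "B"))
  if (anyNA(individuals))
    pv_stop("pv_validation_error", "unit %s/%s contains missing values",
            comparison_id, unit_key(population, environment))
  structure(
    list(study_id = study_id, comparison_id = comparison_id,
         population = population, environment = environment,
         individuals = individuals, n = nrow(individuals)),
    class = "rt_unit"
  )
}

#' Construct a reciprocal transplant comparison
#'
#' @param units Named list with elements `AinA`, `AinB`, `BinB`, `BinA`,
#'   each an [rt_unit()]. All four must share the same trait columns.
#' @param traits Data frame with columns `name`, `trait_type`
#'   (`"morphology"` or `"phenology"`) and optionally `units`.
#' @param species Species label (used for phylogenetic random effects).
#' @param fitness Optional data frame of per-individual fitness observations
#'   with columns `population`, `environment`, `measure_name`, `is_primary`,
#'   `value`.
#' @param ancestral_ambiguous Logical; `TRUE` when the assignment of A as
#'   the ancestral population is uncertain (used by the ancestral-order
#'   sensitivity analysis).
#' @inheritParams rt_unit
#' @return An object of class `rt_comparison`.
#' @export
rt_comparison <- function(units, traits, species = "sp1",
                          study_id = "S1", comparison_id = "C1",
                          fitness = NULL, ancestral_ambiguous = FALSE) {
  missing_units <- setdiff(UNIT_KEYS, names(units))
  if (length(missing_units))
    pv_stop("pv_structure_error",
            "comparison %s is missing experimental unit(s): %s",
            comparison_id, paste(missing_units, collapse = ", "))
  units <- units[UNIT_KEYS]
  d <- ncol(units[[1]]$individuals)
  for (u in units) {
    if (ncol(u$individuals) != d)
      pv_stop("pv_structure_error",
              "comparison %s: units have differing trait counts", comparison_id)
    if (u$n < 3)
      pv_stop("pv_validation_error",
              "comparison %s unit %s has n = %d < 3", comparison_id,
              unit_key(u$population, u$environment), u$n)
  }
  if (d < 2)
    pv_stop("pv_validation_error",
            "comparison %s measures %d trait(s); at least 2 required",
            comparison_id, d)
  traits <- as.data.frame(traits)
  if (!all(c("name", "trait_type") %in% names(traits)))
    pv_stop("pv_metadata_error", "trait metadata needs columns name, trait_type")
  if (anyDuplicated(traits$name))
    pv_stop("pv_metadata_error", "duplicate trait names in metadata")
  if (!all(traits$trait_type %in% c("morphology", "phenology")))
    pv_stop("pv_metadata_error",
            "trait_type must be 'morphology' or 'phenology'")
  if (nrow(traits) != d)
    pv_stop("pv_metadata_error",
            "comparison %s: %d traits in data but %d in metadata",
            comparison_id, d, nrow(traits))
  structure(
    list(study_id = study_id, comparison_id = comparison_id,
         species = species, units = units, traits = traits,
         fitness = fitness, ancestral_ambiguous = isTRUE(ancestral_ambiguous),
         standardized = FALSE, standardization = NULL),
    class = "rt_comparison"
  )
}

#' @export
print.rt_comparison <- function(x, ...) {
  cat(sprintf("<rt_comparison %s/%s (%s)%s>\n", x$study_id, x$comparison_id,
              x$species, if (x$standardized) " standardized" else ""))
  ns <- vapply(x$units, function(u) u$n, integer(1))
  cat(sprintf("  %d traits (%d morphology, %d phenology); n = %s\n",
              nrow(x$traits), sum(x$traits$trait_type == "morphology"),
              sum(x$traits$trait_type == "phenology"),
              paste(sprintf("%s:%d", names(ns), ns), collapse = " ")))
  invisible(x)
}

#' Read a tidy study table into validated comparisons
#'
#' The study CSV is wide: one row per individual with columns `study_id`,
#' `comparison_id`, `species`, `population`, `environment`, `individual_id`,
#' optionally `ancestral_ambiguous`, plus one numeric column per trait.
#' The trait metadata CSV maps each trait `name` to a `trait_type`
#' (`morphology` or `phenology`). Rows with any missing trait value are
#' dropped (listwise deletion) and the count is reported via `message()`.
#'
#' @param path Path to the study CSV.
#' @param trait_meta Path to the trait metadata CSV (columns `name`,
#'   `trait_type`, optional `units`).
#' @param fitness Optional path to a fitness CSV with columns
#'   `comparison_id`, `population`, `environment`, `measure_name`,
#'   `is_primary`, `value` (one row per observation).
#' @return A list of [rt_comparison()] objects, named by comparison id.
#' @export
read_study_table <- function(path, trait_meta, fitness = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(trait_meta, stringsAsFactors = FALSE)
  req <- c("study_id", "comparison_id", "species", "population",
           "environment", "individual_id")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    pv_stop("pv_format_error", "study table lacks required column(s): %s",
            paste(miss, collapse = ", "))
  trait_cols <- setdiff(names(dat), c(req, "ancestral_ambiguous"))
  if (!length(trait_cols))
    pv_stop("pv_format_error", "study table has no trait columns")
  unknown <- setdiff(trait_cols, meta$name)
  if (length(unknown))
    pv_stop("pv_metadata_error", "trait(s) absent from metadata: %s",
            paste(unknown, collapse = ", "))

  fit_all <- if (!is.null(fitness))
    utils::read.csv(fitness, stringsAsFactors = FALSE) else NULL

  n_dropped <- 0L
  comps <- lapply(split(dat, dat$comparison_id), function(cd) {
    cid <- cd$comparison_id[[1]]
    # a comparison's trait set = columns with any measurement for it; this
    # lets a wide multi-study table carry heterogeneous trait sets
    tc <- trait_cols[colSums(!is.na(cd[trait_cols])) > 0]
    if (!length(tc))
      pv_stop("pv_format_error", "comparison %s has no trait columns", cid)
    complete <- stats::complete.cases(cd[tc])
    n_dropped <<- n_dropped + sum(!complete)
    cd <- cd[complete, , drop = FALSE]
    cmeta <- meta[match(tc, meta$name), , drop = FALSE]
    units <- list()
    for (pop in c("A", "B")) for (env in c("A", "B")) {
      rows <- cd$population == pop & cd$environment == env
      if (!any(rows))
        pv_stop("pv_structure_error",
                "comparison %s is missing experimental unit(s): %s",
                cid, unit_key(pop, env))
      m <- as.matrix(cd[rows, tc, drop = FALSE])
      rownames(m) <- cd$individual_id[rows]
      units[[unit_key(pop, env)]] <-
        rt_unit(m, pop, env, cd$study_id[[1]], cid)
    }
    fit <- NULL
    if (!is.null(fit_all)) {
      fit <- fit_all[fit_all$comparison_id == cid, , drop = FALSE]
      if (!nrow(fit)) fit <- NULL
    }
    rt_comparison(
      units, cmeta, species = cd$species[[1]],
      study_id = cd$study_id[[1]], comparison_id = cid, fitness = fit,
      ancestral_ambiguous =
        isTRUE(as.logical(cd$ancestral_ambiguous[[1]] %||% FALSE))
    )
  })
  if (n_dropped > 0)
    message(sprintf("read_study_table: dropped %d row(s) with missing trait values",
                    n_dropped))
  comps[order(names(comps))]
}

#' Write comparisons back to the tidy CSV schema
#'
#' Inverse of [read_study_table()]: writes the study table and the trait
#' metadata (and the fitness table when present), so that reading the files
#' back reproduces the comparisons.
#'
#' @param comps List of [rt_comparison()] objects.
#' @param path,trait_meta,fitness Output CSV paths (`fitness` optional).
#' @return Invisibly, the study-table data frame.
#' @export
write_study_table <- function(comps, path, trait_meta, fitness = NULL) {
  if (inherits(comps, "rt_comparison")) comps <- list(comps)
  all_traits <- unique(do.call(rbind, lapply(comps, `[[`, "traits")))
  if (anyDuplicated(all_traits$name))
    pv_stop("pv_metadata_error",
            "same trait name mapped to conflicting metadata across comparisons")
  rows <- lapply(comps, function(comp) {
    do.call(rbind, lapply(comp$units, function(u) {
      df <- data.frame(
        study_id = u$study_id, comparison_id = u$comparison_id,
        species = comp$species, population = u$population,
        environment = u$environment,
        individual_id = rownames(u$individuals) %||%
          paste0(unit_key(u$population, u$environment), "_", seq_len(u$n)),
        ancestral_ambiguous = comp$ancestral_ambiguous,
        stringsAsFactors = FALSE
      )
      m <- matrix(NA_real_, u$n, nrow(all_traits),
                  dimnames = list(NULL, all_traits$name))
      m[, colnames(u$individuals) %||% comp$traits$name] <- u$individuals
      cbind(df, as.data.frame(m))
    }))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  utils::write.csv(all_traits, trait_meta, row.names = FALSE)
  if (!is.null(fitness)) {
    ft <- do.call(rbind, lapply(comps, function(comp) {
      if (is.null(comp$fitness)) return(NULL)
      cbind(comparison_id = comp$comparison_id,
            comp$fitness[setdiff(names(comp$fitness), "comparison_id")])
    }))
    if (!is.null(ft)) utils::write.csv(ft, fitness, row.names = FALSE)
  }
  invisible(tab)
}

#' Standardize traits within a comparison
#'
#' Each trait column is z-scored with the grand mean over all individuals of
#' the four units and the pooled within-unit standard deviation
#' `sqrt(sum_u SS_u / sum_u (n_u - 1))`. Between-unit mean shifts are
#' preserved (the scaling is common to all units), which keeps plasticity
#' and divergence vectors meaningful while making traits on different raw
#' scales commensurable for angle calculations.
#'
#' @param comp An [rt_comparison()].
#' @return The comparison with standardized trait values; the transformation
#'   parameters are stored in `$standardization`.
#' @export
standardize_traits <- function(comp) {
  stopifnot(inherits(comp, "rt_comparison"))
  all_rows <- do.call(rbind, lapply(comp$units, `[[`, "individuals"))
  grand_mean <- colMeans(all_rows)
  ss <- Reduce(`+`, lapply(comp$units, function(u) {
    ctr <- sweep(u$individuals, 2, colMeans(u$individuals))
    colSums(ctr^2)
  }))
  df_within <- sum(vapply(comp$units, function(u) u$n - 1L, integer(1)))
  pooled_sd <- sqrt(ss / df_within)
  degen <- pooled_sd <= 0
  if (any(degen))
    pv_stop("pv_degenerate_trait_error",
            "trait(s) with zero pooled within-unit SD in %s: %s",
            comp$comparison_id,
            paste(comp$traits$name[degen], collapse = ", "))
  comp$units <- lapply(comp$units, function(u) {
    u$individuals <- sweep(sweep(u$individuals, 2, grand_mean), 2,
                           pooled_sd, `/`)
    u
  })
  comp$standardized <- TRUE
  comp$standardization <- list(grand_mean = grand_mean, pooled_sd = pooled_sd)
  comp
}

#' Summarize a validated dataset
#'
#' @param comps List of [rt_comparison()] objects.
#' @return A list with counts of studies, comparisons, species and traits,
#'   printed as structured text.
#' @export
dataset_report <- function(comps) {
  rep <- list(
    n_studies = length(unique(vapply(comps, `[[`, "", "study_id"))),
    n_comparisons = length(comps),
    n_species = length(unique(vapply(comps, `[[`, "", "species"))),
    n_traits = vapply(comps, function(c) nrow(c$traits), integer(1)),
    n_ambiguous = sum(vapply(comps, `[[`, TRUE, "ancestral_ambiguous"))
  )
  class(rep) <- "pv_dataset_report"
  rep
}

#' @export
print.pv_dataset_report <- function(x, ...) {
  cat(sprintf("Reciprocal transplant dataset: %d studies, %d comparisons, %d species\n",
              x$n_studies, x$n_comparisons, x$n_species))
  cat(sprintf("  traits per comparison: %s (mean %.2f)\n",
              paste(range(x$n_traits), collapse = "-"), mean(x$n_traits)))
  cat(sprintf("  ancestral order ambiguous: %d\n", x$n_ambiguous))
  invisible(x)
}
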