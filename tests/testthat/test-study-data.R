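test_that("well-formed study tables round-trip through the CSV schema", {
  dir <- withr::local_tempdir()
  comp <- toy_comparison(fitness = toy_fitness())
  paths <- file.path(dir, c("study.csv", "traits.csv", "fitness.csv"))
  write_study_table(list(comp), paths[1], paths[2], paths[3])
  comps <- read_study_table(paths[1], paths[2], paths[3])

  expect_length(comps, 1)
  got <- comps[[1]]
  expect_s3_class(got, "rt_comparison")
  expect_equal(nrow(got$traits), 2)
  expect_equal(vapply(got$units, `[[`, integer(1), "n"),
               c(AinA = 8L, AinB = 8L, BinB = 8L, BinA = 8L))
  for (k in names(comp$units))
    expect_equal(unname(got$units[[k]]$individuals),
                 unname(comp$units[[k]]$individuals))
  expect_equal(got$fitness$value, comp$fitness$value)

  # second round trip is the identity on the table itself
  paths2 <- file.path(dir, c("study2.csv", "traits2.csv"))
  write_study_table(comps, paths2[1], paths2[2])
  expect_identical(readLines(paths[1]), readLines(paths2[1]))
})

test_that("a comparison lacking one of the four units is a structure error", {
  dir <- withr::local_tempdir()
  comp <- toy_comparison()
  paths <- file.path(dir, c("study.csv", "traits.csv"))
  write_study_table(list(comp), paths[1], paths[2])
  tab <- read.csv(paths[1])
  tab <- tab[!(tab$population == "B" & tab$environment == "A"), ]
  write.csv(tab, paths[1], row.names = FALSE)
  expect_error(read_study_table(paths[1], paths[2]),
               "BinA", class = "pv_structure_error")
})

test_that("multiple comparisons group under their studies and traits may differ", {
  dir <- withr::local_tempdir()
  comps_in <- list(
    toy_comparison(comparison_id = "c1", study_id = "S1", species = "sp1"),
    toy_comparison(comparison_id = "c2", study_id = "S1", species = "sp1",
                   AinA = c(0, 0, 0), AinB = c(1, 1, 0), BinB = c(2, 0, 1),
                   BinA = c(1, -1, 1)),
    toy_comparison(comparison_id = "c3", study_id = "S2", species = "sp2")
  )
  # third comparison uses different trait names
  comps_in[[3]]$traits$name <- c("leafArea", "height")
  for (k in seq_along(comps_in[[3]]$units))
    colnames(comps_in[[3]]$units[[k]]$individuals) <- c("leafArea", "height")
  comps_in[[2]]$traits <- toy_traits(3)
  paths <- file.path(dir, c("study.csv", "traits.csv"))
  write_study_table(comps_in, paths[1], paths[2])
  comps <- read_study_table(paths[1], paths[2])

  expect_length(comps, 3)
  studies <- vapply(comps, `[[`, "", "study_id")
  expect_equal(sort(unique(studies)), c("S1", "S2"))
  expect_equal(as.integer(table(studies)[c("S1", "S2")]), c(2L, 1L))
  expect_equal(nrow(comps[["c2"]]$traits), 3)
  expect_equal(comps[["c3"]]$traits$name, c("leafArea", "height"))
})

test_that("rows with missing trait values are dropped with a logged count", {
  dir <- withr::local_tempdir()
  comp <- toy_comparison(n = 9)
  paths <- file.path(dir, c("study.csv", "traits.csv"))
  write_study_table(list(comp), paths[1], paths[2])
  tab <- read.csv(paths[1])
  tab$trait1[c(2, 11)] <- NA
  write.csv(tab, paths[1], row.names = FALSE)
  expect_message(comps <- read_study_table(paths[1], paths[2]),
                 "dropped 2 row")
  expect_equal(comps[[1]]$units$AinA$n, 8L)
})

test_that("required columns and trait metadata are validated", {
  dir <- withr::local_tempdir()
  comp <- toy_comparison()
  paths <- file.path(dir, c("study.csv", "traits.csv"))
  write_study_table(list(comp), paths[1], paths[2])
  tab <- read.csv(paths[1])
  write.csv(tab[setdiff(names(tab), "environment")], paths[1],
            row.names = FALSE)
  expect_error(read_study_table(paths[1], paths[2]),
               "environment", class = "pv_format_error")

  write_study_table(list(comp), paths[1], paths[2])
  meta <- read.csv(paths[2])
  write.csv(meta[1, ], paths[2], row.names = FALSE)
  expect_error(read_study_table(paths[1], paths[2]),
               "trait2", class = "pv_metadata_error")
})

test_that("units with fewer than three complete individuals are rejected", {
  u_small <- matrix(rnorm(4), 2, 2)
  expect_error(
    rt_comparison(list(AinA = rt_unit(u_small, "A", "A"),
                       AinB = fixed_unit(c(1, 0), "A", "B"),
                       BinB = fixed_unit(c(1, 1), "B", "B"),
                       BinA = fixed_unit(c(0, 1), "B", "A")),
                  toy_traits()),
    "n = 2", class = "pv_validation_error")
})

test_that("standardization z-scores by grand mean and pooled within-unit SD", {
  comp <- toy_comparison(AinA = c(10, 3), AinB = c(14, 5),
                         BinB = c(12, 4), BinA = c(11, 2), n = 4)
  std <- standardize_traits(comp)

  # direct spreadsheet-style oracle on the raw numbers
  raw <- lapply(comp$units, `[[`, "individuals")
  for (j in 1:2) {
    xs <- lapply(raw, function(m) m[, j])
    grand <- mean(unlist(xs))
    pooled <- sqrt(sum(vapply(xs, function(x) sum((x - mean(x))^2),
                              numeric(1))) /
                     sum(vapply(xs, function(x) length(x) - 1, numeric(1))))
    for (k in names(raw))
      expect_equal(std$units[[k]]$individuals[, j],
                   (raw[[k]][, j] - grand) / pooled, tolerance = 1e-12)
  }

  # post-conditions: grand mean 0, pooled within-unit SD 1
  all_rows <- do.call(rbind, lapply(std$units, `[[`, "individuals"))
  expect_lt(max(abs(colMeans(all_rows))), 1e-10)
  ss <- Reduce(`+`, lapply(std$units, function(u)
    colSums(sweep(u$individuals, 2, colMeans(u$individuals))^2)))
  dfree <- sum(vapply(std$units, function(u) u$n - 1, numeric(1)))
  expect_equal(unname(sqrt(ss / dfree)), c(1, 1), tolerance = 1e-10)

  # idempotence: standardizing standardized data changes nothing
  std2 <- standardize_traits(std)
  for (k in names(std$units))
    expect_equal(std2$units[[k]]$individuals, std$units[[k]]$individuals,
                 tolerance = 1e-12)
})

test_that("a trait with zero pooled variance is a degenerate-trait error", {
  comp <- toy_comparison()
  for (k in seq_along(comp$units))
    comp$units[[k]]$individuals[, 2] <- 7
  expect_error(standardize_traits(comp), "trait2",
               class = "pv_degenerate_trait_error")
})

test_that("dataset_report counts studies, comparisons and ambiguity flags", {
  comps <- list(toy_comparison(comparison_id = "c1", study_id = "S1"),
                toy_comparison(comparison_id = "c2", study_id = "S1",
                               ancestral_ambiguous = TRUE),
                toy_comparison(comparison_id = "c3", study_id = "S2"))
  rep <- dataset_report(comps)
  expect_equal(rep$n_studies, 2)
  expect_equal(rep$n_comparisons, 3)
  expect_equal(rep$n_ambiguous, 1)
  expect_output(print(rep), "2 studies, 3 comparisons")
})
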