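test_that("centroids and P-matrices match direct summation oracles", {
  expect_equal(unname(centroid(rt_unit(rbind(c(0, 0), c(2, 2), c(1, 1)),
                                       "A", "A"))), c(1, 1))
  set.seed(11)
  m <- matrix(rnorm(24), 8, 3)
  u <- rt_unit(m, "A", "A")
  expect_equal(unname(centroid(u)), unname(colSums(m) / 8))

  # two-pass covariance oracle
  set.seed(12)
  m2 <- matrix(rnorm(20), 10, 2)
  P <- p_matrix(rt_unit(m2, "B", "A"))
  ctr <- sweep(m2, 2, colMeans(m2))
  expect_equal(unname(P), unname(t(ctr) %*% ctr / 9), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(P, "n"), 10L)

  expect_equal(unname(p_matrix(rt_unit(rbind(c(0, 0), c(1, 0), c(2, 0)),
                                       "A", "A"))),
               rbind(c(1, 0), c(0, 0)), ignore_attr = TRUE)
  expect_error(p_matrix(rt_unit(rbind(c(0, 0), c(1, 1)), "A", "A")),
               class = "pv_insufficient_sample_error")
})

test_that("difference vectors are centroid differences with 3-4-5 lengths", {
  uA <- fixed_unit(c(0, 0), "A", "A")
  uB <- fixed_unit(c(3, 4), "A", "B")
  v <- difference_vector(uA, uB, "plasticity_A")
  expect_equal(as.numeric(v), c(3, 4))
  expect_equal(sqrt(sum(v^2)), 5)
  expect_equal(as.numeric(difference_vector(uA, uA, "total_difference")),
               c(0, 0))
  u3 <- fixed_unit(c(0, 0, 0), "B", "B")
  expect_error(difference_vector(uA, u3, "evolutionary_divergence"),
               class = "pv_structure_error")
})

test_that("directed and undirected angles reproduce analytic values", {
  expect_equal(angle_directed(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_directed(c(1, 0), c(-1, 0)), 180)
  expect_equal(angle_directed(c(1, 0), c(1, 1)), 45)
  expect_equal(angle_undirected(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_undirected(c(1, 0), c(-1, 0)), 0)
  expect_equal(angle_undirected(c(1, 1) / sqrt(2), c(1, 0)), 45)
  expect_error(angle_directed(c(0, 0), c(1, 0)),
               class = "pv_undefined_angle_error")
  expect_error(angle_undirected(c(1, 0), c(0, 0)),
               class = "pv_undefined_angle_error")
})

test_that("angle identities hold on random vectors", {
  set.seed(21)
  for (i in 1:50) {
    d <- sample(2:6, 1)
    v <- rnorm(d); w <- rnorm(d)
    a <- angle_directed(v, w)
    expect_equal(angle_directed(w, v), a, tolerance = 1e-10)
    expect_equal(angle_directed(3.7 * v, 0.2 * w), a, tolerance = 1e-10)
    expect_equal(angle_directed(v, -w), 180 - a, tolerance = 1e-10)
    expect_equal(angle_undirected(v, w), min(a, 180 - a), tolerance = 1e-10)
  }
})

test_that("eigendecomposition is deterministic and reconstructs P", {
  e <- eigen_axes(diag(c(4, 1)))
  expect_equal(e$values, c(4, 1))
  expect_equal(e$vectors[, 1], c(1, 0))

  # documented tie rule on the identity
  e_id <- eigen_axes(diag(2))
  expect_equal(e_id$values, c(1, 1))
  expect_equal(e_id$vectors[, 1], c(1, 0))

  P <- random_psd(3, seed = 5)
  e3 <- eigen_axes(P)
  expect_true(all(diff(e3$values) <= 0))
  recon <- Reduce(`+`, lapply(1:3, function(i)
    e3$values[i] * tcrossprod(e3$vectors[, i])))
  expect_equal(recon, P, tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) expect_gt(max(e3$vectors[, j]), 0)
})

test_that("eigen shape ratio spans sphere to needle", {
  expect_equal(eigen_ratio(diag(2)), 1)
  expect_equal(eigen_ratio(diag(c(4, 1))), 0.25)
  v <- c(2, 1) / sqrt(5)
  expect_equal(eigen_ratio(tcrossprod(v)), 0, tolerance = 1e-12)
  expect_error(eigen_ratio(matrix(0, 2, 2)),
               class = "pv_degenerate_matrix_error")
})

test_that("projection fraction handles undershoot, overshoot and opposition", {
  expect_equal(projection_fraction(c(0.5, 0), c(1, 0)), 50)
  expect_equal(projection_fraction(c(2, 0), c(1, 0)), 200)
  expect_equal(projection_fraction(c(-1, 0), c(1, 0)), -100)
  expect_error(projection_fraction(c(1, 0), c(0, 0)),
               class = "pv_undefined_angle_error")
})

test_that("alignment classification follows the angle/projection rule", {
  expect_equal(classify_alignment(120, -40), "opposite")
  expect_equal(classify_alignment(30, 200), "overshoot")
  expect_equal(classify_alignment(30, 60), "undershoot")
  expect_equal(classify_alignment(90, 0), "undershoot")

  # mutual consistency: opposite <=> negative projection <=> angle > 90
  set.seed(31)
  for (i in 1:100) {
    d <- sample(2:5, 1)
    p <- rnorm(d); t <- rnorm(d)
    ang <- angle_directed(p, t)
    frac <- projection_fraction(p, t)
    expect_equal(frac < 0, ang > 90)
    expect_equal(classify_alignment(ang, frac) == "opposite", ang > 90)
  }
})

test_that("log length difference and variance change match arithmetic", {
  expect_equal(log_length_difference(c(1, 1), c(1, 1)), 0)
  expect_equal(log_length_difference(exp(1) * c(0, 2), c(0, 2)), 1)
  expect_equal(log_length_difference(c(3, 4), c(1, 0)), log(5))
  expect_equal(variance_change(diag(2), diag(2)), 0)
  expect_equal(variance_change(diag(c(1.4, 0.8)), diag(c(1.1, 0.9))), 10)
  expect_equal(variance_change(diag(2), diag(c(0.5, 0.5))), 100)
  expect_equal(variance_change(diag(c(1.4, 0.8)), diag(c(1.1, 0.9)),
                               scale = "log"), log(1.1))
  expect_error(variance_change(diag(2), matrix(0, 2, 2)),
               class = "pv_degenerate_matrix_error")
})

test_that("comparison_geometry reproduces constructed configurations", {
  # mirrored plasticity: anti-parallel vectors, angle 180
  comp <- toy_comparison(AinA = c(0, 0), AinB = c(1, 0),
                         BinB = c(1, 0.4), BinA = c(0, 0.4))
  g <- comparison_geometry(standardize_traits(comp))
  expect_equal(unname(g$stats["angle_pp"]), 180)

  # total difference equal to plasticity: angle 0, projection 100%
  comp2 <- toy_comparison(AinA = c(0, 0), AinB = c(1, 0.5),
                          BinB = c(1, 0.5), BinA = c(0.2, 0.1))
  g2 <- comparison_geometry(standardize_traits(comp2))
  expect_equal(unname(g2$stats["angle_pt"]), 0, tolerance = 1e-9)
  expect_equal(unname(g2$stats["projection_pct"]), 100, tolerance = 1e-9)
  expect_equal(unname(g2$stats["angle_pe"]), NA_real_)

  expect_equal(g$classification, "undershoot")
  expect_named(g$eigen_ratios, c("AinA", "AinB", "BinB", "BinA"))
})

test_that("large-sample estimates converge to generator truth", {
  gen <- generate_comparison(generator_spec(
    d_traits = 3, n_per_unit = 10000,
    plasticity_A = c(1, 0, 0),
    divergence = c(cos(pi / 3), sin(pi / 3), 0) * 0.8,
    P_eigenvalues = rep(0.5, 3),  # spherical: angles survive standardization
    seed = 77))
  # angle between plasticity and divergence set to 60 degrees
  expect_equal(unname(gen$truth$stats["angle_pe"]), 60, tolerance = 1e-9)
  g <- comparison_geometry(standardize_traits(gen$comparison))
  expect_lt(abs(g$stats["angle_pe"] - 60), 2)
  expect_lt(abs(g$stats["angle_pt"] - gen$truth$stats["angle_pt"]), 2)
  expect_lt(abs(g$stats["projection_pct"] -
                  gen$truth$stats["projection_pct"]), 5)
})

test_that("geometry_table emits one labelled row per comparison", {
  tab <- geometry_table(list(toy_comparison(comparison_id = "c1"),
                             toy_comparison(comparison_id = "c2",
                                            BinB = c(2, 1), BinA = c(1, 1))))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("angle_pp", "angle_pt", "classification",
                    "plasticity_A", "eigen_ratio_AinB") %in% names(tab)))
})
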