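# Vector geometry of a reciprocal transplant comparison: centroids,
# P-matrices, the four named vectors, and every scalar statistic defined on
# them. Angles are computed in radians with the dot product clipped to
# [-1, 1] and reported in degrees.
#
# Vector conventions (population A ancestral, B derived):
#   plasticity_A           AinA -> AinB
#   plasticity_B           BinB -> BinA
#   total_difference       AinA -> BinB
#   evolutionary_divergence AinB -> BinB
# With these conventions "similar plasticity in the two populations" shows
# up as an angle between the plasticity vectors near 180 degrees
# (anti-parallel), because the two vectors run home -> away in opposite
# environmental directions.

#' Multivariate centroid of an experimental unit
#'
#' @param unit An [rt_unit()].
#' @return Numeric vector of trait means.
#' @export
centroid <- function(unit) {
  colMeans(unit$individuals)
}

#' Phenotypic covariance matrix (P-matrix) of an experimental unit
#'
#' Sample covariance with denominator `n - 1`. Requires `n >= 3` so that
#' the Monte Carlo resampling of the matrix is meaningful.
#'
#' @param unit An [rt_unit()].
#' @return A `d x d` covariance matrix with attribute `n`.
#' @export
p_matrix <- function(unit) {
  if (unit$n < 3)
    pv_stop("pv_insufficient_sample_error",
            "P-matrix needs n >= 3 individuals, got %d", unit$n)
  P <- stats::cov(unit$individuals)
  attr(P, "n") <- unit$n
  P
}

#' Centroid-difference vector between two experimental units
#'
#' @param from,to [rt_unit()] objects from the same comparison.
#' @param kind Label for the vector, one of `"plasticity_A"`,
#'   `"plasticity_B"`, `"total_difference"`, `"evolutionary_divergence"`.
#' @return `centroid(to) - centroid(from)` with attribute `kind`.
#' @export
difference_vector <- function(from, to, kind = c("plasticity_A", "plasticity_B",
                                                 "total_difference",
                                                 "evolutionary_divergence")) {
  kind <- match.arg(kind)
  c_from <- centroid(from); c_to <- centroid(to)
  if (length(c_from) != length(c_to))
    pv_stop("pv_structure_error", "units have mismatched trait dimensions")
  v <- c_to - c_from
  attr(v, "kind") <- kind
  v
}

#' Angle between two directed vectors, in degrees
#'
#' `acos` of the clipped normalized dot product; range `[0, 180]`.
#'
#' @param v1,v2 Numeric vectors of equal length, both nonzero.
#' @param tol Vectors with norm below `tol` are rejected as undefined.
#' @export
angle_directed <- function(v1, v2, tol = 1e-12) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= tol || n2 <= tol)
    pv_stop("pv_undefined_angle_error",
            "angle undefined: vector with (near-)zero length")
  deg(acos(clip_unit(sum(v1 * v2) / (n1 * n2))))
}

#' Angle between an undirected axis and a vector, in degrees
#'
#' Eigenvectors carry no sign, so the angle folds at 90:
#' `acos(|cos|)`; range `[0, 90]`. 45 degrees is the random expectation in
#' two dimensions.
#'
#' @param axis,v Numeric vectors of equal length; `v` nonzero.
#' @inheritParams angle_directed
#' @export
angle_undirected <- function(axis, v, tol = 1e-12) {
  n1 <- sqrt(sum(axis^2)); n2 <- sqrt(sum(v^2))
  if (n1 <= tol || n2 <= tol)
    pv_stop("pv_undefined_angle_error",
            "angle undefined: vector with (near-)zero length")
  deg(acos(clip_unit(abs(sum(axis * v)) / (n1 * n2))))
}

#' Eigendecomposition of a P-matrix with deterministic sign and tie rules
#'
#' Eigenvalues are returned in descending order. Each eigenvector is
#' sign-normalized so that its largest-magnitude component is positive;
#' among equal-magnitude candidates (exact ties) the axis with the largest
#' loading on the first trait is preferred. Small negative eigenvalues from
#' roundoff are clipped to zero.
#'
#' @param P Symmetric positive semi-definite matrix.
#' @return List with `values` (descending) and `vectors` (columns,
#'   unit-norm, sign-normalized).
#' @export
eigen_axes <- function(P) {
  if (!is_square_symmetric(P, tol = 1e-10))
    pv_stop("pv_validation_error", "P must be a symmetric matrix")
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10)
    pv_stop("pv_validation_error",
            "P is not positive semi-definite (min eigenvalue %.3e)",
            min(e$values))
  e$values <- pmax(e$values, 0)
  V <- e$vectors
  # within groups of (numerically) tied eigenvalues, order axes by their
  # loading on the first trait so the decomposition is deterministic
  grp <- cumsum(c(TRUE, diff(e$values) < -1e-12 * max(e$values, 1)))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1)
      V[, idx] <- V[, idx[order(-abs(V[1, idx]))]]
  }
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    i_max <- which.max(abs(v))
    if (abs(abs(v[1]) - abs(v[i_max])) < 1e-12) i_max <- 1L
    if (v[i_max] < 0) v <- -v
    V[, j] <- v
  }
  list(values = e$values, vectors = V)
}

#' First eigenvector (Pmax) of a P-matrix
#'
#' @inheritParams eigen_axes
#' @return Unit-norm axis with attribute `eigenvalue`.
#' @export
p_max <- function(P) {
  e <- eigen_axes(P)
  ax <- e$vectors[, 1]
  attr(ax, "eigenvalue") <- e$values[1]
  ax
}

#' Eigenvalue shape ratio lambda2 / lambda1 of a P-matrix
#'
#' 1 for a spherical distribution, 0 for a rank-1 (needle) distribution.
#'
#' @inheritParams eigen_axes
#' @export
eigen_ratio <- function(P) {
  e <- eigen_axes(P)
  if (e$values[1] <= 0)
    pv_stop("pv_degenerate_matrix_error", "leading eigenvalue is zero")
  e$values[2] / e$values[1]
}

#' Signed projection of the plasticity vector onto the total difference
#'
#' `100 * (plasticity . t_hat) / ||total||` where `t_hat` is the unit vector
#' along the total phenotypic difference: the percentage of the population
#' difference accounted for by plasticity. Above 100 the plastic response
#' overshoots the locally adapted phenotype; negative values mean the
#' response points away from it.
#'
#' @param plasticity,total Numeric vectors; `total` nonzero.
#' @inheritParams angle_directed
#' @return Signed percentage.
#' @export
projection_fraction <- function(plasticity, total, tol = 1e-12) {
  nt <- sqrt(sum(total^2))
  if (nt <= tol)
    pv_stop("pv_undefined_angle_error",
            "projection undefined: zero total-difference vector")
  100 * sum(plasticity * total) / (nt * nt)
}

#' Classify a plasticity vector against the total phenotypic difference
#'
#' `"opposite"` when the angle exceeds 90 degrees; otherwise `"overshoot"`
#' when the projection exceeds 100% of the total difference, else
#' `"undershoot"`. An angle of exactly 90 (projection 0) counts as
#' undershoot.
#'
#' @param angle Angle in degrees, `[0, 180]`.
#' @param fraction Signed projection percentage.
#' @return One of `"opposite"`, `"overshoot"`, `"undershoot"`.
#' @export
classify_alignment <- function(angle, fraction) {
  stopifnot(angle >= 0, angle <= 180)
  if (angle > 90) "opposite"
  else if (fraction > 100) "overshoot"
  else "undershoot"
}

#' Log difference of two vector lengths
#'
#' `ln ||vB|| - ln ||vA||`; 0 when the two plasticity vectors have equal
#' standardized magnitude.
#'
#' @param vB,vA Nonzero numeric vectors.
#' @inheritParams angle_directed
#' @export
log_length_difference <- function(vB, vA, tol = 1e-12) {
  nB <- sqrt(sum(vB^2)); nA <- sqrt(sum(vA^2))
  if (nB <= tol || nA <= tol)
    pv_stop("pv_undefined_angle_error",
            "log length difference undefined for zero-length vector")
  log(nB) - log(nA)
}

#' Change in total phenotypic variation between two units
#'
#' Total variation is summarized by the trace of the (standardized)
#' P-matrix, which is invariant to orthogonal rotation of trait space. The
#' change is computed as the log trace ratio (the scale used for pooling)
#' and reported as a percentage by default.
#'
#' @param P_foreign,P_home P-matrices of equal dimension.
#' @param scale `"percent"` for `100 * (trace ratio - 1)`, `"log"` for
#'   `ln(trace ratio)`.
#' @export
variance_change <- function(P_foreign, P_home, scale = c("percent", "log")) {
  scale <- match.arg(scale)
  tr_f <- sum(diag(P_foreign)); tr_h <- sum(diag(P_home))
  if (tr_h <= 0)
    pv_stop("pv_degenerate_matrix_error", "home unit has zero total variance")
  lr <- log(tr_f / tr_h)
  if (scale == "log") lr else 100 * (exp(lr) - 1)
}

#' Names of the per-comparison effect-size statistics
#'
#' `angle_pp`, `angle_pt`, `angle_pe` are directed angles in degrees
#' (0-180); `angle_pmax_e`, `angle_pmax_p` are undirected angles (0-90);
#' `projection_pct` is the signed projection percentage; `log_length_diff`
#' the log plasticity-length difference (B minus A); `log_var_ratio_A` /
#' `log_var_ratio_B` the log trace ratios of the foreign vs home P-matrix.
#'
#' @export
EFFECT_NAMES <- c("angle_pp", "angle_pt", "angle_pe", "angle_pmax_e",
                  "angle_pmax_p", "projection_pct", "log_length_diff",
                  "log_var_ratio_A", "log_var_ratio_B")

# Statistics computed from centroids only (no eigen work needed).
CENTROID_ONLY_NAMES <- c("angle_pp", "angle_pt", "angle_pe",
                         "projection_pct", "log_length_diff")

geometry_centroids <- function(comp) {
  lapply(comp$units, centroid)
}

# Core scalar computation from the four centroids (and optionally the
# P-matrices). Returns a named numeric vector with NA for undefined
# statistics; callers decide whether NA is an error.
geometry_stats <- function(cen, P = NULL,
                           names = EFFECT_NAMES, tol = 1e-12) {
  pA <- cen$AinB - cen$AinA
  pB <- cen$BinA - cen$BinB
  tot <- cen$BinB - cen$AinA
  ed <- cen$BinB - cen$AinB
  nrm <- function(v) sqrt(sum(v^2))
  ang <- function(u, v) {
    nu <- nrm(u); nv <- nrm(v)
    if (nu <= tol || nv <= tol) return(NA_real_)
    deg(acos(clip_unit(sum(u * v) / (nu * nv))))
  }
  uang <- function(a, v) {
    na <- nrm(a); nv <- nrm(v)
    if (na <= tol || nv <= tol) return(NA_real_)
    deg(acos(clip_unit(abs(sum(a * v)) / (na * nv))))
  }
  out <- stats::setNames(rep(NA_real_, length(names)), names)
  if ("angle_pp" %in% names) out["angle_pp"] <- ang(pA, pB)
  if ("angle_pt" %in% names) out["angle_pt"] <- ang(pA, tot)
  if ("angle_pe" %in% names) out["angle_pe"] <- ang(pA, ed)
  if ("projection_pct" %in% names) {
    nt <- nrm(tot)
    out["projection_pct"] <-
      if (nt <= tol) NA_real_ else 100 * sum(pA * tot) / (nt * nt)
  }
  if ("log_length_diff" %in% names) {
    nA <- nrm(pA); nB <- nrm(pB)
    out["log_length_diff"] <-
      if (nA <= tol || nB <= tol) NA_real_ else log(nB) - log(nA)
  }
  if (!is.null(P)) {
    if ("angle_pmax_e" %in% names) {
      e1 <- eigen((P$AinB + t(P$AinB)) / 2, symmetric = TRUE)$vectors[, 1]
      out["angle_pmax_e"] <- uang(e1, ed)
    }
    if ("angle_pmax_p" %in% names) {
      e1 <- eigen((P$AinA + t(P$AinA)) / 2, symmetric = TRUE)$vectors[, 1]
      out["angle_pmax_p"] <- uang(e1, pA)
    }
    if ("log_var_ratio_A" %in% names)
      out["log_var_ratio_A"] <- log(sum(diag(P$AinB)) / sum(diag(P$AinA)))
    if ("log_var_ratio_B" %in% names)
      out["log_var_ratio_B"] <- log(sum(diag(P$BinA)) / sum(diag(P$BinB)))
  }
  out
}

#' All point-estimate geometry statistics for one comparison
#'
#' Computes the four named vectors and every scalar statistic defined on
#' them: the angle between the two plasticity vectors (`angle_pp`; near 180
#' when the populations respond alike), between plasticity of A and the
#' total phenotypic difference (`angle_pt`), between plasticity of A and
#' evolutionary divergence (`angle_pe`), the undirected angles of Pmax
#' (AinB) with divergence and Pmax (AinA) with plasticity, the signed
#' projection percentage and its overshoot/undershoot/opposite
#' classification, the log length difference of the plasticity vectors, the
#' log trace-ratio variance changes (AinB vs AinA, BinA vs BinB), and the
#' eigenvalue shape ratio of each unit's P-matrix.
#'
#' Undefined components (zero-length vectors) are recorded as `NA`, not
#' raised as errors.
#'
#' @param comp A standardized [rt_comparison()].
#' @return An object of class `rt_geometry`: list with `vectors`, `stats`
#'   (named numeric), `classification`, `eigen_ratios`, `var_change_pct`.
#' @export
comparison_geometry <- function(comp) {
  stopifnot(inherits(comp, "rt_comparison"))
  cen <- geometry_centroids(comp)
  P <- lapply(comp$units, function(u) p_matrix(u))
  stats_vec <- geometry_stats(cen, P)
  vectors <- list(
    plasticity_A = cen$AinB - cen$AinA,
    plasticity_B = cen$BinA - cen$BinB,
    total_difference = cen$BinB - cen$AinA,
    evolutionary_divergence = cen$BinB - cen$AinB
  )
  classification <-
    if (is.na(stats_vec["angle_pt"]) || is.na(stats_vec["projection_pct"]))
      NA_character_
    else classify_alignment(stats_vec[["angle_pt"]],
                            stats_vec[["projection_pct"]])
  structure(
    list(
      study_id = comp$study_id, comparison_id = comp$comparison_id,
      species = comp$species,
      centroids = cen, P = P, vectors = vectors,
      stats = stats_vec, classification = classification,
      eigen_ratios = vapply(P, eigen_ratio, numeric(1)),
      var_change_pct = c(
        A = variance_change(P$AinB, P$AinA),
        B = variance_change(P$BinA, P$BinB)
      )
    ),
    class = "rt_geometry"
  )
}

#' @export
print.rt_geometry <- function(x, ...) {
  cat(sprintf("<rt_geometry %s/%s>\n", x$study_id, x$comparison_id))
  s <- x$stats
  cat(sprintf("  angle_pp %.2f  angle_pt %.2f  angle_pe %.2f  angle_pmax_e %.2f\n",
              s["angle_pp"], s["angle_pt"], s["angle_pe"], s["angle_pmax_e"]))
  cat(sprintf("  projection %.1f%%  (%s)  log length diff %+.4f\n",
              s["projection_pct"], x$classification, s["log_length_diff"]))
  invisible(x)
}

#' Effect-size table for a set of comparisons
#'
#' One row per comparison with every named statistic, the classification and
#' the component vector coordinates (as comma-separated strings).
#'
#' @param geoms List of `rt_geometry` objects (or comparisons, which are
#'   standardized and processed first).
#' @return A data frame.
#' @export
geometry_table <- function(geoms) {
  geoms <- lapply(geoms, function(g) {
    if (inherits(g, "rt_comparison"))
      comparison_geometry(if (g$standardized) g else standardize_traits(g))
    else g
  })
  do.call(rbind, lapply(geoms, function(g) {
    row <- data.frame(study_id = g$study_id, comparison_id = g$comparison_id,
                      species = g$species, t(g$stats),
                      classification = g$classification,
                      stringsAsFactors = FALSE)
    for (nm in names(g$vectors))
      row[[nm]] <- paste(signif(g$vectors[[nm]], 8), collapse = ",")
    for (nm in names(g$eigen_ratios))
      row[[paste0("eigen_ratio_", nm)]] <- g$eigen_ratios[[nm]]
    row
  }))
}
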