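# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
pv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "plastvec_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Deterministic 31-bit hash of a string, used to derive per-comparison RNG
# seeds from a master seed. Plain polynomial rolling hash; stability across
# platforms matters more than dispersion quality here.
str_hash31 <- function(x) {
  h <- 0
  for (k in utf8ToInt(as.character(x))) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

#' Derive a child RNG seed from a master seed and a string label
#' @keywords internal
derive_seed <- function(master_seed, label) {
  as.integer((as.numeric(master_seed) * 48271 + str_hash31(label)) %% 2147483647)
}

is_square_symmetric <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Clip to [-1, 1] before acos; guards against |cos| = 1 + eps roundoff.
clip_unit <- function(x) pmin(1, pmax(-1, x))

deg <- function(rad) rad * 180 / pi
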