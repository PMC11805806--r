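#' @importFrom rlang abort warn inform %||%
#' @importFrom stats runif rnorm setNames
NULL

# Validate and normalize an interaction matrix: square, numeric, finite.
as_interaction_matrix <- function(A, arg = "A") {
  if (is.data.frame(A)) A <- as.matrix(A)
  if (!is.matrix(A) || !is.numeric(A)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be square, got %d x %d.", arg, nrow(A), ncol(A)))
  }
  if (nrow(A) < 1L) abort(sprintf("`%s` must have at least one species.", arg))
  if (!all(is.finite(A))) abort(sprintf("`%s` contains non-finite entries.", arg))
  unname(A)
}

# Growth-rate vector; a scalar is recycled to length n (all-ones default
# mirrors the convention used throughout for the worked examples).
as_growth_rates <- function(b, n, arg = "b") {
  if (is.null(b)) b <- 1
  if (!is.numeric(b)) abort(sprintf("`%s` must be numeric.", arg))
  if (length(b) == 1L) b <- rep(b, n)
  if (length(b) != n) {
    abort(sprintf("`%s` has length %d but the matrix has %d species.",
                  arg, length(b), n))
  }
  if (!all(is.finite(b))) abort(sprintf("`%s` contains non-finite entries.", arg))
  unname(as.double(b))
}

# "(1,2,3)" style community labels, "()" for the empty community.
community_label <- function(members) {
  paste0("(", paste(members, collapse = ","), ")")
}

# Evaluate `expr` under a temporary seed when one is given, otherwise use the
# current RNG stream (lets experiments drive many calls from one master seed).
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

largest_eigenvalue_sym <- function(M) {
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}
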