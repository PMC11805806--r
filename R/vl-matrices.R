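#' Build an interaction matrix from a Volterra-Lyapunov decomposition
#'
#' A real matrix \eqn{A} is Volterra-Lyapunov (VL) stable when some positive
#' diagonal matrix \eqn{H} makes \eqn{HA + A^T H} negative definite. Every
#' such matrix, and only such matrices, can be written \eqn{A = H(S + J)} with
#' \eqn{H} positive diagonal, \eqn{S} symmetric stable and \eqn{J}
#' antisymmetric. `vl_compose()` assembles \eqn{A} from the triple, so the
#' result is VL stable by construction, with the identity
#' \eqn{H^{-1}A + A^T H^{-1} = 2S} as its certificate.
#'
#' @param decomp A VL decomposition as returned by [vl_decomposition()] or
#'   [random_vl_stable()].
#' @return The interaction matrix `A = H (S + J)` (plain numeric matrix).
#' @examples
#' d <- vl_decomposition(
#'   h = c(1, 1, 1),
#'   s = -0.5 * diag(3),
#'   jmat = rbind(c(0, -1, 1), c(1, 0, -1), c(-1, 1, 0))
#' )
#' vl_compose(d) # the rock-paper-scissors matrix with diagonal -0.5
#' @seealso [vl_decomposition()], [random_vl_stable()], [detect_vl()]
#' @export
vl_compose <- function(decomp) {
  if (!inherits(decomp, "vl_decomposition")) {
    decomp <- vl_decomposition(decomp$h, decomp$s, decomp$jmat)
  }
  decomp$h * (decomp$s + decomp$jmat) # diag(h) %*% M == row scaling
}

#' Construct and validate a Volterra-Lyapunov decomposition
#'
#' Validates the triple \eqn{(H, S, J)}: `h` strictly positive, `s` symmetric
#' with strictly negative largest eigenvalue, `jmat` antisymmetric. Symmetry
#' and antisymmetry are tested with absolute tolerance `1e-12` and the stored
#' matrices are exactly (anti)symmetrized on ingest so later algebra cannot
#' drift.
#'
#' @param h Positive numeric vector, the diagonal of \eqn{H}.
#' @param s Symmetric stable matrix \eqn{S}.
#' @param jmat Antisymmetric matrix \eqn{J}.
#' @return An object of class `vl_decomposition`: a list with elements `h`,
#'   `s`, `jmat` and `n`.
#' @export
vl_decomposition <- function(h, s, jmat) {
  h <- as.double(h)
  n <- length(h)
  if (n < 1L || !all(is.finite(h))) abort("`h` must be finite and non-empty.")
  if (any(h <= 0)) abort("`h` must be strictly positive on the diagonal of H.")
  s <- as_interaction_matrix(s, "s")
  jmat <- as_interaction_matrix(jmat, "jmat")
  if (nrow(s) != n || nrow(jmat) != n) {
    abort("`h`, `s` and `jmat` must share one dimension.")
  }
  tol <- 1e-12
  if (max(abs(s - t(s))) > tol) abort("`s` must be symmetric (tolerance 1e-12).")
  if (max(abs(jmat + t(jmat))) > tol) {
    abort("`jmat` must be antisymmetric (tolerance 1e-12).")
  }
  s <- (s + t(s)) / 2
  jmat <- (jmat - t(jmat)) / 2
  if (largest_eigenvalue_sym(s) >= 0) {
    abort("`s` must be stable: its largest eigenvalue must be strictly negative.")
  }
  structure(list(h = h, s = s, jmat = jmat, n = n),
            class = "vl_decomposition")
}

#' @export
print.vl_decomposition <- function(x, ...) {
  cat(sprintf("<vl_decomposition> n = %d, lambda_max(S) = %.4g\n",
              x$n, largest_eigenvalue_sym(x$s)))
  invisible(x)
}

#' Generate a random Volterra-Lyapunov stable matrix
#'
#' Draws a random positive diagonal \eqn{H}, an antisymmetric
#' \eqn{J = K - K^T} from a random \eqn{K}, and a symmetric stable
#' \eqn{S = F + F^T - \alpha I} from a random \eqn{F}, where
#' \eqn{\alpha = \max(0, \lambda_{max}(F + F^T)) + } `margin` guarantees
#' strict stability of \eqn{S}. The returned matrix \eqn{A = H(S+J)} is VL
#' stable by construction, which makes the generator a ground-truth source for
#' benchmarking the numerical detector.
#'
#' The entry distributions are choices (uniform \eqn{H} on `h_range`, Gaussian
#' `K` and `F`); all scales are exposed as arguments.
#'
#' @param n Number of species (`n >= 1`).
#' @param seed Optional integer seed; when given the draw is bit-reproducible
#'   and the caller's RNG state is untouched.
#' @param h_range Range of the uniform draw for the diagonal of \eqn{H}.
#' @param sd_k,sd_f Standard deviations of the Gaussian entries of \eqn{K} and
#'   \eqn{F}.
#' @param margin Stability margin added to the diagonal shift \eqn{\alpha}.
#' @return A list with elements `A` (the matrix) and `decomposition` (the
#'   generating `vl_decomposition`).
#' @examples
#' sys <- random_vl_stable(5, seed = 1)
#' detect_vl(sys$A, seed = 1)$verdict
#' @export
random_vl_stable <- function(n, seed = NULL, h_range = c(0.1, 1.1),
                             sd_k = 1, sd_f = 1, margin = 0.5) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be an integer >= 1.")
  if (margin <= 0) abort("`margin` must be positive.")
  with_seed_if(seed, {
    h <- runif(n, h_range[1], h_range[2])
    K <- matrix(rnorm(n * n, sd = sd_k), n, n)
    jmat <- K - t(K)
    F0 <- matrix(rnorm(n * n, sd = sd_f), n, n)
    s0 <- F0 + t(F0)
    alpha <- max(0, largest_eigenvalue_sym(s0)) + margin
    s <- s0 - alpha * diag(n)
    decomp <- vl_decomposition(h, s, jmat)
    list(A = vl_compose(decomp), decomposition = decomp)
  })
}

#' Split a matrix into its symmetric and antisymmetric parts
#'
#' Returns \eqn{A_S = (A + A^T)/2} and \eqn{A_J = (A - A^T)/2}, so that
#' \eqn{A = A_S + A_J}. The balance between the two parts governs cyclic
#' behaviour: antisymmetric (predator-prey-like, rock-paper-scissors-like)
#' interactions promote heteroclinic cycles, symmetric ones inhibit them.
#'
#' @param A Square numeric matrix.
#' @return A list with elements `a_s` (symmetric part) and `a_j`
#'   (antisymmetric part).
#' @export
symmetry_split <- function(A) {
  A <- as_interaction_matrix(A)
  list(a_s = (A + t(A)) / 2, a_j = (A - t(A)) / 2)
}

#' Entrywise matrix norm and the antisymmetric-to-symmetric ratio
#'
#' `entrywise_norm()` is the sum of the absolute values of all entries,
#' \eqn{|M| = \sum_{ij} |m_{ij}|}. `asym_sym_ratio()` is \eqn{|A_J|/|A_S|}
#' for the symmetric/antisymmetric split of `A`; it errors when the symmetric
#' part vanishes (the ratio is then undefined).
#'
#' @param M,A Square numeric matrix.
#' @return A non-negative scalar.
#' @export
entrywise_norm <- function(M) {
  M <- as_interaction_matrix(M, "M")
  sum(abs(M))
}

#' @rdname entrywise_norm
#' @export
asym_sym_ratio <- function(A) {
  sp <- symmetry_split(A)
  ns <- sum(abs(sp$a_s))
  if (ns == 0) {
    abort("asym/sym ratio undefined: the symmetric part has entrywise norm 0.")
  }
  sum(abs(sp$a_j)) / ns
}

#' Row norm and strong diagonal dominance
#'
#' `row_norm()` returns \eqn{\max_i \sum_j |a_{ij}|}. `is_row_dd()` tests
#' strong row diagonal dominance, \eqn{|a_{ii}| > \sum_{j \ne i} |a_{ij}|}
#' for every row; `is_col_dd()` is the analogue over columns. Either form of
#' dominance excludes invasion-graph cycles among single-species communities.
#'
#' @param A Square numeric matrix.
#' @return `row_norm()`: a non-negative scalar; the predicates: a single
#'   logical.
#' @export
row_norm <- function(A) {
  A <- as_interaction_matrix(A)
  max(rowSums(abs(A)))
}

#' @rdname row_norm
#' @export
is_row_dd <- function(A) {
  A <- as_interaction_matrix(A)
  all(2 * abs(diag(A)) > rowSums(abs(A)))
}

#' @rdname row_norm
#' @export
is_col_dd <- function(A) {
  A <- as_interaction_matrix(A)
  all(2 * abs(diag(A)) > colSums(abs(A)))
}

#' Canonical interaction matrices with cyclic dynamics
#'
#' Printed reference systems, all with default growth rates equal to one:
#' \describe{
#'   \item{`may_leonard(alpha, beta)`}{The 3-species May-Leonard competition
#'     matrix with `-1` diagonal and off-diagonal `-beta`, `-alpha` in cyclic
#'     arrangement. The cyclic (heteroclinic) regime is
#'     `0 < alpha < 1 < beta`, `alpha * beta < 1`, `alpha + beta < 2`;
#'     parameters outside it are accepted with a warning, since the
#'     constraints only place the system in that regime.}
#'   \item{`rps3(d)`}{Rock-paper-scissors: diagonal `d` plus the cyclic
#'     antisymmetric pattern on 3 species. Cycles exist for `d` in `(-1, 0)`.}
#'   \item{`rpsls5(d)`}{Rock-paper-scissors-lizard-spock: the 5-species
#'     generalization, diagonal `d` plus a pentagram antisymmetric pattern.}
#'   \item{`cycle4(d)`}{A 4-species system whose invasion graph carries a
#'     mixed-dimension cycle `{1} -> {2,3} -> {4} -> {1}` (a two-species
#'     invasion of a single-species state).}
#' }
#'
#' @param alpha,beta May-Leonard competition strengths.
#' @param d Self-regulation (diagonal) coefficient, `d < 0`.
#' @return The interaction matrix.
#' @examples
#' rps3(-0.5)
#' enumerate_admissible(rpsls5(-0.5), b = 1)
#' @export
may_leonard <- function(alpha, beta) {
  if (!(alpha > 0 && alpha < 1 && beta > 1 && alpha * beta < 1 &&
        alpha + beta < 2)) {
    warn(paste0(
      "may_leonard parameters outside the cyclic regime ",
      "(0 < alpha < 1 < beta, alpha*beta < 1, alpha + beta < 2); ",
      "the matrix is returned anyway."
    ))
  }
  rbind(
    c(-1, -beta, -alpha),
    c(-alpha, -1, -beta),
    c(-beta, -alpha, -1)
  )
}

#' @rdname may_leonard
#' @export
rps3 <- function(d) {
  rbind(
    c(d, -1, 1),
    c(1, d, -1),
    c(-1, 1, d)
  )
}

#' @rdname may_leonard
#' @export
rpsls5 <- function(d) {
  rbind(
    c(d, -1, 1, -1, 1),
    c(1, d, -1, 1, -1),
    c(-1, 1, d, -1, 1),
    c(1, -1, 1, d, -1),
    c(-1, 1, -1, 1, d)
  )
}

#' @rdname may_leonard
#' @export
cycle4 <- function(d) {
  rbind(
    c(d, -1, -1, 1),
    c(1, d, 0, -1),
    c(1, 0, d, -1),
    c(-1, 1, 1, d)
  )
}
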