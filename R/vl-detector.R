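#' Objective function of the Volterra-Lyapunov stability test
#'
#' \eqn{\mathcal{O}(H)} is the largest eigenvalue of the symmetric matrix
#' \eqn{HA + A^T H} for a positive diagonal \eqn{H}. The matrix \eqn{A} is VL
#' stable iff this objective attains a strictly negative value somewhere on
#' the open box \eqn{h \in (0,1)^n} (scaling \eqn{h} by a positive constant
#' scales the objective, so restricting to the unit box loses nothing).
#'
#' @param A Square interaction matrix.
#' @param h Strictly positive numeric vector, the diagonal of \eqn{H}.
#' @return The largest eigenvalue of `diag(h) %*% A + t(A) %*% diag(h)`.
#' @export
vl_objective <- function(A, h) {
  A <- as_interaction_matrix(A)
  h <- as.double(h)
  if (length(h) != nrow(A)) abort("`h` must have one entry per species.")
  if (any(!is.finite(h)) || any(h <= 0)) abort("`h` must be strictly positive.")
  HA <- h * A
  largest_eigenvalue_sym(HA + t(HA))
}

# Objective + analytic (sub)gradient: with unit top eigenvector v,
# d lambda_max / d h_i = 2 v_i (A v)_i (exact where the eigenvalue is simple).
objective_with_grad <- function(A, h) {
  HA <- h * A
  e <- eigen(HA + t(HA), symmetric = TRUE)
  v <- e$vectors[, 1L]
  list(value = e$values[1L], grad = 2 * v * drop(A %*% v))
}

#' Verify a Volterra-Lyapunov stability certificate
#'
#' Recomputes the objective \eqn{\lambda_{max}(HA + A^T H)} at the certified
#' multiplier and checks that it is strictly negative. Independent of any
#' optimizer, so a verified certificate is a proof of VL stability up to
#' floating-point eigenvalue accuracy.
#'
#' @param A Square interaction matrix.
#' @param cert A certificate (list with element `h`) as found in
#'   [detect_vl()] results, or a bare positive vector `h`.
#' @return `TRUE` iff the recomputed objective is strictly negative.
#' @export
verify_certificate <- function(A, cert) {
  h <- if (is.list(cert)) cert$h else cert
  isTRUE(vl_objective(A, h) < 0)
}

new_detection_result <- function(verdict, certificate, n_starts_used,
                                 threshold, trace, method) {
  structure(
    list(verdict = verdict, certificate = certificate,
         n_starts_used = n_starts_used, threshold = threshold,
         trace = trace, method = method),
    class = "vl_detection"
  )
}

#' @export
print.vl_detection <- function(x, ...) {
  cat(sprintf("<vl_detection> verdict: %s (%s, %d start%s)\n",
              x$verdict, x$method, x$n_starts_used,
              if (x$n_starts_used == 1L) "" else "s"))
  if (!is.null(x$certificate)) {
    cat(sprintf("  certificate objective: %.6g\n", x$certificate$objective_value))
  }
  invisible(x)
}

# condition used to abort a local minimization as soon as the objective
# crosses the stopping threshold
early_stop_condition <- function(h, value) {
  structure(class = c("lv_vl_early_stop", "condition"),
            list(message = "objective below threshold", call = NULL,
                 h = h, value = value))
}

#' Numerical Volterra-Lyapunov stability test by multi-start minimization
#'
#' Minimizes the objective [vl_objective()] over positive diagonal multipliers
#' \eqn{h \in (0,1)^n} from up to `n_initial` pseudo-random starting points,
#' stopping at the first iterate whose objective falls below the (negative)
#' `threshold`. A `vl_stable` verdict always carries a certificate `h` that
#' passes [verify_certificate()], so the test has 100% precision: it declares
#' stability only when the matrix really is VL stable. The converse does not
#' hold -- local minima can hide a negative value -- so failure to certify is
#' reported as `inconclusive`, never as "unstable".
#'
#' The `n = 1` case is decided analytically (`a11 < 0`), bypassing
#' optimization.
#'
#' @param A Square interaction matrix.
#' @param n_initial Maximum number of optimizer starts (default 50).
#' @param threshold Negative stopping threshold for the objective
#'   (default `-1e-10`).
#' @param seed Optional integer seed for the starting points.
#' @param eps Box margin: optimization is constrained to
#'   `(eps, 1 - eps)^n`.
#' @return A `vl_detection` object: `verdict` (`"vl_stable"` or
#'   `"inconclusive"`), `certificate` (list with `h` and `objective_value`, or
#'   `NULL`), `n_starts_used`, `threshold`, and `trace` (best objective per
#'   start).
#' @examples
#' detect_vl(rps3(-0.5), seed = 1)
#' detect_vl(rbind(c(0, 1), c(1, 0)), n_initial = 5, seed = 1) # inconclusive
#' @seealso [detect_vl_dense()] for the deterministic dense-sequence variant.
#' @export
detect_vl <- function(A, n_initial = 50, threshold = -1e-10, seed = NULL,
                      eps = 1e-6) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  n_initial <- as.integer(n_initial)
  if (is.na(n_initial) || n_initial < 1L) abort("`n_initial` must be >= 1.")
  if (!is.finite(threshold) || threshold >= 0) {
    abort("`threshold` must be a strictly negative number.")
  }

  if (n == 1L) {
    if (A[1, 1] < 0) {
      cert <- list(h = 0.5, objective_value = A[1, 1])
      return(new_detection_result("vl_stable", cert, 0L, threshold,
                                  numeric(0), "analytic"))
    }
    return(new_detection_result("inconclusive", NULL, 0L, threshold,
                                numeric(0), "analytic"))
  }

  starts <- with_seed_if(seed, matrix(runif(n_initial * n), n_initial, n))
  trace <- numeric(0)
  for (k in seq_len(n_initial)) {
    h0 <- pmin(pmax(starts[k, ], eps), 1 - eps)
    hit <- NULL
    fn <- function(h) {
      val <- objective_with_grad(A, h)$value
      if (val < threshold) stop(early_stop_condition(h, val))
      val
    }
    gr <- function(h) objective_with_grad(A, h)$grad
    res <- tryCatch(
      stats::optim(h0, fn, gr, method = "L-BFGS-B",
                   lower = eps, upper = 1 - eps,
                   control = list(maxit = 200)),
      lv_vl_early_stop = function(c) c,
      error = function(e) NULL
    )
    if (inherits(res, "lv_vl_early_stop")) {
      hit <- list(h = res$h, objective_value = res$value)
      trace <- c(trace, res$value)
    } else if (!is.null(res)) {
      trace <- c(trace, res$value)
      if (res$value < threshold) {
        hit <- list(h = res$par, objective_value = res$value)
      }
    } else {
      trace <- c(trace, NA_real_)
    }
    if (!is.null(hit)) {
      return(new_detection_result("vl_stable", hit, k, threshold, trace,
                                  "multistart"))
    }
  }
  new_detection_result("inconclusive", NULL, n_initial, threshold, trace,
                       "multistart")
}

# Dyadic enumeration of (0,1)^n: level k contributes the grid points with
# coordinates i/2^k, i = 1..2^k-1, skipping points already seen at level k-1
# (all numerators even); within a level the order is lexicographic.
dyadic_points <- function(n, level) {
  num <- seq_len(2^level - 1)
  grid <- as.matrix(expand.grid(rep(list(num), n), KEEP.OUT.ATTRS = FALSE))
  # expand.grid varies the first factor fastest; flip to lexicographic order
  grid <- grid[, rev(seq_len(n)), drop = FALSE]
  if (level > 1L) {
    seen <- rowSums(grid %% 2 == 0) == n
    grid <- grid[!seen, , drop = FALSE]
  }
  ord <- do.call(order, lapply(seq_len(n), function(j) grid[, j]))
  grid[ord, , drop = FALSE] / 2^level
}

#' Dense-sequence semi-decision test for Volterra-Lyapunov stability
#'
#' Walks a fixed countable dense subset of \eqn{(0,1)^n} -- dyadic rationals
#' ordered by denominator level, then lexicographically -- and evaluates the
#' objective at each point, declaring `vl_stable` at the first strictly
#' negative value. If \eqn{A} is VL stable, the open region where the
#' objective is negative meets the dense sequence, so the walk halts; if it is
#' not, the walk never halts, hence the practical iteration cap (VL stability
#' is partially decidable).
#'
#' @param A Square interaction matrix.
#' @param max_iterations Cap on evaluated points (default `1e4`).
#' @return A `vl_detection` object, as in [detect_vl()].
#' @export
detect_vl_dense <- function(A, max_iterations = 1e4) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    abort("`max_iterations` must be >= 1.")
  }
  used <- 0L
  level <- 1L
  while (used < max_iterations) {
    pts <- dyadic_points(n, level)
    for (r in seq_len(nrow(pts))) {
      used <- used + 1L
      val <- vl_objective(A, pts[r, ])
      if (val < 0) {
        cert <- list(h = unname(pts[r, ]), objective_value = val)
        return(new_detection_result("vl_stable", cert, used, 0,
                                    numeric(0), "dense"))
      }
      if (used >= max_iterations) break
    }
    level <- level + 1L
  }
  new_detection_result("inconclusive", NULL, used, 0, numeric(0), "dense")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-start trace of a detection result
#'
#' @param x A `vl_detection` object.
#' @param ... Unused.
#' @return A tibble with one row per optimizer start (`start`, `objective`).
#' @export
tidy.vl_detection <- function(x, ...) {
  tibble::tibble(start = seq_along(x$trace), objective = x$trace)
}

#' One-row summary of a detection result
#'
#' @param x A `vl_detection` object.
#' @param ... Unused.
#' @return A one-row tibble with `verdict`, `certified_objective`,
#'   `n_starts_used`, `threshold` and `method`.
#' @export
glance.vl_detection <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    certified_objective = if (is.null(x$certificate)) NA_real_ else
      x$certificate$objective_value,
    n_starts_used = x$n_starts_used,
    threshold = x$threshold,
    method = x$method
  )
}
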