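#' Integrate the Lotka-Volterra dynamics
#'
#' Numerically solves \eqn{\dot u_i = u_i (b_i + \sum_j a_{ij} u_j)} on
#' `[0, t_final]` with an adaptive solver (`deSolve::ode`, `lsoda`).
#' Coordinates that start at exactly zero are removed from the integrated
#' subsystem rather than carried along as tiny values, so the faces of the
#' positive cone are invariant *exactly*: wall dynamics are the true
#' restricted subsystems. A norm cap guards against blow-up (which cannot
#' occur for VL stable matrices but protects against misuse).
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled).
#' @param u0 Nonnegative initial state.
#' @param t_final End time; defaults to `200 / |min(diag(A))|`.
#' @param n_steps Number of saved time points.
#' @param rtol,atol Solver tolerances.
#' @param method `deSolve` integration method; the default `"vode"` (adaptive
#'   BDF/Adams) stays robust when abundances decay to the bottom of the
#'   floating-point range, where `"lsoda"`'s dense-output interpolation can
#'   fail.
#' @param blowup_cap Error out if any state magnitude exceeds this.
#' @return An `lv_trajectory`: a tibble with column `time` and one column per
#'   species (`u1`, ..., `un`), with solver metadata in attributes.
#' @examples
#' tr <- simulate_lv(rps3(-0.5), 1, u0 = c(1, 1, 1), t_final = 200)
#' tail(tr, 1) # near the interior equilibrium (2,2,2)
#' @export
simulate_lv <- function(A, b = 1, u0, t_final = NULL, n_steps = 400,
                        rtol = 1e-9, atol = 1e-12, blowup_cap = 1e8,
                        method = "vode") {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  b <- as_growth_rates(b, n)
  u0 <- as.double(u0)
  if (length(u0) != n) abort("`u0` must have one entry per species.")
  if (any(u0 < 0)) abort("`u0` must be nonnegative.")
  if (is.null(t_final)) {
    dmin <- min(abs(diag(A)))
    t_final <- if (dmin > 0) 200 / dmin else 200
  }
  if (t_final <= 0) abort("`t_final` must be positive.")
  times <- seq(0, t_final, length.out = n_steps + 1L)

  active <- which(u0 > 0)
  states <- matrix(0, length(times), n)
  if (length(active) > 0L) {
    Aa <- A[active, active, drop = FALSE]
    ba <- b[active]
    rhs <- function(t, y, parms) {
      list(y * (ba + drop(Aa %*% y)))
    }
    sol <- tryCatch(
      suppressWarnings(
        deSolve::ode(y = u0[active], times = times, func = rhs,
                     parms = NULL, method = method,
                     rtol = rtol, atol = atol, maxsteps = 1e5)
      ),
      error = function(e) {
        abort(paste0("trajectory blow-up or solver failure detected; ",
                     "is the matrix VL stable? (", conditionMessage(e), ")"))
      }
    )
    ys <- sol[, -1L, drop = FALSE]
    if (nrow(sol) < length(times) || any(!is.finite(ys)) ||
        max(abs(ys)) > blowup_cap) {
      abort("trajectory blow-up or solver failure detected; is the matrix VL stable?")
    }
    states[, active] <- pmax(ys, 0)
  }
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- paste0("u", seq_len(n))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  structure(out,
            class = c("lv_trajectory", class(tibble::tibble())),
            A = A, b = b, rtol = rtol, atol = atol, active = active)
}

#' Identify the omega-limit of a simulated trajectory
#'
#' Examines the terminal window (last `window` fraction of samples) of a
#' trajectory: if its diameter is below `settle_tol` the trajectory has
#' numerically settled, and the catalogued equilibrium nearest (Euclidean) to
#' the terminal state is returned with its distance. Otherwise the check is
#' inconclusive.
#'
#' @param traj An `lv_trajectory` from [simulate_lv()].
#' @param catalog The `lv_catalog` of the same system.
#' @param window Terminal fraction of samples inspected.
#' @param settle_tol Maximum diameter of the terminal window.
#' @return A list: `converged`, `label` (nearest equilibrium, `NA` when not
#'   settled), `distance`, `window_diameter`.
#' @export
omega_limit_check <- function(traj, catalog, window = 0.1, settle_tol = 1e-6) {
  stopifnot(inherits(traj, "lv_trajectory"), inherits(catalog, "lv_catalog"))
  n <- attr(catalog, "n")
  S <- as.matrix(traj[, paste0("u", seq_len(n))])
  k <- max(2L, ceiling(window * nrow(S)))
  tail_states <- S[(nrow(S) - k + 1L):nrow(S), , drop = FALSE]
  diam <- max(apply(tail_states, 2, function(col) diff(range(col))))
  terminal <- tail_states[nrow(tail_states), ]
  dists <- vapply(catalog$u, function(u) sqrt(sum((terminal - u)^2)), numeric(1))
  best <- which.min(dists)
  if (diam > settle_tol) {
    return(list(converged = FALSE, label = NA_character_,
                distance = dists[best], window_diameter = diam))
  }
  list(converged = TRUE, label = catalog$label[best],
       distance = dists[best], window_diameter = diam)
}
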