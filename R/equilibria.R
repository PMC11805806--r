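#' Principal submatrix and subvector for a community
#'
#' For a community `J` (a sorted set of species indices) the principal
#' submatrix `A(J)` keeps the rows and columns of `A` indexed by `J`, in
#' order; `subvector(b, J)` keeps the matching entries of `b`.
#'
#' @param A Square interaction matrix.
#' @param J Integer vector of species indices (1-based, strictly increasing).
#' @param b Numeric vector.
#' @return A `|J| x |J|` matrix, or a length-`|J|` vector.
#' @export
principal_submatrix <- function(A, J) {
  A <- as_interaction_matrix(A)
  J <- check_community(J, nrow(A))
  if (length(J) == 0L) abort("`J` must be nonempty for submatrix extraction.")
  A[J, J, drop = FALSE]
}

#' @rdname principal_submatrix
#' @export
subvector <- function(b, J) {
  J <- check_community(J, length(b))
  b[J]
}

check_community <- function(J, n) {
  if (is.null(J) || length(J) == 0L) return(integer(0))
  J <- as.integer(J)
  if (anyNA(J) || any(J < 1L) || any(J > n)) {
    abort(sprintf("community indices must lie in 1..%d.", n))
  }
  if (is.unsorted(J, strictly = TRUE)) J <- sort(unique(J))
  J
}

# Core solver used by everything downstream. Returns a plain list; the
# tibble-facing wrappers sit on top. The equilibrium of community J solves
# -A(J) u = b(J); it is admissible when every in-community coordinate is
# strictly positive (tolerance `tol`).
solve_community <- function(A, b, J, tol = 1e-9, rcond_min = 1e-12) {
  n <- nrow(A)
  u <- numeric(n)
  if (length(J) == 0L) {
    return(list(members = integer(0), u = u, admissible = TRUE,
                reason = NA_character_, rcond = 1))
  }
  AJ <- A[J, J, drop = FALSE]
  rc <- rcond(AJ)
  if (!is.finite(rc) || rc < rcond_min) {
    return(list(members = J, u = NULL, admissible = FALSE,
                reason = "singular", rcond = rc))
  }
  uJ <- solve(-AJ, b[J])
  u[J] <- uJ
  list(members = J, u = u,
       admissible = all(uJ > tol),
       reason = if (all(uJ > tol)) NA_character_ else "negative",
       rcond = rc)
}

#' Solve the equilibrium of one community
#'
#' Solves the linear system \eqn{-A(J) u = b(J)} and embeds the solution into
#' the full species space with zeros off `J`. The candidate is admissible when
#' all in-community coordinates exceed `tol`; a near-singular `A(J)`
#' (reciprocal condition number below `1e-12`) is reported as rejected with
#' reason `"singular"` rather than an error.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (a scalar is recycled).
#' @param J Community: integer vector of species indices; empty for the zero
#'   equilibrium.
#' @param tol Strict-positivity tolerance for admissibility.
#' @return A one-row tibble with columns `community` (list), `label`, `dim`,
#'   `admissible`, `reason`, `u` (list of the full-length abundance vector, or
#'   `NULL` when singular).
#' @examples
#' solve_equilibrium(rps3(-0.5), 1, c(1, 2)) # not admissible
#' @export
solve_equilibrium <- function(A, b, J, tol = 1e-9) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  J <- check_community(J, nrow(A))
  res <- solve_community(A, b, J, tol = tol)
  tibble::tibble(
    community = list(res$members),
    label = community_label(res$members),
    dim = length(res$members),
    admissible = res$admissible,
    reason = res$reason,
    u = list(res$u)
  )
}

#' Invasion rates at a community equilibrium
#'
#' The invasion rate of species `i` on community `I` with equilibrium
#' \eqn{u^I} is \eqn{r_i(I) = b_i + \sum_{j \in I} a_{ij} u^I_j}: the
#' per-capita growth rate of `i` introduced at vanishing density into the
#' resident equilibrium. For the empty community the convention is
#' \eqn{r_i(\emptyset) = b_i}. Residents (`i` in `I`) have rate zero up to the
#' equilibrium residual.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled).
#' @param members Community index vector.
#' @param u Full-length abundance vector of the community's equilibrium; when
#'   missing it is solved from `(A, b, members)`.
#' @return Numeric vector of length `n`: `r_i(I)` for every species.
#' @examples
#' invasion_rates(rps3(-0.5), 1, members = 1) # c(0, 3, -1)
#' @export
invasion_rates <- function(A, b, members, u = NULL) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  members <- check_community(members, nrow(A))
  if (is.null(u)) {
    res <- solve_community(A, b, members)
    if (is.null(res$u)) abort("community has a singular submatrix; no equilibrium.")
    u <- res$u
  }
  if (length(members) == 0L) return(b)
  drop(b + A[, members, drop = FALSE] %*% u[members])
}

new_catalog <- function(entries, rejected, A, b, tol) {
  structure(entries,
            class = c("lv_catalog", class(tibble::tibble())),
            A = A, b = b, n = nrow(A), tol = tol, rejected = rejected)
}

#' @export
print.lv_catalog <- function(x, ...) {
  cat(sprintf("# Community catalog: %d admissible of %d communities (n = %d)\n",
              nrow(x), 2^attr(x, "n"), attr(x, "n")))
  NextMethod()
}

#' Enumerate all admissible communities of a Lotka-Volterra system
#'
#' Sweeps all \eqn{2^n} subsets of species, solves \eqn{-A(J) u = b(J)} for
#' each, and catalogues the admissible communities (strictly positive
#' solutions) together with their equilibria and full invasion-rate vectors.
#' The empty community is always admissible (the zero equilibrium) and carries
#' the \eqn{r_i(\emptyset) = b_i} convention. For a VL stable `A` each
#' community has at most one equilibrium, so the catalog is exactly the
#' equilibrium set of the system.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled; defaults to all ones).
#' @param tol Strict-positivity tolerance for admissibility.
#' @param max_species Enumeration cap (the sweep is exponential in `n`).
#' @return An `lv_catalog`: a tibble with one row per admissible community
#'   (`community`, `label`, `dim`, `u`, `rates` as list-columns), carrying
#'   `A`, `b`, `tol` and the tibble of rejected communities (`reason` either
#'   `"negative"` or `"singular"`) as attributes.
#' @examples
#' enumerate_admissible(rps3(-0.5), b = 1) # 5 communities, none of size 2
#' @export
enumerate_admissible <- function(A, b = 1, tol = 1e-9, max_species = 20L) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  if (n > max_species) {
    abort(sprintf("n = %d exceeds the enumeration cap (%d); the sweep is 2^n.",
                  n, max_species))
  }
  b <- as_growth_rates(b, n)
  species <- seq_len(n)
  keep <- vector("list", 2^n)
  rej_members <- list()
  rej_reason <- character(0)
  k <- 0L
  for (mask in 0:(2^n - 1)) {
    J <- species[bitwAnd(mask, bitwShiftL(1L, species - 1L)) != 0L]
    res <- solve_community(A, b, J, tol = tol)
    if (res$admissible) {
      r <- if (length(J) == 0L) b else
        drop(b + A[, J, drop = FALSE] %*% res$u[J])
      k <- k + 1L
      keep[[k]] <- list(members = J, u = res$u, rates = r)
    } else {
      rej_members <- c(rej_members, list(J))
      rej_reason <- c(rej_reason, res$reason)
    }
  }
  keep <- keep[seq_len(k)]
  entries <- tibble::tibble(
    community = lapply(keep, `[[`, "members"),
    label = vapply(keep, function(e) community_label(e$members), character(1)),
    dim = vapply(keep, function(e) length(e$members), integer(1)),
    u = lapply(keep, `[[`, "u"),
    rates = lapply(keep, `[[`, "rates")
  )
  rejected <- tibble::tibble(
    community = rej_members,
    label = vapply(rej_members, community_label, character(1)),
    reason = rej_reason
  )
  new_catalog(entries, rejected, A, b, tol)
}

#' Globally asymptotically stable stationary solution (GASS)
#'
#' For a VL stable matrix the system has a unique globally asymptotically
#' stable equilibrium. It is identified in the catalog as the unique
#' *saturated* admissible equilibrium: the one whose absent-species invasion
#' rates are all \eqn{\le} `tol`. The function errors loudly when zero or
#' several saturated equilibria are found, which signals a non-VL-stable input
#' or a tolerance failure rather than silently picking one.
#'
#' @param catalog An `lv_catalog` from [enumerate_admissible()].
#' @param tol Saturation tolerance on the absent-species rates.
#' @return The one-row tibble of the saturated equilibrium.
#' @examples
#' find_gass(enumerate_admissible(rps3(-0.5), b = 1)) # interior (2,2,2)
#' @export
find_gass <- function(catalog, tol = 1e-9) {
  stopifnot(inherits(catalog, "lv_catalog"))
  n <- attr(catalog, "n")
  saturated <- vapply(seq_len(nrow(catalog)), function(i) {
    out <- setdiff(seq_len(n), catalog$community[[i]])
    all(catalog$rates[[i]][out] <= tol)
  }, logical(1))
  hits <- which(saturated)
  if (length(hits) == 0L) {
    abort("no saturated equilibrium found; is the matrix VL stable?")
  }
  if (length(hits) > 1L) {
    abort(sprintf(
      "multiple saturated equilibria (%s); non-VL-stable input or tolerance failure.",
      paste(catalog$label[hits], collapse = ", ")))
  }
  catalog[hits, ]
}

#' Hyperbolicity of all catalogued equilibria
#'
#' Every admissible equilibrium is hyperbolic iff every absent-species
#' invasion rate is nonzero: `|r_i(J)| > tol` for all admissible `J` and all
#' `i` not in `J`. Non-hyperbolic equilibria make the invasion graph an
#' unreliable picture of the attractor, so the violations are reported.
#'
#' @param catalog An `lv_catalog`.
#' @param tol Rate-magnitude tolerance.
#' @return A list with `hyperbolic` (logical) and `violations` (tibble with
#'   `label`, `species`, `rate` for each rate within `tol` of zero).
#' @export
is_hyperbolic <- function(catalog, tol = 1e-9) {
  stopifnot(inherits(catalog, "lv_catalog"))
  n <- attr(catalog, "n")
  viol <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    out <- setdiff(seq_len(n), catalog$community[[i]])
    r <- catalog$rates[[i]][out]
    bad <- abs(r) <= tol
    if (!any(bad)) return(NULL)
    tibble::tibble(label = catalog$label[i], species = out[bad], rate = r[bad])
  })
  list(hyperbolic = nrow(viol) == 0L, violations = viol)
}

#' Tidy a community catalog into per-species rows
#'
#' @param x An `lv_catalog`.
#' @param ... Unused.
#' @return A long tibble with one row per (community, species): columns
#'   `label`, `dim`, `species`, `member`, `abundance`, `rate`.
#' @export
tidy.lv_catalog <- function(x, ...) {
  n <- attr(x, "n")
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    tibble::tibble(
      label = x$label[i],
      dim = x$dim[i],
      species = seq_len(n),
      member = seq_len(n) %in% x$community[[i]],
      abundance = x$u[[i]],
      rate = x$rates[[i]]
    )
  })
}

#' One-row summary of a community catalog
#'
#' @param x An `lv_catalog`.
#' @param ... Unused.
#' @return A one-row tibble: `n_species`, `n_admissible`, `n_rejected`,
#'   `max_dim`, `frondose` (all communities admissible), `hyperbolic`.
#' @export
glance.lv_catalog <- function(x, ...) {
  tibble::tibble(
    n_species = attr(x, "n"),
    n_admissible = nrow(x),
    n_rejected = nrow(attr(x, "rejected")),
    max_dim = max(x$dim),
    frondose = nrow(x) == 2^attr(x, "n"),
    hyperbolic = is_hyperbolic(x)$hyperbolic
  )
}
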