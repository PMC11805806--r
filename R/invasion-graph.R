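#' Build the invasion graph of a community catalog
#'
#' The invasion graph (IG) has the admissible communities as nodes and the
#' directed edge \eqn{I \to J} exactly when \eqn{I \ne J}, every invader
#' grows (\eqn{r_j(I) > 0} for all \eqn{j \in J \setminus I}) and every
#' leaver dies out (\eqn{r_i(J) < 0} for all \eqn{i \in I \setminus J});
#' vacuous conditions (empty difference sets) count as satisfied. Inequalities
#' are taken strictly at tolerance `tol`: a rate within `tol` of zero licenses
#' nothing (such systems are non-hyperbolic and should be flagged by
#' [is_hyperbolic()] rather than silently assigned a sign).
#'
#' Under VL stability the IG is a subgraph of the connection graph of actual
#' heteroclinic orbits, and when additionally all equilibria are hyperbolic
#' the two coincide, so an acyclic IG certifies a gradient attractor.
#'
#' @param catalog An `lv_catalog` from [enumerate_admissible()].
#' @param tol Strict-sign tolerance for the licensing rates.
#' @param include_empty Keep the empty community as a node (default `TRUE`).
#' @return An `lv_igraph`: a list with `nodes` (tibble: `label`, `dim`,
#'   `community`), `edges` (tibble: `from`, `to`, `invaders`, `leavers`,
#'   `invader_rates`, `leaver_rates`), the underlying `igraph` object, and the
#'   originating catalog.
#' @examples
#' g <- build_ig(enumerate_admissible(rps3(-0.5), b = 1))
#' find_cycles(g)$has_cycle
#' @export
build_ig <- function(catalog, tol = 1e-9, include_empty = TRUE) {
  stopifnot(inherits(catalog, "lv_catalog"))
  cat_use <- if (include_empty) catalog else catalog[catalog$dim > 0L, ]
  m <- nrow(cat_use)
  comm <- cat_use$community
  rates <- cat_use$rates
  labels <- cat_use$label
  from <- character(0); to <- character(0)
  invaders <- list(); leavers <- list()
  inv_rates <- list(); lv_rates <- list()
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      I <- comm[[i]]; J <- comm[[j]]
      inv <- setdiff(J, I)
      out <- setdiff(I, J)
      if (all(rates[[i]][inv] > tol) && all(rates[[j]][out] < -tol)) {
        from <- c(from, labels[i]); to <- c(to, labels[j])
        invaders <- c(invaders, list(inv))
        leavers <- c(leavers, list(out))
        inv_rates <- c(inv_rates, list(rates[[i]][inv]))
        lv_rates <- c(lv_rates, list(rates[[j]][out]))
      }
    }
  }
  nodes <- tibble::tibble(label = labels, dim = cat_use$dim, community = comm)
  edges <- tibble::tibble(from = from, to = to,
                          invaders = invaders, leavers = leavers,
                          invader_rates = inv_rates, leaver_rates = lv_rates)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE, vertices = nodes["label"])
  structure(list(nodes = nodes, edges = edges, graph = g, catalog = catalog,
                 tol = tol, include_empty = include_empty),
            class = "lv_igraph")
}

#' @export
print.lv_igraph <- function(x, ...) {
  cat(sprintf("<lv_igraph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_ig Edge list of an invasion graph as a tibble.
#' @param x An `lv_igraph`.
#' @param ... Unused.
#' @export
tidy.lv_igraph <- function(x, ...) x$edges

#' @describeIn build_ig One-row summary (`n_nodes`, `n_edges`, `has_cycle`).
#' @export
glance.lv_igraph <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 has_cycle = find_cycles(x, max_cycles = 0)$has_cycle)
}

# Johnson's elementary-circuit algorithm on an adjacency list; nodes are
# integers 1..m. Enumeration stops once `max_cycles` circuits are collected.
johnson_cycles <- function(adj, max_cycles) {
  m <- length(adj)
  cycles <- list()
  cap_hit <- FALSE
  blocked <- logical(m)
  Bsets <- vector("list", m)
  stack <- integer(0)

  unblock <- function(v) {
    blocked[v] <<- FALSE
    for (w in Bsets[[v]]) if (blocked[w]) unblock(w)
    Bsets[[v]] <<- integer(0)
  }

  circuit <- function(v, s, sub_adj) {
    found <- FALSE
    stack <<- c(stack, v)
    blocked[v] <<- TRUE
    for (w in sub_adj[[v]]) {
      if (cap_hit) break
      if (w == s) {
        cycles[[length(cycles) + 1L]] <<- stack
        if (length(cycles) >= max_cycles) cap_hit <<- TRUE
        found <- TRUE
      } else if (!blocked[w]) {
        if (circuit(w, s, sub_adj)) found <- TRUE
      }
    }
    if (found) {
      unblock(v)
    } else {
      for (w in sub_adj[[v]]) {
        if (!(v %in% Bsets[[w]])) Bsets[[w]] <<- c(Bsets[[w]], v)
      }
    }
    stack <<- stack[-length(stack)]
    found
  }

  if (max_cycles > 0) {
    for (s in seq_len(m)) {
      if (cap_hit) break
      # subgraph induced by {s, s+1, ..., m}
      sub_adj <- lapply(seq_len(m), function(v) {
        if (v < s) integer(0) else adj[[v]][adj[[v]] >= s]
      })
      blocked[] <- FALSE
      Bsets <- vector("list", m)
      for (i in seq_len(m)) Bsets[[i]] <- integer(0)
      stack <- integer(0)
      circuit(s, s, sub_adj)
    }
  }
  list(cycles = cycles, cap_hit = cap_hit)
}

#' Detect cycles in an invasion graph
#'
#' Strongly-connected-component analysis always completes, so `has_cycle` is
#' exact; elementary cycles are additionally enumerated (Johnson's algorithm)
#' up to `max_cycles`, with `cap_hit` flagging truncation. A cycle in the IG
#' of a hyperbolic VL stable system corresponds to a heteroclinic cycle of
#' the dynamics.
#'
#' @param g An `lv_igraph` from [build_ig()].
#' @param max_cycles Cap on enumerated elementary cycles (default `1e5`;
#'   `0` skips enumeration, leaving only the SCC verdict).
#' @return A list: `has_cycle`, `sccs` (list of node-label sets of size > 1),
#'   `cycles` (list of label sequences, each an elementary cycle in
#'   lexicographically deterministic order), `cap_hit`.
#' @export
find_cycles <- function(g, max_cycles = 1e5) {
  stopifnot(inherits(g, "lv_igraph"))
  labels <- g$nodes$label
  m <- length(labels)
  comp <- igraph::components(g$graph, mode = "strong")
  scc_sizes <- tabulate(comp$membership, nbins = comp$no)
  sccs <- lapply(which(scc_sizes > 1L), function(k) {
    sort(labels[comp$membership == k])
  })
  has_scc_cycle <- length(sccs) > 0L
  # self-loops cannot occur (the edge rule requires I != J), so has_cycle
  # is exactly "some SCC has size > 1"
  idx <- setNames(seq_len(m), labels)
  adj <- lapply(seq_len(m), function(v) integer(0))
  if (nrow(g$edges) > 0L) {
    for (r in seq_len(nrow(g$edges))) {
      v <- idx[[g$edges$from[r]]]
      adj[[v]] <- c(adj[[v]], idx[[g$edges$to[r]]])
    }
    adj <- lapply(adj, sort)
  }
  jc <- johnson_cycles(adj, max_cycles)
  cycles <- lapply(jc$cycles, function(cyc) labels[cyc])
  if (length(cycles) > 1L) {
    key <- vapply(cycles, function(cc) paste(cc, collapse = " "), character(1))
    cycles <- cycles[order(key)]
  }
  list(has_cycle = has_scc_cycle,
       sccs = sccs,
       cycles = cycles,
       cap_hit = jc$cap_hit)
}

#' Structural verdict: hyperbolicity, acyclicity, gradient certification
#'
#' Combines [is_hyperbolic()] and the cycle test: when all equilibria are
#' hyperbolic and the IG has no cycles, the dynamics is gradient and the IG
#' recovers the whole structure of the global attractor. A cyclic or
#' non-hyperbolic IG is inconclusive about the attractor (there may be
#' connections the graph does not show), which the verdict records.
#'
#' @param catalog An `lv_catalog`.
#' @param g The matching `lv_igraph`; built from `catalog` when missing.
#' @param tol Rate tolerance passed to [is_hyperbolic()].
#' @return A one-row tibble: `hyperbolic`, `acyclic`, `gradient_certified`,
#'   `frondose`, `notes`.
#' @export
structure_verdict <- function(catalog, g = NULL, tol = 1e-9) {
  stopifnot(inherits(catalog, "lv_catalog"))
  if (is.null(g)) g <- build_ig(catalog, tol = tol)
  hyp <- is_hyperbolic(catalog, tol = tol)$hyperbolic
  acyclic <- !find_cycles(g, max_cycles = 0)$has_cycle
  frondose <- nrow(catalog) == 2^attr(catalog, "n")
  notes <- if (hyp && acyclic) {
    "gradient dynamics; the IG equals the connection graph of the attractor"
  } else if (!hyp) {
    "non-hyperbolic equilibria present; the IG may miss heteroclinic connections"
  } else {
    "IG has cycles; the attractor contains heteroclinic cycles"
  }
  tibble::tibble(hyperbolic = hyp, acyclic = acyclic,
                 gradient_certified = hyp && acyclic,
                 frondose = frondose, notes = notes)
}

#' Maximal frondosity: is every community admissible?
#'
#' Checks whether for every nonempty community `J` the solution of
#' \eqn{-A(J) u = b(J)} exists and is strictly positive. When it does, all
#' \eqn{2^n} communities are admissible ("maximal frondosity") and the system
#' has no heteroclinic cycles; if moreover all equilibria are hyperbolic the
#' IG is exactly the subset order \eqn{I \subsetneq J}.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled).
#' @param tol Strict-positivity tolerance.
#' @param max_species Enumeration cap.
#' @return A list: `frondose` (logical), `first_failure` (label of the first
#'   failing community or `NA`), `reason` (`"negative"`, `"singular"` or
#'   `NA`).
#' @examples
#' check_frondosity(rpsls5(-1.5), 1)$frondose # TRUE: all 32 admissible
#' @export
check_frondosity <- function(A, b = 1, tol = 1e-9, max_species = 20L) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  if (n > max_species) abort("n exceeds the enumeration cap.")
  b <- as_growth_rates(b, n)
  species <- seq_len(n)
  for (mask in 1:(2^n - 1)) {
    J <- species[bitwAnd(mask, bitwShiftL(1L, species - 1L)) != 0L]
    res <- solve_community(A, b, J, tol = tol)
    if (!res$admissible) {
      return(list(frondose = FALSE, first_failure = community_label(J),
                  reason = res$reason))
    }
  }
  list(frondose = TRUE, first_failure = NA_character_, reason = NA_character_)
}

#' Sufficient conditions for maximal frondosity
#'
#' `frondosity_sufficient_dd()` evaluates the strong diagonal-dominance
#' criterion
#' \eqn{\max_i \sum_{j \ne i} |a_{ij}/a_{jj}| < 1/(1+M)} with
#' \eqn{M = \max_i b_i / \min_i b_i}, which (for VL stable `A` and positive
#' `b`) guarantees every community is admissible. The condition is sufficient,
#' not necessary. `frondosity_sufficient_cooperative()` reports the fully
#' cooperative case: all off-diagonal \eqn{a_{ij} > 0} and \eqn{\min_i b_i >
#' 0} (with VL stability, which the caller certifies separately, this also
#' forces maximal frondosity).
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled); must be strictly positive
#'   for the diagonal-dominance criterion.
#' @return `frondosity_sufficient_dd()`: a list with `holds` and `slack`
#'   (right-hand side minus left-hand side). The cooperative variant: a
#'   single logical.
#' @export
frondosity_sufficient_dd <- function(A, b) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  if (min(b) <= 0) abort("the criterion requires min(b) > 0.")
  if (any(diag(A) == 0)) abort("the criterion requires nonzero diagonal entries.")
  P <- abs(sweep(A, 2, diag(A), "/"))
  diag(P) <- 0
  lhs <- max(rowSums(P))
  M <- max(b) / min(b)
  rhs <- 1 / (1 + M)
  list(holds = lhs < rhs, slack = rhs - lhs, lhs = lhs, rhs = rhs)
}

#' @rdname frondosity_sufficient_dd
#' @export
frondosity_sufficient_cooperative <- function(A, b) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  off <- A[row(A) != col(A)]
  structural <- all(off > 0) && min(b) > 0
  if (structural) {
    inform("fully cooperative structure holds; VL stability of A is a prerequisite certified separately.")
  }
  structural
}

#' Cycles among single-species communities and the product criterion
#'
#' Scans the invasion graph for elementary cycles visiting only
#' single-species communities and, for each, evaluates the necessary product
#' condition \eqn{\prod_i |a_{i,i+1}| \ge \prod_i |a_{ii}|} along the cyclic
#' ordering. Row or column diagonal dominance of `A` makes that condition
#' impossible, so a reported singleton cycle together with a dominant matrix
#' is flagged as an inconsistency.
#'
#' @param A Square interaction matrix.
#' @param b Growth-rate vector (scalar recycled).
#' @param g Optional prebuilt `lv_igraph` for `(A, b)`.
#' @param max_cycles Cycle-enumeration cap.
#' @return A list: `cycles` (tibble with `cycle` label-sequence list-column,
#'   `species` list-column, `product_holds`), `row_dd`, `col_dd`,
#'   `consistent` (`FALSE` only in the contradictory dominant-and-cyclic
#'   case).
#' @export
single_species_cycle_test <- function(A, b = 1, g = NULL, max_cycles = 1e5) {
  A <- as_interaction_matrix(A)
  b <- as_growth_rates(b, nrow(A))
  if (is.null(g)) g <- build_ig(enumerate_admissible(A, b))
  singleton_labels <- g$nodes$label[g$nodes$dim == 1L]
  sub_edges <- g$edges[g$edges$from %in% singleton_labels &
                         g$edges$to %in% singleton_labels, ]
  # restrict the graph to singleton nodes and enumerate its cycles
  sub_nodes <- g$nodes[g$nodes$dim == 1L, ]
  sub <- structure(list(
    nodes = sub_nodes,
    edges = sub_edges,
    graph = igraph::graph_from_data_frame(
      sub_edges[, c("from", "to")], directed = TRUE,
      vertices = sub_nodes["label"])
  ), class = "lv_igraph")
  rep <- find_cycles(sub, max_cycles = max_cycles)
  cyc_tbl <- purrr::map_dfr(rep$cycles, function(cc) {
    sp <- vapply(cc, function(lb) {
      sub_nodes$community[[match(lb, sub_nodes$label)]][1L]
    }, integer(1))
    nxt <- c(sp[-1L], sp[1L])
    prod_off <- prod(abs(A[cbind(sp, nxt)]))
    prod_diag <- prod(abs(diag(A)[sp]))
    tibble::tibble(cycle = list(cc), species = list(unname(sp)),
                   product_holds = prod_off >= prod_diag)
  })
  row_dd <- is_row_dd(A)
  col_dd <- is_col_dd(A)
  has_cycle <- rep$has_cycle
  list(cycles = cyc_tbl, has_cycle = has_cycle,
       row_dd = row_dd, col_dd = col_dd,
       consistent = !((row_dd || col_dd) && has_cycle))
}
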