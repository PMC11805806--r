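#' Benchmark the Volterra-Lyapunov detector on constructed ground truth
#'
#' For each dimension, generates `n_matrices` VL stable matrices with
#' [random_vl_stable()] (VL stable by construction, so ground truth is known)
#' and runs [detect_vl()] on each. Recall is the fraction detected; since the
#' detector has 100% precision, `1 - recall` is the inconclusive rate. Every
#' returned certificate is re-verified independently of the optimizer.
#'
#' @param dims Integer vector of dimensions.
#' @param n_matrices Matrices generated per dimension.
#' @param n_initial Optimizer starts per matrix.
#' @param seed Master seed; all generation and detection randomness derives
#'   from it, so the table is bit-reproducible.
#' @param threshold Detector stopping threshold.
#' @return A tibble (class `lv_benchmark`) with one row per dimension:
#'   `dim`, `n_matrices`, `n_initial`, `recall`, `inconclusive_rate`,
#'   `all_certificates_valid`, `seed`.
#' @examples
#' detector_benchmark(dims = 2:5, n_matrices = 3, seed = 1)
#' @export
detector_benchmark <- function(dims, n_matrices = 10, n_initial = 50,
                               seed = 1, threshold = -1e-10) {
  stopifnot(all(dims >= 1), n_matrices >= 0)
  rows <- with_seed_if(seed, purrr::map_dfr(dims, function(d) {
    detected <- 0L
    certs_ok <- TRUE
    for (k in seq_len(n_matrices)) {
      sys <- random_vl_stable(d)
      res <- detect_vl(sys$A, n_initial = n_initial, threshold = threshold)
      if (res$verdict == "vl_stable") {
        detected <- detected + 1L
        certs_ok <- certs_ok && verify_certificate(sys$A, res$certificate)
      }
    }
    recall <- if (n_matrices > 0) detected / n_matrices else NA_real_
    tibble::tibble(dim = d, n_matrices = n_matrices, n_initial = n_initial,
                   recall = recall, inconclusive_rate = 1 - recall,
                   all_certificates_valid = certs_ok, seed = seed)
  }))
  structure(rows, class = c("lv_benchmark", class(rows)))
}

# Sample a VL stable matrix (H = I) whose antisymmetric/symmetric entrywise
# norm ratio equals `ratio`: draw a Gaussian matrix, split it, shift the
# symmetric part's diagonal to enforce stability, rescale the antisymmetric
# part onto the target ratio.
sample_ratio_matrix <- function(n, ratio, margin = 0.5) {
  M <- matrix(rnorm(n * n), n, n)
  sp <- symmetry_split(M)
  s <- sp$a_s - (max(0, largest_eigenvalue_sym(sp$a_s)) + margin) * diag(n)
  aj <- sp$a_j
  nj <- sum(abs(aj))
  if (ratio == 0 || nj == 0) return(s)
  s + aj * (ratio * sum(abs(s)) / nj)
}

#' Cycle density as a function of the antisymmetric-to-symmetric ratio
#'
#' Samples random VL stable matrices whose entrywise-norm ratio
#' \eqn{|A_J|/|A_S|} is pinned to each target value (by rescaling the
#' antisymmetric part of a Gaussian draw whose symmetric part is shifted to
#' stability), builds the community catalog and invasion graph of each, and
#' records the fraction of invasion graphs containing a cycle. Growth rates
#' are all ones. Antisymmetric interactions promote cycles, symmetric ones
#' inhibit them: the density vanishes as the ratio tends to zero and rises
#' with it.
#'
#' @param dims Integer vector of dimensions.
#' @param ratios Nonnegative target ratios.
#' @param n_samples Matrices per (dim, ratio) cell.
#' @param seed Master seed.
#' @return A tibble (class `lv_cycle_density`): `dim`, `ratio`, `n_samples`,
#'   `cycle_density`, `seed`.
#' @examples
#' cycle_density(dims = 4, ratios = c(0, 2), n_samples = 20, seed = 1)
#' @export
cycle_density <- function(dims, ratios, n_samples = 100, seed = 1) {
  stopifnot(all(ratios >= 0), n_samples >= 0)
  grid <- tidyr::expand_grid(dim = dims, ratio = ratios)
  rows <- with_seed_if(seed, purrr::pmap_dfr(grid, function(dim, ratio) {
    n_cyclic <- 0L
    for (k in seq_len(n_samples)) {
      A <- sample_ratio_matrix(dim, ratio)
      g <- build_ig(enumerate_admissible(A, b = 1))
      if (find_cycles(g, max_cycles = 0)$has_cycle) n_cyclic <- n_cyclic + 1L
    }
    tibble::tibble(dim = dim, ratio = ratio, n_samples = n_samples,
                   cycle_density = if (n_samples > 0) n_cyclic / n_samples
                   else NA_real_,
                   seed = seed)
  }))
  structure(rows, class = c("lv_cycle_density", class(rows)))
}

# Random strongly row- or column-diagonally-dominant matrix: mixed-sign
# off-diagonals and growth rates, strictly negative diagonal (self-regulation)
# scaled above the off-diagonal row/column sums.
sample_dd_system <- function(n, mode = c("row", "col")) {
  mode <- match.arg(mode)
  A <- matrix(runif(n * n, -1, 1), n, n)
  diag(A) <- 0
  sums <- if (mode == "row") rowSums(abs(A)) else colSums(abs(A))
  diag(A) <- -(sums + runif(n, 0.05, 1))
  b <- runif(n, -1, 1)
  list(A = A, b = b, mode = mode)
}

#' Sweep random diagonally dominant systems for invasion-graph cycles
#'
#' Samples strongly row- or column-diagonally-dominant interaction matrices
#' with mixed-sign off-diagonal interactions and mixed-sign growth rates,
#' builds each invasion graph, and reports any cyclic IG found. Diagonal
#' dominance provably excludes cycles among single-species communities; that
#' no cycle of any kind has ever been observed is an open conjecture, so this
#' sweep reports rather than proves.
#'
#' @param n_samples Number of sampled systems.
#' @param dims Dimensions to sample from (uniformly).
#' @param seed Master seed.
#' @return A list: `n_samples`, `n_cyclic`, `n_singleton_cyclic`,
#'   `counterexamples` (tibble with the offending `A`, `b`, `mode`; empty in
#'   every run we have performed).
#' @export
dd_sweep <- function(n_samples, dims = 3:6, seed = 1) {
  stopifnot(n_samples >= 0)
  counter <- list()
  n_cyclic <- 0L
  n_singleton_cyclic <- 0L
  with_seed_if(seed, {
    for (k in seq_len(n_samples)) {
      n <- if (length(dims) == 1L) dims else sample(dims, 1L)
      mode <- if (runif(1) < 0.5) "row" else "col"
      sys <- sample_dd_system(n, mode)
      g <- build_ig(enumerate_admissible(sys$A, sys$b))
      cyc <- find_cycles(g, max_cycles = 0)
      if (cyc$has_cycle) {
        n_cyclic <- n_cyclic + 1L
        counter[[length(counter) + 1L]] <-
          tibble::tibble(A = list(sys$A), b = list(sys$b), mode = mode)
        sing <- single_species_cycle_test(sys$A, sys$b, g)
        if (sing$has_cycle) n_singleton_cyclic <- n_singleton_cyclic + 1L
      }
    }
  })
  list(n_samples = n_samples,
       n_cyclic = n_cyclic,
       n_singleton_cyclic = n_singleton_cyclic,
       counterexamples = if (length(counter)) dplyr::bind_rows(counter)
       else tibble::tibble(A = list(), b = list(), mode = character(0)))
}

#' Self-regulation sweep of the rock-paper-scissors-lizard-spock system
#'
#' Builds the 5-species RPSLS system [rpsls5()] for each value of the
#' diagonal `d` and summarizes its catalog and invasion graph. Cycles exist
#' for `d` in `(-1, 0)`; at `d = -1` the system is non-hyperbolic and the
#' cycles disappear; for `d < -1` all 32 communities become admissible and
#' the IG coincides with that of the purely diagonal (symmetric-part) system
#' `diag(d, 5)`, which the sweep verifies edge-for-edge.
#'
#' @param d_values Negative diagonal values.
#' @return A tibble: `d`, `n_admissible`, `has_cycle`, `n_cycles`,
#'   `hyperbolic`, `frondose`, `matches_symmetric_part` (`NA` when `d >= -1`).
#' @examples
#' rpsls_d_sweep(c(-0.5, -1, -1.5))
#' @export
rpsls_d_sweep <- function(d_values) {
  stopifnot(all(d_values < 0))
  purrr::map_dfr(d_values, function(d) {
    A <- rpsls5(d)
    cat5 <- enumerate_admissible(A, b = 1)
    g <- build_ig(cat5)
    cyc <- find_cycles(g)
    hyp <- is_hyperbolic(cat5)$hyperbolic
    matches <- NA
    if (d < -1) {
      gd <- build_ig(enumerate_admissible(diag(d, 5), b = 1))
      edge_key <- function(gg) sort(paste(gg$edges$from, gg$edges$to, sep = "->"))
      matches <- identical(edge_key(g), edge_key(gd))
    }
    tibble::tibble(d = d, n_admissible = nrow(cat5),
                   has_cycle = cyc$has_cycle, n_cycles = length(cyc$cycles),
                   hyperbolic = hyp, frondose = nrow(cat5) == 32L,
                   matches_symmetric_part = matches)
  })
}
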