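# Shared fixtures and small oracles used across the suite.

# Brute-force admissibility oracle: solve every subset directly with solve(),
# independent of the package's enumeration path.
oracle_admissible_labels <- function(A, b) {
  n <- nrow(A)
  b <- rep(b, length.out = n)
  labs <- character(0)
  for (mask in 0:(2^n - 1)) {
    J <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(J) == 0L) {
      labs <- c(labs, "()")
      next
    }
    u <- tryCatch(solve(-A[J, J, drop = FALSE], b[J]), error = function(e) NULL)
    if (!is.null(u) && all(u > 1e-9)) {
      labs <- c(labs, paste0("(", paste(J, collapse = ","), ")"))
    }
  }
  labs
}

edge_pairs <- function(g) sort(paste(g$edges$from, g$edges$to, sep = "->"))

random_symmetric_stable <- function(n, margin = 0.3) {
  M <- matrix(rnorm(n * n), n, n)
  S <- (M + t(M)) / 2
  S - (max(0, max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)) +
         margin) * diag(n)
}
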