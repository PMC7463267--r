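# Independent naive implementations of the three feature transforms,
# written as literal nested loops over the defining sums.  They are the
# oracles the vectorized production code is checked against and must stay
# loop-literal.

naive_ac <- function(X, LG) {
  L <- nrow(X)
  out <- numeric(0)
  for (lg in seq_len(LG)) {
    for (i in 1:20) {
      mu <- mean(X[, i])
      s <- 0
      for (j in seq_len(L - lg)) s <- s + (X[j, i] - mu) * (X[j + lg, i] - mu)
      out <- c(out, unname(s / (L - lg)))
    }
  }
  out
}

naive_cc <- function(X, LG) {
  L <- nrow(X)
  out <- numeric(0)
  for (lg in seq_len(LG)) {
    for (i1 in 1:20) {
      for (i2 in 1:20) {
        if (i1 == i2) next
        m1 <- mean(X[, i1]); m2 <- mean(X[, i2])
        s <- 0
        for (j in seq_len(L - lg))
          s <- s + (X[j, i1] - m1) * (X[j + lg, i2] - m2)
        out <- c(out, unname(s / (L - lg)))
      }
    }
  }
  out
}

naive_sd <- function(X, k) {
  L <- nrow(X)
  out <- numeric(0)
  for (m in 1:20) {
    for (n in 1:20) {
      s <- 0
      for (i in seq_len(L - k)) s <- s + X[i, m] * X[i + k, n]
      out <- c(out, unname(s))
    }
  }
  out
}

# A random integer-score profile in the PSI-BLAST range.
random_profile <- function(L, id = "rnd", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(sample(-10:12, L * 20, replace = TRUE), L, 20)
  colnames(X) <- pssm_alphabet()
  new_pssm_profile(id, paste(sample(pssm_alphabet(), L, replace = TRUE),
                             collapse = ""), X)
}

# A profile whose first two columns are prescribed, the rest zero.
two_col_profile <- function(col1, col2) {
  L <- length(col1)
  X <- matrix(0, L, 20)
  X[, 1] <- col1; X[, 2] <- col2
  colnames(X) <- pssm_alphabet()
  new_pssm_profile("twocol", strrep("A", L), X)
}

# PSI-BLAST-style ASCII text with an arbitrary header column order.
pssm_text_with_order <- function(scores_in_order, order_letters,
                                 residues = NULL) {
  L <- nrow(scores_in_order)
  if (is.null(residues)) residues <- rep("A", L)
  c("",
    "Last position-specific scoring matrix computed",
    paste0("            ", paste(order_letters, collapse = "  "), "   ",
           paste(order_letters, collapse = "  ")),
    vapply(seq_len(L), function(i)
      paste0(sprintf("%5d %s ", i, residues[i]),
             paste(scores_in_order[i, ], collapse = " "), "  ",
             paste(rep(0, 20), collapse = " "), " 0.00 0.00"),
      character(1)),
    "")
}
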