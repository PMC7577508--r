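# two-sample chi-squared homogeneity test on a cell partition defined by
# the pooled per-axis quartiles: p-value for "A and B share one law"
two_sample_chisq_p <- function(A, B, nbins = 4) {
  cells <- function(M, br1, br2)
    table(cut(M[, 1], br1, include.lowest = TRUE),
          cut(M[, 2], br2, include.lowest = TRUE))
  pooled <- rbind(A, B)
  br1 <- unique(quantile(pooled[, 1], seq(0, 1, length.out = nbins + 1)))
  br2 <- unique(quantile(pooled[, 2], seq(0, 1, length.out = nbins + 1)))
  tab <- cbind(as.vector(cells(A, br1, br2)), as.vector(cells(B, br1, br2)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  suppressWarnings(chisq.test(tab)$p.value)
}

# independent oracle for the target law: plain prior draws filtered by the
# support predicate are uniform on support-within-box by construction
reference_support_sample <- function(mod, prior, n) {
  out <- matrix(NA_real_, 0, prior$d)
  while (nrow(out) < n) {
    cand <- sample_prior(prior, 4 * n, drop = FALSE)
    out <- rbind(out, cand[proposal_in_support(mod, prior, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
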