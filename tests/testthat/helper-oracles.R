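# Independent brute-force oracles used to cross-check the package's
# closed-form and optimizer-based results.

# Direct Gillespie simulation of a linear birth-death lineage started from
# one cell; returns TRUE if extinct by time t_end.
gillespie_lineage_extinct <- function(birth, death, t_end) {
  n <- 1L
  t <- 0
  repeat {
    if (n == 0L) return(TRUE)
    rate <- n * (birth + death)
    if (rate == 0) return(FALSE)
    t <- t + rexp(1, rate)
    if (t >= t_end) return(FALSE)
    if (runif(1) < birth / (birth + death)) n <- n + 1L else n <- n - 1L
  }
}

gillespie_extinction_fraction <- function(birth, death, t_end, n_lineages) {
  mean(vapply(seq_len(n_lineages), function(i) {
    gillespie_lineage_extinct(birth, death, t_end)
  }, logical(1)))
}

# Dense grid-search maximizer of the tag-loss log-likelihood.
grid_mle_loss <- function(n, lost, n_grid = 1e5) {
  grid <- exp(seq(log(1e-6), log(1), length.out = n_grid))
  ll <- vapply(grid, function(b) {
    sum(lost * (-b * n) + (1 - lost) * log1p(-exp(-b * n)))
  }, 0)
  grid[which.max(ll)]
}

loss_loglik_oracle <- function(beta, n, lost) {
  sum(lost * (-beta * n) + (1 - lost) * log1p(-exp(-beta * n)))
}
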