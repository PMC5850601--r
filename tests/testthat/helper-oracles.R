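# Independent oracles used across tests; these never call the package's
# simulation or estimation code paths.

# Neutral Wright-Fisher transition matrix on allele-copy counts 0..ng.
wf_transition_matrix <- function(ng) {
  p <- (0:ng) / ng
  outer(0:ng, 0:ng, function(i, j) dbinom(j, ng, p[i + 1L]))
}

# Exact allele-frequency distribution after t neutral generations.
wf_distribution <- function(p0, ng, t) {
  M <- wf_transition_matrix(ng)
  v <- dbinom(0:ng, ng, p0) # one generation of sampling from p0
  if (t > 1) for (k in seq_len(t - 1L)) v <- as.vector(v %*% M)
  v
}

wf_exact_var <- function(p0, ng, t) {
  v <- wf_distribution(p0, ng, t)
  x <- (0:ng) / ng
  sum(v * x^2) - sum(v * x)^2
}

wf_exact_loss_prob <- function(p0, ng, t) wf_distribution(p0, ng, t)[1L]

# Hand-rolled (weighted) OLS via normal equations, independent of the
# package's closed-form batch implementation.
ols_slope_intercept <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = b[1L], slope = b[2L])
}

std_design <- function(...) {
  sim_design(Ne = 300, generations = 60, interval = 10, replicates = 6,
             coverage = 80, ...)
}
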