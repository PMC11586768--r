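# Independent oracles and small fixture builders used across the suite.

# Michelot's alternating-projection algorithm for
#   min_z  g.z + beta ||z||^2   s.t.  sum z = 1, z >= 0,
# i.e. the Euclidean projection of -g/(2 beta) onto the probability simplex.
# Finite and exact; algorithmically unrelated to the package's sort-based
# closed form, so it serves as an independent solver.
michelot_simplex_qp <- function(g, beta) {
  v <- -g / (2 * beta)
  active <- rep(TRUE, length(v))
  repeat {
    v[active] <- v[active] - (sum(v[active]) - 1) / sum(active)
    neg <- active & (v < -1e-15)
    if (!any(neg)) break
    v[neg] <- 0
    active <- active & !neg
  }
  v[!active] <- 0
  pmax(v, 0)
}

simplex_qp_objective <- function(z, g, beta) sum(g * z) + beta * sum(z^2)

random_orthonormal <- function(n, m) {
  qr.Q(qr(matrix(stats::rnorm(n * m), n, m)))[, seq_len(m), drop = FALSE]
}

# block-constant similarity: `within` inside each block, `between` outside
block_similarity <- function(sizes, within = 1, between = 0) {
  lab <- rep(seq_along(sizes), sizes)
  S <- matrix(between, length(lab), length(lab))
  S[outer(lab, lab, "==")] <- within
  S
}

# tiny clustered feature matrix: one Gaussian blob per cluster mean
clustered_matrix <- function(n_per, means, p = 5, sigma = 0.1, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(seq_along(means), each = n_per)
    X <- matrix(stats::rnorm(length(lab) * p, mean = means[lab], sd = sigma),
                length(lab), p)
    rownames(X) <- sprintf("S%02d", seq_along(lab))
    list(X = X, labels = lab)
  })
}
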