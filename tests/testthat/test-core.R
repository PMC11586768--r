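test_that("initialization shifts distances and extracts spectral bases", {
  # all-zero distances: Z constant, so I - Z has a flat spectrum
  D0 <- matrix(0, 5, 5)
  st <- init_state(list(D0), C_s = 2, C = 2)
  expect_true(all(st$states[[1]]$Z == st$states[[1]]$Z[1, 1]))
  expect_identical(st$states[[1]]$weight, 1) # S = 1
  expect_equal(crossprod(st$consensus$Y), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # block structure: the spectral objective equals the sum of the smallest
  # eigenvalues of I - Z (full eigendecomposition oracle)
  D <- 1 - block_similarity(c(4, 4, 4))
  st <- init_state(list(D), C_s = 3, C = 3)
  Z <- st$states[[1]]$Z
  F_ <- st$states[[1]]$F
  M <- diag(12) - (Z + t(Z)) / 2
  obj <- sum(diag(crossprod(F_, M %*% F_)))
  expect_equal(obj, sum(sort(eigen(M, symmetric = TRUE)$values)[1:3]),
               tolerance = 1e-8)
  expect_error(init_state(list(D0, matrix(0, 4, 4)), 2, 2), "n mismatch")
})

test_that("the adaptive row update yields simplex rows with exactly k nonzeros", {
  withr::with_seed(31, {
    D <- as.matrix(dist(matrix(rnorm(12 * 3), 12, 3)))
    F_ <- random_orthonormal(12, 3)
    up <- update_Z(D, F_, beta = "adaptive", gamma = 0.2, k = 4)
    expect_equal(unname(rowSums(up$Z)), rep(1, 12), tolerance = 1e-12)
    expect_true(all(up$Z >= 0))
    expect_identical(unname(rowSums(up$Z > 0)), rep(4, 12))
    expect_identical(unname(diag(up$Z)), rep(0, 12))
    # each adaptive row is reproduced by an independent simplex-QP solver
    # run at that row's closed-form ridge value
    G <- D - 0.2 * tcrossprod(F_)
    for (i in c(1, 5, 12)) {
      z_oracle <- michelot_simplex_qp(G[i, -i], up$beta_rows[i])
      expect_equal(unname(up$Z[i, -i]), unname(z_oracle), tolerance = 1e-8)
    }
  })
})

test_that("tied costs give uniform rows and small ridges concentrate mass", {
  D <- 1 - block_similarity(c(6)) # all off-diagonal distances equal 0
  up <- update_Z(D + 1, matrix(0, 6, 1), beta = "adaptive", gamma = 0, k = 3)
  expect_equal(unname(up$Z[1, up$Z[1, ] > 0]), rep(1 / 3, 3), tolerance = 1e-12)
  # fixed beta -> 0+: all mass on the unique row minimum
  D2 <- matrix(5, 4, 4)
  D2[1, 3] <- 1
  z <- update_Z(D2, matrix(0, 4, 1), beta = 1e-8, gamma = 0, k = 2)$Z
  expect_equal(unname(z[1, ]), c(0, 0, 1, 0), tolerance = 1e-6)
})

test_that("fixed-ridge row updates match the independent simplex-QP solver", {
  withr::with_seed(32, {
    D <- as.matrix(dist(matrix(rnorm(10 * 4), 10, 4)))
    F_ <- random_orthonormal(10, 2)
    beta <- 0.7
    up <- update_Z(D, F_, beta = beta, gamma = 0.5, k = 4)
    G <- D - 0.5 * tcrossprod(F_)
    for (i in 1:10) {
      z_oracle <- michelot_simplex_qp(G[i, -i], beta)
      expect_equal(simplex_qp_objective(up$Z[i, -i], G[i, -i], beta),
                   simplex_qp_objective(z_oracle, G[i, -i], beta),
                   tolerance = 1e-10)
    }
  })
})

test_that("basis updates attain the spectral optimum", {
  withr::with_seed(33, {
    n <- 12
    Z <- update_Z(as.matrix(dist(matrix(rnorm(n * 3), n, 3))),
                  matrix(0, n, 1), k = 4)$Z
    Y <- random_orthonormal(n, 3)
    F_ <- update_F(Z, Y, w = 0.4, C_s = 3)
    expect_equal(crossprod(F_), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
    M <- (diag(n) - (Z + t(Z)) / 2) + 0.4 * (diag(n) - 2 * tcrossprod(Y))
    ev <- sort(eigen(M, symmetric = TRUE)$values)
    expect_equal(attr(F_, "objective"), sum(ev[1:3]), tolerance = 1e-8)
    expect_equal(sum(diag(crossprod(F_, M %*% F_))), sum(ev[1:3]),
                 tolerance = 1e-8)
  })
})

test_that("block-structured similarities give block-constant partition projectors", {
  Z <- block_similarity(c(5, 5), within = 0.2) # rows sum to 1 inside blocks
  F_ <- update_F(Z, random_orthonormal(10, 2), w = 1e-9, C_s = 2)
  P <- tcrossprod(F_)
  lab <- rep(1:2, each = 5)
  same <- P[outer(lab, lab, "==")]
  diff <- P[outer(lab, lab, "!=")]
  expect_lt(max(abs(diff)), 1e-6)
  expect_equal(unname(same), rep(0.2, length(same)), tolerance = 1e-6)
})

test_that("the consensus update recovers single and duplicated bases", {
  withr::with_seed(34, {
    F1 <- random_orthonormal(9, 3)
    Y1 <- update_Y(list(F1), list(1), C = 3)
    expect_lt(norm(tcrossprod(Y1) - tcrossprod(F1), "F"), 1e-8)
    Y2 <- update_Y(list(F1, F1), list(0.5, 0.5), C = 3)
    expect_lt(norm(tcrossprod(Y2) - tcrossprod(F1), "F"), 1e-8)
    # returned Y beats 100 random orthonormal candidates (n = 15, S = 3)
    Fs <- replicate(3, random_orthonormal(15, 3), simplify = FALSE)
    w <- c(0.5, 0.3, 0.2)
    Y <- update_Y(Fs, as.list(w), C = 3)
    cons_obj <- function(Yc) {
      sum(vapply(seq_along(Fs), function(s) {
        w[s] * norm(tcrossprod(Yc) - tcrossprod(Fs[[s]]), "F")^2
      }, numeric(1)))
    }
    best_random <- min(replicate(100, cons_obj(random_orthonormal(15, 3))))
    expect_lte(cons_obj(Y), best_random + 1e-10)
  })
})

test_that("continuation keeps degenerate trailing eigenvectors stable", {
  withr::with_seed(35, {
    F1 <- random_orthonormal(10, 2)
    # C = 3 > rank 2: the third direction is arbitrary without continuation
    Y0 <- update_Y(list(F1), list(1), C = 3)
    Y1 <- update_Y(list(F1), list(1), C = 3, prev = Y0)
    expect_lt(norm(tcrossprod(Y1) - tcrossprod(Y0), "F"), 1e-8)
  })
})

test_that("weights follow inverse residual norms and sum to one", {
  withr::with_seed(36, {
    Y <- random_orthonormal(8, 2)
    F1 <- random_orthonormal(8, 2)
    # residuals equal by symmetry of a duplicated basis
    expect_equal(update_weights(list(F1, F1), Y), c(0.5, 0.5), tolerance = 1e-12)
    expect_equal(update_weights(list(Y, Y), Y), c(0.5, 0.5)) # zero residuals
    # one exact agreement dominates
    w <- update_weights(list(Y, F1), Y)
    expect_gt(w[1], 0.999)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  })
  # residual norms (1, 2): raw (0.5, 0.25) normalizes to (2/3, 1/3)
  raw <- 1 / (2 * c(1, 2))
  expect_equal(raw / sum(raw), c(2 / 3, 1 / 3))
})

test_that("the loss decomposition sums its parts and matches direct accumulation", {
  withr::with_seed(37, {
    n <- 8
    D_list <- replicate(2, as.matrix(dist(matrix(rnorm(n * 3), n, 3))),
                        simplify = FALSE)
    states <- purrr::map(D_list, function(D) {
      list(Z = update_Z(D, matrix(0, n, 1), k = 3)$Z,
           F = random_orthonormal(n, 2), weight = 0.5, C_s = 2)
    })
    Y <- random_orthonormal(n, 2)
    beta <- 0.4; gamma <- 0.9
    lb <- parties_loss(states, list(Y = Y), D_list, beta, gamma)
    expect_equal(lb$total, lb$fidelity + lb$ridge + lb$spectral + lb$consensus,
                 tolerance = 1e-10)
    # direct scalar accumulation over entries
    tot <- 0
    for (s in 1:2) {
      Z <- states[[s]]$Z; F_ <- states[[s]]$F
      tot <- tot + sum(D_list[[s]] * Z) + beta * sum(Z^2) +
        gamma * (sum(diag(t(F_) %*% (diag(n) - (Z + t(Z)) / 2) %*% F_)) +
                   0.5 * sum((tcrossprod(Y) - tcrossprod(F_))^2))
    }
    expect_equal(lb$total, tot, tolerance = 1e-10)
    # one-hot rows: ||Z||_F^2 = n so the ridge term is beta * n * S
    one_hot <- diag(n)[, c(2:n, 1)]
    states_oh <- purrr::map(states, function(st) { st$Z <- one_hot; st })
    lb_oh <- parties_loss(states_oh, list(Y = Y), D_list, beta, gamma)
    expect_equal(lb_oh$ridge, beta * n * 2, tolerance = 1e-12)
  })
})

test_that("the full fit recovers well-separated clusters and is deterministic", {
  dat <- clustered_matrix(6, c(0, 10, 20), p = 8, sigma = 0.1, seed = 5)
  fit <- parties(dat$X, consensus_clusters = 3, per_type_clusters = 3)
  expect_equal(nmi(fit$labels, dat$labels), 1)
  expect_true(fit$converged)
  # bit-identical labels and trace across reruns
  fit2 <- parties(dat$X, consensus_clusters = 3, per_type_clusters = 3)
  expect_identical(fit$labels, fit2$labels)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  # duplicated data type agrees with the single-type fit up to relabeling
  fit_dup <- parties(list(a = dat$X, b = dat$X), consensus_clusters = 3,
                     per_type_clusters = 3)
  expect_equal(nmi(fit_dup$labels, fit$labels), 1)
  expect_equal(unname(fit_dup$weights), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("permuting input samples permutes the recovered partition", {
  dat <- clustered_matrix(5, c(0, 6, 12), p = 6, sigma = 0.3, seed = 6)
  fit <- parties(dat$X, consensus_clusters = 3, per_type_clusters = 3)
  perm <- withr::with_seed(7, sample(nrow(dat$X)))
  fit_p <- parties(dat$X[perm, ], consensus_clusters = 3, per_type_clusters = 3)
  expect_equal(nmi(fit_p$labels, fit$labels[perm]), 1)
})

test_that("the fit rejects invalid inputs with informative errors", {
  dat <- clustered_matrix(3, c(0, 5), p = 4, seed = 8)
  expect_error(parties(dat$X, consensus_clusters = 10), "fewer samples")
  Xconst <- matrix(2, 6, 3, dimnames = list(rownames(dat$X), NULL))
  expect_error(parties(list(ok = dat$X, bad = Xconst), consensus_clusters = 2),
               "bad.*zero variance")
  X2 <- dat$X
  rownames(X2) <- paste0("T", seq_len(nrow(X2)))
  expect_error(parties(list(a = dat$X, b = X2), consensus_clusters = 2),
               "harmonize_samples")
})

test_that("broom-style accessors expose assignments and diagnostics", {
  dat <- clustered_matrix(5, c(0, 8), p = 5, seed = 9)
  fit <- parties(dat$X, consensus_clusters = 2, per_type_clusters = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("sample_id", "cluster"))
  expect_identical(td$sample_id, rownames(dat$X))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_identical(gl$n, 10L)
  wt <- weight_table(fit)
  expect_equal(sum(wt$weight), 1, tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
})
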