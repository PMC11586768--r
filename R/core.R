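# Partition-level integration: the loss, its alternating optimization
# (simplex-constrained Z rows, spectral F/Y updates, adaptive weights),
# and the user-facing fitting front-end parties().

#' Configuration for partition-level integration
#'
#' @param k Neighbourhood size used for the kernel bandwidth, the diffusion
#'   transition matrix and the number of nonzeros per row of the learned
#'   similarity Z. Default `NULL` means `round(n/4)`.
#' @param per_type_clusters Integer vector of per-data-type cluster numbers
#'   `C_s`, a single integer recycled across data types, or `"auto"`
#'   (default) to select each by the eigengap criterion on the enhanced
#'   kernel.
#' @param consensus_clusters Number of consensus clusters C, or `"auto"` to
#'   select by the eigengap criterion on the initial integrated
#'   partition-level similarity.
#' @param beta Ridge penalty on Z. `"adaptive"` (default) sets a per-row
#'   value in closed form so each row of Z has exactly k nonzeros; a
#'   nonnegative number applies a fixed ridge with the row update solved by
#'   exact simplex projection.
#' @param gamma Strength of the partition feedback in the similarity row
#'   update (and the multiplier of the spectral/consensus terms in the
#'   reported loss). Default 0: the learned similarity is driven by the
#'   enhanced kernel distances alone, which keeps the row supports stable
#'   (positive feedback can lock borderline neighbours into a limit cycle
#'   on near-tied, e.g. presence/absence, distances). `"adaptive"` tracks
#'   the mean per-row adaptive ridge; any nonnegative number is accepted.
#' @param max_iterations Maximum outer alternating iterations (default 30).
#' @param tolerance Relative Frobenius change of the consensus projector
#'   `Y Y'` below which iteration stops (default 1e-6).
#' @param max_inner Maximum rounds of the within-iteration partition/
#'   consensus refinement: after each similarity update the basis updates
#'   are cycled to their joint fixed point (each round is a descent step of
#'   the loss), so the outer convergence monitor tracks the similarity and
#'   weight updates rather than the slow linear tail of the basis
#'   alternation. Default 100; 1 reproduces plain single-pass updates.
#' @param kmeans_restarts Restarts for the final k-means (default 20).
#' @param random_seed Seed for k-means initialization (default 0).
#' @param row_normalize_Y Row-normalize Y before k-means (default FALSE;
#'   plain k-means on Y is the method's convention).
#' @param freeze_weights Keep weights fixed at their initial value 1/S
#'   (used for optimization diagnostics; default FALSE).
#' @param eigengap_on Similarity the eigengap criterion is applied to when
#'   `per_type_clusters = "auto"`: `"localized"` (default; the
#'   kNN-localized similarity learned from the enhanced kernel distance,
#'   see [localized_similarity()]) or `"kernel"` (the dense enhanced
#'   kernel). The adaptive-bandwidth kernel is near-constant when many
#'   noise features dominate pairwise distances, which masks the spectral
#'   gap; localization restores it.
#' @return List of class `parties_config`.
#' @export
parties_config <- function(k = NULL,
                           per_type_clusters = "auto",
                           consensus_clusters = "auto",
                           beta = "adaptive",
                           gamma = 0,
                           max_iterations = 30L,
                           tolerance = 1e-6,
                           max_inner = 100L,
                           kmeans_restarts = 20L,
                           random_seed = 0L,
                           row_normalize_Y = FALSE,
                           freeze_weights = FALSE,
                           eigengap_on = c("localized", "kernel")) {
  stopifnot(max_iterations >= 1L, tolerance > 0, kmeans_restarts >= 1L,
            max_inner >= 1L)
  if (is.numeric(beta) && beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (is.numeric(gamma) && gamma < 0) stop("gamma must be nonnegative", call. = FALSE)
  if (is.numeric(consensus_clusters) && consensus_clusters < 2)
    stop("consensus_clusters must be at least 2", call. = FALSE)
  if (is.numeric(per_type_clusters) && any(per_type_clusters < 2))
    stop("per_type_clusters must all be at least 2", call. = FALSE)
  structure(list(
    k = if (is.null(k)) NULL else as.integer(k),
    per_type_clusters = per_type_clusters,
    consensus_clusters = consensus_clusters,
    beta = beta, gamma = gamma,
    max_iterations = as.integer(max_iterations),
    tolerance = tolerance,
    max_inner = as.integer(max_inner),
    kmeans_restarts = as.integer(kmeans_restarts),
    random_seed = as.integer(random_seed),
    row_normalize_Y = isTRUE(row_normalize_Y),
    freeze_weights = isTRUE(freeze_weights),
    eigengap_on = match.arg(eigengap_on)
  ), class = "parties_config")
}

# Euclidean projection of v onto the probability simplex (sort-based exact
# algorithm); used for the fixed-beta row update.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(u)
  rho <- max(j[u + (1 - css) / j > 0])
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

#' Initialize the optimization state
#'
#' Shifts each enhanced kernel distance into an initial similarity
#' `Z = max(D) - D`, extracts each partition basis `F_s` as the bottom `C_s`
#' eigenvectors of `I - Z_s`, sets uniform weights `1/S`, and initializes the
#' consensus basis `Y` from the weighted average partition-level similarity.
#'
#' @param D_enh_list List of enhanced kernel distance matrices, one per data
#'   type, sharing dimension n.
#' @param C_s Integer vector of per-data-type cluster numbers.
#' @param C Number of consensus clusters.
#' @return List with `states` (per data type: `Z`, `F`, `weight`, `C_s`) and
#'   `consensus` (list with `Y`, `C`).
#' @export
init_state <- function(D_enh_list, C_s, C) {
  ns <- vapply(D_enh_list, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all data types must share the same samples (n mismatch)", call. = FALSE)
  n <- ns[1]
  S <- length(D_enh_list)
  C_s <- rep_len(as.integer(C_s), S)
  states <- purrr::map2(D_enh_list, C_s, function(D, cs) {
    D <- check_square(D, "D_enh")
    Z <- max(D) - D
    F_ <- bottom_eigenvectors(diag(n) - (Z + t(Z)) / 2, cs)
    list(Z = Z, F = F_, weight = 1 / S, C_s = cs)
  })
  Y <- update_Y(purrr::map(states, "F"), rep(1 / S, S), C)
  list(states = states, consensus = list(Y = Y, C = as.integer(C)))
}

#' Row-wise simplex-constrained update of a learned similarity
#'
#' For each sample i the row of Z solves
#' \deqn{\min_{z \in \Delta} \sum_j z_j g_{ij} + \beta \sum_j z_j^2,\qquad
#'       g_{ij} = D(i,j) - \gamma (F F^\top)_{ij},}
#' with the self entry excluded from the support. With `beta = "adaptive"`
#' a per-row ridge is set in closed form so the solution has exactly k
#' nonzeros (the adaptive-neighbour construction); with numeric `beta` the
#' row is the exact Euclidean projection of `-g/(2 beta)` onto the simplex.
#'
#' @param D_enh Enhanced kernel distance matrix.
#' @param F_ Orthonormal partition basis of the data type.
#' @param beta `"adaptive"` or a positive number.
#' @param gamma Nonnegative spectral weight.
#' @param k Target nonzeros per row (adaptive mode).
#' @return List with `Z` (rows on the simplex, zero diagonal) and
#'   `beta_rows` (the per-row ridge values; equals `beta` in fixed mode).
#' @export
update_Z <- function(D_enh, F_, beta = "adaptive", gamma = 0, k = NULL) {
  D_enh <- check_square(D_enh, "D_enh")
  n <- nrow(D_enh)
  if (is.null(k)) k <- default_k(n)
  k <- as.integer(min(k, n - 2L))
  if (k < 1L) stop("n too small for the adaptive row update", call. = FALSE)
  G <- D_enh - gamma * tcrossprod(F_)
  Z <- matrix(0, n, n, dimnames = dimnames(D_enh))
  beta_rows <- numeric(n)
  adaptive <- identical(beta, "adaptive")
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    g <- G[i, idx]
    if (adaptive) {
      ord <- order(g, idx)
      gs <- g[ord]
      top <- gs[seq_len(k)]
      gk1 <- gs[k + 1L]
      denom <- k * gk1 - sum(top)
      beta_rows[i] <- denom / 2
      z <- if (denom > 1e-12) (gk1 - top) / denom else rep(1 / k, k)
      Z[i, idx[ord[seq_len(k)]]] <- z
    } else {
      beta_rows[i] <- beta
      Z[i, idx] <- project_simplex(-g / (2 * beta))
    }
  }
  list(Z = Z, beta_rows = beta_rows)
}

#' Spectral update of a per-data-type partition basis
#'
#' Returns the bottom `C_s` eigenvectors of
#' \eqn{M = (I - sym(Z)) + w (I - 2 Y Y^\top)} (with
#' \eqn{sym(Z) = (Z + Z^\top)/2}), the minimizer of the data type's spectral
#' plus consensus terms over orthonormal bases.
#'
#' @param Z Learned similarity (row-stochastic; symmetrized internally).
#' @param Y Consensus basis.
#' @param w Positive weight of the data type.
#' @param C_s Basis dimension (number of clusters for the data type).
#' @param prev Previous basis (optional); when the eigenvalue at the cut is
#'   (near-)degenerate the returned basis is chosen, within the optimal
#'   invariant subspace, to maximize overlap with `prev`. Any orthonormal
#'   basis of that subspace attains the same objective; continuation makes
#'   the iteration deterministic and stops phantom rotations.
#' @return n x C_s orthonormal matrix with attribute `objective`, the sum of
#'   the C_s smallest eigenvalues of M.
#' @export
update_F <- function(Z, Y, w, C_s, prev = NULL) {
  n <- nrow(Z)
  M <- (diag(n) - (Z + t(Z)) / 2) + w * (diag(n) - 2 * tcrossprod(Y))
  bottom_subspace(M, C_s, prev)
}

# bottom-m invariant subspace of symmetric M with continuation across a
# degenerate cut: directions inside the eigenvalue block straddling the cut
# are picked to maximize overlap with the previous basis
bottom_subspace <- function(M, m, prev = NULL, tol = 1e-8) {
  e <- eigen_ascending(M)
  vals <- e$values
  objective <- sum(vals[seq_len(m)])
  band <- tol * max(1, abs(vals[m]))
  if (!is.null(prev) && m < length(vals) && vals[m + 1L] - vals[m] < band) {
    in_block <- abs(vals - vals[m]) < band
    fixed <- which(vals < vals[m] - band)
    block <- which(in_block)
    need <- m - length(fixed)
    B <- e$vectors[, block, drop = FALSE]
    # overlap of the previous projector with the degenerate block
    G <- crossprod(B, prev)
    sv <- svd(G)
    pick <- B %*% sv$u[, seq_len(need), drop = FALSE]
    V <- cbind(e$vectors[, fixed, drop = FALSE], pick)
  } else {
    V <- e$vectors[, seq_len(m), drop = FALSE]
  }
  attr(V, "objective") <- objective
  V
}

#' Spectral update of the consensus basis
#'
#' Returns the bottom `C` eigenvectors of
#' \eqn{I - \sum_s 2 w_s F_s F_s^\top}, the minimizer of the weighted
#' consensus term over orthonormal bases.
#'
#' @param F_list List of per-data-type orthonormal bases.
#' @param w_list Positive weights summing to 1.
#' @param C Consensus basis dimension.
#' @param prev Previous consensus basis (optional); see [update_F()] for the
#'   degenerate-cut continuation rule.
#' @return n x C orthonormal matrix with attribute `objective`.
#' @export
update_Y <- function(F_list, w_list, C, prev = NULL) {
  n <- nrow(F_list[[1]])
  M <- diag(n)
  for (s in seq_along(F_list)) M <- M - 2 * w_list[[s]] * tcrossprod(F_list[[s]])
  bottom_subspace(M, C, prev)
}

#' Adaptive data-type weights
#'
#' \eqn{w_s \propto 1 / (2 \|Y Y^\top - F_s F_s^\top\|_F)}, normalized to sum
#' to 1, so data types whose partition structure agrees with the consensus
#' contribute more. An epsilon guard (1e-10) protects the exact-agreement
#' limit; if every residual is below the guard, weights fall back to uniform.
#'
#' @param F_list List of per-data-type orthonormal bases.
#' @param Y Consensus basis.
#' @return Numeric weights, one per data type, summing to 1.
#' @export
update_weights <- function(F_list, Y) {
  YY <- tcrossprod(Y)
  res <- vapply(F_list, function(F_) norm(YY - tcrossprod(F_), "F"), numeric(1))
  S <- length(res)
  if (all(res < 1e-10)) return(rep(1 / S, S))
  raw <- 1 / (2 * res + 1e-10)
  raw / sum(raw)
}

#' Loss decomposition of the integration objective
#'
#' Evaluates the four terms of the objective at the supplied state: the
#' fidelity term \eqn{\sum_s \langle D_s, Z_s\rangle_F}, the ridge
#' \eqn{\beta \sum_s \|Z_s\|_F^2}, the spectral term
#' \eqn{\gamma \sum_s tr(F_s^\top (I - Z_s) F_s)} and the consensus term
#' \eqn{\gamma \sum_s w_s \|Y Y^\top - F_s F_s^\top\|_F^2}.
#'
#' @param states Per-data-type states (as from [init_state()]).
#' @param consensus Consensus state (list with `Y`).
#' @param D_enh_list Enhanced kernel distances, one per data type.
#' @param beta,gamma Scalar hyper-parameters the terms are evaluated at.
#' @return Tibble with one row: `fidelity`, `ridge`, `spectral`,
#'   `consensus`, `total`.
#' @export
parties_loss <- function(states, consensus, D_enh_list, beta, gamma) {
  YY <- tcrossprod(consensus$Y)
  fidelity <- ridge <- spectral <- consens <- 0
  for (s in seq_along(states)) {
    st <- states[[s]]
    n <- nrow(st$Z)
    fidelity <- fidelity + sum(D_enh_list[[s]] * st$Z)
    ridge <- ridge + beta * sum(st$Z^2)
    spectral <- spectral +
      gamma * sum(diag(crossprod(st$F, (diag(n) - (st$Z + t(st$Z)) / 2) %*% st$F)))
    consens <- consens + gamma * st$weight * norm(YY - tcrossprod(st$F), "F")^2
  }
  tibble::tibble(fidelity = fidelity, ridge = ridge, spectral = spectral,
                 consensus = consens, total = fidelity + ridge + spectral + consens)
}

#' kNN-localized similarity from a kernel distance
#'
#' Symmetrized solution of the adaptive-neighbour row update at `gamma = 0`:
#' each row keeps its k nearest neighbours (by the supplied distance) with
#' simplex-normalized weights. Unlike the dense adaptive-bandwidth kernel —
#' whose entries become near-constant when noise features dominate pairwise
#' distances — this similarity exposes the cluster block structure, and it
#' is what the eigengap criterion is applied to by default.
#'
#' @param D Symmetric distance matrix (typically an enhanced kernel
#'   distance).
#' @param k Nonzeros per row before symmetrization (default `round(n/4)`).
#' @return Symmetric nonnegative n x n similarity matrix.
#' @export
localized_similarity <- function(D, k = NULL) {
  D <- check_square(D, "D")
  n <- nrow(D)
  if (is.null(k)) k <- default_k(n)
  Z <- update_Z(D, matrix(0, n, 1L), beta = "adaptive", gamma = 0, k = k)$Z
  (Z + t(Z)) / 2
}

# one full alternating optimization given enhanced kernel distances;
# returns states, consensus, loss trace, convergence diagnostics
parties_core <- function(D_enh_list, C_s, C, config, keep_history = FALSE) {
  n <- nrow(D_enh_list[[1]])
  S <- length(D_enh_list)
  k <- config$k %||% default_k(n)
  k <- min(k, n - 2L)
  init <- init_state(D_enh_list, C_s, C)
  states <- init$states
  consensus <- init$consensus
  weights <- rep(1 / S, S)

  # initial gamma for the adaptive rule: mean adaptive ridge of a
  # partition-free (gamma = 0) pass over the distances
  adaptive_gamma <- identical(config$gamma, "adaptive")
  gamma <- if (adaptive_gamma) {
    mean(vapply(D_enh_list, function(D) {
      mean(update_Z(D, matrix(0, n, 1L), beta = "adaptive", gamma = 0, k = k)$beta_rows)
    }, numeric(1)))
  } else config$gamma

  trace <- vector("list", config$max_iterations)
  subspace_change <- numeric(0)
  history <- if (keep_history) list() else NULL
  converged <- FALSE
  YY_prev <- tcrossprod(consensus$Y)
  iter <- 0L

  for (t in seq_len(config$max_iterations)) {
    iter <- t
    beta_means <- numeric(S)
    for (s in seq_len(S)) {
      up <- update_Z(D_enh_list[[s]], states[[s]]$F, beta = config$beta,
                     gamma = gamma, k = k)
      states[[s]]$Z <- up$Z
      beta_means[s] <- mean(up$beta_rows)
    }
    beta_scalar <- if (identical(config$beta, "adaptive")) mean(beta_means) else config$beta
    if (adaptive_gamma) gamma <- mean(beta_means)

    if (!config$freeze_weights) {
      weights <- update_weights(purrr::map(states, "F"), consensus$Y)
    }
    for (s in seq_len(S)) states[[s]]$weight <- weights[s]
    # cycle the basis updates to their joint fixed point; every round is a
    # descent step of the loss at fixed Z, weights, beta, gamma
    inner_tol <- config$tolerance / 100
    for (j in seq_len(config$max_inner)) {
      YY_inner <- tcrossprod(consensus$Y)
      for (s in seq_len(S)) {
        states[[s]]$F <- update_F(states[[s]]$Z, consensus$Y, weights[s],
                                  C_s[s], prev = states[[s]]$F)
      }
      consensus$Y <- update_Y(purrr::map(states, "F"), weights, C,
                              prev = consensus$Y)
      if (norm(tcrossprod(consensus$Y) - YY_inner, "F") /
            norm(YY_inner, "F") < inner_tol) break
    }

    YY <- tcrossprod(consensus$Y)
    delta <- norm(YY - YY_prev, "F") / norm(YY_prev, "F")
    subspace_change <- c(subspace_change, delta)
    YY_prev <- YY

    lb <- parties_loss(states, consensus, D_enh_list, beta_scalar, gamma)
    trace[[t]] <- dplyr::mutate(lb, iteration = t, beta = beta_scalar,
                                gamma = gamma, subspace_change = delta,
                                .before = 1)
    if (keep_history) {
      history[[t]] <- list(states = states, consensus = consensus,
                           weights = weights, loss = lb)
    }
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }

  list(states = states, consensus = consensus, weights = weights,
       loss_trace = dplyr::bind_rows(trace[seq_len(iter)]),
       converged = converged, iterations = iter, gamma = gamma,
       history = history)
}

#' Fit the partition-level integration model
#'
#' Full pipeline on one or more omics feature matrices sharing samples:
#' feature standardization, adaptive Gaussian kernel, one-hop diffusion
#' enhancement, eigengap selection of cluster numbers (when `"auto"`), the
#' alternating partition-level optimization, and final k-means on the
#' consensus basis Y.
#'
#' @param X_list A named list of feature matrices (samples x features) or
#'   data frames with a `sample_id` column; a single matrix/data frame is
#'   also accepted. All data types must share the same sample identifiers
#'   (use [harmonize_samples()] first if they do not).
#' @param config A [parties_config()] object; individual fields can also be
#'   overridden through `...`.
#' @param standardize Standardize features to mean 0 / SD 1 (default TRUE).
#' @param keep_history Keep per-iteration states for diagnostics (memory-
#'   heavy; default FALSE).
#' @param ... Named [parties_config()] arguments overriding `config`.
#' @return Object of class `parties`: cluster `labels`, consensus basis `Y`,
#'   per-data-type `states` (`Z`, `F`, `weight`, `C_s`), `weights`,
#'   `loss_trace` tibble, `eigengap` reports, convergence diagnostics and
#'   the resolved configuration.
#' @export
parties <- function(X_list, config = parties_config(), standardize = TRUE,
                    keep_history = FALSE, ...) {
  dots <- list(...)
  if (length(dots)) {
    config <- do.call(parties_config, utils::modifyList(unclass(config), dots))
  }
  if (is.matrix(X_list) || is.data.frame(X_list)) X_list <- list(data1 = X_list)
  if (is.null(names(X_list)) || any(!nzchar(names(X_list))))
    names(X_list) <- paste0("data", seq_along(X_list))
  X_list <- purrr::imap(X_list, ~ as_feature_matrix(.x, .y))

  ids <- rownames(X_list[[1]])
  for (nm in names(X_list)) {
    if (!setequal(rownames(X_list[[nm]]), ids))
      stop("sample identifiers differ across data types; ",
           "use harmonize_samples() first", call. = FALSE)
    X_list[[nm]] <- X_list[[nm]][ids, , drop = FALSE]
    if (all(apply(X_list[[nm]], 2, stats::var) == 0))
      stop("data type '", nm, "' has zero variance everywhere", call. = FALSE)
  }
  n <- length(ids)
  S <- length(X_list)
  k <- config$k %||% default_k(n)

  sims <- purrr::map(X_list, enhance_similarity, k = k, standardize = standardize)
  D_enh_list <- purrr::map(sims, "D_enh")

  # per-data-type cluster numbers
  eigengap_reports <- NULL
  if (identical(config$per_type_clusters, "auto")) {
    eigengap_reports <- purrr::map(sims, function(sm) {
      Sgap <- if (config$eigengap_on == "kernel") sm$K_enh else
        localized_similarity(sm$D_enh, k)
      eigengap_select(Sgap, c_max = min(10L, n - 1L))
    })
    C_s <- vapply(eigengap_reports, `[[`, integer(1), "selected")
  } else {
    C_s <- rep_len(as.integer(config$per_type_clusters), S)
  }

  # consensus cluster number
  if (identical(config$consensus_clusters, "auto")) {
    F0 <- purrr::map2(D_enh_list, C_s, function(D, cs) {
      Z0 <- max(D) - D
      bottom_eigenvectors(diag(n) - (Z0 + t(Z0)) / 2, cs)
    })
    Sbar <- Reduce(`+`, purrr::map(F0, ~ 2 / S * tcrossprod(.x)))
    C <- eigengap_select(Sbar, c_max = min(10L, n - 1L))$selected
  } else {
    C <- as.integer(config$consensus_clusters)
  }
  if (n < C) stop("fewer samples than consensus clusters", call. = FALSE)

  core <- parties_core(D_enh_list, C_s, C, config, keep_history = keep_history)

  Yk <- core$consensus$Y
  if (config$row_normalize_Y) {
    rn <- sqrt(rowSums(Yk^2))
    rn[rn == 0] <- 1
    Yk <- Yk / rn
  }
  labels <- seeded_kmeans(Yk, C, config$kmeans_restarts, config$random_seed)
  names(labels) <- ids

  structure(list(
    labels = labels, Y = core$consensus$Y, C = C, C_s = C_s,
    states = purrr::set_names(core$states, names(X_list)),
    weights = purrr::set_names(core$weights, names(X_list)),
    loss_trace = core$loss_trace, subspace_change = core$loss_trace$subspace_change,
    converged = core$converged, iterations = core$iterations,
    eigengap = eigengap_reports, gamma = core$gamma,
    kernels = purrr::map(sims, "K_enh"),
    sample_ids = ids, n = n, config = config, history = core$history
  ), class = "parties")
}

#' @export
print.parties <- function(x, ...) {
  cat("Partition-level integration fit\n")
  cat("  samples:", x$n, " data types:", length(x$states),
      " consensus clusters:", x$C, "\n")
  cat("  per-type clusters:", paste(x$C_s, collapse = ", "), "\n")
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  cat("  ", if (x$converged) "converged" else "stopped", "after",
      x$iterations, "iterations (subspace change ",
      signif(utils::tail(x$subspace_change, 1), 3), ")\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}
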