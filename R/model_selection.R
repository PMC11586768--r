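# Spectral embedding, spectral clustering, and eigengap-based selection of
# the number of clusters.

# symmetric normalized graph Laplacian I - D^{-1/2} S D^{-1/2};
# isolated vertices get degree-guard 1 so L stays finite
normalized_laplacian <- function(S) {
  S <- check_square(S, "S")
  S <- (S + t(S)) / 2
  deg <- rowSums(abs(S))
  deg[deg < .Machine$double.eps] <- 1
  dmh <- 1 / sqrt(deg)
  L <- diag(nrow(S)) - (dmh * S) %*% diag(dmh)
  (L + t(L)) / 2
}

# eigenpairs of a symmetric matrix, ascending by eigenvalue
eigen_ascending <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

# orthonormal basis of the m smallest eigenvectors of symmetric M
bottom_eigenvectors <- function(M, m) {
  e <- eigen_ascending(M)
  e$vectors[, seq_len(m), drop = FALSE]
}

#' Smallest eigenvalues of the normalized graph Laplacian
#'
#' @param S Symmetric similarity matrix (symmetrized if not exactly so).
#' @param how_many Number of smallest eigenvalues to return.
#' @return Ascending numeric vector of length `how_many`.
#' @export
laplacian_eigenvalues <- function(S, how_many = nrow(as.matrix(S))) {
  L <- normalized_laplacian(S)
  if (how_many > nrow(L)) stop("how_many exceeds the matrix dimension", call. = FALSE)
  eigen_ascending(L)$values[seq_len(how_many)]
}

#' Select the number of clusters by the eigengap criterion
#'
#' Computes the ascending spectrum of the normalized graph Laplacian of a
#' similarity matrix and selects the candidate c in `[c_min, c_max]`
#' maximizing the gap \eqn{\lambda_{c+1} - \lambda_c}; ties go to the
#' smallest c. A flat spectrum (all candidate gaps below 1e-12) indicates an
#' uninformative data type: the report is flagged and `c_min` returned.
#'
#' @param S Symmetric similarity matrix.
#' @param c_min,c_max Candidate range for the number of clusters (defaults 2
#'   and 10; `c_max` is clamped to n - 1).
#' @return Object of class `eigengap_report`: list with `selected`,
#'   `candidate_range`, `eigenvalues`, `gaps` (named by candidate c), and
#'   `flat` (logical flag).
#' @export
eigengap_select <- function(S, c_min = 2L, c_max = 10L) {
  S <- check_square(S, "S")
  n <- nrow(S)
  c_max <- min(as.integer(c_max), n - 1L)
  c_min <- as.integer(c_min)
  if (c_min < 1L || c_min > c_max) stop("invalid candidate range", call. = FALSE)
  lam <- laplacian_eigenvalues(S, c_max + 1L)
  cand <- c_min:c_max
  gaps <- lam[cand + 1L] - lam[cand]
  names(gaps) <- cand
  flat <- all(gaps < 1e-12)
  selected <- if (flat) c_min else cand[which.max(gaps)]
  structure(
    list(selected = selected, candidate_range = c(c_min, c_max),
         eigenvalues = lam, gaps = gaps, flat = flat),
    class = "eigengap_report"
  )
}

#' @export
print.eigengap_report <- function(x, ...) {
  cat("Eigengap report: selected C =", x$selected,
      if (x$flat) "(flat spectrum; uninformative similarity)" else "", "\n")
  cat("  candidates:", paste(x$candidate_range, collapse = "-"),
      " gaps:", paste(signif(x$gaps, 3), collapse = " "), "\n")
  invisible(x)
}

#' Tidy an eigengap report
#'
#' @param x An `eigengap_report`.
#' @param ... Unused.
#' @return Tibble with one row per candidate cluster number: `c`, `lambda`,
#'   `gap`, `selected`.
#' @export
tidy.eigengap_report <- function(x, ...) {
  cand <- x$candidate_range[1]:x$candidate_range[2]
  tibble::tibble(
    c = cand,
    lambda = x$eigenvalues[cand],
    gap = unname(x$gaps),
    selected = cand == x$selected
  )
}

#' Spectral clustering on a similarity matrix
#'
#' Embeds samples in the bottom `C` eigenvectors of the normalized graph
#' Laplacian and partitions the embedding with k-means (multiple restarts,
#' seeded for determinism).
#'
#' @param S Symmetric similarity matrix.
#' @param C Number of clusters.
#' @param restarts k-means restarts (default 20).
#' @param seed Integer seed for the k-means initialization.
#' @return Integer cluster labels in 1..C, named by the similarity's dimnames.
#' @export
spectral_cluster <- function(S, C, restarts = 20L, seed = 0L) {
  S <- check_square(S, "S")
  if (C < 2L || C > nrow(S)) stop("C out of range", call. = FALSE)
  U <- bottom_eigenvectors(normalized_laplacian(S), C)
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn # NJW row normalization of the embedding
  labels <- seeded_kmeans(U, C, restarts, seed)
  names(labels) <- rownames(S)
  labels
}

# deterministic k-means labels: fixed local seed, best of `restarts` starts
seeded_kmeans <- function(U, C, restarts, seed) {
  withr::with_seed(as.integer(seed), {
    km <- stats::kmeans(U, centers = C, nstart = restarts, iter.max = 100L)
  })
  as.integer(km$cluster)
}
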