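# Per-data-type similarity construction: adaptive-bandwidth Gaussian kernels,
# kernel distances, kNN transition matrices and one-hop diffusion enhancement.

#' Standardize features to mean 0 and SD 1
#'
#' Centers each feature (column) and scales it by its population standard
#' deviation (denominator n). Constant columns are mapped to all-zeros rather
#' than NaN so that downstream pairwise distances ignore them.
#'
#' @param X Numeric matrix, samples in rows; row names are sample identifiers.
#' @return Matrix of the same dimensions with each non-constant column having
#'   mean 0 and population SD 1.
#' @export
zscore_features <- function(X) {
  X <- as_feature_matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sds <- sqrt(colMeans(Xc^2))
  sds[sds == 0] <- Inf # constant features -> 0 after scaling
  sweep(Xc, 2L, sds, "/")
}

# validate and coerce a samples-by-features input (matrix or data frame with
# an optional sample_id column) to a numeric matrix with rownames
as_feature_matrix <- function(X, name = "X") {
  if (is.data.frame(X)) {
    id_col <- intersect(c("sample_id", "sample", "id"), names(X))[1]
    if (!is.na(id_col)) {
      ids <- as.character(X[[id_col]])
      X <- as.matrix(X[setdiff(names(X), id_col)])
      rownames(X) <- ids
    } else {
      X <- as.matrix(X)
    }
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(name, " must be a numeric matrix or a data frame of numeric features",
         call. = FALSE)
  }
  if (nrow(X) < 1L || ncol(X) < 1L) stop(name, " is empty", call. = FALSE)
  if (!all(is.finite(X))) stop(name, " contains non-finite values", call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (anyDuplicated(rownames(X))) stop("duplicate sample identifiers in ", name, call. = FALSE)
  X
}

# k nearest neighbours of each row of a distance matrix, self excluded,
# ties broken by ascending sample index; returns n x k index matrix
knn_index <- function(Dm, k) {
  n <- nrow(Dm)
  if (k < 1L || k > n - 1L) {
    stop("k must be between 1 and n - 1 (n = ", n, ", k = ", k, ")", call. = FALSE)
  }
  res <- vapply(seq_len(n), function(i) {
    d <- Dm[i, ]
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  }, integer(k))
  if (is.null(dim(res))) res <- matrix(res, nrow = 1L) # k = 1
  t(res)
}

#' Gaussian kernel with adaptive local bandwidth
#'
#' Pairwise sample similarities
#' \deqn{K(i,j) = \exp\{-\|x_i - x_j\|_2^2 / (2\,\epsilon(i,j)^2)\}}
#' with \eqn{\epsilon(i,j) = \mu_i + \mu_j}, where \eqn{\mu_i} is the mean
#' Euclidean distance from sample i to its k nearest neighbours (self
#' excluded). The locally adaptive bandwidth makes the similarity scale
#' follow each sample's neighbourhood density.
#'
#' @param X Numeric matrix (samples x features) or data frame with a
#'   `sample_id` column.
#' @param k Number of nearest neighbours defining the local bandwidth;
#'   defaults to `round(n/4)`.
#' @return Symmetric n x n kernel matrix with unit diagonal and entries in
#'   (0, 1], with sample identifiers as dimnames and attribute `k`.
#' @export
gaussian_kernel <- function(X, k = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(k)) k <- default_k(n)
  k <- as.integer(k)
  E <- as.matrix(stats::dist(X))
  nn <- knn_index(E, k)
  mu <- vapply(seq_len(n), function(i) mean(E[i, nn[i, ]]), numeric(1))
  eps <- outer(mu, mu, "+")
  eps <- pmax(eps, 1e-12) # coincident neighbourhoods: continuity limit K = 1
  K <- exp(-(E^2) / (2 * eps^2))
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "k") <- k
  K
}

#' Default neighbourhood size
#'
#' The method's working neighbourhood size, `round(n/4)`, clamped to
#' `[1, n - 1]`.
#'
#' @param n Number of samples.
#' @return Integer neighbourhood size.
#' @export
default_k <- function(n) {
  max(1L, min(n - 1L, as.integer(round(n / 4))))
}

#' Kernel-induced distance
#'
#' \eqn{D(i,j) = K(i,i) + K(j,j) - 2 K(i,j)}; for a kernel with unit diagonal
#' this is \eqn{2(1 - K(i,j))}.
#'
#' @param K Square symmetric kernel (raw or diffusion-enhanced).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
kernel_distance <- function(K) {
  K <- check_square(K, "K")
  # note: a diffusion-enhanced kernel is not positive semi-definite, so
  # off-diagonal entries can be (slightly) negative; the formula is kept
  # exact because the neighbour ordering it induces is what matters
  dK <- diag(K)
  D <- outer(dK, dK, "+") - 2 * K
  diag(D) <- 0
  D
}

check_square <- function(M, name) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop(name, " must be square", call. = FALSE)
  if (!all(is.finite(M))) stop(name, " contains non-finite values", call. = FALSE)
  M
}

#' k-nearest-neighbour transition matrix
#'
#' Row-stochastic local similarity
#' \eqn{P(i,j) = K(i,j) I\{j \in N_k(i)\} / \sum_{l \in N_k(i)} K(i,l)}.
#' Neighbourhoods are defined by the kernel distance induced by `K`, self
#' excluded, ties broken by ascending sample index.
#'
#' @param K Kernel matrix as produced by [gaussian_kernel()].
#' @param k Neighbourhood size; defaults to `attr(K, "k")` or `round(n/4)`.
#' @return Row-stochastic n x n matrix supported on each row's k nearest
#'   neighbours.
#' @export
knn_transition <- function(K, k = NULL) {
  K <- check_square(K, "K")
  n <- nrow(K)
  if (is.null(k)) k <- attr(K, "k") %||% default_k(n)
  k <- as.integer(k)
  nn <- knn_index(kernel_distance(K), k)
  P <- matrix(0, n, n, dimnames = dimnames(K))
  for (i in seq_len(n)) {
    w <- K[i, nn[i, ]]
    P[i, nn[i, ]] <- w / sum(w)
  }
  attr(P, "k") <- k
  P
}

#' One-hop diffusion enhancement of a kernel
#'
#' Smooths a kernel by one step of the kNN random walk,
#' \eqn{K_{enh} = (K P^\top + P K) / 2}, which denoises similarities using
#' neighbourhood information while keeping the matrix symmetric.
#'
#' @param K Kernel matrix.
#' @param P Row-stochastic transition matrix from [knn_transition()].
#' @return Symmetric enhanced kernel, same dimension as `K`.
#' @export
diffuse_kernel <- function(K, P) {
  K <- check_square(K, "K")
  P <- check_square(P, "P")
  if (nrow(K) != nrow(P)) stop("K and P must have the same dimension", call. = FALSE)
  Kenh <- (K %*% t(P) + P %*% K) / 2
  Kenh <- (Kenh + t(Kenh)) / 2 # enforce exact symmetry
  dimnames(Kenh) <- dimnames(K)
  Kenh
}

#' Full per-data-type similarity pipeline
#'
#' Convenience wrapper: standardize features, build the adaptive Gaussian
#' kernel, the kNN transition matrix, the diffusion-enhanced kernel and both
#' kernel distances.
#'
#' @inheritParams gaussian_kernel
#' @param standardize Standardize features to mean 0 / SD 1 first (default TRUE).
#' @return List with elements `K`, `P`, `K_enh`, `D`, `D_enh`, `k`.
#' @export
enhance_similarity <- function(X, k = NULL, standardize = TRUE) {
  X <- as_feature_matrix(X)
  if (standardize) X <- zscore_features(X)
  if (is.null(k)) k <- default_k(nrow(X))
  K <- gaussian_kernel(X, k)
  P <- knn_transition(K, k)
  K_enh <- diffuse_kernel(K, P)
  list(K = K, P = P, K_enh = K_enh,
       D = kernel_distance(K), D_enh = kernel_distance(K_enh), k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
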