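# Clustering accuracy metrics and replicate aggregation for the simulation
# benchmarks.

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI = I(a;b) / \sqrt{H(a) H(b)}} by default (geometric-mean
#' normalization); `normalization = "arithmetic"` uses
#' \eqn{I / ((H(a)+H(b))/2)}. NMI is 1 iff the partitions are equal up to
#' relabeling; if either partition is a single cluster (zero entropy), NMI
#' is 0 by convention.
#'
#' @param a,b Cluster label vectors of equal length (any atomic type).
#' @param normalization `"sqrt"` (default) or `"arithmetic"`.
#' @return A number in \[0, 1\].
#' @export
nmi <- function(a, b, normalization = c("sqrt", "arithmetic")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  if (length(a) == 0L) stop("empty partitions", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 || hb == 0) return(0)
  denom <- if (normalization == "sqrt") sqrt(ha * hb) else (ha + hb) / 2
  min(1, max(0, mi / denom))
}

#' Mean NMI across simulation replicates
#'
#' Runs a user-supplied clustering function on independently seeded
#' replicates of a simulation and aggregates NMI against the true labels.
#' Failing replicates are recorded, excluded from the mean, and reported.
#'
#' @param runner Function `(data, labels, replicate)` returning predicted
#'   cluster labels, where `data` is the named list of feature matrices of
#'   one replicate.
#' @param spec A [simulation_spec()].
#' @param n_replicates Number of replicates (>= 2).
#' @return List with `mean`, `se`, `values` (per-replicate tibble:
#'   `replicate`, `nmi`, `ok`) and `n_failed`.
#' @export
mean_nmi_over_replicates <- function(runner, spec, n_replicates) {
  stopifnot(n_replicates >= 2L)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    sim <- simulate_mixed(spec, replicate = r)
    val <- tryCatch(nmi(runner(sim$data, sim$labels, r), sim$labels),
                    error = function(e) NA_real_)
    tibble::tibble(replicate = r, nmi = val, ok = is.finite(val))
  })
  values <- dplyr::bind_rows(rows)
  good <- values$nmi[values$ok]
  list(mean = mean(good),
       se = stats::sd(good) / sqrt(length(good)),
       values = values,
       n_failed = sum(!values$ok))
}

#' Benchmark a preset: integration vs per-data-type spectral clustering
#'
#' For each replicate of a named preset, fits the partition-level
#' integration and, as baselines, spectral clustering on each single data
#' type's diffusion-enhanced kernel. Results are returned as a tidy table.
#'
#' @param preset Preset name (see [sim_preset()]).
#' @param n_replicates Number of replicates.
#' @param seed Base seed for the generator.
#' @param n_signal,sigma Optional preset overrides.
#' @param config A [parties_config()] for the integration fits; per-type
#'   cluster numbers default to eigengap selection and the consensus C to
#'   the true cluster count.
#' @param include_raw Also benchmark spectral clustering on the raw
#'   (undiffused) kernels (default FALSE).
#' @return Tibble with columns `scenario`, `replicate`, `method`, `nmi`.
#' @export
benchmark_preset <- function(preset, n_replicates = 5L, seed = 0L,
                             n_signal = NULL, sigma = NULL,
                             config = NULL, include_raw = FALSE) {
  spec <- sim_preset(preset, n_signal = n_signal, sigma = sigma, seed = seed)
  C_true <- length(spec$n_per_cluster)
  if (is.null(config)) config <- parties_config(consensus_clusters = C_true)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    sim <- simulate_mixed(spec, replicate = r)
    n <- length(sim$labels)
    k <- config$k %||% default_k(n)
    fit <- parties(sim$data, config = config)
    out <- list(tibble::tibble(scenario = preset, replicate = r,
                               method = "parties", nmi = nmi(fit$labels, sim$labels)))
    for (nm in names(sim$data)) {
      sm <- enhance_similarity(sim$data[[nm]], k = k)
      lab_enh <- spectral_cluster(sm$K_enh, C_true,
                                  restarts = config$kmeans_restarts,
                                  seed = config$random_seed)
      out <- c(out, list(tibble::tibble(
        scenario = preset, replicate = r,
        method = paste0("spectral_enh_", nm), nmi = nmi(lab_enh, sim$labels))))
      if (include_raw) {
        lab_raw <- spectral_cluster(sm$K, C_true,
                                    restarts = config$kmeans_restarts,
                                    seed = config$random_seed)
        out <- c(out, list(tibble::tibble(
          scenario = preset, replicate = r,
          method = paste0("spectral_raw_", nm), nmi = nmi(lab_raw, sim$labels))))
      }
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Diffusion benefit experiment on a single data type
#'
#' Generates replicates of the single-data-type scenario (n = 150, three
#' clusters of 50, signal means 1/2/3) and compares spectral clustering on
#' the raw kernel vs the diffusion-enhanced kernel.
#'
#' @param n_replicates Replicates per condition.
#' @param sigma Signal SD.
#' @param n_signal Number of signal features (default 180).
#' @param seed Base seed.
#' @param restarts,kmeans_seed k-means settings.
#' @return Tibble with `sigma`, `n_signal`, `replicate`, `method`
#'   (`"raw"`/`"enhanced"`), `nmi`.
#' @export
diffusion_benefit <- function(n_replicates = 50L, sigma = 1, n_signal = 180L,
                              seed = 0L, restarts = 20L, kmeans_seed = 0L) {
  spec <- sim_preset("fig2_sigma", n_signal = n_signal, sigma = sigma, seed = seed)
  C_true <- length(spec$n_per_cluster)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    sim <- simulate_mixed(spec, replicate = r)
    sm <- enhance_similarity(sim$data[[1]])
    tibble::tibble(
      sigma = sigma, n_signal = n_signal, replicate = r,
      method = c("raw", "enhanced"),
      nmi = c(
        nmi(spectral_cluster(sm$K, C_true, restarts, kmeans_seed), sim$labels),
        nmi(spectral_cluster(sm$K_enh, C_true, restarts, kmeans_seed), sim$labels)
      ))
  })
  dplyr::bind_rows(rows)
}
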