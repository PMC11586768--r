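# Synthetic multi-omics generator: Gaussian signal/noise feature matrices
# with cluster-specific means, optional Bernoulli data types mimicking
# mutation presence/absence, and named presets for the benchmark scenarios.

#' Specify a synthetic multi-omics simulation
#'
#' Each data type has `p` features: the first `n_signal` are signal features
#' with cluster-specific distributions, the remaining `p - n_signal` are
#' noise. Gaussian data types draw signal features from
#' \eqn{N(\mu_{s,j}, \sigma^2)} for cluster j and noise features from
#' N(0, 1). Bernoulli data types draw signal features from
#' Bernoulli(\eqn{p_{s,j}}) and noise features from Bernoulli(`noise_prob`).
#'
#' @param n_per_cluster Integer vector of cluster sizes.
#' @param p Total features per data type (default 10000).
#' @param n_signal Number of signal features per data type.
#' @param cluster_means Numeric matrix, data types x clusters, of signal
#'   means (Gaussian data types; rows for Bernoulli types are ignored).
#' @param sigma Signal SD for Gaussian data types (default 1).
#' @param feature_model Character vector, one of `"gaussian"`/`"bernoulli"`
#'   per data type (recycled).
#' @param bernoulli_probs Numeric matrix, data types x clusters, of signal
#'   success probabilities for Bernoulli data types (rows for Gaussian types
#'   ignored; required if any type is Bernoulli).
#' @param noise_prob Success probability of Bernoulli noise features
#'   (default 0.05).
#' @param seed Base integer seed; replicate r of a run uses `seed + r`.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_per_cluster, p = 10000L, n_signal,
                            cluster_means, sigma = 1,
                            feature_model = "gaussian",
                            bernoulli_probs = NULL, noise_prob = 0.05,
                            seed = 0L) {
  cluster_means <- rbind(cluster_means)
  n_types <- nrow(cluster_means)
  feature_model <- rep_len(match.arg(feature_model, c("gaussian", "bernoulli"),
                                     several.ok = TRUE), n_types)
  if (n_signal > p) stop("n_signal cannot exceed p", call. = FALSE)
  if (any(n_per_cluster < 1L)) stop("cluster sizes must be positive", call. = FALSE)
  if (ncol(cluster_means) != length(n_per_cluster))
    stop("cluster_means must have one column per cluster", call. = FALSE)
  if (any(feature_model == "bernoulli")) {
    if (is.null(bernoulli_probs))
      stop("bernoulli_probs required for Bernoulli data types", call. = FALSE)
    bernoulli_probs <- rbind(bernoulli_probs)
    if (ncol(bernoulli_probs) != length(n_per_cluster) ||
        nrow(bernoulli_probs) < sum(feature_model == "bernoulli"))
      stop("bernoulli_probs must cover every Bernoulli data type and cluster",
           call. = FALSE)
    if (any(bernoulli_probs <= 0 | bernoulli_probs >= 1))
      stop("bernoulli_probs must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(sigma > 0, noise_prob > 0, noise_prob < 1)
  structure(list(
    n_per_cluster = as.integer(n_per_cluster), p = as.integer(p),
    n_signal = as.integer(n_signal), cluster_means = cluster_means,
    sigma = sigma, feature_model = feature_model,
    bernoulli_probs = bernoulli_probs, noise_prob = noise_prob,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Generate Gaussian multi-omics matrices
#'
#' @param spec A [simulation_spec()] whose data types are all Gaussian.
#' @param replicate Replicate index; the RNG is seeded with
#'   `spec$seed + replicate` so each replicate is reproducible on its own.
#' @return List with `data` (named list of n x p matrices with sample
#'   identifiers) and `labels` (integer vector of true cluster memberships).
#' @export
simulate_gaussian <- function(spec, replicate = 0L) {
  if (any(spec$feature_model != "gaussian"))
    stop("spec contains non-Gaussian data types; use simulate_mixed()", call. = FALSE)
  simulate_mixed(spec, replicate)
}

#' Generate mixed Bernoulli/Gaussian multi-omics matrices
#'
#' Gaussian data types follow [simulate_gaussian()]; Bernoulli data types
#' draw signal features from cluster-specific Bernoulli probabilities and
#' noise features from `noise_prob`, mimicking mutation presence/absence
#' profiles.
#'
#' @inheritParams simulate_gaussian
#' @return List with `data` and `labels` as in [simulate_gaussian()].
#' @export
simulate_mixed <- function(spec, replicate = 0L) {
  stopifnot(inherits(spec, "simulation_spec"))
  labels <- rep(seq_along(spec$n_per_cluster), spec$n_per_cluster)
  n <- length(labels)
  ids <- sprintf("S%03d", seq_len(n))
  withr::with_seed(spec$seed + as.integer(replicate), {
    data <- purrr::map(seq_along(spec$feature_model), function(s) {
      X <- matrix(0, n, spec$p, dimnames = list(ids, sprintf("f%05d", seq_len(spec$p))))
      nsig <- spec$n_signal
      if (spec$feature_model[s] == "gaussian") {
        mu <- spec$cluster_means[s, labels]
        X[, seq_len(nsig)] <- stats::rnorm(n * nsig, mean = mu, sd = spec$sigma)
        if (spec$p > nsig) {
          X[, (nsig + 1L):spec$p] <- stats::rnorm(n * (spec$p - nsig))
        }
      } else {
        pr <- spec$bernoulli_probs[s, labels]
        X[, seq_len(nsig)] <- stats::rbinom(n * nsig, 1L, pr)
        if (spec$p > nsig) {
          X[, (nsig + 1L):spec$p] <- stats::rbinom(n * (spec$p - nsig), 1L,
                                                   spec$noise_prob)
        }
      }
      X
    })
    names(data) <- paste0("data", seq_along(data))
    list(data = data, labels = labels)
  })
}

#' Named simulation presets for the benchmark scenarios
#'
#' Available presets:
#' \describe{
#'   \item{fig2_nsignal}{Single Gaussian data type, n = 150 (3 x 50), signal
#'     means (1, 2, 3), sigma 1, variable `n_signal` (default 180).}
#'   \item{fig2_sigma}{As above with `n_signal` fixed at 180 and variable
#'     `sigma` (default 1).}
#'   \item{setting1}{Three Gaussian data types, n = 200 (4 x 50), same
#'     cluster structure, similar effect sizes: means
#'     (0.5, 0.8, 1.5, 2) / (0.5, 1.2, 1.5, 2) / (0.5, 1, 1.3, 2).}
#'   \item{setting2}{Similar structures, different effect sizes:
#'     (0.5, 1, 1.5, 2) / (2, 0.5, 1, 1.5) / (1.5, 2, 0.5, 1).}
#'   \item{setting3}{Different cluster structures (the design scenario):
#'     (1, 1.5, 3, 3.5) / (1, 2, 3, 3) / (3, 3, 1, 2).}
#'   \item{mixed_large}{n = 200 (4 x 50): data type 1 Bernoulli with signal
#'     probabilities (0.4, 0.1, 0.1, 0.1) and noise probability 0.05
#'     (implementer defaults), data types 2-3 Gaussian with the setting3
#'     means.}
#'   \item{mixed_small}{As mixed_large with n = 60 (4 x 15).}
#' }
#' Defaults `n_signal = 200` and `sigma = 1` apply to the multi-type
#' presets.
#'
#' @param name Preset name.
#' @param n_signal,sigma,seed Optional overrides of the preset's defaults.
#' @return A [simulation_spec()].
#' @export
sim_preset <- function(name, n_signal = NULL, sigma = NULL, seed = 0L) {
  name <- match.arg(name, c("fig2_nsignal", "fig2_sigma", "setting1",
                            "setting2", "setting3", "mixed_small", "mixed_large"))
  m3 <- rbind(c(1, 1.5, 3, 3.5), c(1, 2, 3, 3), c(3, 3, 1, 2))
  bp <- rbind(c(0.4, 0.1, 0.1, 0.1), c(NA, NA, NA, NA), c(NA, NA, NA, NA))
  bp[is.na(bp)] <- 0.5 # placeholder rows for Gaussian types, never sampled
  spec <- switch(name,
    fig2_nsignal = ,
    fig2_sigma = simulation_spec(
      n_per_cluster = rep(50L, 3), p = 10000L,
      n_signal = n_signal %||% 180L,
      cluster_means = rbind(c(1, 2, 3)), sigma = sigma %||% 1, seed = seed),
    setting1 = simulation_spec(
      n_per_cluster = rep(50L, 4), p = 10000L, n_signal = n_signal %||% 200L,
      cluster_means = rbind(c(0.5, 0.8, 1.5, 2), c(0.5, 1.2, 1.5, 2),
                            c(0.5, 1, 1.3, 2)),
      sigma = sigma %||% 1, seed = seed),
    setting2 = simulation_spec(
      n_per_cluster = rep(50L, 4), p = 10000L, n_signal = n_signal %||% 200L,
      cluster_means = rbind(c(0.5, 1, 1.5, 2), c(2, 0.5, 1, 1.5),
                            c(1.5, 2, 0.5, 1)),
      sigma = sigma %||% 1, seed = seed),
    setting3 = simulation_spec(
      n_per_cluster = rep(50L, 4), p = 10000L, n_signal = n_signal %||% 200L,
      cluster_means = m3, sigma = sigma %||% 1, seed = seed),
    mixed_large = simulation_spec(
      n_per_cluster = rep(50L, 4), p = 10000L, n_signal = n_signal %||% 200L,
      cluster_means = m3, sigma = sigma %||% 1,
      feature_model = c("bernoulli", "gaussian", "gaussian"),
      bernoulli_probs = bp, noise_prob = 0.05, seed = seed),
    mixed_small = simulation_spec(
      n_per_cluster = rep(15L, 4), p = 10000L, n_signal = n_signal %||% 200L,
      cluster_means = m3, sigma = sigma %||% 1,
      feature_model = c("bernoulli", "gaussian", "gaussian"),
      bernoulli_probs = bp, noise_prob = 0.05, seed = seed)
  )
  attr(spec, "preset") <- name
  spec
}

#' Generate one replicate of a named preset
#'
#' @inheritParams sim_preset
#' @param replicate Replicate index (see [simulate_mixed()]).
#' @return List with `data`, `labels` and the `spec` used.
#' @export
simulate_preset <- function(name, replicate = 0L, n_signal = NULL,
                            sigma = NULL, seed = 0L) {
  spec <- sim_preset(name, n_signal = n_signal, sigma = sigma, seed = seed)
  out <- simulate_mixed(spec, replicate)
  out$spec <- spec
  out
}
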