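# broom-style accessors and ggplot2 methods for fitted integrations

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy cluster assignments of a fit
#'
#' @param x A `parties` fit.
#' @param ... Unused.
#' @return Tibble with columns `sample_id` and `cluster` (integer, 1..C).
#' @export
tidy.parties <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids, cluster = as.integer(x$labels))
}

#' One-row summary of a fit
#'
#' @param x A `parties` fit.
#' @param ... Unused.
#' @return Tibble with sample/data-type counts, cluster numbers, iteration
#'   and convergence diagnostics, and the final total loss.
#' @export
glance.parties <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_types = length(x$states),
    consensus_clusters = x$C,
    iterations = x$iterations,
    converged = x$converged,
    subspace_change = utils::tail(x$subspace_change, 1),
    total_loss = utils::tail(x$loss_trace$total, 1),
    min_weight = min(x$weights),
    max_weight = max(x$weights)
  )
}

#' Per-data-type weight table
#'
#' @param x A `parties` fit.
#' @return Tibble with `data_type`, `clusters` (the selected C_s) and the
#'   learned consensus `weight`.
#' @export
weight_table <- function(x) {
  stopifnot(inherits(x, "parties"))
  tibble::tibble(data_type = names(x$weights), clusters = x$C_s,
                 weight = unname(x$weights))
}

#' Plot optimization diagnostics of a fit
#'
#' Loss components and the consensus-subspace change per iteration.
#'
#' @param object A `parties` fit.
#' @param ... Unused.
#' @return A ggplot object (faceted line plot, free y scales; the subspace
#'   change panel is on log10 scale values).
#' @export
autoplot.parties <- function(object, ...) {
  tr <- object$loss_trace
  long <- tidyr_pivot(tr[, c("iteration", "fidelity", "ridge", "spectral",
                             "consensus", "total", "subspace_change")])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = NULL,
                  title = "Partition-level integration: optimization trace")
}

# minimal wide-to-long reshape (iteration + value columns)
tidyr_pivot <- function(df) {
  comps <- setdiff(names(df), "iteration")
  dplyr::bind_rows(lapply(comps, function(cp) {
    tibble::tibble(iteration = df$iteration, component = cp, value = df[[cp]])
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Line plot of a benchmark NMI table
#'
#' @param results Tidy tibble as returned by [benchmark_preset()], with
#'   columns `scenario`, `replicate`, `method`, `nmi` and optionally a grid
#'   variable `n_signal`.
#' @return A ggplot object: mean NMI per method (against `n_signal` when
#'   present).
#' @export
plot_benchmark <- function(results) {
  grid_var <- intersect(c("n_signal", "sigma"), names(results))[1]
  if (!is.na(grid_var)) {
    sm <- dplyr::summarise(
      dplyr::group_by(results, .data$method, .data[[grid_var]]),
      nmi = mean(.data$nmi), .groups = "drop")
    ggplot2::ggplot(sm, ggplot2::aes(x = .data[[grid_var]], y = .data$nmi,
                                     colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = "Mean NMI")
  } else {
    sm <- dplyr::summarise(dplyr::group_by(results, .data$method),
                           nmi = mean(.data$nmi), .groups = "drop")
    ggplot2::ggplot(sm, ggplot2::aes(x = .data$method, y = .data$nmi)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "Mean NMI")
  }
}

#' @importFrom rlang .data
NULL
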