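#' Tidy the segment table of a simulation
#'
#' @param x An `ibd_sim` from [simulate_ibd()].
#' @param ... Unused.
#' @return The segments tibble: one row per detectable IBD segment with
#'   0-based haploid ids `id_a < id_b`, `left`/`right`/`length` in Morgans
#'   and `tmrca` in generations.
#' @method tidy ibd_sim
#' @export
tidy.ibd_sim <- function(x, ...) x$segments

#' One-row summary of a simulation run
#'
#' @param x An `ibd_sim` from [simulate_ibd()].
#' @param ... Unused.
#' @return A one-row tibble: sample size (haploids), threshold, algorithm,
#'   segment/prune/merge/comparison counters, active records at the end,
#'   and the sample TMRCA in generations.
#' @method glance ibd_sim
#' @export
glance.ibd_sim <- function(x, ...) {
  tibble::tibble(
    n_haploid = x$config$n_haploid, w = x$config$w,
    algorithm = x$config$algorithm,
    n_segments = x$stats$n_segments, n_pruned = x$stats$n_pruned,
    n_merge_events = x$stats$n_merge_events,
    n_comparisons = x$stats$n_comparisons,
    n_active_at_end = x$stats$n_active_at_end,
    tmrca = tmrca(x$tree)
  )
}

#' @rdname tidy.ibd_sim
#' @method tidy ibd_result
#' @export
tidy.ibd_result <- function(x, ...) x$segments

#' @rdname glance.ibd_sim
#' @method glance ibd_result
#' @export
glance.ibd_result <- function(x, ...) {
  tibble::as_tibble(x$stats)
}

#' Plot the detectable segment length distribution
#'
#' @param object An `ibd_sim`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot: histogram of segment lengths (Morgans) with the
#'   detection threshold marked.
#' @method autoplot ibd_sim
#' @export
autoplot.ibd_sim <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$segments, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$config$w, linetype = "dashed") +
    ggplot2::labs(x = "IBD segment length (Morgans)", y = "count",
                  title = sprintf("%d detectable segments (w = %g M)",
                                  object$stats$n_segments, object$config$w))
}

#' Plot a demographic model
#'
#' @param object A [demography()] object.
#' @param t_max Oldest time (generations) to display; defaults to twice the
#'   last epoch boundary (or 1000 for a single-epoch model).
#' @param ... Unused.
#' @return A ggplot of haploid population size against generations before
#'   present (log scale).
#' @method autoplot demography
#' @export
autoplot.demography <- function(object, t_max = NULL, ...) {
  if (is.null(t_max)) {
    t_max <- if (nrow(object) > 1L) 2 * max(object$start) else 1000
  }
  tt <- sort(unique(c(seq(0, t_max, length.out = 400),
                      object$start[object$start <= t_max],
                      pmax(object$start[object$start <= t_max] - 1e-9, 0))))
  df <- tibble::tibble(t = tt, N = size_at(object, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$N)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "haploid size N(t)",
                  title = attr(object, "label"))
}
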