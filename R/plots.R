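#' Histograms of pairwise cohort distances
#'
#' Side-by-side histograms of the pairwise prescription distances and the
#' pairwise feature (Gower) distances of a historical index. Prescription
#' distances typically pile up at 0 and a few discrete values (many
#' patients share a prescription); feature distances show spikes at
#' multiples of 1/(number of features) from categorical mismatches.
#'
#' @param index An [build_index()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_distance_histograms <- function(index, bins = 40) {
  stopifnot(inherits(index, "rx_index"))
  d_rx <- as.numeric(dist(index$scaled_rx))
  s <- index$s
  g <- unlist(lapply(seq_len(s - 1L), function(k) {
    gower_to_cohort(index$records[k, , drop = FALSE],
                    index$records[(k + 1L):s, , drop = FALSE],
                    index$schema)
  }))
  df <- dplyr::bind_rows(
    tibble(metric = "prescription distance", value = d_rx),
    tibble(metric = "feature (Gower) distance", value = g)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "pairwise distance", y = "pairs",
                  title = paste0("Pairwise distances, technique ",
                                 index$technique, " (S = ", s, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a batch of detections in the (R, F) plane
#'
#' Scatter of feature distance F against prescription distance R with the
#' two decision thresholds; type I anomalies (F not evaluated) are drawn on
#' the R axis. Points are coloured by verdict.
#'
#' @param detections A detection tibble from [detect_batch()].
#' @return A ggplot object.
#' @export
plot_detections <- function(detections) {
  df <- detections[!is.na(detections$verdict), , drop = FALSE]
  df$f_plot <- ifelse(is.na(df$f), 0, df$f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$f_plot,
                                   colour = .data$anomaly_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$t_rx),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$t_f),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "R (closest-m prescription distance)",
                  y = "F (closest-n feature distance)",
                  colour = "type",
                  title = "Distance-model verdicts") +
    ggplot2::theme_minimal()
}

#' @describeIn tune-plots f1 trace of a tuning run: per-evaluation mean f1
#'   with the running best overlaid.
#' @name tune-plots
#' @param object An `rx_tuning` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rx_tuning <- function(object, ...) {
  tr <- object$trace
  tr$best_so_far <- cummax(tr$f1_mean)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f1_mean), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_so_far), colour = "firebrick") +
    ggplot2::labs(x = "evaluation", y = "mean f1 over holdout resamples",
                  title = paste0("Hyperparameter search (", object$method, ")")) +
    ggplot2::theme_minimal()
}
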