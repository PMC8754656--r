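#' @export
print.reel_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<reel_screen> %d tiles (%d functional), %d sub-libraries, depth %g\n",
    g$n_tiles, g$n_functional, g$n_sublibraries, g$depth
  ))
  invisible(x)
}

#' @export
tidy.reel_screen <- function(x, ...) as_tibble(x$counts)

#' @export
glance.reel_screen <- function(x, ...) {
  tibble(
    n_tiles = nrow(x$truth),
    n_functional = sum(x$truth$functional),
    n_sublibraries = nrow(distinct(
      x$counts, .data$library_id, .data$condition, .data$round, .data$replicate
    )),
    rounds_total = x$design$rounds_total,
    depth = x$design$depth,
    pool_size = x$design$pool_size,
    s0 = x$model$s0,
    pcr_sigma = x$model$pcr_sigma
  )
}

#' @export
tidy.reel_quant <- function(x, ...) as_tibble(x$counts)

#' @export
glance.reel_quant <- function(x, ...) {
  tibble(
    n_sublibraries = nrow(x$qc),
    total_reads = sum(x$qc$total_reads),
    matched_reads = sum(x$qc$matched_reads),
    recovery_rate = sum(x$qc$matched_reads) / sum(x$qc$total_reads)
  )
}

#' @export
print.reel_quant <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<reel_quant> %d sub-libraries, %d/%d reads matched (recovery %.1f%%)\n",
    g$n_sublibraries, g$matched_reads, g$total_reads, 100 * g$recovery_rate
  ))
  invisible(x)
}

#' @export
glance.reel_calls <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_slope_negative = sum(x$slope < 0),
    n_candidates = sum(x$is_candidate),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.reel_overlap <- function(x, ...) {
  as_tibble(as.data.frame(x$table)) |>
    rename(n = "Freq")
}

#' @export
glance.reel_overlap <- function(x, ...) {
  tibble(
    n1 = x$n1, N1 = x$N1, n2 = x$n2, N2 = x$N2,
    observed = x$observed, expected = x$expected,
    chi2 = x$chi2, df = x$df, pvalue = x$pvalue, p_floored = x$p_floored
  )
}

#' @export
print.reel_overlap <- function(x, ...) {
  cat(sprintf(
    "<reel_overlap> observed %d vs expected %.2f candidate pairs (chi^2 = %.1f, p %s %.3g)\n",
    x$observed, x$expected, x$chi2, if (x$p_floored) "<" else "=", x$pvalue
  ))
  invisible(x)
}

#' @export
tidy.reel_clusters <- function(x, ...) as_tibble(x$membership)

#' @export
glance.reel_clusters <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$membership),
    n_clusters = x$n_clusters,
    fraction_clustered = x$fraction_clustered,
    window_bp = x$window_bp
  )
}

#' @export
print.reel_clusters <- function(x, ...) {
  cat(sprintf(
    "<reel_clusters> %d candidates in %d clusters (window %d bp); %.0f%% in clusters of >= 2\n",
    nrow(x$membership), x$n_clusters, x$window_bp, 100 * x$fraction_clustered
  ))
  invisible(x)
}

#' @export
tidy.reel_density <- function(x, ...) as_tibble(x$per_interval)

#' @export
glance.reel_density <- function(x, ...) {
  tibble(
    n_intervals = nrow(x$per_interval),
    n_empty = x$n_empty,
    n_assigned = x$n_assigned,
    mean_per_nonempty = x$mean_per_nonempty
  )
}

#' @export
print.reel_density <- function(x, ...) {
  cat(sprintf(
    "<reel_density> %d intervals (%d empty); mean %.2f candidates per non-empty interval\n",
    nrow(x$per_interval), x$n_empty, x$mean_per_nonempty
  ))
  invisible(x)
}

#' Plot mean depletion trajectories of a simulated screen
#'
#' Mean NE/buffer percentage ratio per round, one line per tile, coloured by
#' ground-truth label. Functional tiles should slope downward; neutral tiles
#' hover at 1.
#'
#' @param object A `reel_screen`.
#' @param pseudocount Passed to [to_percentages()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reel_screen <- function(object, pseudocount = 0.5, ...) {
  traj <- to_percentages(object$counts, pseudocount) |>
    condition_means() |>
    ratio_trajectory() |>
    left_join(object$truth, by = c("tile_id", "library_id"))
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$round, y = .data$ratio,
    group = .data$tile_id, colour = .data$functional
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
      name = "functional"
    ) +
    ggplot2::labs(
      x = "selection round", y = "NE / buffer percentage ratio",
      title = "Depletion trajectories"
    ) +
    ggplot2::theme_minimal()
}

#' Plot depletion slope against per-round significance
#'
#' Volcano-style summary of candidate calling: fitted slope on the x axis,
#' the weakest (largest) per-round p-value on the y axis, candidates
#' highlighted. The call region is slope < 0 and max p < alpha.
#'
#' @param object A `reel_calls` tibble from [call_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reel_calls <- function(object, ...) {
  p_cols <- grep("^p_r[0-9]+$", names(object), value = TRUE)
  df <- mutate(as_tibble(object),
    p_max = do.call(pmax, as_tibble(object)[p_cols])
  )
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$slope, y = -log10(.data$p_max), colour = .data$is_candidate
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "candidate"
    ) +
    ggplot2::labs(
      x = "depletion slope (ratio per round)",
      y = expression(-log[10] ~ "max per-round p"),
      title = "Candidate calls"
    ) +
    ggplot2::theme_minimal()
}

#' Plot candidate counts per annotation interval
#'
#' @param object A `reel_density` from [annotate_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reel_density <- function(object, ...) {
  ggplot2::ggplot(
    object$per_interval, ggplot2::aes(x = .data$n_candidates)
  ) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(
      x = "candidates per interval", y = "intervals",
      title = "Candidate density in annotation intervals"
    ) +
    ggplot2::theme_minimal()
}
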