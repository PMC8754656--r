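#' Average replicate percentages per condition and round
#'
#' Arithmetic mean of a tile's percentage over the replicate sub-libraries of
#' each condition at each sequenced round: the first step of the calling
#' statistic.
#'
#' @param pct Percentage tibble from [to_percentages()].
#' @return Tibble with columns `tile_id`, `library_id`, `condition`, `round`,
#'   `mean_fraction`.
#' @export
condition_means <- function(pct, rounds = NULL) {
  stopifnot("fraction" %in% names(pct))
  if (!is.null(rounds)) pct <- filter(pct, .data$round %in% rounds)
  n_rep <- length(unique(pct$replicate))
  if (n_rep < 2L) abort("condition_means needs >= 2 replicates")
  means <- pct |>
    group_by(.data$tile_id, .data$library_id, .data$condition, .data$round) |>
    summarise(
      mean_fraction = mean(.data$fraction), .n = n(), .groups = "drop"
    )
  bad <- means[means$.n != n_rep, ]
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "missing replicate cell: tile %s, %s, round %s",
      bad$tile_id[1L], bad$condition[1L], bad$round[1L]
    ))
  }
  select(means, -".n")
}

#' @rdname condition_means
#' @param rounds Optional subset of rounds to keep.
#' @export
ratio_trajectory <- function(means) {
  wide <- pivot_wider(means,
    names_from = "condition", values_from = "mean_fraction"
  )
  if (!all(c("NE", "buffer") %in% names(wide))) {
    abort("expected conditions 'NE' and 'buffer'")
  }
  if (any(wide$buffer <= 0)) {
    abort("zero buffer mean; use a positive pseudocount")
  }
  wide |>
    mutate(ratio = .data$NE / .data$buffer) |>
    rename(mean_NE = "NE", mean_buffer = "buffer")
}

#' Least-squares slope of a depletion trajectory
#'
#' Ordinary least-squares slope of the NE/buffer percentage ratio against
#' round number. Candidate elements show a progressive decrease across the
#' sequenced rounds, i.e. a negative slope.
#'
#' @param ratios Numeric vector of per-round ratios.
#' @param rounds Abscissae, default the sequenced round numbers
#'   `c(1, 4, 7, 10)`. Only the sign of the slope is used for calling, so
#'   round numbers vs round indices does not affect calls.
#' @return The slope (numeric scalar).
#' @examples
#' fit_slope(c(1.0, 0.9, 0.8, 0.7)) # -1/30
#' @export
fit_slope <- function(ratios, rounds = c(1, 4, 7, 10)) {
  if (length(ratios) != length(rounds) || length(ratios) < 2L) {
    abort("`ratios` and `rounds` must have equal length >= 2")
  }
  if (any(!is.finite(ratios)) || any(!is.finite(rounds))) {
    abort("non-finite input to fit_slope")
  }
  x <- rounds - mean(rounds)
  sum(x * (ratios - mean(ratios))) / sum(x^2)
}

#' Two-sample Student's t-test for one tile at one round
#'
#' Compares the NE replicate percentages against the buffer replicate
#' percentages, two-sided. Pooled-variance Student's t by default (the
#' screen's named test); Welch available. Degenerate cases: zero pooled
#' variance with equal means gives p = 1 by convention; zero pooled variance
#' with unequal means gives a vanishing p, returned as the smallest positive
#' double and flagged `degenerate`.
#'
#' @param ne,buffer Numeric replicate vectors (>= 2 each).
#' @param test `"pooled"` (default) or `"welch"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' per_round_test(c(1, 2, 3), c(4, 5, 6))
#' @export
per_round_test <- function(ne, buffer, test = c("pooled", "welch")) {
  test <- match.arg(test)
  stopifnot(length(ne) >= 2L, length(buffer) >= 2L)
  if (any(!is.finite(ne)) || any(!is.finite(buffer))) {
    abort("non-finite input to per_round_test")
  }
  res <- t_from_stats(
    mean(ne), stats::var(ne), length(ne),
    mean(buffer), stats::var(buffer), length(buffer),
    welch = identical(test, "welch")
  )
  tibble(
    statistic = res$t, df = res$df, p_value = res$p, degenerate = res$degenerate
  )
}

# vectorized two-sample t from summary statistics
t_from_stats <- function(mx, vx, nx, my, vy, ny, welch = FALSE) {
  if (welch) {
    se2x <- vx / nx
    se2y <- vy / ny
    se <- sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  t <- (mx - my) / se
  p <- 2 * pt(-abs(t), df)
  zero_var <- se == 0 | !is.finite(df)
  degenerate <- zero_var & mx != my
  t[zero_var & mx == my] <- 0
  p[zero_var & mx == my] <- 1
  df[zero_var & !welch] <- nx + ny - 2
  t[degenerate] <- sign(mx - my)[degenerate] * Inf
  p[degenerate] <- .Machine$double.xmin
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Build per-tile depletion records
#'
#' Assembles, for every tile, the full calling statistic: per-round condition
#' means, NE/buffer ratios at the sequenced rounds, the OLS slope of ratio
#' vs round, and a per-round two-sample t-test of the NE vs buffer replicate
#' percentages (`test_scope = "per_round"`, the default reading) or a single
#' test pooling all sequenced rounds (`test_scope = "combined"`, an
#' alternative reading of the procedure).
#'
#' @param pct Percentage tibble from [to_percentages()].
#' @param rounds Sequenced rounds used for ratios/slope/tests
#'   (default `c(1, 4, 7, 10)`).
#' @param test `"pooled"` Student's t (default) or `"welch"`.
#' @param test_scope `"per_round"` (one test per sequenced round, all must
#'   pass) or `"combined"` (one test across rounds).
#' @param slope_x `"round_number"` (default) or `"round_index"` abscissae for
#'   the slope; sign-invariant, so calls are unaffected.
#' @param log_ratio Fit the slope on `log(ratio)` instead of the ratio.
#' @return A tibble of class `reel_records`, one row per tile, with columns
#'   `mean_NE_r*`, `mean_buffer_r*`, `ratio_r*`, `slope`, `p_r*` (or
#'   `p_combined`) and `degenerate`.
#' @export
depletion_records <- function(pct, rounds = c(1, 4, 7, 10),
                              test = c("pooled", "welch"),
                              test_scope = c("per_round", "combined"),
                              slope_x = c("round_number", "round_index"),
                              log_ratio = FALSE) {
  test <- match.arg(test)
  test_scope <- match.arg(test_scope)
  slope_x <- match.arg(slope_x)
  pct <- filter(pct, .data$round %in% rounds)
  got <- sort(unique(pct$round))
  if (!setequal(got, rounds)) {
    abort(sprintf(
      "percentages cover rounds {%s}, need {%s}",
      paste(got, collapse = ","), paste(rounds, collapse = ",")
    ))
  }

  stats_tbl <- pct |>
    group_by(.data$tile_id, .data$library_id, .data$condition, .data$round) |>
    summarise(
      m = mean(.data$fraction), v = stats::var(.data$fraction), k = n(),
      .groups = "drop"
    )
  if (any(stats_tbl$k < 2L)) abort("need >= 2 replicates per condition")

  wide <- stats_tbl |>
    pivot_wider(
      names_from = "condition", values_from = c("m", "v", "k")
    ) |>
    mutate(ratio = .data$m_NE / .data$m_buffer)
  if (any(wide$m_buffer <= 0)) {
    abort("zero buffer mean; use a positive pseudocount")
  }

  tt <- t_from_stats(
    wide$m_NE, wide$v_NE, wide$k_NE,
    wide$m_buffer, wide$v_buffer, wide$k_buffer,
    welch = identical(test, "welch")
  )
  wide$p <- tt$p
  wide$deg <- tt$degenerate

  x <- if (slope_x == "round_number") rounds else seq_along(rounds)
  per_tile <- wide |>
    arrange(.data$tile_id, .data$round) |>
    group_by(.data$tile_id, .data$library_id) |>
    summarise(
      slope = fit_slope(
        if (log_ratio) log(.data$ratio) else .data$ratio, x
      ),
      degenerate = any(.data$deg),
      .groups = "drop"
    )

  wide_cols <- wide |>
    select(all_of(c("tile_id", "library_id", "round")),
      mean_NE = "m_NE", mean_buffer = "m_buffer", ratio = "ratio", p = "p"
    ) |>
    pivot_wider(
      names_from = "round",
      values_from = c("mean_NE", "mean_buffer", "ratio", "p"),
      names_glue = "{.value}_r{round}"
    )

  records <- left_join(wide_cols, per_tile, by = c("tile_id", "library_id"))
  if (test_scope == "combined") {
    comb <- pct |>
      group_by(.data$tile_id, .data$library_id, .data$condition) |>
      summarise(
        m = mean(.data$fraction), v = stats::var(.data$fraction), k = n(),
        .groups = "drop"
      ) |>
      pivot_wider(names_from = "condition", values_from = c("m", "v", "k"))
    cb <- t_from_stats(
      comb$m_NE, comb$v_NE, comb$k_NE, comb$m_buffer, comb$v_buffer,
      comb$k_buffer,
      welch = identical(test, "welch")
    )
    records <- left_join(
      records,
      tibble(
        tile_id = comb$tile_id, library_id = comb$library_id,
        p_combined = cb$p
      ),
      by = c("tile_id", "library_id")
    )
  }
  attr(records, "rounds") <- rounds
  attr(records, "test_scope") <- test_scope
  class(records) <- c("reel_records", class(records))
  records
}

#' Call candidate cis-regulatory elements
#'
#' The conjunctive rule of the screen: a tile is a candidate iff its
#' depletion slope is negative and its NE-vs-buffer test is significant at
#' `alpha` at every sequenced round. No multiple-testing adjustment gates the
#' call -- the screen deliberately keeps as many positives as possible and
#' defers to downstream validation -- but Benjamini-Hochberg adjusted
#' per-round p-values are emitted for reference (`p_bh_r*`).
#'
#' @param records A `reel_records` tibble from [depletion_records()].
#' @param alpha Per-round significance level (default 0.05).
#' @return The records with `is_candidate` (and `p_bh_r*`) columns added;
#'   class `reel_calls`. `glance()` summarises: tiles tested, tiles with
#'   negative slope, candidates.
#' @export
call_candidates <- function(records, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  scope <- attr(records, "test_scope") %||% "per_round"
  if (identical(scope, "combined")) {
    records$is_candidate <- records$slope < 0 & records$p_combined < alpha
  } else {
    p_cols <- grep("^p_r[0-9]+$", names(records), value = TRUE)
    if (length(p_cols) == 0L) abort("no per-round p-value columns found")
    pmat <- as.matrix(records[p_cols])
    records$is_candidate <- records$slope < 0 &
      apply(pmat < alpha, 1L, all)
    for (pc in p_cols) {
      records[[sub("^p_", "p_bh_", pc)]] <- stats::p.adjust(records[[pc]], "BH")
    }
  }
  attr(records, "alpha") <- alpha
  class(records) <- unique(c("reel_calls", class(records)))
  records
}
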