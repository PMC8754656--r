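#' Pair offset-library tiles by maximal overlap
#'
#' Maps every Library 2 tile to the Library 1 tile it shares the most base
#' pairs with (ties broken toward the left, i.e. smaller-start, tile). With
#' the default 17-bp offset each Library 2 tile overlaps its left Library 1
#' neighbour by 18 bp and its right by 17 bp, so pairs left.
#'
#' @param tiles A `reel_tiles` tibble containing both libraries, or a tibble
#'   with columns `tile_id`, `library_id`, `start`, `end`.
#' @return Tibble with one row per Library 2 tile: `tile_id_2`, `tile_id_1`,
#'   `overlap_bp`.
#' @export
pair_tiles <- function(tiles) {
  lib1 <- filter(tiles, .data$library_id == 1L)
  lib2 <- filter(tiles, .data$library_id == 2L)
  if (nrow(lib1) == 0L || nrow(lib2) == 0L) {
    abort("pair_tiles needs tiles from both libraries")
  }
  ir1 <- IRanges::IRanges(start = lib1$start + 1L, end = lib1$end)
  ir2 <- IRanges::IRanges(start = lib2$start + 1L, end = lib2$end)
  hits <- IRanges::findOverlaps(ir2, ir1)
  if (length(hits) == 0L) abort("disjoint libraries: no tile overlaps")
  ov <- IRanges::width(IRanges::pintersect(
    ir2[S4Vectors::queryHits(hits)], ir1[S4Vectors::subjectHits(hits)]
  ))
  cand <- tibble(
    q = S4Vectors::queryHits(hits),
    s = S4Vectors::subjectHits(hits),
    overlap_bp = ov,
    s_start = lib1$start[S4Vectors::subjectHits(hits)]
  ) |>
    arrange(.data$q, dplyr::desc(.data$overlap_bp), .data$s_start) |>
    group_by(.data$q) |>
    dplyr::slice(1L) |>
    ungroup()
  if (nrow(cand) < nrow(lib2)) {
    abort("disjoint libraries: some Library 2 tiles overlap no Library 1 tile")
  }
  tibble(
    tile_id_2 = lib2$tile_id[cand$q],
    tile_id_1 = lib1$tile_id[cand$s],
    overlap_bp = as.integer(cand$overlap_bp)
  )
}

#' Cross-library candidate concordance
#'
#' Counts Library 2 candidates whose paired Library 1 tile is also a
#' candidate, compares against the count expected under independence
#' (`n2 * n1 / N1`), and tests association with Pearson's chi-squared on the
#' 2x2 table {Library 2 candidate yes/no} x {paired Library 1 tile candidate
#' yes/no} over all pairs. A published-scale example: 209 candidates among
#' 1669 Library 1 tiles and 199 among 1668 Library 2 tiles give an expected
#' overlap of 199 * 209 / 1669 = 24.92, i.e. ~25.
#'
#' @param pairing Pairing tibble from [pair_tiles()].
#' @param calls1,calls2 Call tables for Library 1 and 2 (tibbles with
#'   `tile_id` and logical `is_candidate`, e.g. from [call_candidates()]).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @param p_floor Report p-values below this as the floor itself (default
#'   2.2e-16, the conventional reporting floor).
#' @return A list of class `reel_overlap`: `n1`, `N1`, `n2`, `N2`,
#'   `observed`, `expected`, `chi2`, `df`, `pvalue`, `p_floored`, `table`
#'   (the 2x2 contingency table). `glance()` returns it as one row.
#' @export
overlap_stats <- function(pairing, calls1, calls2, correct = FALSE,
                          p_floor = 2.2e-16) {
  for (cl in list(calls1, calls2)) {
    if (!all(c("tile_id", "is_candidate") %in% names(cl))) {
      abort("call tables need columns `tile_id` and `is_candidate`")
    }
  }
  N1 <- nrow(calls1)
  N2 <- nrow(calls2)
  if (N1 == 0L || N2 == 0L) abort("empty call table")
  n1 <- sum(calls1$is_candidate)
  n2 <- sum(calls2$is_candidate)

  cand1 <- setNames(calls1$is_candidate, calls1$tile_id)
  cand2 <- setNames(calls2$is_candidate, calls2$tile_id)
  if (any(is.na(cand1[pairing$tile_id_1])) ||
    any(is.na(cand2[pairing$tile_id_2]))) {
    abort("calls missing for some paired tiles")
  }
  c2 <- cand2[pairing$tile_id_2]
  c1 <- cand1[pairing$tile_id_1]
  observed <- sum(c2 & c1)
  expected <- n2 * n1 / N1

  tab <- table(
    lib2_candidate = factor(c2, levels = c(TRUE, FALSE)),
    lib1_candidate = factor(c1, levels = c(TRUE, FALSE))
  )
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  }
  p_floored <- !is.na(p) && p < p_floor
  structure(
    list(
      n1 = n1, N1 = N1, n2 = n2, N2 = N2,
      observed = observed, expected = expected,
      chi2 = chi2, df = 1L,
      pvalue = if (p_floored) p_floor else p,
      p_floored = p_floored,
      table = tab
    ),
    class = "reel_overlap"
  )
}
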