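#' Cluster candidates into enhancer-scale windows
#'
#' Two candidates belong to the same cluster iff some window of `window_bp`
#' contains both entirely -- equivalently, the start-to-end span of the pair
#' is at most `window_bp` -- extended transitively (single-linkage chaining).
#' 140 bp, four tile lengths, is the default enhancer-scale window; a typical
#' enhancer binds several regulatory proteins, so true candidates cluster.
#' `mode = "fixed"` instead partitions the coordinate axis into consecutive
#' `window_bp` windows and clusters candidates wholly contained in the same
#' window, a stricter non-chaining variant.
#'
#' @param candidates Tibble of candidate intervals with columns `start`,
#'   `end` (and optionally `tile_id`).
#' @param window_bp Window size in bp (default 140). Must be at least as long
#'   as the widest candidate.
#' @param mode `"chain"` (default) or `"fixed"`.
#' @return A list of class `reel_clusters`: `membership` (candidates with
#'   `cluster_id` and `cluster_size`), `n_clusters`, `fraction_clustered`
#'   (fraction of candidates in clusters of size >= 2) and `window_bp`.
#' @examples
#' x <- tibble::tibble(start = c(0, 70, 300), end = c(35, 105, 335))
#' cluster_candidates(x)$fraction_clustered # 2/3
#' @export
cluster_candidates <- function(candidates, window_bp = 140L, mode = c("chain", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(all(c("start", "end") %in% names(candidates)))
  n <- nrow(candidates)
  if (n > 0L && window_bp < max(candidates$end - candidates$start)) {
    abort("window_bp smaller than a candidate; clusters undefined")
  }
  if (n == 0L) {
    return(structure(
      list(
        membership = mutate(candidates,
          cluster_id = integer(), cluster_size = integer()
        ),
        n_clusters = 0L, fraction_clustered = NA_real_, window_bp = window_bp
      ),
      class = "reel_clusters"
    ))
  }
  ord <- order(candidates$start, candidates$end)
  s <- candidates$start[ord]
  e <- candidates$end[ord]

  cluster_of <- integer(n)
  if (mode == "chain") {
    # union-find over the pairwise co-window graph
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (j in seq_len(n)[-1L]) {
      for (i in (j - 1L):1L) {
        if (s[j] - s[i] > window_bp) break
        if (max(e[i], e[j]) - min(s[i], s[j]) <= window_bp) {
          parent[find(i)] <- find(j)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cluster_of[ord] <- match(roots, unique(roots))
  } else {
    win <- s %/% window_bp
    contained <- (e - 1L) %/% window_bp == win
    key <- ifelse(contained, paste0("w", win), paste0("solo", seq_len(n)))
    cluster_of[ord] <- match(key, unique(key))
  }

  membership <- mutate(candidates, cluster_id = cluster_of) |>
    group_by(.data$cluster_id) |>
    mutate(cluster_size = n()) |>
    ungroup()
  structure(
    list(
      membership = membership,
      n_clusters = length(unique(cluster_of)),
      fraction_clustered = mean(membership$cluster_size >= 2L),
      window_bp = window_bp
    ),
    class = "reel_clusters"
  )
}

#' Candidate density within annotation intervals
#'
#' Counts, for each annotation interval (e.g. predicted enhancers), the
#' candidates overlapping it by at least one base pair (standard BED
#' intersect semantics; `min_overlap_frac` switches to a majority-overlap
#' style rule). Summarises the mean count over non-empty intervals -- the
#' published screen found ~2.5 candidate elements per matched enhancer. A
#' candidate straddling two abutting intervals is counted in both.
#'
#' @param candidates Tibble with `chrom`, `start`, `end` (absolute
#'   coordinates); a missing `chrom` column is treated as a single shared
#'   chromosome.
#' @param annotations Tibble of intervals with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param min_overlap_frac Minimum overlap as a fraction of the candidate's
#'   width (default 0: any shared bp counts; 0.5 gives majority overlap).
#' @return A list of class `reel_density`: `per_interval` (annotations with
#'   `n_candidates`), `mean_per_nonempty`, `n_empty`, `n_assigned`.
#' @export
annotate_density <- function(candidates, annotations, min_overlap_frac = 0) {
  stopifnot(all(c("start", "end") %in% names(candidates)))
  stopifnot(all(c("start", "end") %in% names(annotations)))
  if (!"chrom" %in% names(candidates)) candidates$chrom <- "."
  if (!"chrom" %in% names(annotations)) annotations$chrom <- "."
  if (!"name" %in% names(annotations)) {
    annotations$name <- sprintf("interval_%d", seq_len(nrow(annotations)))
  }
  if (nrow(annotations) == 0L) {
    return(structure(
      list(
        per_interval = mutate(annotations, n_candidates = integer()),
        mean_per_nonempty = NA_real_, n_empty = 0L, n_assigned = 0L
      ),
      class = "reel_density"
    ))
  }
  shared <- intersect(unique(candidates$chrom), unique(annotations$chrom))
  if (nrow(candidates) > 0L && length(shared) == 0L) {
    warn("no shared chromosomes between candidates and annotations")
  }

  n_cand <- integer(nrow(annotations))
  for (ch in shared) {
    ci <- which(candidates$chrom == ch)
    ai <- which(annotations$chrom == ch)
    irc <- IRanges::IRanges(candidates$start[ci] + 1L, candidates$end[ci])
    ira <- IRanges::IRanges(annotations$start[ai] + 1L, annotations$end[ai])
    hits <- IRanges::findOverlaps(irc, ira)
    if (min_overlap_frac > 0 && length(hits) > 0L) {
      ov <- IRanges::width(IRanges::pintersect(
        irc[S4Vectors::queryHits(hits)], ira[S4Vectors::subjectHits(hits)]
      ))
      keep <- ov >= min_overlap_frac *
        IRanges::width(irc[S4Vectors::queryHits(hits)])
      hits <- hits[keep]
    }
    tab <- table(factor(S4Vectors::subjectHits(hits), levels = seq_along(ai)))
    n_cand[ai] <- n_cand[ai] + as.integer(tab)
  }
  per_interval <- mutate(annotations, n_candidates = n_cand)
  nonempty <- n_cand[n_cand > 0L]
  structure(
    list(
      per_interval = per_interval,
      mean_per_nonempty = if (length(nonempty) > 0L) mean(nonempty) else NA_real_,
      n_empty = sum(n_cand == 0L),
      n_assigned = sum(n_cand)
    ),
    class = "reel_density"
  )
}

#' Export candidate calls as BED and TSV
#'
#' Writes a BED6 of called candidates in absolute coordinates (region offset
#' applied), with name = tile id and score = the negated slope scaled
#' linearly to 0-1000 (strongest depletion = 1000), plus a TSV of the full
#' per-tile statistics.
#'
#' @param calls A `reel_calls` tibble from [call_candidates()].
#' @param tiles The `reel_tiles` the calls were computed on (supplies
#'   coordinates and the region offset).
#' @param dir Output directory.
#' @param stem File stem (default `"candidates"`).
#' @return Invisibly, the paths written (`bed`, `tsv`).
#' @export
export_candidates <- function(calls, tiles, dir, stem = "candidates") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  region <- tile_region(tiles)
  joined <- inner_join(
    calls, select(tiles, all_of(c("tile_id", "library_id", "start", "end"))),
    by = c("tile_id", "library_id")
  )
  if (nrow(joined) < nrow(calls)) abort("tiles missing for some calls")
  if (any(region$start + joined$end > region$end)) {
    abort("tile coordinates overflow the region end")
  }
  neg <- -joined$slope
  top <- max(neg[neg > 0], 0)
  score <- if (top > 0) as.integer(round(1000 * pmax(neg, 0) / top)) else 0L

  cand <- joined[joined$is_candidate, , drop = FALSE]
  bed <- tibble(
    chrom = region$chrom,
    start = region$start + cand$start,
    end = region$start + cand$end,
    name = cand$tile_id,
    score = score[joined$is_candidate],
    strand = "+"
  )
  paths <- list(
    bed = file.path(dir, paste0(stem, ".bed")),
    tsv = file.path(dir, paste0(stem, ".tsv"))
  )
  readr::write_tsv(bed, paths$bed, col_names = FALSE)
  readr::write_tsv(
    mutate(joined,
      chrom = region$chrom,
      abs_start = region$start + .data$start,
      abs_end = region$start + .data$end
    ),
    paths$tsv
  )
  invisible(paths)
}

#' Read a BED file of intervals
#'
#' Plain BED3-6 reader returning a tibble in 0-based half-open coordinates.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  bed <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, comment = "#"
  )
  if (ncol(bed) < 3L) abort(paste0("malformed BED (need >= 3 columns): ", path))
  names(bed)[seq_len(min(6L, ncol(bed)))] <- cols[seq_len(min(6L, ncol(bed)))]
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$start >= bed$end)) {
    abort(paste0("malformed BED interval (start >= end) in ", path))
  }
  as_tibble(bed)
}

#' Validation hit and false-positive rates
#'
#' Summarises a downstream validation experiment: of `n_tested` candidates
#' put through an orthogonal assay (e.g. EMSA), `n_confirmed` showed the
#' expected specific signal. The complement is the screen's empirical
#' false-positive rate (8 of 10 confirmed gives 20%).
#'
#' @param n_confirmed Candidates confirmed by the assay.
#' @param n_tested Candidates tested.
#' @return One-row tibble: `n_tested`, `n_confirmed`, `confirmed_rate`,
#'   `false_positive_rate`, `false_positive_pct`.
#' @export
validation_rates <- function(n_confirmed, n_tested) {
  stopifnot(n_tested > 0, n_confirmed >= 0, n_confirmed <= n_tested)
  fpr <- (n_tested - n_confirmed) / n_tested
  tibble(
    n_tested = n_tested, n_confirmed = n_confirmed,
    confirmed_rate = n_confirmed / n_tested,
    false_positive_rate = fpr,
    false_positive_pct = 100 * fpr
  )
}
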