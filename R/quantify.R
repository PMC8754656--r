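#' Count exact-matching reads per tile
#'
#' A read increments a tile's count iff its sequence equals the tile's full
#' construct sequence -- or, by default, its reverse complement -- over the
#' full construct length. No alignment, no partial matching: the screen
#' counts only reads matching perfectly to their templates, and the recovery
#' rate (matched / total) is itself a QC statistic. Sub-library identity
#' comes from the manifest (one FASTQ per sub-library); demultiplexing is
#' upstream.
#'
#' @param manifest Tibble with columns `file`, `library_id`, `condition`,
#'   `round`, `replicate` (as produced by [simulate_reads()]).
#' @param constructs Construct tibble from [build_constructs()].
#' @param accept_revcomp Also match the reverse complement of each construct
#'   (default `TRUE`; real sequencers read either strand).
#' @return A list of class `reel_quant`: `counts` (every (tile, sub-library)
#'   cell explicit, zeros included) and `qc` (per sub-library: `total_reads`,
#'   `matched_reads`, `recovery_rate`). `tidy()` returns the counts,
#'   `glance()` an overall QC row.
#' @export
assign_reads <- function(manifest, constructs, accept_revcomp = TRUE) {
  need <- c("file", "library_id", "condition", "round", "replicate")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0L) {
    abort(paste0("manifest missing column(s): ", paste(missing, collapse = ", ")))
  }
  lookup <- setNames(constructs$tile_id, constructs$full_sequence)
  if (accept_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(constructs$full_sequence)
    ))
    lookup <- c(lookup, setNames(constructs$tile_id, rc))
  }

  per_sub <- pmap(manifest, function(file, library_id, condition, round, replicate) {
    reads <- Biostrings::readDNAStringSet(file, format = "fastq")
    total <- length(reads)
    if (total == 0L) {
      warn(paste0("empty FASTQ: ", file))
      hits <- character(0)
    } else {
      hits <- lookup[as.character(reads)]
      hits <- hits[!is.na(hits)]
    }
    tab <- table(factor(hits, levels = constructs$tile_id))
    list(
      counts = tibble(
        tile_id = constructs$tile_id,
        library_id = constructs$library_id,
        condition = condition, round = round, replicate = replicate,
        count = as.integer(tab)
      ),
      qc = tibble(
        file = file, library_id = library_id, condition = condition,
        round = round, replicate = replicate,
        total_reads = total, matched_reads = length(hits),
        recovery_rate = if (total > 0L) length(hits) / total else NA_real_
      )
    )
  })

  structure(
    list(
      counts = list_rbind(map(per_sub, "counts")),
      qc = list_rbind(map(per_sub, "qc"))
    ),
    class = "reel_quant"
  )
}

#' Convert counts to within-sub-library percentages
#'
#' The calling statistic works on the percentage of each fragment within its
#' sub-library. A pseudocount (default 0.5) is added to every tile before
#' normalizing, so downstream NE/buffer ratios are always finite even for
#' tiles sequenced to zero in some sub-library.
#'
#' @param counts Count tibble (`tile_id`, `library_id`, `condition`, `round`,
#'   `replicate`, `count`) or a `reel_screen`/`reel_quant` object.
#' @param pseudocount Added to every count before normalization (default 0.5).
#' @return The tibble with a `fraction` column added; within every
#'   (library, condition, round, replicate) sub-library the fractions sum
#'   to 1.
#' @examples
#' counts <- tibble::tibble(
#'   tile_id = c("a", "b", "c"), library_id = 1,
#'   condition = "NE", round = 1, replicate = 1, count = c(10L, 30L, 60L)
#' )
#' to_percentages(counts, pseudocount = 0)$fraction
#' @export
to_percentages <- function(counts, pseudocount = 0.5) {
  counts <- as_count_tbl(counts)
  stopifnot(pseudocount >= 0)
  out <- counts |>
    group_by(.data$library_id, .data$condition, .data$round, .data$replicate) |>
    mutate(fraction = (.data$count + pseudocount) /
      sum(.data$count + pseudocount)) |>
    ungroup()
  if (any(!is.finite(out$fraction))) {
    abort("empty sub-library: all-zero column with pseudocount 0")
  }
  attr(out, "pseudocount") <- pseudocount
  out
}

as_count_tbl <- function(x) {
  if (inherits(x, "reel_screen") || inherits(x, "reel_quant")) x <- x$counts
  need <- c("tile_id", "library_id", "condition", "round", "replicate", "count")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    abort(paste0("count table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(x$count < 0)) abort("negative counts")
  x
}

#' Pairwise replicate concordance
#'
#' Computes the Pearson R^2 between the percentage vectors of every replicate
#' pair within each (library, condition, round) sub-library group. The
#' published screen reports R^2 > 0.99 for all pairs; pairs below `threshold`
#' are flagged, as are pairs whose correlation is negative (R^2 alone hides
#' the sign).
#'
#' @param pct Percentage tibble from [to_percentages()].
#' @param threshold Flag pairs with R^2 below this (default 0.99).
#' @return Tibble with one row per replicate pair: `library_id`, `condition`,
#'   `round`, `rep_a`, `rep_b`, `r`, `r_squared`, `flag`. A constant vector
#'   gives an undefined correlation, reported `NA` with a warning.
#' @export
replicate_concordance <- function(pct, threshold = 0.99) {
  stopifnot("fraction" %in% names(pct))
  wide <- pct |>
    select(all_of(c(
      "tile_id", "library_id", "condition", "round", "replicate", "fraction"
    ))) |>
    tidyr::nest(.by = all_of(c("library_id", "condition", "round")))

  rows <- pmap(wide, function(library_id, condition, round, data) {
    m <- pivot_wider(data,
      id_cols = "tile_id", names_from = "replicate",
      values_from = "fraction"
    )
    reps <- setdiff(names(m), "tile_id")
    if (length(reps) < 2L) abort("replicate_concordance needs >= 2 replicates")
    pairs <- utils::combn(reps, 2L, simplify = FALSE)
    map(pairs, function(pr) {
      a <- m[[pr[1L]]]
      b <- m[[pr[2L]]]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warn(sprintf(
          "constant replicate vector in %s round %s; R^2 undefined",
          condition, round
        ))
        NA_real_
      } else {
        cor(a, b)
      }
      tibble(
        library_id = library_id, condition = condition, round = round,
        rep_a = pr[1L], rep_b = pr[2L], r = r, r_squared = r^2,
        flag = is.na(r) | r^2 < threshold | r < 0
      )
    }) |> list_rbind()
  })
  list_rbind(rows)
}
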