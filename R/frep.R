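#' Read a peptide spectral-count table
#'
#' TSV with columns `protein`, `sample1`, `sample2`, `control1`, `control2`
#' and optionally `element` (the cis-RE bait each pulldown used).
#'
#' @param path TSV path.
#' @return Tibble of counts, one row per (element, protein).
#' @export
read_peptide_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("protein", "sample1", "sample2", "control1", "control2")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort(paste0(
      "peptide count table missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!"element" %in% names(tab)) tab$element <- "element_1"
  as_tibble(tab)
}

#' Call specific cis-RE-binding proteins from spectral counts
#'
#' The FREP-MS decision rule is strict presence/absence: a protein is a
#' specific binder iff it has peptide counts in both pulldown samples and in
#' neither control. Everything else is rejected, with the reason recorded:
#' `control-positive` (any control count > 0) or `single-sample-only` (not
#' detected in both samples).
#'
#' @param table Tibble with columns `protein`, `sample1`, `sample2`,
#'   `control1`, `control2` and optionally `element`; counts must be
#'   non-negative integers, protein ids unique within an element (duplicates
#'   are rejected, not summed -- they indicate an upstream table error).
#' @return The table with `is_specific` and `reason` columns added.
#' @examples
#' call_binders(tibble::tibble(
#'   protein = c("PABPC1", "BG1"),
#'   sample1 = c(6L, 3L), sample2 = c(2L, 2L),
#'   control1 = c(0L, 1L), control2 = c(0L, 0L)
#' ))
#' @export
call_binders <- function(table) {
  need <- c("protein", "sample1", "sample2", "control1", "control2")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"element" %in% names(table)) table$element <- "element_1"
  cnt <- as.matrix(table[c("sample1", "sample2", "control1", "control2")])
  if (any(cnt < 0)) abort("negative counts")
  dup <- duplicated(table[c("element", "protein")])
  if (any(dup)) {
    abort(paste0("duplicate protein id: ", table$protein[which(dup)[1L]]))
  }
  control_pos <- table$control1 > 0 | table$control2 > 0
  both_samples <- table$sample1 > 0 & table$sample2 > 0
  mutate(as_tibble(table),
    is_specific = both_samples & !control_pos,
    reason = dplyr::case_when(
      both_samples & !control_pos ~ "both-samples-positive-controls-zero",
      control_pos ~ "control-positive",
      .default = "single-sample-only"
    )
  )
}

#' Summarise specific binders per element
#'
#' @param calls Output of [call_binders()], or a raw count table (called
#'   first), possibly spanning several elements.
#' @return Tibble with one row per element: `element`, `n_specific`,
#'   `binders` (comma-separated, sorted).
#' @examples
#' path <- system.file("extdata", "frep_table1.tsv", package = "reelscan")
#' read_peptide_counts(path) |> summarize_binders()
#' @export
summarize_binders <- function(calls) {
  if (!"is_specific" %in% names(calls)) calls <- call_binders(calls)
  calls |>
    group_by(.data$element) |>
    summarise(
      n_specific = sum(.data$is_specific),
      binders = paste(sort(.data$protein[.data$is_specific]), collapse = ","),
      .groups = "drop"
    )
}
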