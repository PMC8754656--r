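one_sub_manifest <- function(file) {
  tibble::tibble(
    file = file, library_id = 1L, condition = "NE", round = 1L, replicate = 1L
  )
}

test_that("only full-length exact matches are counted; recovery reflects it", {
  cons <- demo_constructs(n_tiles = 4)
  t1 <- cons$full_sequence[1]
  mismatched <- sub("^A", "C", sub("^C", "A", t1)) # one substitution
  stopifnot(mismatched != t1)
  dir <- withr::local_tempdir()
  fq <- write_fastq_plain(c(rep(t1, 10), rep(mismatched, 5)), file.path(dir, "s.fastq"))
  res <- assign_reads(one_sub_manifest(fq), cons)
  counts <- res$counts[res$counts$tile_id == cons$tile_id[1], ]
  expect_identical(counts$count, 10L)
  expect_identical(sum(res$counts$count), 10L)
  expect_equal(res$qc$recovery_rate, 10 / 15)
})

test_that("reverse-complement reads are counted unless disabled", {
  cons <- demo_constructs(n_tiles = 3)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons$full_sequence[2])
  ))
  dir <- withr::local_tempdir()
  fq <- write_fastq_plain(rep(rc, 4), file.path(dir, "s.fastq"))
  with_rc <- assign_reads(one_sub_manifest(fq), cons)
  expect_identical(sum(with_rc$counts$count), 4L)
  no_rc <- assign_reads(one_sub_manifest(fq), cons, accept_revcomp = FALSE)
  expect_identical(sum(no_rc$counts$count), 0L)
})

test_that("error-free simulated reads recover the simulator's counts exactly", {
  cons <- demo_constructs(n_tiles = 24, seed = 3)
  m <- selection_model(f = rep(0, nrow(cons)), mismatch_rate = 0, seed = 4)
  scr <- simulate_screen(
    cons, model = m, design = screen_design(depth = 400, pool_size = 5e4)
  )
  dir <- withr::local_tempdir()
  manifest <- simulate_reads(scr$counts, cons, m, dir)
  res <- assign_reads(manifest, cons)
  key <- c("tile_id", "condition", "round", "replicate")
  a <- dplyr::arrange(scr$counts, dplyr::pick(dplyr::all_of(key)))
  b <- dplyr::arrange(res$counts, dplyr::pick(dplyr::all_of(key)))
  expect_identical(a$count, b$count)
  expect_equal(glance(res)$recovery_rate, 1)
})

test_that("recovery rate decreases as the sequencing error rate rises", {
  cons <- demo_constructs(n_tiles = 8, seed = 5)
  counts <- tidyr::expand_grid(
    tile_id = cons$tile_id, library_id = 1L, condition = "NE",
    round = 1L, replicate = 1L
  )
  counts$count <- 50L
  dir <- withr::local_tempdir()
  rec <- vapply(c(0, 0.01, 0.03), function(rate) {
    m <- selection_model(f = rep(0, nrow(cons)), mismatch_rate = rate, seed = 6)
    man <- simulate_reads(counts, cons, m, file.path(dir, paste0("r", rate * 100)))
    glance(assign_reads(man, cons))$recovery_rate
  }, numeric(1))
  expect_true(all(diff(rec) < 0))
  expect_equal(rec[1], 1)
})

test_that("empty FASTQ warns and yields a zero column", {
  cons <- demo_constructs(n_tiles = 3)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "empty.fastq")
  writeLines(character(0), fq)
  expect_warning(res <- assign_reads(one_sub_manifest(fq), cons), "empty FASTQ")
  expect_true(all(res$counts$count == 0L))
})

test_that("percentages normalize, pseudocount handles zeros, scale invariance", {
  counts <- tibble::tibble(
    tile_id = c("a", "b", "c"), library_id = 1L, condition = "NE",
    round = 1L, replicate = 1L, count = c(10L, 30L, 60L)
  )
  expect_equal(to_percentages(counts, pseudocount = 0)$fraction, c(0.1, 0.3, 0.6))

  zeros <- dplyr::mutate(counts[1:2, ], count = 0L)
  expect_equal(to_percentages(zeros, pseudocount = 0.5)$fraction, c(0.5, 0.5))
  expect_error(to_percentages(zeros, pseudocount = 0), "empty sub-library")

  scaled <- dplyr::mutate(counts, count = count * 7L)
  expect_equal(
    to_percentages(scaled, pseudocount = 0)$fraction,
    to_percentages(counts, pseudocount = 0)$fraction
  )

  # random columns always sum to 1
  set.seed(1)
  big <- tidyr::expand_grid(
    tile_id = sprintf("t%02d", 1:20), library_id = 1L,
    condition = c("buffer", "NE"), round = c(1L, 4L), replicate = 1:3
  )
  big$count <- rpois(nrow(big), 40)
  sums <- to_percentages(big) |>
    dplyr::summarise(
      s = sum(fraction), .by = c(condition, round, replicate)
    )
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("replicate concordance computes pairwise R^2 with sign-aware flags", {
  base <- tidyr::expand_grid(
    tile_id = c("a", "b", "c"), library_id = 1L, condition = "NE",
    round = 1L, replicate = 1:2
  )
  pct <- dplyr::mutate(base,
    fraction = dplyr::if_else(replicate == 1, c(1, 2, 3)[match(tile_id, c("a", "b", "c"))] / 6,
      c(1, 2, 3)[match(tile_id, c("a", "b", "c"))] / 6
    )
  )
  cc <- replicate_concordance(pct)
  expect_equal(cc$r_squared, 1)
  expect_false(cc$flag)

  anti <- dplyr::mutate(base,
    fraction = dplyr::if_else(replicate == 1,
      c(1, 2, 3)[match(tile_id, c("a", "b", "c"))] / 6,
      c(3, 2, 1)[match(tile_id, c("a", "b", "c"))] / 6
    )
  )
  cc2 <- replicate_concordance(anti)
  expect_equal(cc2$r_squared, 1)
  expect_equal(cc2$r, -1)
  expect_true(cc2$flag) # R^2 meets the threshold but the sign is anomalous

  set.seed(2)
  noise <- tidyr::expand_grid(
    tile_id = sprintf("t%04d", 1:1000), library_id = 1L, condition = "NE",
    round = 1L, replicate = 1:2
  )
  noise$fraction <- runif(nrow(noise))
  cc3 <- replicate_concordance(noise)
  expect_lt(cc3$r_squared, 0.05)
  expect_true(cc3$flag)
})

test_that("constant replicate vectors give NA concordance with a warning", {
  base <- tidyr::expand_grid(
    tile_id = c("a", "b", "c"), library_id = 1L, condition = "NE",
    round = 1L, replicate = 1:2
  )
  flat <- dplyr::mutate(base, fraction = dplyr::if_else(replicate == 1, 1 / 3,
    c(0.5, 0.3, 0.2)[match(tile_id, c("a", "b", "c"))]
  ))
  expect_warning(cc <- replicate_concordance(flat), "constant")
  expect_true(is.na(cc$r))
  expect_true(cc$flag)
})

test_that("simulated replicate percentages of a deep non-uniform pool agree at R^2 > 0.99", {
  # a synthesized pool has a wide abundance spread; at the screen's own
  # per-tile coverage every replicate pair reproduces it almost exactly
  tiles <- dplyr::filter(design_tiling(rand_region(35 * 120, seed = 8)), library_id == 1)
  m <- selection_model(
    f = rep(0, nrow(tiles)), pcr_sigma = 0.01, library_sigma = 1.0, seed = 9
  )
  scr <- simulate_screen(
    tiles, model = m, design = screen_design(depth = 1e6, pool_size = 1e7)
  )
  cc <- replicate_concordance(to_percentages(scr$counts))
  expect_identical(nrow(cc), 24L) # 2 conditions x 4 rounds x 3 pairs
  expect_true(all(cc$r_squared > 0.99))
  expect_false(any(cc$flag))
})
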