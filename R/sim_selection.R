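#' Describe the layout of a depletion screen
#'
#' The screen performs `rounds_total` rounds of gel-shift selection on each of
#' `replicates` independent trajectories per condition (nuclear-extract
#' treated samples vs buffer-treated controls), and sequences the recovered
#' unshifted pool at the rounds in `rounds_sequenced`. The defaults mirror
#' the published protocol: 10 rounds, 3 replicates per condition, sequencing
#' at rounds 1, 4, 7 and 10 (24 sub-libraries per library).
#'
#' @param rounds_total Total selection rounds (default 10).
#' @param rounds_sequenced Ascending subset of `1:rounds_total` that is
#'   sequenced (default `c(1, 4, 7, 10)`).
#' @param replicates Independent trajectories per condition (default 3).
#' @param depth Sequencing reads per sub-library (default 1e5, a desk-scale
#'   stand-in for the millions of matched reads per real sub-library).
#' @param pool_size Molecules carried between rounds (default 1e6).
#' @return A list of class `screen_design`.
#' @export
screen_design <- function(rounds_total = 10L, rounds_sequenced = c(1L, 4L, 7L, 10L),
                          replicates = 3L, depth = 1e5, pool_size = 1e6) {
  rounds_total <- as.integer(rounds_total)
  rounds_sequenced <- as.integer(rounds_sequenced)
  stopifnot(
    rounds_total >= 1L,
    all(rounds_sequenced >= 1L), all(rounds_sequenced <= rounds_total),
    !is.unsorted(rounds_sequenced, strictly = TRUE),
    replicates >= 2L, depth > 0, pool_size > 0
  )
  structure(
    list(
      rounds_total = rounds_total, rounds_sequenced = rounds_sequenced,
      replicates = as.integer(replicates), depth = depth,
      pool_size = pool_size, conditions = c("buffer", "NE")
    ),
    class = "screen_design"
  )
}

#' Parameterize the selection model of the screen simulator
#'
#' Each round, a tile is carried into the next pool with probability equal to
#' its retention weight: `(1 - s0) * (1 - f_i)` in the NE condition and
#' `1 - eps_buffer` in buffer. `s0` is the nonspecific shift probability --
#' the evenly and randomly distributed background shifting that removes about
#' half of all fragments per round regardless of sequence -- and `f_i` is the
#' tile's specific, protein-binding shift probability (0 for neutral tiles).
#' Because `s0` hits every tile equally it cancels after renormalization;
#' only `f` produces depletion of a tile relative to the pool. PCR
#' amplification applies i.i.d. per-tile log-normal efficiency jitter
#' (`pcr_sigma` on the log scale) each round.
#'
#' @param f Numeric vector of per-tile functional shift probabilities in
#'   `[0, 1)`, one per tile of the library being simulated.
#' @param s0 Baseline nonspecific shift probability per round in NE
#'   (default 0.5, matching the observed ~50% of fragments shifted).
#' @param eps_buffer Per-round loss probability in buffer (default 0: no
#'   protein, no specific shift).
#' @param pcr_sigma SD of log-normal per-tile amplification noise per round
#'   (default 0.01, calibrated so that after 10 rounds the replicate
#'   percentage vectors of a realistically non-uniform pool still show the
#'   observed all-pairs R^2 > 0.99 concordance).
#' @param library_sigma SD (log scale) of the synthesized pool's per-tile
#'   abundance spread. One abundance vector is drawn per library and shared
#'   by every condition and replicate -- all trajectories start from aliquots
#'   of the same synthesis -- so it cancels from NE/buffer ratios. Default 0
#'   (equimolar pool); 0.5 is typical of a good array synthesis.
#' @param mismatch_rate Per-base sequencing error rate for
#'   [simulate_reads()] (default 0.014, calibrated so ~75-bp constructs give
#'   a ~35% perfect-match recovery rate).
#' @param seed Integer seed; sub-streams are derived per
#'   (library, condition, replicate) so adding replicates does not perturb
#'   existing trajectories.
#' @return A list of class `selection_model`.
#' @export
selection_model <- function(f, s0 = 0.5, eps_buffer = 0, pcr_sigma = 0.01,
                            library_sigma = 0, mismatch_rate = 0.014,
                            seed = 1L) {
  stopifnot(
    is.numeric(f), all(f >= 0), all(f <= 1),
    s0 >= 0, s0 <= 1, eps_buffer >= 0, eps_buffer <= 1,
    pcr_sigma >= 0, library_sigma >= 0, mismatch_rate >= 0, mismatch_rate <= 1
  )
  structure(
    list(
      f = f, s0 = s0, eps_buffer = eps_buffer, pcr_sigma = pcr_sigma,
      library_sigma = library_sigma, mismatch_rate = mismatch_rate,
      seed = as.integer(seed)
    ),
    class = "selection_model"
  )
}

# deterministic sub-stream seed per (library, condition, replicate);
# kept < 2^31 so set.seed() accepts it
substream_seed <- function(seed, library_id, cond_idx, replicate) {
  (abs(seed) * 100003 + library_id * 10007 + cond_idx * 1009 + replicate) %%
    2147483629
}

#' Simulate the iterative EMSA depletion screen
#'
#' Forward-simulates read counts for every sequenced sub-library of a tiling
#' library, alongside ground-truth labels. Each (condition, replicate)
#' trajectory evolves independently from a uniform starting pool: per round,
#' tile abundances are weighted by the retention probabilities of
#' [selection_model()], multinomially resampled to `pool_size` molecules
#' (gel extraction of the unshifted band), multiplied by per-tile log-normal
#' PCR noise, and renormalized; at each sequenced round, `depth` reads are
#' drawn multinomially from the current pool.
#'
#' `f` may be supplied directly through `model`; alternatively
#' `n_functional`/`effect` plant that many functional tiles (chosen from the
#' seeded stream) with retention multiplier `effect` = `1 - f`.
#'
#' @param tiles A tile tibble from [design_tiling()] (one or both libraries).
#' @param model A [selection_model()]; its `f` must have one entry per row of
#'   `tiles`. If `NULL`, one is built from `n_functional`, `effect` and the
#'   remaining defaults.
#' @param design A [screen_design()].
#' @param n_functional,effect Convenience alternative to an explicit `f`:
#'   plant `n_functional` tiles per library with retention `effect`
#'   (so `f = 1 - effect`).
#' @param seed Seed used when `model` is `NULL`.
#' @return A list of class `reel_screen` with elements `counts` (tibble:
#'   `tile_id`, `library_id`, `condition`, `round`, `replicate`, `count`,
#'   zeros explicit), `truth` (tibble: `tile_id`, `library_id`, `f`,
#'   `functional`), `design` and `model`. `tidy()` returns the counts,
#'   `glance()` a one-row design summary.
#' @examples
#' tiles <- design_tiling(genomic_region(strrep("ACGT", 200)))
#' scr <- simulate_screen(tiles,
#'   design = screen_design(depth = 1e3, pool_size = 1e4),
#'   n_functional = 2, effect = 0.8, seed = 7
#' )
#' glance(scr)
#' @export
simulate_screen <- function(tiles, model = NULL, design = screen_design(),
                            n_functional = 0L, effect = 0.8, seed = 1L) {
  stopifnot(inherits(design, "screen_design"))
  n <- nrow(tiles)
  if (is.null(model)) {
    f <- numeric(n)
    if (n_functional > 0L) {
      set.seed(substream_seed(seed, 0L, 0L, 0L))
      for (lib in unique(tiles$library_id)) {
        idx <- which(tiles$library_id == lib)
        k <- min(n_functional, length(idx))
        f[sample(idx, k)] <- 1 - effect
      }
    }
    model <- selection_model(f, seed = seed)
  }
  if (length(model$f) != n) {
    abort(sprintf(
      "`f` has %d entries but `tiles` has %d rows", length(model$f), n
    ))
  }

  libs <- unique(tiles$library_id)
  # one synthesized abundance vector per library, shared by all trajectories
  start_abund <- rep(1, n)
  if (model$library_sigma > 0) {
    for (lib in libs) {
      idx <- which(tiles$library_id == lib)
      set.seed(substream_seed(model$seed, lib, 0L, 0L))
      start_abund[idx] <- rlnorm(length(idx), 0, model$library_sigma)
    }
  }
  cells <- expand_grid(
    library_id = libs,
    condition = design$conditions,
    replicate = seq_len(design$replicates)
  )
  counts <- pmap(cells, function(library_id, condition, replicate) {
    idx <- which(tiles$library_id == library_id)
    retention <- if (condition == "NE") {
      (1 - model$s0) * (1 - model$f[idx])
    } else {
      rep(1 - model$eps_buffer, length(idx))
    }
    cond_idx <- match(condition, design$conditions)
    set.seed(substream_seed(model$seed, library_id, cond_idx, replicate))
    reads <- simulate_trajectory(
      retention, design, model$pcr_sigma, start_abund[idx]
    )
    tibble(
      tile_id = rep(tiles$tile_id[idx], times = ncol(reads)),
      library_id = library_id,
      condition = condition,
      round = rep(design$rounds_sequenced, each = length(idx)),
      replicate = replicate,
      count = as.integer(reads)
    )
  }) |> list_rbind()

  truth <- tibble(
    tile_id = tiles$tile_id,
    library_id = tiles$library_id,
    f = model$f,
    functional = model$f > 0
  )
  structure(
    list(counts = counts, truth = truth, design = design, model = model),
    class = "reel_screen"
  )
}

# one (condition, replicate) trajectory; returns tiles x sequenced-rounds
# matrix of read counts
simulate_trajectory <- function(retention, design, pcr_sigma,
                                start_abund = NULL) {
  n <- length(retention)
  p <- if (is.null(start_abund)) rep(1 / n, n) else start_abund / sum(start_abund)
  reads <- matrix(0L, nrow = n, ncol = length(design$rounds_sequenced))
  for (r in seq_len(design$rounds_total)) {
    w <- p * retention
    tot <- sum(w)
    if (tot <= 0) abort("library extinguished: all retention weights zero")
    pool <- rmultinom(1L, size = design$pool_size, prob = w / tot)[, 1L]
    amp <- if (pcr_sigma > 0) pool * rlnorm(n, 0, pcr_sigma) else pool
    p <- amp / sum(amp)
    hit <- match(r, design$rounds_sequenced)
    if (!is.na(hit)) {
      reads[, hit] <- rmultinom(1L, size = design$depth, prob = p)[, 1L]
    }
  }
  reads
}

#' Write simulated sequencing reads for each sub-library
#'
#' Emits one FASTQ file per sequenced sub-library. Each count unit of a tile
#' becomes one read of its construct's full sequence, with independent
#' per-base substitution errors at the model's `mismatch_rate`. Read names
#' encode the sub-library and source tile for debugging only; quantification
#' never uses them.
#'
#' @param counts Count tibble (e.g. `screen$counts`).
#' @param constructs Construct tibble from [build_constructs()] (must carry
#'   `full_sequence`).
#' @param model The [selection_model()] (for `mismatch_rate` and `seed`).
#' @param dir Output directory.
#' @return A manifest tibble (`file`, `library_id`, `condition`, `round`,
#'   `replicate`), the input [assign_reads()] expects.
#' @export
simulate_reads <- function(counts, constructs, model, dir) {
  if (!"full_sequence" %in% names(constructs)) {
    abort("`constructs` must come from build_constructs()")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seq_of <- setNames(constructs$full_sequence, constructs$tile_id)
  cells <- distinct(
    counts, .data$library_id, .data$condition, .data$round, .data$replicate
  )
  set.seed(substream_seed(model$seed, 0L, 9L, 0L))
  manifest <- pmap(cells, function(library_id, condition, round, replicate) {
    sub <- counts[counts$library_id == library_id &
      counts$condition == condition &
      counts$round == round &
      counts$replicate == replicate & counts$count > 0L, ]
    seqs <- rep(seq_of[sub$tile_id], times = sub$count)
    seqs <- mutate_bases(unname(seqs), model$mismatch_rate)
    file <- file.path(dir, sprintf(
      "lib%d_%s_r%02d_rep%d.fastq", library_id, condition, round, replicate
    ))
    ids <- sprintf(
      "lib%d_%s_r%d_rep%d:%s:%d",
      library_id, condition, round, replicate,
      rep(sub$tile_id, times = sub$count),
      seq_along(seqs)
    )
    write_fastq(seqs, ids, file)
    tibble(
      file = file, library_id = library_id, condition = condition,
      round = round, replicate = replicate
    )
  }) |> list_rbind()
  manifest
}

# independent per-base substitutions at rate `rate`
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

write_fastq <- function(seqs, ids, file) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dna, file, format = "fastq", qualities = quals)
  invisible(file)
}
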