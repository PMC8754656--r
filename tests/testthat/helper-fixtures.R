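# shared fixtures and independent oracles

rand_seq <- function(len, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rand_region <- function(len, seed = 1, chrom = "chr9", start = 0L) {
  genomic_region(rand_seq(len, seed), chrom = chrom, start = start)
}

# independent tiling oracle: walk the region with a cursor, no arithmetic
# shortcuts shared with design_tiling()
oracle_tile_starts <- function(region_len, tile_len, from) {
  starts <- integer(0)
  pos <- from
  while (pos + tile_len <= region_len) {
    starts <- c(starts, pos)
    pos <- pos + tile_len
  }
  starts
}

# deterministic-limit depletion recursion: abundance vector evolves by
# retention weighting + renormalization only (infinite pool/depth, no noise)
oracle_ratios <- function(retention_ne, rounds) {
  n <- length(retention_ne)
  p_ne <- rep(1 / n, n)
  p_buf <- rep(1 / n, n)
  out <- matrix(NA_real_, nrow = n, ncol = length(rounds))
  k <- 0L
  for (r in seq_len(max(rounds))) {
    p_ne <- p_ne * retention_ne
    p_ne <- p_ne / sum(p_ne)
    if (r %in% rounds) {
      k <- k + 1L
      out[, k] <- p_ne / p_buf
    }
  }
  out
}

# plain-text FASTQ writer independent of the package's Biostrings path
write_fastq_plain <- function(seqs, path) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(
      lines,
      paste0("@read", i), seqs[i], "+", strrep("I", nchar(seqs[i]))
    )
  }
  writeLines(lines, path)
  path
}

# brute-force cluster oracle: slide a window_bp window one bp at a time,
# connect candidates fully contained in a common window, take components
oracle_clusters <- function(starts, ends, window_bp) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  lo <- min(starts)
  hi <- max(ends)
  for (w in lo:(max(lo, hi - window_bp))) {
    inside <- which(starts >= w & ends <= w + window_bp)
    if (length(inside) > 1L) adj[inside, inside] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a partition for comparison across labelings
partition_sets <- function(ids) {
  sets <- split(seq_along(ids), ids)
  sets <- lapply(sets, sort)
  sets <- sets[order(vapply(sets, function(s) s[[1L]], integer(1)))]
  unname(sets)
}

demo_constructs <- function(n_tiles = 24, seed = 3) {
  reg <- rand_region(35 * n_tiles, seed = seed)
  tiles <- dplyr::filter(design_tiling(reg), library_id == 1)
  build_constructs(tiles, "ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA")
}
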