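#' Build a mismatch pileup from aligned reads
#'
#' Tallies, per genomic position, the bases contributed by reads passing
#' the mapping-quality gate. Reads with `mapq < mapq_min` (and MAPQ 255,
#' "unavailable") contribute nothing; N bases contribute to neither
#' counts nor depth. By default only positions where at least one
#' passing read differs from the reference are emitted; those positions
#' carry one row per observed base so that the counts sum to the depth.
#'
#' Each row also records the number of distinct (start, end) alignment
#' intervals among the reads carrying that base, the quantity used to
#' require support from reads mapped to overlapping but not identical
#' positions (a PCR-duplicate guard).
#'
#' @param reads read tibble
#'   (`read_id, chrom, start, length, mapq, seq`, see [read_sam()]).
#' @param genome a [Biostrings::DNAStringSet].
#' @param mapq_min minimum MAPQ for a read to contribute (default 30).
#' @param mismatch_only emit only mismatch-bearing positions (default);
#'   `FALSE` emits every covered position (needed for exact pooled
#'   depths in [merge_samples()]).
#' @return a pileup tibble:
#'   `chrom, pos, ref, base, count, distinct, depth`, sorted by
#'   position; `depth` is the per-position total over passing reads.
#' @export
build_pileup <- function(reads, genome, mapq_min = 30L,
                         mismatch_only = TRUE) {
  assert_genome(genome)
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  base = character(), count = integer(),
                  distinct = integer(), depth = integer())
  if (nrow(reads) == 0) return(empty)
  glens <- genome_lengths(genome)
  if (!all(reads$chrom %in% names(glens))) {
    abort("read aligned to a chromosome absent from the genome")
  }
  ends <- reads$start + reads$length - 1L
  if (any(reads$start < 1L) || any(ends > glens[reads$chrom])) {
    abort("read extends beyond its chromosome end")
  }
  pass <- reads$mapq >= mapq_min & reads$mapq != 255L
  reads <- reads[pass, ]
  if (nrow(reads) == 0) return(empty)

  lens <- reads$length
  dt <- data.table::data.table(
    chrom = rep(reads$chrom, lens),
    pos = rep(reads$start, lens) + sequence(lens) - 1L,
    base = unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE),
    rstart = rep(reads$start, lens),
    rend = rep(reads$start + lens - 1L, lens))
  dt <- dt[base != "N"]
  if (nrow(dt) == 0) return(empty)

  gstr <- genome_strings(genome)
  counts <- dt[, {
    iv <- as.numeric(rstart) * 1e9 + rend  # interval key
    list(count = .N, distinct = data.table::uniqueN(iv))
  }, by = .(chrom, pos, base)]
  counts[, depth := sum(count), by = .(chrom, pos)]
  counts[, ref := base_at(gstr[[chrom[1]]], pos), by = chrom]
  if (mismatch_only) {
    counts[, has_mm := any(base != ref), by = .(chrom, pos)]
    counts <- counts[has_mm == TRUE][, has_mm := NULL]
  }
  data.table::setorder(counts, chrom, pos, base)
  as_tibble(counts[, .(chrom, pos, ref, base, count, distinct, depth)])
}

#' Distinct supporting alignment intervals for one base
#'
#' Accessor over a pileup: the number of distinct (start, end) mapped
#' intervals among reads carrying `alt` at (`chrom`, `pos`); 0 when the
#' base was not observed there.
#'
#' @param pileup a pileup tibble from [build_pileup()].
#' @param chrom,pos position.
#' @param alt base.
#' @return an integer.
#' @export
distinct_support <- function(pileup, chrom, pos, alt) {
  row <- pileup[pileup$chrom == chrom & pileup$pos == pos &
                  pileup$base == alt, ]
  if (nrow(row) == 0) 0L else row$distinct[1]
}
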