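# Independent brute-force oracles and small fixture builders.
# These deliberately use plain loops and base R so they share no code
# path with the package implementation they check.

empty_sites_fixture <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), strand = character(), level = double(),
                 n_support = integer(), distinct_support = integer(),
                 depth = integer(), region = character(),
                 gene_id = character())
}

# a tiny read tibble builder
mk_reads <- function(chrom, start, seq, mapq = 60L,
                     id = sprintf("r%03d", seq_along(start)),
                     strand = "+") {
  tibble::tibble(
    read_id = id, chrom = chrom, start = as.integer(start),
    end = as.integer(start + nchar(seq) - 1L),
    length = nchar(seq), strand = strand,
    mapq = as.integer(mapq), seq = seq)
}

mk_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# naive per-position pileup: loop positions, vectorised only over reads
naive_pileup <- function(reads, genome, mapq_min = 30L,
                         mismatch_only = TRUE) {
  pass <- reads[reads$mapq >= mapq_min & reads$mapq != 255L, , drop = FALSE]
  rows <- list()
  for (cn in names(genome)) {
    gseq <- as.character(genome[[cn]])
    rr <- pass[pass$chrom == cn, , drop = FALSE]
    if (nrow(rr) == 0) next
    for (p in seq_len(nchar(gseq))) {
      cov <- which(rr$start <= p & rr$end >= p)
      if (length(cov) == 0) next
      bases <- substr(rr$seq[cov], p - rr$start[cov] + 1L,
                      p - rr$start[cov] + 1L)
      keep <- bases != "N"
      bases <- bases[keep]; cov <- cov[keep]
      if (length(bases) == 0) next
      ref <- substr(gseq, p, p)
      if (mismatch_only && all(bases == ref)) next
      for (b in sort(unique(bases))) {
        sel <- cov[bases == b]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, pos = p, ref = ref, base = b,
          count = length(sel),
          distinct = length(unique(paste(rr$start[sel], rr$end[sel]))),
          depth = length(bases))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               base = character(), count = integer(), distinct = integer(),
               depth = integer())
  tibble::as_tibble(out[order(out$chrom, out$pos, out$base), ])
}

# naive caller applying the filters literally on top of naive_pileup
naive_call <- function(reads, genome, config = editome::caller_config()) {
  pile <- naive_pileup(reads, genome, mapq_min = config$mapq_min)
  sites <- list()
  key <- paste(pile$chrom, pile$pos)
  for (cols in split(seq_len(nrow(pile)), factor(key, levels = unique(key)))) {
    col <- pile[cols, , drop = FALSE]
    ref <- col$ref[1]
    alts <- col[col$base != ref, , drop = FALSE]
    if (nrow(alts) == 0) next
    types <- alts[alts$distinct >= config$multi_type_min, , drop = FALSE]
    if (config$discard_multi_type && nrow(types) > 1) next
    cand <- if (nrow(types) == 1) types else {
      alts[order(-alts$distinct, -alts$count, alts$base), ][1, , drop = FALSE]
    }
    if (!is.null(config$genomic_mask) &&
        any(config$genomic_mask$chrom == cand$chrom &
              config$genomic_mask$pos == cand$pos)) next
    strand <- if (ref == "A" && cand$base == "G") "+"
      else if (ref == "T" && cand$base == "C") "-" else NA
    if (is.na(strand)) next
    if (cand$distinct < config$min_support) next
    level <- cand$count / cand$depth
    if (level <= config$min_level) next
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = cand$chrom, pos = cand$pos, ref = ref, alt = cand$base,
      strand = strand, level = level, n_support = cand$count,
      distinct_support = cand$distinct, depth = cand$depth)
  }
  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), strand = character(), level = double(),
               n_support = integer(), distinct_support = integer(),
               depth = integer())
  tibble::as_tibble(out[order(out$chrom, out$pos), ])
}

# a random small alignment instance with mismatches, duplicates,
# low-MAPQ and MAPQ-255 reads
random_instance <- function(n_chrom = sample(1:2, 1),
                            chrom_len = sample(500:3000, 1),
                            n_reads = sample(20:100, 1),
                            read_len = 50L,
                            mismatch_rate = 0.02) {
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("c", seq_len(n_chrom))
  chrom <- sample(names(genome), n_reads, replace = TRUE)
  start <- vapply(chrom, function(cn) {
    sample.int(chrom_len - read_len + 1L, 1)
  }, integer(1))
  seq <- substring(seqs[match(chrom, names(genome))], start,
                   start + read_len - 1L)
  for (i in seq_len(n_reads)) {
    hits <- which(stats::runif(read_len) < mismatch_rate)
    if (length(hits)) {
      s <- strsplit(seq[i], "")[[1]]
      s[hits] <- vapply(s[hits], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      seq[i] <- paste(s, collapse = "")
    }
  }
  mapq <- sample(c(0:60, 255L), n_reads, replace = TRUE)
  reads <- mk_reads(chrom, start, seq, mapq = mapq)
  # sprinkle exact duplicates
  n_dup <- stats::rbinom(1, n_reads, 0.15)
  if (n_dup > 0) {
    di <- sample.int(n_reads, n_dup, replace = TRUE)
    dup <- reads[di, ]
    dup$read_id <- paste0(dup$read_id, "_dup")
    reads <- rbind(reads, dup)
  }
  list(genome = genome, reads = reads)
}

# brute-force seed-site scanner: checks every window of every class
# base by base against an explicit pairing table
brute_seed_scan <- function(mirna_seq, target_seq, wobble = FALSE) {
  pair <- function(t, m) {
    wc <- paste(t, m) %in% c("A U", "U A", "G C", "C G")
    if (wobble) wc | paste(t, m) %in% c("G U", "U G") else wc
  }
  tv <- strsplit(target_seq, "")[[1]]
  mv <- strsplit(mirna_seq, "")[[1]]
  n <- length(tv)
  hits <- list()
  for (j in seq_len(max(0, n - 5L))) {
    ok6 <- TRUE
    for (k in 0:5) if (!pair(tv[j + k], mv[7 - k])) { ok6 <- FALSE; break }
    if (!ok6) next
    m8 <- j > 1 && pair(tv[j - 1], mv[8])
    a1 <- (j + 6) <= n && tv[j + 6] == "A"
    cls <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
      else if (a1) "7mer-A1" else "6mer"
    win <- switch(cls,
      "8mer" = c(j - 1, j + 6), "7mer-m8" = c(j - 1, j + 5),
      "7mer-A1" = c(j, j + 6), "6mer" = c(j, j + 5))
    hits[[length(hits) + 1L]] <- data.frame(
      match_start = win[1], match_end = win[2], match_class = cls)
  }
  if (length(hits)) tibble::as_tibble(do.call(rbind, hits)) else
    tibble::tibble(match_start = integer(), match_end = integer(),
                   match_class = character())
}

impact_verdict_fixture <- function(a, b) editome:::impact_verdict(a, b)

# drop bookkeeping attributes before frame comparisons
strip_sites <- function(x) {
  attr(x, "rejections") <- NULL
  attr(x, "antisense_genic") <- NULL
  as.data.frame(x)
}

# whole-protein translation oracle for coding effects (vectorised:
# translates every unedited/edited CDS pair in one batch)
translation_effect_oracle <- function(cds, cds_pos) {
  stopifnot(all(substr(cds, cds_pos, cds_pos) == "A"))
  edited <- cds
  substr(edited, cds_pos, cds_pos) <- "G"
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds)))
  aa_alt <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(edited)))
  ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous")
}

# a deterministic two-gene model set on a hand-built genome, for
# annotation tests: known exact coordinates
fixture_two_genes <- function() {
  # chrom of 600 bp, gene A (+): exon 101-220, 301-400;
  # CDS 151-220, 301-380; gene B (-): exon 451-560, CDS 471-540
  base <- paste(rep("T", 600), collapse = "")
  models <- tibble::tibble(
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB"),
    transcript_id = paste0(c("gA", "gA", "gA", "gA", "gB", "gB"), ".t1"),
    chrom = "c1",
    strand = c("+", "+", "+", "+", "-", "-"),
    type = c("exon", "exon", "CDS", "CDS", "exon", "CDS"),
    start = c(101L, 301L, 151L, 301L, 451L, 471L),
    end = c(220L, 400L, 220L, 380L, 560L, 540L))
  # write valid ORFs into the genome so coding_effect works
  gchars <- strsplit(base, "")[[1]]
  cdsA <- c(151:220, 301:380)  # 150 nt, + strand
  seqA <- paste0("ATG", paste(rep("AAA", 48), collapse = ""), "TAA")
  gchars[cdsA] <- strsplit(seqA, "")[[1]]
  cdsB <- 471:540              # 70 nt is not %3; use 69 + pad -> 471:539? keep 69*...
  # 70 not divisible by 3; shift CDS end to 539 (69 nt = 23 codons)
  models$end[models$gene_id == "gB" & models$type == "CDS"] <- 539L
  cdsB <- 471:539
  seqB <- paste0("ATG", paste(rep("AAA", 21), collapse = ""), "TAG")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gchars[cdsB] <- rev(comp[strsplit(seqB, "")[[1]]])
  genome <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
  names(genome) <- "c1"
  list(genome = genome, models = models)
}
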