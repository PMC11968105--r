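#' Simulation configuration
#'
#' Bundles every knob of the synthetic editome generator. The defaults
#' describe a desk-scale haploid genome whose genic-region mix of planted
#' editing sites follows the region distribution observed in the
#' *Metopolophium dirhodum* editome (about 37% intergenic, 39% intronic,
#' 17% CDS, with small UTR fractions), with editing levels drawn
#' uniformly on (0.1, 0.9) and 50x read coverage.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_lengths integer vector of chromosome lengths (bp),
#'   recycled to `n_chrom`; each must be at least 1000.
#' @param gc_fraction expected GC content of the background genome.
#' @param n_genes number of non-overlapping protein-coding genes to place.
#' @param exons_per_gene length-2 integer range of exon counts per gene.
#' @param n_truth_sites number of editing sites to plant.
#' @param region_mix named proportions over
#'   `c("cds","intron","five_prime_utr","three_prime_utr","intergenic")`;
#'   must sum to 1.
#' @param level_range length-2 range in (0, 1] for per-site true editing
#'   levels (drawn uniformly).
#' @param coverage mean read depth per base.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param mapq_low_fraction fraction of reads given MAPQ below 30.
#' @param duplicate_rate fraction of reads re-emitted as exact
#'   coordinate-and-sequence duplicates (PCR duplicates).
#' @param seed integer RNG seed; the whole simulation is a pure function
#'   of the configuration including this seed.
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_chrom = 1, chrom_lengths = 5000, n_genes = 2,
#'                   n_truth_sites = 5, coverage = 20, seed = 42)
#' @export
sim_config <- function(n_chrom = 3,
                       chrom_lengths = c(60000L, 50000L, 40000L),
                       gc_fraction = 0.30,
                       n_genes = 30,
                       exons_per_gene = c(2L, 5L),
                       n_truth_sites = 200,
                       region_mix = c(cds = 0.171, intron = 0.387,
                                      five_prime_utr = 0.029,
                                      three_prime_utr = 0.040,
                                      intergenic = 0.373),
                       level_range = c(0.1, 0.9),
                       coverage = 50,
                       read_length = 100L,
                       error_rate = 0.005,
                       mapq_low_fraction = 0.1,
                       duplicate_rate = 0.05,
                       seed = 1L) {
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chrom))
  if (n_chrom < 1) abort("`n_chrom` must be at least 1")
  if (any(chrom_lengths < 1000)) {
    abort("all chromosome lengths must be at least 1000 bp")
  }
  check_fraction(gc_fraction, "gc_fraction")
  check_fraction(error_rate, "error_rate")
  check_fraction(mapq_low_fraction, "mapq_low_fraction")
  check_fraction(duplicate_rate, "duplicate_rate")
  check_fraction(region_mix, "region_mix")
  if (abs(sum(region_mix) - 1) > 1e-6) abort("`region_mix` must sum to 1")
  classes <- c("cds", "intron", "five_prime_utr", "three_prime_utr",
               "intergenic")
  if (!all(names(region_mix) %in% classes)) {
    abort(sprintf("region_mix names must be among: %s",
                  paste(classes, collapse = ", ")))
  }
  if (length(level_range) != 2 || level_range[1] <= 0 ||
      level_range[2] > 1 || level_range[1] > level_range[2]) {
    abort("`level_range` must be an increasing pair within (0, 1]")
  }
  if (read_length > min(chrom_lengths)) {
    abort("`read_length` must not exceed the shortest chromosome")
  }
  if (read_length < 1) abort("`read_length` must be positive")
  structure(
    list(n_chrom = as.integer(n_chrom), chrom_lengths = chrom_lengths,
         gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         n_truth_sites = as.integer(n_truth_sites),
         region_mix = region_mix, level_range = level_range,
         coverage = coverage, read_length = as.integer(read_length),
         error_rate = error_rate, mapq_low_fraction = mapq_low_fraction,
         duplicate_rate = duplicate_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a background genome
#'
#' Draws each base independently with the configured GC fraction
#' (G and C each at `gc_fraction/2`). Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a named [Biostrings::DNAStringSet] with chromosomes
#'   `chr1 ... chrN`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    probs <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
               config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
    seqs <- vapply(config$chrom_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(config$n_chrom))
    genome
  })
}

# sample one internal (non-stop) codon sequence of n codons
sample_cds_sequence <- function(n_codons) {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                            DNA_BASES, paste0))
  internal <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG",
         paste(sample(internal, n_codons, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Simulate stranded multi-exon gene models
#'
#' Places `n_genes` non-overlapping genes on both strands. Each gene has
#' a 5' UTR, a spliced CDS whose length is divisible by three, starts
#' with ATG and ends with a single stop codon, and a 3' UTR. The genome
#' bases under each CDS are rewritten so the open reading frame is valid
#' by construction, which makes exact synonymous/nonsynonymous oracles
#' possible downstream.
#'
#' @param genome a [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param config a [sim_config()].
#' @return a list with `models` (a gene-model tibble with columns
#'   `gene_id, transcript_id, chrom, strand, type, start, end` where
#'   `type` is `"exon"` or `"CDS"`) and `genome` (the rewritten genome).
#' @export
simulate_gene_models <- function(genome, config) {
  assert_genome(genome)
  if (config$n_genes == 0) {
    return(list(models = empty_gene_models(), genome = genome))
  }
  withr::with_seed(config$seed + 1L, {
    glens <- genome_lengths(genome)
    gchars <- lapply(genome_strings(genome),
                     function(s) strsplit(s, "", fixed = TRUE)[[1]])
    placed <- stats::setNames(
      rep(list(data.frame(start = integer(), end = integer())),
          length(glens)), names(glens))
    strands <- sample(rep_len(c("+", "-"), config$n_genes))
    rows <- vector("list", config$n_genes)

    for (i in seq_len(config$n_genes)) {
      u5 <- sample(30:90, 1)
      n_codons <- sample(50:200, 1)
      cds_len <- 3L * (n_codons + 2L)          # ATG + internal + stop
      u3 <- sample(60:180, 1)
      splice_len <- u5 + cds_len + u3
      k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      exon_lens <- exon_partition(splice_len, k)
      intron_lens <- if (k > 1) sample(60:200, k - 1, replace = TRUE) else integer()
      span <- splice_len + sum(intron_lens)

      loc <- NULL
      for (try in seq_len(400)) {
        chrom <- sample(names(glens), 1, prob = glens)
        if (glens[[chrom]] < span + 400) next
        start <- sample.int(glens[[chrom]] - span - 200L, 1) + 100L
        end <- start + span - 1L
        p <- placed[[chrom]]
        if (!any(start <= p$end + 100L & end >= p$start - 100L)) {
          loc <- list(chrom = chrom, start = start)
          break
        }
      }
      if (is.null(loc)) {
        abort("genome too small to place the requested number of genes")
      }

      ex_start <- integer(k); ex_end <- integer(k)
      s <- loc$start
      for (j in seq_len(k)) {
        ex_start[j] <- s
        ex_end[j] <- s + exon_lens[j] - 1L
        s <- ex_end[j] + (if (j < k) intron_lens[j] else 0L) + 1L
      }
      placed[[loc$chrom]] <- rbind(
        placed[[loc$chrom]],
        data.frame(start = loc$start, end = ex_end[k]))

      strand <- strands[i]
      gpos <- unlist(Map(seq.int, ex_start, ex_end), use.names = FALSE)
      t2g <- if (strand == "+") gpos else rev(gpos)
      cds_t <- seq.int(u5 + 1L, u5 + cds_len)
      cds_g <- t2g[cds_t]

      cds_seq <- chars(sample_cds_sequence(n_codons))
      write_base <- if (strand == "+") cds_seq else DNA_COMPLEMENT[cds_seq]
      gchars[[loc$chrom]][cds_g] <- write_base

      cds_sorted <- sort(cds_g)
      runs <- cumsum(c(1L, diff(cds_sorted) != 1L))
      cds_iv <- vapply(split(cds_sorted, runs), range, integer(2))

      gene_id <- sprintf("gene%03d", i)
      rows[[i]] <- bind_rows(
        tibble(gene_id = gene_id, chrom = loc$chrom, strand = strand,
               type = "exon", start = ex_start, end = ex_end),
        tibble(gene_id = gene_id, chrom = loc$chrom, strand = strand,
               type = "CDS", start = cds_iv[1, ], end = cds_iv[2, ])
      )
    }

    genome2 <- Biostrings::DNAStringSet(
      vapply(gchars, paste, character(1), collapse = ""))
    names(genome2) <- names(genome)
    models <- list_rbind(rows) |>
      mutate(transcript_id = paste0(.data$gene_id, ".t1"),
             .after = "gene_id") |>
      arrange(.data$chrom, .data$start, .data$type)
    list(models = models, genome = genome2)
  })
}

empty_gene_models <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         chrom = character(), strand = character(), type = character(),
         start = integer(), end = integer())
}

# split a spliced length into k exon pieces, each at least 20 bp
exon_partition <- function(len, k) {
  if (k == 1) return(len)
  for (try in seq_len(100)) {
    cuts <- sort(sample.int(len - 1L, k - 1L))
    pieces <- diff(c(0L, cuts, len))
    if (all(pieces >= 20L)) return(as.integer(pieces))
  }
  # fall back to an even split
  base <- len %/% k
  pieces <- rep(base, k)
  pieces[k] <- pieces[k] + len - sum(pieces)
  as.integer(pieces)
}

#' Plant true editing sites
#'
#' Chooses `n_truth_sites` genomic positions according to `region_mix`,
#' each on an adenosine of its transcript strand (genomic A for `+`
#' sites, genomic T for `-` sites), with per-site true editing levels
#' drawn uniformly from `level_range`. Genic classes inherit the strand
#' of their gene; intergenic sites take the strand implied by the
#' genomic base.
#'
#' @param genome genome as rewritten by [simulate_gene_models()].
#' @param models gene-model tibble.
#' @param config a [sim_config()].
#' @return a truth tibble with columns
#'   `chrom, pos, strand, true_level, region_class`.
#' @export
plant_truth_sites <- function(genome, models, config) {
  assert_genome(genome)
  if (config$n_truth_sites == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  strand = character(), true_level = double(),
                  region_class = character()))
  }
  withr::with_seed(config$seed + 2L, {
    gstr <- genome_strings(genome)
    regions <- gene_regions(models)
    spans <- gene_spans(models)
    n_by_class <- apportion_counts(config$region_mix, config$n_truth_sites)

    out <- list()
    for (cls in names(n_by_class)) {
      need <- n_by_class[[cls]]
      if (need == 0) next
      if (cls == "intergenic") {
        out[[cls]] <- sample_intergenic_sites(gstr, spans, need)
        next
      }
      rr <- filter(regions, .data$region == region_key(cls))
      if (nrow(rr) == 0) {
        abort(sprintf("region_mix requests %s sites but no such regions exist",
                      cls))
      }
      cand <- list_rbind(pmap(rr, function(gene_id, chrom, strand, region,
                                           start, end, ...) {
        pos <- seq.int(start, end)
        base <- base_at(gstr[[chrom]], pos)
        want <- if (strand == "+") "A" else "T"
        tibble(chrom = chrom, pos = pos[base == want], strand = strand)
      }))
      if (nrow(cand) < need) {
        abort(sprintf(
          "region_mix infeasible: %d %s sites requested, %d A positions available",
          need, cls, nrow(cand)))
      }
      out[[cls]] <- cand[sample.int(nrow(cand), need), ] |>
        mutate(region_class = cls)
    }
    truth <- list_rbind(out) |>
      mutate(true_level = runif(n(), config$level_range[1],
                                config$level_range[2])) |>
      select("chrom", "pos", "strand", "true_level", "region_class") |>
      arrange(.data$chrom, .data$pos)
    stopifnot(!anyDuplicated(truth[c("chrom", "pos")]))
    truth
  })
}

region_key <- function(cls) {
  c(cds = "cds", intron = "intron", five_prime_utr = "utr5",
    three_prime_utr = "utr3")[[cls]]
}

apportion_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.list(base)
}

sample_intergenic_sites <- function(gstr, spans, need) {
  glens <- vapply(gstr, nchar, integer(1))
  got <- tibble(chrom = character(), pos = integer(), strand = character())
  for (round in seq_len(50)) {
    if (nrow(got) >= need) break
    m <- (need - nrow(got)) * 4L + 20L
    chrom <- sample(names(glens), m, replace = TRUE, prob = glens)
    pos <- vapply(chrom, function(cn) sample.int(glens[[cn]], 1), integer(1))
    cand <- tibble(chrom = chrom, pos = as.integer(pos)) |> distinct()
    if (nrow(spans) > 0) {
      cand <- anti_join(
        cand, spans,
        by = join_by("chrom", between("pos", "start", "end")))
    }
    if (nrow(cand) == 0) next
    base <- map_chr(seq_len(nrow(cand)),
                    function(i) base_at(gstr[[cand$chrom[i]]], cand$pos[i]))
    cand <- cand[base %in% c("A", "T"), ]
    cand$strand <- ifelse(
      base[base %in% c("A", "T")] == "A", "+", "-")
    got <- bind_rows(got, cand) |> distinct(.data$chrom, .data$pos,
                                            .keep_all = TRUE)
  }
  if (nrow(got) < need) {
    abort("could not place the requested number of intergenic sites")
  }
  got[seq_len(need), ] |> mutate(region_class = "intergenic")
}

#' Simulate aligned RNA reads with planted edits
#'
#' Emits gapless single-end alignments. Read counts per chromosome are
#' Poisson with mean `coverage * length / read_length`; starts are
#' uniform. A read overlapping a truth site carries the edited base
#' (G at `+` sites, C at `-` sites, in genomic coordinates) with
#' probability `true_level`, independently per read; every base is then
#' substituted to a random other base with probability `error_rate`.
#' `mapq_low_fraction` of reads get MAPQ drawn from 0-29, the rest
#' 30-60; `duplicate_rate` of reads are re-emitted with identical
#' coordinates and sequence (PCR duplicates).
#'
#' @param genome genome as rewritten by [simulate_gene_models()].
#' @param models gene-model tibble (unused for placement; reads are
#'   genome-uniform, matching a genomic-coordinate caller).
#' @param truth truth tibble from [plant_truth_sites()].
#' @param config a [sim_config()].
#' @return a read tibble with columns
#'   `read_id, chrom, start, end, length, strand, mapq, seq`.
#' @export
simulate_reads <- function(genome, models, truth, config) {
  assert_genome(genome)
  if (config$coverage <= 0) abort("`coverage` must be positive")
  withr::with_seed(config$seed + 3L, {
    gstr <- genome_strings(genome)
    rl <- config$read_length
    out <- vector("list", length(gstr))
    for (ci in seq_along(gstr)) {
      cn <- names(gstr)[ci]
      L <- nchar(gstr[[cn]])
      n_reads <- rpois(1, config$coverage * L / rl)
      if (n_reads == 0) { out[[ci]] <- NULL; next }
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      ends <- starts + rl - 1L
      seqs <- substring(gstr[[cn]], starts, ends)

      tt <- truth[truth$chrom == cn, ]
      for (ti in seq_len(nrow(tt))) {
        pos <- tt$pos[ti]
        idx <- which(starts <= pos & ends >= pos)
        if (length(idx) == 0) next
        hit <- idx[runif(length(idx)) < tt$true_level[ti]]
        if (length(hit) == 0) next
        off <- pos - starts[hit] + 1L
        edited <- if (tt$strand[ti] == "+") "G" else "C"
        substr(seqs[hit], off, off) <- edited
      }

      if (config$error_rate > 0) {
        n_err <- rbinom(n_reads, rl, config$error_rate)
        for (ri in which(n_err > 0)) {
          at <- sample.int(rl, n_err[ri])
          cur <- chars(seqs[ri])
          for (p in at) {
            cur[p] <- sample(setdiff(DNA_BASES, cur[p]), 1)
          }
          seqs[ri] <- paste(cur, collapse = "")
        }
      }

      low <- runif(n_reads) < config$mapq_low_fraction
      mapq <- integer(n_reads)
      mapq[low] <- sample(0:29, sum(low), replace = TRUE)
      mapq[!low] <- sample(30:60, sum(!low), replace = TRUE)
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)

      reads <- tibble(
        read_id = sprintf("%s_r%06d", cn, seq_len(n_reads)),
        chrom = cn, start = as.integer(starts), end = as.integer(ends),
        length = rl, strand = strand, mapq = mapq, seq = seqs)

      n_dup <- rbinom(1, n_reads, config$duplicate_rate)
      if (n_dup > 0) {
        di <- sample.int(n_reads, n_dup, replace = TRUE)
        dup <- reads[di, ]
        dup$read_id <- sprintf("%s_dup%05d", dup$read_id, seq_len(n_dup))
        reads <- bind_rows(reads, dup)
      }
      out[[ci]] <- reads
    }
    list_rbind(out) |> arrange(.data$chrom, .data$start, .data$read_id)
  })
}

#' Run the whole synthetic-data generator
#'
#' Chains [simulate_genome()], [simulate_gene_models()],
#' [plant_truth_sites()] and [simulate_reads()] under the config's seed,
#' optionally writing `genome.fa`, `genes.gff3`, `reads.sam` and
#' `truth.tsv` to a directory. Identical configurations produce
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write the four files into.
#' @return a list with `genome`, `models`, `truth`, `reads` and, when
#'   `out_dir` is given, `paths`.
#' @export
simulate_editome <- function(config = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(config)
  gm <- simulate_gene_models(genome, config)
  truth <- plant_truth_sites(gm$genome, gm$models, config)
  reads <- simulate_reads(gm$genome, gm$models, truth, config)
  res <- list(genome = gm$genome, models = gm$models, truth = truth,
              reads = reads)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      models = file.path(out_dir, "genes.gff3"),
      reads = file.path(out_dir, "reads.sam"),
      truth = file.path(out_dir, "truth.tsv"))
    write_genome_fasta(gm$genome, paths$genome)
    write_gene_models(gm$models, paths$models)
    write_sam(reads, gm$genome, paths$reads)
    readr::write_tsv(truth, paths$truth)
    res$paths <- paths
  }
  res
}
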