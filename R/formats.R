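# readers and writers for every on-disk format the pipeline touches.
# Coordinates are 1-based closed everywhere internally; BED output is the
# only 0-based half-open surface.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `A,C,G,T,N`; duplicate record names or illegal characters raise a
#' format error naming the offending record.
#'
#' @param path FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    dup <- names(raw)[duplicated(names(raw))][1]
    abort(sprintf("duplicate FASTA record name: '%s'", dup))
  }
  seqs <- toupper(as.character(raw))
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    abort(sprintf("record '%s' contains characters outside A/C/G/T/N",
                  names(raw)[bad[1]]))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(raw)
  genome
}

#' Write a genome to FASTA (60-column wrap)
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  assert_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' Accepts DNA or RNA input; T is converted to U on load. Records must
#' be 18-26 nt over `A,U,C,G`.
#'
#' @param path FASTA file of mature miRNAs.
#' @return a tibble with columns `mirna_id`, `sequence` (RNA, 5'->3').
#' @export
read_mirna_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicate miRNA record name: '%s'",
                  names(raw)[duplicated(names(raw))][1]))
  }
  seqs <- dna_to_rna(toupper(as.character(raw)))
  bad <- which(grepl("[^AUCG]", seqs))
  if (length(bad)) {
    abort(sprintf("miRNA record '%s' contains characters outside A/U/C/G",
                  names(raw)[bad[1]]))
  }
  short <- which(nchar(seqs) < 18 | nchar(seqs) > 26)
  if (length(short)) {
    abort(sprintf("miRNA record '%s' is outside the 18-26 nt mature range",
                  names(raw)[short[1]]))
  }
  tibble(mirna_id = names(raw), sequence = unname(seqs))
}

# gene models ----------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Expects `gene`/`mRNA`/`exon`/`CDS` features linked by `ID`/`Parent`
#' (UTR features are accepted but re-derived from the exon-CDS
#' difference). When a gene carries several mRNAs the transcript with
#' the longest spliced CDS represents the gene.
#'
#' @param path GFF3 file.
#' @return a gene-model tibble with columns
#'   `gene_id, transcript_id, chrom, strand, type, start, end`
#'   (`type` in `exon`, `CDS`), validated: exons sorted and disjoint,
#'   CDS within the exon union.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_gene_models())
  df <- as_tibble(as.data.frame(gr)) |>
    mutate(seqnames = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           type = as.character(.data$type))
  if (!"Parent" %in% names(df)) df$Parent <- NA_character_
  df$Parent <- map_chr(as.list(df$Parent),
                       function(p) if (length(p)) as.character(p)[1] else NA_character_)

  mrna <- filter(df, .data$type %in% c("mRNA", "transcript"))
  feats <- filter(df, .data$type %in% c("exon", "CDS"))
  if (nrow(mrna) > 0) {
    tx <- tibble(transcript_id = mrna$ID,
                 gene_id = dplyr::coalesce(mrna$Parent, mrna$ID))
    feats <- feats |>
      left_join(tx, by = c(Parent = "transcript_id"), keep = TRUE) |>
      filter(!is.na(.data$transcript_id))
  } else {
    feats <- feats |>
      mutate(transcript_id = .data$Parent,
             gene_id = .data$Parent)
  }
  models <- feats |>
    select(gene_id = "gene_id", transcript_id = "transcript_id",
           chrom = "seqnames", "strand", "type", "start", "end") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$gene_id, .data$start)

  # one transcript per gene: keep the longest spliced CDS
  cds_len <- models |>
    filter(.data$type == "CDS") |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  keep <- cds_len |>
    arrange(.data$gene_id, dplyr::desc(.data$len), .data$transcript_id) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  if (nrow(keep) > 0) {
    models <- dplyr::semi_join(models, keep,
                               by = c("gene_id", "transcript_id"))
  }
  validate_gene_models(models)
  models
}

validate_gene_models <- function(models) {
  for (gid in unique(models$gene_id)) {
    g <- models[models$gene_id == gid, ]
    ex <- g[g$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) == 0) abort(sprintf("gene '%s' has no exons", gid))
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(sprintf("gene '%s' has overlapping or unsorted exons", gid))
    }
    cds <- g[g$type == "CDS", ]
    if (nrow(cds) > 0) {
      exr <- IRanges::IRanges(ex$start, ex$end)
      cdr <- IRanges::IRanges(cds$start, cds$end)
      if (length(IRanges::setdiff(cdr, exr)) > 0) {
        abort(sprintf("gene '%s' has CDS outside its exons", gid))
      }
    }
  }
  invisible(models)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features with `ID`/`Parent` links and CDS phase.
#'
#' @param models gene-model tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (nrow(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  regions <- gene_regions(models)
  rows <- list()
  for (gid in unique(models$gene_id)) {
    g <- models[models$gene_id == gid, ]
    tid <- g$transcript_id[1]
    chrom <- g$chrom[1]; strand <- g$strand[1]
    span <- c(min(g$start), max(g$end))
    ex <- g[g$type == "exon", ]
    cds <- g[g$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    # phase in transcript order
    ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    lens <- cds$end - cds$start + 1L
    before <- cumsum(c(0L, lens[ord]))[seq_len(nrow(cds))]
    phase <- integer(nrow(cds))
    phase[ord] <- (3L - (before %% 3L)) %% 3L
    rg <- regions[regions$gene_id == gid, ]
    utr5 <- rg[rg$region == "utr5", ]
    utr3 <- rg[rg$region == "utr3", ]
    mk <- function(type, start, end, id = NA_character_,
                   parent = NA_character_, ph = NA_integer_) {
      if (length(start) == 0) return(NULL)
      tibble(chrom = chrom, start = start, end = end, strand = strand,
             type = type, ID = id, Parent = parent, phase = ph)
    }
    rows[[gid]] <- bind_rows(
      mk("gene", span[1], span[2], id = gid),
      mk("mRNA", span[1], span[2], id = tid, parent = gid),
      mk("exon", ex$start, ex$end, parent = tid),
      mk("CDS", cds$start, cds$end, parent = tid, ph = phase),
      mk("five_prime_UTR", utr5$start, utr5$end, parent = tid),
      mk("three_prime_UTR", utr3$start, utr3$end, parent = tid)
    )
  }
  df <- list_rbind(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "editome"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# SAM ------------------------------------------------------------------------

#' Write aligned reads as SAM
#'
#' Emits an `@HD`/`@SQ` header (coordinate-sorted) and one gapless
#' alignment line per read (`<len>M` CIGAR, FLAG bit 16 for
#' reverse-strand reads, constant placeholder base qualities).
#'
#' @param reads read tibble
#'   (`read_id, chrom, start, length, strand, mapq, seq`).
#' @param genome the reference the reads were simulated from (for `@SQ`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  assert_genome(genome)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      genome_lengths(genome)))
  reads <- arrange(reads, .data$chrom, .data$start, .data$read_id)
  body <- if (nrow(reads) == 0) character() else sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
    reads$read_id, ifelse(reads$strand == "-", 16L, 0L), reads$chrom,
    reads$start, reads$mapq, reads$length, reads$seq,
    strrep("I", reads$length))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read aligned reads from SAM
#'
#' Unmapped records are skipped with a logged count. Only gapless
#' alignments are accepted: a single match run, optionally flanked by
#' soft clips, which are trimmed; any other CIGAR is an error. When a
#' genome is supplied the `@SQ` lines must match its names and lengths.
#'
#' @param path SAM file with `@HD`/`@SQ` header.
#' @param genome optional [Biostrings::DNAStringSet] to validate against.
#' @return a read tibble
#'   (`read_id, chrom, start, end, length, strand, mapq, seq`).
#' @export
read_sam <- function(path, genome = NULL) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!is.null(genome)) {
    glens <- genome_lengths(genome)
    if (!setequal(names(hdr), names(glens)) ||
        any(hdr[names(glens)] != glens)) {
      abort("SAM @SQ lines do not match the supplied genome")
    }
  }
  b <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0 | is.na(b$pos)
  if (any(unmapped)) {
    warn(sprintf("skipped %d unmapped record(s)", sum(unmapped)))
  }
  keep <- !unmapped
  if (!any(keep)) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer(), length = integer(),
                  strand = character(), mapq = integer(), seq = character()))
  }
  cig <- b$cigar[keep]
  m <- regmatches(cig, regexec("^(?:([0-9]+)S)?([0-9]+)M(?:([0-9]+)S)?$", cig))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad)) {
    abort(sprintf("unsupported CIGAR '%s' (gapless contract: [S]M[S] only)",
                  cig[bad[1]]))
  }
  clip5 <- vapply(m, function(x) {
    if (x[2] == "") 0L else as.integer(x[2])
  }, integer(1))
  mlen <- vapply(m, function(x) as.integer(x[3]), integer(1))
  seqs <- as.character(b$seq[keep])
  seqs <- substr(seqs, clip5 + 1L, clip5 + mlen)
  mapq <- b$mapq[keep]
  mapq[is.na(mapq)] <- 255L
  tibble(
    read_id = b$qname[keep],
    chrom = as.character(b$rname[keep]),
    start = b$pos[keep],
    end = b$pos[keep] + mlen - 1L,
    length = mlen,
    strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0, "-", "+"),
    mapq = as.integer(mapq),
    seq = seqs)
}

# sites ----------------------------------------------------------------------

sites_tsv_cols <- function() {
  readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    strand = readr::col_character(), level = readr::col_double(),
    n_support = readr::col_integer(),
    distinct_support = readr::col_integer(),
    depth = readr::col_integer(), region = readr::col_character(),
    gene_id = readr::col_character(), cds_pos = readr::col_integer(),
    coding_effect = readr::col_character())
}

#' Write / read called editing sites as TSV
#'
#' Columns: `chrom pos ref alt strand level n_support distinct_support
#' depth region gene_id cds_pos coding_effect`; annotation columns are
#' NA before [annotate_sites()]. The round trip is lossless.
#'
#' @param sites an editing-site tibble.
#' @param path file path.
#' @return `path` (write) or the site tibble (read).
#' @export
write_sites_tsv <- function(sites, path) {
  cols <- names(sites_tsv_cols()$cols)
  for (cc in setdiff(cols, names(sites))) sites[[cc]] <- NA
  readr::write_tsv(sites[cols], path)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  readr::read_tsv(path, col_types = sites_tsv_cols(), progress = FALSE)
}

#' Write called editing sites as VCF 4.3
#'
#' Genomic REF/ALT with INFO keys `STRAND`, `EL` (editing level), `NS`
#' (supporting reads), `DS` (distinct support intervals), `DP` (depth)
#' and `RG` (region, when annotated).
#'
#' @param sites an editing-site tibble.
#' @param genome the reference genome (for `##contig` lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, genome, path) {
  assert_genome(genome)
  header <- c(
    "##fileformat=VCFv4.3",
    "##source=editome",
    sprintf("##contig=<ID=%s,length=%d>", names(genome),
            genome_lengths(genome)),
    '##INFO=<ID=STRAND,Number=1,Type=String,Description="Edited transcript strand">',
    '##INFO=<ID=EL,Number=1,Type=Float,Description="Editing level">',
    '##INFO=<ID=NS,Number=1,Type=Integer,Description="Reads supporting the edit">',
    '##INFO=<ID=DS,Number=1,Type=Integer,Description="Distinct supporting alignment intervals">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Passing-read depth">',
    '##INFO=<ID=RG,Number=1,Type=String,Description="Genic region">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(sites) == 0) character() else {
    rg <- if ("region" %in% names(sites) && !all(is.na(sites$region))) {
      sprintf(";RG=%s", sites$region)
    } else ""
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSTRAND=%s;EL=%.6g;NS=%d;DS=%d;DP=%d%s",
            sites$chrom, sites$pos, sites$ref, sites$alt, sites$strand,
            sites$level, sites$n_support, sites$distinct_support,
            sites$depth, rg)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genomic-variant mask
#'
#' Accepts a VCF (positions with known genomic variation to exclude from
#' calling) or a two-column TSV with `chrom` and `pos` headers.
#'
#' @param path VCF (`.vcf`) or TSV site list.
#' @return a tibble with columns `chrom`, `pos`.
#' @export
read_site_mask <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    tibble(chrom = fix$CHROM, pos = as.integer(fix$POS)) |> distinct()
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer()),
      progress = FALSE) |> distinct()
  }
}

#' Write a density track as BED
#'
#' BED5 (`chrom start end name score`), 0-based half-open, one row per
#' window with the window's site count as score.
#'
#' @param track a density tibble from [density_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_density_bed <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d",
                   track$chrom, track$start, track$end,
                   sprintf("%s_w%05d", track$chrom, track$window), track$n_sites)
  writeLines(lines, path)
  invisible(path)
}
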