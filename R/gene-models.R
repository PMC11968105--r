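# derived views of a gene-model tibble

#' Gene spans
#'
#' One row per gene with its full genomic span (min exon start to max
#' exon end).
#'
#' @param models gene-model tibble.
#' @return tibble `gene_id, transcript_id, chrom, strand, start, end,
#'   span_len`.
#' @export
gene_spans <- function(models) {
  if (nrow(models) == 0) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(), span_len = integer()))
  }
  models |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(span_len = .data$end - .data$start + 1L)
}

#' Derived genic regions
#'
#' Partitions each gene span into `utr5`, `cds`, `intron` and `utr3`
#' intervals: the exon-minus-CDS difference split by transcript side
#' gives the UTRs, the span-minus-exon difference the introns.
#'
#' @param models gene-model tibble.
#' @return tibble `gene_id, chrom, strand, region, start, end` with
#'   `region` in `utr5, cds, intron, utr3`.
#' @export
gene_regions <- function(models) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), region = character(),
                  start = integer(), end = integer())
  if (nrow(models) == 0) return(empty)
  out <- list()
  for (gid in unique(models$gene_id)) {
    g <- models[models$gene_id == gid, ]
    chrom <- g$chrom[1]; strand <- g$strand[1]
    ex <- IRanges::reduce(IRanges::IRanges(
      g$start[g$type == "exon"], g$end[g$type == "exon"]))
    cds <- IRanges::reduce(IRanges::IRanges(
      g$start[g$type == "CDS"], g$end[g$type == "CDS"]))
    utr <- IRanges::setdiff(ex, cds)
    intron <- IRanges::setdiff(range(ex), ex)
    iv <- function(r, region) {
      if (length(r) == 0) return(NULL)
      tibble(gene_id = gid, chrom = chrom, strand = strand,
             region = region,
             start = IRanges::start(r), end = IRanges::end(r))
    }
    if (length(cds) > 0 && length(utr) > 0) {
      left <- utr[IRanges::end(utr) < min(IRanges::start(cds))]
      right <- utr[IRanges::start(utr) > max(IRanges::end(cds))]
      u5 <- if (strand == "+") left else right
      u3 <- if (strand == "+") right else left
    } else {
      u5 <- utr[0]; u3 <- utr
    }
    out[[gid]] <- bind_rows(iv(u5, "utr5"), iv(cds, "cds"),
                            iv(intron, "intron"), iv(u3, "utr3"))
  }
  res <- list_rbind(out)
  if (nrow(res) == 0) empty else arrange(res, .data$chrom, .data$start)
}

# transcript-order genomic positions of a feature type for one gene
transcript_positions <- function(g, type = "exon") {
  f <- g[g$type == type, ]
  f <- f[order(f$start), ]
  gpos <- unlist(Map(seq.int, f$start, f$end), use.names = FALSE)
  if (g$strand[1] == "+") gpos else rev(gpos)
}

#' Spliced sequences of one gene
#'
#' `cds_sequence()` returns the spliced CDS and `transcript_sequence()`
#' the spliced exon sequence, both 5'->3' in transcript orientation
#' (reverse-complemented for minus-strand genes).
#'
#' @param models gene-model tibble (rows of one or more genes).
#' @param genome a [Biostrings::DNAStringSet].
#' @param gene_id which gene.
#' @return a character DNA string.
#' @export
cds_sequence <- function(models, genome, gene_id) {
  spliced_sequence(models, genome, gene_id, "CDS")
}

#' @rdname cds_sequence
#' @export
transcript_sequence <- function(models, genome, gene_id) {
  spliced_sequence(models, genome, gene_id, "exon")
}

spliced_sequence <- function(models, genome, gene_id, type) {
  g <- models[models$gene_id == gene_id, ]
  if (nrow(g) == 0) abort(sprintf("unknown gene_id '%s'", gene_id))
  f <- g[g$type == type, ]
  f <- f[order(f$start), ]
  s <- paste(substring(genome_strings(genome)[[g$chrom[1]]],
                       f$start, f$end), collapse = "")
  if (g$strand[1] == "-") revcomp_chr(s) else s
}

# 1-based position of a genomic coordinate within the spliced feature,
# transcript orientation; NA when outside
spliced_position <- function(g, pos, type = "exon") {
  match(pos, transcript_positions(g, type))
}
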