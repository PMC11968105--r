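#' Locate the genic region of editing sites
#'
#' A site is genic iff it lies inside the span of a gene on the same
#' strand as the site's inferred edited strand; a site inside only
#' antisense gene spans is classified intergenic (no sense transcript is
#' edited) and tallied separately. Within a gene the precedence is
#' CDS > UTR > intron; ties across overlapping same-strand genes go to
#' the smallest gene span, then lexicographic `gene_id`.
#'
#' @param sites editing-site tibble (needs `chrom, pos, strand`).
#' @param models gene-model tibble.
#' @return `sites` with columns `region` (here `cds` pending the coding
#'   effect, or `five_prime_utr`, `intron`, `three_prime_utr`,
#'   `intergenic`), `gene_id`, `transcript_id`; attribute
#'   `antisense_genic` counts sites inside opposite-strand gene spans.
#' @export
locate_region <- function(sites, models) {
  if (nrow(sites) == 0) {
    return(mutate(sites, region = character(), gene_id = character(),
                  transcript_id = character()))
  }
  regions <- gene_regions(models)
  spans <- gene_spans(models)
  # drop any stale annotation columns (e.g. a re-annotated sites TSV)
  sites <- select(sites, -dplyr::any_of(c(
    "region", "gene_id", "transcript_id", "cds_pos", "ref_codon",
    "alt_codon", "aa_ref", "aa_alt", "coding_effect")))
  sites <- mutate(sites, .site = row_number())

  hit <- if (nrow(regions) == 0) {
    tibble(.site = integer(), region = character(),
           gene_id = character())
  } else {
    sites |>
      select(".site", "chrom", "pos", "strand") |>
      left_join(regions,
                by = join_by("chrom", "strand", between("pos", "start", "end")),
                relationship = "many-to-many") |>
      filter(!is.na(.data$region)) |>
      left_join(select(spans, "gene_id", "span_len", "transcript_id"),
                by = "gene_id") |>
      mutate(rnk = c(cds = 1L, utr5 = 2L, utr3 = 2L, intron = 3L)[.data$region]) |>
      arrange(.data$.site, .data$rnk, .data$span_len, .data$gene_id) |>
      distinct(.data$.site, .keep_all = TRUE) |>
      select(".site", "region", "gene_id", "transcript_id")
  }
  out <- sites |>
    left_join(hit, by = ".site") |>
    mutate(region = case_when(
      is.na(.data$region) ~ "intergenic",
      .data$region == "utr5" ~ "five_prime_utr",
      .data$region == "utr3" ~ "three_prime_utr",
      TRUE ~ .data$region))

  # antisense-genic bookkeeping
  n_anti <- 0L
  if (nrow(spans) > 0) {
    anti <- out |>
      filter(.data$region == "intergenic") |>
      dplyr::inner_join(spans, by = join_by("chrom", between("pos", "start", "end")),
                        suffix = c("", ".gene"),
                        relationship = "many-to-many") |>
      filter(.data$strand != .data$strand.gene) |>
      distinct(.data$.site)
    n_anti <- nrow(anti)
  }
  out <- select(out, -".site")
  attr(out, "antisense_genic") <- n_anti
  out
}

#' Position within the spliced CDS
#'
#' 1-based offset of a genomic position within the spliced CDS of a
#' gene, in transcript orientation (minus-strand genes count from the
#' 3'-most genomic CDS base).
#'
#' @param models gene-model tibble.
#' @param gene_id the gene.
#' @param pos genomic position (vectorised).
#' @return integer positions; error if any position is outside the CDS.
#' @export
cds_position <- function(models, gene_id, pos) {
  g <- models[models$gene_id == gene_id, ]
  if (nrow(g) == 0) abort(sprintf("unknown gene_id '%s'", gene_id))
  res <- spliced_position(g, pos, "CDS")
  if (anyNA(res)) {
    abort(sprintf("position %s is outside the CDS of '%s'",
                  pos[which(is.na(res))[1]], gene_id))
  }
  res
}

#' Codon position of a CDS offset
#'
#' @param cds_pos 1-based position within the spliced CDS (vectorised).
#' @return 1, 2 or 3: the position within its codon.
#' @examples
#' codon_position(c(1, 528, 759)) # 1 3 3
#' @export
codon_position <- function(cds_pos) {
  if (any(cds_pos < 1)) abort("`cds_pos` must be at least 1")
  ((as.integer(cds_pos) - 1L) %% 3L) + 1L
}

#' Coding effect of an A-to-I edit in a CDS
#'
#' Builds the spliced, strand-oriented CDS, substitutes the
#' transcript-strand A with G at the given CDS position, translates the
#' affected codon with the standard genetic code, and reports
#' `synonymous` iff the amino acid is unchanged (stop is treated as an
#' ordinary amino-acid symbol).
#'
#' @param models gene-model tibble.
#' @param genome a [Biostrings::DNAStringSet].
#' @param gene_id the gene.
#' @param cds_pos 1-based position within the spliced CDS; the
#'   reference base there must be A in transcript orientation.
#' @return a one-row tibble
#'   `cds_pos, codon_pos, ref_codon, alt_codon, aa_ref, aa_alt, effect`.
#' @export
coding_effect <- function(models, genome, gene_id, cds_pos) {
  cds <- cds_sequence(models, genome, gene_id)
  if (cds_pos < 1 || cds_pos > nchar(cds)) {
    abort(sprintf("cds_pos %d outside the %d nt CDS of '%s'",
                  cds_pos, nchar(cds), gene_id))
  }
  if (substr(cds, cds_pos, cds_pos) != "A") {
    abort(sprintf(
      "CDS base at position %d of '%s' is %s, not A: strand or annotation disagreement",
      cds_pos, gene_id, substr(cds, cds_pos, cds_pos)))
  }
  cp <- codon_position(cds_pos)
  c0 <- cds_pos - cp + 1L
  ref_codon <- substr(cds, c0, c0 + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cp, cp) <- "G"
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  tibble(cds_pos = as.integer(cds_pos), codon_pos = cp,
         ref_codon = ref_codon, alt_codon = alt_codon,
         aa_ref = aa_ref, aa_alt = aa_alt,
         effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous")
}

#' Annotate called sites with region and coding effect
#'
#' Runs [locate_region()] and, for CDS sites, [cds_position()] and
#' [coding_effect()], expanding the `cds` label into `cds_synonymous`
#' or `cds_nonsynonymous`.
#'
#' @param sites editing-site tibble from [call_sites()].
#' @param models gene-model tibble.
#' @param genome a [Biostrings::DNAStringSet].
#' @return `sites` with columns `region, gene_id, transcript_id,
#'   cds_pos, ref_codon, alt_codon, aa_ref, aa_alt, coding_effect`.
#' @export
annotate_sites <- function(sites, models, genome) {
  out <- locate_region(sites, models) |>
    mutate(cds_pos = NA_integer_, ref_codon = NA_character_,
           alt_codon = NA_character_, aa_ref = NA_character_,
           aa_alt = NA_character_, coding_effect = NA_character_)
  idx <- which(out$region == "cds")
  for (i in idx) {
    cp <- cds_position(models, out$gene_id[i], out$pos[i])
    eff <- coding_effect(models, genome, out$gene_id[i], cp)
    out$cds_pos[i] <- cp
    out$ref_codon[i] <- eff$ref_codon
    out$alt_codon[i] <- eff$alt_codon
    out$aa_ref[i] <- eff$aa_ref
    out$aa_alt[i] <- eff$aa_alt
    out$coding_effect[i] <- eff$effect
    out$region[i] <- paste0("cds_", eff$effect)
  }
  out
}
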