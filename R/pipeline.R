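#' Run pipeline stages against an output directory
#'
#' File-based front end over the package: each stage reads its inputs
#' from `out_dir`, writes its outputs there, and records the
#' configuration, seed and package version in `run_metadata.json`.
#' Stages:
#'
#' * `simulate` — writes `genome.fa`, `genes.gff3`, `reads.sam`,
#'   `truth.tsv` from a [sim_config()].
#' * `call` — pileup + caller on `reads.sam`; writes `sites.tsv`,
#'   `rejections.tsv` and optionally `sites.vcf`.
#' * `annotate` — rewrites `sites.tsv` with region/coding-effect
#'   columns.
#' * `summarize` — writes `summary_chrom.tsv`, `summary_region.tsv`,
#'   `summary_totals.tsv` and `density.bed`.
#' * `mir_impact` — edit-aware seed scan of every exonic genic site
#'   against a miRNA FASTA; writes `impact.tsv`.
#' * `all` — chains the five stages.
#'
#' Outputs are pure functions of inputs plus configuration (including
#' the seed); a failed stage removes its partial outputs.
#'
#' @param stage one of `simulate`, `call`, `annotate`, `summarize`,
#'   `mir_impact`, `all`.
#' @param out_dir working directory for stage files.
#' @param sim a [sim_config()] (stage `simulate`).
#' @param caller a [caller_config()] (stage `call`).
#' @param mask optional path to a genomic-variant mask (VCF or TSV).
#' @param write_vcf also write `sites.vcf` (stage `call`).
#' @param window_bp density-track window (stage `summarize`).
#' @param mirna_fasta path to a mature-miRNA FASTA (stage `mir_impact`).
#' @param wobble permit G:U seed pairs (stage `mir_impact`).
#' @return invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(stage = c("simulate", "call", "annotate",
                                   "summarize", "mir_impact", "all"),
                         out_dir,
                         sim = sim_config(),
                         caller = caller_config(),
                         mask = NULL,
                         write_vcf = FALSE,
                         window_bp = 100000L,
                         mirna_fasta = NULL,
                         wobble = FALSE) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "call", "annotate", "summarize",
      if (!is.null(mirna_fasta)) "mir_impact")
  } else stage
  written <- list()
  for (s in stages) {
    new_files <- stage_outputs(s, out_dir, write_vcf)
    res <- tryCatch(
      switch(s,
        simulate = stage_simulate(out_dir, sim),
        call = stage_call(out_dir, caller, mask, write_vcf),
        annotate = stage_annotate(out_dir),
        summarize = stage_summarize(out_dir, window_bp),
        mir_impact = stage_mir_impact(out_dir, mirna_fasta, wobble)),
      error = function(e) {
        unlink(unlist(new_files))
        abort(sprintf("stage '%s' failed: %s", s, conditionMessage(e)))
      })
    written <- c(written, res)
  }
  meta <- list(
    stage = stage,
    seed = sim$seed,
    sim_config = unclass(sim),
    caller_config = unclass(
      caller[setdiff(names(caller), "genomic_mask")]),
    window_bp = window_bp,
    wobble = wobble,
    package_version = as.character(utils::packageVersion("editome")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(written)
}

stage_outputs <- function(s, out_dir, write_vcf) {
  f <- switch(s,
    simulate = c("genome.fa", "genes.gff3", "reads.sam", "truth.tsv"),
    call = c("sites.tsv", "rejections.tsv", if (write_vcf) "sites.vcf"),
    annotate = character(),  # rewrites sites.tsv in place
    summarize = c("summary_chrom.tsv", "summary_region.tsv",
                  "summary_totals.tsv", "density.bed"),
    mir_impact = "impact.tsv")
  file.path(out_dir, f)
}

require_input <- function(out_dir, file) {
  p <- file.path(out_dir, file)
  if (!file.exists(p)) {
    abort(sprintf("missing input '%s' in %s", file, out_dir))
  }
  p
}

stage_simulate <- function(out_dir, sim) {
  res <- simulate_editome(sim, out_dir = out_dir)
  res$paths
}

stage_call <- function(out_dir, caller, mask, write_vcf) {
  genome <- read_genome_fasta(require_input(out_dir, "genome.fa"))
  reads <- read_sam(require_input(out_dir, "reads.sam"), genome = genome)
  if (!is.null(mask)) caller$genomic_mask <- read_site_mask(mask)
  pile <- build_pileup(reads, genome, mapq_min = caller$mapq_min)
  sites <- call_sites(pile, caller)
  paths <- list(sites = file.path(out_dir, "sites.tsv"),
                rejections = file.path(out_dir, "rejections.tsv"))
  write_sites_tsv(sites, paths$sites)
  readr::write_tsv(call_rejections(sites), paths$rejections)
  if (write_vcf) {
    paths$vcf <- file.path(out_dir, "sites.vcf")
    write_sites_vcf(sites, genome, paths$vcf)
  }
  paths
}

stage_annotate <- function(out_dir) {
  genome <- read_genome_fasta(require_input(out_dir, "genome.fa"))
  models <- read_gene_models(require_input(out_dir, "genes.gff3"))
  sites <- read_sites_tsv(require_input(out_dir, "sites.tsv"))
  ann <- annotate_sites(sites, models, genome)
  path <- file.path(out_dir, "sites.tsv")
  write_sites_tsv(ann, path)
  list(sites = path)
}

stage_summarize <- function(out_dir, window_bp) {
  genome <- read_genome_fasta(require_input(out_dir, "genome.fa"))
  sites <- read_sites_tsv(require_input(out_dir, "sites.tsv"))
  summ <- summarize_editome(sites, genome)
  track <- density_track(sites, genome, window_bp = window_bp)
  paths <- list(chrom = file.path(out_dir, "summary_chrom.tsv"),
                region = file.path(out_dir, "summary_region.tsv"),
                totals = file.path(out_dir, "summary_totals.tsv"),
                bed = file.path(out_dir, "density.bed"))
  readr::write_tsv(summ$per_chrom, paths$chrom)
  readr::write_tsv(summ$region, paths$region)
  readr::write_tsv(summ$totals, paths$totals)
  write_density_bed(track, paths$bed)
  paths
}

stage_mir_impact <- function(out_dir, mirna_fasta, wobble) {
  if (is.null(mirna_fasta)) {
    abort("stage 'mir_impact' needs `mirna_fasta`")
  }
  genome <- read_genome_fasta(require_input(out_dir, "genome.fa"))
  models <- read_gene_models(require_input(out_dir, "genes.gff3"))
  sites <- read_sites_tsv(require_input(out_dir, "sites.tsv"))
  mirnas <- read_mirna_fasta(mirna_fasta)
  impacts <- mirna_impact_table(sites, models, genome, mirnas,
                                wobble = wobble)
  path <- file.path(out_dir, "impact.tsv")
  readr::write_tsv(impacts, path)
  list(impact = path)
}

#' Seed-impact table for annotated exonic sites
#'
#' For every annotated site falling in an exonic genic region (UTRs and
#' CDS), computes the transcript-coordinate position of the edit and
#' runs [edit_impact()] against each miRNA on the spliced transcript
#' (as RNA).
#'
#' @param sites annotated editing-site tibble.
#' @param models gene-model tibble.
#' @param genome a [Biostrings::DNAStringSet].
#' @param mirnas tibble from [read_mirna_fasta()].
#' @param wobble permit G:U seed pairs.
#' @return a tibble `mirna_id, transcript_id, site_pos, unedited_class,
#'   edited_class, verdict` (site_pos in transcript coordinates).
#' @export
mirna_impact_table <- function(sites, models, genome, mirnas,
                               wobble = FALSE) {
  exonic <- sites[!is.na(sites$region) &
                    sites$region %in% c("five_prime_utr", "three_prime_utr",
                                        "cds_synonymous",
                                        "cds_nonsynonymous"), ]
  out <- list()
  tx_cache <- list()
  for (i in seq_len(nrow(exonic))) {
    gid <- exonic$gene_id[i]
    if (is.null(tx_cache[[gid]])) {
      tx_cache[[gid]] <- dna_to_rna(transcript_sequence(models, genome, gid))
    }
    g <- models[models$gene_id == gid, ]
    tpos <- spliced_position(g, exonic$pos[i], "exon")
    if (is.na(tpos)) next
    tid <- g$transcript_id[1]
    if (is.null(tid) || is.na(tid)) tid <- gid
    for (k in seq_len(nrow(mirnas))) {
      out[[length(out) + 1L]] <- edit_impact(
        mirnas[k, ], tx_cache[[gid]], tpos, wobble = wobble,
        target_id = tid) |>
        rename(transcript_id = "target_id")
    }
  }
  if (length(out) == 0) {
    tibble(mirna_id = character(), transcript_id = character(),
           site_pos = integer(), unedited_class = character(),
           edited_class = character(), verdict = character())
  } else {
    list_rbind(out) |>
      select("mirna_id", "transcript_id", "site_pos",
             "unedited_class", "edited_class", "verdict")
  }
}
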