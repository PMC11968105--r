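#' Summarise an editome
#'
#' Per-chromosome counts, unweighted mean editing levels and densities
#' (sites per Mb); the genic-region distribution with percentages of the
#' total (half-up rounding at one decimal); and totals including the
#' number of distinct genes carrying sites.
#'
#' @param sites annotated editing-site tibble (see [annotate_sites()]).
#' @param genome a [Biostrings::DNAStringSet] (defines the chromosome
#'   set and lengths).
#' @param models optional gene-model tibble (unused in the tables but
#'   kept for interface symmetry).
#' @return an `editome_summary` list with tibbles `per_chrom`
#'   (`chrom, n_sites, mean_level, density_sites_per_mb`), `region`
#'   (`region, n_sites, pct_of_total`) and `totals`.
#' @export
summarize_editome <- function(sites, genome, models = NULL) {
  assert_genome(genome)
  glens <- genome_lengths(genome)
  per_chrom <- tibble(chrom = names(glens), length_bp = unname(glens)) |>
    left_join(
      sites |> group_by(.data$chrom) |>
        summarise(n_sites = n(), mean_level = mean(.data$level),
                  .groups = "drop"),
      by = "chrom") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L),
           mean_level = dplyr::coalesce(.data$mean_level, 0),
           density_sites_per_mb = .data$n_sites / (.data$length_bp / 1e6)) |>
    select("chrom", "n_sites", "mean_level", "density_sites_per_mb")

  has_region <- "region" %in% names(sites) && nrow(sites) > 0
  region_counts <- stats::setNames(rep(0L, length(REGION_LEVELS)),
                                   REGION_LEVELS)
  if (has_region) {
    tab <- table(factor(sites$region, levels = REGION_LEVELS))
    region_counts[names(tab)] <- as.integer(tab)
  }
  region <- region_percentages(region_counts)

  n_total <- nrow(sites)
  n_intergenic <- as.integer(region_counts[["intergenic"]])
  totals <- tibble(
    n_total = n_total,
    n_genic = n_total - n_intergenic,
    n_intergenic = n_intergenic,
    n_genes_with_sites = if (has_region && "gene_id" %in% names(sites)) {
      dplyr::n_distinct(sites$gene_id[!is.na(sites$gene_id)])
    } else 0L)

  structure(list(per_chrom = per_chrom, region = region, totals = totals,
                 genome_mb = sum(as.numeric(glens)) / 1e6),
            class = "editome_summary")
}

#' Region percentages from counts
#'
#' Shares of a site total per genic region, half-up rounded at one
#' decimal (the convention used for reported editome percentages). The
#' total defaults to the sum of the counts but can be given explicitly,
#' e.g. when recomputing published percentages against a published
#' total.
#'
#' @param counts named integer vector (or tibble with `region`,
#'   `n_sites`) of per-region site counts.
#' @param total denominator for the percentages.
#' @return a tibble `region, n_sites, pct_of_total`.
#' @export
region_percentages <- function(counts, total = NULL) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n_sites, counts$region)
  }
  total <- total %||% sum(counts)
  tibble(
    region = names(counts),
    n_sites = as.integer(counts),
    pct_of_total = if (total > 0) {
      round_half_up(100 * as.numeric(counts) / total, 1)
    } else rep(0, length(counts)))
}

#' Site-density track over genome windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_bp`
#' (the last window truncated at the chromosome end) and scores each
#' window with its site count. Coordinates are 0-based half-open,
#' ready for BED export via [write_density_bed()].
#'
#' @param sites editing-site tibble.
#' @param genome a [Biostrings::DNAStringSet].
#' @param window_bp window size in bp (default 100 kb).
#' @return a tibble `chrom, window, start, end, n_sites`.
#' @export
density_track <- function(sites, genome, window_bp = 100000L) {
  assert_genome(genome)
  if (window_bp < 1) abort("`window_bp` must be at least 1")
  glens <- genome_lengths(genome)
  windows <- list_rbind(map(names(glens), function(cn) {
    starts <- seq.int(0L, glens[[cn]] - 1L, by = window_bp)
    tibble(chrom = cn, window = seq_along(starts),
           start = as.integer(starts),
           end = as.integer(pmin(starts + window_bp, glens[[cn]])))
  }))
  counted <- if (nrow(sites) == 0) {
    mutate(windows, n_sites = 0L)
  } else {
    windows |>
      left_join(
        sites |> mutate(pos0 = .data$pos - 1L) |>
          select("chrom", "pos0"),
        by = join_by("chrom", "start" <= "pos0", "end" > "pos0"),
        relationship = "many-to-many") |>
      group_by(.data$chrom, .data$window, .data$start, .data$end) |>
      summarise(n_sites = sum(!is.na(.data$pos0)), .groups = "drop")
  }
  arrange(counted, .data$chrom, .data$start)
}

#' @export
print.editome_summary <- function(x, ...) {
  cat("Editome summary\n")
  cat(sprintf("  sites: %d total, %d genic in %d genes, %d intergenic\n",
              x$totals$n_total, x$totals$n_genic,
              x$totals$n_genes_with_sites, x$totals$n_intergenic))
  cat("  per chromosome:\n")
  print(x$per_chrom, n = Inf)
  cat("  by region:\n")
  print(x$region, n = Inf)
  invisible(x)
}

#' Tidy an editome summary
#'
#' `tidy()` returns the per-region table, `glance()` a one-row tibble
#' of totals with the genome-wide mean editing level and density.
#'
#' @param x an `editome_summary`.
#' @param ... ignored.
#' @return a tibble.
#' @method tidy editome_summary
#' @export
tidy.editome_summary <- function(x, ...) {
  x$region
}

#' @rdname tidy.editome_summary
#' @method glance editome_summary
#' @export
glance.editome_summary <- function(x, ...) {
  pc <- x$per_chrom
  total_sites <- sum(pc$n_sites)
  x$totals |>
    mutate(
      mean_level = if (total_sites > 0) {
        sum(pc$mean_level * pc$n_sites) / total_sites
      } else 0,
      density_sites_per_mb = total_sites / x$genome_mb)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
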