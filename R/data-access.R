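#' Published Metopolophium dirhodum editome counts
#'
#' Loads the published per-chromosome and per-region A-to-I
#' editing-site counts of the rose-grain aphid editome, shipped as
#' plain TSV under `inst/extdata`. These are the worked-example inputs
#' for [region_percentages()]: the chromosome counts sum to the
#' reported 11,678-site total, against which the region percentages
#' reproduce at one-decimal half-up rounding. (The published region
#' counts themselves sum to 11,679 — one more than the reported total,
#' consistent with a single ambiguous assignment — which is why the
#' percentage denominator is taken from the chromosome table.)
#'
#' @param which `"chrom"` or `"region"`.
#' @return a tibble of counts.
#' @examples
#' chrom <- mdirhodum_editome_counts("chrom")
#' sum(chrom$n_sites) # 11678
#' @export
mdirhodum_editome_counts <- function(which = c("chrom", "region")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("mdirhodum_%s_counts.tsv", which),
                      package = "editome", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    n_sites = readr::col_integer()), progress = FALSE)
}
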