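# shared small helpers

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

REGION_LEVELS <- c(
  "intergenic", "five_prime_utr", "intron",
  "cds_synonymous", "cds_nonsynonymous", "three_prime_utr"
)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for
#' reported editome percentages; base [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(c(2.25, 2.35), 1) # 2.3 2.4
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# reverse complement of a plain DNA character string
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

# genome accessors -----------------------------------------------------------

genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

genome_strings <- function(genome) {
  stats::setNames(as.character(genome), names(genome))
}

assert_genome <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    abort("`genome` must be a DNAStringSet (see read_genome_fasta()).")
  }
  if (anyDuplicated(names(genome))) {
    abort("genome chromosome names must be unique")
  }
  invisible(genome)
}

# base at 1-based positions, vectorised over a single chromosome string
base_at <- function(chrom_string, pos) {
  substring(chrom_string, pos, pos)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name))
  }
  invisible(x)
}
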