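#' Caller configuration
#'
#' Thresholds for calling A-to-I editing sites from a mismatch pileup.
#' The defaults encode the candidate definition used throughout the
#' package: support from at least three reads mapped to overlapping but
#' not identical positions, editing level strictly above 5%, reads below
#' MAPQ 30 discarded, and candidate positions showing more than one
#' editing type dropped.
#'
#' @param min_support minimum number of distinct supporting alignment
#'   intervals (default 3, compared with `>=`).
#' @param min_level editing-level threshold (default 0.05, strict `>`).
#' @param mapq_min minimum read MAPQ (default 30); must match the value
#'   used in [build_pileup()].
#' @param discard_multi_type drop positions where more than one
#'   alternative base qualifies as an editing type (default `TRUE`).
#' @param multi_type_min distinct-interval support an alternative base
#'   needs to count as an "editing type" for the multi-type filter.
#'   Defaults to `min_support`, so isolated sequencing-error reads do
#'   not veto a well-supported candidate; set to 1 for the strict
#'   any-observation reading.
#' @param genomic_mask optional tibble of `chrom, pos` to exclude
#'   (known genomic variants); see [read_site_mask()].
#' @return a list of class `caller_config`.
#' @export
caller_config <- function(min_support = 3L, min_level = 0.05,
                          mapq_min = 30L, discard_multi_type = TRUE,
                          multi_type_min = min_support,
                          genomic_mask = NULL) {
  if (min_support < 1) abort("`min_support` must be at least 1")
  if (min_level < 0 || min_level >= 1) abort("`min_level` must be in [0, 1)")
  structure(
    list(min_support = as.integer(min_support), min_level = min_level,
         mapq_min = as.integer(mapq_min),
         discard_multi_type = isTRUE(discard_multi_type),
         multi_type_min = as.integer(multi_type_min),
         genomic_mask = genomic_mask),
    class = "caller_config")
}

#' Editing level
#'
#' The fraction of reads supporting the edit out of all reads covering
#' the site.
#'
#' @param n_support reads carrying the edited base.
#' @param depth total reads covering the site.
#' @return `n_support / depth`.
#' @examples
#' editing_level(3, 10) # 0.3
#' @export
editing_level <- function(n_support, depth) {
  if (any(depth < 1)) abort("editing level is undefined at depth 0")
  if (any(n_support < 0) || any(n_support > depth)) {
    abort("`n_support` must lie in [0, depth]")
  }
  n_support / depth
}

#' Classify a genomic mismatch as A-to-I or not
#'
#' Inosine is read as guanosine, so A-to-I editing appears as an A->G
#' mismatch on the edited strand: genomic (A,G) implies a plus-strand
#' edit and genomic (T,C) a minus-strand edit. Every other ordered base
#' pair is a non-A-to-I mismatch (tracked only for the multi-type
#' filter).
#'
#' @param ref,alt genomic reference and alternative base (vectorised).
#' @return a tibble `ref, alt, a_to_i, strand` (`strand` NA when not
#'   A-to-I).
#' @examples
#' classify_mismatch("A", "G") # A-to-I on "+"
#' classify_mismatch("C", "T") # not A-to-I
#' @export
classify_mismatch <- function(ref, alt) {
  if (any(ref == alt)) abort("`ref` and `alt` must differ")
  tibble(
    ref = ref, alt = alt,
    a_to_i = (ref == "A" & alt == "G") | (ref == "T" & alt == "C"),
    strand = case_when(
      ref == "A" & alt == "G" ~ "+",
      ref == "T" & alt == "C" ~ "-",
      TRUE ~ NA_character_))
}

#' Call A-to-I editing sites from a pileup
#'
#' A position becomes a site iff, among passing reads, exactly one
#' alternative base qualifies as an editing type (otherwise the
#' position is discarded as multi-type when `discard_multi_type`); the
#' (ref, alt) pair is an A-to-I pair; the alt is carried by at least
#' `min_support` distinct alignment intervals; the editing level is
#' strictly above `min_level`; and the position is not in the genomic
#' mask. Rejected candidates are tallied by reason in the
#' `"rejections"` attribute.
#'
#' @param pileup a pileup tibble from [build_pileup()] built with the
#'   same `mapq_min`.
#' @param config a [caller_config()].
#' @return an editing-site tibble
#'   (`chrom, pos, ref, alt, strand, level, n_support,
#'   distinct_support, depth`), sorted by position, with attribute
#'   `rejections` (tibble `reason, n`).
#' @export
call_sites <- function(pileup, config = caller_config()) {
  empty <- empty_sites()
  if (nrow(pileup) == 0) {
    attr(empty, "rejections") <- tibble(reason = character(), n = integer())
    return(empty)
  }
  alts <- pileup |>
    filter(.data$base != .data$ref) |>
    mutate(is_type = .data$distinct >= config$multi_type_min)

  cand <- alts |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$depth) |>
    summarise(
      n_types = sum(.data$is_type),
      # the candidate alt: the qualifying type if unique, else the
      # best-supported alternative (for rejection bookkeeping)
      alt = .data$base[order(-.data$is_type, -.data$distinct,
                             -.data$count, .data$base)][1],
      n_support = .data$count[.data$base == alt][1],
      distinct_support = .data$distinct[.data$base == alt][1],
      .groups = "drop")

  masked <- rep(FALSE, nrow(cand))
  if (!is.null(config$genomic_mask) && nrow(config$genomic_mask) > 0) {
    key <- paste(cand$chrom, cand$pos)
    masked <- key %in% paste(config$genomic_mask$chrom,
                             config$genomic_mask$pos)
  }
  cls <- classify_mismatch(cand$ref, cand$alt)
  level <- cand$n_support / cand$depth

  reason <- case_when(
    masked ~ "masked",
    config$discard_multi_type & cand$n_types > 1 ~ "multi_type",
    !cls$a_to_i ~ "not_a_to_i",
    cand$distinct_support < config$min_support ~ "low_support",
    level <= config$min_level ~ "low_level",
    TRUE ~ "pass")

  sites <- cand[reason == "pass", ] |>
    mutate(strand = cls$strand[reason == "pass"],
           level = level[reason == "pass"]) |>
    select("chrom", "pos", "ref", "alt", "strand", "level",
           "n_support", "distinct_support", "depth") |>
    arrange(.data$chrom, .data$pos)

  rej <- tibble(reason = reason[reason != "pass"]) |>
    count(.data$reason, name = "n") |>
    arrange(.data$reason)
  attr(sites, "rejections") <- rej
  sites
}

empty_sites <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), strand = character(), level = double(),
         n_support = integer(), distinct_support = integer(),
         depth = integer())
}

#' Rejection summary of a call
#'
#' @param sites the result of [call_sites()].
#' @return a tibble `reason, n` of filtered candidate positions.
#' @export
call_rejections <- function(sites) {
  attr(sites, "rejections") %||% tibble(reason = character(), n = integer())
}

#' Merge editing sites called in several samples
#'
#' Takes the union of sites over samples by (chrom, pos, strand) and
#' recomputes each pooled editing level from the summed supporting
#' reads and depths across the samples covering the site. Positions
#' called with conflicting alternative bases across samples are
#' discarded (multi-type across samples). For exact pooled depths the
#' per-sample pileups should be built with `mismatch_only = FALSE`;
#' with mismatch-only pileups a sample that shows no mismatch at the
#' position contributes nothing to the pooled depth.
#'
#' @param per_sample_sites list of site tibbles from [call_sites()].
#' @param per_sample_pileups list (same order) of the pileups the calls
#'   were made from.
#' @return a pooled editing-site tibble.
#' @export
merge_samples <- function(per_sample_sites, per_sample_pileups) {
  stopifnot(length(per_sample_sites) >= 1,
            length(per_sample_sites) == length(per_sample_pileups))
  if (length(per_sample_sites) == 1) return(per_sample_sites[[1]])
  all_sites <- list_rbind(per_sample_sites)
  if (nrow(all_sites) == 0) return(empty_sites())

  conflicted <- all_sites |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_alt = n_distinct(.data$alt), .groups = "drop") |>
    filter(.data$n_alt > 1)
  keys <- all_sites |>
    anti_join(conflicted, by = c("chrom", "pos")) |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$strand)
  if (nrow(keys) == 0) return(empty_sites())

  per_sample <- map(per_sample_pileups, function(p) {
    depth_tbl <- p |> distinct(.data$chrom, .data$pos, .data$depth)
    support <- keys |>
      left_join(p, by = c("chrom", "pos", alt = "base")) |>
      select("chrom", "pos",
             s_support = "count", s_distinct = "distinct") |>
      left_join(depth_tbl, by = c("chrom", "pos")) |>
      mutate(across(c("s_support", "s_distinct"),
                    ~ dplyr::coalesce(.x, 0L)),
             depth = dplyr::coalesce(.data$depth, 0L))
    support
  })
  pooled <- list_rbind(per_sample) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_support = sum(.data$s_support),
              distinct_support = sum(.data$s_distinct),
              depth = sum(.data$depth), .groups = "drop")
  keys |>
    left_join(pooled, by = c("chrom", "pos")) |>
    mutate(level = .data$n_support / .data$depth) |>
    select("chrom", "pos", "ref", "alt", "strand", "level",
           "n_support", "distinct_support", "depth") |>
    arrange(.data$chrom, .data$pos)
}
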