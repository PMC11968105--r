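# canonical miRNA seed-site scanning and edit-impact verdicts.
#
# Seed classes follow the canonical site hierarchy: the seed is miRNA
# positions 2-8; a target site pairs the seed by Watson-Crick
# complementarity, reading the target 5'->3':
#   6mer     pairs miRNA 2-7
#   7mer-A1  pairs miRNA 2-7 with an A opposite position 1
#   7mer-m8  pairs miRNA 2-8
#   8mer     pairs miRNA 2-8 with an A opposite position 1
# With wobble mode on, G:U pairs are permitted inside the seed and
# counted. An edited A is read as G, so it pairs with C (and with U only
# as a wobble), which is how a single edit can destroy or create a site.

MATCH_CLASS_RANK <- c(none = 0L, "6mer" = 1L, "7mer-A1" = 2L,
                      "7mer-m8" = 3L, "8mer" = 4L)

# is target base t paired with miRNA base m? (RNA alphabet)
rna_pairs <- function(t, m, wobble = FALSE) {
  wc <- (t == "A" & m == "U") | (t == "U" & m == "A") |
    (t == "G" & m == "C") | (t == "C" & m == "G")
  if (!wobble) return(wc)
  wc | (t == "G" & m == "U") | (t == "U" & m == "G")
}

rna_is_wobble <- function(t, m) {
  (t == "G" & m == "U") | (t == "U" & m == "G")
}

assert_rna <- function(x, what) {
  if (grepl("[^AUCG]", x)) {
    abort(sprintf("%s contains characters outside the RNA alphabet A/U/C/G",
                  what))
  }
  invisible(x)
}

#' Scan a transcript for canonical miRNA seed matches
#'
#' Finds every target window whose pairing to the miRNA seed (positions
#' 2-7/2-8, Watson-Crick; G:U permitted in wobble mode and counted in
#' `wobble_count`) forms a canonical site, reporting the best class per
#' window (`8mer > 7mer-m8 > 7mer-A1 > 6mer`). Windows are 1-based
#' closed intervals on the target, which is read 5'->3'.
#'
#' @param mirna a one-row tibble from [read_mirna_fasta()], or a single
#'   (optionally named) RNA string, 5'->3'.
#' @param target_seq target transcript sequence (RNA, 5'->3'), length
#'   at least 8.
#' @param wobble permit G:U pairs within the seed (default `FALSE`).
#' @param target_id label for the output.
#' @return a tibble `mirna_id, target_id, match_start, match_end,
#'   match_class, wobble_count`, one row per matching window.
#' @export
seed_scan <- function(mirna, target_seq, wobble = FALSE,
                      target_id = "target") {
  m <- normalize_mirna(mirna)
  target_seq <- toupper(target_seq)
  assert_rna(target_seq, "target_seq")
  assert_rna(m$sequence, sprintf("miRNA '%s'", m$mirna_id))
  n <- nchar(target_seq)
  if (n < 8) abort("target transcript must be at least 8 nt")
  tv <- chars(target_seq)
  mv <- chars(m$sequence)
  if (length(mv) < 8) abort("miRNA must be at least 8 nt")

  out <- list()
  for (j in seq_len(n - 5L)) {
    seed6_t <- tv[j:(j + 5L)]
    seed6_m <- mv[7:2]
    if (!all(rna_pairs(seed6_t, seed6_m, wobble))) next
    w6 <- sum(rna_is_wobble(seed6_t, seed6_m))
    has_m8 <- j > 1L && rna_pairs(tv[j - 1L], mv[8], wobble)
    w8 <- if (has_m8) rna_is_wobble(tv[j - 1L], mv[8]) else FALSE
    has_a1 <- j + 6L <= n && tv[j + 6L] == "A"
    if (has_m8 && has_a1) {
      cls <- "8mer"; win <- c(j - 1L, j + 6L); wc <- w6 + w8
    } else if (has_m8) {
      cls <- "7mer-m8"; win <- c(j - 1L, j + 5L); wc <- w6 + w8
    } else if (has_a1) {
      cls <- "7mer-A1"; win <- c(j, j + 6L); wc <- w6
    } else {
      cls <- "6mer"; win <- c(j, j + 5L); wc <- w6
    }
    out[[length(out) + 1L]] <- tibble(
      mirna_id = m$mirna_id, target_id = target_id,
      match_start = win[1], match_end = win[2],
      match_class = cls, wobble_count = as.integer(wc))
  }
  if (length(out) == 0) {
    tibble(mirna_id = character(), target_id = character(),
           match_start = integer(), match_end = integer(),
           match_class = character(), wobble_count = integer())
  } else {
    list_rbind(out)
  }
}

normalize_mirna <- function(mirna) {
  if (is.data.frame(mirna)) {
    stopifnot(nrow(mirna) == 1)
    list(mirna_id = mirna$mirna_id[1],
         sequence = toupper(mirna$sequence[1]))
  } else if (is.list(mirna) && all(c("mirna_id", "sequence") %in%
                                     names(mirna))) {
    mirna
  } else {
    id <- names(mirna) %||% "mirna"
    list(mirna_id = id[1], sequence = toupper(unname(mirna[1])))
  }
}

#' Impact of an A-to-I edit on miRNA seed matching
#'
#' Scans the unedited transcript and the transcript with A->G
#' substituted at `site_pos`, compares the best seed match overlapping
#' the site, and returns a verdict: `destroyed` (a match existed, none
#' remains), `created` (the mirror case), `weakened` / `strengthened`
#' (both match, class rank changed) or `unchanged`.
#'
#' @param mirna as in [seed_scan()].
#' @param target_seq target transcript (RNA, 5'->3').
#' @param site_pos 1-based transcript position of the edited base,
#'   which must be A.
#' @param wobble permit G:U seed pairs.
#' @param target_id label for the output.
#' @return a one-row tibble `mirna_id, target_id, site_pos,
#'   unedited_class, edited_class, verdict`.
#' @export
edit_impact <- function(mirna, target_seq, site_pos, wobble = FALSE,
                        target_id = "target") {
  target_seq <- toupper(target_seq)
  if (site_pos < 1 || site_pos > nchar(target_seq)) {
    abort("`site_pos` outside the transcript")
  }
  if (substr(target_seq, site_pos, site_pos) != "A") {
    abort(sprintf("transcript base at position %d is %s, not A",
                  site_pos, substr(target_seq, site_pos, site_pos)))
  }
  edited <- target_seq
  substr(edited, site_pos, site_pos) <- "G"
  m <- normalize_mirna(mirna)
  un <- seed_scan(m, target_seq, wobble = wobble, target_id = target_id)
  ed <- seed_scan(m, edited, wobble = wobble, target_id = target_id)
  # overlap is judged on the full 8-nt seed footprint of each match's
  # anchor (positions opposite miRNA 1-8), so that a class change at
  # the same anchor (e.g. 8mer -> 7mer-m8 after editing the A1
  # adenosine) compares as weakened rather than destroyed
  best <- function(matches) {
    if (nrow(matches) == 0) return("none")
    anchor <- ifelse(matches$match_class %in% c("8mer", "7mer-m8"),
                     matches$match_start + 1L, matches$match_start)
    ov <- matches[anchor - 1L <= site_pos & anchor + 6L >= site_pos, ]
    if (nrow(ov) == 0) "none" else
      ov$match_class[which.max(MATCH_CLASS_RANK[ov$match_class])]
  }
  b_un <- best(un); b_ed <- best(ed)
  tibble(mirna_id = m$mirna_id, target_id = target_id,
         site_pos = as.integer(site_pos),
         unedited_class = b_un, edited_class = b_ed,
         verdict = impact_verdict(b_un, b_ed))
}

impact_verdict <- function(unedited_class, edited_class) {
  ru <- MATCH_CLASS_RANK[[unedited_class]]
  re <- MATCH_CLASS_RANK[[edited_class]]
  if (ru == re) "unchanged"
  else if (re == 0L) "destroyed"
  else if (ru == 0L) "created"
  else if (re < ru) "weakened"
  else "strengthened"
}
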