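---
title: "Calling A-to-I editing sites from RNA-seq pileups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling A-to-I editing sites from RNA-seq pileups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editome)
```

## The model

A-to-I editing deaminates adenosine to inosine in double-stranded RNA;
both reverse transcriptases and the ribosome read inosine as
guanosine. Against a haploid reference, an edited position therefore
shows an A→G mismatch between RNA reads and genomic DNA when the
edited transcript is on the plus strand, and T→C in genomic
coordinates when it is on the minus strand. The mismatch type itself
identifies the edited strand; no annotation is consulted during
calling. The quantity attached to every site is the *editing level*

$$\ell = \frac{\text{reads supporting the edit}}{\text{reads covering the site}},$$

an exact per-site ratio, not a model-based estimate.

The haploid assumption matters: in a diploid, heterozygous A/G genomic
SNPs are indistinguishable from editing without a matched DNA library.
For clonal, parthenogenetic organisms that confound largely vanishes,
which is why the caller takes only an *optional* genomic-variant mask
(`caller_config(genomic_mask = ...)`) rather than requiring genotypes.

## The candidate filters

A pileup column becomes a site iff all of the following hold:

1. **Support** — the alternative base is carried by at least
   `min_support = 3` *distinct* (start, end) alignment intervals.
   Counting distinct intervals rather than reads operationalises
   "overlapping but not identical positions": a stack of PCR
   duplicates contributes one interval, so three duplicated copies of
   a single molecule cannot clear the bar. The reported `n_support`
   still counts all passing edited reads, and the level uses
   `n_support`, so duplicates are neutralised in the gate but not
   silently dropped from depth.
2. **Level** — $\ell$ strictly greater than `min_level = 0.05`. The
   inequality is strict: 1 edited read in 20 is exactly 0.05 and is
   rejected.
3. **Mapping quality** — reads with MAPQ < `mapq_min = 30` contribute
   to nothing, neither counts nor depth. MAPQ 255 ("unavailable") is
   treated as failing, the conservative reading. There is no
   base-quality filter; MAPQ is the only read-level gate. N bases are
   ignored entirely.
4. **Single editing type** — positions at which more than one
   alternative base *qualifies as an editing type* are discarded.

### What counts as an "editing type"

The one genuinely open design point in the filter set is what
"multiple editing types" means at a column. The strict reading — any
second non-reference base, at any count, vetoes the position — is not
usable at realistic depth: with a per-base error rate $e$ and depth
$d$, a true site survives only with probability
$(1 - 2e/3)^{d}$, about 85% at $d \approx 47$, $e = 0.005$, and
tending to zero as depth grows, so a pooled multi-library analysis
would discard nearly everything. No plausible pipeline behaves that
way. `editome` therefore counts an alternative base as an editing
type only when it reaches `multi_type_min` distinct supporting
intervals (default: equal to `min_support`, i.e. 3). Isolated
sequencing-error reads then cannot veto a well-supported candidate,
while two genuinely supported mismatch types still discard the
position. Setting `multi_type_min = 1` restores the strict
any-observation reading, and `discard_multi_type = FALSE` disables
the filter.

### Multi-sample pooling

`merge_samples()` takes the union of per-sample calls keyed by
(chrom, pos, strand) and recomputes each pooled level from summed
supports and depths over the samples covering the site; positions
called with conflicting alternative bases across samples are
discarded. Union-with-pooled-level is a documented choice, not an
inference — an intersection rule is easy to express by filtering the
merged table on per-sample membership. Exact pooled depths require
pileups built with `mismatch_only = FALSE`, since a mismatch-only
pileup cannot report the depth of a sample that shows no mismatch at
the position.

## Annotation

Each called site receives exactly one region label. A site is genic
iff it falls inside the span of a gene *on the same strand as the
edit's inferred strand*; a site inside only antisense gene spans is
labelled intergenic (no sense transcript carries the edit) and tallied
separately. Within a gene the precedence is CDS > UTR > intron; ties
across overlapping same-strand genes go to the smallest gene span,
then lexicographic gene id, enforcing a strict partition. When a gene
has several transcripts, the longest spliced CDS represents it.

CDS sites get a 1-based offset within the spliced CDS in transcript
orientation (minus-strand genes count from the 3′-most genomic CDS
base). The codon position is $((\text{cds\_pos}-1) \bmod 3) + 1$; the
coding effect substitutes A→G at that offset and translates the
affected codon with the standard genetic code only (the package
targets nuclear insect genes), with stop treated as an ordinary
amino-acid symbol. A CDS base that is not A in transcript orientation
at a site position raises a consistency error rather than a silent
fix, because it indicates strand or annotation disagreement.

Percentages in the region summary are half-up rounded at one decimal
(`round_half_up()`), the convention under which the shipped published
counts reproduce their printed percentages exactly. Mean editing
levels are unweighted across sites.

## miRNA seed matching

The scanner implements canonical seed classes by Watson–Crick
complementarity of miRNA positions 2–7 (6mer) or 2–8 (7mer-m8), with
an A opposite position 1 upgrading each to 7mer-A1 and 8mer
respectively. With `wobble = TRUE`, G:U pairs are permitted inside the
seed and counted per match. This is a deliberate simplification of
full hybridisation energetics (miRanda/RNAhybrid-style folding is out
of scope): the canonical classes are sufficient to express the
mechanism of interest — an edited A, read as G, no longer pairs a
seed U except as a wobble, so a single edit can destroy a site, and
symmetrically can create one.

`edit_impact()` compares the best match overlapping the edit before
and after the A→G substitution. Overlap is judged on the full 8-nt
seed footprint of a match's anchor rather than the class-specific
window: editing the unpaired A1 adenosine of an 8mer leaves a
7mer-m8 whose window no longer contains the edited base, and the
footprint rule correctly reports that as *weakened* rather than
*destroyed*. Verdicts are `destroyed` / `created` when a match exists
on exactly one side, `weakened` / `strengthened` when the class rank
changes (8mer > 7mer-m8 > 7mer-A1 > 6mer), else `unchanged`.

## What the generator emulates — and what it does not

The synthetic generator exists so that every stage is testable with
exact ground truth. Its defaults describe the study conditions the
package is validated under:

| parameter | default | rationale |
|---|---|---|
| genome | 3 chromosomes, 150 kb total | desk-scale stand-in for a multi-chromosome genome |
| `gc_fraction` | 0.30 | AT-rich, typical of aphid genomes |
| `n_genes` | 30 | both strands, 2–5 exons, valid ORFs |
| `region_mix` | 37.3% intergenic, 38.7% intron, 17.1% CDS, 2.9%/4.0% UTR | the observed genic-region distribution of the *M. dirhodum* editome |
| `n_truth_sites` | 200 | enough for stable sensitivity estimates |
| `level_range` | U(0.1, 0.9) | spans weakly to near-fully edited sites |
| `coverage` | 50× | mid-range bulk RNA-seq depth |
| `error_rate` | 0.005/base | Illumina-like substitution noise |
| `mapq_low_fraction` | 0.10 | reads that must be excluded by the MAPQ gate |
| `duplicate_rate` | 0.05 | PCR duplicates that must not inflate distinct support |

Reads are single-end, gapless and pre-aligned (SAM is emitted
directly; no aligner runs), uniformly placed over the genome.
Consequences worth keeping in mind when extrapolating from green
tests to real data:

* no splice-junction reads and no intron/exon coverage contrast —
  real RNA-seq covers exons far more deeply than introns and
  intergenic sequence;
* no paired-end structure, indels, or quality-string variation
  (placeholder base qualities);
* errors are uniform substitutions; real error profiles are
  position- and context-dependent;
* editing events are independent per read; clustered hyper-editing
  is not modelled.

One RNG governs the whole simulation. Draw order is fixed: the genome
is drawn under `seed`, gene placement and ORF content under
`seed + 1`, truth-site placement and levels under `seed + 2`, and
reads (placement, per-read edits, errors, MAPQ, strand flags,
duplicates, in that order per chromosome) under `seed + 3`; identical
configurations therefore produce byte-identical FASTA, GFF3, SAM and
truth-table output.

## Numerical and engineering choices

* Coordinates are 1-based closed everywhere internally; the BED
  density track is the only 0-based half-open surface.
* The gapless-alignment contract is enforced at SAM ingest: a CIGAR
  other than one match run with optional soft clips (which are
  trimmed) is an error, not a warning.
* The pileup is built by expanding reads to per-base records and
  aggregating with `data.table`; an independent per-position loop
  implementation in the test suite must agree exactly on every random
  instance (up to 100 reads, 10 kb), which guards the fast path.
* Degenerate inputs are defined, not special-cased away: empty read
  sets and empty site lists produce empty, correctly-typed tables;
  zero-gene simulations produce a bare GFF3 header; depth-0 editing
  levels are an error.
* Rejected candidates are tallied by reason (`masked`, `multi_type`,
  `not_a_to_i`, `low_support`, `low_level` — checked in that order)
  and written as `rejections.tsv` by the pipeline front end.

## Validation problem sizes

The shipped tests validate: exact pileup+caller equivalence with the
naive implementation on 50 random instances; recovery of 200 planted
sites at 50× (observed sensitivity 0.98 at seed 1, ≥ 0.95 required,
with ≥ 95% of recovered levels within 3 binomial SD of truth and
false positives ≤ 1 per 10 kb); zero calls on an error-free,
edit-free simulation; 1,000 random CDS edits classified identically
to a whole-protein translation oracle; exhaustive seed-match recovery
against a brute-force scanner plus 100 constructed destroy cases with
the destroyed↔created symmetry; and conservation of site counts
across chromosome, region and window summaries. These sizes were
chosen to make the stochastic bounds sharp while keeping the suite
fast to run routinely.

## Known limitations

* No statistical test of editing-level differences between
  conditions; the package reports levels, it does not compare groups.
* No ADAR-motif scoring, repeat enrichment, or hyper-editing cluster
  detection.
* Seed matching ignores 3′-supplementary pairing and duplex free
  energy; a `destroyed` verdict means the canonical seed match is
  gone, not that binding is thermodynamically impossible.
* The annotator's strict partition resolves overlapping-gene and
  multi-isoform ambiguity by rule; other conventions (e.g. counting a
  site once per overlapping gene) will differ at the margins, which
  is also the most plausible source of off-by-one totals in published
  region tables.
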