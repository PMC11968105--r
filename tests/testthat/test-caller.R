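test_that("editing level is the exact support/depth ratio with a strict gate", {
  expect_equal(editing_level(3, 10), 0.3)
  expect_equal(editing_level(0, 7), 0)
  expect_equal(editing_level(1, 20), 0.05)
  expect_false(editing_level(1, 20) > caller_config()$min_level)
  expect_error(editing_level(1, 0), "depth")
  expect_error(editing_level(5, 3), "n_support")
})

test_that("only A>G and T>C mismatches are A-to-I, with inferred strand", {
  expect_true(classify_mismatch("A", "G")$a_to_i)
  expect_equal(classify_mismatch("A", "G")$strand, "+")
  expect_true(classify_mismatch("T", "C")$a_to_i)
  expect_equal(classify_mismatch("T", "C")$strand, "-")
  others <- expand.grid(ref = c("A", "C", "G", "T"),
                        alt = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  others <- others[others$ref != others$alt, ]
  others <- others[!(others$ref == "A" & others$alt == "G") &
                     !(others$ref == "T" & others$alt == "C"), ]
  res <- classify_mismatch(others$ref, others$alt)
  expect_false(any(res$a_to_i))
  expect_true(all(is.na(res$strand)))
  expect_error(classify_mismatch("A", "A"), "differ")
})

test_that("call_sites applies support, level, type and mask filters", {
  genome <- mk_genome(c1 = strrep("A", 400))
  gseq <- function(off, len = 20, base = "G") {
    paste0(strrep("A", off - 1), base, strrep("A", len - off))
  }
  # 2 distinct supporting intervals: below the three-read requirement
  low <- dplyr::bind_rows(
    mk_reads("c1", c(100, 101), c(gseq(11), gseq(10)), id = c("a", "b")),
    mk_reads("c1", c(103, 104, 105), rep(strrep("A", 21), 3),
             id = c("c", "d", "e")))
  s <- call_sites(build_pileup(low, genome))
  expect_equal(nrow(s), 0)
  expect_equal(call_rejections(s)$reason, "low_support")

  # 4 edited of 100 reads: level 0.04 <= 0.05 fails the strict gate
  many <- dplyr::bind_rows(
    mk_reads("c1", 100:103, sapply(11:8, gseq),
             id = sprintf("e%d", 1:4)),
    mk_reads("c1", rep(91:110, length.out = 96), strrep("A", 20),
             id = sprintf("n%d", 1:96)))
  s2 <- call_sites(build_pileup(many, genome))
  expect_equal(nrow(s2), 0)
  expect_equal(call_rejections(s2)$reason, "low_level")

  # two well-supported alternative bases: multi-type discard
  multi <- dplyr::bind_rows(
    mk_reads("c1", 100:102, sapply(11:9, gseq), id = sprintf("g%d", 1:3)),
    mk_reads("c1", 103:105, sapply(8:6, function(o) gseq(o, base = "T")),
             id = sprintf("t%d", 1:3)),
    mk_reads("c1", 106:109, rep(strrep("A", 20), 4),
             id = sprintf("n%d", 1:4)))
  s3 <- call_sites(build_pileup(multi, genome))
  expect_equal(nrow(s3), 0)
  expect_equal(call_rejections(s3)$reason, "multi_type")
  # with the filter off the best-supported A-to-I alt is still callable
  s3b <- call_sites(build_pileup(multi, genome),
                    caller_config(discard_multi_type = FALSE))
  expect_equal(nrow(s3b), 1)
  expect_equal(s3b$alt, "G")

  # an isolated error read does not veto a supported candidate, but the
  # strict any-observation reading (multi_type_min = 1) does
  noisy <- dplyr::bind_rows(
    mk_reads("c1", 100:102, sapply(11:9, gseq), id = sprintf("g%d", 1:3)),
    mk_reads("c1", 103, gseq(8, base = "T"), id = "err"),
    mk_reads("c1", 104:107, rep(strrep("A", 20), 4),
             id = sprintf("n%d", 1:4)))
  s4 <- call_sites(build_pileup(noisy, genome))
  expect_equal(nrow(s4), 1)
  expect_equal(s4$n_support, 3L)
  s4strict <- call_sites(build_pileup(noisy, genome),
                         caller_config(multi_type_min = 1))
  expect_equal(nrow(s4strict), 0)
  expect_equal(call_rejections(s4strict)$reason, "multi_type")

  # clean call: {A:6, G:4} over 4 distinct intervals
  ok <- dplyr::bind_rows(
    mk_reads("c1", 100:103, sapply(11:8, gseq), id = sprintf("g%d", 1:4)),
    mk_reads("c1", 104:109, rep(strrep("A", 20), 6),
             id = sprintf("n%d", 1:6)))
  s5 <- call_sites(build_pileup(ok, genome))
  expect_equal(nrow(s5), 1)
  expect_equal(s5$level, 0.4)
  expect_equal(s5$strand, "+")
  expect_equal(s5$ref, "A")
  expect_equal(s5$alt, "G")
  expect_equal(s5$depth, 10L)

  # the same position under a genomic mask is excluded
  s6 <- call_sites(build_pileup(ok, genome),
                   caller_config(genomic_mask = tibble::tibble(
                     chrom = "c1", pos = 110L)))
  expect_equal(nrow(s6), 0)
  expect_equal(call_rejections(s6)$reason, "masked")

  # C>T and friends are never emitted as sites
  ct <- dplyr::bind_rows(
    mk_reads("c1", 100:102, sapply(11:9, function(o) gseq(o, base = "C")),
             id = sprintf("c%d", 1:3)),
    mk_reads("c1", 104:109, rep(strrep("A", 20), 6),
             id = sprintf("n%d", 1:6)))
  s7 <- call_sites(build_pileup(ct, genome))
  expect_equal(nrow(s7), 0)
  expect_equal(call_rejections(s7)$reason, "not_a_to_i")
})

test_that("caller matches the literal naive implementation on random instances", {
  withr::local_seed(8123)
  for (i in 1:12) {
    inst <- random_instance()
    cfg <- caller_config()
    mine <- call_sites(build_pileup(inst$reads, inst$genome,
                                    mapq_min = cfg$mapq_min), cfg)
    ref <- naive_call(inst$reads, inst$genome, cfg)
    expect_equal(strip_sites(mine), as.data.frame(ref),
                 label = sprintf("instance %d", i))
  }
})

test_that("an error-free haploid simulation with no edits yields zero calls", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(20000, 15000),
                    n_genes = 6, n_truth_sites = 0, coverage = 20,
                    error_rate = 0, seed = 55)
  sim <- simulate_editome(cfg)
  sites <- call_sites(build_pileup(sim$reads, sim$genome))
  expect_equal(nrow(sites), 0)
})

test_that("calling is symmetric under reverse-complementing the instance", {
  withr::local_seed(2718)
  inst <- random_instance(n_chrom = 1, chrom_len = 1500, n_reads = 90,
                          mismatch_rate = 0.04)
  L <- Biostrings::width(inst$genome)[1]
  rc_genome <- Biostrings::reverseComplement(inst$genome)
  names(rc_genome) <- names(inst$genome)
  rc_reads <- inst$reads
  rc_reads$start <- L - inst$reads$end + 1L
  rc_reads$end <- L - inst$reads$start + 1L
  rc_reads$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(inst$reads$seq)))

  fwd <- call_sites(build_pileup(inst$reads, inst$genome))
  rev <- call_sites(build_pileup(rc_reads, rc_genome))
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  strand_flip <- c(`+` = "-", `-` = "+")
  fwd_t <- dplyr::arrange(dplyr::mutate(
    fwd, pos = L - pos + 1L, ref = unname(flip[ref]),
    alt = unname(flip[alt]), strand = unname(strand_flip[strand])),
    chrom, pos)
  expect_equal(strip_sites(fwd_t), strip_sites(rev))
})

test_that("merging samples pools supports and depths by union", {
  genome <- mk_genome(c1 = strrep("A", 50))
  # sample reads all cover position 10; alt reads are staggered so
  # their support intervals are distinct
  mk_sample <- function(n_alt, n_ref, base = "G") {
    alt <- if (n_alt > 0) {
      mk_reads("c1", seq_len(n_alt),
               vapply(seq_len(n_alt), function(i)
                 paste0(strrep("A", 10 - i), base, strrep("A", 9 + i)),
                 character(1)),
               id = sprintf("a%d", seq_len(n_alt)))
    }
    ref <- if (n_ref > 0) {
      mk_reads("c1", seq_len(n_ref),
               vapply(seq_len(n_ref), function(i) strrep("A", 20),
                      character(1)),
               id = sprintf("r%d", seq_len(n_ref)))
    }
    dplyr::bind_rows(alt, ref)
  }
  p1 <- build_pileup(mk_sample(3, 7), genome, mismatch_only = FALSE)
  p2 <- build_pileup(mk_sample(4, 6), genome, mismatch_only = FALSE)
  p3 <- build_pileup(mk_sample(0, 10), genome, mismatch_only = FALSE)
  s1 <- call_sites(p1); s2 <- call_sites(p2); s3 <- call_sites(p3)
  expect_equal(nrow(s1), 1); expect_equal(nrow(s3), 0)

  # one sample: identity
  expect_equal(merge_samples(list(s1), list(p1)), s1)

  merged <- merge_samples(list(s1, s2, s3), list(p1, p2, p3))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_support, 7L)
  expect_equal(merged$depth, 30L)
  expect_equal(merged$level, 7 / 30)

  # conflicting alternative alleles across samples are discarded
  pc <- build_pileup(mk_sample(3, 7, base = "C"), genome,
                     mismatch_only = FALSE)
  sc <- call_sites(pc, caller_config(min_level = 0.01))
  # force a fake conflicting site table at the same position
  sc$alt <- "C"; sc$ref <- "A"; sc$strand <- "+"
  if (nrow(sc) == 0) {
    sc <- s1; sc$alt <- "C"
  }
  expect_equal(nrow(merge_samples(list(s1, sc), list(p1, pc))), 0)
})
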