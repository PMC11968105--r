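test_that("simulated genomes honour length, alphabet, GC and determinism", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(5000, 3000), seed = 5)
  g <- simulate_genome(cfg)
  expect_equal(unname(Biostrings::width(g)), c(5000L, 3000L))
  expect_false(any(grepl("[^ACGT]", as.character(g))))

  # GC within 3 binomial SD of the target
  cfg2 <- sim_config(n_chrom = 1, chrom_lengths = 100000,
                     gc_fraction = 0.5, seed = 9)
  g2 <- simulate_genome(cfg2)
  gc <- sum(strsplit(as.character(g2[[1]]), "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(100000 * 0.5 * 0.5)
  expect_lt(abs(gc - 50000), sd3)

  # same seed twice => byte-identical FASTA
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(simulate_genome(cfg), f1)
  write_genome_fasta(simulate_genome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_config(chrom_lengths = 500), "1000")
  expect_error(sim_config(gc_fraction = 1.4), "fraction")
})

test_that("generated gene models carry valid ORFs on both strands", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(30000, 20000),
                    n_genes = 12, seed = 21)
  gm <- simulate_gene_models(simulate_genome(cfg), cfg)
  expect_setequal(unique(gm$models$strand), c("+", "-"))

  spans <- gene_spans(gm$models)
  # non-overlapping genes per chromosome
  for (cn in unique(spans$chrom)) {
    s <- spans[spans$chrom == cn, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }

  for (gid in unique(gm$models$gene_id)) {
    cds <- cds_sequence(gm$models, gm$genome, gid)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    # exactly one stop, at the end
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }

  # minus-strand oracle: first codon of the reverse-complemented
  # spliced genomic CDS is ATG
  minus <- unique(gm$models$gene_id[gm$models$strand == "-"])
  g0 <- minus[1]
  rows <- gm$models[gm$models$gene_id == g0 & gm$models$type == "CDS", ]
  rows <- rows[order(rows$start), ]
  genomic <- paste(substring(as.character(gm$genome[[rows$chrom[1]]]),
                             rows$start, rows$end), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genomic)))
  expect_equal(substr(rc, 1, 3), "ATG")

  # empty case writes a bare GFF3 header
  cfg0 <- sim_config(n_genes = 0, seed = 1)
  gm0 <- simulate_gene_models(simulate_genome(cfg0), cfg0)
  expect_equal(nrow(gm0$models), 0)
  f <- tempfile(fileext = ".gff3")
  write_gene_models(gm0$models, f)
  expect_equal(readLines(f), "##gff-version 3")

  # a genome too small to host the genes is a placement error
  tiny <- sim_config(n_chrom = 1, chrom_lengths = 1200, n_genes = 10,
                     seed = 2)
  expect_error(simulate_gene_models(simulate_genome(tiny), tiny),
               "place")
})

test_that("planted truth sites obey strand rule, region class and uniqueness", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(40000, 30000),
                    n_genes = 10, n_truth_sites = 200, seed = 33)
  gm <- simulate_gene_models(simulate_genome(cfg), cfg)
  truth <- plant_truth_sites(gm$genome, gm$models, cfg)

  expect_equal(nrow(truth), 200)
  expect_equal(nrow(dplyr::distinct(truth, chrom, pos)), 200)
  expect_true(all(truth$true_level >= 0.1 & truth$true_level <= 0.9))

  gstr <- as.character(gm$genome)
  base <- mapply(function(cn, p) substr(gstr[[cn]], p, p),
                 truth$chrom, truth$pos)
  expect_true(all(base[truth$strand == "+"] == "A"))
  expect_true(all(base[truth$strand == "-"] == "T"))

  # the annotator agrees with each site's requested region class
  sites <- tibble::tibble(chrom = truth$chrom, pos = truth$pos,
                          strand = truth$strand)
  ann <- locate_region(sites, gm$models)
  got <- ifelse(ann$region == "cds", "cds", ann$region)
  expect_equal(unname(got), truth$region_class)

  # all-intergenic mix stays outside every gene span
  cfg_ig <- sim_config(n_chrom = 1, chrom_lengths = 20000, n_genes = 3,
                       n_truth_sites = 10,
                       region_mix = c(intergenic = 1), seed = 4)
  gm2 <- simulate_gene_models(simulate_genome(cfg_ig), cfg_ig)
  t2 <- plant_truth_sites(gm2$genome, gm2$models, cfg_ig)
  spans <- gene_spans(gm2$models)
  inside <- mapply(function(cn, p) {
    any(spans$chrom == cn & spans$start <= p & spans$end >= p)
  }, t2$chrom, t2$pos)
  expect_false(any(inside))
})

test_that("simulated reads carry edits at the planted level", {
  genome <- mk_genome(c1 = paste(
    paste(rep("C", 499), collapse = ""), "A",
    paste(rep("C", 500), collapse = ""), sep = ""))
  cfg <- sim_config(n_chrom = 1, chrom_lengths = 1000, coverage = 400,
                    read_length = 100, error_rate = 0,
                    mapq_low_fraction = 0, duplicate_rate = 0, seed = 8)
  expect_error(
    simulate_reads(genome, NULL,
                   tibble::tibble(chrom = character(), pos = integer(),
                                  strand = character(),
                                  true_level = double()),
                   sim_config(coverage = 0)),
    "coverage")

  # full-level site with no error: every overlapping read shows G
  truth1 <- tibble::tibble(chrom = "c1", pos = 500L, strand = "+",
                           true_level = 1.0)
  reads <- simulate_reads(genome, NULL, truth1, cfg)
  over <- reads[reads$start <= 500 & reads$end >= 500, ]
  shown <- substr(over$seq, 500 - over$start + 1, 500 - over$start + 1)
  expect_true(all(shown == "G"))

  # half-level site: edited fraction within 3 binomial SD of 0.5
  truth2 <- tibble::tibble(chrom = "c1", pos = 500L, strand = "+",
                           true_level = 0.5)
  reads2 <- simulate_reads(genome, NULL, truth2, cfg)
  over2 <- reads2[reads2$start <= 500 & reads2$end >= 500, ]
  shown2 <- substr(over2$seq, 500 - over2$start + 1, 500 - over2$start + 1)
  phat <- mean(shown2 == "G")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / length(shown2)))

  # total aligned bases within 3 Poisson SD of coverage * length
  cfg30 <- sim_config(n_chrom = 1, chrom_lengths = 5000, coverage = 30,
                      read_length = 100, duplicate_rate = 0, seed = 12)
  g30 <- simulate_genome(cfg30)
  r30 <- simulate_reads(g30, NULL, truth1[0, ], cfg30)
  mu_reads <- 30 * 5000 / 100
  expect_lt(abs(nrow(r30) - mu_reads), 3 * sqrt(mu_reads))
  expect_equal(sum(r30$length), nrow(r30) * 100)
})

test_that("the full simulation is byte-deterministic across formats", {
  cfg <- sim_config(n_chrom = 1, chrom_lengths = 12000, n_genes = 3,
                    n_truth_sites = 15, coverage = 15, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_editome(cfg, out_dir = d1)
  simulate_editome(cfg, out_dir = d2)
  for (f in c("genome.fa", "genes.gff3", "reads.sam", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
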