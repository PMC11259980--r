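test_that("generated genomes honour size, mask fraction and determinism", {
  asm <- make_genome(2, 50000, 0.3, 0.4, seed = 7)
  expect_equal(unname(chrom_sizes(asm)), c(50000L, 50000L))
  mf <- masked_fraction(asm)
  expect_true(all(mf$masked_fraction >= 0.24 & mf$masked_fraction <= 0.36))

  empty <- make_genome(1, 100000, 0, 0.5, seed = 1)
  expect_equal(nrow(empty$mask), 0L)

  again <- make_genome(2, 50000, 0.3, 0.4, seed = 7)
  expect_identical(asm$seq, again$seq)
  expect_identical(asm$mask, again$mask)

  # byte-identical FASTA under a fixed seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_assembly(asm, f1); write_assembly(again, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(make_genome(1, 5000), "chrom_length")
  expect_error(make_genome(1, 100000, repeat_fraction = 1), "repeat_fraction")
})

test_that("generated GC fraction tracks the requested value", {
  for (gc in c(0.35, 0.5, 0.6)) {
    asm <- make_genome(1, 50000, 0, gc, seed = round(100 * gc))
    got <- retroscape:::gc_of(asm$seq[[1]])
    expect_lt(abs(got - gc), 0.02)
  }
})

test_that("planted genes have the stated layout and an intact ORF", {
  g <- make_genome(1, 100000, 0, 0.45, seed = 3)
  g <- plant_gene(g, n_exons = 2, exon_len = 300, intron_len = 500, seed = 4)
  gm <- gene_models(g)
  expect_equal(gm$end - gm$start, 1100L) # 2x300 + 500
  expect_equal(gm$spliced_len, 600L)

  expect_error(plant_gene(g, n_exons = 1), "two exons")

  # independent codon scan of the emitted spliced sequence
  sp <- spliced_sequence(g, "gene1")
  aa <- oracle_translate(substr(sp, 1, gm$cds_end))
  expect_equal(substr(aa, 1, 1), "M")
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))

  # minus-strand gene still yields a clean ORF through the spliced transcript
  g2 <- plant_gene(g, n_exons = 3, exon_len = 210, intron_len = 300,
                   strand = "-", seed = 9)
  gm2 <- gene_models(g2)[2, ]
  sp2 <- spliced_sequence(g2, "gene2")
  aa2 <- oracle_translate(substr(sp2, 1, gm2$cds_end))
  expect_equal(substr(aa2, 1, 1), "M")
  expect_false(grepl("*", substr(aa2, 1, nchar(aa2) - 1), fixed = TRUE))

  # footprint collisions error out
  expect_error(
    plant_gene(g2, n_exons = 2, exon_len = 300, intron_len = 500,
               chrom = gm$chrom, site = gm$start + 50),
    class = "retroscape_placement_error"
  )
})

test_that("planted retrocopies follow the staggered-cut insertion model", {
  g <- make_genome(1, 100000, 0, 0.45, seed = 3)
  g <- plant_gene(g, n_exons = 3, exon_len = 400, intron_len = 500, seed = 4)

  # all decorations off: inserted sequence equals the exact spliced cDNA
  g0 <- plant_retrocopy(g, "gene1", tsd_len = 0, polya_len = 0,
                        truncation = 0, divergence = 0, cleavage = NULL,
                        seed = 11)
  tr0 <- truth_records(g0)
  expect_identical(seq_slice(g0, tr0$chrom, tr0$start, tr0$end),
                   spliced_sequence(g0, "gene1"))

  # tsd_len = 12: the 12 bp flanking both ends of the insertion are identical
  g1 <- plant_retrocopy(g, "gene1", tsd_len = 12, polya_len = 10, seed = 5)
  tr <- truth_records(g1)
  up <- seq_slice(g1, tr$chrom, tr$start, tr$start + 12)
  dn <- seq_slice(g1, tr$chrom, tr$end - 12, tr$end)
  expect_identical(up, dn)
  expect_identical(up, tr$tsd_seq)
  # round trip: re-extraction reproduces the recorded inserted sequence
  expect_identical(seq_slice(g1, tr$chrom, tr$start, tr$end), tr$inserted_seq)

  # canonical cleavage motif is spelled at the 5' TSD boundary
  expect_equal(cleavage_site(g1, tr$chrom, "+", tr$start, tr$end, 12),
               "TTTTAAA")
  g2 <- plant_retrocopy(g, "gene1", orientation = "-", tsd_len = 10,
                        polya_len = 8, seed = 9)
  tr2 <- truth_records(g2)
  expect_equal(cleavage_site(g2, tr2$chrom, "-", tr2$start, tr2$end, 10),
               "TTTTAAA")
  # minus-strand poly(A) is a T run on the genomic strand
  expect_identical(seq_slice(g2, tr2$chrom, tr2$start + 10, tr2$start + 18),
                   strrep("T", 8))

  expect_error(plant_retrocopy(g, "gene1", tsd_len = 3), "tsd_len")
  expect_error(plant_retrocopy(g, "gene1", polya_len = 2), "polya_len")
})

test_that("retrocopy truncation and divergence act on the cDNA as stated", {
  g <- make_genome(1, 100000, 0, 0.45, seed = 13)
  g <- plant_gene(g, n_exons = 3, exon_len = 400, intron_len = 500, seed = 14)
  cdna <- spliced_sequence(g, "gene1")

  gt <- plant_retrocopy(g, "gene1", tsd_len = 0, polya_len = 0,
                        truncation = 0.25, divergence = 0, cleavage = NULL,
                        seed = 15)
  tr <- truth_records(gt)
  expect_identical(seq_slice(gt, tr$chrom, tr$locus_start, tr$locus_end),
                   substr(cdna, floor(0.25 * nchar(cdna)) + 1, nchar(cdna)))

  gd <- plant_retrocopy(g, "gene1", tsd_len = 0, polya_len = 0,
                        truncation = 0, divergence = 0.05, cleavage = NULL,
                        seed = 16)
  trd <- truth_records(gd)
  got <- seq_slice(gd, trd$chrom, trd$locus_start, trd$locus_end)
  idy <- oracle_identity(got, cdna)
  expect_gt(idy, 0.92)
  expect_lt(idy, 0.98)
})

test_that("planted duplications carry the requested divergence and layout", {
  g <- make_genome(2, 120000, 0, 0.45, seed = 3)

  # tandem, zero divergence: copy is byte-identical and adjacent
  gt <- plant_duplication(g, "chr1", 20000, 22000, n_copies = 1,
                          divergence = 0, placement = "tandem", seed = 5)
  tr <- truth_records(gt)
  src <- tr[tr$role == "source", ]; cp <- tr[tr$role == "copy", ]
  expect_equal(cp$start, src$end)
  expect_identical(seq_slice(gt, src$chrom, src$start, src$end),
                   seq_slice(gt, cp$chrom, cp$start, cp$end))

  # five dispersed copies at 2% divergence: identity in [0.97, 0.99] each
  gd <- plant_duplication(g, "chr2", 30000, 32000, n_copies = 5,
                          divergence = 0.02, seed = 6)
  trd <- truth_records(gd)
  srcseq <- seq_slice(gd, "chr2",
                      trd$start[trd$role == "source"],
                      trd$end[trd$role == "source"])
  copies <- trd[trd$role == "copy", ]
  expect_equal(nrow(copies), 5L)
  expect_equal(unique(copies$copy_number), 12) # 2 * (5 + 1)
  for (i in seq_len(nrow(copies))) {
    idy <- oracle_identity(
      seq_slice(gd, copies$chrom[i], copies$start[i], copies$end[i]), srcseq)
    expect_gte(idy, 0.97); expect_lte(idy, 0.995)
  }

  expect_error(plant_duplication(g, "chr1", 0, 900), ">= 1,000")
  expect_error(plant_duplication(g, "chr1", 0, 2000, n_copies = 0), "n_copies")
})

test_that("sister assemblies accumulate binomial SNPs and private insertions", {
  base <- make_genome(1, 500000, 0, 0.42, seed = 20)
  base <- plant_gene(base, n_exons = 3, exon_len = 300, intron_len = 400,
                     seed = 21)

  # zero generations, zero private copies: sister identical
  d0 <- diverge_assembly(base, 0, private_retros = 0, seed = 22)
  expect_identical(d0$assembly$seq, base$seq)
  expect_equal(nrow(d0$truth), 0L)

  # SNP totals across seeds match the binomial expectation within 3 sigma
  L <- sum(chrom_sizes(base)) - (gene_models(base)$end - gene_models(base)$start)
  g <- 100000; mu <- 4.5e-9
  expected <- 2 * mu * g * L
  counts <- vapply(1:20, function(s) {
    d <- diverge_assembly(base, g, mu = mu, seed = 300 + s)
    sum(d$truth$kind == "snp")
  }, double(1))
  tot <- sum(counts)
  expect_lt(abs(tot - 20 * expected), 3 * sqrt(20 * expected))
  # and each SNP record is a real substitution at the recorded position
  d <- diverge_assembly(base, g, mu = mu, seed = 321)
  snp <- d$truth[d$truth$kind == "snp", ][1:10, ]
  for (i in 1:10) {
    expect_identical(seq_slice(d$assembly, snp$chrom[i], snp$start[i],
                               snp$end[i]), snp$alt[i])
    expect_identical(seq_slice(base, snp$chrom[i], snp$start[i], snp$end[i]),
                     snp$ref[i])
  }

  # exactly the requested number of sister-private retrocopies
  d3 <- diverge_assembly(base, 1000, private_retros = 3, seed = 23)
  expect_equal(sum(d3$truth$kind == "retrocopy"), 3L)
  expect_equal(sum(truth_records(base)$kind == "retrocopy"), 0L)
})

test_that("simulated depth tracks scale with planted copy number", {
  g <- make_genome(1, 1200000, 0, 0.42, seed = 30)
  d <- simulate_depth(g, mean_depth = 30, gc_bias = 0, seed = 31)
  expect_gte(nrow(d), 1000)
  expect_lt(abs(mean(d$depth) - 30) / 30, 0.02)
  # every window carries exactly 1,000 unmasked bases except the last
  expect_true(all(d$unmasked[-nrow(d)] == 1000))

  g2 <- plant_duplication(g, "chr1", 300000, 330000, n_copies = 1,
                          divergence = 0.01, seed = 32)
  tr <- truth_records(g2)[1, ] # source interval
  d2 <- simulate_depth(g2, mean_depth = 30, seed = 33)
  inside <- d2$start >= tr$start & d2$end <= tr$end
  expect_gt(sum(inside), 10)
  ratio <- mean(d2$depth[inside]) / 30
  expect_lt(abs(ratio - 2), 0.15) # 4 copies vs diploid 2
})

test_that("masked windows are excluded from depth tabulation", {
  g <- make_genome(1, 200000, 0.3, 0.42, seed = 40)
  d <- simulate_depth(g, mean_depth = 20, window_unmasked = 500, seed = 41)
  expect_true(all(d$unmasked[-nrow(d)] == 500))
  # windows skip masked bases, so genomic spans exceed the unmasked count
  expect_gte(sum(d$end - d$start), sum(d$unmasked))
  # all windows inside chromosome bounds
  expect_true(all(d$end <= chrom_sizes(g)[d$chrom]))
})
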