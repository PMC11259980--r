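# shared fixture: a base assembly, a sister sharing its loci plus privates
fixture_pair <- function(seed = 200, size = 150000, g = 15000, privates = 2) {
  base <- make_genome(1, size, 0, 0.42, seed = seed)
  base <- plant_gene(base, n_exons = 3, exon_len = 350, intron_len = 400,
                     seed = seed + 1)
  for (i in 1:3) base <- plant_retrocopy(base, "gene1", seed = seed + 1 + i)
  d <- diverge_assembly(base, g, private_retros = privates, seed = seed + 9)
  list(base = base, sister = d$assembly, new = d$truth)
}

test_that("presence assessment distinguishes shared, absent and unresolved", {
  fx <- fixture_pair(seed = 210)
  tr <- subset(truth_records(fx$base), kind == "retrocopy")
  # loci planted before divergence are shared
  expect_equal(assess_presence(fx$base, tr$chrom[1], tr$start[1], tr$end[1],
                               fx$sister), "shared")
  # sister-private insertions are absent from the base assembly
  pr <- subset(fx$new, kind == "retrocopy")
  expect_equal(assess_presence(fx$sister, pr$chrom[1], pr$start[1], pr$end[1],
                               fx$base), "absent")
  # flanks falling into a deleted region are unresolved
  broken <- fx$sister
  del_start <- pr$start[1] - 1200
  s <- broken$seq[[pr$chrom[1]]]
  broken$seq[[pr$chrom[1]]] <- paste0(substr(s, 1, del_start),
                                      substr(s, pr$end[1] + 1200, nchar(s)))
  expect_equal(assess_presence(fx$sister, pr$chrom[1], pr$start[1], pr$end[1],
                               broken), "unresolved")
})

test_that("presence symmetry holds on unrearranged sister pairs", {
  fx <- fixture_pair(seed = 220)
  tr <- subset(truth_records(fx$base), kind == "retrocopy")
  for (i in seq_len(nrow(tr))) {
    expect_equal(assess_presence(fx$base, tr$chrom[i], tr$start[i], tr$end[i],
                                 fx$sister), "shared")
  }
  # lift the locus from the sister and re-test in the base
  trs <- subset(truth_records(fx$sister), kind == "retrocopy" &
                  id %in% tr$id)
  for (i in seq_len(nrow(trs))) {
    expect_equal(assess_presence(fx$sister, trs$chrom[i], trs$start[i],
                                 trs$end[i], fx$base), "shared")
  }
})

test_that("presence-matrix pattern counts match the planted truth", {
  base <- make_genome(1, 150000, 0, 0.42, seed = 230)
  base <- plant_gene(base, n_exons = 3, exon_len = 350, intron_len = 400,
                     seed = 231)
  for (i in 1:4) base <- plant_retrocopy(base, "gene1", seed = 231 + i)
  asms <- list(ref = base)
  privates <- c(A = 2L, B = 1L)
  loci <- subset(truth_records(base), kind == "retrocopy")[, c("chrom", "start", "end")]
  loci$assembly <- "ref"
  for (a in names(privates)) {
    d <- diverge_assembly(base, 12000, private_retros = privates[[a]],
                          seed = 240 + match(a, names(privates)))
    asms[[a]] <- d$assembly
    # this assembly's call set: every retrocopy it carries (shared + private)
    mine <- subset(truth_records(d$assembly),
                   kind == "retrocopy")[, c("chrom", "start", "end")]
    mine$assembly <- a
    loci <- rbind(loci, mine)
  }
  pm <- build_presence_matrix(asms, loci, priority = c("ref", "A", "B"))
  pat <- pm$patterns
  expect_equal(pat$n_loci[pat$pattern == "111"], 4L) # the shared loci
  expect_equal(pat$n_loci[pat$pattern == "010"], 2L) # A-private
  expect_equal(pat$n_loci[pat$pattern == "001"], 1L) # B-private
  expect_equal(sum(pat$n_loci), 7L)
})

test_that("independent insertions at coincident sites are discounted, not miscounted", {
  base <- make_genome(1, 120000, 0, 0.42, seed = 290)
  base <- plant_gene(base, n_exons = 3, exon_len = 300, intron_len = 400,
                     seed = 291)
  base <- plant_retrocopy(base, "gene1", seed = 292)
  sA <- diverge_assembly(base, 10000, seed = 293)$assembly
  sB <- diverge_assembly(base, 10000, seed = 294)$assembly
  # private insertions 200 bp apart in base coordinates, one per sister:
  # each falls inside the other's flank window and cannot be resolved there
  site <- 60000L
  sA <- plant_retrocopy(sA, "gene1", chrom = "chr1", site = site, seed = 295)
  sB <- plant_retrocopy(sB, "gene1", chrom = "chr1", site = site + 200L,
                        seed = 296)
  grab <- function(asm, nm) {
    out <- subset(truth_records(asm), kind == "retrocopy")[, c("chrom", "start", "end")]
    out$assembly <- nm
    out
  }
  loci <- rbind(grab(base, "ref"), grab(sA, "A"), grab(sB, "B"))
  pm <- build_presence_matrix(list(ref = base, A = sA, B = sB), loci,
                              priority = c("ref", "A", "B"))
  # the shared locus stays resolved; the colliding pair is discounted
  expect_equal(pm$patterns$n_loci[pm$patterns$pattern == "111"], 1L)
  expect_false(any(pm$patterns$pattern %in% c("010", "001")))
  expect_gte(sum(!pm$matrix$resolved), 1)
})

test_that("divergence counting filters SNPs and callable size together", {
  snps <- tibble::tibble(chrom = "c1", pos = c(100L, 5000L, 9000L, 15000L))
  called <- tibble::tibble(chrom = "c1", start = 0L, end = 20000L)

  # no exclusions: everything counted
  d0 <- count_divergence(snps, called)
  expect_equal(d0$snp_count, 4L)
  expect_equal(d0$callable_bp, 20000)

  # exclusions covering all variants zero the count
  d1 <- count_divergence(snps, called,
                         tibble::tibble(chrom = "c1", start = 0L, end = 16000L))
  expect_equal(d1$snp_count, 0L)
  expect_equal(d1$callable_bp, 4000)

  # random configuration equals a per-base bitmap oracle
  set.seed(41)
  rs <- tibble::tibble(chrom = "c1", pos = sort(sample.int(50000, 200)))
  excl <- list(
    tibble::tibble(chrom = "c1", start = c(1000L, 30000L), end = c(8000L, 33000L)),
    tibble::tibble(chrom = "c1", start = 25000L, end = 31000L)
  )
  called2 <- tibble::tibble(chrom = "c1", start = 500L, end = 45000L)
  got <- count_divergence(rs, called2, excl)
  bit <- logical(50000)
  bit[501:45000] <- TRUE
  bit[1001:8000] <- FALSE; bit[30001:33000] <- FALSE; bit[25001:31000] <- FALSE
  expect_equal(got$callable_bp, sum(bit))
  expect_equal(got$snp_count, sum(bit[rs$pos + 1]))
})

test_that("generation arithmetic reproduces the published divergence numbers", {
  expect_equal(estimate_generations(4219105, 2022154146, 4.5e-9), 231827)
  expect_equal(estimate_generations(4219105, 2022154146, 2.6e-9), 401239)
  expect_equal(estimate_generations(4219105, 2022154146, 7.1e-9), 146932)
  expect_equal(estimate_generations(0, 2e9, 4.5e-9), 0)
  expect_error(estimate_generations(100, 0, 4.5e-9), "positive")
  expect_error(estimate_generations(100, 2e9, 0), "positive")
})

test_that("insertion-rate arithmetic reproduces the published table", {
  r <- estimate_rate(48, 79, 231827, snps = 4219105, size = 2022154146)
  expect_equal(r$rate, 2.74e-4)
  expect_equal(r$births, 3650)
  expect_equal(r$bounds$rate_low, 1.58e-4)
  expect_equal(r$bounds$rate_high, 4.32e-4)
  expect_equal(r$bounds$births_low, 2315)
  expect_equal(r$bounds$births_high, 6329)
  td <- tidy(r)
  expect_equal(td$generations_low, 146932)
  expect_equal(td$generations_high, 401239)
  gl <- glance(r)
  expect_equal(gl$rate, 2.74e-4)

  # the two-significant-figure variant
  rc <- estimate_rate(48, 92, 226008, sigfigs = 2)
  expect_equal(rc$rate, 3.1e-4)
  expect_equal(rc$births, 3226)

  expect_equal(estimate_rate(0, 0, 1000)$rate, 0)
  expect_error(estimate_rate(1, 1, 0), "generations")
})

test_that("generations fall as mu rises and births fall as the rate rises", {
  mus <- seq(2e-9, 8e-9, by = 1e-9)
  gens <- vapply(mus, function(m) estimate_generations(4219105, 2022154146, m),
                 double(1))
  expect_true(all(diff(gens) < 0))
  rates <- c(1e-4, 2e-4, 4e-4)
  births <- vapply(rates, function(r) estimate_rate(50, 50, round(50 / r))$births,
                   double(1))
  expect_true(all(diff(births) < 0))
})

test_that("ancestral presence classifies outgroup states", {
  base <- make_genome(1, 150000, 0, 0.42, seed = 260)
  base <- plant_gene(base, n_exons = 3, exon_len = 400, intron_len = 400,
                     seed = 261)
  base <- plant_retrocopy(base, "gene1", seed = 262)
  tr <- subset(truth_records(base), kind == "retrocopy")
  # outgroup = a moderately diverged relative carrying the insertion
  og <- diverge_assembly(base, 50000, seed = 263)$assembly
  expect_equal(ancestral_presence(base, tr$chrom, tr$start, tr$end, og),
               "present")

  # outgroup with the insertion excised (flanks adjacent): absent
  og2 <- og
  s <- og2$seq[[tr$chrom]]
  tro <- subset(truth_records(og), kind == "retrocopy")
  og2$seq[[tr$chrom]] <- paste0(substr(s, 1, tro$start),
                                substr(s, tro$end + 1, nchar(s)))
  expect_equal(ancestral_presence(base, tr$chrom, tr$start, tr$end, og2),
               "absent")

  # outgroup fragmented so the flanks land on different contigs: unresolved
  og3 <- og
  cut <- tro$start + 500
  og3$seq <- c(ctgA = substr(s, 1, cut), ctgB = substr(s, cut + 1, nchar(s)))
  og3$mask <- og3$mask[0, ]; og3$genes <- og3$genes[0, ]; og3$truth <- og3$truth[0, ]
  expect_equal(ancestral_presence(base, tr$chrom, tr$start, tr$end, og3),
               "unresolved")
})

test_that("simulated divergence recovers the generation and insertion rates", {
  base <- make_genome(1, 2000000, 0, 0.42, seed = 270)
  base <- plant_gene(base, n_exons = 3, exon_len = 350, intron_len = 400,
                     seed = 271)
  g_true <- 100000; mu <- 4.5e-9
  d <- diverge_assembly(base, g_true, mu = mu, private_retros = 2, seed = 272)
  snps <- subset(d$truth, kind == "snp")
  dv <- count_divergence(tibble::tibble(chrom = snps$chrom, pos = snps$start),
                         tibble::tibble(chrom = "chr1", start = 0L,
                                        end = chrom_sizes(d$assembly)[["chr1"]]))
  g_hat <- estimate_generations(dv$snp_count, dv$callable_bp, mu)
  expected_snps <- 2 * mu * g_true * dv$callable_bp
  sigma_g <- g_true / sqrt(expected_snps)
  expect_lt(abs(g_hat - g_true), 3 * sigma_g)
})
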