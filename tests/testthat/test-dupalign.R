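test_that("self-alignment recovers planted duplications and nothing else", {
  g <- make_genome(2, 120000, 0, 0.45, seed = 3)
  # clean genome: no pairs
  expect_equal(nrow(find_pairwise_duplications(g)), 0L)

  # one 5 kb dispersed copy at 2% divergence: exactly one pair
  g1 <- plant_duplication(g, "chr1", 20000, 25000, n_copies = 1,
                          divergence = 0.02, seed = 5)
  p1 <- find_pairwise_duplications(g1)
  expect_equal(nrow(p1), 1L)
  expect_gte(p1$identity, 0.97)
  expect_lte(p1$identity, 0.99)
  tr <- truth_records(g1)
  # both ends recover the planted intervals (exact-match extension may add a
  # base or two where the flanking sequence continues to agree by chance)
  expect_lte(abs(p1$start1 - tr$start[tr$role == "source"]), 2)
  expect_lte(abs(p1$end1 - tr$end[tr$role == "source"]), 2)
  # brute-force identity agrees with the reported one
  idy <- oracle_identity(seq_slice(g1, p1$chrom1, p1$start1, p1$end1),
                         seq_slice(g1, p1$chrom2, p1$start2, p1$end2))
  expect_equal(p1$identity, idy, tolerance = 1e-9)

  # a 900 bp copy is below the segmental-duplication floor
  g2 <- g
  src <- seq_slice(g2, "chr1", 40000, 40900)
  g2 <- retroscape:::asm_insert(g2, "chr2", 60000, src)
  expect_equal(nrow(find_pairwise_duplications(g2)), 0L)
})

test_that("planted duplications across divergences are all recovered with true identity", {
  for (dv in c(0.01, 0.03, 0.05)) {
    g <- make_genome(1, 60000, 0, 0.42, seed = round(1000 * dv))
    g <- plant_duplication(g, "chr1", 10000, 11500, n_copies = 1,
                           divergence = dv, seed = round(2000 * dv))
    p <- find_pairwise_duplications(g)
    expect_equal(nrow(p), 1L)
    expect_lt(abs(p$identity - (1 - dv)), 0.01)
  }
})

test_that("masked seeds cannot initiate alignments", {
  g <- make_genome(1, 80000, 0, 0.42, seed = 8)
  g <- plant_duplication(g, "chr1", 10000, 13000, n_copies = 1,
                         divergence = 0, seed = 9)
  tr <- truth_records(g)
  # mask both copies plus one seed length of flank: seeds start outside
  # masked intervals (soft-mask semantics), so nothing can initiate here
  g$mask <- tibble::tibble(chrom = tr$chrom,
                           start = pmax(0L, tr$start - 31L),
                           end = tr$end + 31L)
  expect_equal(nrow(find_pairwise_duplications(g)), 0L)
})

test_that("pair projections merge like a per-base bitmap union", {
  pairs <- tibble::tibble(
    chrom1 = "c1", start1 = c(100L, 1500L), end1 = c(2100L, 3500L),
    chrom2 = "c1", start2 = c(6000L, 8000L), end2 = c(8000L, 10000L),
    identity = 0.99, length = 2000L
  )
  m <- merge_duplicated_intervals(pairs)
  expect_equal(m$start[1], 100L)
  expect_equal(m$end[1], 3500L) # overlap merge
  expect_equal(m$end[2], 10000L) # book-ended merge

  expect_equal(nrow(merge_duplicated_intervals(retroscape:::empty_pairs())), 0L)

  # 10 random pairs: merged bp equals the bitmap union
  set.seed(77)
  rp <- tibble::tibble(
    chrom1 = sample(c("c1", "c2"), 10, replace = TRUE),
    start1 = sample.int(50000, 10), chrom2 = sample(c("c1", "c2"), 10,
                                                    replace = TRUE),
    start2 = sample.int(50000, 10)
  )
  rp$end1 <- rp$start1 + sample(1000:4000, 10)
  rp$end2 <- rp$start2 + sample(1000:4000, 10)
  rp$identity <- 0.95; rp$length <- rp$end1 - rp$start1
  mm <- merge_duplicated_intervals(rp)
  proj <- rbind(
    data.frame(chrom = rp$chrom1, start = rp$start1, end = rp$end1),
    data.frame(chrom = rp$chrom2, start = rp$start2, end = rp$end2)
  )
  expect_equal(sum(mm$end - mm$start),
               oracle_union_bp(proj, c(c1 = 60000, c2 = 60000)))
})

test_that("high-recurrence segments follow the rounding and counting rules", {
  expect_equal(round_to_hundred(2349), 2300)
  expect_equal(round_to_hundred(3175), 3200)
  expect_equal(round_to_hundred(250), 300) # half away from zero

  # 3 co-located short duplications: below the count threshold
  p3 <- tibble::tibble(
    chrom1 = "c1", start1 = c(10000L, 10020L, 9990L),
    end1 = c(11200L, 11210L, 11180L),
    chrom2 = "c1", start2 = c(30000L, 50000L, 70000L),
    end2 = c(31200L, 51190L, 71190L),
    identity = 0.95, length = 1200L
  )
  expect_equal(nrow(detect_high_recurrence(p3)), 0L)

  # retrocopies of one parent: each footprint collects >= 4 duplications
  g <- make_genome(1, 300000, 0, 0.42, seed = 2)
  g <- plant_gene(g, n_exons = 4, exon_len = 350, intron_len = 400, seed = 3)
  for (i in 1:5) {
    g <- plant_retrocopy(g, "gene1", tsd_len = 10, polya_len = 10,
                         seed = 10 + i)
  }
  p <- find_pairwise_duplications(g)
  expect_equal(nrow(p), 10L) # all copy-copy pairs
  hr <- detect_high_recurrence(p)
  expect_equal(nrow(hr), 5L)
  expect_true(all(hr$n_dups >= 4))
  # counts equal an exhaustive interval-stabbing oracle on rounded projections
  proj <- rbind(
    data.frame(pair = seq_len(nrow(p)), chrom = p$chrom1,
               start = round_to_hundred(p$start1),
               end = round_to_hundred(p$end1)),
    data.frame(pair = seq_len(nrow(p)), chrom = p$chrom2,
               start = round_to_hundred(p$start2),
               end = round_to_hundred(p$end2))
  )
  for (i in seq_len(nrow(hr))) {
    ids <- unique(proj$pair[proj$chrom == hr$chrom[i] &
                              proj$start < hr$end[i] & proj$end > hr$start[i]])
    expect_equal(hr$n_dups[i], length(ids))
  }
  # long duplications never enter
  expect_equal(nrow(detect_high_recurrence(p, max_len = 500)), 0L)
})

test_that("edge enrichment is calibrated under its own null", {
  sizes <- c(chrA = 10e6, chrB = 8e6)
  set.seed(99)
  ints <- tibble::tibble(
    chrom = sample(names(sizes), 200, replace = TRUE),
    start = NA_integer_
  )
  ints$start <- floor(runif(200) * (sizes[ints$chrom] - 5000))
  ints$end <- ints$start + 5000
  ee <- edge_enrichment(ints, sizes, n_perm = 200, seed = 7)
  expect_true(all(ee$fold >= 0.5 & ee$fold <= 2.0))

  # all intervals inside the first Mb
  ints2 <- tibble::tibble(chrom = "chrA",
                          start = as.integer(floor(runif(50) * 9e5)))
  ints2$end <- ints2$start + 1000L
  ee2 <- edge_enrichment(ints2, sizes["chrA"], n_perm = 100, seed = 8)
  expect_gt(ee2$fold[ee2$edge == "first"], 3)
  expect_equal(ee2$observed_frac[ee2$edge == "last"], 0)

  # seeded determinism
  ee3 <- edge_enrichment(ints, sizes, n_perm = 50, seed = 11)
  ee4 <- edge_enrichment(ints, sizes, n_perm = 50, seed = 11)
  expect_identical(ee3, ee4)

  # short chromosomes are skipped with a warning
  expect_warning(
    edge_enrichment(ints, c(sizes, chrC = 1e6), n_perm = 10, seed = 1),
    "skipping"
  )
})

test_that("self-alignment and read-depth comparison reports overlap correctly", {
  win <- tibble::tibble(chrom = "c1",
                        start = seq(1000000L, 1999000L, by = 1000L))
  win$end <- win$start + 1000L
  win$copy_number <- ifelse(win$start >= 1200000 & win$end <= 1260000, 4, 2)

  mkpairs <- function(s, e) {
    tibble::tibble(chrom1 = "c1", start1 = s, end1 = e,
                   chrom2 = "c1", start2 = s + 500000L, end2 = e + 500000L,
                   identity = 0.99, length = e - s)
  }
  # identical filtered sets: intersection equals union
  pairs <- mkpairs(1200000L, 1260000L)
  rd <- tibble::tibble(chrom = "c1",
                       start = c(1200000L, 1700000L),
                       end = c(1260000L, 1760000L),
                       n_windows = 60L, median_cn = 4)
  rep1 <- compare_with_readdepth(pairs, rd, win)
  expect_equal(rep1$both_bp, 120000)
  expect_equal(rep1$union_bp, 120000)
  expect_equal(rep1$selfalign_only_bp + rep1$readdepth_only_bp, 0)
  expect_equal(rep1$n_selfalign_supported, 1L) # CN 4 windows under the A end
  expect_equal(rep1$n_readdepth_supported, 2L)

  # disjoint sets: union adds, intersection empty
  rd2 <- tibble::tibble(chrom = "c1", start = 1400000L, end = 1430000L,
                        n_windows = 30L, median_cn = 3)
  pairs2 <- mkpairs(1200000L, 1220000L)
  rep2 <- compare_with_readdepth(pairs2, rd2, win)
  expect_equal(rep2$both_bp, 0)
  # both 20 kb pair projections plus the disjoint 30 kb read-depth region
  expect_equal(rep2$union_bp, 20000 + 20000 + 30000)

  # overlap bp equals a bitmap oracle on a random configuration
  set.seed(12)
  sa <- mkpairs(1100000L, 1160000L)
  rd3 <- tibble::tibble(chrom = "c1", start = 1130000L, end = 1190000L,
                        n_windows = 60L, median_cn = 3)
  rep3 <- compare_with_readdepth(sa, rd3, win)
  sizes <- c(c1 = 2100000)
  sa_int <- data.frame(chrom = c("c1", "c1"),
                       start = c(1100000, 1600000), end = c(1160000, 1660000))
  expect_equal(rep3$both_bp,
               oracle_intersect_bp(sa_int,
                                   data.frame(chrom = "c1", start = 1130000,
                                              end = 1190000), sizes))

  # filters: pairs below identity or length are dropped
  weak <- mkpairs(1200000L, 1260000L); weak$identity <- 0.92
  rep4 <- compare_with_readdepth(weak, rd, win)
  expect_equal(rep4$n_selfalign, 0L)
  short <- mkpairs(1200000L, 1210000L)
  rep5 <- compare_with_readdepth(short, rd, win)
  expect_equal(rep5$n_selfalign, 0L)
})

test_that("merge is idempotent and canonical ordering dedupes symmetric pairs", {
  g <- make_genome(1, 80000, 0, 0.42, seed = 51)
  g <- plant_duplication(g, "chr1", 10000, 12000, n_copies = 2,
                         divergence = 0.01, seed = 52)
  p <- find_pairwise_duplications(g)
  # canonical ordering: A lexicographically <= B
  expect_true(all(p$chrom1 < p$chrom2 |
                    (p$chrom1 == p$chrom2 & p$start1 <= p$start2)))
  m1 <- merge_duplicated_intervals(p)
  # re-merging the merged intervals is a no-op
  fake <- tibble::tibble(chrom1 = m1$chrom, start1 = m1$start, end1 = m1$end,
                         chrom2 = m1$chrom, start2 = m1$start, end2 = m1$end,
                         identity = 1, length = m1$end - m1$start)
  m2 <- merge_duplicated_intervals(fake)
  expect_equal(m2[, c("chrom", "start", "end")],
               m1[, c("chrom", "start", "end")])
})
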