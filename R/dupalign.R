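#' Find pairwise segmental duplications by genome self-alignment
#'
#' A light-weight self-alignment: exact k-mer seeds (seeds never start inside
#' masked intervals), chained along shared diagonals, extended outwards by
#' mismatch-tolerant X-drop extension. Emitted pairs satisfy the segmental-duplication
#' contract: both intervals at least `min_len` bp, identity (matches over
#' matches plus mismatches, gap-free) at least `min_identity`, mitochondrial
#' sequences excluded, and each pair stored once with interval A
#' lexicographically before interval B.
#'
#' @param asm A [genome_assembly()].
#' @param min_len Minimum duplication length in bp.
#' @param min_identity Minimum sequence identity (fraction).
#' @param k Seed k-mer size.
#' @param max_gap Maximum seed gap along a diagonal before a chain is split.
#' @param max_occ Seeds occurring more than this many times are skipped.
#' @param mito Name of the mitochondrial sequence to exclude.
#' @return Tibble with `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`,
#'   `identity`, `length`, one row per duplication pair.
#' @export
find_pairwise_duplications <- function(asm, min_len = 1000, min_identity = 0.90,
                                       k = 31, max_gap = 500, max_occ = 64,
                                       mito = "chrM") {
  if (length(asm$seq) == 0) abort("empty assembly")
  keep <- setdiff(names(asm$seq), mito)
  if (length(keep) == 0) abort("no non-mitochondrial sequences")
  seqs <- asm$seq[keep]
  mask_starts <- lapply(keep, function(cc) {
    as.integer(asm$mask$start[asm$mask$chrom == cc])
  })
  mask_ends <- lapply(keep, function(cc) {
    as.integer(asm$mask$end[asm$mask$chrom == cc])
  })
  seeds <- cpp_self_seed_pairs(unname(seqs), as.integer(k), as.integer(max_occ),
                               mask_starts, mask_ends)
  if (nrow(seeds) == 0) return(empty_pairs())
  seeds <- as_tibble(seeds) |>
    filter(!(.data$chrom1 == .data$chrom2 & .data$pos1 == .data$pos2)) |>
    mutate(diag = .data$pos2 - .data$pos1)

  chains <- seeds |>
    arrange(.data$chrom1, .data$chrom2, .data$diag, .data$pos1) |>
    group_by(.data$chrom1, .data$chrom2, .data$diag) |>
    mutate(chain = cumsum(c(0L, diff(.data$pos1)) > max_gap)) |>
    group_by(.data$chrom1, .data$chrom2, .data$diag, .data$chain) |>
    summarise(s1 = min(.data$pos1), e1 = max(.data$pos1) + k,
              n_seeds = n(), .groups = "drop") |>
    filter(!(.data$chrom1 == .data$chrom2 & .data$diag == 0))

  if (nrow(chains) == 0) return(empty_pairs())
  out <- purrr::pmap_dfr(chains, function(chrom1, chrom2, diag, chain, s1, e1,
                                          n_seeds) {
    c1 <- keep[chrom1]; c2 <- keep[chrom2]
    s2 <- s1 + diag; e2 <- e1 + diag
    ext <- extend_homology(seqs[[chrom1]], seqs[[chrom2]], s1, e1, s2, e2)
    len <- ext$xe - ext$xs
    if (len < min_len) return(NULL)
    idy <- hamming_identity(seq_slice(asm, c1, ext$xs, ext$xe),
                            seq_slice(asm, c2, ext$ys, ext$ye))
    if (is.na(idy) || idy < min_identity) return(NULL)
    tibble(chrom1 = c1, start1 = ext$xs, end1 = ext$xe,
           chrom2 = c2, start2 = ext$ys, end2 = ext$ye,
           identity = idy, length = len)
  })
  if (nrow(out) == 0) return(empty_pairs())
  # canonical A <= B ordering, then dedupe
  flip <- out$chrom1 > out$chrom2 |
    (out$chrom1 == out$chrom2 & out$start1 > out$start2)
  out[flip, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")] <-
    out[flip, c("chrom2", "start2", "end2", "chrom1", "start1", "end1")]
  out |>
    distinct(.data$chrom1, .data$start1, .data$end1,
             .data$chrom2, .data$start2, .data$end2, .keep_all = TRUE) |>
    arrange(.data$chrom1, .data$start1, .data$chrom2, .data$start2)
}

empty_pairs <- function() {
  tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
         chrom2 = character(), start2 = integer(), end2 = integer(),
         identity = double(), length = integer())
}

# both projections (A and B ends) of each pair as plain intervals
project_pairs <- function(pairs) {
  bind_rows(
    pairs |> transmute(pair = row_number(), chrom = .data$chrom1,
                       start = .data$start1, end = .data$end1),
    pairs |> transmute(pair = row_number(), chrom = .data$chrom2,
                       start = .data$start2, end = .data$end2)
  )
}

#' Merge duplication pairs into a nonredundant set of duplicated intervals
#'
#' Projects both ends of every pair onto the genome, merges overlapping or
#' book-ended projections per chromosome, and partitions the result into
#' assembled versus unplaced sequences.
#'
#' @param pairs Pair tibble from [find_pairwise_duplications()].
#' @param assembled Character vector of assembled chromosome names; everything
#'   else is treated as unplaced. Default: all chromosomes present.
#' @return Tibble with `partition`, `chrom`, `start`, `end`, `n_pairs` (number
#'   of contributing pairwise records) and an attached `duplicated_bp` summary
#'   (attribute) of total merged bp per partition.
#' @export
merge_duplicated_intervals <- function(pairs, assembled = NULL) {
  proj <- project_pairs(pairs)
  assembled <- assembled %||% unique(proj$chrom)
  merged <- reduce_intervals(proj) |>
    mutate(partition = ifelse(.data$chrom %in% assembled, "assembled", "unplaced"))
  if (nrow(merged) > 0) {
    merged$n_pairs <- vapply(seq_len(nrow(merged)), function(i) {
      hits <- proj$chrom == merged$chrom[i] &
        proj$start < merged$end[i] & proj$end > merged$start[i]
      length(unique(proj$pair[hits]))
    }, integer(1))
  } else {
    merged$n_pairs <- integer()
  }
  out <- merged |> select("partition", "chrom", "start", "end", "n_pairs")
  attr(out, "duplicated_bp") <- out |>
    group_by(.data$partition) |>
    summarise(bp = sum(as.numeric(.data$end - .data$start)), .groups = "drop")
  out
}

#' Round a coordinate to the nearest hundred
#'
#' Half-way values round away from zero: 2,349 becomes 2,300 and 3,175
#' becomes 3,200.
#'
#' @param x Numeric coordinates.
#' @return Rounded coordinates.
#' @export
round_to_hundred <- function(x) {
  floor(x / 100 + 0.5) * 100
}

#' Detect short high-recurrence duplication segments
#'
#' Restricts to duplications shorter than `max_len`, rounds each projected
#' interval to the nearest hundred, merges the rounded intervals into
#' segments, counts the distinct pairwise duplications overlapping each
#' segment, and keeps segments with at least `min_count` of them. Such
#' segments are diagnostic of loci aligned to many paralogous copies --
#' typically retrocopies of a shared parent gene.
#'
#' @param pairs Pair tibble from [find_pairwise_duplications()].
#' @param max_len Only duplications strictly shorter than this enter.
#' @param min_count Minimum overlapping-duplication count.
#' @return Tibble with `chrom`, `start`, `end` (rounded coordinates) and
#'   `n_dups`.
#' @export
detect_high_recurrence <- function(pairs, max_len = 2500, min_count = 4) {
  small <- pairs |> filter(.data$length < max_len)
  if (nrow(small) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_dups = integer()))
  }
  proj <- project_pairs(small) |>
    mutate(start = as.integer(round_to_hundred(.data$start)),
           end = as.integer(round_to_hundred(.data$end))) |>
    filter(.data$end > .data$start)
  segs <- reduce_intervals(proj)
  if (nrow(segs) == 0) return(tibble(chrom = character(), start = integer(),
                                     end = integer(), n_dups = integer()))
  segs$n_dups <- vapply(seq_len(nrow(segs)), function(i) {
    hits <- proj$chrom == segs$chrom[i] &
      proj$start < segs$end[i] & proj$end > segs$start[i]
    length(unique(proj$pair[hits]))
  }, integer(1))
  segs |> filter(.data$n_dups >= min_count)
}

#' Permutation test for duplication enrichment at chromosome ends
#'
#' Compares the observed fraction of duplicated intervals overlapping the
#' first and last `edge` bp of each chromosome against `n_perm` random
#' re-placements (uniform within the same chromosome, preserving interval
#' length, avoiding the mask when one is supplied).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param edge Edge width in bp (default 1 Mb).
#' @param n_perm Number of permutations.
#' @param mask Optional mask tibble to exclude from random placements.
#' @param seed Optional integer seed.
#' @return Tibble with one row per edge (`first`, `last`): observed count and
#'   fraction, permutation mean and max fraction, and fold enrichment
#'   (observed / permutation mean).
#' @export
edge_enrichment <- function(intervals, chrom_sizes, edge = 1e6, n_perm = 1000,
                            mask = NULL, seed = NULL) {
  usable <- names(chrom_sizes)[chrom_sizes >= 2 * edge]
  skipped <- setdiff(names(chrom_sizes), usable)
  if (length(skipped) > 0) {
    warn(paste("skipping chromosomes shorter than twice the edge:",
               paste(skipped, collapse = ", ")))
  }
  ints <- intervals |> filter(.data$chrom %in% usable)
  if (nrow(ints) == 0) abort("no intervals on usable chromosomes")
  sizes <- chrom_sizes[usable]

  edge_frac <- function(df) {
    first_hit <- df$start < edge
    last_hit <- df$end > sizes[df$chrom] - edge
    c(first = mean(first_hit), last = mean(last_hit))
  }
  obs <- edge_frac(ints)

  obs_count <- c(sum(ints$start < edge),
                 sum(ints$end > sizes[ints$chrom] - edge))
  with_seed_opt(seed, {
    perm <- replicate(n_perm, {
      shuf <- shuffle_intervals(ints, sizes, mask)
      edge_frac(shuf)
    })
    tibble(
      edge = c("first", "last"),
      n_intervals = nrow(ints),
      observed_count = obs_count,
      observed_frac = as.numeric(obs),
      perm_mean_frac = c(mean(perm["first", ]), mean(perm["last", ])),
      perm_max_frac = c(max(perm["first", ]), max(perm["last", ])),
      fold = .data$observed_frac / .data$perm_mean_frac
    )
  })
}

# uniform re-placement of intervals within their chromosome, length preserved
shuffle_intervals <- function(ints, sizes, mask = NULL, max_tries = 50) {
  len <- ints$end - ints$start
  hi <- sizes[ints$chrom] - len
  start <- floor(runif(nrow(ints)) * (hi + 1))
  if (!is.null(mask) && nrow(mask) > 0) {
    cand <- tibble(chrom = ints$chrom, start = start, end = start + len)
    bad <- overlaps_any(cand, mask)
    tries <- 0
    while (any(bad) && tries < max_tries) {
      tries <- tries + 1
      start[bad] <- floor(runif(sum(bad)) * (hi[bad] + 1))
      cand$start <- start; cand$end <- start + len
      bad <- overlaps_any(cand, mask)
    }
  }
  tibble(chrom = ints$chrom, start = start, end = start + len)
}

#' Compare self-alignment and read-depth duplication calls
#'
#' Both call sets are filtered the same way before comparison: assembled
#' chromosomes only, span greater than `min_len`, self-alignment pairs at
#' `min_identity` or above, and (optionally) outside the first megabase of
#' each chromosome. Reports base-pair overlap of the two sets and per-set
#' support: a self-alignment interval is supported when the median copy
#' number of its intersecting windows is at least 2.5; a read-depth region is
#' supported when it overlaps any self-alignment interval.
#'
#' @param pairs Self-alignment pairs ([find_pairwise_duplications()]).
#' @param rd_regions Read-depth regions ([call_duplicated_regions()]).
#' @param windows Copy-number windows ([estimate_copy_number()]).
#' @param min_len Minimum span (bp) after merging.
#' @param min_identity Minimum pair identity for the self-alignment set.
#' @param exclude_first_mb Drop calls overlapping the first Mb of a chromosome.
#' @param assembled Character vector of assembled chromosome names.
#' @return One-row tibble: filtered counts, union/intersection/unique bp, the
#'   fraction duplicated in both, and support counts for each method.
#' @export
compare_with_readdepth <- function(pairs, rd_regions, windows,
                                   min_len = 15000, min_identity = 0.95,
                                   exclude_first_mb = TRUE, assembled = NULL) {
  assembled <- assembled %||%
    union(unique(c(pairs$chrom1, pairs$chrom2)), unique(rd_regions$chrom))
  if (nrow(rd_regions) > 0 && !all(rd_regions$chrom %in% assembled) &&
      !any(rd_regions$chrom %in% unique(c(pairs$chrom1, pairs$chrom2)))) {
    abort("self-alignment and read-depth sets share no chromosome names")
  }
  sa <- pairs |>
    filter(.data$identity >= min_identity,
           .data$chrom1 %in% assembled, .data$chrom2 %in% assembled)
  sa_int <- reduce_intervals(project_pairs(sa)) |>
    filter(.data$end - .data$start > min_len)
  rd <- rd_regions |>
    filter(.data$chrom %in% assembled, .data$end - .data$start > min_len)
  if (exclude_first_mb) {
    sa_int <- sa_int |> filter(.data$start >= 1e6)
    rd <- rd |> filter(.data$start >= 1e6)
  }
  both <- intersect_intervals(sa_int, rd)
  union_bp <- total_bp(bind_rows(sa_int |> select("chrom", "start", "end"),
                                 rd |> select("chrom", "start", "end")))
  both_bp <- total_bp(both)

  sa_support <- vapply(seq_len(nrow(sa_int)), function(i) {
    w <- windows |> filter(.data$chrom == sa_int$chrom[i],
                           .data$start < sa_int$end[i],
                           .data$end > sa_int$start[i])
    nrow(w) > 0 && median(w$copy_number) >= 2.5
  }, logical(1))
  rd_support <- if (nrow(rd) == 0) logical() else {
    overlaps_any(rd, sa_int)
  }

  tibble(
    n_selfalign = nrow(sa_int), n_readdepth = nrow(rd),
    union_bp = union_bp, both_bp = both_bp,
    selfalign_only_bp = total_bp(sa_int) - both_bp,
    readdepth_only_bp = total_bp(rd |> select("chrom", "start", "end")) - both_bp,
    frac_both = ifelse(union_bp > 0, both_bp / union_bp, NA_real_),
    n_selfalign_supported = sum(sa_support),
    n_readdepth_supported = sum(rd_support)
  )
}
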