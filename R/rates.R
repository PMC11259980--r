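#' Map a query sequence onto an assembly
#'
#' Seed-and-chain placement of a query (e.g. a retrocopy flank) on both
#' strands of an assembly, reporting chained hits with identity and query
#' coverage. Used by the presence/absence machinery.
#'
#' @param query Query sequence.
#' @param asm A [genome_assembly()].
#' @param k Seed size.
#' @param max_occ Over-representation threshold for genome k-mers.
#' @param max_gap Maximum seed gap along a diagonal.
#' @return Tibble of placements: `chrom`, `strand`, `tstart`, `tend`,
#'   `qstart`, `qend`, `identity`, `coverage`, sorted by descending coverage
#'   then identity.
#' @export
map_sequence <- function(query, asm, k = 15, max_occ = 16, max_gap = 200) {
  blocks <- align_cdna(query, asm, k = k, max_occ = max_occ,
                       max_gap = max_gap, min_seeds = 1)
  if (nrow(blocks) == 0) return(mutate(empty_blocks(), coverage = double()))
  blocks |>
    mutate(coverage = (.data$qend - .data$qstart) / nchar(query)) |>
    arrange(desc(.data$coverage), desc(.data$identity))
}

# unique, confident placement of a flank: >= min_identity over >= min_cov of
# the flank, and no second placement of comparable coverage elsewhere
map_flank_unique <- function(flank, asm, min_identity = 0.90, min_cov = 0.80,
                             ...) {
  hits <- map_sequence(flank, asm, ...)
  good <- hits |> filter(.data$identity >= min_identity,
                         .data$coverage >= min_cov)
  if (nrow(good) == 0) return(NULL)
  if (nrow(good) > 1) {
    second <- good[2, ]
    first <- good[1, ]
    distinct_site <- second$chrom != first$chrom ||
      second$tstart > first$tend + 100 || second$tend < first$tstart - 100
    if (distinct_site) return(NULL) # ambiguous placement
  }
  good[1, ]
}

#' Assess presence of a retrocopy locus in another assembly
#'
#' Extracts `flank` bp on each side of the locus from the donor assembly and
#' maps both flanks to the target. Both flanks must place uniquely on one
#' chromosome, in consistent orientation and order, with a spacing of at
#' most twice the donor span; otherwise the locus is `unresolved`. The gap
#' between the mapped flanks is then tested against the donor insert: a gap
#' carrying the insert sequence is `shared`, flanks joined without the
#' insert are `absent`, anything else is `unresolved`.
#'
#' @param donor A [genome_assembly()] carrying the locus.
#' @param chrom,start,end Locus coordinates in the donor.
#' @param target A [genome_assembly()] to test.
#' @param flank Flank width in bp.
#' @param min_identity,min_cov Flank mapping thresholds.
#' @return One of `"shared"`, `"absent"`, `"unresolved"`.
#' @export
assess_presence <- function(donor, chrom, start, end, target, flank = 500,
                            min_identity = 0.90, min_cov = 0.80) {
  sizes <- chrom_sizes(donor)
  if (start - flank < 0 || end + flank > sizes[[chrom]]) return("unresolved")
  up <- seq_slice(donor, chrom, start - flank, start)
  dn <- seq_slice(donor, chrom, end, end + flank)
  hu <- map_flank_unique(up, target, min_identity, min_cov)
  hd <- map_flank_unique(dn, target, min_identity, min_cov)
  if (is.null(hu) || is.null(hd)) return("unresolved")
  if (hu$chrom != hd$chrom || hu$strand != hd$strand) return("unresolved")
  L <- end - start
  if (hu$strand == "+") {
    gap <- hd$tstart - hu$tend
  } else {
    gap <- hu$tstart - hd$tend
  }
  span_limit <- 2 * (L + 2 * flank)
  if (gap < -20 || gap > span_limit) return("unresolved")
  gap <- max(gap, 0)
  if (gap <= max(60, 0.25 * L)) return("absent")
  if (gap < 0.5 * L) return("unresolved")
  # candidate intervening sequence must carry the insert
  inner <- if (hu$strand == "+") {
    seq_slice(target, hu$chrom, hu$tend, hd$tstart)
  } else {
    revcomp(seq_slice(target, hu$chrom, hd$tend, hu$tstart))
  }
  insert <- seq_slice(donor, chrom, start, end)
  tiny <- genome_assembly(c(site = inner))
  m <- map_sequence(insert, tiny, k = 15, max_occ = 32)
  ok <- nrow(m) > 0 && m$coverage[1] >= 0.75 && m$identity[1] >= 0.90
  if (ok) "shared" else "unresolved"
}

#' Build a presence/absence matrix of retrocopy loci across assemblies
#'
#' Loci from all assemblies are unified by flank anchoring onto the
#' highest-priority assembly where their flanks place; each unified locus is
#' then re-sourced from the highest-priority assembly carrying it and tested
#' in every assembly with [assess_presence()]. Loci with any unresolved cell
#' are discounted from the pattern counts.
#'
#' @param assemblies Named list of [genome_assembly()] objects.
#' @param loci Tibble with `assembly`, `chrom`, `start`, `end` (one row per
#'   per-assembly retrocopy call).
#' @param priority Assembly names in re-sourcing priority order (default:
#'   the order of `assemblies`).
#' @param flank Flank width for presence testing.
#' @param anchor_tol Anchor distance (bp) within which two per-assembly loci
#'   are treated as the same event.
#' @return List with `matrix` (tibble: locus, anchor position, one status
#'   column per assembly, `resolved`) and `patterns` (tibble of
#'   presence-pattern counts over fully resolved loci).
#' @export
build_presence_matrix <- function(assemblies, loci, priority = names(assemblies),
                                  flank = 500, anchor_tol = 100) {
  stopifnot(!is.null(names(assemblies)))
  ref_name <- priority[1]
  ref <- assemblies[[ref_name]]

  anchored <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    row <- loci[i, ]
    donor <- assemblies[[row$assembly]]
    if (row$assembly == ref_name) {
      # anchor at the locus start, matching the mapped up-flank end used for
      # loci anchored from other assemblies
      return(mutate(row, anchor_chrom = row$chrom,
                    anchor_pos = as.numeric(row$start)))
    }
    up <- seq_slice(donor, row$chrom, row$start - flank, row$start)
    hu <- map_flank_unique(up, ref)
    if (is.null(hu)) {
      return(mutate(row, anchor_chrom = NA_character_, anchor_pos = NA_real_))
    }
    mutate(row, anchor_chrom = hu$chrom,
           anchor_pos = as.numeric(if (hu$strand == "+") hu$tend else hu$tstart))
  })
  anchored <- anchored |> filter(!is.na(.data$anchor_pos))
  if (nrow(anchored) == 0) abort("no locus could be anchored")

  # cluster anchors within anchor_tol on one reference chromosome
  anchored <- anchored |>
    arrange(.data$anchor_chrom, .data$anchor_pos) |>
    group_by(.data$anchor_chrom) |>
    mutate(cluster = cumsum(c(1, diff(.data$anchor_pos) > anchor_tol))) |>
    ungroup() |>
    mutate(locus = paste0(.data$anchor_chrom, "_", .data$cluster))

  cells <- purrr::map_dfr(unique(anchored$locus), function(lc) {
    members <- anchored |> filter(.data$locus == lc)
    src_name <- priority[priority %in% members$assembly][1]
    src_row <- members |> filter(.data$assembly == src_name) |> slice(1)
    donor <- assemblies[[src_name]]
    status <- vapply(names(assemblies), function(an) {
      if (an == src_name) return("shared")
      assess_presence(donor, src_row$chrom, src_row$start, src_row$end,
                      assemblies[[an]], flank = flank)
    }, "")
    tibble(locus = lc, assembly = names(assemblies), status = status,
           anchor_chrom = src_row$anchor_chrom,
           anchor_pos = src_row$anchor_pos)
  })

  wide <- cells |>
    select("locus", "anchor_chrom", "anchor_pos", "assembly", "status") |>
    tidyr::pivot_wider(names_from = "assembly", values_from = "status") |>
    mutate(resolved = !purrr::pmap_lgl(
      across(all_of(names(assemblies))), function(...) any(c(...) == "unresolved")
    ))
  patterns <- wide |>
    filter(.data$resolved) |>
    mutate(pattern = purrr::pmap_chr(
      across(all_of(names(assemblies))),
      function(...) paste(ifelse(c(...) == "shared", "1", "0"), collapse = "")
    )) |>
    count(.data$pattern, name = "n_loci") |>
    arrange(desc(.data$n_loci))
  list(matrix = wide, patterns = patterns)
}

#' Count filtered SNP divergence and callable genome size
#'
#' @param snps Tibble of variants with `chrom`, `pos` (0-based).
#' @param called_regions Tibble of intervals where the assembly comparison
#'   made calls.
#' @param exclusions List (or single tibble) of interval sets to remove:
#'   read-depth duplications, self-alignment duplications, tandem repeats.
#' @return One-row tibble: `snp_count`, `callable_bp`.
#' @export
count_divergence <- function(snps, called_regions, exclusions = list()) {
  if (is.data.frame(exclusions)) exclusions <- list(exclusions)
  excl <- if (length(exclusions)) {
    bind_rows(lapply(exclusions, function(d) select(d, "chrom", "start", "end")))
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  callable <- setdiff_intervals(called_regions, excl)
  inside <- overlaps_any(
    tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1L),
    callable
  )
  tibble(snp_count = sum(inside), callable_bp = total_bp(callable))
}

#' Generations since divergence from SNP counts
#'
#' Two lineages diverging for g generations accumulate `2 * mu * g`
#' substitutions per base pair, so `g = SNPs / (2 * size * mu)`, reported
#' rounded to the nearest generation.
#'
#' @param snps Autosomal SNP count between the two assemblies (after
#'   duplication and tandem-repeat filtering).
#' @param size Callable autosomal genome size in bp.
#' @param mu Single-nucleotide mutation rate per bp per generation.
#' @return Estimated generations (rounded).
#' @export
estimate_generations <- function(snps, size, mu) {
  if (size <= 0 || mu <= 0) abort("size and mu must be positive")
  if (snps < 0) abort("snps must be non-negative")
  round(0.5 * snps / (size * mu))
}

#' Estimate the retrocopy insertion rate per generation
#'
#' The rate is the mean count of lineage-private retrocopies divided by the
#' generations since divergence, reported to `sigfigs` significant figures;
#' births per insertion is the reciprocal of the rounded rate. When `snps`
#' and `size` are supplied, the generation count and rate are recomputed at
#' the lower and upper mutation-rate bounds.
#'
#' @param unique_a,unique_b Retrocopies private to each assembly.
#' @param generations Point estimate of generations since divergence.
#' @param mu_bounds Length-2 vector: lower and upper mutation rate.
#' @param snps,size Inputs for recomputing generations at the bounds.
#' @param sigfigs Significant figures for the reported rate.
#' @return A `rate_estimate` object; see [tidy.rate_estimate()].
#' @export
estimate_rate <- function(unique_a, unique_b, generations,
                          mu_bounds = c(2.6e-9, 7.1e-9),
                          snps = NULL, size = NULL, sigfigs = 3) {
  if (generations <= 0) abort("generations must be positive")
  mean_unique <- mean(c(unique_a, unique_b))
  rate <- signif(mean_unique / generations, sigfigs)
  births <- if (rate > 0) round(1 / rate) else Inf
  bounds <- NULL
  if (!is.null(snps) && !is.null(size)) {
    g_hi_mu <- estimate_generations(snps, size, mu_bounds[2]) # fewer generations
    g_lo_mu <- estimate_generations(snps, size, mu_bounds[1])
    r_low <- signif(mean_unique / g_lo_mu, sigfigs)
    r_high <- signif(mean_unique / g_hi_mu, sigfigs)
    bounds <- list(
      generations_low = g_hi_mu, generations_high = g_lo_mu,
      rate_low = r_low, rate_high = r_high,
      births_low = round(1 / r_high), births_high = round(1 / r_low)
    )
  }
  structure(
    list(unique_a = unique_a, unique_b = unique_b, mean_unique = mean_unique,
         generations = generations, rate = rate, births = births,
         mu_bounds = mu_bounds, snps = snps, size = size, sigfigs = sigfigs,
         bounds = bounds),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Retrocopy insertion rate\n")
  cat(sprintf("  private retrocopies: %d and %d (mean %.1f)\n",
              x$unique_a, x$unique_b, x$mean_unique))
  cat(sprintf("  generations since divergence: %s\n",
              format(x$generations, big.mark = ",")))
  cat(sprintf("  rate: %.3g per generation (~1 in %s births)\n",
              x$rate, format(x$births, big.mark = ",")))
  if (!is.null(x$bounds)) {
    cat(sprintf("  mutation-rate bounds: rate %.3g to %.3g (1/%s to 1/%s births)\n",
                x$bounds$rate_low, x$bounds$rate_high,
                format(x$bounds$births_low, big.mark = ","),
                format(x$bounds$births_high, big.mark = ",")))
  }
  invisible(x)
}

#' Tidy a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble mirroring the published rate-table columns:
#'   private counts, generations (point and range), insertion rate (point
#'   and range) and births per insertion.
#' @export
tidy.rate_estimate <- function(x, ...) {
  out <- tibble(
    unique_a = x$unique_a, unique_b = x$unique_b,
    generations = x$generations, rate = x$rate, births = x$births
  )
  if (!is.null(x$bounds)) {
    out <- out |> mutate(
      generations_low = x$bounds$generations_low,
      generations_high = x$bounds$generations_high,
      rate_low = x$bounds$rate_low, rate_high = x$bounds$rate_high,
      births_low = x$bounds$births_low, births_high = x$bounds$births_high
    )
  }
  out
}

#' Glance at a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with `rate`, `births`, `generations`.
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble(rate = x$rate, births = x$births, generations = x$generations)
}

#' Assess ancestral presence of a retrocopy in an outgroup assembly
#'
#' Both 1 kb flanks must place on a single outgroup contig; the intervening
#' outgroup sequence must be at least 75% of the retrocopy length and must
#' map back over the original locus in the focal assembly. Flanks mapped
#' with intervening sequence failing the length test give `absent`;
#' anything else that cannot be anchored is `unresolved`.
#'
#' @param focal A [genome_assembly()] carrying the retrocopy.
#' @param chrom,start,end Locus coordinates in the focal assembly.
#' @param outgroup A [genome_assembly()] of the outgroup.
#' @param flank Flank width (bp).
#' @param min_size_frac Minimum intervening/retrocopy length ratio.
#' @return One of `"present"`, `"absent"`, `"unresolved"`.
#' @export
ancestral_presence <- function(focal, chrom, start, end, outgroup,
                               flank = 1000, min_size_frac = 0.75) {
  sizes <- chrom_sizes(focal)
  if (start - flank < 0 || end + flank > sizes[[chrom]]) return("unresolved")
  up <- seq_slice(focal, chrom, start - flank, start)
  dn <- seq_slice(focal, chrom, end, end + flank)
  hu <- map_flank_unique(up, outgroup)
  hd <- map_flank_unique(dn, outgroup)
  if (is.null(hu) || is.null(hd)) return("unresolved")
  if (hu$chrom != hd$chrom || hu$strand != hd$strand) return("unresolved")
  L <- end - start
  gap <- if (hu$strand == "+") hd$tstart - hu$tend else hu$tstart - hd$tend
  if (gap < 0) return("unresolved")
  if (gap < min_size_frac * L) return("absent")
  inner <- if (hu$strand == "+") {
    seq_slice(outgroup, hu$chrom, hu$tend, hd$tstart)
  } else {
    revcomp(seq_slice(outgroup, hu$chrom, hd$tend, hu$tstart))
  }
  # map-back requirement: the candidate must land over the original locus
  mb <- map_sequence(inner, focal)
  if (nrow(mb) == 0) return("unresolved")
  top <- mb[1, ]
  over <- top$chrom == chrom && top$tstart < end && top$tend > start
  if (over) "present" else "unresolved"
}
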