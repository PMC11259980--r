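#' Prepare retrocopy loci for hallmark detection
#'
#' Excludes loci composed of multiple alignment segments, loci within 100 bp
#' of a chromosome end, and loci within 100 bp of an N gap, then extracts
#' symmetric `flank` bp of sequence upstream and downstream of each
#' remaining locus.
#'
#' @param calls Retrocopy calls ([find_retrocopies()]); needs `locus_id`,
#'   `chrom`, `start`, `end`, `strand`, `segments`.
#' @param asm A [genome_assembly()].
#' @param flank Flank width in bp.
#' @param gap_margin Exclusion distance from N gaps and chromosome ends.
#' @return `calls` with `excluded` (reason or NA), `up_seq` and `down_seq`.
#' @export
prepare_loci <- function(calls, asm, flank = 60, gap_margin = 100) {
  sizes <- chrom_sizes(asm)
  out <- calls
  out$excluded <- NA_character_
  out$up_seq <- NA_character_
  out$down_seq <- NA_character_
  for (i in seq_len(nrow(out))) {
    cc <- out$chrom[i]; s <- out$start[i]; e <- out$end[i]
    if (!is.na(out$segments[i]) && out$segments[i] > 1) {
      out$excluded[i] <- "multi_segment"
    } else if (s < gap_margin || e > sizes[[cc]] - gap_margin) {
      out$excluded[i] <- "chromosome_end"
    } else if (grepl("N", seq_slice(asm, cc, s - gap_margin, e + gap_margin),
                     fixed = TRUE)) {
      out$excluded[i] <- "near_gap"
    } else {
      out$up_seq[i] <- seq_slice(asm, cc, s - flank, s)
      out$down_seq[i] <- seq_slice(asm, cc, e, e + flank)
    }
  }
  out
}

#' Detect a target-site duplication between insertion flanks
#'
#' Best-scoring local alignment of the upstream against the downstream flank
#' under the hallmark scoring scheme: +2 per match, -6 per mismatch, -1000
#' for any column involving N (which eliminates N-containing alignments),
#' gap opening and extension penalties of 10. Alignments shorter than
#' `min_len` columns are reported absent. Ties are broken by the smallest
#' upstream start, then the smallest downstream start.
#'
#' @param up_flank,down_flank Flank sequences (plus strand, upstream first).
#' @param min_len Minimum alignment length (columns).
#' @param match,mismatch,gap_open,gap_ext,n_pen Scoring parameters.
#' @return One-row tibble: `found`, `length`, `score`, 0-based half-open
#'   offsets of the aligned copies within each flank (`up_start`, `up_end`,
#'   `down_start`, `down_end`), the TSD `seq` (upstream copy), and edge flags
#'   `at_up_edge`/`at_down_edge` (alignment within 5 bp of the outer flank
#'   boundaries, the trigger for flank re-extension).
#' @export
detect_tsd <- function(up_flank, down_flank, min_len = 5, match = 2,
                       mismatch = -6, gap_open = 10, gap_ext = 10,
                       n_pen = -1000) {
  if (nchar(up_flank) == 0 || nchar(down_flank) == 0) {
    abort("flanks must be non-empty")
  }
  aln <- cpp_sw_affine(up_flank, down_flank, match, mismatch,
                       gap_open, gap_ext, n_pen)
  absent <- tibble(found = FALSE, length = 0L, score = 0,
                   up_start = NA_integer_, up_end = NA_integer_,
                   down_start = NA_integer_, down_end = NA_integer_,
                   seq = NA_character_, at_up_edge = FALSE,
                   at_down_edge = FALSE)
  if (aln$score <= 0 || aln$columns < min_len) return(absent)
  seq <- substr(up_flank, aln$a_start, aln$a_end)
  if (grepl("N", seq, fixed = TRUE)) return(absent)
  tibble(
    found = TRUE, length = as.integer(aln$columns), score = aln$score,
    up_start = aln$a_start - 1L, up_end = aln$a_end,
    down_start = aln$b_start - 1L, down_end = aln$b_end,
    seq = seq,
    at_up_edge = aln$a_start <= 5,
    at_down_edge = aln$b_end >= nchar(down_flank) - 4
  )
}

#' Detect a poly(A) tail in the region beyond a retrocopy 3' end
#'
#' Scans the reference-strand region left to right for runs of the
#' homopolymer base (A for a plus-orientation retrocopy, T for minus). A run
#' absorbs a non-homopolymeric base when at least 4 of the following 5 bases
#' are homopolymeric; it is then trimmed until it starts and ends with 3
#' homopolymeric bases in a row. Runs are never extended into the TSD
#' footprint. Among candidates of at least `min_len` bp, the one closest to
#' the TSD is reported (closest to the retrocopy side when no TSD exists).
#'
#' @param region Reference-strand sequence beyond the annotated 3' end.
#' @param orientation Retrocopy orientation, `"+"` or `"-"`.
#' @param tsd Optional 0-based half-open interval `c(start, end)` of the TSD
#'   footprint within `region`.
#' @param retro_side Which side of `region` touches the retrocopy (`"left"`
#'   for plus orientation, `"right"` for minus).
#' @param min_len Minimum reported run length.
#' @return One-row tibble: `found`, `start`, `end` (0-based half-open within
#'   `region`), `length`.
#' @export
detect_polya <- function(region, orientation, tsd = NULL,
                         retro_side = if (orientation == "+") "left" else "right",
                         min_len = 5) {
  stopifnot(orientation %in% c("+", "-"))
  base <- if (orientation == "+") "A" else "T"
  x <- strsplit(region, "")[[1]]
  n <- length(x)
  is_h <- x == base
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!is_h[i]) { i <- i + 1; next }
    j <- i
    while (j < n) {
      if (is_h[j + 1]) { j <- j + 1; next }
      if (j + 2 > n) break
      nxt <- is_h[(j + 2):min(j + 6, n)]
      if (sum(nxt) >= 4) { j <- j + 1 } else break
    }
    runs[[length(runs) + 1]] <- c(i, j)
    i <- j + 2
  }
  trim_run <- function(s, e) {
    while (e - s + 1 >= 3 && !all(is_h[s:(s + 2)])) s <- s + 1
    while (e - s + 1 >= 3 && !all(is_h[(e - 2):e])) e <- e - 1
    if (e - s + 1 < 3 || !all(is_h[s:(s + 2)]) || !all(is_h[(e - 2):e])) {
      return(NULL)
    }
    tibble(start = s - 1L, end = e, length = e - s + 1L)
  }
  candidates <- purrr::map_dfr(runs, function(r) {
    s <- r[1]; e <- r[2]
    if (!is.null(tsd)) { # never extend into the TSD footprint (1-based s..e)
      ts <- tsd[1] + 1; te <- tsd[2]
      if (s <= te && e >= ts) {
        # a run overlapping the TSD yields the fragment(s) outside it
        out <- NULL
        if (s < ts) out <- bind_rows(out, trim_run(s, ts - 1))
        if (e > te) out <- bind_rows(out, trim_run(te + 1, e))
        return(out)
      }
    }
    trim_run(s, e)
  })
  absent <- tibble(found = FALSE, start = NA_integer_, end = NA_integer_,
                   length = 0L)
  if (nrow(candidates) == 0) return(absent)
  candidates <- candidates |> filter(.data$length >= min_len)
  if (nrow(candidates) == 0) return(absent)
  anchor <- if (!is.null(tsd)) {
    mean(tsd)
  } else if (retro_side == "left") 0 else n
  candidates <- candidates |>
    mutate(dist = pmin(abs(.data$start - anchor), abs(.data$end - anchor))) |>
    arrange(.data$dist, .data$start)
  tibble(found = TRUE, start = as.integer(candidates$start[1]),
         end = as.integer(candidates$end[1]),
         length = as.integer(candidates$length[1]))
}

#' Classify hallmark evidence at a locus
#'
#' Lenient categories require a TSD or poly(A) of at least `min_len` bp.
#' Strict categories require at least `strict_min` bp each and, for `both`,
#' a TSD-poly(A) separation of fewer than `max_sep` bases. A locus is
#' concordant when both hallmarks are present and separated by fewer than
#' `max_sep` bases.
#'
#' @param tsd_len,polya_len Detected lengths (0 when absent).
#' @param separation Reference bases strictly between the two footprints.
#' @param min_len,strict_min,max_sep Thresholds.
#' @return One-row tibble: `category`, `strict_category`, `concordant`.
#' @export
classify_hallmarks <- function(tsd_len, polya_len, separation = NA,
                               min_len = 5, strict_min = 10, max_sep = 5) {
  has_tsd <- !is.na(tsd_len) & tsd_len >= min_len
  has_polya <- !is.na(polya_len) & polya_len >= min_len
  category <- case_when(
    has_tsd & has_polya ~ "both",
    has_tsd ~ "tsd_only",
    has_polya ~ "polya_only",
    TRUE ~ "neither"
  )
  s_tsd <- !is.na(tsd_len) & tsd_len >= strict_min
  s_polya <- !is.na(polya_len) & polya_len >= strict_min
  adjacent <- !is.na(separation) & separation < max_sep
  strict_category <- case_when(
    s_tsd & s_polya & adjacent ~ "both",
    s_tsd ~ "tsd_only",
    s_polya ~ "polya_only",
    TRUE ~ "neither"
  )
  tibble(category = category, strict_category = strict_category,
         concordant = has_tsd & has_polya & adjacent)
}

#' Extract the LINE-1 endonuclease cleavage 7-mer at a TSD
#'
#' The 7-mer is the two bases preceding the TSD plus the first five TSD
#' bases, read in retrocopy orientation; when the retrocopy lies on the
#' chromosome's forward strand the sequence is reverse-complemented so that
#' all cleavage sites are reported on the minus strand.
#'
#' @param asm A [genome_assembly()].
#' @param chrom Chromosome of the locus.
#' @param strand Retrocopy orientation relative to the chromosome.
#' @param tsd_up_start 0-based genomic start of the upstream TSD copy.
#' @param tsd_down_end 0-based genomic end of the downstream TSD copy.
#' @param tsd_len TSD length (must be >= 5).
#' @return The 7-mer (character scalar).
#' @export
cleavage_site <- function(asm, chrom, strand, tsd_up_start, tsd_down_end,
                          tsd_len) {
  if (is.na(tsd_len) || tsd_len < 5) abort("cleavage site needs a TSD of >= 5 bp")
  if (strand == "+") {
    raw <- paste0(seq_slice(asm, chrom, tsd_up_start - 2, tsd_up_start),
                  seq_slice(asm, chrom, tsd_up_start, tsd_up_start + 5))
    revcomp(raw)
  } else {
    paste0(revcomp(seq_slice(asm, chrom, tsd_down_end, tsd_down_end + 2)),
           revcomp(seq_slice(asm, chrom, tsd_down_end - 5, tsd_down_end)))
  }
}

#' Position frequency matrix of cleavage-site 7-mers
#'
#' @param sites Character vector of equal-length cleavage sequences.
#' @return A `cleavage_profile`: list with `counts` and `freq` matrices
#'   (nucleotide x position) and `n`.
#' @export
cleavage_profile <- function(sites) {
  sites <- sites[!is.na(sites)]
  if (length(sites) == 0) abort("no cleavage sites supplied")
  w <- unique(nchar(sites))
  if (length(w) != 1) abort("cleavage sites have mixed lengths")
  m <- do.call(rbind, strsplit(sites, ""))
  counts <- sapply(seq_len(w), function(j) {
    table(factor(m[, j], levels = BASES))
  })
  colnames(counts) <- paste0("p", seq_len(w))
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(counts = counts, freq = freq, n = length(sites)),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat("<cleavage_profile> n =", x$n, "sites\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' Annotate retrocopy loci with retrotransposition hallmarks
#'
#' Runs the full hallmark stage on a set of retrocopy calls: locus
#' preparation and exclusion, TSD detection with bounded flank re-extension
#' (flanks grow by 5 bp, up to `max_reextend` times, while the best
#' alignment touches an outer flank edge), poly(A) detection in the original
#' flank distance beyond the 3' end, classification, and cleavage-site
#' extraction for TSD-bearing loci.
#'
#' @param calls Retrocopy calls ([find_retrocopies()]).
#' @param asm A [genome_assembly()].
#' @param flank Flank width in bp (60 bp maximises TSD/poly(A) concordance).
#' @param strict_min,max_sep Strict-mode thresholds (see
#'   [classify_hallmarks()]).
#' @param max_reextend Maximum number of 5 bp flank re-extensions.
#' @return One row per locus: detection results, genomic hallmark
#'   coordinates, `separation`, categories, `concordant`, `cleavage`.
#' @export
annotate_hallmarks <- function(calls, asm, flank = 60, strict_min = 10,
                               max_sep = 5, max_reextend = 10) {
  prep <- prepare_loci(calls, asm, flank = flank)
  purrr::map_dfr(seq_len(nrow(prep)), function(i) {
    row <- prep[i, ]
    base <- tibble(
      locus_id = row$locus_id, chrom = row$chrom, start = row$start,
      end = row$end, strand = row$strand, excluded = row$excluded,
      tsd_len = NA_integer_, tsd_seq = NA_character_,
      tsd_up_start = NA_integer_, tsd_down_start = NA_integer_,
      polya_len = NA_integer_, polya_start = NA_integer_,
      separation = NA_integer_, category = NA_character_,
      strict_category = NA_character_, concordant = NA,
      cleavage = NA_character_
    )
    if (!is.na(row$excluded)) return(base)

    f <- flank
    tsd <- detect_tsd(seq_slice(asm, row$chrom, row$start - f, row$start),
                      seq_slice(asm, row$chrom, row$end, row$end + f))
    iter <- 0
    while (tsd$found && (tsd$at_up_edge || tsd$at_down_edge) &&
           iter < max_reextend && row$start - (f + 5) >= 0) {
      f <- f + 5
      iter <- iter + 1
      tsd <- detect_tsd(seq_slice(asm, row$chrom, row$start - f, row$start),
                        seq_slice(asm, row$chrom, row$end, row$end + f))
    }
    tsd_up_g <- if (tsd$found) row$start - f + tsd$up_start else NA_integer_
    tsd_up_g_end <- if (tsd$found) row$start - f + tsd$up_end else NA_integer_
    tsd_down_g <- if (tsd$found) row$end + tsd$down_start else NA_integer_
    tsd_down_g_end <- if (tsd$found) row$end + tsd$down_end else NA_integer_

    # poly(A) search in the original flank distance beyond the 3' end
    if (row$strand == "+") {
      reg_start <- row$end
      region <- seq_slice(asm, row$chrom, reg_start, reg_start + flank)
    } else {
      reg_start <- row$start - flank
      region <- seq_slice(asm, row$chrom, reg_start, row$start)
    }
    tsd_in_region <- NULL
    if (tsd$found) {
      cand <- if (row$strand == "+") c(tsd_down_g, tsd_down_g_end) else
        c(tsd_up_g, tsd_up_g_end)
      rel <- c(cand[1] - reg_start, cand[2] - reg_start)
      if (rel[2] > 0 && rel[1] < nchar(region)) {
        tsd_in_region <- c(max(0L, rel[1]), min(nchar(region), rel[2]))
      }
    }
    pa <- detect_polya(region, row$strand, tsd = tsd_in_region)
    pa_g <- if (pa$found) c(reg_start + pa$start, reg_start + pa$end) else NULL

    sep_val <- NA_integer_
    if (tsd$found && pa$found) {
      tsd_g <- if (row$strand == "+") c(tsd_down_g, tsd_down_g_end) else
        c(tsd_up_g, tsd_up_g_end)
      sep_val <- as.integer(max(tsd_g[1] - pa_g[2], pa_g[1] - tsd_g[2], 0))
    }
    cls <- classify_hallmarks(
      ifelse(tsd$found, tsd$length, 0L),
      ifelse(pa$found, pa$length, 0L),
      sep_val, strict_min = strict_min, max_sep = max_sep
    )
    cleav <- if (tsd$found && tsd$length >= 5) {
      cleavage_site(asm, row$chrom, row$strand, tsd_up_g, tsd_down_g_end,
                    tsd$length)
    } else NA_character_

    base |>
      mutate(tsd_len = ifelse(tsd$found, tsd$length, 0L),
             tsd_seq = tsd$seq,
             tsd_up_start = tsd_up_g, tsd_down_start = tsd_down_g,
             polya_len = ifelse(pa$found, pa$length, 0L),
             polya_start = if (pa$found) pa_g[1] else NA_integer_,
             separation = sep_val,
             category = cls$category, strict_category = cls$strict_category,
             concordant = cls$concordant, cleavage = cleav)
  })
}

#' Confirm a TSD at a dimorphic (filled/empty) locus
#'
#' Compares the filled allele of an insertion locus against the empty allele
#' from a second assembly. The insertion is localised by exact flank
#' anchoring (longest common prefix/suffix); it must be at least
#' `min_insertion` bp, its best local match to the parent cDNA must cover
#' more than `min_cdna_cov` of its length, and structural variation on both
#' sides of the site is rejected. The confirmed TSD is the maximal exact
#' repeat flanking the insertion boundary (at least 5 bp to count), with its
#' cleavage 7-mer.
#'
#' @param filled Sequence of the locus plus flanks carrying the insertion.
#' @param empty Same locus from an assembly lacking the insertion.
#' @param cdna Parent transcript sequence.
#' @param min_insertion Minimum insertion size (bp).
#' @param min_cdna_cov Minimum fraction of the insertion matched by cDNA.
#' @param anchor_tol Tolerated unanchored bases before calling structural
#'   variation on both sides.
#' @return One-row tibble: `status` (`confirmed`, `rejected`, `unresolved`),
#'   `reason`, `ins_start`, `ins_len`, `orientation`, `tsd_len`, `tsd_seq`,
#'   `cleavage`.
#' @export
confirm_at_empty_site <- function(filled, empty, cdna, min_insertion = 80,
                                  min_cdna_cov = 0.75, anchor_tol = 20) {
  out <- function(status, reason = NA_character_, ins_start = NA_integer_,
                  ins_len = NA_integer_, orientation = NA_character_,
                  tsd_len = NA_integer_, tsd_seq = NA_character_,
                  cleavage = NA_character_) {
    tibble(status = status, reason = reason, ins_start = ins_start,
           ins_len = ins_len, orientation = orientation, tsd_len = tsd_len,
           tsd_seq = tsd_seq, cleavage = cleavage)
  }
  nf <- nchar(filled); ne <- nchar(empty)
  ins_len <- nf - ne
  if (ins_len <= 0) return(out("unresolved", "no_insertion_detected"))
  lcp <- common_prefix_len(filled, empty)
  lcs <- common_suffix_len(filled, empty)
  if (lcp == 0 || lcs == 0) return(out("unresolved", "flanks_fail_to_anchor"))
  if (ins_len < min_insertion) return(out("rejected", "insertion_too_small"))
  if (lcp + lcs < ne - anchor_tol) {
    return(out("rejected", "structural_variation_both_sides"))
  }
  s <- min(lcp, nf - ins_len - 0L) # 0-based insertion start
  ins <- substr(filled, s + 1, s + ins_len)

  fwd <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ins),
                                       Biostrings::DNAString(cdna),
                                       type = "local")
  rev <- Biostrings::pairwiseAlignment(Biostrings::DNAString(ins),
                                       Biostrings::DNAString(revcomp(cdna)),
                                       type = "local")
  orientation <- if (Biostrings::score(fwd) >= Biostrings::score(rev)) "+" else "-"
  best <- if (orientation == "+") fwd else rev
  cov <- Biostrings::nchar(Biostrings::pattern(best)) / ins_len
  if (cov <= min_cdna_cov) return(out("rejected", "insufficient_cdna_match",
                                      as.integer(s), as.integer(ins_len),
                                      orientation))
  # maximal exact repeat at the boundary: suffix of insertion == bases
  # immediately preceding it
  t <- 0
  while (t < s && t < ins_len &&
         substr(filled, s - t, s - t) ==
         substr(filled, s + ins_len - t, s + ins_len - t)) {
    t <- t + 1
  }
  if (t < 5) return(out("confirmed", "no_tsd", as.integer(s),
                        as.integer(ins_len), orientation, 0L))
  tsd_seq <- substr(filled, s - t + 1, s)
  cleav <- if (orientation == "+") {
    revcomp(substr(filled, s - t - 1, s - t + 5))
  } else {
    e <- s + ins_len
    paste0(revcomp(substr(filled, e + 1, e + 2)),
           revcomp(substr(filled, e - 4, e)))
  }
  out("confirmed", NA_character_, as.integer(s), as.integer(ins_len),
      orientation, as.integer(t), tsd_seq, cleav)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ra <- charToRaw(a)[seq_len(n)]; rb <- charToRaw(b)[seq_len(n)]
  neq <- which(ra != rb)
  if (length(neq) == 0) n else neq[1] - 1L
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ra <- rev(charToRaw(a))[seq_len(n)]; rb <- rev(charToRaw(b))[seq_len(n)]
  neq <- which(ra != rb)
  if (length(neq) == 0) n else neq[1] - 1L
}
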