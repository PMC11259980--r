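#' Generate a random genome assembly with a repeat mask
#'
#' Chromosome sequences are i.i.d. nucleotides at a target GC fraction, with a
#' set of non-overlapping intervals flagged as repetitive (the mask). Masked
#' intervals are placed randomly with lengths of 500-2,000 bp until the target
#' masked fraction is reached.
#'
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome in bp (>= 10,000).
#' @param repeat_fraction Target masked fraction per chromosome, in `[0, 1)`.
#' @param gc Target GC fraction.
#' @param seed Optional integer seed; a fixed seed gives byte-identical output.
#' @return A [genome_assembly()].
#' @export
make_genome <- function(n_chroms = 1, chrom_length = 100000,
                        repeat_fraction = 0, gc = 0.42, seed = NULL) {
  if (n_chroms < 1 || chrom_length < 10000) {
    abort("need n_chroms >= 1 and chrom_length >= 10,000")
  }
  if (repeat_fraction < 0 || repeat_fraction >= 1) {
    abort("repeat_fraction must be in [0, 1)")
  }
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  with_seed_opt(seed, {
    seqs <- setNames(
      vapply(seq_len(n_chroms), function(i) random_dna(chrom_length, gc), ""),
      paste0("chr", seq_len(n_chroms))
    )
    mask <- purrr::map_dfr(names(seqs), function(cc) {
      target <- round(repeat_fraction * chrom_length)
      if (target <= 0) return(NULL)
      placed <- tibble(chrom = character(), start = integer(), end = integer())
      total <- 0L
      tries <- 0L
      while (total < target && tries < 10000L) {
        tries <- tries + 1L
        len <- sample(500:2000, 1)
        len <- min(len, target - total + 0L)
        if (len < 50) len <- target - total
        pos <- sample.int(chrom_length - len, 1)
        cand <- tibble(chrom = cc, start = pos, end = pos + len)
        if (nrow(placed) == 0 || !any(overlaps_any(cand, placed))) {
          placed <- bind_rows(placed, cand)
          total <- total + len
        }
      }
      placed
    })
    genome_assembly(seqs, mask)
  })
}

#' Plant a multi-exon protein-coding gene
#'
#' Writes a gene with an intact open reading frame (ATG ... stop across the
#' spliced exons) into the assembly at `site`, overwriting the existing
#' sequence. Exons all have length `exon_len` and introns length `intron_len`.
#'
#' @param asm A [genome_assembly()].
#' @param n_exons Number of exons (>= 2; single-exon genes are not useful
#'   retrocopy parents because a retrocopy is recognised by its missing introns).
#' @param exon_len,intron_len Exon and intron lengths in bp.
#' @param site 0-based start position, or `NULL` to pick a free site.
#' @param chrom Chromosome for an explicit `site`.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Optional identifier; defaults to `gene<k>`.
#' @param seed Optional integer seed.
#' @return The updated assembly; the new model is the last row of
#'   [gene_models()].
#' @export
plant_gene <- function(asm, n_exons, exon_len = 300, intron_len = 500,
                       site = NULL, chrom = NULL, strand = "+",
                       gene_id = NULL, seed = NULL) {
  if (n_exons < 2) abort("genes must have at least two exons")
  if (exon_len < 30 || intron_len < 1) abort("exon/intron lengths too small")
  stopifnot(strand %in% c("+", "-"))
  with_seed_opt(seed, {
    span <- n_exons * exon_len + (n_exons - 1) * intron_len
    if (is.null(site)) {
      loc <- free_site(asm, span)
      chrom <- loc$chrom; site <- loc$pos
    } else {
      check_site(asm, chrom, site, span, "gene")
    }
    gene_id <- gene_id %||% paste0("gene", nrow(asm$genes) + 1)

    spliced_len <- n_exons * exon_len
    cds_len <- spliced_len - spliced_len %% 3
    orf <- random_orf(cds_len / 3)
    utr3 <- random_dna(spliced_len - cds_len, 0.45)
    spliced <- paste0(orf, utr3)

    exons_tx <- substring(spliced,
                          (seq_len(n_exons) - 1) * exon_len + 1,
                          seq_len(n_exons) * exon_len)
    introns <- vapply(seq_len(n_exons - 1), function(i) random_dna(intron_len, 0.4), "")
    pre_mrna <- paste0(paste0(exons_tx[-n_exons], introns, collapse = ""),
                       exons_tx[n_exons])
    genomic <- if (strand == "+") pre_mrna else revcomp(pre_mrna)
    asm <- seq_assign(asm, chrom, site, genomic)

    # genomic exon intervals, left to right
    off <- (seq_len(n_exons) - 1) * (exon_len + intron_len)
    if (strand == "+") {
      ex_start <- site + off
    } else {
      ex_start <- site + span - rev(off) - exon_len
    }
    asm$genes <- bind_rows(asm$genes, tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = as.integer(site), end = as.integer(site + span),
      exon_starts = list(as.integer(ex_start)),
      exon_ends = list(as.integer(ex_start + exon_len)),
      cds_start = 0L, cds_end = as.integer(cds_len),
      n_exons = as.integer(n_exons), spliced_len = as.integer(spliced_len)
    ))
    asm
  })
}

#' Spliced transcript sequence of a planted gene
#'
#' @param asm A [genome_assembly()].
#' @param gene_id Gene identifier in [gene_models()].
#' @return Character scalar: the spliced (intron-free) transcript, read 5' to
#'   3' on the coding strand.
#' @export
spliced_sequence <- function(asm, gene_id) {
  g <- asm$genes[asm$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) abort(paste0("unknown gene ", gene_id))
  parts <- mapply(function(s, e) seq_slice(asm, g$chrom, s, e),
                  g$exon_starts[[1]], g$exon_ends[[1]])
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp(s) else s
}

# offsets of exon-exon junctions within the spliced transcript
junction_offsets <- function(gene_row) {
  lens <- gene_row$exon_ends[[1]] - gene_row$exon_starts[[1]]
  if (gene_row$strand == "-") lens <- rev(lens)
  cumsum(lens)[-length(lens)]
}

# canonical LINE-1 endonuclease 7-mer (minus-strand report convention:
# T-rich run then the AA that follows the cut)
CANONICAL_CLEAVAGE <- "TTTTAAA"

#' Plant a retrocopy of a gene
#'
#' Emulates the staggered-cut integration mechanism: the `tsd_len` bp of
#' target sequence at `site` become the target-site duplication, and the
#' insertion body (the possibly 5'-truncated, point-mutated cDNA plus a
#' poly(A) run in transcript orientation) followed by a second TSD copy is
#' inserted immediately after it, so the final locus reads
#' `TSD + body + TSD` while the pre-integration allele keeps a single TSD
#' copy. When a cleavage motif is requested and a TSD is present, the two
#' bases preceding the TSD and its first five bases (in retrocopy
#' orientation) are rewritten so that the extracted cleavage 7-mer
#' (minus-strand convention) equals the motif.
#'
#' @param asm A [genome_assembly()].
#' @param gene_id Parent gene (must be planted in `asm`).
#' @param site 0-based insertion point, or `NULL` for a random free site.
#' @param chrom Chromosome for an explicit `site`.
#' @param orientation `"+"` or `"-"` relative to the chromosome.
#' @param tsd_len Target-site duplication length: 0 or 5-50 bp.
#' @param polya_len Poly(A) length: 0 or 5-50 bp.
#' @param truncation Fraction of the transcript removed from its 5' end.
#' @param divergence Per-base substitution probability applied to the cDNA.
#' @param cleavage `NULL` for a random insertion context, or a 7-mer such as
#'   the canonical `"TTTTAAA"` to plant a LINE-1 endonuclease site (requires
#'   `tsd_len >= 5`).
#' @param seed Optional integer seed.
#' @return The updated assembly; the event is the last row of [truth_records()].
#' @export
plant_retrocopy <- function(asm, gene_id, site = NULL, chrom = NULL,
                            orientation = "+", tsd_len = 12, polya_len = 12,
                            truncation = 0, divergence = 0,
                            cleavage = CANONICAL_CLEAVAGE, seed = NULL) {
  stopifnot(orientation %in% c("+", "-"))
  if (!(tsd_len == 0 || (tsd_len >= 5 && tsd_len <= 50))) {
    abort("tsd_len must be 0 or in [5, 50]")
  }
  if (!(polya_len == 0 || (polya_len >= 5 && polya_len <= 50))) {
    abort("polya_len must be 0 or in [5, 50]")
  }
  if (truncation < 0 || truncation > 1 || divergence < 0 || divergence > 1) {
    abort("truncation and divergence must be fractions in [0, 1]")
  }
  if (!is.null(cleavage) && nchar(cleavage) != 7) abort("cleavage must be a 7-mer")
  with_seed_opt(seed, {
    cdna <- spliced_sequence(asm, gene_id)
    drop5 <- floor(truncation * nchar(cdna))
    kept <- substr(cdna, drop5 + 1, nchar(cdna))
    kept <- diverge_sequence(kept, divergence)$seq
    body_tx <- paste0(kept, strrep("A", polya_len))
    body <- if (orientation == "+") body_tx else revcomp(body_tx)

    if (is.null(site)) {
      loc <- free_site(asm, tsd_len + nchar(body))
      chrom <- loc$chrom; site <- loc$pos
    } else {
      check_site(asm, chrom, site, tsd_len, "retrocopy insertion")
    }

    # staggered-cut model: the TSD is the target sequence at the site; the
    # insertion (cDNA body + a second TSD copy) lands just after it, leaving
    # a single TSD copy at the pre-integration (empty) allele
    plant_motif <- !is.null(cleavage) && tsd_len >= 5
    if (plant_motif) {
      rc <- revcomp(cleavage) # [2 bp before TSD][first 5 TSD bp], plus strand
      if (orientation == "+") {
        asm <- seq_assign(asm, chrom, site - 2L, substr(rc, 1, 2))
        asm <- seq_assign(asm, chrom, site, substr(rc, 3, 7))
      } else {
        # read from the right TSD end on the minus strand
        asm <- seq_assign(asm, chrom, site + tsd_len - 5L,
                          revcomp(substr(cleavage, 3, 7)))
        asm <- seq_assign(asm, chrom, site + tsd_len,
                          revcomp(substr(cleavage, 1, 2)))
      }
    }
    tsd <- if (tsd_len > 0) seq_slice(asm, chrom, site, site + tsd_len) else ""
    asm <- asm_insert(asm, chrom, site + tsd_len, paste0(body, tsd))

    locus_start <- if (orientation == "+") site + tsd_len else site + tsd_len + polya_len
    id <- paste0("retro", sum(asm$truth$kind == "retrocopy") + 1)
    asm$truth <- bind_rows(asm$truth, tibble(
      kind = "retrocopy", id = id, chrom = chrom,
      start = as.integer(site),
      end = as.integer(site + 2L * tsd_len + nchar(body)),
      locus_start = as.integer(locus_start),
      locus_end = as.integer(locus_start + nchar(kept)),
      parent_gene = gene_id, orientation = orientation,
      tsd_len = as.integer(tsd_len), tsd_seq = tsd,
      polya_len = as.integer(polya_len),
      truncation = truncation, divergence = divergence,
      cleavage = if (plant_motif) cleavage else NA_character_,
      inserted_seq = paste0(tsd, body, tsd)
    ))
    asm
  })
}

#' Find an unmasked, event-free interval
#'
#' Scans a chromosome left to right for the first window of `len` bp that
#' overlaps neither the repeat mask nor any planted feature. Segmental
#' duplications are defined on non-repetitive sequence, so duplication
#' sources should be chosen this way.
#'
#' @param asm A [genome_assembly()].
#' @param len Window length in bp.
#' @param chrom Chromosome to scan (default: first).
#' @param from 0-based position to start scanning at.
#' @param step Scan stride in bp.
#' @return A list with `chrom`, `start`, `end`, or an error if nothing fits.
#' @export
find_unmasked_interval <- function(asm, len, chrom = NULL, from = 0,
                                   step = 500) {
  chrom <- chrom %||% names(asm$seq)[1]
  size <- chrom_sizes(asm)[[chrom]]
  avoid <- bind_rows(
    asm$mask |> filter(.data$chrom == .env$chrom) |> select("start", "end"),
    occupied_intervals(asm) |> filter(.data$chrom == .env$chrom) |>
      select("start", "end")
  )
  pos <- from
  while (pos + len <= size - 1000) {
    hit <- nrow(avoid) > 0 && any(avoid$start < pos + len & avoid$end > pos)
    if (!hit) {
      return(list(chrom = chrom, start = as.integer(pos),
                  end = as.integer(pos + len)))
    }
    pos <- pos + step
  }
  abort(paste0("no unmasked window of ", len, " bp on ", chrom))
}

#' Reconstruct the pre-integration (empty) allele of a planted retrocopy
#'
#' Returns the locus as it looked before integration: the upstream flank,
#' a single TSD copy, and the downstream flank, taken from the filled
#' assembly itself (so any planted cleavage-motif context is preserved).
#'
#' @param asm A [genome_assembly()] carrying the retrocopy.
#' @param retro_id Truth-record id of the retrocopy (e.g. `"retro1"`).
#' @param flank Flank width in bp on each side.
#' @return Character scalar: the empty-allele sequence.
#' @export
empty_site_sequence <- function(asm, retro_id, flank = 5000) {
  tr <- asm$truth[asm$truth$kind == "retrocopy" & asm$truth$id == retro_id, ]
  if (nrow(tr) != 1) abort(paste0("unknown retrocopy ", retro_id))
  paste0(
    seq_slice(asm, tr$chrom, tr$start - flank, tr$start + tr$tsd_len),
    seq_slice(asm, tr$chrom, tr$end, tr$end + flank)
  )
}

#' Plant a segmental duplication
#'
#' Copies `[start, end)` of `chrom` (the source, >= 1,000 bp so that copies are
#' detectable as segmental duplications) `n_copies` times, each copy carrying
#' independent point mutations at the given per-base rate. Tandem copies stack
#' immediately after the source; dispersed copies go to random free sites.
#'
#' @param asm A [genome_assembly()].
#' @param chrom,start,end Source interval (0-based half-open, >= 1,000 bp).
#' @param n_copies Number of new copies (>= 1).
#' @param divergence Per-base substitution probability per copy.
#' @param placement `"tandem"` or `"dispersed"`.
#' @param seed Optional integer seed.
#' @return The updated assembly; the event adds one `source` row plus one
#'   `copy` row per copy to [truth_records()], all sharing a `dup_id` and a
#'   diploid `copy_number` of `2 * (n_copies + 1)`.
#' @export
plant_duplication <- function(asm, chrom, start, end, n_copies = 1,
                              divergence = 0, placement = c("dispersed", "tandem"),
                              seed = NULL) {
  placement <- match.arg(placement)
  if (end - start < 1000) abort("duplication source must be >= 1,000 bp")
  if (n_copies < 1) abort("n_copies must be >= 1")
  with_seed_opt(seed, {
    src_seq <- seq_slice(asm, chrom, start, end)
    dup_id <- paste0("dup", length(unique(stats::na.omit(asm$truth$dup_id))) + 1)
    cn <- 2 * (n_copies + 1)
    asm$truth <- bind_rows(asm$truth, tibble(
      kind = "duplication", id = paste0(dup_id, "_source"), chrom = chrom,
      start = as.integer(start), end = as.integer(end),
      dup_id = dup_id, role = "source", divergence = divergence,
      copy_number = cn
    ))
    for (i in seq_len(n_copies)) {
      copy_seq <- diverge_sequence(src_seq, divergence)$seq
      if (placement == "tandem") {
        src_now <- asm$truth |>
          filter(.data$dup_id == .env$dup_id, .data$role == "source")
        cchrom <- src_now$chrom
        cpos <- src_now$end +
          (i - 1L) * 0L # copies stack book-ended after the source
        prev <- asm$truth |>
          filter(.data$dup_id == .env$dup_id, .data$role == "copy")
        if (nrow(prev) > 0) cpos <- max(prev$end)
      } else {
        loc <- free_site(asm, nchar(copy_seq))
        cchrom <- loc$chrom; cpos <- loc$pos
      }
      asm <- asm_insert(asm, cchrom, cpos, copy_seq)
      asm$truth <- bind_rows(asm$truth, tibble(
        kind = "duplication", id = paste0(dup_id, "_copy", i), chrom = cchrom,
        start = as.integer(cpos), end = as.integer(cpos + nchar(copy_seq)),
        dup_id = dup_id, role = "copy", divergence = divergence,
        copy_number = cn, inserted_seq = copy_seq
      ))
    }
    asm
  })
}

#' Derive a diverged sister assembly
#'
#' Models two lineages separating `generations` generations ago: each unmasked,
#' event-free site substitutes with probability `2 * mu * generations`, and the
#' sister additionally gains `private_retros` retrocopy insertions (drawn from
#' the planted gene models) absent from the input assembly.
#'
#' @param asm A [genome_assembly()] (genes must be planted if
#'   `private_retros > 0`).
#' @param generations Generations since divergence.
#' @param mu Single-nucleotide mutation rate per bp per generation.
#' @param private_retros Number of sister-private retrocopy insertions.
#' @param seed Optional integer seed.
#' @return A list with `assembly` (the sister) and `truth` (tibble of the
#'   sister-private SNPs and retrocopies, in sister coordinates).
#' @export
diverge_assembly <- function(asm, generations, mu = 4.5e-9, private_retros = 0,
                             seed = NULL) {
  if (generations < 0 || mu < 0) abort("generations and mu must be non-negative")
  with_seed_opt(seed, {
    sister <- asm
    p <- 2 * mu * generations
    snp_rows <- NULL
    if (p > 0) {
      sizes <- chrom_sizes(sister)
      blocked <- bind_rows(sister$mask |> select("chrom", "start", "end"),
                           occupied_intervals(sister, buffer = 0L))
      snp_rows <- purrr::map_dfr(names(sizes), function(cc) {
        elig <- complement_intervals(blocked |> filter(.data$chrom == cc),
                                     sizes[cc])
        if (nrow(elig) == 0) return(NULL)
        pos_pool <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                                  elig$start, elig$end, SIMPLIFY = FALSE))
        n_snp <- rbinom(1, length(pos_pool), p)
        if (n_snp == 0) return(NULL)
        pos <- sort(sample(pos_pool, n_snp))
        raw <- charToRaw(sister$seq[[cc]])
        ref <- rawToChar(raw[pos + 1], multiple = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "",
                      USE.NAMES = FALSE)
        raw[pos + 1] <- charToRaw(paste(alt, collapse = ""))
        sister$seq[[cc]] <<- rawToChar(raw)
        tibble(kind = "snp", id = paste0(cc, "_", pos), chrom = cc,
               start = as.integer(pos), end = as.integer(pos + 1L),
               ref = ref, alt = alt)
      })
      if (!is.null(snp_rows) && nrow(snp_rows) > 0) {
        sister$truth <- bind_rows(sister$truth, snp_rows)
      }
    }
    n_before <- nrow(sister$truth)
    if (private_retros > 0) {
      if (nrow(sister$genes) == 0) abort("no genes planted to source retrocopies from")
      for (i in seq_len(private_retros)) {
        gid <- sample(sister$genes$gene_id, 1)
        sister <- plant_retrocopy(
          sister, gid,
          orientation = sample(c("+", "-"), 1),
          tsd_len = sample(8:20, 1), polya_len = sample(8:20, 1),
          truncation = 0, divergence = 0.005
        )
      }
    }
    new_truth <- bind_rows(
      sister$truth |> slice((n_before + 1):n()) |> filter(.data$kind == "retrocopy"),
      sister$truth |> filter(.data$kind == "snp")
    )
    list(assembly = sister, truth = new_truth)
  })
}

#' Simulate a read-depth track
#'
#' Windows contain exactly `window_unmasked` unmasked positions (except
#' possibly the last per chromosome). Window depth is Poisson with mean
#' `mean_depth * cn / 2 * (1 + gc_bias * 2 * (gc - 0.5))`, where `cn` is the
#' mean planted diploid copy number over the window's unmasked positions.
#'
#' @param asm A [genome_assembly()].
#' @param dups Tibble of duplication truth intervals with a `copy_number`
#'   column; defaults to the assembly's planted duplications.
#' @param mean_depth Expected depth at copy number 2.
#' @param window_unmasked Unmasked positions per window.
#' @param gc_bias Strength of the (linear) GC modulation; 0 disables it.
#' @param seed Optional integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `unmasked`, `gc`, `depth`.
#' @export
simulate_depth <- function(asm, dups = NULL, mean_depth = 30,
                           window_unmasked = 1000, gc_bias = 0, seed = NULL) {
  if (mean_depth <= 0) abort("mean_depth must be positive")
  dups <- dups %||% (truth_records(asm) |> filter(.data$kind == "duplication"))
  with_seed_opt(seed, {
    sizes <- chrom_sizes(asm)
    purrr::map_dfr(names(sizes), function(cc) {
      unm <- complement_intervals(asm$mask |> filter(.data$chrom == cc), sizes[cc])
      if (nrow(unm) == 0) return(NULL)
      pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                           unm$start, unm$end, SIMPLIFY = FALSE))
      n <- length(pos)
      if (n == 0) return(NULL)
      # per-position extra copy count from planted duplications: a position
      # inside any member of a duplication family receives depth from every
      # paralog under multi-mapped read placement, so each covering interval
      # contributes its family's extra copies (copy_number/2 - 1)
      dc <- dups |> filter(.data$chrom == cc)
      cov <- numeric(n)
      if (nrow(dc) > 0) {
        w <- dc$copy_number / 2 - 1
        covr <- IRanges::coverage(as_iranges0(dc$start, dc$end),
                                  width = sizes[[cc]], weight = w)
        cov <- as.numeric(covr)[pos + 1L]
      }
      win <- (seq_len(n) - 1L) %/% window_unmasked
      starts <- tapply(pos, win, min)
      ends <- tapply(pos, win, max) + 1L
      unmasked <- tapply(pos, win, length)
      cn <- tapply(2 * (1 + cov), win, mean)
      gc <- mapply(function(s, e) gc_of(seq_slice(asm, cc, s, e)), starts, ends)
      mod <- 1 + gc_bias * 2 * (gc - 0.5)
      mod[mod < 0.05] <- 0.05
      depth <- rpois(length(starts), mean_depth * cn / 2 * mod)
      tibble(chrom = cc, start = as.integer(starts), end = as.integer(ends),
             unmasked = as.integer(unmasked), gc = as.numeric(gc),
             depth = as.integer(depth))
    })
  })
}
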