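#' Build the representative transcript of a planted gene
#'
#' @param asm A [genome_assembly()].
#' @param gene_id Gene identifier.
#' @return One-row tibble: `gene_id`, `chrom`, `strand`, parent footprint
#'   (`parent_start`, `parent_end`), spliced `cdna`, exon-exon `junctions`
#'   (offsets within the spliced transcript, list-column), coding offsets
#'   `cds_start`/`cds_end`, `n_exons`, `min_intron`.
#' @export
build_transcript <- function(asm, gene_id) {
  g <- asm$genes[asm$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) abort(paste0("unknown gene ", gene_id))
  introns <- g$exon_starts[[1]][-1] - g$exon_ends[[1]][-g$n_exons]
  tibble(
    gene_id = gene_id, chrom = g$chrom, strand = g$strand,
    parent_start = g$start, parent_end = g$end,
    cdna = spliced_sequence(asm, gene_id),
    junctions = list(junction_offsets(g)),
    cds_start = g$cds_start, cds_end = g$cds_end,
    n_exons = g$n_exons,
    min_intron = if (length(introns)) min(introns) else NA_integer_
  )
}

#' Select one representative transcript per gene
#'
#' Among a gene's isoforms, picks the longest spliced transcript, breaking
#' ties by the fewest exons; the chosen isoform is then rejected outright if
#' it has any intron shorter than `min_intron_len` or fewer than two exons
#' (single-exon genes cannot evidence retrotransposition).
#'
#' @param isoforms Tibble with at least `gene_id`, `transcript_id`,
#'   `spliced_len`, `n_exons`, `min_intron` (NA allowed for single-exon rows).
#' @param min_intron_len Minimum tolerated intron (bp).
#' @return Tibble with one row per gene: the winning `transcript_id`,
#'   `status` (`"selected"` or `"rejected"`) and `reason` (NA when selected).
#' @export
select_transcript <- function(isoforms, min_intron_len = 50) {
  isoforms |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$spliced_len), .data$n_exons, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(
      reason = case_when(
        .data$n_exons < 2 ~ "single_exon",
        !is.na(.data$min_intron) & .data$min_intron < min_intron_len ~ "short_intron",
        TRUE ~ NA_character_
      ),
      status = ifelse(is.na(.data$reason), "selected", "rejected")
    )
}

#' Align a cDNA against an assembly
#'
#' Seed-and-chain local alignment of the spliced transcript against both
#' strands of the assembly: exact `k`-mer seeds (genome k-mers occurring more
#' than `max_occ` times are skipped, the over-represented-seed filter),
#' chained along shared diagonals and extended by mismatch-tolerant
#' X-drop extension.
#' Planted homologies carry substitutions only, so each contiguous homologous
#' segment occupies a single diagonal and alignments are gap-free.
#'
#' @param cdna Spliced transcript sequence (character scalar).
#' @param asm A [genome_assembly()].
#' @param k Seed size (BLAT-style 11 by default).
#' @param max_occ Over-representation threshold for genome k-mers.
#' @param max_gap Maximum seed gap along a diagonal within one block.
#' @param min_seeds Minimum seeds per block (filters random 11-mer noise).
#' @return Tibble of alignment blocks: `chrom`, `strand`, `tstart`, `tend`
#'   (genomic), `qstart`, `qend` (transcript orientation), `matches`,
#'   `mismatches`, `identity`, `n_seeds`.
#' @export
align_cdna <- function(cdna, asm, k = 11, max_occ = 10, max_gap = 100,
                       min_seeds = 2) {
  chroms <- names(asm$seq)
  L <- nchar(cdna)
  queries <- c(cdna, revcomp(cdna))
  hits <- as_tibble(cpp_query_seed_hits(queries, unname(asm$seq),
                                        as.integer(k), as.integer(max_occ)))
  if (nrow(hits) == 0) return(empty_blocks())
  blocks <- hits |>
    mutate(diag = .data$tpos - .data$qpos) |>
    arrange(.data$query, .data$chrom, .data$diag, .data$qpos) |>
    group_by(.data$query, .data$chrom, .data$diag) |>
    mutate(chain = cumsum(c(0L, diff(.data$qpos)) > max_gap)) |>
    group_by(.data$query, .data$chrom, .data$diag, .data$chain) |>
    summarise(qs = min(.data$qpos), qe = max(.data$qpos) + k,
              n_seeds = n(), .groups = "drop") |>
    filter(.data$n_seeds >= min_seeds)
  if (nrow(blocks) == 0) return(empty_blocks())

  purrr::pmap_dfr(blocks, function(query, chrom, diag, chain, qs, qe, n_seeds) {
    cc <- chroms[chrom]
    qseq <- queries[query] # in genome (plus-strand) orientation
    ts <- qs + diag; te <- qe + diag
    ext0 <- extend_homology(qseq, asm$seq[[cc]], qs, qe, ts, te)
    ext <- list(qs = ext0$xs, qe = ext0$xe, ts = ext0$ys, te = ext0$ye)
    tgt <- seq_slice(asm, cc, ext$ts, ext$te)
    qry <- substr(qseq, ext$qs + 1, ext$qe)
    cmp <- cpp_base_compare(qry, tgt)
    idy <- if (cmp$matches + cmp$mismatches > 0) {
      cmp$matches / (cmp$matches + cmp$mismatches)
    } else NA_real_
    strand <- if (query == 1) "+" else "-"
    # query coordinates in transcript orientation
    if (strand == "+") {
      q0 <- ext$qs; q1 <- ext$qe
    } else {
      q0 <- L - ext$qe; q1 <- L - ext$qs
    }
    tibble(chrom = cc, strand = strand,
           tstart = ext$ts, tend = ext$te,
           qstart = q0, qend = q1,
           matches = cmp$matches, mismatches = cmp$mismatches,
           identity = idy, n_seeds = n_seeds)
  })
}

empty_blocks <- function() {
  tibble(chrom = character(), strand = character(),
         tstart = integer(), tend = integer(),
         qstart = integer(), qend = integer(),
         matches = integer(), mismatches = integer(),
         identity = double(), n_seeds = integer())
}

#' Sequence identity from match counts
#'
#' Identity is the number of matches over matches plus mismatches; gap
#' columns are excluded from the denominator.
#'
#' @param matches,mismatches Aligned column counts.
#' @return Fraction in `[0, 1]`.
#' @export
compute_identity <- function(matches, mismatches) {
  if (any(matches + mismatches <= 0)) abort("matches + mismatches must be positive")
  matches / (matches + mismatches)
}

#' Call retrocopies of one transcript from its alignments
#'
#' Applies the filter cascade: blocks shorter than `min_len` aligned bp,
#' blocks overlapping the parent gene's genomic footprint, blocks under
#' `min_identity`, and blocks that do not cross an exon-exon junction (at
#' least `junction_margin` aligned bases on both sides of at least one
#' junction offset) are removed. Surviving blocks within `merge_gap` bp of
#' each other on one chromosome and strand are merged into a single
#' multi-segment locus.
#'
#' @param alignments Block tibble from [align_cdna()].
#' @param transcript One-row tibble from [build_transcript()].
#' @param asm The [genome_assembly()] the alignments refer to (used for the
#'   full-ORF check; pass `NULL` to skip it).
#' @param min_len Minimum aligned length (bp).
#' @param min_identity Minimum identity.
#' @param junction_margin Minimum aligned bases on each side of a junction.
#' @param merge_gap Merge distance for blocks of one locus.
#' @return Tibble of retrocopy calls: locus coordinates, `strand` (relative
#'   to the parent transcript), `parent_gene`, `aligned_len`, `identity`,
#'   `junctions_crossed`, `segments`, `full_orf`.
#' @export
call_retrocopies <- function(alignments, transcript, asm = NULL,
                             min_len = 100, min_identity = 0.90,
                             junction_margin = 10, merge_gap = 100) {
  calls_for_transcript(alignments, transcript, asm,
                       list(min_len = min_len, min_identity = min_identity,
                            junction_margin = junction_margin,
                            merge_gap = merge_gap))
}

empty_calls <- function() {
  tibble(chrom = character(), strand = character(),
         start = integer(), end = integer(), parent_gene = character(),
         aligned_len = integer(), identity = double(),
         junctions_crossed = integer(), segments = integer(),
         full_orf = logical())
}

#' Does a retrocopy retain the full parental open reading frame?
#'
#' True when one alignment block covers the parental coding region
#' end-to-end and its genomic translation has the original start codon, no
#' premature stop, and a terminal stop.
#'
#' @param blocks Alignment blocks of the locus (as in [align_cdna()] output).
#' @param transcript One-row tibble from [build_transcript()].
#' @param asm A [genome_assembly()] (needed to extract the genomic sequence).
#' @return Logical flag.
#' @export
check_full_orf <- function(blocks, transcript, asm) {
  if (is.null(asm)) return(NA)
  cds0 <- transcript$cds_start
  cds1 <- transcript$cds_end
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$qstart > cds0 || b$qend < cds1) next
    tgt <- seq_slice(asm, b$chrom, b$tstart, b$tend)
    if (b$strand == "-") tgt <- revcomp(tgt)
    orf <- substr(tgt, cds0 - b$qstart + 1, cds0 - b$qstart + (cds1 - cds0))
    aa <- translate_dna(orf)
    n <- nchar(aa)
    if (n < 2) next
    body <- substr(aa, 1, n - 1)
    if (substr(aa, 1, 1) == "M" && substr(aa, n, n) == "*" &&
        !grepl("\\*", body, fixed = FALSE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Find retrocopies of all planted genes in an assembly
#'
#' Runs [build_transcript()], [align_cdna()] and [call_retrocopies()] for
#' every gene model and binds the results.
#'
#' @param asm A [genome_assembly()].
#' @param gene_ids Genes to scan (default: all planted genes).
#' @param ... Passed to [align_cdna()] and [call_retrocopies()].
#' @return Tibble of retrocopy calls with a `locus_id` column.
#' @export
find_retrocopies <- function(asm, gene_ids = NULL, ...) {
  gene_ids <- gene_ids %||% asm$genes$gene_id
  dots <- list(...)
  align_args <- dots[names(dots) %in% c("k", "max_occ", "max_gap", "min_seeds")]
  call_args <- dots[names(dots) %in%
                      c("min_len", "min_identity", "junction_margin", "merge_gap")]
  out <- purrr::map_dfr(gene_ids, function(gid) {
    tx <- build_transcript(asm, gid)
    alns <- do.call(align_cdna, c(list(tx$cdna, asm), align_args))
    calls_for_transcript(alns, tx, asm, call_args)
  })
  if (nrow(out) == 0) return(mutate(empty_calls(), locus_id = character()))
  out |> mutate(locus_id = paste0("rc", row_number()))
}

# internal: call_retrocopies with full-ORF evaluation wired to the assembly
calls_for_transcript <- function(alns, tx, asm, call_args = list()) {
  min_len <- call_args$min_len %||% 100
  min_identity <- call_args$min_identity %||% 0.90
  junction_margin <- call_args$junction_margin %||% 10
  merge_gap <- call_args$merge_gap %||% 100
  juncs <- tx$junctions[[1]]
  keep <- alns |>
    mutate(alen = .data$qend - .data$qstart) |>
    filter(.data$alen >= min_len,
           !(.data$chrom == tx$chrom &
               .data$tstart < tx$parent_end & .data$tend > tx$parent_start),
           .data$identity >= min_identity)
  if (nrow(keep) == 0) return(empty_calls())
  keep$junctions_crossed <- vapply(seq_len(nrow(keep)), function(i) {
    sum(juncs >= keep$qstart[i] + junction_margin &
          juncs <= keep$qend[i] - junction_margin)
  }, integer(1))
  keep <- keep |> filter(.data$junctions_crossed >= 1)
  if (nrow(keep) == 0) return(empty_calls())

  keep <- keep |> arrange(.data$chrom, .data$strand, .data$tstart)
  grp <- integer(nrow(keep))
  gid <- 0L
  last_chrom <- ""; last_strand <- ""; last_end <- -Inf
  for (i in seq_len(nrow(keep))) {
    if (keep$chrom[i] != last_chrom || keep$strand[i] != last_strand ||
        keep$tstart[i] > last_end + merge_gap) {
      gid <- gid + 1L
      last_end <- keep$tend[i]
    } else {
      last_end <- max(last_end, keep$tend[i])
    }
    grp[i] <- gid
    last_chrom <- keep$chrom[i]; last_strand <- keep$strand[i]
  }
  keep$locus <- grp
  purrr::map_dfr(split(keep, keep$locus), function(d) {
    crossed <- unique(unlist(purrr::map2(d$qstart, d$qend, function(a, b) {
      juncs[juncs >= a + junction_margin & juncs <= b - junction_margin]
    })))
    tibble(
      chrom = d$chrom[1], strand = d$strand[1],
      start = min(d$tstart), end = max(d$tend),
      parent_gene = tx$gene_id,
      aligned_len = as.integer(sum(d$qend - d$qstart)),
      identity = sum(d$matches) / (sum(d$matches) + sum(d$mismatches)),
      junctions_crossed = length(crossed),
      segments = nrow(d),
      full_orf = check_full_orf(d, tx, asm)
    )
  })
}
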