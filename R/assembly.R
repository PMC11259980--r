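#' Genome assembly container
#'
#' A `genome_assembly` bundles named chromosome sequences with a repeat mask,
#' the gene models planted on it, and the ground-truth records of every
#' simulated event. All coordinates are 0-based half-open (BED convention).
#'
#' @param sequences Named character vector of chromosome sequences (A/C/G/T/N).
#' @param mask Tibble with columns `chrom`, `start`, `end` flagging repetitive
#'   intervals (may be empty).
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(sequences,
                            mask = tibble(chrom = character(),
                                          start = integer(), end = integer())) {
  if (length(sequences) == 0) abort("assembly needs at least one sequence")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("sequence names must be present and unique")
  }
  mask <- as_tibble(mask)
  if (nrow(mask) == 0) {
    mask <- tibble(chrom = character(), start = integer(), end = integer())
  }
  sizes <- nchar(sequences)
  if (nrow(mask) > 0) {
    bad <- !(mask$chrom %in% names(sequences)) |
      mask$start < 0 | mask$end <= mask$start |
      mask$end > sizes[mask$chrom]
    if (any(bad)) abort("mask intervals must be non-empty and lie within their chromosome")
  }
  structure(
    list(
      seq = sequences,
      mask = mask,
      genes = empty_gene_models(),
      truth = empty_truth()
    ),
    class = "genome_assembly"
  )
}

empty_gene_models <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(),
    exon_starts = list(), exon_ends = list(),
    cds_start = integer(), cds_end = integer(),
    n_exons = integer(), spliced_len = integer()
  )
}

empty_truth <- function() {
  tibble(
    kind = character(), id = character(), chrom = character(),
    start = integer(), end = integer(),
    locus_start = integer(), locus_end = integer(),
    parent_gene = character(), orientation = character(),
    tsd_len = integer(), tsd_seq = character(),
    polya_len = integer(), truncation = double(), divergence = double(),
    cleavage = character(), dup_id = character(), role = character(),
    copy_number = double(), ref = character(), alt = character(),
    inserted_seq = character()
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  sizes <- chrom_sizes(x)
  cat("<genome_assembly> ", length(sizes), " sequence(s), ",
      format(sum(sizes), big.mark = ","), " bp total\n", sep = "")
  cat("  masked bp: ", format(total_bp(x$mask), big.mark = ","),
      " | genes: ", nrow(x$genes),
      " | truth records: ", nrow(x$truth), "\n", sep = "")
  invisible(x)
}

#' Chromosome sizes of an assembly
#' @param asm A `genome_assembly`.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(asm) {
  vapply(asm$seq, nchar, integer(1))
}

#' Ground-truth records of planted events
#' @param asm A `genome_assembly`.
#' @return Tibble with one row per planted event (retrocopy, duplication, snp).
#' @export
truth_records <- function(asm) asm$truth

#' Gene models planted on an assembly
#' @param asm A `genome_assembly`.
#' @return Tibble of gene models (exons as list-columns, 0-based half-open).
#' @export
gene_models <- function(asm) asm$genes

#' Extract assembly sequence
#'
#' @param asm A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates; defaults to the whole
#'   chromosome. Out-of-range requests are clipped.
#' @return Character scalar.
#' @export
seq_slice <- function(asm, chrom, start = 0L, end = NULL) {
  s <- asm$seq[[chrom]]
  n <- nchar(s)
  end <- min(end %||% n, n)
  start <- max(0L, start)
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# overwrite bases at [start, start+nchar(value)) on chrom
seq_assign <- function(asm, chrom, start, value) {
  s <- asm$seq[[chrom]]
  substr(s, start + 1L, start + nchar(value)) <- value
  asm$seq[[chrom]] <- s
  asm
}

# shift interval columns of a tibble for an insertion of `len` bp at `pos`;
# intervals straddling pos are split (used for the mask only)
shift_for_insert <- function(df, chrom, pos, len, split = FALSE) {
  if (nrow(df) == 0) return(df)
  sel <- df$chrom == chrom
  if (!any(sel)) return(df)
  if (split) {
    straddle <- sel & df$start < pos & df$end > pos
    if (any(straddle)) {
      left <- df[straddle, ]; right <- df[straddle, ]
      left$end <- pos
      right$start <- pos + len
      right$end <- right$end + len
      df <- bind_rows(df[!straddle, ], left, right)
      sel <- df$chrom == chrom
    }
  }
  for (col in intersect(c("start", "end", "locus_start", "locus_end"), names(df))) {
    v <- df[[col]]
    move <- sel & !is.na(v) & v >= pos
    # ends at exactly pos belong to the upstream feature and stay put
    if (col %in% c("end", "locus_end")) move <- sel & !is.na(v) & v > pos
    v[move] <- v[move] + len
    df[[col]] <- v
  }
  df
}

# insert `value` at `pos` on `chrom`, shifting mask/genes/truth coordinates
asm_insert <- function(asm, chrom, pos, value) {
  s <- asm$seq[[chrom]]
  n <- nchar(s)
  stopifnot(pos >= 0, pos <= n)
  asm$seq[[chrom]] <- paste0(substr(s, 1, pos), value, substr(s, pos + 1, n))
  len <- nchar(value)
  asm$mask <- shift_for_insert(asm$mask, chrom, pos, len, split = TRUE)
  asm$truth <- shift_for_insert(asm$truth, chrom, pos, len)
  if (nrow(asm$genes) > 0) {
    asm$genes <- shift_for_insert(asm$genes, chrom, pos, len)
    sel <- which(asm$genes$chrom == chrom)
    for (i in sel) {
      es <- asm$genes$exon_starts[[i]]
      ee <- asm$genes$exon_ends[[i]]
      es[es >= pos] <- es[es >= pos] + len
      ee[ee > pos] <- ee[ee > pos] + len
      asm$genes$exon_starts[[i]] <- es
      asm$genes$exon_ends[[i]] <- ee
    }
  }
  asm
}

# intervals occupied by planted features, used to keep newly planted events
# from colliding; the buffer keeps a flank's worth of clean sequence around
# every event so flank-based analyses are never confounded by a neighbour
occupied_intervals <- function(asm, buffer = 600L) {
  occ <- bind_rows(
    asm$genes |> select("chrom", "start", "end"),
    asm$truth |>
      filter(.data$kind %in% c("retrocopy", "duplication")) |>
      select("chrom", "start", "end")
  )
  if (nrow(occ) == 0) return(occ)
  occ$start <- pmax(0L, occ$start - buffer)
  occ$end <- occ$end + buffer
  occ
}

# pick a position where a feature of `len` bp can be placed without touching
# occupied intervals or (optionally) the mask; bounded rejection sampling
free_site <- function(asm, len, avoid_mask = TRUE, margin = 1000L,
                      max_tries = 100L) {
  sizes <- chrom_sizes(asm)
  avoid <- occupied_intervals(asm)
  if (avoid_mask && nrow(asm$mask) > 0) {
    avoid <- bind_rows(avoid, asm$mask |> select("chrom", "start", "end"))
  }
  for (i in seq_len(max_tries)) {
    cc <- sample(names(sizes), 1, prob = sizes)
    hi <- sizes[[cc]] - len - margin
    if (hi <= margin) next
    pos <- sample.int(hi - margin, 1) + margin
    cand <- tibble(chrom = cc, start = pos, end = pos + max(len, 1L))
    if (nrow(avoid) == 0 || !any(overlaps_any(cand, avoid))) {
      return(list(chrom = cc, pos = as.integer(pos)))
    }
  }
  abort("could not place event after bounded retries",
        class = "retroscape_placement_error")
}

# check an explicit site for collisions
check_site <- function(asm, chrom, pos, len, what = "event") {
  sizes <- chrom_sizes(asm)
  if (!chrom %in% names(sizes)) abort(paste0("unknown chromosome ", chrom))
  if (pos < 0 || pos + len > sizes[[chrom]]) {
    abort(paste0(what, " footprint does not fit in ", chrom),
          class = "retroscape_placement_error")
  }
  occ <- occupied_intervals(asm)
  cand <- tibble(chrom = chrom, start = pos, end = pos + max(len, 1L))
  if (nrow(occ) > 0 && any(overlaps_any(cand, occ))) {
    abort(paste0(what, " collides with a previously planted feature"),
          class = "retroscape_placement_error")
  }
  invisible(TRUE)
}

#' Masked fraction per chromosome
#' @param asm A `genome_assembly`.
#' @return Tibble with `chrom`, `masked_bp`, `size`, `masked_fraction`.
#' @export
masked_fraction <- function(asm) {
  sizes <- chrom_sizes(asm)
  tibble(chrom = names(sizes), size = as.integer(sizes)) |>
    left_join(
      asm$mask |> group_by(.data$chrom) |>
        summarise(masked_bp = sum(.data$end - .data$start), .groups = "drop"),
      by = "chrom"
    ) |>
    mutate(masked_bp = coalesce(.data$masked_bp, 0L),
           masked_fraction = .data$masked_bp / .data$size)
}
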