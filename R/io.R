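# File interchange: FASTA + BED for assemblies and masks, BED12 for gene
# models, TSV for depth tracks and truth tables, BEDPE for duplication pairs.
# All files use 0-based half-open coordinates.

#' Write an assembly to FASTA (and its mask to BED)
#'
#' @param asm A [genome_assembly()].
#' @param fasta Output FASTA path.
#' @param mask_bed Optional output BED path for the repeat mask.
#' @return `asm`, invisibly.
#' @export
write_assembly <- function(asm, fasta, mask_bed = NULL) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(asm$seq), fasta)
  if (!is.null(mask_bed)) {
    readr::write_tsv(asm$mask, mask_bed, col_names = FALSE)
  }
  invisible(asm)
}

#' Read an assembly from FASTA (and optionally a mask BED)
#'
#' @param fasta FASTA path.
#' @param mask_bed Optional BED path (chrom, start, end; no header).
#' @return A [genome_assembly()].
#' @export
read_assembly <- function(fasta, mask_bed = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  mask <- if (!is.null(mask_bed)) {
    readr::read_tsv(mask_bed, col_names = c("chrom", "start", "end"),
                    col_types = "cii", progress = FALSE)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  genome_assembly(seqs, mask)
}

#' Write gene models as BED12
#'
#' Exon block structure goes in columns 10-12; the thick interval holds the
#' genomic extent of the coding region.
#'
#' @param genes Gene-model tibble ([gene_models()]).
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  rows <- purrr::pmap_dfr(genes, function(gene_id, chrom, strand, start, end,
                                          exon_starts, exon_ends, cds_start,
                                          cds_end, n_exons, spliced_len, ...) {
    sizes <- exon_ends - exon_starts
    tibble(chrom = chrom, start = start, end = end, name = gene_id, score = 0L,
           strand = strand, thick_start = start, thick_end = end,
           rgb = "0", block_count = n_exons,
           block_sizes = paste0(paste(sizes, collapse = ","), ","),
           block_starts = paste0(paste(exon_starts - start, collapse = ","), ","),
           cds_start = cds_start, cds_end = cds_end)
  })
  readr::write_tsv(rows, path, col_names = FALSE)
}

#' Read gene models from BED12
#'
#' @param path BED12 path written by [write_gene_models()].
#' @return Gene-model tibble.
#' @export
read_gene_models <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thick_start", "thick_end", "rgb", "block_count",
                  "block_sizes", "block_starts", "cds_start", "cds_end"),
    col_types = "ciiciciiciccii", progress = FALSE
  )
  purrr::pmap_dfr(raw, function(chrom, start, end, name, score, strand,
                                thick_start, thick_end, rgb, block_count,
                                block_sizes, block_starts, cds_start, cds_end) {
    sizes <- as.integer(strsplit(block_sizes, ",")[[1]])
    offs <- as.integer(strsplit(block_starts, ",")[[1]])
    tibble(gene_id = name, chrom = chrom, strand = strand,
           start = start, end = end,
           exon_starts = list(start + offs),
           exon_ends = list(start + offs + sizes),
           cds_start = cds_start, cds_end = cds_end,
           n_exons = block_count, spliced_len = sum(sizes))
  })
}

#' Write / read a depth track
#'
#' Columns: chrom, start, end, unmasked, gc, depth.
#'
#' @param track Depth-track tibble.
#' @param path TSV path.
#' @export
write_depth_track <- function(track, path) {
  readr::write_tsv(track |> select("chrom", "start", "end", "unmasked",
                                   "gc", "depth"), path)
}

#' @rdname write_depth_track
#' @export
read_depth_track <- function(path) {
  readr::read_tsv(path, col_types = "ciiidi", progress = FALSE)
}

#' Write / read duplication pairs as BEDPE
#'
#' Columns: chromA, startA, endA, chromB, startB, endB, identity, length.
#'
#' @param pairs Pair tibble ([find_pairwise_duplications()]).
#' @param path BEDPE path.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, col_names = FALSE)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_names = c("chrom1", "start1", "end1", "chrom2",
                                      "start2", "end2", "identity", "length"),
                  col_types = "ciiciidi", progress = FALSE)
}

#' Write truth records to TSV
#'
#' One file per event kind is conventional; this writer keeps all kinds in
#' one table with a `kind` column.
#'
#' @param truth Truth tibble ([truth_records()]).
#' @param path TSV path.
#' @export
write_truth_records <- function(truth, path) {
  readr::write_tsv(truth, path)
}
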