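#' Estimate per-window copy number from a depth track
#'
#' Depth is corrected for local GC content by dividing each window's raw
#' depth by the mean depth of control windows in the same GC bin (bins of
#' width 0.05), then scaled so that control windows average copy number 2.
#' Control regions must exclude known duplications and deletions (the
#' caller's responsibility); a GC bin containing no control window falls back
#' to the global control mean with a warning.
#'
#' @param track Depth-track tibble (`chrom`, `start`, `end`, `unmasked`, `gc`,
#'   `depth`), e.g. from [simulate_depth()] or [read_depth_track()].
#' @param controls Tibble of control intervals (`chrom`, `start`, `end`);
#'   windows fully contained in a control interval are the normalisation set.
#' @param gc_binwidth GC bin width.
#' @return The track with `corrected` depth and `copy_number` columns added.
#' @export
estimate_copy_number <- function(track, controls, gc_binwidth = 0.05) {
  if (is.null(controls) || nrow(controls) == 0) abort("control regions required")
  is_control <- window_in_intervals(track, controls)
  if (sum(is_control) < 1) abort("no windows fall inside the control regions")
  bins <- pmin(floor(track$gc / gc_binwidth), ceiling(1 / gc_binwidth) - 1)
  ctrl_depth <- track$depth[is_control]
  ctrl_bins <- bins[is_control]
  global_mean <- mean(ctrl_depth)
  bin_means <- tapply(ctrl_depth, ctrl_bins, mean)
  key <- as.character(bins)
  mu <- as.numeric(bin_means[key])
  if (anyNA(mu)) {
    warn("GC bins without control windows; falling back to the global control mean")
    mu[is.na(mu)] <- global_mean
  }
  corrected <- track$depth / mu
  scale <- 2 / mean(corrected[is_control])
  track |>
    mutate(control = is_control, corrected = corrected,
           copy_number = corrected * scale)
}

# windows fully contained in any of the given intervals
window_in_intervals <- function(track, intervals) {
  out <- logical(nrow(track))
  for (cc in unique(track$chrom)) {
    sel <- which(track$chrom == cc)
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    if (nrow(iv) == 0) next
    for (i in sel) {
      out[i] <- any(iv$start <= track$start[i] & iv$end >= track$end[i])
    }
  }
  out
}

#' Call duplicated regions from copy-number windows
#'
#' A duplicated region is a maximal run of consecutive windows (adjacent in
#' the sorted window list of one chromosome) whose copy numbers all exceed
#' `cn_min`, kept if the run has at least `min_windows` windows and spans at
#' least `min_span` genomic bp (first window start to last window end).
#' Region copy number is the median over member windows.
#'
#' @param windows Window tibble with `copy_number` (from
#'   [estimate_copy_number()]).
#' @param cn_min Copy-number threshold (exclusive).
#' @param min_windows Minimum run length in windows.
#' @param min_span Minimum genomic span in bp.
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`, `median_cn`.
#' @export
call_duplicated_regions <- function(windows, cn_min = 2.5, min_windows = 4,
                                    min_span = 10000) {
  windows |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      empty <- tibble(start = integer(), end = integer(),
                      n_windows = integer(), median_cn = double())
      high <- as.logical(d$copy_number > cn_min)
      if (!any(high)) return(empty)
      r <- rle(high)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- tibble(from = starts[r$values], to = ends[r$values])
      purrr::pmap_dfr(runs, function(from, to) {
        span_start <- d$start[from]; span_end <- d$end[to]
        if (to - from + 1 < min_windows || span_end - span_start < min_span) {
          return(NULL)
        }
        tibble(start = span_start, end = span_end,
               n_windows = to - from + 1L,
               median_cn = median(d$copy_number[from:to]))
      })
    }) |>
    ungroup()
}

#' Gene copy number from encompassed windows
#'
#' A gene's copy number is the median copy number of the windows it fully
#' encompasses; genes encompassing fewer than `min_windows` windows are
#' omitted. A gene is flagged duplicated when its copy number exceeds
#' `cn_dup`.
#'
#' @param windows Window tibble with `copy_number`.
#' @param genes Gene-model tibble ([gene_models()]) or any tibble with
#'   `gene_id`, `chrom`, `start`, `end`.
#' @param min_windows Minimum number of fully encompassed windows.
#' @param cn_dup Duplication threshold (exclusive).
#' @return Tibble with `gene_id`, `n_windows`, `copy_number`, `duplicated`.
#' @export
gene_copy_number <- function(windows, genes, min_windows = 3, cn_dup = 2.5) {
  purrr::pmap_dfr(
    genes |> select("gene_id", "chrom", "start", "end"),
    function(gene_id, chrom, start, end) {
      w <- windows |> filter(.data$chrom == .env$chrom,
                             .data$start >= .env$start, .data$end <= .env$end)
      if (nrow(w) < min_windows) return(NULL)
      cn <- median(w$copy_number)
      tibble(gene_id = gene_id, n_windows = nrow(w), copy_number = cn,
             duplicated = cn > cn_dup)
    }
  )
}
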