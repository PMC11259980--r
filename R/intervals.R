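# Interval arithmetic on tibbles with 0-based half-open `start`/`end` columns,
# one `chrom` column. Thin wrappers over IRanges, applied per chromosome.

as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

from_iranges0 <- function(ir) {
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# merge overlapping or book-ended intervals per chromosome
reduce_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  df |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      from_iranges0(IRanges::reduce(as_iranges0(d$start, d$end)))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

total_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  red <- reduce_intervals(df)
  sum(as.numeric(red$end - red$start))
}

# per-chromosome set operations; both inputs tibbles(chrom,start,end)
intersect_intervals <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  purrr::map_dfr(chroms, function(cc) {
    ia <- as_iranges0(a$start[a$chrom == cc], a$end[a$chrom == cc])
    ib <- as_iranges0(b$start[b$chrom == cc], b$end[b$chrom == cc])
    out <- IRanges::intersect(IRanges::reduce(ia), IRanges::reduce(ib))
    if (length(out) == 0) return(NULL)
    bind_cols(tibble(chrom = cc), from_iranges0(out))
  })
}

setdiff_intervals <- function(a, b) {
  purrr::map_dfr(unique(a$chrom), function(cc) {
    ia <- IRanges::reduce(as_iranges0(a$start[a$chrom == cc], a$end[a$chrom == cc]))
    ib <- b[b$chrom == cc, , drop = FALSE]
    out <- if (nrow(ib) == 0) ia else {
      IRanges::setdiff(ia, IRanges::reduce(as_iranges0(ib$start, ib$end)))
    }
    if (length(out) == 0) return(NULL)
    bind_cols(tibble(chrom = cc), from_iranges0(out))
  })
}

# logical: does each row of `a` overlap any interval of `b`?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical())
  out <- logical(nrow(a))
  for (cc in unique(a$chrom)) {
    sel <- a$chrom == cc
    ib <- b[b$chrom == cc, , drop = FALSE]
    if (nrow(ib) == 0) next
    hits <- IRanges::overlapsAny(as_iranges0(a$start[sel], a$end[sel]),
                                 as_iranges0(ib$start, ib$end))
    out[sel] <- hits
  }
  out
}

# count of b-intervals overlapping each a-interval
count_overlaps <- function(a, b) {
  if (nrow(a) == 0) return(integer())
  out <- integer(nrow(a))
  for (cc in unique(a$chrom)) {
    sel <- a$chrom == cc
    ib <- b[b$chrom == cc, , drop = FALSE]
    if (nrow(ib) == 0) next
    out[sel] <- IRanges::countOverlaps(as_iranges0(a$start[sel], a$end[sel]),
                                       as_iranges0(ib$start, ib$end))
  }
  out
}

# complement of `df` within chromosomes of the given sizes
complement_intervals <- function(df, sizes) {
  purrr::map_dfr(names(sizes), function(cc) {
    full <- tibble(chrom = cc, start = 0L, end = as.integer(sizes[[cc]]))
    setdiff_intervals(full, df[df$chrom == cc, , drop = FALSE])
  })
}
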