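# Independent oracles used to cross-check the implementation. These are
# deliberately written as direct, brute-force procedures sharing no code with
# the package internals.

# Plain-R affine-gap Smith-Waterman with the hallmark scoring scheme and the
# documented tie rule (smallest a_start, then b_start, then a_end, then
# b_end; traceback prefers diagonal, then gap-in-b, then gap-in-a).
oracle_sw <- function(a, b, match = 2, mismatch = -6, gap_open = 10,
                      gap_ext = 10, n_pen = -1000) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  sc <- function(x, y) {
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T"))) {
      return(n_pen)
    }
    if (x == y) match else mismatch
  }
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (gap_open + gap_ext),
                             E[i + 1, j] - gap_ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (gap_open + gap_ext),
                             F[i, j + 1] - gap_ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + sc(av[i], bv[j]),
                             E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0, a_start = 0, a_end = 0, b_start = 0, b_end = 0,
                columns = 0))
  }
  cand <- NULL
  for (i in 1:n) for (j in 1:m) {
    if (H[i + 1, j + 1] != best) next
    ti <- i; tj <- j; cols <- 0
    as_ <- i; bs_ <- j
    state <- "H"
    repeat {
      if (state == "H") {
        v <- H[ti + 1, tj + 1]
        if (v == 0) break
        s <- sc(av[ti], bv[tj])
        if (v == H[ti, tj] + s) {
          as_ <- ti; bs_ <- tj; ti <- ti - 1; tj <- tj - 1; cols <- cols + 1
        } else if (v == F[ti + 1, tj + 1]) {
          state <- "F"
        } else {
          state <- "E"
        }
      } else if (state == "F") {
        cols <- cols + 1
        v <- F[ti + 1, tj + 1]
        as_ <- ti
        if (v == H[ti, tj + 1] - (gap_open + gap_ext)) {
          ti <- ti - 1; state <- "H"
        } else {
          ti <- ti - 1; state <- "F"
        }
      } else {
        cols <- cols + 1
        v <- E[ti + 1, tj + 1]
        bs_ <- tj
        if (v == H[ti + 1, tj] - (gap_open + gap_ext)) {
          tj <- tj - 1; state <- "H"
        } else {
          tj <- tj - 1; state <- "E"
        }
      }
    }
    key <- c(as_, bs_, i, j)
    if (is.null(cand) || lex_less(key, cand$key)) {
      cand <- list(key = key, score = best, a_start = as_, a_end = i,
                   b_start = bs_, b_end = j, columns = cols)
    }
  }
  cand[c("score", "a_start", "a_end", "b_start", "b_end", "columns")]
}

lex_less <- function(x, y) {
  for (k in seq_along(x)) {
    if (x[k] < y[k]) return(TRUE)
    if (x[k] > y[k]) return(FALSE)
  }
  FALSE
}

# brute-force duplicated-region caller: tests every window run directly
oracle_region_scan <- function(windows, cn_min = 2.5, min_windows = 4,
                               min_span = 10000) {
  out <- NULL
  for (cc in unique(windows$chrom)) {
    d <- windows[windows$chrom == cc, ]
    d <- d[order(d$start), ]
    n <- nrow(d)
    i <- 1
    while (i <= n) {
      if (d$copy_number[i] > cn_min) {
        j <- i
        while (j < n && d$copy_number[j + 1] > cn_min) j <- j + 1
        if (j - i + 1 >= min_windows && d$end[j] - d$start[i] >= min_span) {
          out <- rbind(out, data.frame(
            chrom = cc, start = d$start[i], end = d$end[j],
            n_windows = j - i + 1, median_cn = median(d$copy_number[i:j])
          ))
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), median_cn = double())
  }
  out
}

# per-base bitmap union size of intervals (0-based half-open)
oracle_union_bp <- function(intervals, sizes) {
  total <- 0
  for (cc in unique(intervals$chrom)) {
    bit <- logical(sizes[[cc]])
    d <- intervals[intervals$chrom == cc, ]
    for (r in seq_len(nrow(d))) {
      bit[(d$start[r] + 1):d$end[r]] <- TRUE
    }
    total <- total + sum(bit)
  }
  total
}

oracle_intersect_bp <- function(a, b, sizes) {
  total <- 0
  for (cc in union(unique(a$chrom), unique(b$chrom))) {
    bita <- logical(sizes[[cc]]); bitb <- logical(sizes[[cc]])
    da <- a[a$chrom == cc, ]; db <- b[b$chrom == cc, ]
    for (r in seq_len(nrow(da))) bita[(da$start[r] + 1):da$end[r]] <- TRUE
    for (r in seq_len(nrow(db))) bitb[(db$start[r] + 1):db$end[r]] <- TRUE
    total <- total + sum(bita & bitb)
  }
  total
}

# interval-stabbing count: how many of the given intervals overlap [s, e)?
oracle_stab_count <- function(intervals, chrom, s, e) {
  d <- intervals[intervals$chrom == chrom, ]
  sum(d$start < e & d$end > s)
}

# independent codon scan: translate an ORF with a lookup table built here
oracle_translate <- function(seq) {
  codons <- substring(seq, seq(1, nchar(seq) - 2, by = 3),
                      seq(3, nchar(seq), by = 3))
  tab <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
           CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
           GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
           TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
           ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
           GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
           CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
           AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
           TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
           CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
           GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  paste(tab[codons], collapse = "")
}

# Hamming identity computed without package helpers
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av == bv)
}
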