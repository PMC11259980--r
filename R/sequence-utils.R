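# Small nucleotide-string helpers. Sequences are plain upper-case character
# strings; coordinates throughout the package are 0-based, half-open (BED).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# random sequence with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substitute bases at `pos` (0-based) of `seq` with random *different* bases
mutate_bases <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  raw <- charToRaw(seq)
  cur <- rawToChar(raw[pos + 1], multiple = TRUE)
  new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1), "", USE.NAMES = FALSE)
  raw[pos + 1] <- charToRaw(paste(new, collapse = ""))
  rawToChar(raw)
}

# point-mutate with per-base probability p; returns list(seq, n_changed)
diverge_sequence <- function(seq, p) {
  n <- nchar(seq)
  if (p <= 0 || n == 0) return(list(seq = seq, positions = integer()))
  pos <- which(runif(n) < p) - 1L
  list(seq = mutate_bases(seq, pos), positions = pos)
}

gc_of <- function(seq) {
  if (nchar(seq) == 0) return(NA_real_)
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  sum(counts[c("G", "C")]) / nchar(seq)
}

# translate a DNA string (must start in frame); returns AA string with "*" stops
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     if.fuzzy.codon = "X"))
}

# random open reading frame of `n_codons` codons: ATG ... stop
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  mid <- sample(sense, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), sample(STOP_CODONS, 1))
}

# X-drop extension of a gap-free homology: walk outward scoring +1 per match
# and -3 per mismatch, stop when the score falls more than `xdrop` below its
# running maximum, then trim back to the outermost terminal anchor (a base
# that matches and closes a window of `anchor` columns with at most one
# mismatch). The X-drop tolerates the isolated substitutions of a diverged
# copy; the anchor requirement stops chance-match creep into unrelated
# sequence. Coordinates are 0-based half-open.
extend_homology <- function(x, y, xs, xe, ys, ye, xdrop = 12, match = 1,
                            mismatch = -3, max_ext = 400, anchor = 8) {
  ext_len <- function(eq) {
    if (length(eq) == 0) return(0L)
    sc <- cumsum(ifelse(eq, match, mismatch))
    drop <- which(cummax(sc) - sc > xdrop)
    lim <- if (length(drop) == 0) length(eq) else drop[1] - 1L
    if (lim == 0) return(0L)
    eq <- eq[seq_len(lim)]
    cm <- cumsum(eq)
    lag_cm <- c(rep(0L, anchor), cm)[seq_along(cm)]
    win_hits <- cm - lag_cm
    anchored <- eq & win_hits >= pmin(seq_along(eq), anchor) - 1L
    hits <- which(anchored)
    if (length(hits) == 0) 0L else tail(hits, 1)
  }
  nl <- min(xs, ys, max_ext)
  if (nl > 0) {
    xa <- rev(charToRaw(substr(x, xs - nl + 1, xs)))
    ya <- rev(charToRaw(substr(y, ys - nl + 1, ys)))
    k <- ext_len(xa == ya)
    xs <- xs - k; ys <- ys - k
  }
  nr <- min(nchar(x) - xe, nchar(y) - ye, max_ext)
  if (nr > 0) {
    xa <- charToRaw(substr(x, xe + 1, xe + nr))
    ya <- charToRaw(substr(y, ye + 1, ye + nr))
    k <- ext_len(xa == ya)
    xe <- xe + k; ye <- ye + k
  }
  list(xs = xs, xe = xe, ys = ys, ye = ye)
}

# matches / (matches + mismatches) between equal-length strings, gap-free
hamming_identity <- function(a, b) {
  cmp <- cpp_base_compare(a, b)
  if (cmp$matches + cmp$mismatches == 0) return(NA_real_)
  cmp$matches / (cmp$matches + cmp$mismatches)
}
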