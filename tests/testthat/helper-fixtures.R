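# Shared fixture builders (all generated in code, seeded for determinism).

# small assembly with two genes and a handful of retrocopies
fixture_retro_genome <- function(seed = 101, chrom_length = 150000) {
  g <- make_genome(2, chrom_length, 0.05, 0.42, seed = seed)
  g <- plant_gene(g, n_exons = 4, exon_len = 350, intron_len = 400,
                  seed = seed + 1)
  g <- plant_gene(g, n_exons = 3, exon_len = 300, intron_len = 600,
                  strand = "-", seed = seed + 2)
  g <- plant_retrocopy(g, "gene1", orientation = "+", tsd_len = 12,
                       polya_len = 14, seed = seed + 3)
  g <- plant_retrocopy(g, "gene1", orientation = "-", tsd_len = 9,
                       polya_len = 8, divergence = 0.03, seed = seed + 4)
  g <- plant_retrocopy(g, "gene2", orientation = "+", tsd_len = 15,
                       polya_len = 10, truncation = 0.4, seed = seed + 5)
  g
}

# random hallmark locus flanks with a planted TSD whose flanks cannot contain
# competing alignments: upstream context uses {A,C}, downstream uses {G,T},
# so only the planted TSD copies can align
fixture_tsd_flanks <- function(tsd_len, flank = 60, polya_gap = 0) {
  alpha_up <- c("A", "C"); alpha_dn <- c("G", "T")
  tsd <- paste(sample(c("A", "C", "G", "T"), tsd_len, replace = TRUE),
               collapse = "")
  up <- paste0(paste(sample(alpha_up, flank - tsd_len, replace = TRUE),
                     collapse = ""), tsd)
  pad <- if (polya_gap > 0) {
    paste(sample(alpha_dn, polya_gap, replace = TRUE), collapse = "")
  } else ""
  dn <- paste0(pad, tsd,
               paste(sample(alpha_dn, flank - tsd_len - polya_gap,
                            replace = TRUE), collapse = ""))
  list(up = up, down = dn, tsd = tsd)
}

# Six-assembly presence/absence replicate with known sharing truth.
# Independent private insertions in *different* sisters can land within one
# flank width of each other; such loci are unresolvable by flank mapping
# (the method discounts them, which is asserted separately), so the
# replicate is re-drawn until all cross-assembly private sites are at least
# 1,500 bp apart in base coordinates and the simple truth tabulation holds.
make_presence_replicate <- function(seed0, n_assemblies = 6,
                                    n_shared = 4, generations = 10000) {
  for (try in 0:5) {
    s0 <- seed0 + 7777 * try
    base <- make_genome(1, 120000, 0, 0.42, seed = s0)
    base <- plant_gene(base, n_exons = 3, exon_len = 300, intron_len = 400,
                       seed = s0 + 1)
    for (i in seq_len(n_shared)) {
      base <- plant_retrocopy(base, "gene1", seed = s0 + 1 + i)
    }
    asms <- list(ref = base)
    loci <- subset(truth_records(base),
                   kind == "retrocopy")[, c("chrom", "start", "end")]
    loci$assembly <- "ref"
    priv_truth <- list(ref = 0L)
    withr::with_seed(s0 + 99, {
      privates <- sample(0:2, n_assemblies - 1, replace = TRUE)
    })
    priv_sites <- NULL
    for (a in seq_len(n_assemblies - 1)) {
      nm <- paste0("asm", a)
      d <- diverge_assembly(base, generations, private_retros = privates[a],
                            seed = s0 + 10 + a)
      asms[[nm]] <- d$assembly
      mine <- subset(truth_records(d$assembly),
                     kind == "retrocopy")[, c("chrom", "start", "end")]
      if (nrow(mine) > 0) {
        mine$assembly <- nm
        loci <- rbind(loci, mine)
      }
      priv <- subset(d$truth, kind == "retrocopy")
      if (nrow(priv) > 0) {
        priv <- priv[order(priv$start), ]
        lens <- priv$end - priv$start
        base_pos <- priv$start - c(0, cumsum(lens))[seq_len(nrow(priv))]
        priv_sites <- rbind(priv_sites,
                            data.frame(assembly = nm, pos = base_pos))
      }
      priv_truth[[nm]] <- privates[a]
    }
    collision <- FALSE
    if (!is.null(priv_sites) && nrow(priv_sites) > 1) {
      for (i in seq_len(nrow(priv_sites) - 1)) {
        for (j in (i + 1):nrow(priv_sites)) {
          if (priv_sites$assembly[i] != priv_sites$assembly[j] &&
              abs(priv_sites$pos[i] - priv_sites$pos[j]) < 1500) {
            collision <- TRUE
          }
        }
      }
    }
    if (!collision) {
      return(list(asms = asms, loci = loci, n_shared = n_shared,
                  priv_truth = priv_truth))
    }
  }
  stop("could not draw a collision-free presence replicate")
}

# a clean poly(A) region: run of P homopolymer bases then a terminator
# context that cannot extend the run under the 4-of-5 rule
fixture_polya_region <- function(P, base = "A", lead = 0, total = 60) {
  other <- setdiff(c("C", "G"), base)[1]
  lead_seq <- if (lead > 0) {
    paste(sample(c("C", "G"), lead, replace = TRUE), collapse = "")
  } else ""
  tail_len <- total - lead - P
  tail_seq <- paste(rep(other, max(tail_len, 2)), collapse = "")
  paste0(lead_seq, strrep(base, P), tail_seq)
}
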