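---
title: "Duplication and retrocopy analysis: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplication and retrocopy analysis: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscape)
```

## The scientific problem

Gene duplications arise either at the DNA level (segmental duplications:
non-repetitive sequence of at least 1 kb present in more than one copy per
haploid genome) or through retrotransposition, where an mRNA is reverse
transcribed by the LINE-1 machinery and reintegrated as an intronless
*retrocopy*. A retrocopy insertion leaves mechanistic scars: a target-site
duplication (TSD) — a short direct repeat created by staggered endonuclease
cleavage — a poly(A) run inherited from the transcript, and an endonuclease
cleavage-site motif (canonically read TTTT/AA on the minus strand).

retroscape implements the full analysis chain used to characterise these
events in genome assemblies, with canine genomes as the motivating system:
duplication discovery by genome self-alignment and by read-depth, retrocopy
discovery from cDNA-to-genome alignment, hallmark annotation, cross-assembly
presence/absence by flank mapping, and a calibrated estimate of the
per-generation retrocopy insertion rate. Because the real data of interest
(multi-gigabase assemblies and their Illumina depth profiles) cannot ship
with a package, a synthetic-genome generator is a first-class component:
every stage is validated against planted ground truth.

## The synthetic-data generator

`make_genome()` draws i.i.d. nucleotides at a target GC fraction and places
non-overlapping mask intervals (500–2,000 bp) until a target repeat fraction
is reached. The mask plays the role of a RepeatMasker/WindowMasker track: it
suppresses seeding during self-alignment and defines the unmasked positions
on which depth windows are built. Masked intervals contain ordinary random
sequence — the generator does not simulate transposon families, so the mask
models *where* repeats are, not *what* they look like.

`plant_gene()` writes a multi-exon gene with an intact ORF (ATG, no internal
stop, terminal stop across the spliced exons). Genes overwrite sequence in
place; retrocopies and duplications insert sequence, shifting all downstream
coordinates (mask, genes, previous truth records) — an insertion landing
inside a mask interval splits it.

`plant_retrocopy()` follows the staggered-cut integration mechanism: the
`tsd_len` bases of target sequence at the chosen site become the TSD, and
the insertion body — the 5′-truncated, point-mutated cDNA plus a poly(A) run
written in transcript orientation — followed by a second TSD copy lands
immediately after it. The pre-integration allele therefore keeps a single
TSD copy, which is what makes filled/empty (dimorphic-locus) comparison
meaningful; `empty_site_sequence()` reconstructs that allele exactly. When a
cleavage motif is requested (the default plants the canonical site as the
7-mer TTTTAAA, which contains the printed TTTT/AA consensus), the two bases
preceding the TSD and its first five bases in retrocopy orientation are
rewritten so the extraction convention below recovers the motif on either
strand.

Placement uses bounded rejection sampling (100 tries, then an error rather
than a silent overlap). Planted events keep 600 bp of clear sequence from
each other and 1,000 bp from chromosome ends, so that flank-based analyses
(hallmarks at 60 bp, presence testing at 500 bp, ancestral mapping at 1 kb)
always see uncontaminated flanks. Real genomes offer no such guarantee —
nested and adjacent insertions exist — so passing tests here demonstrate
correctness of the rules, not robustness to every genomic configuration.

`diverge_assembly()` models two lineages separated for *g* generations:
every unmasked, event-free site substitutes with probability 2·μ·*g*
(binomial, matching the expectation used in the generation formula below),
and the sister optionally gains private retrocopy insertions. SNPs avoid
masked and event positions so that truth SNP counts remain interpretable
after the duplication/repeat filtering the rate estimate prescribes.

`simulate_depth()` tabulates windows of exactly 1,000 unmasked positions
(the last window per chromosome may be short) and draws window depth as
Poisson(mean_depth × CN/2 × GC-modulation). The diploid copy number of a
window inside a planted duplication family with *n* extra copies is
2·(*n*+1): under multi-mapped read placement every family member receives
reads from all paralogs, which is the regime the read-depth method operates
in. The GC modulation is linear (1 + gc_bias·2·(GC−0.5)); real Illumina
bias is nonlinear and library-dependent, but a monotone bias is all the
bin-mean correction needs to be exercised against. No read-level error
model, no FASTQ.

## Duplication discovery by self-alignment

The published analyses use a dedicated segmental-duplication aligner whose
internals are not part of this package's claims; retroscape honours its
output contract with a transparent stand-in: exact 31-mer seeds (never
initiated inside masked intervals; k-mers occurring more than 64 times are
skipped), chained along shared diagonals (seed gaps over 500 bp split a
chain), extended outward by gap-free X-drop extension (+1 per match, −3 per
mismatch, stop 12 below the running maximum, then trimmed back to a
terminal anchor of at least 7 matches in the trailing 8 columns), and
reported when at least 1,000 bp at identity ≥ 0.90. Identity is matches/(matches+mismatches),
gap-free — the generator plants substitutions only, so homologous pairs sit
on a single diagonal and gap handling is unnecessary. Mitochondrial
sequences (`chrM`) are excluded; each pair is stored once with its intervals
in canonical order. Inverted duplications are not searched: the generator
plants direct copies, and the downstream statistics never use orientation.
The X-drop tolerates the isolated substitutions of a diverged copy (a
clean 31-mer becomes rare near 5% divergence, so exact-match extension
alone would lose tens of bases per edge), while the terminal anchor stops
chance-match creep into unrelated sequence within a few bases. Reported
boundaries therefore sit within a few bases of the planted ones; recovery
tests compare intervals with that small slack rather than exactly.

Post-processing follows the published rules exactly: projections of both
pair ends are merged (overlapping or book-ended) into a nonredundant
interval set, split into assembled versus unplaced partitions;
high-recurrence segments take duplications under 2.5 kb, round their
coordinates to the nearest hundred (half away from zero: the stated
examples 2,349 → 2,300 and 3,175 → 3,200 do not exercise ties, so a fixed
rule is required), merge them, and keep segments with at least four distinct
contributing duplications. A pair whose two ends both land in one segment
counts once. Edge enrichment compares the observed fraction of intervals in
the first/last megabase of each chromosome against 1,000 uniform
re-placements within the same chromosome (lengths preserved, mask avoided
when supplied); chromosomes shorter than twice the edge are skipped with a
warning.

The self-alignment versus read-depth comparison filters both sets the same
way — assembled chromosomes, spans over 15 kb, pair identity at least 0.95,
first megabase excluded — and reports union/intersection/unique base pairs
plus per-set support: a self-alignment interval is supported when the median
copy number of its intersecting windows is at least 2.5; a read-depth region
is supported when it overlaps any self-alignment interval.

## Read-depth copy number

GC correction is deliberately simple: control windows (windows fully inside
caller-supplied control regions, which must exclude known CNVs) are binned
by GC in bins of width 0.05; each window's depth is divided by its bin's
control mean (empty bins fall back to the global control mean with a
warning), and the result is scaled so control windows average copy number 2.
A loess fit would be smoother, but bin-mean scaling is the simplest contract
that removes a monotone bias and keeps the normalisation target explicit.
Doubling all depths leaves copy numbers unchanged.

Duplicated regions are maximal runs of windows with CN > 2.5 — consecutive
means adjacent in the sorted window list of one chromosome, regardless of
the masked gap between them, because windows are defined on unmasked bases —
kept when the run has ≥ 4 windows and spans ≥ 10 kb of genomic sequence
(first window start to last window end, masked interior included). Region
and gene copy numbers are medians over member windows (even counts average
the two central values); a gene must fully encompass at least three windows
to be reported and is duplicated when its median exceeds 2.5.

## Retrocopy discovery

One representative transcript per gene: longest spliced form, ties broken
by fewest exons; genes whose chosen isoform has an intron under 50 bp or a
single exon are rejected (a retrocopy is recognised by its missing introns,
so single-exon genes carry no signal). The cDNA aligner mirrors the BLAT
contract — 11-mer seeds with over-represented genome words skipped
(occurrence > 10, the `-ooc` analogue) — with the same diagonal chaining and
anchored X-drop extension as above, on both strands.

The filter cascade keeps alignments that (a) cover at least 100 aligned bp,
(b) do not overlap the parent gene's genomic footprint (first exon start to
last exon end), (c) reach identity ≥ 0.90 by matches/(matches+mismatches),
and (d) cross at least one exon–exon junction with at least 10 aligned bases
on each side — the margin is a package choice; the rule without a margin
admits 1 bp overhang artifacts. Surviving alignments of one transcript
within 100 bp on one strand merge into a single locus whose segment count is
recorded (multi-segment loci are later excluded from hallmark detection). A
call is full-ORF when one alignment block covers the parental coding region
end-to-end and its genomic translation retains the original start, no
premature stop, and the terminal stop.

## Hallmark detection

Loci within 100 bp of an N gap or a chromosome end, and multi-segment loci,
are excluded. Sixty bp of flank is extracted on each side — 60 bp maximises
TSD/poly(A) concordance while keeping the search windows small.

**TSD.** The flanks are aligned with a local Smith–Waterman under +2/match,
−6/mismatch, −1000 for any column involving N, and gap penalties of 10 for
opening and 10 per extended column (so a gap of length *g* costs 10 + 10·*g*;
with +2 matches a gap never pays for itself in practice). Alignments under
5 bp are absent. Among equal-scoring alignments the one with the smallest
upstream start, then smallest downstream start, wins — the referenced tool
reports "the highest scoring alignment only" without a tie rule, and
determinism is required; an independent plain-R implementation of the same
dynamic programme serves as the test oracle. When the best alignment starts
within 5 bp of the upstream flank's outer edge or ends within 5 bp of the
downstream flank's outer edge, both flanks are re-extended by 5 bp
(symmetrically, matching the symmetric extraction) and detection repeats, at
most 10 times. Note the detected TSD is the *maximal scoring repeat* at the
boundary: when adjacent sequence happens to continue the repeat, it can
exceed the mechanistic TSD by a base or two, which is why truth-recovery
tests on pipeline-planted loci allow ±2 bp while tests on constructed
unambiguous flanks demand exact recovery.

**Poly(A).** The original flank distance is re-extracted beyond the
annotated 3′ end (downstream flank for plus-orientation retrocopies,
upstream for minus) and scanned from its 5′-most base for runs of A (plus)
or T (minus). A non-homopolymeric base is absorbed when at least 4 of the
following 5 bases are homopolymeric; runs are trimmed until they start and
end with 3 homopolymeric bases in a row, never extend into the detected TSD
footprint, and must reach 5 bp. Among candidates the one nearest the TSD is
reported; with no TSD, the one nearest the retrocopy. "Nearest" is by
absolute distance — the source procedure does not define the measure when
the TSD lies upstream of all candidates.

**Classification.** Lenient categories need 5 bp of each hallmark; strict
categories need 10 bp and, for `both`, a TSD–poly(A) separation under 5
bases, counted as reference bases strictly between the two footprints.
Concordance means both hallmarks present and separated by fewer than 5
bases.

**Cleavage site.** The 7-mer is the two bases before the TSD plus its first
five bases, read in retrocopy orientation and reverse-complemented for
forward-strand retrocopies, so all sites are reported on the minus strand.
The canonical profile is T-rich before the inferred cut and AA after it.

**Filled/empty confirmation.** `confirm_at_empty_site()` is a deliberately
simplified excision comparator, not a reimplementation of a full
gap-excision aligner: the insertion is localised by exact longest common
prefix/suffix anchoring, must be at least 80 bp, must match the parent cDNA
over more than 75% of its length (local alignment, both orientations), and
unanchored sequence on both sides beyond a 20 bp tolerance is rejected as
structural variation. The confirmed TSD is the maximal exact repeat at the
insertion boundary (5 bp to count). Exact anchoring means the comparator is
intended for loci whose flanks are identical between the two alleles; flank
SNPs shorten the anchors and push a locus toward rejection, mirroring the
source procedure's "perfect sequence identity" stringency.

## Presence across assemblies and the insertion rate

`assess_presence()` extracts 500 bp flanks around a locus and maps each to
the target assembly with the seed aligner (15-mers). A flank placement
counts when it is unique at ≥ 90% identity over ≥ 80% of the flank; both
flanks must land on one chromosome in consistent orientation and order with
spacing at most twice the donor span. The source procedure states the
flank-mapping idea without thresholds, so these are package choices, as are
the gap rules: a flank gap of at most max(60 bp, 25% of the insert) means
the insertion is absent (an empty site retains only the TSD), a gap of at
least 50% of the insert is tested for the insert sequence (75% coverage at
90% identity → shared), and everything else — including the ambiguous
middle zone — is unresolved. `build_presence_matrix()` unifies loci across
assemblies by anchoring each locus's upstream flank onto the
highest-priority assembly (anchors within 100 bp cluster as one event),
re-sources each unified locus from the highest-priority assembly carrying
it, and tests it everywhere; loci with any unresolved cell are discounted
from pattern counts, exactly as the source procedure discounts them.

`estimate_generations()` implements g = SNPs / (2 · size · μ): two lineages
diverging for g generations accumulate 2μg substitutions per base pair. The
SNP count and callable size come from `count_divergence()`, which subtracts
duplication and tandem-repeat exclusions from the called regions before
counting. `estimate_rate()` divides the mean count of lineage-private
retrocopies by the generations, reports it to 3 significant figures (2 when
requested — the published table mixes both), takes births per insertion as
the reciprocal of the *rounded* rate (this reproduces the printed
1/3,650-style figures exactly), and recomputes everything at the
mutation-rate bounds 2.6×10⁻⁹ and 7.1×10⁻⁹. `ancestral_presence()` applies
the outgroup variant: 1 kb flanks on a single contig, intervening sequence
at least 75% of the retrocopy length, and a map-back requirement over the
original locus.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance script are chosen so the
whole chain runs in minutes on one core while keeping every statistical
check well-powered: self-alignment and retrocopy recovery on a 1.2 Mb
two-chromosome genome; TSD/poly(A) recovery on 500 constructed loci;
the alignment oracle on 1,000 random flank pairs up to 80 bp; generation
recovery on 2 Mb sisters at 50k/100k/250k generations (binomial SNP noise
gives a 3σ band of a few percent); presence matrices on twenty six-assembly
replicates of 120 kb genomes. Determinism is end-to-end: every stochastic
operation takes a seed, and the acceptance script derives all of its seeds
from a single `--seed`.

Known limitations worth restating: no inverted duplications and no
indel divergence in the stand-in aligners (both would need gapped chaining);
mask content is random sequence, so repeat-family artifacts (seed
over-representation inside real LINEs/SINEs) are modelled only through the
occurrence filters; the filled/empty comparator requires exact flank
anchors; and the insertion-rate machinery assumes neutral accumulation at a
uniform rate, as the underlying formula does.
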