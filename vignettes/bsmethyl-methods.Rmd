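---
title: "Methods: bisulfite methylome calling and anchored motif discovery"
author: "bsmethyl developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite methylome calling and anchored motif discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmethyl)
```

## Scope and model

bsmethyl reconstructs, as a fully testable desk-scale pipeline, the standard
analysis chain for a bacterial 5-methylcytosine (m5C) methylome measured by
bisulfite sequencing (BS-seq) on a GC-rich linear chromosome of the kind
streptomycetes carry (~70% GC): read mapping against a reference, per-cytosine
methylation calling, CG/CHG/CHH context classification, fixed-window
chromosome profiles, strand-aware upstream-region intersection around
translation starts, and discovery of anchored consensus motifs such as
GGCmCGG and GCCmCG. Because published bacterial BS-seq studies rarely state
their processing parameters, every stage here is an explicit, documented
reconstruction, and a synthetic-data module with complete per-site ground
truth stands in for deposited sequencing data so that each stage is
verifiable without downloads.

The chemistry being modelled: bisulfite deaminates unmethylated cytosine to
uracil (sequenced as T), while 5-methylcytosine is protected and still reads
as C. In a directional library the original-top (OT) strand carries evidence
for top-strand cytosines and the original-bottom (OB) strand for bottom-strand
cytosines (top-strand guanine positions). The residual *non-conversion rate*
ε — the probability that an unmethylated C fails to convert — is the error
floor every caller must test against.

## The simulator and what it does (not) emulate

`generate_genome()` draws i.i.d. bases at a target GC fraction (default
0.70). `generate_annotation()` places non-overlapping genes with random
strands; the translation start is the first base of the start codon.
`plant_methylome()` writes one motif instance into the −500/+100 window
around the translation start of a configurable fraction of genes
(strand-aware; bases are replaced, collisions between instances are avoided
by rejection sampling) and records the anchor cytosine as truth; background
methylation marks a configurable fraction of remaining cytosines per
context. `simulate_reads()` draws fragments uniformly over the linear
chromosome, flips a fair coin for OT/OB, converts unmethylated Cs with
probability `conversion_rate`, protects methylated Cs (Bernoulli per
molecule at the site's methylation fraction — methylated cytosines never
convert; they can only read as non-C through a sequencing error), and
finally applies i.i.d. substitution errors.

Deliberately not emulated: PCR duplicates, indels, adapters, paired ends,
quality-score error profiles, coverage biases (GC bias, origin proximity),
and non-directional library chemistry. A green end-to-end test therefore
establishes correctness of the pipeline's logic under a clean generative
model, not robustness to every artefact of real libraries. Defaults
(directional, 30× coverage, 100 bp reads, conversion 0.995, error 0.001)
are stated configuration, not inferred facts about any particular deposited
dataset.

Two generator choices the contract leaves open, fixed once here:

* **Background site level** — the background *rate* says which fraction of
  cytosines per context is methylated; the per-site methylation *fraction*
  of those sites defaults to 1.0, the simplest model of constitutive
  methyltransferase action.
* **Palindromic motifs** — a motif that equals its own reverse complement is
  planted on both strands' anchors (toggleable). Neither default motif is
  palindromic (the reverse complement of GGCCGG is CCGGCC), so this only
  affects user-supplied motifs.

## Mapping

`build_index()`/`map_reads()` implement reduced-alphabet seeded, ungapped
alignment: the reference is indexed twice, once C→T-converted (OT frame)
and once G→A-converted (OB frame), with every k-mer position stored
(k default 16). A read is converted per frame, its first and last k-mers
seed candidate positions (two seeds tolerate an interior mismatch cheaply),
and each candidate is scored bisulfite-aware against the *unconverted*
reference: in OT, reference C with read T is free but reference T with read
C costs a mismatch; OB mirrors this with reference G / read A. The unique
best candidate within `max_mismatch` (default 2 per 100 bp, scaled by
length) wins; ties are discarded as ambiguous rather than broken
arbitrarily, since an arbitrarily placed read would fabricate methylation
evidence. Indels are out of scope (the simulator emits none). The mapper is
validated against an exhaustive position × frame scan oracle; note the
equivalence is exact only while at least one seed of the best placement is
intact, which is why the oracle-equivalence checks run at zero sequencing
error (conversion still exercises the asymmetric scoring).

## Calling and context

`pileup()` accumulates, per reference cytosine and strand, unconverted (C)
and converted (T) read bases from uniquely mapped reads; other bases are
ignored. `call_methylation()` computes the exact binomial upper tail
p = P(X ≥ n_meth | n_total, ε), applies Benjamini–Hochberg correction
across all sites with coverage ≥ `min_cov` (default 5), and calls a site
when q ≤ α (default 0.05) **and** β = n_meth/n_total ≥ `min_level`
(default 0.5). The β filter matters in bacteria, where per-molecule
methylation by restriction–modification or orphan MTases is expected to be
near-complete at true target sites.

ε defaults to 0.005 (matching the simulator's default conversion of 0.995)
and can be estimated without a spike-in control by `estimate_epsilon()`.
The package pools reads over clearly-unmethylated sites
(`sum(n_meth)/sum(n_total)` where β < 0.1) rather than taking a per-site
median: at 15× per-strand coverage and ε ≈ 0.005 most sites show zero
unconverted reads, so the median is exactly 0 and would degenerate the
test; the median remains available as an option.

Context is read from the two bases 3′ of the cytosine *on its own strand*
(for a bottom-strand site, the complements of the two preceding top-strand
bases): CG if the next base is G, else CHG if the next-next base is G, else
CHH (H ∈ {A, T, C}). Sites with fewer than two downstream bases, or any N,
are `undefined` and excluded from context summaries rather than guessed.
Coordinates are 0-based half-open everywhere internally; GFF3 and SAM
interfaces use their native 1-based conventions, and every text report
states its convention.

Whether genome-wide m5C counts treat the two strands of a CG dinucleotide
separately or as one unit is a reporting convention the field does not fix;
bsmethyl reports strands separately and provides `collapse_cg_pairs()`.

## Windows and tracks

`window_profile()` tiles the chromosome with non-overlapping windows
(default 250 kbp; a "window" without further qualification is read as a
tile, not a sliding window) and reports both a count (`n_called`) and a
level (`mean_beta`) per window, because a "methylation level per window" on
a figure axis can denote either; plots default to the count.
`compare_samples()` requires identical grids and returns per-window
differences — e.g. for two growth timepoints — plus an overlaid two-track
figure. `site_track()` writes called sites as BED6.

## Upstream regions and gene tables

With p the 0-based translation start, the scanned window is [p−500, p+100)
on the + strand and the mirrored interval on the − strand; the
translation-start base counts as the first downstream base (boundary
semantics the literature leaves unstated; both extents are configurable).
Regions are clipped at chromosome ends and flagged. All genes are scanned
(no operon-aware promoter assignment), and a called site inside two
overlapping regions credits both genes — no arbitration.

`genes_with_methylated_upstream()` reports genes with ≥ 1 called site in
the region. With `motifs =` supplied it instead reports the
*consensus-sharing* gene set — genes whose upstream called sites carry one
of the given anchored words — which is how a motif-defined gene list is
assembled from a methylome and the right estimator of the planted gene set
in simulations: under background methylation, the any-site table
necessarily includes genes hit by background sites (~12% of a 1 Mbp genome
lies in some upstream region at the default geometry), while background
sites essentially never match a specific 5–6 bp consensus at its anchor.

## Anchored motif discovery

Each called site contributes, for every word length k (default {5, 6}) and
every anchor offset, the k-word read on the site's own strand with the
methylated C at the anchor. The expected count of a word is the number of
usable sites times its genome-wide frequency among cytosine-anchored
windows (both strands); significance is an exact binomial upper tail with
BH correction across all candidates, and reported motifs must reach
`min_support` (default 5) supporting sites and q ≤ 0.05.

Two design points deserve emphasis:

* **Context-matched null (default).** The word frequency is conditioned on
  the CG/CHG/CHH mix of the input sites: a mixture of per-context
  genome-wide frequencies weighted by the observed context proportions.
  Against an unconditional all-cytosine null, any word that merely contains
  the favoured dinucleotide shows ~2–3× spurious enrichment whenever the
  methylome is context-biased (in the reference synthetic world ~70% of
  called sites are CG-context versus ~35% of genome cytosines, and the
  unconditional null admitted 17 junk words). For sites distributed
  uniformly over all cytosines the two nulls coincide, so null calibration
  is unaffected; `null = "all_cytosines"` restores the unconditional
  version.
* **Greedy sequential masking.** A planted motif resurfaces as dozens of
  shifted, truncated and extended word variants whose supporting sites are
  subsets of the same planted set, with the same expected enrichment and
  higher variance — so a flat ranked list cannot separate the true word
  from its satellites, and pairwise containment rules miss variants that
  overlap without containment. bsmethyl therefore selects motifs the way
  classical motif finders do: take the most significant candidate passing
  the filters, remove its supporting sites, recompute support and
  significance on the remainder, and repeat. Each round re-tests the whole
  anchored-word family on the masked site set, so a candidate must stay
  significant at the family-corrected level (p ≤ q_max divided by the
  family size, Σₖ k·4^(k−1) = 7424 at the defaults) on the
  not-yet-explained sites — otherwise significance borrowed from an
  already-reported motif's sites resurfaces as marginal satellite words.
  For the same reason the initial BH correction runs across the full
  family of valid anchored words, not merely the observed ones
  (conditioning the family on support ≥ 1 is anticonservative and
  measurably broke null calibration). The final list is ranked by
  enrichment.

## Numerical and degenerate-input choices

* Binomial tails use `pbinom(lower.tail = FALSE)`; p = 1 exactly at
  n_meth = 0, and p = εⁿ at full methylation.
* Empty inputs return empty, correctly-typed tables (never errors):
  no calls → empty profile rows/gene table/motif list.
* Corrupt inputs error loudly: alignments out of bounds, call positions
  beyond the genome, mismatched window grids, infeasible gene packings,
  unknown configuration keys.
* A same-position cross-frame alignment tie (possible only for degenerate
  C/G-free reads) is treated as ambiguous: it carries no usable strand
  evidence.
* Seeding: `pipeline_run_all()` expands one global seed into fixed
  per-stage offsets (+1 genome, +2 annotation, +3 methylome, +4 reads), so
  a fixed config and seed reproduce every artifact byte-for-byte (the
  manifest records MD5 checksums).

## Known limitations

BS-seq detects m5C only — m6A/m4C are invisible here. The mapper is
ungapped and single-end. No differential-methylation statistics beyond
per-window deltas are provided. Motif discovery reports exact words (no
IUPAC degeneracy or PWM refinement); a degenerate recognition sequence
appears as several related exact words. The gene tables assign sites to
genes purely by interval overlap, with no operon structure.
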