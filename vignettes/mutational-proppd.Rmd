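---
title: "Methods: mutational peptide-phage display analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutational peptide-phage display analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutppd)
```

# The experiment this package models

Mutational proteomic peptide-phage display probes how missense variants in
intrinsically disordered regions alter short-linear-motif (SLiM) mediated
interactions. A phage library tiles each mutation site with paired
peptides — one wild type, one mutant, identical except at the variant
position — so that selection against an immobilised bait domain reads out
allele preference directly from the relative sequencing counts of the two
members. Selections run over several consecutive days with several
replicate series per bait; enriched pools are barcoded, sequenced, and
the read counts per designed peptide become the raw data.

This vignette records the models and the choices behind each stage, in
the order the pipeline runs them.

# Library design

`tile_region()` places windows of `peptide_len` residues (default 16) at
`step`-residue offsets (default 4) along each disordered region. The
defaults give every interior variant 3–4 covering windows, i.e. 3–4
independent peptide pairs per mutation site; both values are exposed
because they are properties of the oligo pool being emulated, not of the
analysis. Each window overlapping a variant yields one pair, and a window
holding several variants yields one mutant peptide per variant — a
designed peptide never carries more than one mutation. Substitutions may
be multi-residue (equal-length delins strings) as a generalisation of the
single-nucleotide case.

Two rules alter sequences before encoding:

* every cysteine is replaced by alanine in both members
  (`sanitize_peptide()`), avoiding disulphide artefacts on the phage coat;
* reverse translation (`reverse_translate()`) uses a ranked E. coli K-12
  codon table, always choosing the top-ranked codon unless that would
  complete a forbidden restriction site (default SmaI, `CCCGGG`, checked
  across codon boundaries), in which case it backtracks to lower-ranked
  codons at the offending junction. The procedure is deterministic given
  the table, so the design is reproducible byte for byte.

End handling was genuinely open: nothing in the protocol fixes how a
region's trailing residues are tiled. We add one extra window anchored to
the region end *only when it rescues a variant that no grid window
covers*. This keeps the interior coverage count exactly as the grid
implies (an interior variant in a 30-residue region is covered by the 4
windows starting at residues 1, 5, 9, 13) while never losing terminal
variants. Sanitisation can in principle collapse a pair (a C→A variant
becomes A→A after sanitising); such degenerate pairs are dropped with a
warning rather than shipped as identical twins.

# Read processing

Reads carry the layout `barcode5 | adapter5 | insert | adapter3 |
barcode3`. Demultiplexing (`demultiplex()`) requires both barcodes to
match exactly; a read matching one sample's 5' barcode and another's 3'
barcode stays unassigned. No mismatch radius is applied by default since
barcode pairs are short and the dual requirement already suppresses
cross-talk. Reads whose arithmetic mean Phred score is strictly below 20
are discarded (`quality_filter()`; a read at exactly 20.0 is kept).
Inserts are translated in the single fixed frame of the phagemid
architecture; frameshifts are not recovered. A translated peptide is kept
only if it occurs in the library design, and every rejection is tallied
by reason (`no-adapter`, `frame/stop`, `not-in-design`) so read fates
always sum to the input.

Counting and normalisation (`clean_counts()`, `normalise_and_merge()`):

* within each (bait, replicate, day), a peptide observed exactly once is
  removed — singletons in deeply selected pools are carry-over noise;
* retained counts are scaled to counts-per-million within each
  (replicate, day). The constant is arbitrary: all downstream scores are
  built from within-observation count *fractions*, so the scale cancels;
* a replicate's selection days are merged into a per-peptide arithmetic
  mean of the day-normalised counts, with a peptide missing on a
  sequenced day contributing zero (`zero_fill = TRUE`). Zero-filling
  treats absence after cleaning as evidence of depletion; the
  alternative (mean over observed days only) is one switch away because
  the original pipelines do not state which convention they used.

# The mutation-centred analysis

For one bait and one mutation site, let $nc^i_{wt}$ and $nc^i_{mut}$ be
the merged normalised counts of the wild-type and mutant member of
observation $i$ (one observation = one covering window in one replicate;
observations with both counts zero are excluded, because the fractions
below are undefined there). The mutation enrichment score is

$$\mathrm{score} \;=\; \sum_{i=1}^{n}\frac{nc^i_{mut}}{nc^i_{wt}+nc^i_{mut}}
\;-\; \sum_{i=1}^{n}\frac{nc^i_{wt}}{nc^i_{wt}+nc^i_{mut}},$$

a sum of per-observation preferences in $[-1, +1]$, hence bounded by
$\pm n$ and reaching the bound exactly when every observation is fully
one-sided toward the same member. Positive scores mean the mutation
enhances binding. The score is antisymmetric under swapping the labels
and invariant to rescaling any (replicate, day)'s counts.

Significance comes from a two-sided Mann–Whitney test comparing the
vector of wild-type counts against the vector of mutant counts across all
observations (`mw_test()`): the exact null distribution when the pooled
sample size is ≤ 20 with no ties, otherwise midranks with the
tie-corrected normal approximation; all-identical input returns p = 1.
Domain-mutation pairs with p ≤ 0.001 are classified *enhancing* or
*diminishing* by the sign of the score, everything else *neutral* (the
relaxed screening cut-off 0.01 is a parameter). Pairs failing the cut-off
are kept as neutral rather than dropped, and a Benjamini–Hochberg column
is emitted for reference only — classification deliberately uses the raw
cut-off, matching the screening convention. `individual_pair_significance()`
additionally tests each window's replicate-level counts on its own,
reporting how many windows individually support the call.

The observation unit (window × replicate, using day-merged counts) is a
choice: pooling per-day counts instead would inflate $n$ with correlated
observations from the same phage pool lineage. A config switch is not
offered because the merged unit is the only one for which the replicate
structure justifies the rank test's exchangeability assumption.

# Confidence scoring

Each enriched peptide gets one point per satisfied criterion: observation
in ≥ `r_min` replicates (default 2), overlap of ≥ `o_min` residues with
another enriched peptide of the same protein (default 4, one tiling
step), a match of the bait's consensus in the peptide, and a merged count
at or above `c_min` (default: the bait's median merged count, a
self-calibrating support level). Scores 4 / 2–3 / 0–1 map to high /
medium / low confidence. The numeric thresholds are deliberately plain
config keys: the published pipelines defer them to an external service,
so the suite tests the classification rule, not the defaults.

# Motif mapping and Grantham classes

Consensus patterns use an ELM-style subset: literal residues and
bracketed classes are *fixed* (key) positions, `x`/`.` are wild-cards.
Around each mutation a ±20-residue window is cut from the prey protein
(`extract_window()`, truncated at the termini) and both the wild-type and
mutant versions are scanned. The category logic
(`classify_mutation()`):

* a wild-type match covering the mutated position → **key** if the
  position is fixed, else **wildcard**;
* a match covering the position only in the mutant window, with the
  mutated residue at a fixed position → **motif_created**;
* matches only elsewhere in the window → **flanking**, with the distance
  to the nearest match (no maximum distance beyond the window itself);
* otherwise **no_motif**.

Ties between overlapping matches prefer the match covering the mutation,
then the leftmost. Curated known instances, when supplied, replace de
novo scanning of the wild-type window. An optional PSSM scan
(`pssm_scan()`, summed log-odds with a user threshold) exists for baits
whose specificity is poorly captured by a consensus; the consensus path
is primary.

Substitution severity uses the Grantham distance — the classic
composition/polarity/volume metric — frozen as an integer matrix and
classed as conservative (< 51), moderately conservative (51–100),
moderately radical (101–150) or radical (> 150), boundaries closed on the
named ranges. The packaged matrix is recomputed from the original formula
(ρ = 50.723); a few entries of the historically printed table differ from
exact recomputation by ±1 due to rounding at publication time, and the
formula-consistent values are used.

# Affinity analytics

Saturation experiments titrate protein against a fixed 10 nM fluorescent
probe. Because probe and K_D can be comparable, `fit_saturation()` fits
the ligand-depletion (quadratic) binding model — the physical root of the
mass-balance quadratic — rather than a hyperbola; in the limit of protein
far above probe the two coincide. Displacement experiments titrate
unlabelled peptide against a pre-formed probe/protein complex (protein at
1–2× the probe K_D); `fit_displacement()` fits a four-parameter logistic
on log10 concentration. A curve is flagged **non-binding** when no
displacement plateau is resolved inside the titration: the fitted span is
below `min_span` (default 5 mP, below which a "transition" is
indistinguishable from drift at typical instrument noise of ~2 mP) or the
midpoint falls outside the titrated range. Rising polarisation with
competitor is flagged anomalous (probe contamination in practice).

`ic50_to_kd()` converts the displacement midpoint to a competitor K_D
with the full probe-occupancy correction: the zero-competitor complex
from the quadratic, halved at the midpoint, the free-competitor
correction for protein-bound competitor, and the denominator
$L_{50}/K_D + P_0/K_D + 1$. This conversion exactly inverts a numerical
three-species equilibrium (the test suite checks it against an
independent solver); in the dilute limit it approaches the IC50 from
below with leading deviation $(L_{50}+P_0)/K_D$.

Fold-changes are oriented so that fold > 1 means the mutant binds tighter,
making the sign of log2 fold directly comparable to the sign of the
enrichment score. When one member shows no displacement the change is
unbounded and is capped at 20 (log2 = ±4.3, reported to 1 decimal); a
capped record always counts as exceeding the twofold agreement threshold.
A record *agrees* with the phage selection when the K_D change is at
least twofold in the direction of the enrichment score. For baits with
two binding pockets the major (motif-cognate, higher-affinity) pocket's
affinities enter the agreement panel; minor-pocket rows are kept as
supplementary records, and pairs without a phage score are excluded from
the percentage.

# Known-interaction enrichment

`enrichment_ratio()` is the ratio of the known-interaction fraction among
hit protein pairs to that fraction in the searchable background — all
bait × prey protein pairs excluding self-pairs (`background_pairs()`).
Known-interaction sets are consumed as plain pair lists; no live database
queries are made, and pair orientation is ignored.

# The synthetic-data generator

`simulate_library()` builds a toy proteome in which every effect class is
planted explicitly: motif-breaking variants substitute a fixed position
of a planted consensus instance (`[FILV]xFG` by default, planted as
`LAFG`), motif-creating variants complete an almost-instance (`LASG` →
`LAFG`), wild-card variants hit the unconstrained position, and flanking
variants sit 4 residues outside. Background sequence is drawn from an
alphabet that cannot complete the consensus (and contains no cysteine),
so planted instances are the only matches — verified in the tests by
re-scanning every planted variant with the motif-mapping module.

`simulate_counts()` assigns each designed peptide a read propensity from
its motif content: a matching peptide gets the binder baseline, its
non-matching partner a fraction $1-\delta$ of it, and pairs where both or
neither match are symmetric. Deriving propensities from sequence content
(rather than from the truth table) makes the count asymmetries consistent
with the planted classes by construction. Counts per (replicate, day) are
negative binomial (`dispersion` = size 5) around depth-scaled
propensities.

Defaults are the study conditions being emulated: 4 selection days, 5
replicates, 10^5 reads per (replicate, day), δ = 0.9 for the planted
asymmetry, and a binder:background propensity ratio of 5000:1
(`binder_weight` 50, `background_weight` 0.01) — four consecutive
selection rounds at roughly tenfold enrichment per round leave
non-binding clones at 0–1 reads, which the singleton-cleaning rule then
removes. FP curves are generated from the same physical models the
fitters use (quadratic binding; numeric competitive equilibrium) with
Gaussian mP noise (default 2 mP) in technical triplicates, matching how
such measurements are made.

What the generator does *not* emulate: amplification bias across
selection rounds (depth is per-day flat), sequence-composition biases in
display or PCR, partial motif matches of graded affinity, peptides
binding through unmodelled secondary motifs, and correlated noise between
replicates. Passing the recovery benchmarks therefore shows the pipeline
is correct and well-powered under clean planted asymmetries — not that
real screens reach the same sensitivity.

Test problem sizes were chosen to exercise the statistics at meaningful
scale while keeping the default suite quick: the type-I benchmark uses
100 null domain-mutation pairs (the significant fraction is bounded by
the nominal 0.5% plus a two-sigma Monte-Carlo margin for that sample
size), and the power benchmark uses 20 planted breaking/creating variants
at the default replicate structure.

# Numerical choices and degenerate inputs

* Zero/zero paired observations are excluded before scoring (the count
  fractions are undefined); a peptide present on one side only is a valid
  one-sided observation.
* `mw_test()` on all-identical values returns 1; windows with fewer than
  two replicates are skipped (and reported) in per-window testing.
* Curve fitting uses Levenberg–Marquardt (minpack.lm) with data-driven
  starts (half-signal interpolation for K_D, median log concentration
  for IC50); saturation K_D is bounded positive, and a fit is flagged
  rather than returned when it hits bounds, fails to converge, or the
  fitted amplitude is degenerate (flat series).
* Reverse translation backtracks exhaustively, so it fails only if no
  codon assignment avoids the forbidden sites — impossible for the
  default single 6-mer site with ≥ 1 free codon choice per residue pair.
* Reported rounding follows the field's presentation: log2 folds to 1
  decimal, agreement percentages to integers, enrichment ratios to 2
  decimals. Internal computation is never rounded.

# Known limitations

* Confidence-scoring thresholds (replicate count, overlap, count support)
  are defensible defaults, not published constants; conclusions that
  depend on them should scan them.
* The Mann–Whitney test treats observations as exchangeable; windows
  sharing a replicate are correlated in real data, so p-values are
  approximate at small n.
* Motif matching is binary per position; graded specificity requires the
  PSSM path with a user-calibrated threshold.
* The agreement analysis passes SEMs through; it does not propagate
  fitting uncertainty into the fold-changes.
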