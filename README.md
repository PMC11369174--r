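# mutppd

Analysis toolkit for **mutational proteomic peptide-phage display
(ProP-PD)** screens: experiments that ask how disease-associated missense
variants in intrinsically disordered regions (IDRs) break, weaken, enhance
or create protein–protein interactions mediated by short linear motifs
(SLiMs).

In a mutational ProP-PD library every mutation site is tiled by paired
peptides — wild type and mutant, identical except at the variant position —
displayed on phage and selected against purified bait domains. Sequencing
the enriched pools and comparing the paired counts reveals, in a single
selection, which allele each bait prefers. The package implements the full
computational workflow around such a screen, for researchers analysing
their own selections or building simulated ones:

- **Library design** — tiling of disordered regions into wild-type/mutant
  16-mer pairs (4-residue step), cysteine sanitisation, deterministic
  reverse translation with restriction-site avoidance
  (`design_library()`, `tile_region()`, `reverse_translate()`).
- **Read processing** — dual-barcode demultiplexing, average-quality
  filtering (mean Phred < 20 discarded), adapter trimming, fixed-frame
  translation, design matching, singleton cleaning, counts-per-million
  normalisation and selection-day merging (`count_reads()`,
  `clean_counts()`, `normalise_and_merge()`).
- **Confidence scoring** — the 0–4 score over replicate occurrence,
  peptide overlap, motif match and count support; 4 = high confidence,
  2–3 = medium (`score_hits()`).
- **Mutation-centred analysis** — the core of the method. Peptide pairs
  reporting on one mutation site are collapsed per (bait, mutation) and
  scored with the *mutation enrichment score*

  ```
  score = Σᵢ ncᵢ_mut / (ncᵢ_wt + ncᵢ_mut)  −  Σᵢ ncᵢ_wt / (ncᵢ_wt + ncᵢ_mut)
  ```

  over the n paired normalised-count observations (range ±n; positive =
  mutation enhances binding), together with a two-sided Mann–Whitney test
  on the wild-type versus mutant count vectors. Pairs with p ≤ 0.001 are
  classified enhancing or diminishing by the sign of the score
  (`mutation_scan()`, `enrichment_score()`, `mw_test()`).
- **Motif mapping** — classify each mutation against the bait's consensus
  (e.g. `[FILV]xFG`, `PPxY`) as hitting a key residue, a wild-card
  position, a flanking position, or creating the motif instance, with
  Grantham substitution distances and the conservative → radical classes
  (`classify_mutation()`, `grantham()`).
- **Affinity analytics** — fluorescence-polarisation saturation fits
  (ligand-depletion quadratic), displacement fits (4-parameter logistic on
  log concentration), IC50 → K_D conversion with probe-occupancy
  correction, wild-type/mutant fold-changes with non-binder capping at 20
  (|log2| = 4.3), and agreement scoring against the phage enrichment
  scores (`fit_saturation()`, `fit_displacement()`, `ic50_to_kd()`,
  `fold_change()`, `agreement_table()`).
- **Known-interaction enrichment** — fold-enrichment of previously
  reported interactions among hits over the searchable bait × prey
  background (`enrichment_ratio()`, `background_pairs()`).
- **Synthetic data** — a generator of toy proteomes with planted motif
  instances, variant classes with known effect directions, overdispersed
  replicate selection counts and noisy polarisation curves, for end-to-end
  validation with ground truth (`sim_config()`, `simulate_library()`,
  `simulate_counts()`, `simulate_fp_curves()`).

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`tidy()`, `glance()` and `autoplot()` methods (V-shaped score/p plots,
fold-change vs score plots, curve fits).

## Worked example

Simulate a small screen with planted effects, run the mutation-centred
analysis, and check the affinity panel:

```r
library(mutppd)
library(dplyr)

cfg    <- sim_config(seed = 7, n_per_class = 2)   # 8 planted variants
lib    <- simulate_library(cfg)
design <- design_library(lib$regions, lib$variants)
sim    <- simulate_counts(design, cfg)
merged <- normalise_and_merge(clean_counts(sim$counts))
scan   <- mutation_scan(merged, design, p_cutoff = 0.001)

glance(scan)
#> # A tibble: 1 × 5
#>   n_pairs n_enhancing n_diminishing n_neutral p_cutoff
#>     <int>       <int>         <int>     <int>    <dbl>
#> 1       8           2             2         4    0.001

tidy(scan) |>
  select(mutation, n_obs, enrichment_score, p_value, direction) |>
  arrange(p_value)
#> # A tibble: 8 × 5
#>   mutation n_obs enrichment_score      p_value direction
#>   <chr>    <int>            <dbl>        <dbl> <fct>
#> 1 F19S        20          -16.0   0.0000000680 diminishing
#> 2 S20F        16           11.4   0.0000264    enhancing
#> 3 F22S        18          -13.2   0.000328     diminishing
#> 4 S21F        18           11.0   0.000471     enhancing
#> 5 D17S        19            1.41  0.152        neutral
#> 6 A22T        20           -0.775 0.365        neutral
#> 7 M16Q        14           -3.30  0.696        neutral
#> 8 A22T        20           -0.175 0.925        neutral
```

The four planted motif-breaking/-creating variants are recovered with the
correct direction (negative scores = mutation diminishes binding), while
the wild-card and flanking controls stay neutral. `autoplot(scan)` draws
the V-shaped plot of score against −log10 p.

The packaged affinity reference panel (24 wild-type/mutant peptide pairs
measured by FP displacement) is scored for agreement with the phage
selection — at least a twofold K_D difference in the direction of the
enrichment score:

```r
panel <- read_affinity_reference() |> filter(in_agreement_set)
agreement_table(panel)
#> # A tibble: 1 × 3
#>   n_agree n_total   pct
#>     <int>   <int> <dbl>
#> 1      19      24    79
```

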