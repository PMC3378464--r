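---
title: "Predicting nucleosome organization from DNA structural profiles"
author: "nucstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nucleosome organization from DNA structural profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstruct)
library(dplyr)
```

## The model

Nucleosomes — 147 bp of DNA wrapped around a histone octamer — do not form
with equal ease on every sequence. The physicochemical character of the
double helix (how easily it bends, melts, stacks, or flips to non-B forms)
varies with local dinucleotide and trinucleotide content, and this variation
carries a measurable nucleosome-positioning signal. nucstruct turns that
signal into predictions in four stages.

**Structural profiles.** A DNA sequence $s$ is converted into a numeric
vector by replacing each k-mer with its value under one of twelve published
structural scales (propeller twist, DNA denaturation, DNA-bending stiffness,
trinucleotide bendability, duplex disrupt energy, base-stacking energy,
B-to-Z-DNA transition energy, duplex free energy, A-philicity, protein-DNA
twist, B-DNA twist, and protein-induced deformability). The raw vector is
smoothed with a moving average — window 100 bp, step 10 bp — giving the
structure vector $S$ at 10 bp resolution. Smaller windows under-smooth
(< 75 bp leaves k-mer noise) and larger ones (> 150 bp) blur the
inter-nucleosome structure, which is why the window is deliberately smaller
than the ~165 bp nucleosome repeat. Each scale carries a **sign class**:
peaks of positively correlated features and valleys of negatively correlated
features mark nucleosome-favouring DNA, so negative-class profiles are
negated once up front (`oriented_profile()`) and every downstream step works
with peaks only.

**Peak calling (DLaNe).** Per chromosome and feature: (1) the profile is
median-filtered (window 100 bp, i.e. 11 bins) to remove narrow spikes;
(2) the filtered vector $SM$ is cut into non-overlapping scan windows of
165 bp, the typical centre-to-centre spacing of adjacent yeast nucleosomes;
each window's *peak intensity* is $P_i = \max SM - \min SM$, and their mean
$AP_i$ sets the adaptive threshold $P_s \cdot AP_i$ with peak significance
$P_s \in (0, 1]$ (best range 0.3–0.6; default 0.45, the midpoint);
(3) a sliding window then scans left to right, and whenever its intensity
reaches the threshold the position of the maximal $SM$ value becomes a
nucleosome centre $P_c$ with call $[P_c - 73,\; P_c + 74)$ — half a 147 bp
core on each side. Steric exclusion forbids overlapping calls; after a call
the scan resumes immediately right of the called core.

**Meta-prediction.** The per-feature call sets are pooled; each call becomes
a candidate described by its support count (features calling within 73 bp),
the distance to the closest other candidate, and one indicator per feature.
A Random Forest (100 trees, fixed seed), trained on one chromosome labelled
against a reference map (positive iff within 35 bp of a reference centre),
accepts or rejects candidates; accepted centres are single-linkage clustered
at 73 bp and each cluster's middle candidate becomes the consensus call.

**Chromatin HMM.** As an alternative positioning model, a 16-state hidden
Markov model — one linker state L0 and fifteen ordered nucleosome states
N1..N15, one per 10 bp bin of a core — is trained supervised on one
chromosome (empirical transitions with add-one smoothing restricted to the
legal set L0→L0, L0→N1, Nk→Nk+1, N15→L0, N15→N1; Gaussian emissions per
state and feature channel over the six top features) and decoded with
Viterbi. Complete N1..N15 runs become 147 bp calls; non-overlap holds by
construction of the transition set.

**Continuous occupancy.** Least angle regression (LARS) combines the twelve
profiles in a linear model of occupancy, fitted on a training chromosome set
and evaluated on held-out chromosomes; features enter the path in order of
correlation with the residual and the reported model is the Mallows-$C_p$
minimum of the path (a full-path OLS endpoint is available via
`stop = "full"`).

**Evaluation.** A prediction is correct when its centre lies within $L$ bp
of a reference centre ($L = 35$ by default; sweeps use 10–60 bp). With
one-to-one greedy matching, sensitivity $Se$ is the fraction of reference
nucleosomes recovered, specificity $Sp$ the fraction of predictions that
are correct, and $F = 2 \cdot Se \cdot Sp / (Se + Sp)$. The chance baseline
re-draws the same number of non-overlapping 147 bp calls uniformly per
chromosome.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_bp` | 100 | bp | profile smoothing window |
| `step_bp` | 10 | bp | profile resolution |
| `median_window_bp` | 100 | bp | noise filter before peak detection |
| `scan_window_bp` | 165 | bp | DLaNe scan window (≈ nucleosome repeat) |
| `ps` | 0.45 | — | peak significance, fraction of $AP_i$ |
| `cutoff_bp` / `label_cutoff_bp` | 35 | bp | centre-match tolerance |
| `neighbor_bp` / `cluster_bp` | 73 | bp | half-core support/cluster radius |
| `ntree` | 100 | trees | meta-predictor forest size |
| `noise_sd` | 0.5 | occupancy units | simulated occupancy noise |
| `contrast` | 1 | — | synthetic core/linker composition strength |

## Numerical and design choices

Several details are under-determined by the method description alone; the
package fixes them as follows and they are all exercised by the test suite.

* **Coordinates.** 0-based, half-open everywhere (BED convention). A bin's
  representative coordinate is its smoothing-window centre; only full
  windows are emitted, left-aligned, so a sequence of length $\ell$ gives
  $\lfloor(\ell - k + 1 - \mathrm{window})/\mathrm{step}\rfloor + 1$ bins.
* **Masked bases.** Non-ACGT symbols mask their k-mers; masked entries are
  excluded from window means and medians, and a fully masked window yields
  a masked bin rather than an error.
* **Scan-window width in bins** is `floor(165/step + 0.5)` = 17 bins at the
  default step (explicit round-half-up, so the width does not depend on the
  platform's even-rounding of 16.5).
* **Which bin becomes $P_c$.** The centre must attain the window maximum
  *and* be a summit — a centred local maximum over the scan-window width.
  Without the summit condition a left-to-right scan systematically calls
  rising flanks ~20 bp before each peak top (the window's range can exceed
  the threshold while the summit is still outside it). If the window
  maximum is not an eligible summit the window yields no call and the scan
  advances one bin (bin-by-bin advance was the chosen reading of "the
  window moves forward").
* **Plateau ties.** A running median is piecewise constant, so filtered
  peaks are exact-tie plateaus. Taking the leftmost tied bin biases calls
  half a plateau (~20 bp) leftwards; the call is therefore placed on the
  middle of the first tied run, which is equally deterministic and centres
  the call on the plateau.
* **Steric exclusion.** Eligible centres must also not overlap the previous
  call nor run past the covered sequence; the scan resumes at the first bin
  right of an accepted core. Together these guarantee sorted,
  non-overlapping, 147 bp calls.
* **Flat profiles.** A window qualifies only when $P_i \ge P_s \cdot AP_i$
  *and* $P_i > 0$, so constant profiles produce no calls even though their
  threshold is zero.
* **LARS and exact collinearity.** The eleven dinucleotide scales are
  strand-symmetric functions of ~10 free symmetrized dinucleotide
  frequencies, so the 12-feature design matrix is *exactly* rank deficient
  (rank 10 in practice). Instead of refusing such designs, the path skips
  an entrant whose equiangular system is singular (matching the classical
  LARS implementation's behaviour) and a warning reports the deficiency;
  constant features are dropped with a warning, and a rank-0 design is an
  error. Features are standardized internally; coefficients are reported on
  the original scale.
* **Matching cardinality.** One-to-one greedy matching in increasing
  distance order: a reference can absorb only one prediction, so redundant
  calls lower specificity instead of inflating it, and the sensitivity/
  specificity numerators coincide by construction.
* **HMM details.** Diagonal Gaussian emissions keep the parameter count
  trainable from a single chromosome; emission variances are floored at
  1e-8 of the largest channel variance; Viterbi runs in log space with
  leftmost (lower state index) tie-breaking; masked channels simply drop
  their emission term, so a fully masked bin is decided by the transitions.
  The direct N15→N1 transition (zero-linker abutment) is allowed by default
  and can be disabled.
* **Random baseline.** Uniform sampling over *all* legal non-overlapping
  placements via the stars-and-bars bijection (n sorted draws without
  replacement from a shrunken range), which stays exact at the ~90% packing
  densities where naive rejection sampling stalls.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` plants alternating 147 bp cores and 10–20 bp linkers
(plus optional nucleosome-free gaps) and draws sequence from two first-order
Markov chains, one for cores and one for linkers. The two chains were chosen
once, by a maximin search over transition matrices, such that *every* one of
the twelve scales separates cores from linkers in its documented direction
(the search constrained the weakest scales to at least 0.15 k-mer standard
deviations under the chains' stationary law, and pushed the strongest to
about 1 SD). A single mononucleotide (iid) composition provably cannot do this —
A-philicity and protein-induced deformability rise with G+C content while
sharing the negative class with scales that fall with it — hence the
first-order chains. The bundled table
(`inst/extdata/synthetic_composition.tsv`) is a synthetic construction, not
an estimate from any real genome.

Within each core the composition bias is tapered by a squared cosine peaking
at the dyad (`dyad_taper = TRUE`), mimicking the dyad-centred positioning
signal of real nucleosomal DNA; without the taper, 100 bp smoothing turns
every core into a flat-topped plateau whose detected maximum wanders ±25 bp.
Simulated occupancy gives every nucleosome a triangular footprint peaking at
its dyad (the shape of a fragment-midpoint density), binned like the
profiles, plus iid Gaussian noise — so with zero noise, track maxima sit on
planted centres by construction.

Passing the synthetic benchmark therefore shows that the pipeline recovers
planted signal of realistic geometry (147 bp cores, 10–20 bp linkers, ~10%
free regions, profile/occupancy correlations in the 0.3–0.8 range of real
MNase data), with exact ground truth. It does *not* show performance on real
genomes: the generator imitates neither real yeast k-mer statistics, MNase
sequence bias, remodeller-positioned arrays, nor the in vivo factors that
decouple occupancy from sequence. Benchmark sizes are deliberately desk
scale — two 50 kb chromosomes per replicate, 20 replicates in the tests and
5 in `scripts/acceptance.R` — chosen so the whole suite re-runs in minutes
while keeping ~280 nucleosomes per chromosome for stable Se/Sp estimates.

## Known limitations

* The twelve scale tables are transcriptions of the published structural
  models; values are data (`inst/extdata/structural_scales.tsv`) and can be
  replaced file-for-file if a different parameterization is preferred.
* Calls are hard 147 bp intervals; fuzzy or overlapping nucleosomes are out
  of scope, as are duration-explicit HMMs and posterior decoding.
* The meta-predictor needs both accepted and rejected candidates during
  training; perfectly consistent call sets (single-class labels) are an
  error rather than a silently degenerate model.
* Profiles are computed on the given strand only; all bundled dinucleotide
  scales are reverse-complement symmetric, so this matters only for custom
  asymmetric scales.

## A worked run

```{r pipeline, eval = FALSE}
sc <- structural_scales()
sim <- simulate_genome(chrom_lengths = c(chrI = 50000, chrII = 50000),
                       seed = 1)
prof <- structural_profile(sim$genome, sc)

calls <- dlane(prof, sc)
evaluate_calls(calls[calls$chrom == "chrII", ],
               sim$nucleosomes[sim$nucleosomes$chrom == "chrII", ],
               cutoffs = seq(10, 60, 10)) |>
  plot_evaluation()

hl <- hmm_locate(prof[prof$feature %in% top_features(), ],
                 sim$nucleosomes, train_chroms = "chrI")
occ <- simulate_occupancy(sim, seed = 1)
fit <- fit_occupancy(prof, occ, train_chroms = "chrI")
tidy(fit)
autoplot(fit)
```
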