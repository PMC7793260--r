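---
title: "Methods: spectral unmixing, acceptor FRET efficiency, and peptidoglycan composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing, acceptor FRET efficiency, and peptidoglycan composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r setup}
library(fretunmix)
```

## The measurement

The assay quantifies protein–protein interactions in live cells
co-expressing an mKO (donor) fusion and an mCherry (acceptor) fusion. A
spectrofluorimeter records two emission scans per sample:

* a **donor-excitation scan** (excitation near 541 nm, emission recorded to
  the red of it), containing donor emission, directly excited acceptor
  emission, sensitized acceptor emission (FRET), and cellular background;
* an **acceptor-excitation scan** (excitation near 587 nm), containing only
  directly excited acceptor emission and background.

Each experiment also records reference scans: a buffer-only scan per
channel, an *empty cell* scan (cells without fluorophores) per channel, a
donor-only reference, and an acceptor-only reference in both channels.

## Spectral unmixing

After buffer subtraction, every scan is modelled as a non-negative linear
combination of component shapes measured in the same experiment:

$$ y(\lambda) \approx a_{bg}\, s_{bg}(\lambda) + a_D\, s_D(\lambda)
   + a_A\, s_A(\lambda), \qquad a_i \ge 0. $$

The shapes are derived from the reference scans by `build_reference_basis()`:
each background-subtracted reference is smoothed with a spline
(`smooth.spline`, all knots), clipped at zero, and normalized to unit
Euclidean norm. The smoothing step matters: clipping a *noisy* curve at zero
rectifies the noise in the signal-free tail of the donor shape, and because
the donor amplitude is large in the donor channel, that spurious tail
systematically absorbs acceptor signal and biases the acceptor amplitude
downward. Smoothing before clipping removes the bias while leaving the
noiseless case exact.

The amplitudes are fitted by non-negative least squares (`nnls_solve()`, a
Lawson–Hanson active-set solver). Nonnegativity is physically required —
emission cannot be negative — and is what makes the three-component fit
stable when components overlap heavily. Whenever the unconstrained
least-squares solution happens to be nonnegative the two coincide, which is
how the solver is tested.

```{r unmix-example}
cfg <- synthetic_panel_config(true_efficiency = 0.25, noise_sigma = 0.01,
                              n_replicates = 1, seed = 11)
panel <- simulate_pair_spectra(cfg, "tandem")
fit <- fret_analysis(panel)
u <- fit$unmix_fits[[1]]
summary(u)
plot(u)
```

## Acceptor FRET efficiency

Sensitized acceptor emission is spectrally identical to directly excited
acceptor emission, so it cannot be separated by shape. It is separated by
the **cross-talk factor** $\rho$: the ratio of the acceptor-only reference's
fitted acceptor amplitude under donor excitation to that under acceptor
excitation. For a sample with fitted acceptor amplitudes $A_{541}$ (donor
excitation) and $A_{587}$ (acceptor excitation):

$$ F_{direct} = \rho\, A_{587}, \qquad
   F_{sens} = A_{541} - F_{direct}, \qquad
   EfA = 100\,\kappa\, \frac{F_{sens}}{F_{direct}}. $$

$EfA$ estimates (true transfer efficiency) × (fraction of acceptors bound in
donor complexes). Two deliberate choices:

* **κ defaults to 1.** The physical constant is the ratio of acceptor to
  donor extinction coefficients at the donor excitation wavelength. All
  groups in one study are measured on the same instrument with the same
  fluorophores, so relative comparisons — which is what the controls
  calibrate — are unaffected; reported values are instrument-relative EfA.
* **EfA is not floored at zero.** For a non-interacting pair the raw
  sensitized emission scatters symmetrically around zero. Clipping each
  replicate at zero before averaging would bias the group mean upward and
  force mean/SEM of a true-zero group to ≈ 3.35 regardless of noise level,
  making the negative control structurally "significant". Negative values
  are kept (and QC-flagged); the floored sensitized amplitude is reported
  alongside.

```{r efa}
fit$results[, c("sample_id", "efa", "r_squared_donor_exc")]
```

### Replicates and statistics

Each biological replicate is a full experiment with its own reference scans;
reference noise is shared within an experiment, so pooling many replicates
against a single reference set would correlate their errors and understate
the group SD. `summarize_replicates()` reports mean, sample SD (n−1) and n;
`compare_groups()` is the classical two-sided pooled-variance Student t-test
with df = n₁ + n₂ − 2.

### Distances

With the Förster relation $E = (1+(r/R_0)^6)^{-1}$ and $R_0 = 6.4$ nm for
mKO–mCherry, an efficiency converts to an apparent distance:

```{r forster}
efficiency_to_distance(0.127)  # EfA 12.7% -> 8.8 nm
efficiency_to_distance(0.079)  # EfA  7.9% -> 9.6 nm
helix_rise_bound(2)            # two helix residues move a fusion <= 0.3 nm
```

Because EfA mixes efficiency with complex fraction, these are upper-bound
"apparent" distances for the interacting subpopulation.

## The synthetic generator

`simulate_panel()` produces complete experiments — reference scans plus
sample scan pairs — with known ground truth, used for closed-loop
validation. Sample photophysics: with donor and acceptor abundances $D, A$,
complex fraction $f$ and true efficiency $E$, the number of transferring
pairs is $f\min(D,A)$; donor emission is quenched by $E f \min(D,A)$ and the
same quantum flux reappears as sensitized acceptor emission. At zero noise
the pipeline recovers $EfA = 100 f E \min(D,A)/A$ exactly (to numerical
precision), which is the generator/analyzer closed loop the tests assert.

Realism knobs: skew-normal emission shapes, a broad cellular background
component, Gaussian detector noise scaled to the scan peak (default 1%),
and log-normal replicate-to-replicate abundance scatter (default 10% CV).
Limits worth knowing: shapes are smooth idealizations (no vibronic
structure), noise is homoscedastic per scan rather than Poisson, and
bleaching/maturation kinetics are not modelled. With defaults, recovered
per-replicate EfA scatters with an SD of roughly 2–3 percentage points —
comparable to the replicate SDs seen in real data — and is unbiased against
the generator's per-replicate ground truth.

```{r closed-loop}
efa <- vapply(1:8, function(s) {
  p <- simulate_pair_spectra(
    synthetic_panel_config(true_efficiency = 0.31, n_replicates = 1,
                           seed = s), "tandem")
  fret_analysis(p)$results$efa
}, numeric(1))
summarize_replicates(efa, "tandem")
```

## Muropeptide composition

`read_muro_table()` reads an HPLC peak-area table (percent area per
muropeptide species, one column per sample). From the class totals the
package computes:

* **degree of cross-linkage** $= \sum_k \text{area}_k (n_k-1)/n_k$ over
  oligomer classes of size $n_k$ (dimers/2 + 2·trimers/3 + …);
* **mean glycan chain length** in disaccharide units $= 100 / (\text{chain-end
  percentage})$, using the anhydro-MurNAc chain-end fraction;
* **% peptides in cross-links**, implemented as the naive dimers + trimers
  total. For the packaged reference table this gives 44.9 for the wild type
  where the original report prints 47.4; the published number evidently uses
  a different (unstated) weighting, so the naive estimate carries a
  provenance note and is not asserted against the printed row.

A caution on rounded inputs: composition tables are usually printed with one
decimal. The chain-length inversion is sensitive at small chain-end
percentages (100/2.5 vs 100/2.45 differs by 2%), so published per-replicate
values are generally not reachable exactly from the rounded column — two of
the five packaged reference columns reproduce within 2%, the others do not,
and the tests assert exactly that.

```{r muro}
t <- read_muro_table(system.file("extdata", "lmc500_muropeptides.tsv",
                                 package = "fretunmix"))
muro_composition_table(t)
```

The matching generator inverts the math exactly:

```{r muro-loop}
sim <- simulate_muro_table(target_chain_length = 42.8,
                           target_crosslinkage = 23.2, noise = 0)
unlist(muro_composition(sim, "synthetic")[
  c("mean_chain_length_ds", "degree_crosslinkage")])
```

## Problem sizes and performance

A scan has 100–300 wavelength points and the basis has 2–3 columns, so one
NNLS solve is microseconds; a full experiment (references plus a handful of
samples in two channels) fits in well under a second, and the 22-experiment
closed-loop validation runs in about a minute on one CPU.
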