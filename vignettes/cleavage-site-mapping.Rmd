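---
title: "Mapping a sheddase cleavage site from semi-specific peptide evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a sheddase cleavage site from semi-specific peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shedmap)
```

## The problem

Sheddases such as the ADAM metalloproteases release the extracellular domain
of membrane receptors by cleaving a single peptide bond. Locating that bond
on the substrate is hard: the cleavage is not performed by the digestion
enzyme used for mass spectrometry, so its products are invisible to a
conventional fully-specific database search. The trick is a *semi-specific*
search: one peptide terminus must obey the digestion protease, the other may
fall anywhere. A peptide whose "free" terminus is not explained by the
protease or by the protein's own ends — a *non-canonical* terminus — is the
footprint of an in-vivo cleavage event.

`shedmap` implements this logic as a reusable pipeline: in-silico digestion
and terminus classification, aggregation of non-canonical termini into
cleavage-site calls, fragment-spectrum validation via the spectrum contrast
angle, and the downstream quantitative analyses that typically accompany
such a study (label-free proteome comparison, fluorescence shedding assays,
FRET traces, concentration–response curves).

## Terminus classification and site calling

Coordinates are 1-based and inclusive; a cleavage *site* `p` names the bond
between residues `p` and `p + 1`. For a peptide mapped to `[start, end]`:

* the N-terminus is canonical if `start = 1` (protein terminus) or
  `start − 1` is a cut point of the digestion protease;
* the C-terminus is canonical if `end = length` or `end` is a cut point;
* anything else is non-canonical.

A non-canonical C-terminus at `p` supports the site via the *N-terminal
product*; a non-canonical N-terminus at `p + 1` supports the same site via
the *C-terminal product*. A site is **concordant** when both products are
seen. Requiring concordance (`min_products = 2`, the default) is the key
filter: one-sided evidence arises easily from in-source fragmentation or
mis-assignments, but two independent peptide populations ending and starting
at the same bond almost never do.

Each protease digest is evaluated against its own specificity only,
mirroring per-protease separate searches: a terminus that happens to match a
*different* enzyme used elsewhere in the experiment still counts as
evidence. Peptides mapping to several loci are flagged ambiguous and
excluded from concordance by default (`include_ambiguous = TRUE` to
override).

The default protease registry uses the common search-engine definitions:
Trypsin/P (after K/R, no proline veto), LysC (after K), chymotrypsin (after
F/W/Y/L), AspN (before D). Chymotrypsin's residue set and AspN's scope vary
between laboratories, so every rule is plain data (`protease_spec()`) and
can be replaced per run. Digestion defaults — 2 missed cleavages, peptide
length 6–40 — follow common search-engine settings and are exposed as
arguments.

## A worked example

The two diagnostic peptides of the PTHR1/ADAM19 system pinpoint the bond
between residues 64 and 65. The packaged FASTA is a **synthetic stand-in**
for the receptor's N-terminal region: the residues around the site
(54–80) are at their native coordinates, the flanks are fixed filler. It
exists so the example and tests run fully offline; it is not the canonical
database sequence.

```{r worked-example}
fasta <- system.file("extdata", "pthr1_nterm_synthetic.fasta", package = "shedmap")
prot <- read_fasta(fasta)[[1]]
tab <- data.frame(peptide = c("EVLQRPASIME", "SDKGWTSASTSGKPRK"),
                  protein_id = prot$id, protease = "trypsinP")
ev <- collect_terminus_evidence(tab, setNames(list(prot), prot$id))
call_cleavage_sites(ev, min_products = 2)
```

The first peptide ends at residue 64 with a tryptically inexplicable
C-terminus (N-terminal product); the second starts at residue 65 with an
inexplicable N-terminus (C-terminal product). Together they make one
concordant call at site 64.

## Spectrum validation: the contrast angle

Identifications at a single site deserve spectrum-level scrutiny. Acquired
and predicted fragment spectra are matched per charge state against the
theoretical b/y ions (monoisotopic masses; proton 1.007276 Da, water
18.010565 Da), charge-deconvoluted by summing intensities of the same
fragment label across charges, and reduced to labels matched in *both*
spectra. On the eight most intense fragments of the predicted spectrum
(ties broken towards the lower singly-charged m/z) the spectrum contrast
angle is

$$\mathrm{SCA} = 1 - \frac{2\theta}{\pi}, \qquad
\theta = \arccos\frac{a \cdot b}{\lVert a\rVert\,\lVert b\rVert},$$

so identical spectra score 1 and spectra with disjoint fragment support
score 0. The SCA is scale-invariant, so no base-peak normalisation is
applied. Stability is assessed by a bootstrap (default n = 20) that
resamples the fragment *pairs* — the unit the statistic is computed from —
with replacement; a seed is mandatory.

```{r sca}
pair <- simulate_spectrum_pair("EVLQRPASIME", noise_sd = 0.3, dropout = 0.1,
                               seed = 42)
m <- match_fragment_sets(pair$acquired, pair$predicted, "EVLQRPASIME")
bootstrap_sca(m, k = 8, n_boot = 20, seed = 43)
```

Numerical notes: parallel intensity vectors are detected algebraically
(`dot² ≥ ‖a‖²‖b‖²`) and scored exactly 1, avoiding `acos` round-off at the
upper endpoint; the matching tolerance defaults to 20 ppm (typical for
Orbitrap HCD fragment spectra), and peak assignment is greedy closest-wins
with each peak serving at most one ion.

## Label-free proteome comparison

The DIA-style report is filtered (precursor q ≤ 0.01, protein q ≤ 0.01,
mass evidence > 0.5, precursor charge > 1), log2-transformed, and missing
values are imputed from a down-shifted normal: for each sample column with
observed mean μ and SD σ, missing cells draw from
N(μ − 1.8 σ, (0.25 σ)²). This encodes the missing-not-at-random structure
of label-free data — absent proteins are probably low-abundance. Per-column
statistics are the default (`per_column = FALSE` gives one global
distribution); imputation touches only masked cells and is seeded.

Differential abundance uses a per-protein two-sample t test with
Benjamini–Hochberg correction. Welch's unequal-variance form is the default
because label-free variance is rarely homogeneous; the Student form is
available (`var_equal = TRUE`). At three replicates per group the Welch
approximation is mildly conservative (its null raw-p < 0.05 rate falls
below the nominal level), which is why the package's calibration tests
exercise the Student variant under an equal-variance null — there it is
exact.

The volcano classification defaults to |log2FC| ≥ 2 and **adjusted p <
0.5**. The 0.5 is deliberate — it reproduces the analysis as printed — but
it is far more permissive than the conventional 0.05 and should be
overridden (`p_cut`) for most uses. Profile heatmaps use per-condition
medians z-scored per protein with the population-SD convention; constant
rows map to zeros and are flagged.

## Assay quantification

**Shedding ratio.** Per condition, mean background-corrected supernatant
fluorescence over mean background-corrected cell fluorescence
(`Ratio = F_supernatant / F_cell`), normalised so the control condition is
exactly 1. Negative corrected supernatant means are clipped to 0; a
non-positive corrected cell mean is an error. The ratio is invariant to a
common detector gain.

**FRET traces.** Channels are background-subtracted, the acceptor corrected
for donor bleed-through (a supplied fraction, measured from donor-only
controls rather than estimated), and the donor/acceptor ratio mapped
affinely so the mean of the 10 points before ligand addition is 0% and the
mean of the final 10 points after the saturating stimulus is 100%. The
plateau window length is a package choice; only the anchors themselves are
prescribed by the assay design.

**Concentration–response.** The three-parameter logistic
`y = bottom + (top − bottom) / (1 + 10^(logEC50 − log10 c))` (Hill slope
fixed at 1) is fitted by Levenberg–Marquardt least squares with a
deterministic multi-start — both orientations of the response range crossed
with three concentration quantiles for logEC50 — so the fit has no hidden
randomness. `fix_bottom = 0` gives the constrained variant. Curves are
compared with the extra-sum-of-squares F test on nested fits,
`F = ((SS₀ − SS₁)/(df₀ − df₁)) / (SS₁/df₁)`; a zero separate-model SS
yields p = 0 with a warning. Flat responses are returned flagged degenerate
rather than fitted.

**qPCR efficiency** is the closed form `E = (10^(−1/slope) − 1) × 100`.

## What the generators emulate — and what they do not

Every generator is a pure function of its parameters and a mandatory seed,
and each exposes its ground truth so recovery tests never re-derive it.

* `simulate_shedding_identifications()` splits the protein at the planted
  bonds, digests each product fully per protease, and (optionally) drops
  peptides at a detection probability and adds decoy substrings whose
  termini are non-canonical away from the planted bonds. Peptides abutting
  a planted bond are exempt from the length filter: they carry the evidence
  the experiment exists to detect. What is *not* modelled: identification
  scores, co-eluting interference, or FDR structure — the pipeline ingests
  search-engine output and does not re-score it.
* `simulate_spectrum_pair()` uses a deliberately non-physical positional
  intensity heuristic (mid-sequence ions strongest, y slightly above b) in
  place of a learned fragment-intensity predictor, then applies log-normal
  intensity noise, peak dropout, m/z jitter within half the matching
  tolerance, and uniform background peaks.
* `simulate_proteome()` draws per-protein baselines, shifts an affected
  subset between groups, and masks cells with a probability that decreases
  logistically in intensity (MNAR). Defaults (3 samples/group, baseline
  25 ± 3 log2 units, replicate SD 0.5) reflect a typical small label-free
  comparison. Real data additionally carry normalisation drift and
  correlated proteins, which the generator omits — passing tests show the
  statistics are implemented correctly, not that any real dataset satisfies
  their assumptions.
* `simulate_plate()` / `simulate_fret_trace()` embed a known shed fraction
  and known 0/100% anchors plus bleed-through, making the assay functions
  checkable by exact round trip.

Simulation sizes used by the test suite (e.g. 100 seeded site-recovery
experiments, 20 null proteomes of 1,000 proteins, 500 null curve pairs with
duplicate wells per concentration — the duplicate design mirrors how such
assays are actually run) were chosen to make Monte-Carlo checks
statistically meaningful at desk scale.

## Known limitations

* Only b/y fragment series, no neutral losses or a/x/c/z ions.
* No FDR modelling of site calls; ranking is by evidence counts only.
* Bleed-through estimation, raw-file processing and spectral prediction are
  out of scope; their outputs are inputs here.
* The packaged receptor FASTA is a synthetic stand-in (see above), suitable
  for demonstrating coordinates, not for database searching.
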