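---
title: "Distance-based isotopic niche analysis with isonich: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based isotopic niche analysis with isonich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isonich)
```

## The problem and the model

A consumer population's *isotopic niche* is the region of the
two-dimensional space spanned by δ13C and δ15N that its tissue samples
occupy. Where dietary sources contrast isotopically — here a marine versus
a terrestrial prey base for arctic foxes with and without coastal access —
the spread of samples in this plane proxies dietary niche breadth, and the
relationship between individual-level and population-level spread
distinguishes a population of individual generalists from a population of
diverse individual specialists.

`isonich` implements a purely distance-based decomposition of that spread:

* **Total niche width (TNW)** of a group (habitat × age, optionally ×
  tissue): the mean Euclidean distance of the group's samples to the group
  centroid (componentwise arithmetic mean). This is the per-sample response
  of a multivariate variance decomposition on distances, in the spirit of
  permutation-based homogeneity-of-dispersion analysis.
* **Individual niche breadth**: tissues integrate diet over windows set by
  their turnover — muscle over roughly a month, bone collagen over years —
  so the muscle-minus-collagen difference vector of one individual encodes
  its temporal diet variation. Its Euclidean norm is the individual's
  two-tissue niche breadth.
* **Within-individual component (WIC)**: the mean distance of muscle and
  collagen samples to their own individual's centroid. With exactly two
  samples, each lies at half the pair distance, so an individual's breadth
  is exactly twice its per-sample WIC contribution.
* **Dispersion of difference vectors**: the distance of each individual's
  difference vector to the group centroid of difference vectors measures
  *between-individual variation in individual strategy* — the quantity
  that separates "everyone broadened their diet" from "strategies
  diversified".
* **WIC/TNW**: Roughgarden's individual-specialization index, computed
  here from two tissues. Small values indicate individual specialists
  within a broad population niche; larger values indicate individual
  generalists.

Because centroids are arithmetic means, the squared-distance decomposition
is exact: the total sum of squared distances to the grand centroid equals
the within-individual plus the between-individual parts, which the test
suite verifies to 1e-9 and which implies RMS-WIC ≤ RMS-TNW always. The
package reports the *mean-distance* versions of WIC and TNW (matching the
field's usage); the squared identity is the exactly testable law behind
them.

### A genuine ceiling on the two-tissue index

A point worth stressing for interpretation: with only two samples per
individual, the individual centroid is estimated from those same two
samples, which absorbs half of the within-individual variance. For
Gaussian within-individual variation with collagen variability damped by a
factor γ relative to muscle, the index approaches

\[ \frac{\sqrt{1+\gamma^2}}{1+\gamma} \]

— about 0.75 at γ = 0.5, and 1/√2 ≈ 0.71 at γ = 1 — *not* 1, even for a
population of perfect individual generalists with identical long-term
diets. "Near 1 means generalist" is therefore qualitative for this proxy;
comparisons of the index *between* groups remain meaningful, and that is
how it is used throughout.

## Inference

The mixed-model stage the source analysis used (REML, province and
tissue-within-individual random intercepts, a variance power function) is
deliberately delegated to `nlme::lme` behind the `fit_group_effects()`
adapter: the REML engine is mature machinery, not this package's
contribution. The adapter reports F, numerator/denominator df and p per
fixed effect exactly as the engine computes them (containment df; these
are conservative for effects that do not vary within provinces — null
rejection rates below nominal α in simulation — and reproduce the
seemingly odd denominator df of 4 for habitat-level interaction terms that
containment accounting yields with 8 provinces). Non-convergence and
constant responses yield `converged = FALSE` with no F values, never a
silent fallback. The variance power function uses the fitted mean as its
covariate; on homoscedastic data its presence moves the primary F
statistic by a few percent at most (median < 2% in the paired-fit
simulation in the test suite), because the estimated exponent wanders on
finite samples — it is not exactly inert.

The package's own inferential contribution is distribution-free:

* `permutation_dispersion_test()` — a one-way F on distances with a null
  built by permuting group labels over *individuals*, so all records of an
  animal move together (respecting the tissue-within-individual
  dependence). The add-one rule keeps p strictly positive. Calibration is
  part of acceptance: type-I error within [0.03, 0.07] at α = 0.05 over
  500 null simulations, power ≥ 0.8 for a dispersion ratio of 2 at
  n = 30 per group.
* `bootstrap_contrast()` — percentile CIs for between-group differences in
  TNW, WIC, WIC/TNW or mean contrast breadth, resampling individuals with
  replacement within groups. Degenerate replicates (no muscle+collagen
  pair, zero TNW) are redrawn and counted.

Defaults: 9999 permutations, 1999 bootstrap replicates, both overridable;
every resampling routine is byte-reproducible from its seed.

## The synthetic-data generator

No raw per-individual data accompany the source study (its supplement
holds only group means ± sd), so the generator is the package's
verification substrate: it creates data with *known* latent structure so
every metric and test can be checked against ground truth.

The generative model is deliberately statistical, not physiological:

* Two end-members on the δ scale, defaulting to the means of the printed
  prey signatures: marine (−16.905, 12.650) and terrestrial
  (−24.5475, 6.8125) ‰. Consumer values interpolate linearly — no
  concentration dependence, no trophic-enrichment cascade, because the
  metrics only need the mixing geometry, and the source analysis
  explicitly declined to fit mixing models.
* Each individual carries a long-term marine proportion α drawn from a
  Beta distribution per habitat × age cell; each tissue realizes
  p = clamp(α + ε), ε ~ N(0, σ_w), with collagen's ε damped (default 0.5)
  to stand in for its multi-year integration; fur behaves like muscle.
  Clamping events are counted and reported.
* Juveniles are *provisioned*: their α derives from a simulated parent's α
  shifted by a habitat-specific offset plus provisioning noise — encoding
  the interpretation that adults select the prey they carry to dens rather
  than feeding pups a random sample of their own diet.
* Per-tissue offset vectors stand in for fractionation. **These defaults
  are arbitrary placeholders** — no measured tissue-specific fractionation
  values exist for this system, and all between-group comparisons are
  invariant to them since they are common to all individuals.
* Province effects are small common-mode offsets (sd 0.3‰) to give the
  random-term machinery something to estimate; measurement noise is
  N(0, 0.1‰) per axis, the instrument precision reported for the original
  assays.

`true_metrics()` computes the generative expectations of TNW and WIC per
cell by Monte-Carlo with measurement noise suppressed; recovery of these
values (TNW within 10% at n = 200 individuals) and of specialist-versus-
generalist orderings (≥ 95% of seeds at n = 40 per group) are acceptance
criteria.

### The paper-like preset and how its numbers were chosen

`paper_like_config()` (the `sim_config()` defaults) encodes the study's
qualitative findings as generative structure: 84 individuals across 8
provinces in four habitat × age cells (30/10/28/16); coastal adults draw
from a broad marine/terrestrial mixture *and* split between high-σ_w and
low-σ_w strategies (diverse individual strategies, not a uniform niche
expansion); inland adults sit in a narrow terrestrial mixture; coastal
juveniles are uniformly provisioned marine-shifted food (offset +0.45,
heavily clamped at pure marine, tiny provisioning noise); inland juveniles
have very low within-individual variability but diverse provisioning
(provisioning sd 0.18). None of these magnitudes is printed in the source;
they were fixed once, at design time, by back-of-envelope arithmetic so
that the encoded directions are robust at the small group sizes the design
dictates (the initial hand-derived values left the n = 10 coastal-juvenile
cell too noisy, and were strengthened before any acceptance test was
written). The preset reproduces all four reported directions jointly in
97% of 100 seeds at calibration time; the acceptance criterion asserts
≥ 90%.

What a green pattern test establishes: that the analysis pipeline
*recovers the directions the generator encodes* at realistic sample sizes.
What it does not establish: anything about real foxes — the generator has
no seasonality, no spatial resource gradients within habitats, no
age-dependent turnover differences, and linear mixing with placeholder
fractionation.

## Numerical and interface choices

* δ values are carried in ‰ throughout; no internal rescaling.
* Habitat labels follow the published strata: coastal ≤ 3 km from shore,
  inland ≥ 10 km; the 3–10 km gap maps to an explicit `"undefined"` label
  that downstream metrics reject rather than coerce.
* The muscle-minus-collagen sign convention is arbitrary; all dispersion
  results are invariant to a global sign flip (tested).
* WIC/TNW restricts both numerator and denominator to muscle + collagen
  samples of individuals possessing both, with the TNW centroid at the
  habitat × age level; an `all_tissues` TNW scope is available and flagged
  in the output, since the original description is silent on this point.
* Centroid-distance tables for the population-niche analysis default to
  habitat × age × tissue centroids; the index uses habitat × age.
* Collection dates are retained but ignored by default (months pooled); a
  date-window filter is available.
* Groups observed with no computable metric are skipped with a warning
  rather than failing a whole run; empty inputs and vocabulary violations
  are hard errors at the boundary (`read_sample_table()`), while
  `validate_sample_set()` enumerates violations without throwing.
* CSV outputs round numeric fields to six decimals, which both preserves δ
  precision well beyond instrument noise and makes repeated runs
  byte-identical for digest-based manifests.

## Known limitations

* The two-tissue WIC/TNW ceiling discussed above.
* Mixed-model denominator df follow nlme's containment rules; no attempt
  is made to reproduce any particular published df accounting.
* The permutation test assumes exchangeability of individuals under the
  null within the permuted stratum; province structure is not preserved by
  the permutation.
* The generator's clamping of mixture proportions at [0, 1] truncates the
  tails of the diet distribution; configurations that push means near the
  boundaries (as the coastal-juvenile preset deliberately does) have
  compressed spread by construction.
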