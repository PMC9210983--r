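---
title: "Methods: windowed divergence scans with coalescent nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence scans with coalescent nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

# Scope and model

`divscan` analyses genome divergence between a pair of closely related
species (its defaults are calibrated to a pair of sister aspen species
resequenced at 20 and 19 diploid individuals) in four connected stages:

1. **Windowed population-genetic statistics** over non-overlapping 10 kbp
   windows: nucleotide diversity $\theta_\pi$, Watterson's $\theta_w$,
   Tajima's $D$, Fay and Wu's $H$, expected heterozygosity, mean pairwise
   $r^2$, Weir--Cockerham $F_{ST}$, absolute divergence $d_{xy}$, relative
   node depth (RND), and the fixed/shared/private partition of segregating
   sites.
2. **An isolation-with-migration (IM) coalescent simulator** with
   recombination, an outgroup lineage, and a sequencing read layer, serving
   both as the synthetic-data generator and as the engine behind the
   demographic likelihood and the outlier null.
3. **Demographic inference** on the joint two-dimensional site frequency
   spectrum (2D-SFS) by composite (multinomial) likelihood, with AIC and
   Akaike weights for model choice and a parametric bootstrap for intervals.
4. **An outlier scan**: window $F_{ST}$ values are compared against a null
   distribution simulated under the accepted demographic model, two
   one-tailed add-one empirical P-values per window are corrected by
   Benjamini--Hochberg separately per tail, and windows are classed
   `high` / `low` / `background` at FDR < 1%.

# The coalescent engine

The engine (C++) implements a structured continuous-time coalescent in units
of $2N_{\mathrm{ref}}$ generations with $N_{\mathrm{ref}} = N_{anc}$.
Lineages carry lists of ancestral-material segments; competing exponential
clocks drive within-population coalescence (piecewise-exponential population
sizes, waiting times inverted analytically per epoch), migration,
recombination (Hudson-style, rate proportional to the span of ancestral
material), and infinite-sites mutation (rate proportional to total ancestral
length). Material whose leaf set reaches the full sample has found its MRCA
and is dropped, so mutations above the grand MRCA are never generated.
Recombination therefore produces the correlated marginal genealogies that
windowed linkage statistics require; only window-level summaries are
consumed downstream.

Migration is specified forward in time as per-generation probabilities
$m_{12}$ (population 1 into 2) and $m_{21}$; backwards, a lineage sampled in
the sink jumps to the source at rate $m \, N_{\mathrm{source}} /
N_{\mathrm{sink}}$ per generation, using present-day sizes for the
conversion. The conversion is validated against a two-lineage
structured-coalescent oracle (a linear solve for expected within- and
between-deme coalescence times in a symmetric island model).

Mutations are placed on the fly as a Poisson process on segment length
$\times$ branch time, then discretized to integer coordinates in $[1, L]$.
Integer collisions are moved to the nearest free position rather than
re-drawn uniformly: a uniform re-draw would relocate a site anywhere in the
window and dilute the LD-versus-distance signal that the decay statistics
measure.

Two randomness details matter for inference. First, migration events draw
from a private RNG substream, so two models that differ only in migration
rates share the identical main event stream whenever no migration fires;
nested model comparisons under common random numbers then cancel exactly at
the no-migration boundary. Second, every source of randomness flows from
explicit seeds, and a fixed seed reproduces windows bitwise.

## Default demographic model

`default_im_model()` keeps the study system's anchored quantities --
mutation rate $\mu = 3.75\times10^{-8}$ per site per generation, 15-year
generations, a split 53,491 generations (0.80 Ma) ago, and low asymmetric
migration ($3.97\times10^{-7}$, $9.19\times10^{-7}$ forward per generation)
-- and chooses effective sizes self-consistently with the observed diversity
scale: $N_{anc} = 60{,}000$, $N_1 = 59{,}300$, $N_2 = 63{,}300$, so that
$4N\mu \approx 0.009$ matches the within-species $\theta_\pi$ and the
predicted window $F_{ST}$,
$1 - \theta_\pi / (\theta_\pi + 2\mu T_{div} + \ldots) \approx 0.3$, matches
the reported genome-wide differentiation. Point estimates of effective sizes
in the millions, as sometimes printed for this system, are mutually
inconsistent with $\pi \approx 0.009$ under the same $\mu$ (they would imply
$\pi > 0.25$), so they are bundled as reference inputs but not used as
simulation parameters.

## Read layer

The read layer emulates the genotype-likelihood regime of the study:
per individual and site, depth $\sim$ Poisson(20), read bases drawn from the
true diploid genotype with per-base error 0.5%, genotypes re-called by
maximum likelihood over the three diploid genotypes with a uniform prior,
and calls below depth 5 set missing (mirroring the DP < 5 genotype filter;
at 20x this yields a realistic missingness of order $10^{-4}$). Likelihood
ties break toward the heterozygote, then the smaller dosage -- a measure-zero
event except at error rate 0. The closed-form allele-dropout probability
$2(1/2)^d$ for an error-free heterozygote at fixed depth $d$ is checked in
the tests.

# Statistics: conventions for missing data and denominators

* Per-site formulas use the allele copies actually observed at each site;
  Tajima's constants use the window-modal copy number (recomputing constants
  per site changes $D$ negligibly and obscures the definition).
* $\theta_\pi$, $\theta_w$, $d_{xy}$ are reported per site using the
  callable span width as denominator, so missingness does not deflate
  diversity; the window width is retained in the table.
* Weir--Cockerham $F_{ST}$ is computed from per-site variance components on
  allele-copy counts and combined as a ratio of sums across the window;
  monomorphic sites are skipped and negative estimates are reported as
  computed.
* Fay and Wu's $H$ is the unnormalized $\theta_\pi - \theta_H$ version;
  unpolarized sites are excluded from $H$ only, never silently folded.
* $r^2$ uses genotype-dosage correlation for unphased data and haplotype
  correlation when the (simulated) haplotypes are available; the flag is
  explicit.
* Windows are 1-based inclusive in memory and TSV; BED export converts to
  0-based half-open.

A window with no SNP records is monomorphic (statistics 0), while a window
whose records are all uncallable is undefined (`NA`); undefined values are
written as `NA` and never silently dropped.

# Demographic inference

The 2D-SFS is built by direct tally at full sample size; sites with missing
genotypes are either dropped or projected down to a fixed copy number by
hypergeometric projection (expected, possibly fractional, contributions).
Monomorphic corners are masked. The composite log-likelihood is
$\sum m_{ij} \ln p_{ij}$ over unmasked cells.

The expected spectrum under a model is estimated by Monte-Carlo, but not by
placing mutations: each replicate genealogy contributes its **expected
branch length per joint frequency class** (the Rao--Blackwellized
estimator), which removes all mutational noise, and the log of the
Monte-Carlo mean receives a second-order bias correction
($-\mathrm{Var}/2\mathrm{mean}^2$, estimated from per-replicate variances).
Without the correction, the fitted optimum drifts systematically along the
weakly identified scaling ridge of the model family. Zero cells are floored
at $1/(10\,n_{reps})$ before renormalization.

Fitting follows a conditional-maximization design: multi-start
coordinate cycles of bounded Brent searches, with two additions that the
geometry of this family requires. First, because $N_{anc}$ is held fixed
(the segregation-conditioned composite likelihood cannot identify the
absolute scale -- the standard situation for SFS likelihoods without
monomorphic counts; $N_{anc}$ is anchored from genome-wide Watterson
$\theta$ in practice), the remaining sizes and times form a weakly
identified scaling ridge, and each cycle includes one line search along that
ray. Second, Brent never samples interval endpoints, so each coordinate step
checks the bounds explicitly; migration parameters live on a **linear**
scale with lower bound exactly 0, making "no migration" a reachable point of
every with-migration class. Likelihood evaluations within a fit reuse one
seed (common random numbers), so each fit optimizes a deterministic surface.

For model choice, `fit_nested_models()` warm-starts each class from the best
previous fit, lets lagging classes catch up from the richer optimum in a
backward pass, and finally re-evaluates every maximized likelihood at a
larger replicate count with one shared seed -- each class also evaluated at
the other optima projected into its space (feasible points, hence valid
profile lower bounds). With data simulated under no migration, the
with-migration fit collapses onto the no-migration optimum exactly, the
log-likelihood difference is exactly zero, and the AIC penalty alone decides
(true-class weight $1/(1+e^{-2}) \approx 0.88$); with genuine migration
($4Nm = 1$) the richer class wins with weight $\approx 1$. Without these
devices, the Monte-Carlo noise of simulation-based likelihoods (tens to
hundreds of log units at $5\times10^4$ data sites) completely swamps the AIC
penalty of 2 per parameter -- a noise floor that any fastsimcoal-style
pipeline shares.

The parametric bootstrap simulates bootstrap spectra as multinomial draws of
the observed segregating-site count from a high-precision expected spectrum
of the fitted model (sites treated as unlinked, consistent with the
composite likelihood), refits each, and reports 2.5/97.5 percentiles.

# Outlier scan

The null is built by simulating windows under the accepted model at the
observed sample sizes, recombination drawn uniformly from 1--5 kbp$^{-1}$
(population-scaled), passed through the read layer, and summarized by window
$F_{ST}$; replicates with undefined $F_{ST}$ are discarded and counted.
Empirical P-values use the add-one rule $(r+1)/(n+1)$ with ties counted as
extreme, so they are never zero and BH correction is well defined. The two
tails are corrected separately because the analysis reports separate high-
and low-differentiation window counts; a single two-tailed procedure could
not produce asymmetric counts. The configuration warns when
$1/(n_{reps}+1)$ is too large for any discovery at the chosen $q$.

# Sweep emulation

Windows under linked selection are emulated by a crash-and-recovery episode:
the chosen population's size is multiplied by `reduction` between
$0.05\,T_{div}$ and $0.6\,T_{div}$ ago and has recovered since. This
reproduces the full hitchhiking signature -- diversity loss, star-like
genealogies and hence strongly negative Tajima's $D$, elevated $F_{ST}$ and
fixed differences. A constant reduced size (available as `recovery = 0`)
lowers diversity and raises $F_{ST}$ but sits at its own equilibrium with
$D \approx 0$, so it cannot produce the negative-$D$ part of the signature;
this is standard coalescent behaviour, and the reason the crash-and-recovery
shape is the default. The low-differentiation (balancing-selection-like)
analogue used in the contrasts is a model with a ten-fold more recent split,
which keeps shared polymorphism high and differentiation low.

# Problem sizes used by the tests and the acceptance script

All experiment sizes are package choices balancing Monte-Carlo precision
against desk-scale runtimes: simulator calibration uses 2,000 windows (and
5,000 replicates for the $E[S]$ and TMRCA checks); the FDR calibration uses
5,000 null replicates against 2,000 observed windows at the full study
sample sizes (20+19 diploids, 20x, 0.5% error); parameter recovery uses
2,500 windows of 600 bp (about $6\times10^4$ sites -- short windows because
the experiment stipulates effectively unlinked sites, and a 10 kbp window
without recombination is a single genealogy); model choice runs 25 (tests)
or 20 (script) repetitions with reduced run counts, scaled down from the
50-runs-by-40-cycles convention the method family uses at full scale.

# What the synthetic data does and does not show

The generator emulates the data structure the analysis assumes: two diploid
population samples with an optional outgroup, polarized biallelic SNPs in
10 kbp windows, per-window recombination, and depth/error-driven genotype
noise and missingness. It does not emulate mapping bias, indel-proximal
artifacts, repeat regions, variable callability along the genome, linked
selection outside the emulated windows, or population structure within
species. Passing calibration tests therefore demonstrates internal
consistency of the estimators and the scan under the stated model, not
robustness to those real-data complications; the VCF entry path applies the
corresponding SNP-level filters (biallelic, indel distance >= 5 bp,
DP/GQ masking, <= 10% missingness) so that real data arrive in comparable
shape.

# Known limitations

* The composite likelihood ignores linkage between sites; standard errors
  from it would be anticonservative, which is why intervals come from the
  parametric bootstrap.
* Absolute $N_{anc}$ is not estimated; all sizes and times are conditional
  on the anchor.
* The folded-spectrum path and Fu and Li's statistics are not implemented;
  polarization relies on the outgroup majority allele (sites with an evenly
  split or missing outgroup stay unpolarized).
* The read layer calls genotypes site-by-site with a uniform prior; it does
  not emulate ANGSD's allele-frequency priors or joint SFS estimation from
  genotype likelihoods.
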