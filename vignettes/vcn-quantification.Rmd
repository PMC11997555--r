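---
title: "Vector copy number by duplex ddPCR: model, adjustment and assay validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector copy number by duplex ddPCR: model, adjustment and assay validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropvcn)
library(dplyr)
```

## The measurement problem

CAR-T and TCR-T cell products are engineered with integrating viral vectors,
and the number of vector copies per cell (VCN) is a release-critical safety
parameter: more integrations mean more transgene but also more insertional
risk. Droplet digital PCR measures VCN without a standard curve by
partitioning the reaction into ~20,000 nanolitre-scale droplets and counting
which of them contain template. `dropvcn` implements the complete chain from
per-droplet fluorescence amplitudes to a release-style VCN report, plus a
droplet-level simulator that provides ground truth for every stage.

The duplex design reads two channels per droplet: FAM reports the WPRE
element, a sequence present once per integrated vector and absent from the
human genome, and HEX reports TERT, a reference gene present at exactly two
copies per diploid genome. The ratio of the two absolute concentrations
therefore converts directly into copies per cell.

## Poisson partitioning and the concentration estimate

Template molecules distribute into droplets independently, so the copy count
in one droplet of volume $V$ at concentration $c$ is Poisson with rate
$\lambda = cV$. Only presence/absence is observable: a droplet fluoresces
positive when it received at least one copy. The fraction of negative
droplets estimates $e^{-\lambda}$, giving

$$\hat\lambda = -\ln\frac{n_{neg}}{n_{tot}}, \qquad
  \hat c = \hat\lambda / V.$$

`estimate_concentration()` implements this inversion. Two degenerate inputs
are refused rather than extrapolated: a well with no negative droplets is
saturated (the concentration is unbounded above) and a well with no droplets
carries no information. The 95% confidence interval is a Wilson score
interval on the negative fraction mapped through $-\ln(\cdot)/V$; Wilson was
chosen over the Wald interval because it stays calibrated at the extreme
negative fractions seen near the assay limits, and the transformation simply
swaps the endpoints since $-\ln$ is decreasing. Droplet volume defaults to
0.85 nL, the conventional value for the QX200 instrument family; it is a
parameter everywhere, because the instrument vendor may recalibrate it.

The bulk VCN for a diploid sample follows as

$$VCN_{bulk} = 2 \cdot \frac{c_{WPRE}}{c_{TERT}},$$

implemented in `compute_vcn_bulk()`. Because VCN is a ratio, the amount of
DNA loaded cancels; 50 ng versus 20 ng input changes both channels equally.
Replicate wells are combined by `aggregate_replicates()` with weights
proportional to accepted droplets — a well with twice the droplets carries
twice the Poisson information — while dispersion (SD, CV%) is reported
unweighted across replicates.

## Droplet calling

`set_threshold()` places a scalar per-channel threshold, matching the single
threshold line of the instrument software rather than a 2-D cluster model:
the duplex clusters are axis-aligned, so two scalar cuts recover all four
clusters. Two automatic criteria are provided. `"otsu"` maximises
between-class variance over a 512-bin histogram; because the criterion is
flat across an empty inter-cluster gap, all maximising cuts are averaged so
the threshold sits mid-gap rather than hugging the negative cloud.
`"midpoint"` computes the exact 1-D two-means partition (a scan over the
sorted amplitudes) and returns the midpoint of the two cluster centres. Both
refuse degenerate input in which every amplitude is identical, and a manual
threshold can always be supplied — the right choice for wells that lack one
of the clusters entirely, such as no-template controls, where an automatic
two-class criterion would split noise.

`classify_droplets()` calls a droplet positive strictly above the threshold;
a droplet exactly on the threshold is called negative. The tie policy is
conservative for contamination monitoring (it can only under-call
positives), and with continuous amplitudes ties are measure-zero anyway. No
droplet-quality filtering is applied — the instrument already discards
malformed droplets before export — but wells with fewer than 10,000 accepted
droplets are QC-flagged downstream (`min_accepted`, configurable).

## The Poisson adjustment to transduced cells

Bulk VCN averages over transduced and untransduced cells alike, so at 30%
transduction a bulk value of 0.57 conceals that the cells actually carrying
vector average more than one copy. Under the Poisson model of transduction —
integrations are independent, all cells equally susceptible, growth
unaffected by copy number — per-cell copies are $k \sim \text{Pois}(\lambda)$
with $\lambda = VCN_{bulk}$, the fraction of transduced cells (the putative
transduction efficiency) is

$$p_+ = 1 - e^{-VCN_{bulk}},$$

and the mean copy number among transduced cells is the zero-truncated
Poisson mean

$$VCN_{adj} = \frac{VCN_{bulk}}{1 - e^{-VCN_{bulk}}}.$$

```{r}
adjust_vcn(c(0.57, 2.23, 9.00))
```

`adjust_vcn()` satisfies three structural identities that the test suite
checks to near machine precision: it inverts exactly
($VCN_{adj}\,p_+ = VCN_{bulk}$), it is bounded below by $\max(1, VCN_{bulk})$
(a transduced cell has at least one copy), and it converges to the bulk
value as transduction saturates. At $VCN_{bulk} = 0$ the mathematical limit
of the formula is 1, but the package deliberately reports `NA`: a sample
with no detected vector has no transduced-cell population to describe, and
a release report should say so rather than print the limit of a formula.

`vcn_distribution()` tabulates the corresponding per-cell pmf and cdf,
either over all cells (rate $= VCN_{bulk}$; its mass at $k=0$ is the
theoretical untransduced fraction, which is what makes that percentage
well-defined) or zero-truncated for the transduced subpopulation, whose mean
equals $VCN_{adj}$. Internally the support always extends until the
cumulative mass is within $10^{-9}$ of 1, so normalisation checks are exact;
the displayed support defaults to the 0.9999 quantile. The all-cells variant
is the default in reports because it describes the product as infused.

```{r, fig.width = 6, fig.height = 3.5}
autoplot(vcn_distribution(2.23))
```

`untransduced_fraction_check()` compares $e^{-VCN_{bulk}}$ with the
flow-cytometry negative fraction. The expected direction is theory below
flow — some cells carry vector without expressing detectable surface
transgene — and the function flags the opposite direction as an
assay/flow inconsistency.

## Assay limits

From replicate no-template controls and the lowest concentration the
dilution series actually covered, `compute_limits()` computes

$$LoB = \bar{x}_{blank} + 1.645\,s_{blank}, \quad
  LLoD = \max(LoB + 3.3\,s_{blank},\ d_{min}), \quad
  LLoQ = \max(LoB + 10\,s_{blank},\ d_{min}),$$

with the sample (n−1) SD, the standard choice for limit estimation from few
blanks. The MAX terms prevent claiming limits below concentrations the assay
was never challenged at. The ordering $LoB \le LLoD \le LLoQ$ is an
algebraic consequence of the non-negative coefficients and is property-tested
on random inputs. Flagging (`flag_below_limits()`) is strictly-below: a
value exactly at a limit is treated as quantifiable at it. All limits are in
copies/µl of reaction mix; conversion to copies per reaction is I/O-layer
arithmetic and never enters the statistics.

## Validation statistics

`dilution_linearity()` fits measured against expected responses by OLS on
the linear or log-log scale and reports $R^2 = 1 - SS_{res}/SS_{tot}$.
Log-log fits use the natural log; the base rescales slope and intercept but
cannot change $R^2$. `inter_assay_cv()` reports per-condition
$CV\% = 100\,s/\bar{x}$ and its maximum. The routine two-way ANOVA sometimes
reported alongside repeatability panels is deliberately not re-implemented
here — it is a standard test available as `stats::aov`, and CV% plus
linearity carry the assay-performance contract.

## The simulator and what it does (not) emulate

`simulate_well()` generates droplets exactly under the model the estimator
inverts: independent Poisson occupancy per channel, amplitudes from a
two-Gaussian mixture per channel, and an optional uniform "rain" band of
intermediate droplets. Channel independence mirrors the assay chemistry:
genomic DNA is restriction-digested before partitioning so target and
reference loci travel on separate fragments. Defaults (negative mean 1000,
positive mean 8000, SD 400, arbitrary units) give clearly separated
clusters like a clean instrument run; rain defaults to 0 and is applied per
droplet (a rain droplet is intermediate on both channels). The amplitude
landscape is a stylised stand-in — real runs show drifting cluster
positions, amplitude–occupancy correlation and droplet-volume variation that
the simulator does not model — so passing simulation tests demonstrates the
correctness of the statistical chain, not robustness to every instrument
artefact.

`simulate_cell_product()` draws per-cell copies $k_i \sim
\text{Pois}(\lambda)$ and exposes the template totals a reaction on the
product would contain: WPRE $= \sum_i k_i$ and TERT $= 2n$.
`product_concentrations()` converts totals to reaction concentrations by
pinning the reference channel to a chosen copies/µl (default 1500,
i.e. ~0.85 average TERT copies per droplet, a typical mid-range DNA load)
and scaling WPRE by the template ratio; only the ratio reaches the VCN, so
this one free constant stands in for the DNA-mass bookkeeping.

All randomness flows from a mandatory integer seed through one generator per
call, so any simulated object is bit-reproducible from its config.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen to keep every stochastic
assertion far from its noise floor: 20,000 droplets per well (the
instrument's nominal droplet count), 100 seeds per concentration for
estimator coverage, $10^5$–$10^6$ cells for product simulations, and
five-point twofold dilution series. Stochastic assertions use 3–4 SD bands
derived from binomial or delta-method standard errors rather than tuned
tolerances. Coverage of the Wilson-based interval is asserted against 93%
aggregated over 1000 wells, leaving room for the small undercoverage any
score interval shows at extreme negative fractions.

Known limitations: rain droplets are classified like any other droplet (no
rain-exclusion heuristic); thresholds are per-channel scalars, so a
diagonally smeared cluster would need manual thresholds; the per-cell model
ignores clonal expansion, which in real products inflates the copy-number
variance beyond Poisson; and reported confidence intervals for VCN are
conservative endpoint ratios, not profile intervals.
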