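---
title: "Inferring strain-strain interactions in a defined gut community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring strain-strain interactions in a defined gut community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommnet)
```

## The problem

Defined (synthetic) bacterial communities — a dozen strains spanning the
major gut phyla, cultured together in a rich medium — are a workhorse of
mechanistic microbiome research, but the pairwise ecology that shapes their
assembly is rarely known. `ommnet` implements a bottom-up in vitro
inference workflow that turns four kinds of routine batch-culture readouts
into a signed, typed strain-strain interaction network:

1. **Spent-media growth assays.** Each strain is grown to late stationary
   phase; its sterile-filtered supernatant (spent medium, SM) becomes the
   culture medium for every other strain. Growth of a consumer in a
   producer's SM is summarised by the normalized inhibition factor
   $d_{AUC} = (AUC_{SM} - AUC_{fresh}) / AUC_{fresh}$, with
   $d_{AUC} < -0.5$ (strict) called strong inhibition.
2. **Untargeted metabolomics of the supernatants.** Per-feature two-sample
   t-tests against fresh medium define each strain's substrate *depletion
   profile* $D_i$; the asymmetric overlap
   $100\,|D_i \cap D_j|/|D_i|$ quantifies exploitative (resource)
   competition.
3. **Pairwise co-cultures quantified by strain-specific qPCR.** The ratio
   $r_{bm} = m_{i,co}(72\,h) / m_{i,mono}(72\,h)$ of a strain's absolute
   abundance in co-culture to monoculture, tested against 1 across
   replicate experiments, gives each strain a per-partner effect sign
   (+/0/−); the unordered sign pair maps onto the six classical
   interaction types (mutualism, commensalism, neutralism, amensalism,
   competition, predation).
4. **Serial-passage communities** (daily 1:100 dilution), including
   dropout communities lacking one member, summarised as relative
   abundances, dropout-versus-full t-tests, per-strain z-scores and PCA
   ordination.

Because the raw plate-reader, MS and qPCR datasets behind such a study are
not generally redistributable, the package ships a *synthetic twin*: a
generalized Lotka-Volterra (gLV) batch-dilution simulator with designed
ground truth for every readout, so each analysis stage has a
parameter-recovery test that runs at desk scale.

## Models and estimators

### Growth curves

AUC is the trapezoidal integral of blank-corrected linear OD600 over the
recorded window (20 h at 10-min sampling by default). The trapezoid rule is
exact for piecewise-linear curves and has relative truncation error
$(b-a)h^2 f''/12$ otherwise — about 0.5% for an exponential curve sampled
every 0.25 h, quadratically smaller at denser sampling.

The maximum specific growth rate is the largest slope of $\ln(OD)$ over a
sliding window (default 5 points) restricted to readings above a floor
(default `min_od = 0.02`). The floor exists to keep windows off the
plate-reader noise floor; it also bounds the estimator's accuracy on
saturating curves, because a window starting at OD 0.02 in a culture with
capacity $K$ already sits at $0.02/K$ of capacity, where the logistic
slope is depressed by roughly that fraction. For noiseless simulated
curves we therefore validate recovery with the floor just above the
inoculum (`min_od = 0.002`), where the bias is 1-3% across capacities
down to $K = 0.4$; with the default floor the estimator remains within 5%
for $K \gtrsim 0.8$. Rates are classed fast ($> 1.5\,h^{-1}$),
intermediate ($> 1\,h^{-1}$) or slow ($\le 1\,h^{-1}$), with the strict
">" boundary convention, so exactly 1.0 is slow and exactly 1.5
intermediate.

d_AUC uses replicate *means* (not per-replicate ratios); per-replicate
values are available for uncertainty work. Correlations default to Pearson
with the two-sided p from the t distribution on $n-2$ degrees of freedom
(the quantities correlated here are reported as linear correlations);
Spearman is available by flag. Zero-variance input is rejected rather than
returning `NA`.

### Feature calling

Per strain and feature, a two-sided two-sample t-test of strain replicates
against fresh-medium replicates; Welch's unequal-variance form by default,
Student's pooled form by flag. A feature is depleted (produced) when
$p < \alpha$ and the strain mean is below (above) the fresh mean. No
multiple-testing correction is applied by default — the workflow's
reference analysis uses raw $p < 0.05$ — and Benjamini-Hochberg is
available with the caveat that it calls systematically fewer features.
Intensities are compared on the raw scale (log10 by flag). Zero-variance
features are skipped with a warning. Note that Welch's test at $n = 3$
versus 3 is conservative: its true level at nominal 0.05 is near 0.033,
which is what the calibration checks observe.

### Interaction network

qPCR standard curves $C_q = b + a\,\log_{10}(copies)$ require $a < 0$ and
implied efficiency $10^{-1/a} - 1 \in (0, 1.2]$. Copies follow
$d \cdot 10^{(C_q - b)/a}$ with an out-of-calibration-range flag. The
per-sample normalization of copies cancels in $r_{bm}$, so the network is
invariant to it (tested). Ratios are paired by experiment; the sign test
is a two-sided one-sample t-test of the raw ratios against 1 (the closest
literal reading of averaging $r_{bm}$ over three experiments), with a
log-ratio-versus-0 variant by flag since ratio distributions are skewed.
Degenerate zero-variance replicate sets are signed by direction with a
warning rather than producing an undefined statistic. Census conservation
(type counts sum to $S(S-1)/2$) holds by construction.

### Community summaries

Relative abundances carry explicit detection flags (default relative limit
$10^{-4}$, absolute override available) instead of imputing zeros.
Ordination is column-centred PCA on relative abundances (no log-ratio
transform, matching the reference analysis; a CLR option would change the
geometry and is deliberately not the default). Component signs are fixed
by making each component's largest-magnitude loading positive. Per-strain
scaling across conditions is a z-score; constant rows scale to zero with a
warning.

## The synthetic twin

`synthetic_design()` bundles: per-strain growth parameters ($\mu$, $K$,
inoculum, acidification coefficient, 16S copies per OD), a dimensionless
coupling matrix $c_{ij}$ (gLV matrix
$a_{ij} = c_{ij}\mu_i/K_j$, $a_{ii} = -\mu_i/K_i$), a bacteriocin
kill-coupling matrix (always inhibitory), a strain × feature
resource-usage/depletion profile, noise levels, and the dilution schedule.
Dynamics are $dN_i/dt = N_i(\mu_i + \sum_j a_{ij} N_j)$, integrated with
fixed-step RK4 at $dt = 0.01$ h (deterministic and dependency-light; a
tiny-step reference and an adaptive integrator serve as oracles in the
tests), with instantaneous dilution between cycles and a divergence guard
at $10^6 \times \max K$.

Spent-media growth reduces the consumer's effective capacity by the
fraction of its resources the producer has depleted, and its growth rate
by the producer's bacteriocin coupling; this construction couples
substrate overlap to $d_{AUC}$ the way exploitative competition should.
Feature tables are log-normal around per-feature baselines with designed
depletion depths and small per-strain production blocks. qPCR observation
adds Gaussian noise on the $C_q$ scale and censors zero abundances at the
maximum cycle.

### The default design

`default_design()` is the package's stand-in for a 12-member gut
community: growth rates 0.5-2.0 h⁻¹ (4 fast, 5 intermediate, 3 slow
strains, mirroring the reference community's 4/5/3 grouping), one
bacteriocin producer, and a designed interaction census of 46 amensal, 7
competitive, 11 neutral, 1 commensal and 1 predatory pair (no mutualism) —
the census observed in the reference community. One-sided effects are
calibrated so the affected strain's endpoint ratio is about 0.25 (or 4
for beneficial effects), i.e. $|\log_2 r| \approx 2$. Mutual competitive
pairs are a modelling exception: in Lotka-Volterra dynamics a symmetric
competition coupling above 1 destabilises coexistence and collapses the
pair to exclusion — which an endpoint assay reads as (−, 0), not (−, −) —
so competitive couplings are set to 0.9, giving stable coexistence at a
per-side ratio near 0.5, still detected with high power at three
replicates and 20% CV. Resource niches are placed along a 12-leaf
phylogeny (niche centres from the first principal coordinate of the
patristic distance matrix), so related strains share substrates and the
designed negative correlations — shared features versus tree distance, and
overlap versus $d_{AUC}$ — emerge rather than being painted on.

Observation noise defaults: OD s.d. 0.005, intensity CV 10%, abundance CV
20% (three replicates), $C_q$ s.d. 0.1. These are realistic plate-reader,
untargeted-MS and qPCR noise scales for this kind of experiment.

Two honest limitations of the twin. First, its full-community serial
passage is winner-takes-all: forty-six strong pairwise amensalisms
compound in a 12-strain flask, and the community collapses onto the
strongest pair within ten days — unlike the reference community, where
most strains coexist. The pairwise census and the community dynamics are
therefore both faithful to the model, but the model's pairwise-additive
gLV assumption visibly fails to reproduce community-level coexistence;
community-level tests use smaller dedicated designs (a killer strain and
its victims) where ground truth is unambiguous. Second, the generator has
no pH feedback, no explicit resources and no higher-order effects, so
passing recovery tests demonstrates the *pipeline's* correctness, not that
real communities obey gLV.

## Numerical and statistical choices

- Welch t-tests are vectorised over features; p-values match `t.test` to
  machine precision (tested feature by feature).
- The sign map is locale-independent (explicit sign ordering, not
  character comparison).
- Patristic distances come from `ape` and are validated against a
  brute-force breadth-first path enumeration; they are invariant under
  re-rooting (tested), so the correlation analyses do not depend on where
  the input tree is rooted.
- PCA uses the SVD route (`prcomp`); the tests compare scores against a
  direct eigendecomposition of the covariance matrix.
- Reported overlap percentages round half away from zero to one decimal
  (the convention of the worked example they reproduce); full precision is
  retained internally.
- Problem sizes in the shipped tests: 400-feature default universe,
  8000-feature null calibrations, 5000-trial sign-test calibration, 20
  observation seeds for end-to-end sign recovery, 10-day passages. These
  keep the whole suite near half a minute while leaving the binomial
  error on calibration rates well inside the asserted bands.

## Worked example

```{r example, eval = FALSE}
design <- default_design()

# co-culture experiment and network inference
ab <- simulate_cocultures(design, seed = 1)
net <- build_interaction_network(ab, alpha = 0.05)
net$census

# spent-media inhibition matrix
sm <- simulate_spent_media_experiment(design, seed = 1)
cs <- do.call(rbind, lapply(sm$curves, summarise_growth))

# depletion profiles and overlap against phylogeny
ft <- simulate_feature_table(design, seed = 1)
profiles <- call_feature_changes(ft, alpha = 0.05)
ov <- overlap_matrix(profiles)
dm <- patristic_distances(parse_newick(design$tree_newick))
shared_count_vs_distance(ov, dm)
```

## Known limitations

- Endpoint-only interaction calls: the 24/48 h intermediate points are
  simulated but not dynamically modelled (no gLV fitting to data).
- The raw-ratio t-test at $n = 3$ has limited power for per-side ratios
  above ~0.6, so mild competitive effects are sometimes read as neutral;
  the log-ratio variant shifts but does not remove this.
- No peak picking, batch correction or metabolite annotation: the
  metabolomics module starts from an integrated, QC-corrected feature
  table.
- Euler-diagram region counts are exact set algebra; no ellipse fitting.
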