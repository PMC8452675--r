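---
title: "Ancestry assignment with AIM panels: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry assignment with AIM panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimassign)
```

## The model

An AIM profile is a vector of biallelic genotypes, encoded as allele-1
dosages $g_j \in \{0, 1, 2\}$ over markers $j = 1..m$, with `NA` for missing
calls. A reference meta-population supplies, per marker, an allele-1 count
$x_j$ out of $n_j$ typed allele copies. Frequencies are estimated with a
pseudo-count $a$:

$$ q_j = \frac{x_j + a}{n_j + 2a}, \qquad
   \widehat{\mathrm{Var}}(q_j) = \frac{q_j(1-q_j)}{n_j + 2a + 1}. $$

Assuming Hardy–Weinberg equilibrium and independent markers, the profile
log-likelihood under the meta-population is

$$ \ell = \sum_{j:\,g_j \ne \mathrm{NA}} \log P(g_j \mid q_j), \qquad
   P(\cdot) \in \{(1-q_j)^2,\; 2q_j(1-q_j),\; q_j^2\}. $$

Both moments of $\ell$ under the same model are available in closed form per
locus, $E_j = \sum_g P(g)\log P(g)$ and
$V_j = \sum_g P(g)\log^2 P(g) - E_j^2$, and add over loci. The outlier
statistic is

$$ z = \frac{E[\ell] - \ell}{\mathrm{SD}[\ell]}, $$

positive when the profile fits *worse* than a typical member of the
reference. The gate is one-sided: $z > z_{1-\alpha}$ (1.64 at
$\alpha = 0.05$) rejects the meta-population as origin. Missing markers are
dropped from $\ell$, $E[\ell]$ and $\mathrm{SD}[\ell]$ symmetrically, so $z$
stays calibrated for partial profiles.

When the tested individual is itself part of the reference counts, its two
allele copies are subtracted per non-missing marker before estimating $q_j$
(leave-one-out). Keeping the individual in deflates $z$ systematically — the
test suite demonstrates this on paired simulations — which is why the
out-of-sample procedure is not optional when testing reference members.

The evidence weight between meta-populations A and B is
$\log LR = \ell_A - \ell_B$ over the shared non-missing loci, with standard
error $\sqrt{\sum_j \mathrm{Var}_A[t_j]}$ where
$t_j = \log P_A(g_j) - \log P_B(g_j)$ and the variance is taken under A's
genotype distribution. Its expectation under A is the sum of per-locus
Kullback–Leibler divergences, which is why adding informative markers can
only increase the expected evidence — the property the combined-panel
monotonicity tests check.

### Classification

Per profile: compute $z_k$ for every meta-population $k$; the accepted set is
$\{k : z_k \le z_{1-\alpha}\}$.

* **Rejected** — accepted set empty; no LRs are computed or stored.
* **Accepted** — exactly one member; or several members, and the
  highest-likelihood one beats every other accepted alternative one-sidedly
  ($\log LR / SE > z_{1-\alpha}$).
* **Ambiguous** — several members, not separable.

Two deliberate conventions: a zero-SE log-LR (possible when two references
are identical at every informative locus) counts as *not* significantly
different, so duplicated references produce Ambiguous rather than arbitrary
acceptance; and in per-meta-population reporting (`cross_validate`), only the
best accepted meta-population can carry the Accepted label — the other
accepted ones are Ambiguous for that test.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_depth_1`, `hb_window_1` | 45, [0.3, 3.0] | reads, ratio | main acceptance rule for genotype calls |
| `min_depth_2`, `max_depth_2`, `hb_window_2` | 20, 44, [0.7, 1.3] | reads, ratio | rescue rule for low depth; requires noise exactly 0 |
| `max_missing` | 0.10 | fraction | strict (>10%) sample exclusion |
| `alpha` | 0.05 | — | both the z gate (1.64 one-sided) and the LR separation test |
| pseudo-count `a` | 0.5 | allele copies | keeps $q_j \in (0,1)$ so $\ell$ is finite; `a = 0` reproduces raw ML frequencies and is rejected at use time if it yields 0/1 |
| `hwe_steps` | 1e6 | chain steps | Markov-chain HWE option at parity with the conventional setting; enumeration is exact and preferred at desk scale |
| `ld_permutations` | 1000 | permutations | permutation floor is $1/(B+1)$; raise for smaller corrected thresholds |
| `min_size` | 75 | individuals | reference size below this warns (small references inflate z; see limitations) |
| `clamp_eps` | 1e-3 | frequency | simulation clamp keeping frequencies inside (0,1) |

Depth bounds are inclusive on both ends ("20 to 44" meets "≥ 45" with no gap
or overlap); "no noise" means a noise fraction of exactly zero; the
heterozygote-balance windows apply only to heterozygous candidate calls —
for homozygotes Hb is undefined and only depth/noise decide. A heterozygote
with one allele at zero reads has infinite Hb and always fails the window.

## The synthetic-data generator

`sim_config()` + `simulate_study()` emulate: $K$ populations differentiated
from shared ancestral frequencies by the Balding–Nichols model
($\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, mean $p$, variance $p(1-p)F$);
HWE genotypes sampled marker-independently; optional two-way admixture where
each allele copy descends from population A with probability $\alpha$; and a
read-count layer with negative-binomial total depth (Poisson in the
infinite-dispersion limit), binomial heterozygote allele bias, and per-read
errors distributed uniformly over the three non-genotype nucleotides. A
minimum-allele-frequency caller (threshold 0.1, matching common genotyper
defaults) produces the candidate genotypes that QC accepts or rejects, and
the simulated truth is carried alongside so QC accuracy is checkable.

Defaults state a realistic amplicon experiment: mean depth 200 with
dispersion 10 (over-dispersed coverage), allele bias 0.5, error rate 0.002,
100 individuals per population. Where differentiation matters, tests state
their own FST; the regional-vs-continental contrast is represented by the
grid {0.02, 0.15} and is illustrative — no quantitative FST between the real
meta-populations is asserted anywhere.

What the generator does **not** emulate: linked markers (haplotype
structure), so LD tests on its output are null calibrations only; locus-
and strand-specific amplification artefacts; allele-specific dropout;
population substructure within a reference; sequence-level errors (homopolymer
effects). A green test on synthetic data therefore establishes internal
correctness and calibration of the statistics — not panel performance on any
real population.

All randomness flows from one root seed through fixed per-operation
substreams (frequencies, genotypes, admixture, read counts, panel), so every
artefact of a run is reproducible from the configuration alone.

## Numerical choices

* **HWE exact test**: probability-ordering convention — the p-value sums the
  conditional probabilities of all heterozygote configurations no more
  probable than the observed one, computed from log-factorials; a tolerance
  of $10^{-12}$ on the log scale guards ties. Monomorphic tables return 1.
  The Markov-chain option is Metropolis–Hastings over the heterozygote count
  and reports a batch-means Monte-Carlo standard error (attribute `mc_se`)
  so agreement with enumeration can be asserted at 3 MC SEs rather than an
  arbitrary tolerance.
* **LD exact test**: haplotype frequencies for two biallelic loci are
  estimated by EM (only the double heterozygote is phase-ambiguous); the
  statistic is the likelihood ratio of the 4-haplotype model against the
  product of allele frequencies; the null is generated by permuting one
  genotype column, $p = (1 + \#\{S_b \ge S\})/(1 + B)$, which is valid and
  never returns 0. Only complete cases enter.
* **Pruning order**: significant pairs are processed most significant first;
  within a pair the lexicographic performance comparison is dropouts, then
  mean noise, then $|\mathrm{Hb} - 1|$, then locus balance closest to the
  panel mean; exact ties remove the longer amplicon. The order and hierarchy
  are declared conventions (no canonical ordering exists), and every removal
  is logged with the deciding rule so results are auditable.
* **Frequency-variance correction**: reference allele-frequency uncertainty
  can be folded into $\mathrm{Var}[\ell]$ as a second-order term
  ($\widehat{\mathrm{Var}}(q_j)\sum_g P(g)\,(\partial\log P/\partial q)^2$),
  via `include_freq_var = TRUE`. It is off by default: the base statistic
  matches the documented design, and the correction only matters for small
  references.
* **Calibration semantics**: "self-simulated" calibration draws test
  profiles from the reference's *own shrunken frequency estimates*, making
  the model exactly self-consistent (mean z = 0 by construction). Drawing
  from the latent truth behind a finite reference instead leaves a positive
  bias in mean z of order $\sqrt{m}/n_{\mathrm{ref}}$ (measured ≈ 0.33 at
  $n_{\mathrm{ref}} = 75$ with 233 markers, ≈ 0.08 at 500) — a property of
  finite references that the leave-one-out procedure does not remove.
* **Degenerate inputs**: empty profiles give $\ell = 0$ with 0 loci used and
  are flagged rather than scored; a zero-depth record has undefined noise and
  can only fail QC; leave-one-out subtraction below zero raises a
  data-integrity error instead of silently clamping.

## Known limitations

* The z gate is slightly anti-conservative in the extreme tail at a few
  hundred loci ($\ell$ is a sum of skewed discrete terms; rejection at 1.64
  runs nearer 6% than 5% in the calibration suite — within the stated
  binomial tolerance, but visibly above nominal).
* Small references (tens of individuals) inflate z for true members even
  with leave-one-out; the analytic mean correction is derivable but not
  applied, to keep the statistic in its documented form. The 75-individual
  warning threshold reflects this.
* Admixed profiles are simulated but not modelled: an admixed individual is
  accepted wherever its mixed likelihood clears the gate, which is the
  behaviour the classification's caveats anticipate, not an inference of
  admixture proportions.
* Meta-population construction (which source populations pool into one
  reference class) is user configuration; no clustering is performed here.
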