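---
title: "Measuring diversity with generalized Simpson's entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diversity with generalized Simpson's entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsimpson)
```

## The index and what it measures

For a community of $S$ species with proportions $p_1, \dots, p_S$
($p_s > 0$, $\sum_s p_s = 1$), generalized Simpson's entropy of order
$r \in \{1, 2, \dots\}$ is

$$\zeta_r = \sum_{s=1}^{S} p_s (1 - p_s)^r .$$

It has a direct sampling interpretation: $\zeta_r$ is the probability that
the $(r+1)$st individual drawn from the community belongs to a species not
seen in the first $r$ draws — the slope of the species accumulation curve
at rank $r + 1$. Equivalently, if $X$ is the number of species seen exactly
once in a sample of $r + 1$ individuals, $\zeta_r = E[X]/(r+1)$. The
classical Simpson index is $1 - \zeta_1$. The information function is
$I(p) = (1-p)^r$, the probability of missing a species of proportion $p$ in
a sample of size $r$, so larger orders weight rare species more heavily.

Why this family deserves attention when HCDT/Hill and Hurlbert indices
already exist: it admits an *exactly unbiased* estimator at every order
below the sample size. Plug-in estimators of Hill diversities are
substantially biased in under-sampled, species-rich communities, precisely
where diversity estimation matters most; $\zeta_r$ sidesteps that problem.

### Axioms and the valid range of orders

$\zeta_r$ is symmetric and continuous in the proportions, and its
information function is decreasing with $I(1) = 0$. It does **not** satisfy
the full principle of transfers for $r > 1$; it satisfies the *weak*
principle: an order-preserving transfer of probability from a commoner to a
rarer species increases $\zeta_r$ whenever the two proportions sum to at
most $T = 2/(r+1)$ (`transfer_threshold()`). Evenness (the uniform
community maximizes the index) holds for $r \le S - 1$, and this range is
enforced as the advisory bound for diversity profiles. Beyond it the
uniform community can be beaten — for $S = 2$ the first failing order is
$r = 4$, where $\zeta_4(0.25, 0.75) = 0.0820 > 0.0625 = \zeta_4(0.5, 0.5)$.
(For $S = 2$, $r \le 3$, writing $u = p(1-p) \le 1/4$ gives
$\zeta_2 = u$ and $\zeta_3 = u(1 - 2u)$, both maximized at the uniform
community, so $r = 4$ is genuinely the first counterexample.)

The effective number of species (the number of equally frequent species
with the same entropy) inverts $\zeta_r = (1 - 1/D)^r$:

$$ {}^{r}D^{\zeta} = \frac{1}{1 - \zeta_r^{1/r}} . $$

`effective_number()` maps an entropy of exactly 1 to `Inf` instead of
raising an error: clamped upper confidence limits legitimately reach 1 (an
all-singleton sample is consistent with unbounded diversity), and profiles
must not abort there.

## Estimation

With observed counts $n'_1, \dots, n'_K$ ($n = \sum_s n'_s$,
$\hat p'_s = n'_s/n$), the estimator

$$ Z_r = \sum_{s=1}^{K} \hat p'_s \prod_{j=1}^{r}
   \left(1 - \frac{n'_s - 1}{n - j}\right) $$

is the uniformly minimum variance unbiased estimator of $\zeta_r$ for
$1 \le r \le n - 1$; no unbiased estimator exists at $r \ge n$, and the
package refuses such orders. Every factor of the product lies in $[0, 1]$
(a zero factor occurs before any factor could turn negative), so the
product is accumulated directly in input order — no log-space evaluation,
no reordering — and $Z_r \in [0, 1]$ always. The test suite verifies exact
unbiasedness by full multinomial enumeration over a grid of small
communities and sample sizes, against an enumeration oracle written along a
different route (ordered i.i.d. draws), and checks $Z_r$ itself against the
factorial form of the estimator.

### Variance and confidence intervals

$Z_r$ is consistent and asymptotically normal. The asymptotic variance is
estimated by the delta method: with $\hat\Sigma$ the multinomial covariance
of the first $K - 1$ observed proportions and $\hat h_r$ the gradient of
$\zeta_r$ after eliminating the last proportion — component $j$ equal to
$[(1-\hat p_j)^r - r\hat p_j(1-\hat p_j)^{r-1}] -
[(1-\hat p_K)^r - r\hat p_K(1-\hat p_K)^{r-1}]$ —

$$ \hat\sigma_r = \sqrt{\hat h_r^\top \hat\Sigma \hat h_r}, \qquad
   Z_r \pm z_{\alpha/2} \, \hat\sigma_r / \sqrt{n}. $$

Two deliberate choices here. First, the gradient sign convention: we use
the delta-method gradient $\partial \zeta_r / \partial p_j$ with $p_K$
eliminated, the unique form consistent with asymptotic normality of the
plug-in functional; it is validated empirically by the variance-consistency
test (Monte-Carlo sd of $\sqrt{n}(Z_r - \zeta_r)$ within 5% of the analytic
$\sigma_r$ at $n = 2000$, 20000 replicates). Second, which species plays
the "last" role is immaterial — the quadratic form is invariant, and a
permutation test asserts it.

Degenerate cases are handled so profiles never abort mid-range: a
single-species sample has no defined variance (error); an exactly uniform
$\hat p$ makes every gradient component vanish, and $\hat\sigma_r = 0$ is
returned with a warning. Intervals are clamped to $[0, 1]$ because
$\zeta_r$ is a probability (the clamp is our choice; it never affects
inference since the transform to effective numbers is monotone).

Empirical coverage of the 95% interval, measured by
`coverage_experiment()` on a geometric community ($S = 10$, ratio 0.7,
$n = 1000$, $r = 2$, 2000 replicates), sits within $\pm 0.02$ of nominal.

### Profiles

`zeta_profile()` assembles estimates and intervals for $r = 1, \dots, v$.
The envelope is **pointwise** — each order covered at the stated level
individually, no simultaneous-coverage adjustment. Two bounds govern $v$:
the hard statistical bound $v \le n - 1$ and the advisory diversity bound
$r \le \hat S - 1$, with $\hat S$ estimated by the jackknife; by default
the profile runs to $\min(n - 1, \hat S - 1)$, and orders beyond the
richness bound are flagged when a richness estimate is supplied. On the
`"diversity"` scale the estimate and both limits are pushed through the
monotone effective-number transform, so inference is identical on either
scale; `"diversity"` is the default reporting scale in the command-line
tool because effective numbers are directly interpretable.

## Comparing two communities

For independent samples, the difference $\zeta_r^{(1)} - \zeta_r^{(2)}$ has
interval $(Z_r^{(1)} - Z_r^{(2)}) \pm z_{\alpha/2}
\sqrt{\hat\sigma_{r,1}^2/n_1 + \hat\sigma_{r,2}^2/n_2}$, not clamped (a
difference of probabilities lives in $[-1, 1]$). `significance_summary()`
reads the profile: equal diversity is rejected when zero is outside the
envelope at *every* order, not rejected when inside at every order, and
otherwise the comparison is labelled inconclusive. The all/none/mixed rule
is our operationalization of the informal "generally inside/outside the
envelope" reading; it is deliberately conservative, clearly labelled
pointwise, and no multiplicity correction is offered or implied.

## Jackknife richness and order selection

Richness enters only to bound the valid profile order. We use the
Burnham–Overton jackknife family (orders 1–5), built from the frequency
counts $f_i$ (species seen exactly $i$ times), e.g.

$$ \hat S_1 = K + f_1 \frac{n-1}{n}, \qquad
   \hat S_2 = K + f_1 \frac{2n-3}{n} - f_2 \frac{(n-2)^2}{n(n-1)}. $$

The closed-form coefficients for all five orders are cross-checked in the
tests against an independent derivation: the order-$k$ generalized
jackknife is the linear combination of rarefied expected richnesses
$E_n, E_{n-1}, \dots, E_{n-k}$ that cancels bias terms
$1/m, \dots, 1/m^k$, obtained by solving the corresponding Vandermonde
system. The order is selected sequentially: test
$\hat S_{k+1} - \hat S_k$ against its conditional standard error
$\sqrt{\tfrac{n}{n-1}\bigl(\sum_i d_i^2 f_i - (\hat S_{k+1}-\hat
S_k)^2/n\bigr)}$ (with $d_i$ the coefficient differences) and stop at the
smallest $k$ whose increment is non-significant at $\alpha = 0.05$, capped
at order 5. Published variants of this selection rule differ in detail;
this one is stated exactly so results are reproducible. A sample without
singletons selects order 1 immediately. A fractional $\hat S$ is floored
before computing the bound $r \le \hat S - 1$ — conservative, never
exceeding the estimated $S - 1$.

One property worth knowing: the order-2 jackknife *can* fall below the
observed $K$ when $f_1 = 0$ but $f_2 > 0$; it is guaranteed at or above $K$
whenever $f_1 \ge f_2$. The tests assert exactly that.

## Comparator indices

HCDT (Tsallis) entropy ${}^qT = (\sum_s p_s^q - 1)/(1-q)$ and Hill
diversity ${}^qD^T = (\sum_s p_s^q)^{1/(1-q)}$ are provided as plug-in
computations on known or estimated proportions, with the Shannon limit
applied within $10^{-9}$ of $q = 1$. When fed sample proportions these are
the plug-in, negatively biased estimates, and the command-line output
labels them so; bias-corrected Hill estimation is deliberately out of
scope. The identity ${}^2T = \zeta_1$ links the families, and
`match_q()` finds the HCDT order whose Hill diversity equals
${}^rD^\zeta$ by monotone root bracketing (the bracket $[0, 2]$ expands
upward as needed); at $r = 1$ the answer is exactly $q = 2$.

Hurlbert's index ${}^kH = \sum_s [1 - (1-p_s)^k]$, the expected number of
species in a sample of $k$ individuals, has the unbiased rarefaction
estimator $\hat H_k = \sum_s [1 - \binom{n-n'_s}{k}/\binom{n}{k}]$
(evaluated via `lchoose`, so large $n$ is safe), with the cross-family
identity $\hat H_2 = 1 + Z_1$ asserted across modules. Its effective number
solves $D[1 - (1-1/D)^k] = {}^kH$ by monotone root-finding (tolerance
$10^{-9}$); a value equal to $k$ maps to `Inf`.

`bootstrap_envelope()` supplies percentile intervals (multinomial
resampling from $\hat p$, seeded and bit-reproducible) for statistics
without a variance formula. A caveat the tests quantify: for Hurlbert's
index at uniform $S = 10$, $n = 500$, $k = 20$, the percentile envelope
covers the truth at roughly 0.89 rather than 0.95 — resampling from
$\hat p$ recentres the interval at the plug-in value, a standard
percentile-bootstrap shortfall. Treat bootstrap envelopes as descriptive.

## Synthetic data: what it does and does not show

`make_community()` offers uniform, geometric (niche preemption),
log-series, and Zipf abundance models — the standard shapes used to emulate
dominated, long-tailed communities. `sample_community()` draws multinomial
samples (sampling with replacement / infinite population; spatially
structured or without-replacement designs are out of scope). All
stochastic functions take explicit seeds and are bit-reproducible.

`enumerate_expectation()` is the package's exactness oracle: it enumerates
every composition of $n$ individuals into $S$ species with log-space
multinomial weights, and refuses problems beyond $S \le 4$, $n \le 8$.
Unbiasedness claims in the tests are *exact statements checked exactly*,
not simulations.

Passing these tests shows the estimators do what the theory says under
i.i.d. multinomial sampling from a fixed community. Real survey data add
spatial aggregation, detection bias, and taxonomic lumping, none of which
the generator emulates; the random-sampling assumption is the user's
responsibility, as it is for every estimator in this family.

### Problem sizes used in the checks

The validation suite runs at desk scale, chosen to make each check
decisive: exact enumeration over ten communities ($S \in \{2,3\}$, all
$n \le 6$, all valid $r$); variance calibration at $n = 2000$ with 20000
replicates ($r \in \{1,2,3\}$, agreement within 5%); interval coverage at
$n = 1000$ with 2000 replicates (within $\pm 0.02$ of 0.95); and a
two-community workflow with $n = 600$ per sample, where the geometric
$S = 60$, ratio 0.90 community is separated from the geometric $S = 120$,
ratio 0.95 community at every order (the two true profiles never cross, so
"significant at every order" is the correct verdict).

## Known limitations

- Orders are hard-limited by $r \le n - 1$ and advisory-limited by
  $r \le \hat S - 1$; both bounds are enforced/flagged, not silently fixed.
- The difference-profile verdict is pointwise and unadjusted; with many
  orders, "significant at every order" is stronger evidence than any single
  order, but no family-wise level is claimed.
- Plug-in Hill profiles are biased in under-sampled data — that is the
  motivating problem, not a defect to patch here; they are included for
  comparison and labelled plug-in.
- Proportion vectors that do not sum to 1 are refused, never renormalized,
  and zero proportions are refused rather than dropped: both behaviors
  surface upstream data errors instead of hiding them (continuity
  guarantees that pre-filtering zero-probability species does not change
  any index).
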