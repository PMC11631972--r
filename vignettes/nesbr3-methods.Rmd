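---
title: "Methods behind nesbr3: the neutrosophic Burr-III distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind nesbr3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

Neutrosophic statistics replaces a crisp observation $x_L$ by an interval
$[x_L, x_L(1+I_N)]$, where $I \in [I_L, I_N]$ quantifies the indeterminacy
attached to the measurement (with $I_L = 0$ the lower endpoint *is* the
classical analysis).  `nesbr3` builds this machinery on the Burr-III
lifetime distribution.  At a fixed indeterminacy value $I \ge 0$ the CDF is

$$F(x;\lambda,\theta,I) = \bigl\{1 + [(1+I)x]^{-\theta}\bigr\}^{-\lambda},
\qquad \lambda, \theta > 0,\ x > 0 .$$

Structurally this is a pure rescaling: $X = Y/(1+I)$ with $Y$ classical
Burr-III.  All of the package's closed forms follow from that one fact, and
$I_L = I_N = 0$ recovers classical statistics exactly (a package
invariant under test).

**The endpoint-evaluation contract.**  A neutrosophic quantity is the
*ordered pair* of classical evaluations at the two indeterminacy
endpoints.  We deliberately do not do interval arithmetic (no joint
estimation across endpoints, no dependency tracking): the bracketed outputs
of the reference analyses are exactly per-endpoint classical results, and
the pair representation keeps every operation unambiguous.

Assumptions worth stating: observations are positive, uncensored, and
i.i.d. at each endpoint; the indeterminacy is multiplicative and common to
all observations; the two shape parameters are shared across observations.

## Tunable parameters

* $\lambda, \theta$ (dimensionless, $>0$): shapes.  $\theta$ controls the
  tail: $E[X^r]$ exists only for $r < \theta$; variance needs
  $\theta > 2$, kurtosis $\theta > 4$.
* $I \in [I_L, I_N]$ (dimensionless, $\ge 0$): indeterminacy.  The default
  interval for the bundled applications is $[0, 0.05]$ — i.e. "values may
  be understated by up to 5%", the convention under which the bundled
  datasets were interval-ized.
* Optimizer settings (`fit_opts()`): relative objective tolerance
  `1e-10`, Nelder–Mead iteration cap 5000, multi-start set as described
  below, default jitter seed 20240511 (jitter off by default, so fits are
  fully deterministic).

## Conventions where the published formulas disagree with the density

Several printed closed forms for this family circulate with typos.  The
package's policy: *the density is the ground truth*, every closed form must
match adaptive quadrature against it, and literal printed variants are
still available behind explicit flags so users can trace the published
derivations.

* **Quantile.**  The printed quantile form with exponent $q^{+1/\lambda}$
  gives a negative base for $q<1$; the package uses the exact inverse of
  the CDF, $x_q = (1+I)^{-1}(q^{-1/\lambda}-1)^{-1/\theta}$, enforced by
  the round-trip invariant $|F(x_q)-q| \le 10^{-9}$.
* **Positive moments.**  Since $X = Y/(1+I)$,
  $E[X^r] = (1+I)^{-r}\lambda B(1-r/\theta, \lambda+r/\theta)$.  The
  circulated form carries $(1+I)^{+r}$ instead; both are exposed
  (`convention = "pdf_consistent"` (default) vs `"paper_eq6"`), and only
  the pdf-consistent one feeds inference.  Negative moments as circulated
  are already pdf-consistent (reciprocals scale *up* with $1+I$).
* **Mean/variance "literal" form** uses the negative-moment beta arguments;
  it is available only as the flagged `convention = "paper_eq8"` and
  disagrees with the default for generic parameters — the discrepancy is
  reported in the result, never hidden.
* **Stress–strength.**  For two components sharing $\theta$ and $I$,
  $R = P(X_2 < X_1) = \lambda_1/(\lambda_1+\lambda_2)$: the common scale
  $(1+I)^{-1}$ cancels inside the probability.  A circulated variant with a
  $(1+I)$ prefactor is rejected because it permits $R > 1$.
* **Order statistics.**  Built from the standard construction
  $f_{(j)} = \frac{n!}{(j-1)!(n-j)!}F^{j-1}(1-F)^{n-j}f$ (implemented via
  `dbeta(F(x), j, n-j+1) * f(x)` for numerical stability).  The circulated
  finite-sum form carries an underived $(1+I)^{j+k}$ prefactor; it
  coincides with the standard construction at $I=0$ (verified in tests)
  and is available as `variant = "paper"`.
* **Rényi entropy.**  The numeric method,
  $(1-\varepsilon)^{-1}\log\int f^\varepsilon$, by quadrature, is
  authoritative; the circulated beta-function expression disagrees with
  direct integration even at $I=0$ (by $\approx 1.2$ nats at
  $\varepsilon=2,\lambda=2,\theta=3$) and is exposed only as
  `method = "paper"`.
* **Score equations.**  The circulated derivative expressions contain a
  dimensionally inconsistent $-\sum x_i$ term; the package never uses
  them.  Optimization is derivative-free on $-\sum\log f$.

## Hazard shapes

Because the right tail is heavy ($S(x)\sim \lambda[(1+I)x]^{-\theta}$), the
hazard behaves like $\theta/x$ for large $x$ and therefore *always*
decreases eventually.  The attainable shapes are (i) globally decreasing
and (ii) rise-then-fall (upside-down bathtub).  A sustained "bathtub"
upturn does not exist in this family; claims of one come from reading a
finite plotting window.  Tests pin both regimes: strictly decreasing at
$(\lambda,\theta)=(0.5,0.9)$, non-monotone at $(0.5,2)$.

## Estimation

* **Likelihood.**  $-\sum_i \log f(x_i;\lambda,\theta,I)$ through the
  log-density, stable for extreme $\theta$ (the inner
  $\log(1+u)$ with $u = [(1+I)x]^{-\theta}$ is computed as
  `log1p(exp(t))` with a large-$t$ branch).
* **Endpoint-fitting convention.**  The lower-endpoint result is the
  classical Burr-III ML fit to the lower-endpoint values; the upper-endpoint
  result is the classical fit to the upper-endpoint values, *without* an
  extra Jacobian.  This is the only convention whose AIC gap between the
  two endpoints matches the reference analysis of the bundled mortality
  data, and it treats the upper values as what they are declared to be:
  the data in interval form.
* **Optimizer.**  Multi-start Nelder–Mead with a BFGS polish, on
  log-parameters (positivity for free, better conditioning).  Starts: a
  fixed 4×4 log-grid plus model-specific heuristics — quantile matching
  for Burr-III (given $\theta_0$, $\lambda_0$ solves $F(\text{median}) =
  1/2$), profile-MLE starts for Weibull ($\hat a(b) = n/\sum x^b$) and
  Burr-XII ($\hat\kappa(c) = n/\sum\log(1+x^c)$).  The simulation harness
  uses the heuristic starts only (`starts = "light"`).
* **Standard errors.**  Square roots of the diagonal of the inverse
  observed information, from a central-difference Hessian of the negative
  log-likelihood at the MLE in *natural* parameters, steps scaled to
  parameter magnitude.  A non-positive-definite Hessian yields `NA` SEs
  with a warning — which genuinely happens for Burr-XII and
  Nadarajah–Haghighi on the bundled mortality data, whose likelihoods are
  flat ridges with suprema at a parameter boundary ($c\to\infty$ with
  $\kappa c$ fixed for Burr-XII; $\alpha\to\infty$ for NH).  We report the
  ridge honestly rather than stopping early to manufacture an interior
  "optimum"; consequences for the acceptance targets are discussed in the
  project notes.
* **Model selection.**  $AIC = 2k-2\ell$, $CAIC = AIC +
  \frac{2k(k+1)}{n-k-1}$, $BIC = k\ln n - 2\ell$, $HQIC = 2k\ln(\ln n) -
  2\ell$.  These exact identities are audited on every emitted row; they
  reproduce all four reference information criteria of the bundled
  mortality analysis from the single value $\ell = -80.3604$.

## The bundled data

`covid_nl` (30 daily mortality rates, Netherlands, 31 Mar–30 Apr 2020) is
stored with its published upper endpoints verbatim (5 decimals).  One lower
value is corrected from a misprint: the printed pair (10.056, 11.18880) is
internally impossible since $10.056 \times 1.05 = 10.5588$, while $10.656
\times 1.05 = 11.18880$ exactly; the fitted information criteria confirm
10.656 was the value actually analyzed.  The correction travels on the
dataset's `corrections` attribute.  `relief` ships exactly the 14 printed
relief times (of a described 20) and carries an `incomplete` flag — the
package never silently substitutes the similar 20-value dataset from the
literature, and no acceptance claim rests on it.

## The simulation harness and what a green test establishes

`run_simulation()` emulates the reference Monte-Carlo design: for each
sample size $n \in \{30, 50, 100, 200, 300\}$ and each indeterminacy
endpoint, draw samples by inverse transform, refit by ML at the same fixed
$I$, and report $AE = \sum\hat v_i/N$, $Bias = AE - v$,
$MSE = \sum(\hat v_i - v)^2/N$.  Replicates default to 500 for desk-scale
runs (the reference design uses 5000; pass `reps = 5000` to match).
Per-replicate seeds come from a counter-based stream, so any cell is
independently reproducible and identical designs give bit-identical
summaries.  Failed or non-converged fits are excluded and counted in an
explicit `n_fail` column (the reference design is silent on failures).

The generator draws i.i.d. variates from the model itself.  A green
consistency test therefore establishes that the estimator pipeline is
correct and consistent *under the stated model* — it says nothing about
robustness to contamination, dependence, rounding, or misspecification,
all of which real mortality data exhibit.  Published replicate-level MSE
tables for this family (values hovering near 150–190 at every $n$) are
inconsistent with estimator consistency and could not be regenerated under
any procedure we tried; the harness reproduces the *design*, and our own
runs show bias and MSE decreasing in $n$ as theory requires.

## Numerical choices

* Quadrature: adaptive on $(0,\infty)$ after $t = x/(1+x)$; absolute
  tolerance $10^{-10}$, relative $10^{-8}$.  Dual-route checks use
  `integrate`'s own infinite-range transform as the second, independent
  scheme.
* Divergent moments return an explicit "does not exist" signal
  (`exists = FALSE`), never `NaN`, keyed to the $r < \theta$ (positive) and
  $\lambda > r/\theta$ (negative) conditions.
* Hazard at survival underflow returns `Inf` with an explicit warning
  rather than `NaN`, keeping plotting and fitting robust.
* Ties in model ranking are broken by BIC, then model name.

## Known limitations

* No censoring, truncation, or covariates; two-parameter models only.
* Per-endpoint analysis only — no interval-arithmetic propagation or joint
  likelihood across endpoints.
* Comparator likelihoods (Burr-XII, NH) can be boundary-suprema on heavy
  tailed data; the package reports the ridge rather than an interior
  pseudo-optimum, so its comparator AICs can be *lower* than reference
  values obtained from prematurely stopped optimizers.
* The moment existence conditions make low-$\theta$ parameter corners
  (e.g. $\theta < 1$) unusable for moment-based summaries; the property
  table returns `NA` there by design.
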