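---
title: "Stacked genomic selection: models, evaluation, and design notes"
author: "stackGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked genomic selection: models, evaluation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackGS)
```

# The model layer

All base models share the marker-wise linear model
$y_i = \mu + \sum_j Z_{ij}\beta_j + e_i$ with genotypes coded $-1/0/1$ for
aa/Aa/AA and $e_i \sim N(0, \sigma_e^2)$. With $p \gg n$ the likelihood alone
does not identify $\beta$; each model adds a different regularizer.

**rrBLUP and GBLUP.** rrBLUP treats all marker effects as
$u \sim N(0, \sigma_u^2 I)$ and estimates the variance ratio
$\lambda = \sigma_e^2/\sigma_u^2$ by restricted maximum likelihood. GBLUP
works on genetic values $m = Zu$ with covariance proportional to the genomic
relationship matrix $G = kZ_cZ_c'$. We use VanRaden scaling: columns centered
by $2p_j - 1$ (allele frequency $p_j$) and $k = 1/(2\sum_j p_j(1-p_j))$. With
the same centering and scaling on the rrBLUP design the two models are the
same model viewed in marker space versus sample space, and the package
exploits this: `fitRRBLUP` defaults to GRM scaling, making
rrBLUP$\equiv$GBLUP a checkable identity (tested to $10^{-6}$) rather than an
approximation. REML is a one-dimensional profile likelihood over
$\log\lambda$ on the spectral decomposition of the kernel restricted to the
complement of the intercept: `optimize` over $\lambda \in [10^{-5}, 10^5]$
with tolerance $10^{-8}$, with a coarse grid fallback if the profile is flat.
A constant phenotype (zero restricted sum of squares) short-circuits to
zero-variance components and mean prediction. Negative kernel eigenvalues
from numerical noise are floored at zero; $\lambda > 0$ keeps the inversion
well posed.

**The Bayesian alphabet.** BayesA/B/C/L differ in the marker-effect prior
(scaled-t; point mass + t; point mass + Gaussian; Laplace). All four are
fitted by a single-site Gibbs sampler written in compiled code, using R's
RNG so a seed makes fits bit-reproducible. Updates are the standard
conjugate ones: per-marker (or common) variances from scaled-inverse-
chi-square full conditionals, inclusion indicators drawn from the marginal
likelihood with the effect integrated out, $\pi \sim$ Beta posterior
(Beta(2,2) prior, initial value 0.5), the Laplace prior via its
exponential-mixture representation with inverse-Gaussian updates for
$1/\tau_j^2$ and a Gamma update (shape 1.1) for $\lambda^2$, and a Gamma
hyper-prior update for the BayesA/B scale $S_\beta$ (freezable via
`updateSbeta`). Chain defaults are 1500 iterations, 500 burn-in, thinning 5,
all configurable; the repeated-trial study in the test-suite and the
acceptance script uses 600/200 chains, which we found sufficient for
posterior-mean prediction at the problem sizes used there (n of a few
hundred, p of several hundred).

Hyper-parameter scales follow the variance-partition rule: a fraction $R^2$
(default 0.5, tunable by 5-fold CV over a grid via `tuneR2`, ties toward the
smaller value) of the phenotypic variance is assigned to markers. The
residual prior scale is set so its mode is $(1-R^2)\mathrm{Var}(y)$, and the
marker scale so the implied genetic variance
$\sum_j \mathrm{Var}(Z_j)\,E[\beta^2]$ matches $R^2\mathrm{Var}(y)$, with
$E[\beta^2]$ divided by $\pi$ for the variable-selection models.

**Sampler correctness.** Two conjugate reductions pin the samplers to closed
forms: a single-marker model with fixed variances (analytic normal
posterior) and BayesC with $\pi = 1$ and fixed variances (ridge regression).
Both are asserted within 3 Monte-Carlo standard errors, with autocorrelation-
adjusted effective sample sizes.

**RKHS comparator.** A Gaussian kernel
$K_{ij} = \exp(-h\, d^2_{ij}/\bar{d^2})$ on squared Euclidean genotype
distances (scaled by their off-diagonal mean, bandwidth default 1) is run
through the same REML machinery with $K$ in place of the GRM. It is the
nonlinear comparator: it can exploit genotype-class structure that the
marker-linear models cannot.

# The stack

Stacking proceeds in three steps. (1) Folds: a seeded random partition of
the training set into $k$ near-equal folds (default $k = 5$). (2) Features:
each base model is fitted $k$ times on $k-1$ folds and predicts the held-out
fold, giving exactly one out-of-fold prediction per training sample per
model ($k \times s$ fits — the dominant cost, about 30 base-fits for six
models at $k=5$); separately each base model is refitted once on the full
training set and predicts the test samples. (3) Meta-model: a perceptron
with one hidden layer is trained on the out-of-fold feature matrix against
the training phenotypes and applied to the test feature matrix.

The outer 80/20 train/test split belongs to the experiment runner, not to
`runStacking`, which takes an explicit split — this keeps the stacking
function pure and the leakage surface auditable (a test mutating the test
genotypes asserts the meta training inputs are unchanged).

The meta-model is a minimal self-contained network: sigmoid hidden layer
(width $2s$ by default, at least $s$ enforced), linear output, MSE loss,
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, learning
rate 0.001), mini-batches of $\min(50, n)$, 400 epochs, seeded shuffling
and Xavier initialization, so training is exactly reproducible. Base-model
predictions already live on the standardized-phenotype scale, so inputs are
not re-standardized. Within the regime the defaults target, the meta-model
converges to (slightly better than) the best linear combination of its
inputs; we verified the training loss is indistinguishable from the
least-squares loss of a linear fit on the same features.

The bagging comparator trains the same base models on seeded bootstrap
resamples (plain full-data averaging with `bootstrap = FALSE`) and averages
their test predictions with equal weights.

# Evaluation

Phenotypes are standardized per trait with training-split statistics before
any fit, so MSEs are comparable across traits and an MSE of 1 equals
mean-prediction. Errors are absolute differences $|y_i - \hat y_i|$; the
signless variant exists behind a flag but makes the power and margin algebra
degenerate (signed errors have mean near zero for any unbiased predictor),
so absolute errors are the working convention.

**Power and margin.** At a predetermined sample size $N$ the achievable
power of the two-sample comparison is
$1-\beta = \Phi\!\big(|\bar e_b - \bar e_s|\sqrt{N/(S_b^2+S_s^2)} -
Z_{\alpha/2}\big)$, and the non-inferiority margin at target power is
$\Delta = \bar e_b - \bar e_s + \sqrt{(S_b^2+S_s^2)/N}\,(Z_{\alpha/2} +
Z_{1-\beta})$, clipped to the (always positive) variability term if the mean
difference drags it non-positive. Margin and sample-size relations are exact
algebraic inverses, asserted to $10^{-9}$. Defaults $\alpha = 0.05$, target
power 0.8.

**Signed-rank testing.** The test statistic is the signed-rank sum
$T = \sum_i \mathrm{sign}(X_i) R_i$ on shifted differences $X_i = e_{b,i} -
e_{s,i} - \Delta$; zeros dropped, tied ranks averaged; exact null
distribution for $n \le 25$ without ties, normal approximation with
continuity and tie corrections otherwise; the confidence interval is the
Hodges-Lehmann pseudomedian interval from the Walsh averages of the
unshifted differences. p-values are validated against full $2^n$ enumeration
and, together with the interval, against `stats::wilcox.test`.

**Outcomes.** From the interval on $e_b - e_s$: SUPERIOR if $LB > 0$;
otherwise the default rule (`rule = "rejection"`) declares EQUIVALENT
exactly when the non-inferiority null is rejected, $LB > -\Delta$, and
INFERIOR when it is not — the convention of the non-inferiority testing
literature, where inferiority means failure to establish non-inferiority.
An alternative rule (`"ciBounds"`) additionally requires $UB > 0$ for
equivalence, so an interval entirely inside $(-\Delta, 0]$ — a
statistically significant but within-margin deficit — is branded INFERIOR.
The two rules differ only in that cell. We default to the rejection rule
because the conjunctive rule interacts badly with stacking specifically:
a stack's predictions are almost perfectly correlated with its best base
model, so a deficit of a fraction of a percent, far inside any margin,
can be "significant" and would be labelled INFERIOR even though the
non-inferiority test it is meant to summarize was passed. Both rules are
exhaustive and mutually exclusive for $LB \le UB$, $\Delta > 0$.

**Pairing unit.** Two units are offered for the test, and the choice
matters. `testUnit = "trialMSE"` (default) performs one test per comparator,
pairing the per-trial test MSEs across the repeated trials; the margin is
computed from the per-sample absolute errors pooled over trials with $N$
fixed at the dataset's (predetermined) sample size. `testUnit =
"sampleErrors"` tests per trial on the per-sample paired errors. The default
reflects what the repeated-trial design actually produces as its sampling
distribution — a set of per-trial MSEs (the accompanying normality check is
likewise run on MSEs). The per-sample unit is kept for completeness but
deserves a warning: predictions of a stack and its own base models are
extremely correlated, and a paired test on hundreds of near-identical pairs
will flag an arbitrarily small systematic deficit as significant, turning
practically irrelevant differences into INFERIOR verdicts.

**Normality check.** One-sample Kolmogorov-Smirnov against a normal with the
sample's own mean and SD. Plugging in estimated parameters makes the test
conservative (its rejection rate sits below the nominal level); a
parametric-bootstrap (Lilliefors-style) correction is available by flag.

**Linearity diagnostic.** For each of a handful of randomly selected
markers, the mean standardized phenotype is computed within each genotype
class and a line of class mean versus genotype code is fitted *per marker*;
the residual sums of squares are summed. A line through three class means
has one residual degree of freedom, so the statistic isolates exactly the
heterozygote's displacement off the additive line. Fitting one pooled line
across markers instead would confound dominance with between-marker slope
heterogeneity and has essentially no power when marker effects vary in sign
— which is why the per-marker form is used.

# The simulator

`simConfig` fixes the study conditions. Genotype classes are drawn i.i.d.
per entry from one of three frequency profiles observed in real panels —
TWO_HOMOZYGOUS (0.80/0.01/0.19), HOM_HET (0.78/0.20/0.02), THREE_CLASS
(0.45/0.36/0.19, the default) — or explicit frequencies. Marker effects come
from the same families the Bayesian models assume (Gaussian, scaled-t,
Laplace, point-mass mixture). The phenotype is $g_i + e_i$ with
$g_i = \sum_j f(Z_{ij})\beta_j$; $f$ is the identity for an additive trait,
and `dominanceCoeff` $= d$ maps the heterozygote code 0 to $d$, displacing
its class mean off the additive line ($d = 1$ is complete dominance,
$d > 1$ overdominance). Noise variance is set from the *realized* genetic
variance, $\mathrm{Var}(g)(1-h^2)/h^2$, so the target heritability holds per
dataset rather than only in expectation — this stabilizes small-n tests.

What the simulator deliberately omits: linkage disequilibrium, population
structure, pedigrees, and multi-trait correlations. The base models are
marker-wise linear and never use marker positions, so i.i.d. markers test
everything those models can express; but it means passing tests say nothing
about confounding by structure or LD-driven effect smearing in real panels.

Problem sizes in the repeated-trial checks ($n = 300$, $p = 600$, $h^2 =
0.5$, 10 trials, three base models with 600/200 Gibbs chains) were chosen as
the smallest configuration in which the base models clearly beat mean
prediction and the evaluation statistics are stable across seeds. The
dominance-contrast checks (linearity RSS; RKHS versus rrBLUP) use an
oligogenic, high-heritability trait ($p = 20$–$40$ markers, $h^2 = 0.9$,
$d = 1.5$–$3$): per-marker class means are only resolvable above their
sampling noise when individual effects are non-negligible, and the
diagnostic is meant for exactly that regime — a polygenic trait with
thousands of tiny effects leaves nothing for a class-mean diagnostic (or a
kernel method) to see at any realistic sample size.

# Degenerate inputs and numerical choices

Monomorphic-only panels make the GRM scale constant undefined (error);
individual monomorphic markers simply contribute nothing. Constant
phenotypes are an error for standardization and hyper-parameter defaults
(zero variance has no variance to partition), but the REML path handles
them gracefully. Zero shifted differences abort the signed-rank test; zero
pooled variance aborts the power computation. Bootstrap resamples get
uniquified sample ids so the container invariants (unique ids) hold. The
non-inferiority margin's $\Delta > 0$ restriction is enforced by clipping
with a warning, defaulting to the variability term.

# Known limitations

The marker-effect view of GBLUP is only exposed through rrBLUP's matched
scaling; GBLUP itself stores no effects (by design). The Gibbs samplers
update markers in column order, so their draws are order-invariant only in
distribution — deterministic fits are asserted order-invariant to
$10^{-10}$, Bayesian fits are not. The meta-model is deliberately minimal:
no early stopping, dropout, or architecture search. Multiple-testing
correction is not applied to the per-comparator outcomes; proportions of
outcomes are reported as-is. Indirect marker-effect estimation for the stack
(e.g. weighted averages of base-model effects) is out of scope.
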