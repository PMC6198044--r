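---
title: "Quantitative-genetic models for disease resistance across selection and challenging environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-genetic models for disease resistance across selection and challenging environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuniqg)
```

## The problem

Maternal rabbit lines are selected on a highly bio-secure nucleus farm (the
*selection* environment, S) while most of their commercial descendants are
raised under harsher sanitary conditions. To select for resistance to
non-specific disease, binary health records (0 = no clinical sign, 1 =
morbidity or mortality) are taken once per animal at the end of the growing
test, both on the nucleus and on sib-testing farms with deliberately low
biosecurity (the *challenging* environment, Ch). The same disease trait
recorded in the two environments is treated as two traits; a genetic
correlation below one between them is genotype-by-environment interaction.
`cuniqg` implements the full analysis chain for this design: pedigree
machinery, a synthetic-data generator that emulates the recording scheme,
REML estimation for linear and threshold animal models, the derived genetic
parameters with sampling-based standard errors, breeding-objective algebra,
and a deterministic pseudo-BLUP prediction of selection response for
alternative breeding schemes.

## Models

### Threshold (liability) models for binary disease traits

Each binary disease trait is modelled on a latent liability
$\ell = \mathbf{x}'\boldsymbol\beta + a + c + e$, where $a$ is the animal's
additive genetic value ($\sigma^2_a$, covariance structure
$\mathbf{A}\sigma^2_a$ from the pedigree), $c$ a common rearing-litter
effect ($\sigma^2_c$), and $e$ a standard logistic residual (logit link);
the record is 1 when $\ell > 0$. Under this convention the residual
variance is fixed at $\pi^2/3$ and the liability-scale phenotypic variance
is
$$\sigma^2_p = \sigma^2_a + \sigma^2_c + \pi^2/3,$$
so that $h^2 = \sigma^2_a/\sigma^2_p$ and $c^2 = \sigma^2_c/\sigma^2_p$.
This reconstruction reproduces the reference parameter table of the rabbit
case study to its printed rounding, which is why it is adopted as the scale
convention throughout.

`fit_threshold_trait()` fits this model by penalized quasi-likelihood
(PQL): the Bernoulli response is linearized to a working variable with
weights $\mu(1-\mu)$ and the variance components are re-estimated by REML
on the working model (residual dispersion fixed at 1) until the joint fit
stabilizes. PQL is the same family of approximation used by the standard
threshold-model software in animal breeding. Its known limitation matters
here and is stated openly: with unit-level binary data the variance
components are biased downward (in our recovery experiments at ~6,000 kits
with a true liability $h^2$ of 0.08, the mean estimate is about 0.05, i.e.
inside the $\pm 0.04$ recovery tolerance but clearly below the truth).
Ratios are less affected than raw components because the denominator is
dominated by the fixed $\pi^2/3$. Users comparing absolute variance
components across software should expect this behaviour.

### Linear multi-trait animal models

Production traits and all between-trait correlations use Gaussian animal
models. The REML engine (`reml_fit()`) evaluates the restricted
log-likelihood exactly through sparse mixed-model equations — one sparse
Cholesky factorization per evaluation gives $\log|\mathbf{C}|$,
$\mathbf{y}'\mathbf{P}\mathbf{y}$ and the solutions — and maximizes it over
a log-Cholesky parameterization of the per-term covariance matrices
(Nelder–Mead, then a BFGS polish and coordinate-wise Brent refinement;
one-parameter problems use Brent directly). This derivative-free design was
chosen over average-information updates because every quantity it needs is
available from a single sparse factorization, boundary cases (variances at
zero) degrade gracefully, and the acceptance route for the engine is oracle
equivalence: on balanced designs it reproduces the closed-form ANOVA
estimator to $10^{-6}$ and it matches an independent REML implementation on
identity-structure cases to the same precision.

Supported random terms: direct additive (`animal`), maternal additive
(`maternal_genetic`, correlated with the direct effect through a joint
$2\times 2$ covariance over $\mathbf{A}$), common litter, maternal
environment, and doe permanent environment for repeated litter-size
records. Cross-fostered kits (4% of the population in the reference
design) carry their maternal genetic, maternal environmental and litter
effects on the *adoptive* dam, while the additive effect follows the
biological pedigree; fostering therefore changes incidence matrices only,
never relationships.

For traits recorded on disjoint sets of animals — the same disease trait in
S and Ch — the residual covariance is structurally unidentifiable and the
engine constrains it to zero exactly; the genetic covariance across
environments remains free, which is what makes the cross-environment
genetic correlation estimable through the pedigree.

The sampling covariance of the variance components is the inverse of the
numerical observed information at the optimum (central finite differences
on the natural scale). Sampling-based standard errors of ratios
(`sample_parameter_se()`) draw 10,000 multivariate-Gaussian parameter
vectors at the optimum, reject draws with negative variances (so every
draw yields a defined ratio), re-evaluate the ratio per draw and report the
standard deviation of the draws; a skewness/kurtosis omnibus test of the
draw distribution is reported but never gates the result. The
small-covariance limit of this procedure is the first-order delta method,
which the test suite verifies.

### Boundary tests and environment comparisons

Likelihood-ratio tests of a variance equal to zero or a correlation equal
to one are boundary tests; `mixture_lrt_pvalue()` implements the 50:50
mixture of $\chi^2_q$ and $\chi^2_{q+1}$ reference distribution, with $q$
the number of random effects in the reduced model (residual excluded) and
$\chi^2_0$ a point mass at zero. Heritabilities from the two environments
are compared with a two-sided Student's t on the sampled SEs
(`compare_h2()`); the degrees of freedom use a conservative
Welch–Satterthwaite combination based on the draw counts, a convention this
package documents because the reference analysis does not state one.

## The synthetic-data generator

No breeding records of this kind are public, so the generator
(`simulate_population()`) is a first-class module whose defaults *are* the
study design being emulated: 332 sires and 849 dams (does themselves in
paternal half-sib families), four parities of seven kits (≈23,800 growing
rabbits), 29 weaning batches with every second batch sent to the
challenging environment — all males plus just enough females to make the Ch
group 97% male — three Ch farms, 4% cross-fostering, disease prevalence
targets of 26% (S) and 41% (Ch) for composite resistance, and the reference
variance components for all traits. Liability intercepts are solved by
quadrature (`expected_prevalence()`, `solve_liability_intercept()`) so that
the configured marginal prevalences are hit in expectation given all
Gaussian terms and the sex composition of each environment.

The composite resistance trait is generated as the logical OR of the
digestive, respiratory and an "other-disorder" latent trait; the
other-disorder prevalence is calibrated under liability independence so the
composite hits its target. Fixed-effect scales (batch SD 0.3 on the
liability, 30 g for weaning weight, and so on) are single choices of
realistic magnitude, not estimates. What the generator does *not* emulate:
infection dynamics between cage mates (disease events are conditionally
independent given the random effects), longitudinal disease courses,
non-genetic maternal-permanent covariances, and selection within the
simulated generations. Passing recovery tests therefore demonstrate
statistical correctness of the estimators under the assumed model, not
robustness to epidemic clustering in real barns.

## Breeding objectives and selection response

A breeding objective is $H = \mathbf{w}'\mathbf{A}$ over the goal traits
(NBA in kits, direct and maternal weaning weight in g, Resist in S and Ch
in percentage points, with negative disease weights). Covariances and
correlations between objectives are the printed bilinear forms
$\mathrm{Cov}(H_i,H_j) = \mathbf{w}_i'\,\mathrm{Var}(\mathbf{A})\,
\mathbf{w}_j$. The linear-scale genetic variances of the Resist traits are
not estimable from liability fits alone; the defaults convert the liability
ratios through the standard threshold-model transformation
$h^2_{obs} = h^2 \, z^2/(pq)$ at the configured prevalence and are
documented configuration inputs, not estimates — objective-correlation and
disease-response values therefore depend on this configuration.

`predict_response()` is a deterministic pseudo-BLUP predictor for
single-stage truncation selection in a closed nucleus (35 sires, 140 dams,
7 kits per litter, 15%/25% selected) with discrete generations. Per
candidate the index combines: own records (weaning weight; Resist_S when
recorded), the full-sib and paternal-half-sib group means in each
environment (when Ch is recorded, a quarter of the sibs is tested there
and carries Resist_Ch records; weaning weight is recorded on every sib at
weaning, before allocation), and optionally the dam's repeated litter-size
records and the parents' own index values. Index weights are
$\mathbf{b} = \mathbf{P}^{-1}\mathbf{C}\mathbf{v}$; responses are
$R_j = \bar{i}\,\mathrm{Cov}(I, g_j)/\sigma_I$ averaged over the two
selection paths, with Burrows' finite-candidate correction of the
intensities (candidate numbers $n_{selected}/p$ per path; an optional mean
index correlation among candidates further discounts the effective
candidate number). All record covariances are assembled from a template
family pedigree through the package's own relationship machinery, including
the maternal-effect loadings of weaning-weight records and the
within-versus-between-litter structure of the half-sib group means.

Two recursions run jointly to a fixed point: the Bulmer update of the
genetic covariance matrix,
$\mathbf{G}' = \tfrac12\mathbf{G} - \tfrac{k_m+k_f}{4}
\frac{\mathbf{c}\mathbf{c}'}{\sigma_I^2} + \tfrac12\mathbf{G}_0$
with $\mathbf{c} = \mathrm{Cov}(\mathbf{y}, I)$-projected genetic
covariances, and the parental-index information, whose moments are carried
over from the previous iteration with the exact truncation identities
$\mathrm{Var}^*(I) = (1-k)\sigma^2_I$ and
$\mathrm{Cov}^*(I, Z) = (1-k)\,\mathrm{Cov}(I, Z)$. At equilibrium the
parent generation and the candidate generation have the same index, which
is what "pseudo-BLUP" means here; the recursion is truncated at one
ancestral generation (grandparental indexes enter only through the
parents'), a documented approximation.

Two structural choices deserve emphasis. First, candidates are selected at
70 days and have no litter-size phenotype; the default carries *no* NBA
information in the index at all (`use_dam_nba = FALSE`). This was decided
once, on reproduction evidence: with dam litter-size records included the
predicted correlated NBA response under the production-only objective is
positive (+0.03 to +0.12 kits per generation depending on the record
count), while the reference predictions and the no-NBA-information
configuration agree closely (−0.117 vs −0.118 kits; weaning-weight direct
response 35.4 vs 35.0 g). The dam-record source remains implemented and
switchable. Second, the direct–maternal genetic correlation of weaning
weight defaults to −0.71: the reported phenotypic variance of weaning
weight equals the sum of its components only when the direct–maternal
covariance enters negatively, and only a negative correlation produces the
uniformly negative maternal-weight responses alongside positive direct
responses that the reference predictions show.

## Numerical choices and degenerate inputs

* Convergence: REML stops when neither a Nelder-Mead/BFGS step nor a
  coordinate-wise Brent sweep improves the criterion by more than
  $10^{-8}$; variance floors of $10^{-7}\times\mathrm{var}(y)$ flag
  boundary estimates. A constant response vector short-circuits to an
  all-boundary fit rather than chasing an unbounded likelihood.
* The equilibrium iteration of the response predictor declares the index
  degenerate when $\sigma^2_I \le 10^{-12}\max(1, \mathbf{v}'\mathbf{G}_0
  \mathbf{v})$ and returns zero responses; a numerically singular
  information matrix falls back to a relative ridge of $10^{-10}$ before
  raising an error that names the offending sources.
* The desired-gains search (`desired_gains_search()`) is damped
  Gauss-Newton on the targeted weights, accepting only improving steps; it
  renormalizes the weight vector (responses are invariant to its scale) and
  returns best-effort with a warning when the targets are insensitive to
  the weights.
* Problem sizes in the test suite were chosen so the statistical claims are
  sharp at desk scale: 20 replicates of 140 does × 5 parities for the
  litter-size recovery, 10 replicates of ~6,000 kits for the threshold
  recovery, 200-animal pedigrees for the dense-inverse oracle, 50,000
  animals for the stochastic mass-selection oracle.

## Known limitations

PQL's downward bias for unit-level binary variance components (above);
no genetic groups or genomic relationships; no inbreeding accumulation in
the response predictor (relationships use base coefficients with
equilibrium variances); no epidemiological feedback of selection on
pathogen exposure — predicted disease responses assume a constant exposure
level; and the linear-scale Resist variance configuration propagates to all
disease-response and objective-correlation outputs, which should be read as
conditional on it.
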