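---
title: "Estimating youth mortality trends from imperfect data: the youthmort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating youth mortality trends from imperfect data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(youthmort)
```

## The estimation problem

The probability that a 15-year-old dies before their 25th birthday, written
$_{10}q_{15}$, is poorly measured in most of the world. Where complete vital
registration (VR) exists, annual death counts over population denominators
give $_{10}q_{15}$ almost directly. Elsewhere the evidence is a patchwork:
VR systems that register only a fraction of deaths, sibling survival
histories collected in household surveys, census questions on household
deaths in the past 12 months, and sample registration systems (SRS). Each
source carries its own error structure — under-registration, recall bias
that worsens with the length of the retrospective window, underreporting of
recent household deaths — and each country mixes these sources differently.

`youthmort` reconstructs country trajectories of $_{10}q_{15}$ from such a
mixture, splits the result into the 15–19 ($_5q_{15}$) and 20–24
($_5q_{20}$) bands, converts probabilities to death counts via populations,
and aggregates to regions and the world with draw-based 90% uncertainty
intervals (UIs). Because the real multi-source database is an external
compilation, the package ships a synthetic-world generator with known
ground truth; every stage is tested against that truth.

## Life-table identities

All internal probabilities are per 1 (per-1000 only at the reporting
layer). Adjacent bands compose through survival:
$_{10}q_{15} = 1-(1-{}_5q_{15})(1-{}_5q_{20})$, and the central death rate
over a band of width $n$ is $m = q/(n - q(n-a))$, where $a$ is the average
time lived in the band by those dying in it. The separation factor defaults
to $a = n/2$ (deaths uniform within the band): youth survivorship is close
to linear, and the identity pair `q_to_m()` / `m_to_q()` is exact for any
$a$, so downstream conversions round-trip to machine precision. The annual
rate of reduction between years $t_1<t_2$ is
$100\,\log(q_1/q_2)/(t_2-t_1)$. Reported tables round half-away-from-zero
(`report_round()`), which reproduces printed-table arithmetic such as
$-0.55 \to -0.6$; base R's round-half-even does not.

## The synthetic world

`simulate_world()` generates the study conditions. Each country's log
$_{10}q_{15}$ path is a regional intercept (mean $\log(0.0154)$, SD 0.35)
plus a country intercept (SD 0.30), a linear slope (mean $-1.4\%$/year,
regional SD 0.006, country SD 0.005), and a smooth deviation — an
integrated random walk (innovation SD 0.003/year), centred and detrended so
it carries curvature only. These values put the world median near 11 per
1000 in 2019 declining from about 17 per 1000 in 1990, the order of
magnitude of observed global youth mortality. Under-5 mortality is linked
to youth mortality through a log-quadratic relation with country-level
noise (SD 0.13), so the quality screen's reference relation exists
in-world. The $_5q_{15}$ share of $_{10}q_{15}$ starts near 0.46 and
drifts slowly downward, within (0.2, 0.8).

Observation processes:

* **VR**: true deaths are binomial in the annual hazard implied by the band
  probability; registered deaths are a second binomial thinning by the
  completeness $c$; the sampling SE of $\log q$ comes from the registered
  count. Trajectories start in 1985 so the spline has data before the 1990
  reporting window; VR series end in 2017, leaving a short extrapolation to
  2019 as in real compilations.
* **Sibling surveys**: one observation per 5-year recall window over a
  15-year horizon (common survey practice; three windows per survey). On
  the log scale each observation is truth at the window midpoint plus a
  survey-level bias $b_0$ (SD 0.1), a recall-bias slope $b_1$ times the
  retrospective lag (mean $-0.02$/year, SD 0.01), and noise. The effective
  sample size per window (default 6000 sibling exposures, design effect
  1.5) yields SEs of roughly 0.13 on the log scale — order-of-magnitude
  values for survey sibling estimates; the true distribution of effective
  sizes is not documented anywhere, so these are declared defaults.
  Surveys also emit paired under-5 observations from birth histories.
* **Censuses**: household deaths in the past 12 months, thinned by an
  underreporting factor (default 0.85) for ages 15–24 only — leaving child
  deaths unthinned is what makes the age-pattern screen able to see the
  distortion.
* **Crises**: excess deaths in a crisis year compose onto the smooth path
  via the rate-to-probability conversion, with the event table as ground
  truth. The default world gives two countries one crisis year each, with
  excess deaths of 0.2% of band person-years (roughly tripling mortality
  in that year).

Twenty countries cycle through five source portfolios (complete VR;
incomplete VR + survey + census; surveys and censuses only; SRS; complete
VR ending 2010 plus recent surveys) across four regions. Everything is a
pure function of (parameters, seed).

What the generator does *not* emulate: individual-level sibling microdata
(age heaping, omission patterns — only their aggregate bias signature),
migration, HIV-type mortality humps with age structure within the band, or
correlated completeness between neighbouring countries. Passing tests
demonstrate internal consistency of the method under the stated error
model, not performance on any real database.

## Registration completeness (GGB)

For countries with incomplete VR, completeness is estimated by the
generalized growth balance method: in a closed population, for each open
age $x+$, entry rate minus growth rate equals the death rate; with a
fraction $c$ of deaths registered, points of (observed partial death rate,
entry minus growth rate) fall on a line of slope $1/c$. The line is fitted
by orthogonal (total least squares) regression — the standard in
death-distribution methods — over open ages 15+ through 65+ (11 points,
targeting adult ages while keeping at least 8 points). Estimates are
clipped to (0, 1.5]; VR series with $\hat c < 0.5$ are dropped from the
likelihood rather than rescued by a large adjustment, series with
$\hat c \ge 0.5$ have their rates divided by $\min(\hat c, 1)$, their SEs
inflated by a completeness-uncertainty term of 0.05 on the log scale, and
their source relabelled `vr_incomplete` when $\hat c < 0.95$. The
stable-population generator used to exercise the method integrates the
survival and age structure on a 0.05-year grid: coarser grids violate the
growth-balance identity by several percent and would be misread as
registration error. Census universes in the pipeline are sized to the
country's population, so Poisson noise in the GGB inputs scales as it
would in reality.

## The quality screen

Sibling and census series that understate youth mortality badly are
excluded before model fitting. A log-quadratic regression of
$\log {}_{10}q_{15}$ on $\log {}_5q_0$ and its square is fitted to a
reference set (synthetic here, generated with the in-world link; the fit
object is serializable so a real reference can be substituted). A series
is excluded when its pooled $_{10}q_{15}$ — inverse-variance weighted
across its observations on the log scale, because whole surveys rather
than single observations are implausible — falls below the lower 95%
prediction bound at its pooled $_5q_0$. The bound is predictive for the
*observed* pooled value: it includes the regression's residual variance
and leverage, the pooled sampling variance of both indices (the $_5q_0$
error propagated through the curve's local slope), and a 0.05 allowance
for non-sampling error of retrospective series. Without the measurement
terms the nominal one-sided rate of ~2.5% inflates several-fold. The rule
is one-sided by construction — implausibly *high* youth mortality is never
grounds for exclusion — and VR/SRS series are never screened.

## The trend model

For observation $i$ of country $c$, series $s$, at time $t_i$ with
retrospective lag $\ell_i$:

$$\log q_i = \sum_k \alpha_{c,k} B_k(t_i) + \delta_i\,(b_{0,s} + b_{1,s}\ell_i) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0,\; se_i^2 + \omega^2_{type(i)})$$

— each observed probability is the latent risk times a source-specific
error multiplier, additive on the log scale. $\delta_i = 1$ for sibling
and census sources and 0 for VR and SRS; censuses share the
retrospective-lag structure with a lag of 0.5 years from the 12-month
window midpoint. Biases are exchangeable across series,
$b_{0,s} \sim N(\mu_0, \tau_0^2)$, $b_{1,s} \sim N(\mu_1, \tau_1^2)$, so a
survey overlapping unbiased VR informs the bias of surveys in
survey-only countries.

The latent trend uses cubic B-splines on knots every 2.5 years (about one
coefficient per 2.5 years), extended past the data so projection years are
in-span. Second-order differences of the coefficients are shrunk towards
zero, $D_2\alpha_c \sim N(0, \lambda_c^2 I)$ — shrinkage towards a straight
line in log $q$ — with $\log \lambda_c \sim N(\mu_\lambda,
\sigma_\lambda^2)$ shared across countries, which is how countries exchange
information about plausible departures from log-linearity. Hyperpriors:
$\mu_0, \mu_1 \sim N(0, 0.5^2)$; $\tau_0, \tau_1, \sigma_\lambda$ and the
$\omega$'s half-normal(0, 0.5); $\mu_\lambda \sim N(-3, 1)$; the two
penalty-free level/slope components of $\alpha_c$ get a weak $N(\cdot,
2^2)$ prior centred on the country's weighted least-squares line (mapped to
coefficient space through the Greville abscissae, where linear functions
are exactly representable). $\omega$ is fixed at zero for complete VR.

Sampling is a seeded adaptive Metropolis-within-Gibbs scheme: conjugate
multivariate normal updates for $\alpha_c$ and each $(b_0, b_1)$ pair and
for the hierarchical means; log-scale random-walk Metropolis with Robbins–
Monro adaptation to 0.44 acceptance for the SDs. Conditional on the shared
hyperparameters the country blocks are independent, so the sampler scales
linearly in countries. Defaults: 4 chains × (500 warmup + 1000 retained);
split-$\hat R$ on log $q$ at 1990/2000/2019 is reported and fits with
$\hat R \ge 1.1$ are flagged, not silently accepted. The backend is
self-contained so tests need no external engine; the update structure is
pluggable if a different sampler is wanted.

Countries with fewer than 4 usable observations or under 10 years of
coverage are refused by the spline model and routed to the sparse-country
fallback. Crisis handling follows the exclusion-and-reinsertion design:
observations referring to crisis years leave the likelihood, the model
smooths through, and the known excess is composed back into every
posterior draw — an operation that shifts the log-survival scale and
leaves interval widths on that scale untouched.

## Age split, sparse countries, aggregation, validation

**Age split.** The ratio $r$ of $_5q_{15}$ to the median $_{10}q_{15}$ is
modelled on the logit scale by a penalized spline on the same basis
(second-difference penalty, generalized cross-validation over a bounded
grid — the original work states no selection rule). $r$ is applied to
*every* posterior draw: $_5q_{15} = r\,q$, $_5q_{20} =
1-(1-q)/(1-{}_5q_{15})$, so split uncertainty derives entirely from the
$_{10}q_{15}$ posterior and the composition identity holds draw by draw to
machine precision. Whether the original applies the ratio to draws or only
to medians is not documented; draws keep the three reported bands mutually
consistent, which we judged the stronger property. With two or fewer ratio
observations the fit falls back to a constant.

**Sparse countries.** A mixed-effects regression of $\log {}_{10}q_{15}$
on $\log$ U5MR with random intercepts and slopes by region (REML via
`lme4`; deterministic fixed-effects OLS fallback on singular fits) is
trained on the spline-model posterior medians at 5-year grid points of the
data-rich countries — medians rather than raw observations, mirroring the
use of modelled estimates as the cross-country pattern. Predictions emit
normal draws on the log scale in the same container as the spline model
(`q_posterior`), so downstream stages cannot tell the sources apart;
unseen regions get the full random-effect variance added. Residuals are
treated as independent across years — autocorrelation in the U5MR series
is a known limitation.

**Aggregation.** Deaths are $m \times$ person-years per draw and band;
regions sum member-country draws, the world sums the regions, so
conservation is exact per draw by construction (the summation tree matters:
floating-point addition is not associative). Regional band probabilities
come from pooled central rates, and regional $_{10}q_{15}$ composes the
band probabilities. Population counts carry no uncertainty. Point ARRs are
computed on posterior medians with the per-draw ARR distribution supplying
the interval (both conventions are available; tables print the former).

**Validation.** The out-of-sample design splits by *collection* date
(default cutoff 2013): a 2015 survey is wholly left out even where its
recall windows refer to the 2000s. Errors are observed minus predicted in
deaths per 1000; coverage uses the 90% predictive interval for a new
observation — the latent interval widened by the observation's sampling
variance and the posterior median source-type variance $\omega$ — and
"nominal" is operationalized as [0.85, 0.95], since no tolerance is stated
anywhere for it.

## Numerical and testing choices

Problem sizes in the test suite: the parameter-recovery checks pool three
independent 20-country worlds (1990–2019, ~1800 country-years) because
coverage events are strongly correlated within a country, leaving a single
world with only ~20 effectively independent units — too few to place a
[0.85, 0.95] band reliably. Growth-balance recovery uses 100 replicates at
each completeness in {0.4, 0.6, 0.8, 1.0}; the screen's size and power use
500 surveys from 500 distinct countries (distinct, again to avoid shared
country effects); the sparse model trains on 3000 pairs over 15 regions —
with few regions the fixed slope is dominated by region-level noise
regardless of the number of pairs. Unit tests run the sampler at 2 chains
× (250 + 350) draws; reported runs use the 4 × (500 + 1000) default.

Degenerate inputs are refused loudly: non-adjacent bands, $q$ outside
$[0,1)$, separation factors outside $(0,n)$, all-zero death tables,
collinear reference designs, empty training sets. Observation files must
store probabilities per 1; a per-1000 file fails validation rather than
being autodetected.

## Known limitations

Sex-specific estimation, cause-of-death composition, single-year age
detail, migration-adjusted completeness (GGB only; no SEG variant), and
real-database ingestion are out of scope. The error model is log-normal
throughout; gross outliers beyond what the screen removes are not
down-weighted robustly. The sparse-country fallback inherits whatever bias
the U5MR series carries. Coverage statements are properties of the
synthetic error model, not of any real compilation.
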