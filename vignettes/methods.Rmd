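---
title: "Methods: linking assemblage richness to climatic niche properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking assemblage richness to climatic niche properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the pipeline

`nichescape` tests three macroecological hypotheses that link the geography of
species richness to the climatic niches of the species that co-occur there:

* **niche breadth** — species-rich assemblages should be composed of species
  with *narrow* niches (niche packing);
* **niche marginality** — rich assemblages should hold species whose niche
  centroids sit *close to the average climate* of the study area;
* **phylogenetic niche position** — under niche conservatism, rich assemblages
  should hold species whose niches are *close to the reconstructed ancestral
  niche* of the clade.

The pipeline runs in nine stages: occurrence cleaning, PCA of the climate
space, ellipsoid niche models, constrained geographic ranges, a
presence-absence matrix (PAM), species-level niche properties, comparative
analysis on a phylogeny, simultaneous autoregressive (SAR) models of richness
on assemblage-mean properties, and two randomization null models. Each stage
is an exported function; `run_pipeline()` chains them under a single master
seed.

# Models and procedures

## Ellipsoid niche models

A species' niche is modelled as an ellipsoid in a standardized
principal-component climate space: centroid $\mu$, shape matrix $\Sigma$, and
squared coverage radius $c^2$, with a point inside iff its squared Mahalanobis
distance $(x-\mu)^\top\Sigma^{-1}(x-\mu) \le c^2$. `fit_mve()` seeks a
small-volume ellipsoid containing exactly $h = \lceil 0.95\,n \rceil$ of the
$n$ occurrence environments (a 5% omission design). Exhaustive search over
$h$-subsets is combinatorial, so we use a seeded multi-start concentration
heuristic: random $h$-subsets are refined by recomputing the subset mean and
covariance, reselecting the $h$ nearest points, and iterating to a fixed
point; every visited subset is scored and the minimum-volume result over all
starts (default 50, plus one deterministic start from the full-sample shape)
is returned. $c^2$ is set to the $h$-th smallest squared distance under the
final shape, which makes the exactly-$h$ coverage contract directly testable.
The tests verify the heuristic against exhaustive subset enumeration at
$n = 12$, and volume recovery within 10% for points uniform in a known
ellipse.

Ranges are the presence cells (inside-ellipsoid climate) whose centers fall
inside an accessible-area constraint: the minimum convex polygon of the
occurrences dilated by a buffer (planar dilation; arcs approximated at
5-degree steps). All geometry is planar, in km; real-data use assumes inputs
already projected to an equal-area frame.

## PCA of the climate space

Bioclim-style layers have incommensurate units, so layers are standardized
(correlation-matrix PCA) before decomposition; component signs are fixed so
the largest-magnitude loading is positive. Two consequences worth knowing:
with standardized inputs, a set of mutually uncorrelated layers has a
near-identity correlation matrix whose eigenvectors are arbitrary rotations,
and re-fitting a PCA on the (re-standardized) scores likewise pins only the
spanned subspace, not individual axes. The tests therefore check span- and
variance-level properties rather than individual eigenvectors in those
degenerate cases.

## Niche properties

For each modeled species the package computes, in the multivariate approach:
breadth `NB` (ellipsoid volume), marginality `NM` (Mahalanobis distance from
the niche centroid to the component-space origin, which is the study-area
mean by construction of the centered PCA), and phylogenetic position `NP`
(Mahalanobis distance from the centroid to the reconstructed ancestral
centroid). The Mahalanobis metric uses the species' own ellipsoid covariance
— the distance is measured "through" the niche's shape; a background
covariance is a defensible alternative, but the species-ellipsoid metric is
the package default and all results are reported under it. In the univariate
approach: temperature breadth `TB` (warmest-month maximum minus coldest-month
minimum over occupied cells), precipitation breadth `PB` (wettest minus
driest month), centroids as midpoints of those extremes, marginalities
`TM`/`PM` as absolute distances to the study-area means, and positions
`TP`/`PP` as absolute distances to the univariate ancestral reconstructions.
Extremes are taken over occurrence cells (not the predicted range); an
occupied-climate reading of breadth that matches how the occurrences were
used to fit the niche.

## Comparative analysis

Niche centroids (each principal component, and the univariate temperature and
precipitation centroids) are treated as continuous traits on the phylogeny.
Four models are fitted by maximum likelihood through the model-implied tip
covariance: Brownian motion ($\sigma^2 C$, with $C$ the shared path-length
matrix), single-optimum Ornstein-Uhlenbeck (stationary covariance
$\tfrac{\sigma^2}{2\alpha} e^{-2\alpha(T-t_{ij})}(1-e^{-2\alpha t_{ij}})$ on
ultrametric trees; the general form otherwise, with a warning), early burst
(branch lengths transformed by $(e^{rt_1}-e^{rt_0})/r$, $r \le 0$), and a
rate trend. The trend model named in this literature is not standardized; we
implement it as a linear-in-time rate transform (instantaneous rate
$\propto 1 + bt$, so shared path covariance $t_{ij} + b\,t_{ij}^2/2$), with
$b$ allowed on both sides of zero; a mean-drift trend is the common
alternative but is unidentifiable on ultrametric trees. The rate $\sigma^2$
and the mean (root state $z_0$; the optimum $\theta$ for OU) are profiled
analytically, leaving a one-dimensional optimization per model over a
jittered seeded grid refined by golden-section search, with bounds
$\alpha \in [10^{-8}, 50/T]$, $r \in [-10/T, -10^{-8}]$,
$b \in (-0.99/T, 10/T]$ for tree height $T$.

Models are compared by AIC and Akaike weights; each trait selects its own
best model (this reduces to a single shared model when one wins everywhere).
The root state is reconstructed by generalized least squares under the
fitted covariance, $\hat z_0 = (1^\top V^{-1} 1)^{-1} 1^\top V^{-1} z$, with
standard error $\sqrt{(1^\top V^{-1}1)^{-1}}$ — for OU this reads the root as
the stationary mean, which is the natural GLS interpretation of
reconstructing "with the parameters of the selected model". One calibration
worth noting: with three one-extra-parameter alternatives in the candidate
set, pure-BM data are "caught" by a flexible alternative in a substantial
minority of replicates (we measure BM winning AIC in about three quarters of
BM-simulated runs), so model-recovery tests assert clear majorities rather
than near-certainty.

## Spatial statistics

SAR error models $y = X\beta + u$, $u = \lambda W u + \varepsilon$ are fitted
by maximum likelihood with the log-likelihood concentrated over $\lambda$:
for each $\lambda$ the spatially filtered regression
$(I-\lambda W)y \sim (I-\lambda W)X$ is an ordinary least-squares solve, and
$\log|I-\lambda W| = \sum_i \log(1-\lambda e_i)$ uses the eigenvalues of $W$,
computed once per weight matrix through a symmetric similarity transform
(every supported scheme is a positive diagonal rescaling of a symmetric
binary adjacency). A 60-point grid over the feasible interval is refined by
golden-section search, with a guard that the returned optimum is never worse
than $\lambda = 0$. Coefficient standard errors are the GLS asymptotics
conditional on $\hat\lambda$. The eigenvalue log-determinant limits models to
a few thousand cells, ample for coarse-grid assemblage analyses.

Weights: distance-band neighbors under three schemes (row-standardized `W`,
globally standardized `C`, variance-stabilizing `S`) and two distance
classes. The literature's "minimum and maximum" distance classes are
under-specified; here `min` is the largest first-nearest-neighbor distance
(the smallest band leaving no island) and `max` is twice that, both
overridable. Cells with zero richness are excluded from SAR fitting.
Predictors whose per-cell maps have Spearman $|\rho| > 0.7$ are never
included in the same model: conflicting predictors are split by greedy graph
coloring and every model is extended with all predictors that conflict with
none of its members.

## Null models

Two randomizations test whether richness-property slopes could arise from
geometry or co-occurrence structure alone, each with 100 replicates by
default:

* **spreading dye** (geometric constraint): every species' range is replaced
  by a cohesive random range of identical size, grown from a uniformly drawn
  seed cell by uniform draws from the current frontier (rook adjacency by
  default, queen optional; uniform-over-frontier growth is documented as the
  package's choice — it affects range shape statistics only). Species count
  and all range sizes are conserved exactly.
* **property shuffle**: ranges are kept and whole property rows are permuted
  among species, so each property's multiset is conserved exactly and
  inter-property correlations survive the shuffle.

Replicates refit the observed SAR specification and record each predictor's
slope; `p = (1 + \#\{|slope_{null}| \ge |slope_{obs}|\})/(n+1)` (add-one
rule, two-sided on magnitude). For cost control the observed best weight
matrix — and its eigenvalue decomposition — is reused across replicates over
the fixed observed modelling cells. A spreading-dye replicate occasionally
leaves a few of those cells empty; such cells keep their replicate richness
of zero and receive the species-mean property value (the expected assemblage
mean under random membership), so the shared weights remain usable. This
imputation touches well under 1% of cells in the shipped scenarios.

# The synthetic-data generator

Real inputs (occurrence archives, global climate rasters, a published
phylogeny, expert range polygons) are internet resources, so the package
generates complete study scenarios with the statistical structure the
analysis assumes: a planar 1-km climate landscape (latitudinal gradient plus
Gaussian-random-field noise, built by separable Gaussian smoothing of white
noise; a bimodal wet/dry regime for the precipitation-like layer emulates a
bimodal distribution of available environments), bioclim-style derived layers
(warm/cold and wet/dry extremes constructed to bracket their means), a
pure-birth ultrametric phylogeny scaled to height 1, niche centroids evolved
per component under an exact per-branch OU simulation, diagonal ellipsoid
shapes with log-normal axis scales, and occurrences drawn uniformly from
inside-niche cells with within-cell jitter and three-decimal coordinate text
(so the precision filter passes them). Geometric settings scale down the real
design: 1-km pixels with 10-km assemblage cells stand in for ~5-km pixels
with ~110-km (one-degree) cells, and the default scenario uses 60 species on
a 300 x 300 km landscape (a 30 x 30 assemblage grid), 60 records per
species. These sizes keep a full pipeline run with two 100-replicate null
ensembles in the low minutes on a single core while leaving every stage
statistically non-trivial.

Presets fix the built-in effect structure. `breadth_gradient` pulls centroids
toward the warm end of the gradient by OU (`alpha = 1.5`,
`sigma2 = 0.6`) and couples log niche scale to the signed projection of the
centroid along the realized gradient direction in component space (from the
warm-end mean toward the landscape mean; slope 0.3 per component unit, over
a baseline axis sd of 0.5 component units with log-normal spread 0.1), so
richness peaks where niches are narrow and the richness~breadth SAR slope is
negative by construction. The projection direction is computed from the
landscape itself rather than a single component axis because the temperature
gradient can split across components. The coupling strength, the baseline
niche scale and the 25-km climate autocorrelation range were set so that
assemblage means rest on tens of species and the built-in association also
exists at scales coarser than one assemblage cell — gradients living only at
the largest scale are mostly absorbed by the SAR error term, which would
leave the construction undetectable by design rather than by biology.
`neutral` centers the root mid-landscape and draws niche scales
independently of position, so no richness-property relationship is built in.
`conserved_position` uses a strong OU pull so rich assemblages hold species
near the ancestral niche.
A simulated niche occasionally misses the realized environments entirely;
its covariance is then doubled (up to 8 times) until at least five landscape
cells are suitable — a pragmatic validity repair that slightly widens the
smallest niches.

What the generator does *not* emulate: georeferencing error modes, taxonomic
noise, sampling bias, non-equilibrium range dynamics, and real bioclim
inter-layer constraint structure. Passing tests demonstrate that the
implementation recovers effects it was constructed to contain and stays
calibrated when none are present — not that the biological hypotheses hold in
any real system.

A calibration caveat worth stating explicitly: even when niche scales are
drawn independently of position (the `neutral` preset), the *computed* niche
breadth is not independent of richness, because volume drives range size and
widespread species dominate the assemblage means of species-poor cells. The
property-shuffle null correctly detects this mechanical association, so a
small shuffle-null p for breadth in real data is evidence against "no
association" but not, by itself, evidence for an ecological breadth effect
beyond the breadth-range-size link. The package's calibration test therefore
assigns the tested property independently of the ranges (a seeded
re-assignment across species) before checking that the machinery's p-values
are uniform.

# Numerical choices and degenerate inputs

* Cell membership in polygons is decided by cell-center containment; boundary
  points count as inside.
* `fit_mve` refuses rank-deficient point sets (suggesting dimension
  reduction) and fewer than $d+2$ points.
* The MVE volume is monotone in coverage on the shipped test data; the
  deterministic full-sample start makes the envelope bound exact, though the
  heuristic itself carries no global guarantee.
* SAR $\lambda$ is searched strictly inside the feasible interval
  $(1/e_{\min}, 1/e_{\max})$; ties in AIC selection resolve to the earlier
  candidate in the (stable) sort.
* Permutation p-values always use the add-one rule, so $p \in (0, 1]$.
* Seeds: one master seed fans out to every stage and replicate through a
  deterministic integer hash (`derive_seed`), keeping all streams below
  $2^{31}$; identical configs give hash-identical artifacts.

# Known limitations

* No geodesic geometry: real-data inputs must arrive in an equal-area planar
  projection; the packaged raster interchange format is plain-text CSV + JSON
  rather than GeoTIFF.
* Ellipsoid ranges have no continuous suitability; evaluation statistics
  beyond the fixed 5% omission design are out of scope.
* The SAR implementation covers the spatial-error form only (no lag or mixed
  models) and dense weights up to a few thousand cells.
* Phylogenetic uncertainty is not propagated; a single fixed tree is used.
* With 60 species the property-shuffle null is conservative for smooth
  gradient signals (the SAR filter attenuates the observed large-scale
  relationship more than the patchier null maps); the spreading-dye null is
  the sharper of the two at this scale.
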