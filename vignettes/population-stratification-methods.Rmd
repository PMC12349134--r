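---
title: "Discovering population stratification from phenome-wide data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering population stratification from phenome-wide data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Population-scale child-development cohorts measure thousands of phenotypic
variables — behavioral, clinical, cognitive, and sociodemographic — on upward
of ten thousand participants recruited across many data-collection sites.
`phenostrat` implements a workflow for asking a deliberately open-ended
question of such a phenome: *what are the dominant, coherent axes along which
participants differ?* The answer in cohorts of this kind turns out to be
substantially socioeconomic, and — importantly — socioeconomic status (SES)
behaves as a multidimensional construct: several distinct latent components
are each driven by different, largely non-overlapping configurations of SES
measures, and those configurations align differently with geography.

The workflow has six stages, each a module of this package:

1. **Synthetic cohort generation** (`generate_phenome()`) — a planted-truth
   stand-in for access-restricted cohort data.
2. **Curation** (`curate()`) — from raw mixed-type table to model-ready matrix.
3. **Embedding** (`train_cvae()`, `fit_pca_baseline()`,
   `select_architecture()`) — a site-conditioned variational autoencoder
   benchmarked against PCA.
4. **Component analysis** (`ablation_rank()`, `compute_loadings()`,
   `threshold_95()`) — ranking, attribution, and sparsification of latent
   components.
5. **Profiling** (`category_profile()`, `ses_overlap()`) — category-level
   characterisation and SES-measure overlap.
6. **Geographic validation** (`ses_component_scores()`, `predict_state()`) —
   predicting state of residence from SES-only component scores.

# Curation

`curate()` applies, in order: collection-event retention, missingness
pruning, near-constant filtering, sentinel recoding, indicator encoding,
imputation, and robust z-scoring with winsorization. The stage order follows
the narrative in which such protocols are usually described; each stage is
exported separately so the order can be changed.

The parameters that matter:

* `min_family_fraction = 0.95` — an event is kept only if at least 95% of
  baseline participants have any data in it. Coverage is measured as the
  fraction of participants with at least one observed value among the
  event's variables.
* `min_populated = 0.80` — a variable is kept only if observed for at least
  80% of participants.
* `max_top_fraction = 0.99` — a variable is dropped when its most frequent
  non-missing value accounts for *more than* 99% of non-missing entries. The
  informal phrasing of near-constant rules ("most common compared to the
  second most common value") is ambiguous; we adopt the top-value-share
  reading and record the measured share in the report so the rule can be
  swapped without re-deriving anything.
* `z_max = 4` — winsorization bound. For each continuous column we compute
  the mean and SD over observed values; entries beyond `z_max` SDs are
  replaced by the observed value of largest magnitude among in-range entries,
  then the column is z-scored by its post-replacement statistics.

Two numerical facts about winsorization are worth knowing. First, a sample
z-score is bounded by \((n-1)/\sqrt{n}\), so in very short columns a lone
extreme value can never exceed 4 SDs — it *masks itself* by inflating the SD.
The rule therefore only bites for \(n \ge 18\), which is irrelevant at cohort
scale but matters for toy examples. Second, the rule is not exactly
idempotent: an entry replaced at the boundary can sit slightly beyond 4 SDs
under the *post*-replacement statistics of a second pass, and because the
replacement value is chosen by magnitude (not sign-matched), a re-clipped
negative entry can be replaced by a positive value. In practice a second
curation pass moves at most a handful of boundary entries; the test suite
asserts exactly that.

Imputation is column median for continuous variables and column mode for
indicators (ties toward the smaller value, for determinism). The protocol we
follow states *that* imputation occurred but not how; median/mode is the
minimal-assumption choice and is exposed as a configuration option
(`impute = "none"` to disable). Standardization statistics are computed on
the full curated sample by default, matching a workflow that curates before
splitting; a train-only mode (`standardize = "train"`) is available for
leakage-sensitive uses.

# The embedding model

The embedding is a conditional variational autoencoder (CVAE) on the curated
matrix \(X\), conditioned on the data-collection site \(C\) (one-of-n
vector). Site is a known nuisance factor; supplying it to both encoder and
decoder means the latent space need not spend capacity encoding it. The
generative model is
\(p_\theta(X \mid C) = \int p_\theta(X \mid Z, C)\, p(Z)\, dZ\)
with a standard Gaussian prior on \(Z \in \mathbb{R}^K\); the encoder
\(q_\phi(Z \mid X, C)\) is a diagonal Gaussian whose mean \(\mu\) and
log-variance are produced by a two-layer ReLU network; the decoder mirrors it
with a linear output layer. Training minimises the negative evidence lower
bound

\[
\mathcal{L}(\theta,\phi) \;=\;
\mathbb{E}_{q_\phi}\!\left[\lVert X - \hat{X} \rVert^2\right]
\;+\; \beta\, \mathrm{KL}\!\left[q_\phi(Z \mid X, C)\,\Vert\, p(Z)\right],
\]

with the squared-error reconstruction term standing in for the Gaussian
log-likelihood up to constants and the KL term in closed form for diagonal
Gaussians (the definitional integral is cross-checked by quadrature in the
tests). `beta = 1` by default — the plain ELBO; the weight is exposed because
the \(\beta \to 0\) linear-activation limit is a useful diagnostic: it must
approach the PCA optimum at equal latent dimension, and the acceptance suite
verifies that it does.

Architectural choices follow the candidate-grid pattern: optional PCA
front-end projection (fit on the training split only) feeding a hidden layer,
with the grid spanning direct-ingest and front-end variants. Candidates are
compared by mean test-split reconstruction error over several seeded weight
initialisations (`select_architecture()`), since the non-convex optimisation
makes single runs unreliable; diverged replicates are excluded with a
warning and candidates with fewer than 80% successful replicates are
disqualified.

Optimisation is Adam on minibatches with early stopping on the validation
objective (patience 10 epochs by default, best-validation weights restored).
The optimiser, learning rate and batch size are implementation necessities
with conventional defaults (`1e-3`, 128); they are configurable and every
random decision — initial weights, shuffling, reparameterisation noise —
derives from the single configured seed, so training is bit-reproducible.

**MSE convention.** All reported reconstruction errors are *summed over
curated variables and averaged over participants*, measured in the
curated-variable space after inverting the front-end. This makes
architectures with different front-end sizes comparable with each other and
with the PCA baseline, and it is the convention under which a zero-knowledge
predictor on standardized data scores approximately the number of variables.

**Splits.** `stratified_split()` assigns 80/10/10 train/validation/test
proportions within every site by largest-remainder apportionment, so per-site
proportions are preserved to within one participant.

# Component analysis

**Scores** are the encoder posterior means by default. A sampled mode
(seeded) is retained for fidelity to the stochastic view of the latent
variable, but posterior means make every downstream quantity deterministic,
which we consider the better default for an interpretive analysis.

**Loadings** are Pearson correlations between each component's scores and
each curated variable, computed over the test split (unseen participants
avoid optimistically biased attribution). The loading magnitude is the
*weight strength*. Zero-variance variables receive loading 0 with a flag
rather than an error so that downstream thresholding remains total.

**Ablation ranking.** A VAE, unlike PCA, has no intrinsic component
ordering. For each component \(k\) we zero every latent coordinate except
\(k\), decode (condition vector intact — conditioning is part of the decoder
input, not a latent coordinate), and measure test MSE; components are ranked
ascending. On an exactly linear decoder with orthogonal columns this
reproduces the descending generative variance order, which the tests verify
in closed form.

**Elbow.** The number of leading components to interpret is chosen by the
maximum perpendicular distance of the sorted ablation curve to the chord
joining its endpoints. On real data this call is usually made visually; the
algorithmic rule makes it reproducible, and a manual override is first-class
(and logged) precisely because the cut is a judgment. An exactly linear
curve has degenerate geometry and returns 1 with a warning.

**Thresholding.** For each phenotype, all \(K\) components are ranked by
weight strength and the phenotype is retained only in its top
\(\lceil (1-p) K \rceil\) components (5 of 100 at the default
\(p = 0.95\)). Ties break toward the lower component index. A subtle
floating-point point: \(1 - 0.95\) is not exactly \(0.05\) in binary, so the
count is rounded before the ceiling — otherwise \(K = 100\) would retain 6.

# Profiling and geographic validation

Category profiles average weight strengths over the variables of each
predefined category retained in a component, and report the retained count
and percentage of the category. Indicator columns inherit their parent
variable's category. The 23-name category list ships as editable metadata
(`phenome_categories`); any closed vocabulary can be passed instead.

SES overlap reports, for a chosen set of components (the four with the
strongest SES signature, by default), the retained-SES set per component,
every subset intersection cardinality, and the measures unique to each
component. The report satisfies inclusion–exclusion exactly, which the tests
check against a brute-force power-set enumeration.

For geographic validation, each participant's SES-only score in component
\(j\) is the dot product of their curated SES measurements with component
\(j\)'s *retained* SES loadings (masked mode; an unmasked mode using all SES
loadings is provided since the choice is defensible either way, and the mode
is recorded). A one-vs-rest ridge-penalised logistic classifier per state,
under state-stratified 10-fold cross-validation, yields pooled out-of-fold
predictions, a row-percentage confusion matrix, fold-averaged coefficients,
and per-state score density curves. The ridge penalty defaults to unit
strength (glmnet `lambda = 1/n_train`) with no class weighting; both are
configurable. Chance level is \(100/n_{\text{states}}\)%. A
label-permutation null (`permutation_null_accuracy()`) calibrates what
"above chance" means at a given sample size.

# The synthetic cohort generator

Real cohort phenome data of this kind are access-controlled, so the package
ships a generator whose defaults describe the study conditions at desk
scale: 2,000 participants by 300 variables over 21 sites and 17 states, a
rank-5 latent factor structure with descending variances (25, 16, 9, 4, 1),
unit-norm per-variable loading vectors, unit measurement noise, additive
per-site offsets (SD 0.5), 5% completely-at-random missingness, rare
multiplicative outliers, a 20% discrete-variable share (quantile-thresholded
latents with 2–4 levels), a 25% share of variables whose factor link passes
through an odd squashing nonlinearity \(a \tanh(u/a)\), planted near-constant
and heavily-missing variables to exercise the filters, and five collection
events of which one covers only 55% of participants.

Geography enters through the first two factors, designated SES-linked: each
state receives a mean offset drawn with SD `state_ses_shift` (default 2,
i.e. roughly 0.4 within-state SDs of the strongest factor — a moderate,
plausibly detectable geographic gradient; set it to 0 via
`null_state_variant()` for the negative control). Roughly 12% of variables
are assigned the Socioeconomic category so that SES-restricted analyses are
well populated at 300 variables.

What the generator does *not* emulate: real marginal distributions,
questionnaire skip-logic, longitudinal dependence between events,
missingness that is informative rather than completely at random, and
family/sibling structure. Passing tests on this generator therefore
demonstrate that the machinery recovers planted low-rank structure under
batch effects, mixed types, missingness and outliers — not that any
particular real cohort has such structure.

# Choices made where the design was open

* **Nonlinearity choice** — an odd squashing link creates exactly the regime
  where a nonlinear autoencoder should beat PCA at equal latent dimension,
  which is the headline model comparison; the acceptance suite checks the
  direction of that comparison over seeds.
* **Missingness mechanism** — completely at random, the minimal assumption
  that keeps the pruning-rule tests interpretable by simple counting.
* **Scores from posterior means, loadings on the test split, masked SES
  scores** — determinism and out-of-sample attribution over literal fidelity
  to a stochastic description; each alternative remains available behind an
  argument.
* **Replacement value in winsorization** — the single max-magnitude in-range
  value per column, not sign-matched; simple, matches the usual phrasing of
  the rule, and its edge cases are documented above.
* **Problem sizes** — the analysis scripts and test suite run at
  2,000 × 300 with a 20-dimensional latent space, and smaller fixtures where
  a property does not need cohort scale; these sizes keep every planted
  effect detectable with comfortable margins while the whole workflow stays
  inexpensive to reproduce.

# Known limitations

* With \(K\) well above the true factor count, the VAE spends some latent
  dimensions on noise and may split or rotate weak factors; recovery of the
  weakest planted factor (variance 2 against unit noise) is the first to
  degrade. PCA on the same data recovers planted *linear* structure more
  cleanly — the CVAE's advantage appears in the nonlinear regime.
* Ablation ranking measures single-component reconstruction in isolation;
  correlated components can share credit, and the ranking is conditional on
  the fitted decoder.
* The ridge-logistic geographic validation is linear by design; it measures
  the linear separability of states in SES-score space, not any richer
  geographic structure.
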