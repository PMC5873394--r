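---
title: "HGT-constrained divergence dating: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HGT-constrained divergence dating: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtclock)
```

## The problem

Bayesian molecular clocks date the nodes of a species tree from sequence
data, fossil/geochemical calibrations, and a root prior. For deep bacterial
lineages -- phototrophs above all -- calibrations are scarce, and posterior
divergence-date intervals are wide. Horizontal gene transfer (HGT) offers an
extra, *relative* constraint: a gene transferred from a donor lineage into a
recipient lineage forces `age(donor node) > age(recipient node)`, much as an
index fossil ties strata together. An HGT can carry absolute time information
("index HGT") when (i) the transfer's placement within the donor lineage is
well resolved, (ii) donor and recipient clade phylogenies are congruent with
the species tree, and (iii) a date calibration is associated with the donor
or, ideally, the recipient crown group. `check_index_hgt()` evaluates the
calibration criterion mechanically and restates the two gene-tree criteria as
notices, since this package never sees gene trees.

`hgtclock` implements the post-processing side of that idea. It does **not**
run the dating MCMC; it consumes a posterior trace of dated trees (the
"datedist" dialect: one newick chronogram per line, branch lengths in Ma) and

1. trims burn-in (`apply_burn_in()`, default first 20% of saved points,
   `floor(fraction * N)` samples dropped);
2. optionally audits every sample against hard calibration bounds
   (`check_sample()`);
3. **conditionally post-samples** the posterior: a sample is retained iff
   *every* HGT constraint holds, i.e. each donor node is strictly older than
   its recipient node (`filter_trace()`). This rejection step converts the
   unconstrained posterior into the HGT-constrained posterior without
   touching the MCMC itself, and several constraints compose by logical AND;
4. summarizes node ages as medians and 95% highest-posterior-density (HPD)
   intervals (`summarize_model()`), and computes transfer-feasibility
   probabilities `P(age A > age B)` (`prob_older()`).

## Data model and conventions

* **Ages** are in Ma before present; larger is older; tips are extant at age
  0. A node's age is the branch-length path sum down to any descendant leaf.
* **Ultrametricity**: all leaf path sums below a node must agree to a
  relative tolerance of 1e-6. Dating software truncates decimals, so
  `read_datedist(on_violation = "repair")` can instead assign each node the
  mean of its leaf path sums; the default is to reject, because silent repair
  hides malformed input. The per-leaf report (`validate_ultrametric()`)
  compares each root-to-leaf path against the tree-wide *median* path sum, so
  a single corrupted terminal branch flags only its own leaf.
* **Ties**: a parent and child with equal ages (within 1e-9 Ma absolute) are
  rejected at parse. Zero-length time branches would make strict ordering
  constraints ill-defined.
* **Crown vs stem**: a clade's crown node is the MRCA of its sampled leaves;
  its stem node is the parent of that MRCA (the divergence from the sister
  lineage). Stem age > crown age always.
* **Monophyly**: clade operations are strict by default and fail loudly if
  the leaf set is not monophyletic in a sample, rather than silently mixing
  clade identities across topologies. Calibrations are the exception: a
  two-taxon calibration *names a node* by an MRCA and is resolved
  non-strictly.

## Constraint encoding

A transfer "from within" a donor clade postdates that clade's crown, and a
transfer into a recipient stem predates the recipient crown. The weakest safe
encoding is therefore crown(donor) older than crown(recipient), which is the
default for both sides of an `hgt_constraint()`. Which internal donor branch
actually carried the transfer is generally unknowable from the species tree
alone, so the crown default is a documented assumption, overridable per
constraint via a `stem` selector. Satisfaction is a strict inequality; exact
age equality counts as unsatisfied (and ties are reported separately by
`prob_older()`).

The bundled constraint tables encode the two index HGTs of the phototroph
analyses: *SahH* (S-adenosyl-L-homocysteine hydrolase, donor within
Chloroflexi, recipient the Cyanobacteria+Melainabacteria ancestor) and *BchH*
(Mg-chelatase, donor within the green non-sulfur bacteria, recipient the
green sulfur bacteria).

## Estimators

* **HPD**: among all windows of `k = ceiling(level * n)` consecutive order
  statistics, the minimum-width window, ties broken toward the lowest lower
  bound. This is the standard empirical estimator; the source analyses name
  the quantity but not the estimator. It is checked exactly against
  exhaustive window search in the test suite.
* **Median**: mean of the two central order statistics for even n. Reports
  round to whole Ma for display only; computation keeps full precision.
* **Burn-in count** uses `floor`, which never discards a fractional extra
  sample. (With 100 saved points and fraction 0.2, exactly 80 remain.)
* **`prob_older()`** defaults to *paired* evaluation: both age traces come
  from the same posterior samples, so the joint dependence is kept. Unpaired
  (cross-product) evaluation is available for independent runs; whether the
  published probabilities were paired is unstated, and paired is the more
  faithful reading of a single filtered posterior. Feasibility probabilities
  for a constrained model are computed on that model's *filtered* trace,
  because that is the posterior the model defines.
* **Interval precision** is compared as
  `100 * (1 - width_constrained / width_unconstrained)`; negative values mean
  the interval widened.

## The calibrated-prior sampler

`sample_prior()` emulates dating "under the prior" so that calibration
semantics are testable without external software. Its stationary law is:

* root age distributed per the root prior -- `gamma` parameterized by mean m
  and SD s (shape m²/s², scale s²/m; the default 3900 Ma, SD 200 Ma keeps
  ages positive), `normal`, or `flat` between hard bounds;
* conditional on the root, uncalibrated internal node ages uniform over the
  order polytope (parent strictly older than child);
* hard calibration bounds enforced exactly as indicators.

Non-root nodes are updated by exact conditional draws: uniform between the
oldest child and the youngest of (parent age, maximum bound). The root uses a
Gaussian random walk. A subtlety worth recording: accepting root proposals by
the prior density times indicators alone would leave the *wrong* stationary
law -- the root marginal would be size-biased by the order-polytope volume,
which grows like age^m with m the number of free internal nodes. The
acceptance ratio therefore includes the volume correction
`(age_old / age_new)^m`, with m counting uncalibrated non-root internal
nodes. On an unconstrained tree this makes the root marginal exactly the
prior (verified by moment recovery and by the closed form
`E[inner] = E[root] / 2` on a three-leaf caterpillar). With internal
calibrations the polytope volume is no longer a pure power and the correction
is approximate; hard bounds still hold exactly, which is the property the
calibration machinery needs. Infeasible bound sets are rejected before
sampling by interval propagation (minima rootward, maxima tipward). The
sampler discards its first 10% of sweeps and emits every `thin`-th sweep
thereafter; seeds are mandatory and echoed in the trace's source label.

## The pseudo-posterior simulator

`simulate_posterior_trace()` is the test-fixture generator: given a true
chronogram it redraws node ages root-down from normals centered on the truth,
truncated to `(0, parent age)`, so ordering and non-negativity hold by
construction, and it returns the full per-sample age ledger so downstream
results can be checked against generator bookkeeping exactly. It emulates
sample-to-sample jitter of node ages around a fixed topology -- and nothing
else. Real posteriors have topology uncertainty, autocorrelation,
rate-variation structure, and asymmetric marginals; passing tests on this
generator therefore validate the *post-processing arithmetic*, not the
behaviour of any dating model on real data. The bundled 18-taxon example
chronogram (`phototroph_example()`) is likewise synthetic: its clade
structure mirrors the phototroph analyses and its node ages are set to
published medians so that worked examples live on a realistic scale.

Default jitter SD is 10 Ma (small against the hundreds-of-Ma gaps between
deep nodes, so truncation bias is negligible in recovery tests); tests that
need constraint satisfaction to be genuinely uncertain raise it to a few
hundred Ma.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
traces of 60-2000 samples over 4-18 tips, 2e4 prior-sampler draws for moment
recovery, 1e5 draws for the analytic probability check, and 500 random
vectors (n up to 200) for exhaustive HPD verification. These sizes make every
check exact or within stated Monte-Carlo error while keeping a full run
under a minute on one core.

## Known limitations

* No gene-tree analysis: HGT events are *inputs* (detected elsewhere), and
  criteria (i)-(ii) for index HGTs are only restated, not tested.
* Hard calibration bounds only; no soft-tailed calibration densities and no
  effective-prior marginal computation.
* No MCMC convergence diagnostics beyond sample counts; concatenation is the
  only multi-chain support.
* Serially sampled (non-extant) tips are unsupported; tips must be at age 0.
* The prior sampler is a validation stand-in, not a re-implementation of any
  dating package's effective joint prior.
* The datedist reader assumes ages encoded as branch lengths (durations). A
  node-label encoding of ages exists in the wild; it is not parsed.
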