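---
title: "Methods: dated phylogenies, ancestral ranges and range-dependent diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dated phylogenies, ancestral ranges and range-dependent diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rangediv implements, as one tested pipeline, the computational core of a
historical-biogeography analysis on a dated molecular phylogeny: converting
a phylogram into a chronogram by penalized-likelihood rate smoothing,
reconstructing ancestral geographic ranges under the
dispersal-extinction-cladogenesis (DEC) model, translating the
reconstruction into a dated dispersal/extinction event scenario summarized
through time and in time slices, and asking whether diversification rates
depend on geography with the three-state GeoSSE model. Simulators provide
ground truth for every stage, so each method is validated against data whose
generating process is known exactly.

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where a design decision was genuinely open - and
what passing the simulation-based tests does and does not establish about
real data.

## Penalized-likelihood dating

A phylogram carries branch lengths in expected substitutions per site. For
branch $k$ with (unknown) duration $t_k$ Myr and substitution rate $r_k$
(substitutions/site/Myr), the observed count $n_k$ = branch length x
`sites` is modelled as Poisson with mean $\mu_k = r_k \cdot
\text{sites} \cdot t_k$. The dating objective is

$$\sum_k \left[ n_k \log \mu_k - \mu_k \right] \;-\; S \Big[ \sum_k (R_k -
R_{\mathrm{pa}(k)})^2 + \operatorname{var}\{R_j : j \text{ root child}\}
\Big],$$

maximized jointly over node ages and rates, where $R_k = r_k \cdot
\text{sites}$ is the whole-alignment rate. Two deliberate choices:

* **Counts are real-valued.** $n_k$ is the ML expectation (branch length x
  sites), not a rounded integer; rounding would discard signal, and the
  constant $\log n_k!$ term affects no optimization.
* **The penalty acts on whole-alignment rates.** Conventional smoothing
  values ($S \approx 10$, chosen by cross-validation in the tradition this
  package follows) are calibrated against rates expressed in substitutions
  per branch per Myr. On per-site rates ($\sim 10^{-3}$) a
  squared-difference penalty only becomes active around $S \sim 10^8$,
  which would make the conventional scale meaningless; on the $R_k$ scale,
  $S$ between $10^{-3}$ and $10^{3}$ spans under- to over-smoothing.

Ages are parameterized as per-node fractions $u_v \in (0,1)$ of the parent
age (logit scale), so the constraint "parent strictly older than child"
holds by construction and the single calibration - the crown age, fixed
(default 70.1 Ma) - anchors the scale. Rates are optimized on the log
scale. The objective and its analytic gradient (ages are chained through
the $u$ parameterization by one post-order sweep) go to `optim`'s
box-constrained quasi-Newton; a tree of ~250 tips (~760 free parameters)
fits in seconds. Starting values: ages proportional to maximal root-to-tip
substitution path depths, one global clock rate (so the penalty starts at
exactly zero).

Cross-validation over $S$ removes one terminal branch's Poisson term at a
time, refits (the rate of the held-out branch stays in the penalty, so it
is smoothed from its neighbours), and predicts the held-out count as
$\hat r_{\mathrm{adjacent}} \cdot \hat t_k \cdot \text{sites}$, where the
adjacent rate is the parent branch's (for a root child: the mean of the
other root children). The score is the chi-square-flavoured
$\sum (n_k - \hat n_k)^2/\hat n_k$. This leave-one-terminal-out statistic
is one defensible reading of the classical procedure; implementations
differ in detail, which is why the smoothing default remains a user-facing
parameter rather than something silently auto-selected.

Dating a tree *sample* (`date_tree_sample()`) applies one shared $S$ to
every tree and summarizes per-clade age means and 95% quantile intervals on
a reference tree, matching clades by identical descendant tip sets; clades
absent from the whole sample are flagged rather than silently dropped.

## The DEC model

Geographic ranges are subsets of an ordered area codebook (default: eight
areas, `A` South America through `H` Asia). The state space contains every
nonempty subset of at most `max_range_size` areas (default 3; with 8 areas,
93 states including the null range), plus any *observed* tip range larger
than the cap: the cap constrains ranges at nodes, and data must stay
representable. The null range is included in the rate matrix as an
absorbing bookkeeping state (lineage-wide extinction) but excluded from tip
data, cladogenesis, the root prior, and all reported distributions.

Along a branch, range `R` gains area $j \notin R$ at rate $d\,|R|$
(uniform dispersal multipliers - the analysis deliberately has no
adjacency or epoch structure) and loses $j \in R$ at rate $e$; transition
probabilities are $\exp(Qt)$. At a node, a single-area range is copied to
both daughters; a wider range is partitioned by vicariance
($\{a\}$ vs $R \setminus \{a\}$) or peripheral isolation ($\{a\}$ vs $R$),
every distinct ordered outcome weighted uniformly. The pruning pass
combines daughter partials through those weighted outcomes; the root sums
over non-null states under a uniform prior (the classical default; nothing
in the analysis motivates an alternative). `d` and `e` are estimated by
bounded quasi-Newton on the log scale from `(0.01, 0.01)`.

Marginal ancestral ranges are reported **for the range at the node
immediately before its cladogenetic split**, with the subtree likelihood
already summed over cladogenetic outcomes; the convention is recorded in
the output's `convention` attribute. They are computed by an
outside-inside pass (one additional sweep), not by refitting per node.

Numerics: the matrix exponential contract (relative error $\le 10^{-10}$)
is met by `Matrix::expm`; internally, branch propagation uses an
eigendecomposition fast path validated by reconstructing $Q$ to $10^{-9}$
and falling back to `expm` when the validation fails. Partial likelihoods
are renormalized at every node with an accumulated log scaler. The pruning
likelihood and the marginals are tested to $10^{-8}$ relative agreement
against an exhaustive enumeration over all internal range assignments and
cladogenetic outcomes on all tree shapes with up to 4 tips and 3 areas.

### What the extinction rate can and cannot tell you

The test suite demonstrates - deliberately, with a red expectation rather
than a silently weakened one - that `e` is not recoverable at realistic
rates from tip ranges on a fixed tree. The simulator conditions every
lineage on never entering the null range (observed data contain no
globally extinct species), while the likelihood keeps the absorbing null
state unconditioned; the survival factor $e^{-e \cdot (\text{single-area
tree length})}$ then dominates the weak contraction signal and drives
$\hat e$ toward zero in essentially every replicate, across every design
we tried (deep and shallow trees, 4-8 areas, range caps from 2 to none,
narrow and widespread root ranges). The dispersal rate `d` is recovered
within a factor of ~1.5 under the same conditions. This mirrors the
near-zero extinction estimates routinely reported by DEC software on real
data and should be read as a property of the model-data combination:
downstream event summaries should not be interpreted as measuring
extinction intensity.

## From reconstructions to event scenarios

The scenario layer turns per-node range distributions into dated events.
The best range per node is the argmax (ties broken canonically - fewest
areas, then bit order - and flagged). For each branch, the baseline is, by
default, the parent's best range passed through the cladogenetic outcome
that best matches the two daughters' best ranges (minimal total symmetric
difference; under uniform outcome weights every consistent outcome is
equally probable, so minimal-edit is the natural reading of "most
probable consistent outcome"). DEC changes ranges at nodes too; comparing
raw parent vs child ranges (`cladogenesis_aware = FALSE`, available and
tested) inflates event counts. Against the baseline, each gained area is a
dispersal (with the baseline recorded as the source) and each lost area an
extinction - the single-area steps the rate matrix permits; a complete
range swap therefore costs one loss plus one gain.

Event times are placed at quantiles $k/(m+1)$ of the branch's age
interval, oldest first, extinctions before dispersals: events are spread
over the branch rather than stacked at the child node, because the branch
interval is all the reconstruction knows. Time-slice summaries (default
boundary 16 Ma, the Mid-Miocene Climatic Optimum) tabulate directed
(source, recipient) dispersal counts and per-area extinctions per slice;
multi-area sources are attributed fractionally ($1/|\text{source}|$ each)
so slice totals equal event counts exactly. Events on the root's own
branches can be excluded (default in the pipeline), since the deepest
reconstruction is rarely interpretable without outgroup sampling.

On simulated histories, where the generator records every true event, the
inferred total dispersal count tracks the truth (Spearman >= 0.7 across
replicates whose tree sizes are drawn from 40-120 tips, so that true
counts span a wide range) and is a lower bound in most replicates:
best-state reconstruction hides reversals. That is the correct direction
of bias to keep in mind when reading real event tables.

## GeoSSE

For a focal area, tips are coded endemic (`A`), absent (`B`) or shared
(`AB`). The seven rates are within-region speciation `sA`, `sB`,
between-region speciation `sAB`, extinction `xA`, `xB`, and range
expansion `dA` (A to AB), `dB` (B to AB). The likelihood integrates the
six coupled extinction/data ODEs along each branch - implemented in C++
with an adaptive embedded Cash-Karp Runge-Kutta 4(5) scheme, relative
tolerance $10^{-8}$, absolute $10^{-12}$, per-branch renormalization of
the data partials with an accumulated log scaler - and combines daughters
at nodes with the standard GeoSSE node factors. The integrator is checked
against an independent `deSolve` integration on random branches.
Incomplete sampling enters through the tip initial conditions
($D = f$ for the observed state, $E = 1 - f$), supplied per analysis or
per area via a sampling-fraction table; $f = (1,1,1)$ reproduces the
unadjusted likelihood bit for bit.

Root treatment defaults to observed weights (root states weighted by their
own partials), with a flat option; the common SSE default, adopted because
nothing in the analysis dictates otherwise. A useful exact check: with all
tips in `A` and `dA = dB = sAB = 0` *and* `xB = 0`, states `B`/`AB` are
unreachable backward and the likelihood equals the closed-form
constant-rate birth-death likelihood (same root handling) - the package
carries that closed form (`bd_loglik()`) as an independent oracle. Note
the `xB = 0` condition is not decorative: with `xB > 0` an `AB` ancestor
can contract into `A`, $D_{AB}$ becomes positive, and the GeoSSE
likelihood genuinely exceeds the one-state birth-death value.

Model comparison fits the full model and the nested `sAB = 0` model and
applies a likelihood-ratio test with $\chi^2_1$. Two numerical points
matter. The full fit is warm-started off-boundary from the reduced
optimum (on the log scale the gradient vanishes *at* the boundary, so a
boundary start could never lift $s_{AB}$); and when the interior search
ends below the reduced optimum, the boundary point $s_{AB} = 0$ is taken
as the full-model MLE — it lies in the closure of the full model, so the
likelihood ordering of nested fits holds exactly. Statistically, the null
sits on the boundary of the parameter space, so the plain $\chi^2_1$
reference is conservative: under the null roughly half the replicates give
a statistic of exactly zero and the rest follow approximately $\chi^2_1$,
for a true rejection rate near $0.02$ at nominal $\alpha = 0.05$ rather
than $0.05$. The test output flags this. The suite's calibration check
documents the consequence: with 100 replicates a rate this small can
realize as zero rejections, and the fixed-seed replicate block used there
does.

The Bayesian layer is an adaptive Metropolis-Hastings sampler on log
rates: independent exponential priors with means twice the ML estimates
(floored at 0.01) and the chain started at the ML fit - one concrete
reading of seeding priors and chain from the ML analysis. Proposal scales
adapt toward ~30% acceptance during burn-in and are frozen afterwards;
thinning is 1; chains are exactly reproducible given a seed; a
prior-only mode exists purely to validate the sampler against the prior
means. Default chain settings follow the study design (20,000 generations,
5,000 burn-in); the test suite and acceptance script run seeded,
scaled-down chains (2,000/500) and state so here rather than pretending
they are the full-length analysis.

`per_area_scan()` repeats coding, both fits, the LRT, the dispersal
asymmetry indicator (`dB > dA`: more dispersal into the focal area than
out of it) and optionally the posterior per area, skipping areas whose
coding is degenerate (no species outside the area, or the area
unoccupied) with a logged reason.

## The synthetic-data generators

All generators are Gillespie simulations, deterministic under a seed, with
per-module substream seeds derived from one master seed so that adding a
stage never perturbs another stage's draws.

* **Birth-death trees** are grown forward from two crown lineages,
  conditioned on both leaving extant descendants (rejection, capped at
  1000); extinct lineages are pruned. When stopping at a tip count, a
  fresh exponential waiting time is appended after the last birth so the
  youngest node has positive age.
* **DEC histories** draw a root range, a cladogenetic outcome per node
  (uniform inheritance weights), and exact event-time anagenesis along
  branches from the rate matrix; branch histories absorbed in the null
  range are redrawn (and counted), conditioning on survival of observed
  lineages. Every realized event is recorded with its age - this is the
  ground truth the scenario layer is scored against.
* **GeoSSE trees** use state-dependent birth/death/transition rates with
  the GeoSSE cladogenetic state maps (an `AB` parent leaves `(A, AB)`,
  `(B, AB)` or, for between-region speciation, `(A, B)`).
* **Rate variation** assigns each branch its parent branch's rate times a
  lognormal(0, sd) factor and draws branch lengths as
  Poisson(rate x duration x sites)/sites.

The bundled "study-shaped" recipe encodes the study conditions the
pipeline is exercised under: crown age 70.1 Ma, birth 0.10 and death
0.031 /Myr (expected ~256 extant tips; the draw is additionally
conditioned on a 150-400 tip window because crown-conditioned birth-death
tip counts are enormously dispersed), eight areas with the DEC history
rooted in the dominant source area (`C`, sub-Saharan Africa) at
`d = 0.0025`, `e = 0.001` per area per Myr - calibrated once so that one
area holds the majority of tip-area occurrences and most species occupy a
single area, the qualitative shape of the empirical system - and a
plastid-like phylogram (7e-4 substitutions/site/Myr, lognormal sd 0.25,
4000 sites).

What these simulations do *not* emulate: alignment-level noise and model
misspecification in tree inference (trees are taken as given, as in the
original analysis), topological uncertainty (the dated-sample summary is
exercised on jittered clones, not posterior samples), area-specific
dispersal constraints, and diversification that feeds back on range
evolution (the DEC history is simulated on a fixed tree, independent of
the birth-death process). Passing the suite therefore validates the
estimators against their own generating models - it does not certify the
biological adequacy of those models for any real clade.

## Problem sizes and runtime choices

The validation experiments are sized to what the methods need, not more:
exhaustive-enumeration checks use every tree shape up to 4 tips with 2-3
areas and 25 random rate draws; DEC recovery uses 20 replicates of
200-tip trees; event fidelity 50 replicates at 40-120 tips; GeoSSE
recovery 20 replicates of 300-tip trees with 2,000-generation seeded
chains; LRT calibration 100 replicates of 100-tip trees; dating recovery a
30-tip clock tree at 50,000 sites (and the acceptance script re-runs
slightly smaller versions of the same computations). The end-to-end
pipeline runs the full study-shaped recipe (~150-400 tips, 93 DEC states)
twice to assert bit-identical manifests.

## Known limitations

* DEC's local extinction rate is effectively unidentifiable from tip
  ranges (see above); treat `e_hat` ~ 0 and downstream extinction-event
  counts as qualitative.
* Event dating within branches is a convention (quantile placement), not
  an inference; only the branch interval is data-driven.
* The LRT reference ignores the boundary null (flagged conservative); the
  MCMC uses a single chain with no convergence diagnostics beyond
  acceptance rates - adequate for seeded, scaled validation runs, not a
  substitute for convergence assessment on real analyses.
* Time-stratified dispersal matrices, founder-event speciation, Bayesian
  DEC, and hidden-state SSE corrections are out of scope.
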