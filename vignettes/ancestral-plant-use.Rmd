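---
title: "Reconstructing ancestral plant use on language trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral plant use on language trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(norseplants)
```

## The inference problem

Modern Nordic ethnobotanical compilations record, language by language,
whether a plant has a given use (yarrow as medicine, juniper as fuel,
...). If plant knowledge is partly transmitted vertically down speech
communities, the distribution of a use across today's North Germanic
languages carries information about whether the ancestral community —
Old Norse speakers of the Viking Age, roughly 700–1000 CE — already had
that use. `norseplants` turns that idea into a tested pipeline:

1. model each binary plant-use trait as evolving along a language
   phylogeny and estimate the probability that it was present at the
   root, averaging over a posterior sample of trees;
2. score the independent archaeobotanical, historical and linguistic
   evidence for the same plant-use on a 1–5 Likert scale
   ("triangulation");
3. cross-tabulate the two approaches.

The package deliberately separates these stages: each consumes and emits
plain CSV/Newick files, and a seeded synthetic-data generator can stand
in for any input, so the whole chain is testable end to end with known
truth.

## The trait model

A use is a two-state character (0 absent, 1 present). On a branch of
length $t$ the equal-rates (ER) two-state Markov model with rate $q$
gives the transition probabilities

$$P_\text{same}(t) = \tfrac12\left(1 + e^{-2qt}\right), \qquad
  P_\text{diff}(t) = \tfrac12\left(1 - e^{-2qt}\right).$$

Equal gain and loss rates are the only defensible choice on a tree with
six or seven tips: an asymmetric model would add a second parameter that
such data cannot resolve. Branch lengths are treated as opaque time
units; only the product $q \cdot t$ is identified, and the likelihood is
exactly invariant under $(q, t) \mapsto (cq, t/c)$ — a property the test
suite asserts.

The character likelihood is computed by Felsenstein's pruning recursion
over the tree, with tip partial likelihoods set to indicators for
observed states and $(1, 1)$ for missing tips (missing data are
marginalized, not imputed). Partial likelihoods are rescaled per node
with an accumulated log factor; for seven tips this is caution rather
than necessity. The root prior is equal, $\pi = (1/2, 1/2)$, and the
marginal probability of presence at the root is

$$P(\text{root}=1 \mid D) =
  \frac{\pi_1 L_1(\text{root})}{\pi_0 L_0(\text{root}) +
        \pi_1 L_1(\text{root})}.$$

Under the ER model with an equal prior, complementing the data flips
this probability exactly: $P(1 \mid D) + P(1 \mid \bar D) = 1$.

### Ascertainment correction

Plant uses enter the data because somebody recorded a presence; a use
absent from every language could never have been coded. Left
uncorrected, this biases rate estimation. Following the standard
conditional-likelihood correction for such ascertainment, the default
(`asc = "no_all_zero"`) divides each character's likelihood by
$1 - P(\text{all observed tips} = 0)$, with missing tips marginalized
inside the conditioning event. We condition on one excluded pattern, not
on the character being variable: all-present characters are legitimately
observable in ethnobotanical sources, so excluding the all-present
pattern too (`asc = "variable"`, also provided) would over-correct. The
correction cancels in the marginal-root ratio, so it affects root
probabilities only through the fitted rate; the flag used is echoed in
every run manifest.

### Rate estimation

Each character's rate is estimated by maximizing the corrected
log-likelihood over $\log q$ with a bounded golden-section search,
converged to $10^{-8}$ in $\log q$ and deterministic for fixed inputs.
The search interval spans three decades either side of one expected
event per tree height ($q \in [10^{-3}/T, 10^{3}/T]$, $T$ the mean root
height of the sample) — outside that range the likelihood surface is
flat to machine precision for trees this small. Boundary optima are
kept as such: an all-present character correctly drives $\hat q$ to the
lower bound with root probability approaching 1. All-absent characters
are skipped with a warning (they carry no signal, and are impossible
under the correction); all-missing characters are errors.

### Averaging over the posterior

Tree topology and branch lengths are themselves uncertain, so the rate
and root probability are re-fitted independently on every tree of the
posterior sample and the root probabilities averaged. Re-fitting per
tree (rather than sharing one rate across the sample) matches the
per-tree invocation of standard ancestral-state software over a tree
distribution, and lets topologically deviant trees speak with their own
best-fitting rate. Mean root probabilities are classified with
inclusive thresholds: `highly_likely` at $\ge 0.75$, `equivocal` in
$[0.45, 0.55]$, plus an `absent_leaning` call at $\le 0.25$ added for
reporting symmetry (it never affects the first two). For equivocal
characters a diagnostic asks whether the use is present in both clades
descending from the root — if so, basal conflict rather than simple
one-sided absence explains the ambiguity. Because topology varies
across the posterior, this is evaluated per tree and aggregated by
majority (> 50 % of trees, configurable).

### The Norwegian split

Norwegian ethnobotanical records are regionally localized, so the
Norwegian tip is split into northern and southern daughter tips.
`split_tip()` divides the pendant edge at a configurable fraction
(default 0.5): the daughters then share half the original terminal
branch. Zero-length daughters would force identical states at both tips
and defeat the purpose of the split; the chosen fraction is recorded in
the tree sample's provenance and the value only matters weakly (the
daughters' shared history is the same under any interior split point).

## Triangulation scoring

The archaeobotanical, historical and linguistic evidence lines are
coded as typed attributes and scored with a fixed rubric on the Likert
scale 1 (no evidence) to 5 (confirmed):

| line | 5 | 4 | 3 | 2 |
|---|---|---|---|---|
| archaeobotany | find with use-confirming context | — | find, context silent | — |
| historical | — | ≥ 2 unrelated sources | 1 source | — |
| linguistic | pre-Viking loan phonology | use-indicating name traceable to Old Norse | use-indicating name | name attested, no use signal |

The original assessment was expert-qualitative; reproducibility demands
a function, so the rubric above fixes a deterministic mapping that
preserves the stated orderings (context-confirmed finds are confirmed
evidence; more unrelated sources score higher; names traceable to Old
Norse score higher). An `override_score` column lets a curated table
record where expert judgment departed from the mechanical rubric. Lines
are combined by maximum — one confirmed line suffices — and a combined
score of $\ge 4$ is a positive triangulation verdict. Monotonicity
(adding evidence never lowers a score), determinism and range are
enforced by property tests over randomized tables.

## Concordance

`build_concordance()` joins the two verdicts per plant-use into four
agreement cells (`both_positive`, `pcm_only`, `triangulation_only`,
`neither`); combinations missing from either side, or skipped by the
model, are reported in an `unscored` bucket so the join is lossless.
Summaries are produced per general-use category (the nine
economic-botany codes: Agri, AnFood, Constr, Food, Fuel, IndCraft, Med,
SSR, Vet) and globally, with general/specific splits; a cross-check
counts how many model-positive uses are described in the historical
line (score $\ge 3$, i.e. at least one source — configurable).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed at the study conditions:

* **Trees**: 1000 pure-birth trees over the seven post-split Nordic
  tips (`Norwegian_North`, `Norwegian_South`, `Danish`, `Swedish`,
  `Elfdalian`, `Icelandic`, `Faroese`), each rescaled to a root height
  of 1 time unit with lognormal jitter (sd 0.1) to mimic posterior
  spread. Pure-birth is a shape model, not a claim about language
  diversification; real analyses pass an externally inferred posterior.
* **Traits**: 50 characters simulated forward under the same ER process
  used in inference, root state drawn from the equal prior, default
  $q = 0.5$ per unit height — a regime where tips retain signal about
  the root without being frozen copies of it.
* **Missingness**: the Elfdalian rule converts that tip's absences to
  missing (its documentation is too partial to trust a 0), plus
  optional per-language masking probabilities with a guard that never
  removes a character's last observed presence.
* **Evidence**: for characters truly present at the root each line
  fires with sensitivity 0.8; for absent ones with false-positive rate
  0.1. These are a one-time realism choice — field evidence is
  informative but far from perfect — and give end-to-end concordance
  tests a known truth to recover.

One seed fixes every draw; the four stages consume fixed offsets of it
so each is independently reproducible. What the generator does *not*
emulate: horizontal transmission (borrowing between neighbouring
languages), correlated evolution between characters, ecological
constraints on plant distribution, and collection bias beyond the
Elfdalian rule. Passing tests therefore show that the machinery
recovers truth under the model's own assumptions — not that real
cultural data satisfy those assumptions.

## Validation design

The test suite checks every likelihood quantity against brute-force
enumeration over all internal-state assignments on all rooted binary
shapes with up to six tips (tolerance $10^{-9}$), verifies pattern
normalization with and without the correction, matches the closed-form
transition matrix against a numerical matrix exponential, and asserts
the complement symmetry to $10^{-12}$. Statistical recovery is checked
at the package's chosen experiment sizes: pooled rate estimation from
500 characters on a fixed 7-tip tree (bias within 10 % across
$q \in \{0.2, 0.5, 1, 2\}$, ten seeded replicates each), and end-to-end
root-state recovery on twenty replicates of 1000 trees × 50 characters
at $q = 0.5$ (mean AUC above 0.7; observed ≈ 0.8). A fixed 12-species
evidence fixture exercises triangulation and concordance at desk scale.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 7, n_trees = 200, n_characters = 18)
trees <- simulate_trees(cfg)
sim <- simulate_traits(trees, cfg)
traits <- mask_missing(sim$traits, cfg)
est <- run_ase(trees, traits)
est
scores <- triangulate(simulate_evidence(sim$truth, cfg))
conc <- build_concordance(est, scores)
category_summary(conc)
```

The same chain is available file-to-file through `pipeline_simulate()`,
`pipeline_ase()`, `pipeline_triangulate()` and `pipeline_compare()`
(each writing a `manifest.json` with the package version, input digests
and every flag in force), or from a shell via
`inst/cli/norseplants.R`.

## Known limitations

* The model is a single-rate, two-state process on a tree: borrowing,
  rate heterogeneity across lineages, and hidden states are out of
  scope, and a use spread by contact can masquerade as ancestral.
* With six or seven tips, per-character rate estimates are noisy by
  construction; pooled or posterior-averaged summaries are the
  meaningful outputs.
* The triangulation rubric is an explicit formalization of orderings
  that were originally expert judgments; the override column exists
  precisely because no rubric reproduces every curated call.
* Root probabilities near the equivocal band are sensitive to the
  basal topology of the tree sample; the basal-clade diagnostic
  reports, but does not resolve, that sensitivity.
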