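---
title: "Variant prioritization states: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant prioritization states: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstates)
```

## The problem

Dozens of computational predictors score the deleteriousness of missense
variants, and they frequently disagree: a variant flagged by conservation
scores may be ignored by protein language models and vice versa.  Ensemble
methods collapse this disagreement into yet another univariate score.
`varstates` takes the opposite route: it treats the *pattern* of which
predictors prioritize a variant as the object of interest, and summarizes
those combinatorial patterns — together with their spatial organisation
along the coding sequence — as a small number of discrete
**prioritization states**, in the way chromatin-state models summarize
combinatorial patterns of epigenetic marks along the genome.

## The model

Each variant is described by $M$ rank-scaled scores in $[0,1]$
(1 = most damaging).  Each score is binarized: code 1 if the variant sits
in the top $Q\%$ of non-missing values for that score, code 0 otherwise,
code 2 if the score is missing.  A hidden Markov model with $K$ states
runs along each gene's sequence of variant positions.  State $s$ emits
feature $n$ as an independent Bernoulli with "present" probability
$p_{s,n}$; the emission likelihood of an observation row
$S = (S_1, \dots, S_M)$ is

$$ b_s(S) \;=\; \prod_{n=1}^{M}
   p_{s,n}^{\,[S_n = 1]} \,(1 - p_{s,n})^{\,[S_n = 0]}, $$

with missing features ($S_n = 2$) contributing a factor of 1 — no
evidence for or against.  The same convention governs training: a missing
cell is excluded from both the numerator and the denominator of the
emission update.

Training is Baum–Welch over the per-gene sequences, with three deviations
from the textbook recipe that mirror chromatin-state practice at scale:

* **Gene subsampling** — each EM iteration may use a random subset of
  genes (`n_subsample`), which makes the per-iteration likelihood
  estimate noisy; training then runs for a fixed number of iterations and
  does not stop on likelihood decreases.
* **Pseudo-counts** — a constant (default 1 in the pipeline defaults) is
  added to every expected initial, transition and emission count before
  normalization, protecting rare states from degenerating under
  subsampling.
* **Restarts** — initialization is a seeded random draw (emissions
  uniform on $(0.2, 0.8)$, transition rows and initial distribution flat
  Dirichlet); with `n_restarts` the best full-data log-likelihood wins.

In exact mode (no subsampling, no pseudo-counts) the implementation is
plain EM and its log-likelihood trace is non-decreasing; the test suite
asserts this property, and checks posteriors and likelihoods against
exhaustive path enumeration for small models.

## Assigning states to variants

A genomic position can host up to three alternate alleles, but a Markov
chain wants one observation per position.  Training therefore picks one
variant per position at random.  At annotation time every variant gets
its own call through *local combinations*: for a target variant, take up
to $k$ positions on each side within the gene (default $k = 3$), draw one
random variant for each flanking position while keeping the target fixed,
run forward–backward on the little window as a standalone chain started
from the model's initial distribution, and record the
maximum-posterior state at the target.  Repeating this $N$ times (default
$N = 9$) and taking the mode gives the final call; mode ties are broken
uniformly at random, while argmax ties inside a single window go to the
lowest state index so that only the mode step is stochastic.

Two design points deserve justification:

* **Windows never cross gene boundaries.** Training sequences are
  per-gene, so positions in different genes are not neighbours in any
  chain the model ever saw.
* **Posterior decoding, not Viterbi.** The per-position maximum-posterior
  state is the quantity being voted on; a most-likely *path* is never
  needed.

The contribution of spatial context can be isolated by re-annotating with
the same emissions but uniform transitions ($1/K$ everywhere).  Under
uniform transitions the posterior at a position collapses to a function
of that position's own emission likelihood, so the annotation becomes a
per-row classifier — the package tests this factorization exactly — and
segments of consecutive same-state variants become shorter, which the
segment-length comparison (one-sided Mann–Whitney U) quantifies.

## Characterization and evaluation

States are profiled three ways: by which scores rank them in their top
five emissions (states prioritized by many, some, few or no scores, the
basis of the four-group summary in `summarize_states()`); by fold
enrichment of their variants for external interval annotations,
$(B_{s,a}/B_s)/(B_a/B_{\mathrm{total}})$ with all annotated variants as
the default background; and by amino-acid substitution preferences,
within-state substitution proportions minus the overall proportions.

Whether the states carry information *beyond* any single score is tested
with paired models: a logistic regression of a pathogenic/benign label on
the score alone versus the score plus $K-1$ one-hot state indicators
(cross-validated with stratified folds, pooled out-of-fold predictions,
one overall AUROC per feature set), and the analogous linear-regression
comparison for continuous deep-mutational-scanning measurements scored by
Spearman correlation.  The $K-1$ + intercept parameterization fits the
same probabilities as $K$ unpenalized indicators but keeps the design
matrix full-rank; no regularization is applied, identically for both
feature sets so the comparison is fair.  Rows missing the evaluated score
are dropped per score and counted.

## The synthetic data generator

Everything above is testable without downloads because the generator
produces data whose truth is known: a separable ground-truth model
(features partitioned round-robin across states, own features emitted
with probability ≈ 0.8, others ≈ 0.05, transitions with a configurable
diagonal "stickiness"), gene-structured variant tables sampled from it,
interval annotations marking chosen states' footprints, and labels/DMS
measurements with explicit per-state effects (`b_state`, `d_state`), so
null and power cases for the paired evaluations are both constructible.

One generator choice is deliberate and worth explaining.  Scores for
"present" cells share the column maximum (1.0), while "absent" cells are
uniform below a band gap.  A strict top-$Q\%$ binarizer codes exactly
$\lceil Q/100 \cdot n \rceil$ cells as 1 when values are distinct, and a
random Bernoulli bit pattern almost never realizes exactly that count —
so continuous disjoint bands cannot reproduce the bits exactly.  Massing
the present cells at the maximum engages the binarizer's tie rule (more
than $Q\%$ tied at the top are all coded 1), which recovers the simulated
bits exactly whenever each feature's present count reaches the top-$Q\%$
count; the generator warns when a column falls short.  This is not just a
trick: saturated rank-scaled scores are a real phenomenon — score QC
exists precisely because some predictors leave the majority of variants
tied at the maximum — and the tie rule is the pipeline's documented
answer to it.

What the generator does **not** emulate: realistic gene models or
codon-accurate amino-acid consequences, correlation between scores beyond
what the shared state induces, position-dependent missingness, or
class-imbalanced clinical label sets.  Passing tests therefore
demonstrate correctness of the algorithms under the model's own
assumptions, not performance claims about real variant databases.

## Defaults, numerical choices and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| `Q` | 10 | top percent of a score coded as "present" |
| `k` | 3 | flanking positions per side in a local window |
| `N` | 9 | local combinations voted over |
| `pseudocount` | 1 (pipeline), 0 (exact mode) | added to every expected count |
| `n_subsample` | `"all"`; 2000 genes for large corpora | genes per EM iteration |
| `max_iterations` | 200 | EM iteration cap |
| `convergence_delta` | 1e-3 | full-batch early-stopping threshold |
| `n_restarts` | 3 (pipeline) | random restarts, best full-data log-likelihood kept |
| stickiness | 0.7 | diagonal transition mass in the generator |
| missing rate | 0.1 | per-cell missingness in the generator |

Numerics: forward–backward uses per-position scaling constants rather
than log-space recursions; the constants sum to the log-likelihood and
sequences of $10^5$ positions do not underflow.  Emission probabilities
of exactly 0 or 1 are admitted in the likelihood through clamped
logarithms.  A zero-probability sequence raises an error rather than
returning NaN.  Argmax ties break to the lowest state index; all other
tie-breaking and every random draw flows through an explicit seed, and
every pipeline stage is byte-reproducible given one.

The reference problem size used throughout the tests and the acceptance
script is 4 states x 8 scores over 300 genes of 80 positions each
(~48,000 variants, ~24,000 unique positions), which trains in seconds and
annotates in under a minute per model.  At that size, 3-restart training
recovers the generating emissions and transitions to mean absolute errors
well below 0.05 after Hungarian state matching.

## Limitations

HMM states are identifiable only up to relabeling, so all recovery
statements are post-matching; with strongly overlapping emission rows the
matching itself becomes ambiguous.  Binarization discards within-quantile
score information by construction.  The local-combination vote is an
approximation to the mode over all possible per-gene variant selections;
its fidelity degrades for very small `N` or genes with extreme allele
multiplicity.  The model assumes conditional independence of scores given
the state — correlated predictor errors within a state are absorbed into
extra states rather than modelled.  `residuals()` is deliberately not
provided: a discrete-state model over ternary codes has no natural
residual, and posterior state probabilities (`predict(type =
"posterior")`) are the honest diagnostic.
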