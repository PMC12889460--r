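# varstates

Discrete **variant prioritization states** for missense variants, learned
from the combinatorial patterns in which many pathogenicity predictors
prioritize (or ignore) the same variants.

Dozens of missense predictors — conservation scores, supervised
ensembles, protein language models — disagree with each other routinely.
Rather than collapsing them into one more univariate ensemble score,
`varstates` models the *pattern* of prioritization: each score is
binarized (top *Q*% of variants = "present"), and a multivariate
Bernoulli-emission hidden Markov model with *K* states is trained over
per-gene sequences of variant positions.  Each state *s* is a vector of
per-score "present" probabilities $p_{s,n}$, with emission likelihood

$$ b_s(S) = \prod_{n=1}^{M} p_{s,n}^{[S_n=1]} (1-p_{s,n})^{[S_n=0]}, $$

missing scores ($S_n = 2$) contributing no evidence, and a $K \times K$
transition matrix capturing spatial context along the gene.  After
training (Baum–Welch with optional gene subsampling, pseudo-counts and
random restarts), every variant is assigned a state by sampling local
windows around it, running the forward–backward algorithm on each, and
taking the mode of the per-window posterior argmax calls.  This mirrors
the chromatin-state approach to genome segmentation, transplanted onto
protein-coding variants.

The package is for computational geneticists who want to
train/inspect such models on score tables (dbNSFP-style TSVs), assign
states, characterize them (interval enrichments, amino-acid substitution
preferences, cross-model matching), and quantify the *complementary*
predictive information states add to any single score on labeled variant
sets and deep-mutational-scanning (DMS) measurements.  A self-contained
synthetic-data generator with known ground truth makes everything
testable offline.

## Worked example

```r
library(varstates)

truth <- simulate_model(K = 4, M = 8, stickiness = 0.7, seed = 1)
sim   <- simulate_dataset(truth, n_genes = 60, positions_per_gene = 50,
                          missing_rate = 0.1, Q = 10, seed = 2)
sim
#> Synthetic variant dataset: 5980 variants, 60 genes, K = 4, M = 8, Q = 10

seqs <- build_training_sequences(sim$table, sim$codes, seed = 3)
fit  <- fit_hmm(seqs, K = 4, pseudocount = 1, n_restarts = 3, seed = 4)
fit
#> Multivariate Bernoulli HMM (varhmm)
#>   states (K):   4
#>   features (M): 8
#>   fitted on 60 sequences; log-likelihood -8403.2255 after 17 EM iterations

match_states(truth, fit)[c("permutation", "emission_mae", "transition_mae")]
#> $permutation
#> [1] 2 1 3 4
#> $emission_mae
#> [1] 0.009556
#> $transition_mae
#> [1] 0.01197
```

The fitted emissions recover the generating parameters to ~0.01 mean
absolute error (states matched by Hungarian assignment on emission
correlations, since HMM state labels are arbitrary).  Annotation and the
uniform-transition contrast:

```r
ann <- annotate_variants(fit, sim$table, sim$codes, k = 3, N = 9, seed = 5)
ann
#> State annotation of 5980 variants in 60 genes
#>   segments: 1183, mean length 5.055 variants

cmp <- compare_assignments(
  ann, annotate_variants(uniformize_transitions(fit), sim$table,
                         sim$codes, seed = 5))
round(cmp$variant_switch_fraction, 3)          # 0.058
round(cmp$segments_b$mean_length, 2)           # 3.68
format(cmp$segment_length_p, digits = 3)       # "3.56e-13"
```

About 6% of variants change state when spatial context is removed
(uniform transitions), and same-state segments shrink from a mean of 5.1
to 3.7 variants — the one-sided Mann–Whitney U test confirms the sticky
model's segments are stochastically longer.  Downstream,
`fold_enrichment()` profiles states against BED annotations,
`substitution_preferences()` against amino-acid changes, and
`paired_classification_eval()` / `paired_regression_eval()` measure the
AUROC / Spearman gain from adding one-hot state indicators to a single
score.

A command-line front end (`exec/varstates`) exposes the pipeline as
subcommands: `simulate`, `binarize`, `learn`, `annotate`, `enrich`,
`summarize`, `compare-models`.

See `vignettes/prioritization-states.Rmd` for the model's assumptions,
the generator's design and known limitations.

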