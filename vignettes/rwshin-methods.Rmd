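---
title: "Signed heterogeneous network embeddings for drug side-effect prediction"
author: "rwshin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed heterogeneous network embeddings for drug side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwshin)
```

# The problem

Most computational side-effect predictors describe a drug by *which*
targets it binds and *which* substructures it contains. But two drugs can
hit exactly the same receptors with opposite pharmacology — a beta-blocker
and a beta-agonist share their targets while causing very different
adverse events. `rwshin` encodes the *mode of action* (agonist-like vs
antagonist-like) as the **sign** of a drug–target association and learns
drug embeddings from a signed heterogeneous information network (HIN), so
that mode-discordant drugs are pushed apart even when their unsigned
profiles are identical.

# The model

## Network construction

Four drug–drug subnetworks share one drug universe:

* three **unsigned** subnetworks (chemical fingerprints, known
  side-effects, target sets), with edge weight the Jaccard similarity of
  the binary profile vectors,
  $w^u_{ij} = |P_i \cap P_j| / |P_i \cup P_j|$;
* one **signed** subnetwork from the signed association matrix
  $A \in \{-1, 0, +1\}^{m \times n}$ (rows drugs, columns targets, sign
  from the action mode via the packaged `actionModeTable()`), with

$$w^s_{ij} = \frac{\sum_k a_{ik} a_{jk}}{\sum_k |a_{ik} a_{jk}|},$$

which is $+1$ for fully mode-concordant pairs, $-1$ for fully discordant
pairs, and $0$ when no target is shared. As printed in its source the
numerator and denominator of this ratio coincide; the absolute-value
denominator used here is the only reading compatible with the stated
range $[-1, 1]$ and the $\pm 1$ boundary cases, and is what
`signedWeight()` implements.

Whether the signed structure is *usable* is an empirical question:
`triadCensus()` classifies every closed triangle by its sign multiset
(T1 $+\!+\!+$, T2 $-\!-\!+$, T3 $+\!+\!-$, T4 $-\!-\!-$). When the
balanced classes T1 and T2 dominate, "an enemy's enemy is a friend"
holds and the signed walk below is justified.

## Random walks

**Signed subnetwork.** The walker never crosses a negative edge.
From node $s$ it either hops to a friend $h \in F(s)$ with unnormalized
score $p\,w_{sh}/\sum_{i \in F(s)} w_{si}$, or jumps to an *enemy's
enemy* $h$ (some $k \in E(s)$ with $w_{kh} < 0$, $h$ not adjacent to
$s$, $h \neq s$) with score
$q\,|w_{sk}||w_{kh}| / (\sum_{i\in F(s)} |w_{si}| \sum_{j \in E(k)} |w_{kj}|)$,
summed over qualifying intermediaries $k$. The jump is additionally
gated by a common-neighbor similarity $l_s(s,h) > 0$ that adds the
weights of shared friends and shared enemies and subtracts mixed
friend/enemy overlap (`commonNeighborSimilarity()`). As printed, two of
the four overlap sums in the source's similarity formula range over the
same set with opposite signs and would cancel; the implementation reads
the second sum as the common-enemy term, which is the only reading
consistent with the accompanying prose, and uses absolute weights on
the negative-edge terms so every term contributes with its intended
sign.

**Unsigned subnetworks.** A second-order kernel with BFS/DFS biases:
given previous node $t$ and current node $s$, neighbor $h$ scores
$\alpha\,w_{sh}$ when $h$ is adjacent to $t$ or equals $t$, and
$\beta\,w_{sh}$ otherwise (`unsignedTransition()`). The immediate
backtrack $h = t$ is treated as a distance-zero (BFS) move, mirroring
the return-parameter convention of node2vec-style walkers.

Both kernels are renormalized over the candidate set: for arbitrary
$p, q, \alpha, \beta$ the two-branch scores do not form a distribution
on their own. When $F(s) = \emptyset$ the friend normalizer is a common
factor of all remaining scores and is set to 1 before renormalization.
Dead ends terminate a walk early (no restart); length-1 walks stay in
the corpus and are harmless to training. Walks use one private
deterministic random stream per (seed, subnetwork, start node, walk
index), so a corpus is reproducible and independent of generation order.

## Embedding and prediction

`trainSkipgram()` maximizes the Skip-gram context likelihood over the
pooled corpus with negative sampling (unigram$^{0.75}$ noise), fixed
symmetric window that never crosses walk boundaries, linearly decaying
learning rate, single-threaded so results are bitwise reproducible.

Each side-effect term is predicted independently by L2-regularized
logistic regression on the embeddings,
$\min_{w,b} \sum_i \mathrm{Cost}(y_i, \sigma(z_i w + b)) + \lambda \lVert w\rVert^2$,
solved by damped Newton iterations to gradient norm $10^{-6}$
(`fitSideEffectClassifier()`; the intercept is not penalized).
`crossValidate()` evaluates under drug-wise 5-fold cross-validation and
`mergedRocAuc()` pools all (drug, term) scores into one ROC curve.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p`, `q` | 1, 1 | friend-hop vs enemy's-enemy propensity (signed walk) |
| `alpha`, `beta` | 1, 1 | BFS vs DFS propensity (unsigned walk) |
| `walksPerNode`, `walkLength` | 10, 80 | corpus size per subnetwork |
| `dim` | 32 | embedding dimension; 32 was the reported optimum of the original study |
| `window` | 5 | Skip-gram context radius (tokens) |
| `epochs`, `negative`, `lr` | 5, 5, 0.025 | SGD passes, noise samples per pair, initial learning rate |
| `lambda` | 1 | ridge penalty of the per-term classifiers |
| `threshold` | 0 | Jaccard sparsification; 0 keeps every positive-similarity edge |

The original study tuned its walk and regularization parameters by grid
search but never printed the selected values; the defaults above are
standard choices for node2vec/word2vec-scale problems and are all
configurable. Windows, epochs and negative-sample counts follow common
word2vec practice; $d = 32$ and 5-fold drug-wise CV follow the reported
protocol.

# Cross-validation without leakage

The gold-standard labels double as the side-effect *profile*, which is
itself a feature source (one of the four subnetworks). The evaluation
therefore rebuilds the side-effect subnetwork **per fold from training
drugs only**: held-out drugs' side-effect rows are zeroed before network
construction, so their label information cannot reach their own
features. Held-out drugs remain nodes of all four subnetworks (via
chemistry, targets and signs), so they still receive embeddings. A test
asserts that corrupting a held-out drug's labels leaves the fold's
side-effect subnetwork bit-identical. Terms with fewer than two training
positives in a fold are skipped and scored at the uninformative 0.5.

Fold assignment is a seeded uniform shuffle followed by a contiguous
split (sizes equal up to a remainder of one). Top-K ranking breaks score
ties by ascending side-effect id, making hit counts deterministic.

# The synthetic stated world

Real pharmacovigilance inputs cannot be redistributed, so
`generateBundle()` plants the structure the method is designed to
exploit: 120 drugs in 6 groups; each group owns a 10-target block and a
fingerprint-bit block (bits flipped with probability 0.1); **half of
each group acts with inhibitory (−1) modes** on the group targets while
the other half activates (+1); side-effect blocks are assigned per
(group, sign) class with per-term base rates drawn from a long-tailed
distribution (cubed-uniform), then flipped with probability 0.05. Within
a group the *unsigned* target profiles are identical — only the sign
separates the two pharmacological classes, exactly the
beta-blocker/beta-agonist situation that motivates the method.

What a green end-to-end test establishes: the signed walk + Skip-gram
pipeline extracts planted sign structure that the unsigned ablation
(`unsignedOnly = TRUE`) cannot, and permuted labels yield chance-level
AUROC. What it does not establish: performance on real DrugBank/SIDER
marginals (hub drugs, mode-record sparsity, correlated side-effect
terms, 548/1385/780-scale dimensions), which the generator does not
imitate.

# Numerical choices and degenerate inputs

* Two all-zero binary profiles have Jaccard weight 0 (no edge), and a
  drug pair with no shared target has signed weight 0 (no edge).
* Edge signs are strict zero-threshold comparisons of the stored double
  (weights are ratios of small integers; no epsilon needed).
* Transition probabilities must sum to 1 within $10^{-9}$; the samplers
  consume the exact renormalized kernels, and a chi-squared test checks
  20,000 sampled hops against them.
* Unknown action-mode labels map to 0 with a warning by default
  (`strict = TRUE` errors): the packaged 36-label vocabulary is unlikely
  to be exhaustive for arbitrary inputs. A +1/−1 conflict within one
  (drug, target) pair errors by default (`conflict = "zero"` overrides);
  how such conflicts were resolved originally is unstated.
* Multiple enemy intermediaries $k$ for one terminal $h$ pool
  additively; per-terminal pooling is a design choice the source leaves
  open.
* The walk corpus pools all four subnetworks and trains one joint
  Skip-gram model; training per subnetwork and averaging would be an
  alternative the source does not specify.

# Known limitations

* Embedding training is $O(\text{tokens} \times \text{window} \times
  (1 + k_{neg}) \times d)$ single-threaded; corpus sizes beyond a few
  million tokens call for the (deliberately absent) multi-threaded path.
* No inner-CV tuning of `lambda` is performed by default; the grid
  search described for the original protocol is left to the caller.
* Dense weight matrices limit graphs to a few thousand drugs; this
  matches the intended scale (hundreds of drugs).
* The per-term classifier is exactly the regularized logistic layer; no
  deeper network variants are provided.

# Worked example

```{r example, eval = FALSE}
bundle <- generateBundle(syntheticSpec(seed = 1))
tab <- crossValidate(bundle$chemical, bundle$target, bundle$assoc,
                     bundle$labels, seed = 1)
mergedRocAuc(tab)$auroc
tabU <- crossValidate(bundle$chemical, bundle$target, bundle$assoc,
                      bundle$labels, seed = 1, unsignedOnly = TRUE)
mergedRocAuc(tabU)$auroc
```

On this bundle the signed pipeline reaches a merged AUROC well above the
unsigned ablation (see the package tests, which run exactly this
comparison over five seeds); the gap is the value of the sign
information in a world where it matters.
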