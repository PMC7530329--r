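---
title: "Inferring lncRNA-mRNA ceRNA networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-mRNA ceRNA networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The problem and the model

Competing endogenous RNAs (ceRNAs) regulate each other post-transcriptionally
by competing for a shared pool of miRNAs: a lncRNA that binds the same miRNAs
as an mRNA can de-repress that mRNA by sponging their common regulators.
`cernet` infers candidate lncRNA-mRNA ceRNA pairs from two kinds of evidence
and then prioritizes the lncRNAs most likely to matter in disease:

1. **Shared-miRNA evidence.** For a lncRNA with $n$ miRNA partners and an
   mRNA with $t$ partners in a universe of $m$ miRNAs, the probability of
   observing at least $r$ shared partners by chance is the upper
   hypergeometric tail
   $$P = 1 - \sum_{i=0}^{r-1} \frac{\binom{t}{i}\binom{m-t}{n-i}}{\binom{m}{n}}.$$
   Pairs are tested only when they are differentially expressed in the
   paired tumor/normal comparison *and* share at least one miRNA; a pair
   with $r = 0$ cannot be a ceRNA pair and its $P$ is identically 1, so
   including such pairs would only dilute the FDR correction.
   Benjamini–Hochberg correction across all scored pairs and a strict
   `adjusted p < 0.01` cut give the bipartite ceRNA network (the "LCLMN"
   in the lung-cancer setting that motivated the package).

2. **Expression evidence.** Differential expression uses the paired SAM
   score $d = \bar{z} / (\mathrm{se}(z) + s_0)$, where $z$ is the vector of
   per-pair tumor-minus-normal log2 differences and $s_0$ is a fudge
   constant that prevents near-zero-variance transcripts from dominating
   the ranking. Significance comes from a sign-flip permutation null pooled
   across transcripts, followed by Benjamini–Hochberg correction. Screening
   of network edges by co-expression uses the Pearson correlation of log2
   values with the exact $t$-transform p-value, retaining pairs with
   `r > 0.6` and `p < 0.05` (both strict).

Candidate lncRNAs are then prioritized two ways: by the overlap of the
top-$k$ nodes under degree, betweenness and closeness centrality, and by a
random walk with restart (RWR) from disease seed genes,
$$p^{t+1} = (1-r)\,W\,p^t + r\,p^0,$$
with $W$ the column-normalized adjacency matrix, $p^0$ uniform over the
seeds and restart probability $r$. Each candidate's empirical significance
is the fraction of permutations in which a randomly re-seeded walk scores it
strictly higher than the observed walk.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `perfect_match_length` | 60 nt | probe alignment length counted as a perfect match (the array's probe length); identity must also be 100% |
| `de_alpha` | 0.01 | adjusted-p cut for differential transcripts |
| `pair_alpha` | 0.01 | adjusted-p cut for hypergeometric ceRNA pairs |
| `s0` | 5th percentile of the per-transcript standard errors | SAM fudge constant |
| `sam n_perm` | 1000 | sign-flip permutations (minimum 100) |
| `k` | 10 | top-k per centrality dimension before intersecting |
| `r` (restart) | 0.5 | RWR restart probability |
| `tol` | 1e-10 | L1 convergence threshold of the walk |
| `rwr n_perm` | 5000 | permutations behind each lncRNA's empirical p |
| `r_min`, `p_max` | 0.6, 0.05 | co-expression screen (strict inequalities) |

Two conventions deserve comment because they are genuinely open choices:

* **Partner counts are global.** $t$, $n$ and $r$ are counted on the full
  background network while candidate pairs are restricted to differential
  genes. Since the universe $m$ is global (by default the number of
  distinct miRNAs in the merged input tables, overridable via
  `m_universe`), counting partners on the same global footing keeps the
  test internally consistent. Passing the DE subnetwork as `global_net`
  switches to DE-restricted counting.
* **The probe-support criterion counts surviving probes.** A transcript
  needs more than three supporting probes *after* the cross-class and
  multi-target removals, read strictly as $\geq 4$. Counting before those
  removals would credit transcripts with ambiguous probes; the stricter
  reading is implemented.

## Numerical choices

* The hypergeometric tail is evaluated with the numerically stable
  distribution-function implementation rather than naive summation of
  binomial coefficients; the test suite checks it against exhaustive subset
  enumeration for every $(t, n, r)$ with $m \le 12$ to $10^{-12}$.
* SAM permutations exploit the fact that sign flips leave each transcript's
  sum of squares unchanged, so only the flipped means are recomputed; the
  permuted scores are exactly those of a full recomputation.
* Raw permutation p-values pool the null across transcripts (standard SAM
  practice; it stabilizes tail estimates), and the empirical tail uses
  $\geq$, so a transcript larger than every null value gets $p = 0$.
* Betweenness and closeness are **unnormalized**, exactly as their
  reciprocal-sum / path-count definitions read: no $(n-1)(n-2)/2$ or
  $(n-1)$ rescaling. On disconnected graphs closeness sums distances over
  the reachable set only and betweenness accumulates within components;
  the defining formulas are otherwise undefined there.
* Ranking ties at position $k$ are all included (cutting an arbitrary
  subset of tied nodes would make the overlap depend on sort order);
  reported sets are sorted lexicographically for determinism.
* RWR convergence is measured in the L1 norm; since $W$ is column
  stochastic and $p^0$ sums to one, every iterate conserves probability
  mass, which the tests verify. A `max_iter` of 10000 bounds the loop.
* The permutation p-value `m/n` uses strict exceedance with no
  pseudo-count, so `perm_p = 0` is reachable for a candidate that
  dominates every permutation.
* RWR randomization defaults to redrawing pseudo-seed sets of equal size
  uniformly without replacement from the mRNA nodes, which keeps the
  topology untouched; a degree-preserving edge-rewiring null
  (`scheme = "rewire"`) is available as the alternative reading of
  "randomize while maintaining topological properties".
* Co-expression is computed over all samples (tumor and normal pooled) by
  default — the `samples` argument restricts to a subset — and correlation
  p-values are deliberately *not* multiplicity-corrected, mirroring the
  stated `r > 0.6, p < 0.05` rule.
* Probe-level expression collapses to transcripts by the per-sample
  median, which tolerates one aberrant probe among the $\ge 4$ supporting
  ones.

## What the synthetic generator emulates

The generator ([sim_config()], [simulate_expression()],
[simulate_interactions()], [simulate_probe_hits()]) produces inputs with the
statistical structure the pipeline assumes, plus a ground-truth log for
validation:

* **Expression.** Log-normal microarray-like intensities: log2 values are
  baseline $\mathcal{N}(6, 1)$ + condition shift + per-pair random
  intercept (SD $= 0.5 \times$ `noise_sd`, giving the paired statistic its
  advantage over an unpaired analysis) + Gaussian noise. Exactly
  `round(frac_de * n)` transcripts are shifted by $\pm$`de_effect`, split
  evenly up/down.
* **Planted ceRNA pairs** are drawn from the differential truth sets (so
  they survive the DE-mapping stage); each pair adds `shared_mirna_boost`
  common miRNAs on top of background partners sampled per gene-miRNA with
  probability `background_degree / n_mirna`.
* **Planted co-expression.** Pair members share their shift direction and
  a latent component that is constant within each tumor/normal pair —
  shared variation rides on the paired structure rather than fighting it,
  so the paired differences (and hence the SAM scores) are untouched. The
  latent's scale is chosen so the population correlation of log2 values
  across all samples equals `coexpr_r`; when the shared condition shift
  alone already induces more correlation than requested, that floor is
  reported behavior rather than an error.
* **Probe hits** form a fixed boundary-case battery (single-target probes,
  cross-class probes, within-class multi-target probes, 3-vs-4 supporting
  probes, 59-vs-60 nt matches, sub-100% identity) with the intended
  filtering outcome attached, so the filter can be checked exactly.

The defaults — 20 tumor/normal pairs, 50 lncRNAs, 300 mRNAs, 200 miRNAs,
20% differential transcripts at a log2 effect of 2 over noise SD 0.5, 30
planted pairs boosted by 8 shared miRNAs over a background degree of 5,
planted correlation 0.9 — are the conditions under which the validation
suite runs. Oracle checks use deliberately small problems (graphs of up to
200 nodes for the RWR fixed point, up to 40 for brute-force centralities,
2000 transcripts by 10 pairs for the null SAM calibration, 200-permutation
nulls replicated 20 times) so the whole suite completes in well under a
minute per property.

What the generator does **not** emulate: scanner artifacts, dye bias,
normalization residue, real probe sequences, correlated miRNA target sets
(targets are sampled independently per gene), hub-heavy degree
distributions of real interactomes, or negative (repressive) co-expression.
Passing tests therefore demonstrate that the machinery recovers structure
it is designed to detect under clean conditions — not that any particular
biological dataset will yield comparable precision.

## Known limitations

* The miRNA universe defaults to the supplied tables' union; with sparse
  custom tables this understates $m$ and makes the test conservative
  relative to using a full database count (override with `m_universe`).
* Seed genes absent from the network are dropped with a warning; if a
  disease gene panel barely intersects the network, the walk's resolution
  suffers accordingly.
* The permutation p-values are granular at $1/n_{\mathrm{perm}}$; with the
  default 5000 permutations the smallest nonzero p is 0.0002.
* Functional enrichment, survival analysis and visualization are out of
  scope; networks are exported as SIF/GraphML for Cytoscape instead.
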