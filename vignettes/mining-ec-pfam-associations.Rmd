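---
title: "Mining EC-Pfam associations: model, calibration and design notes"
author: "ecpfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining EC-Pfam associations: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecpfam)
```

# The model

`ecpfam` treats domain-level function assignment as a content-based
filtering problem. Two item types — 4-digit Enzyme Commission numbers
and Pfam domains — are never observed together directly; they are linked
through a shared attribute, the non-redundant cluster (CID) of
100%-identical protein chains or sequences on which both kinds of
annotation live. Each EC number and each Pfam domain is a binary
indicator vector over a source's CIDs, and the raw association score of
a pair is the cosine of its two vectors,

$$S_i(ec, d) \;=\;
  \frac{|\mathrm{CIDs}(ec) \cap \mathrm{CIDs}(d)|}
       {\sqrt{|\mathrm{CIDs}(ec)|}\,\sqrt{|\mathrm{CIDs}(d)|}},$$

computed for all pairs at once as the product of a row-normalised EC×CID
matrix and a column-normalised CID×Pfam matrix (sparse `Matrix`
triples). Four sources of very different reliability are combined into a
single confidence score by a weighted average,

$$CS_{ec,d} \;=\; \frac{\sum_i w_i\, S_i(ec,d)}{\sum_i w_i},$$

with $S_i = 0$ wherever a source has no data for the pair. The score is
therefore bounded in $[0,1]$, monotone in every per-source score, and
invariant under duplication of identically annotated clusters — the
reason annotations are collapsed to CIDs in the first place.

Key modelling assumptions:

* **Co-occurrence carries signal.** A domain that genuinely provides an
  activity appears on most clusters annotated with that activity, and
  the activity appears on most clusters carrying the domain. Accessory
  (non-catalytic) domains fail on the second count: their carriers are
  overwhelmingly not annotated with any one EC number, which dilutes the
  cosine's denominator.
* **The candidate universe is the co-occurrence universe.** Only pairs
  sharing at least one CID in at least one source are scored; all-zero
  rows or columns cannot be normalised and produce no candidates. Pairs
  absent everywhere are treated as having $CS = 0$ wherever a score is
  needed.
* **Identity clustering, not similarity clustering.** A few point
  mutations can change substrate specificity (the 4th EC digit), so
  pooling merely similar sequences would blur exactly the distinction
  the 4-digit level encodes.

# Calibration

**Weights.** Each $w_i$ is varied over $\{0, 0.1, \ldots, 1\}$ and every
combination except all-zero is evaluated by the area under the ROC curve
of the curated positive training pairs ranked against the *background* —
all scored candidates minus the training positives. AUC is computed by
the Mann–Whitney identity with midrank ties (identical to trapezoidal
ROC area; the suite cross-checks against `pROC`). Because $CS$ is
invariant under rescaling of the weight vector, many grid points tie
exactly; ties are broken toward the lexicographically smallest tuple in
the fixed source order (SIFTS-like, SwissProt-like, TrEMBL-like,
UniRule-like), which makes calibration deterministic and testable.

Two documented consequences of the background definition: reference
pairs *not* sampled into the training half (including the held-out test
half) remain in the background, so the attainable AUC has a structural
ceiling below 1 even for a perfect ranker; and the grid search measures
only ranking quality, so sources whose noise never outranks a positive
exert little gradient — the synthetic generator deliberately includes
structures (curated-only families, systematic transfer errors) that make
source quality matter.

**Threshold.** The acceptance threshold on $CS$ scans $\{0, 0.01,
\ldots, 1\}$ for the best F-measure on the labelled training half
(equal numbers of positives and sampled negatives), with
$R = TP/(TP+FN)$, $P = TP/(TP+FP)$, $F = 2RP/(P+R)$ and $F = 0$ when
$P + R = 0$. Acceptance is the closed condition $CS \ge t$, so the
selected grid value itself accepts; ties go to the smallest threshold.
Negative pairs are produced by independently permuting the CID columns
of one source's EC–CID and Pfam–CID lists and rejecting anything that
genuinely co-occurs in any source or appears among the positives. A
direct consequence worth knowing: since every sampled negative then has
$CS = 0$ exactly, the optimal threshold on a cleanly separable training
set is the smallest positive grid value (0.01). The threshold's real
work is done by the *magnitude* of the scores — e.g. accessory domains
must score below it — not by a finely tuned cut-point.

**Hierarchy rescue.** The whole calibration is repeated at the 3-digit
EC level (keys truncated, sibling support pooled, negatives regenerated
by shuffling at level 3 to avoid truncation collisions). Any scored
4-digit candidate below the 4-digit threshold whose (parent class,
domain) pair is accepted at level 3 is added to the final list with
provenance `rescued3`. Rescue never invents pairs: a 4-digit
co-occurrence must exist. This recovers enzymes whose specific substrate
variant has too few annotated clusters to stand on its own.

**Significance.** For each accepted pair and each source with support
for both labels, the upper-tail hypergeometric probability of the
observed joint support is computed (`stats::phyper`, the log-space
implementation; the suite verifies it against exhaustive enumeration of
all draws for $N \le 12$ and a seeded Monte-Carlo sampler for
$N \le 50$). The per-source level is Bonferroni-corrected, $0.05/T_i$
with $T_i$ the source's candidate-pair count, compared strictly
($p < \alpha$). Sources where either label is absent are non-evaluable
and excluded from the "all p-values significant" conjunction — the tail
is undefined there — and an association with no evaluable source is
never all-significant; this evaluability rule is a design choice, made
explicit here. Gold/Silver/Bronze classes then partition the accepted
set as described in the README.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `weight_step` | 0.1 | weight grid resolution (11 values per source) |
| `threshold_step` | 0.01 | F-measure scan resolution |
| `train_fraction` | 0.5 | reference split; equal train/test halves |
| `seed` | 1515 | drives negative sampling and the split; one seed, fully reproducible |
| `max_arity` | 4 | largest obligate tuple enumerated |
| `max_domains` | 25 | per-EC cap on domains enumerated for tuples (combinatorial guard) |

All scores are plain doubles; score equality in tests is asserted to
1e-12, and the package never compares floating-point scores for exact
equality internally except on the deterministic weight grid.

# Obligate tuples

For each EC number, subsets of size 2–4 of its accepted partner domains
are screened: a tuple is rejected if, in any source, some EC-annotated
CID carries a proper non-empty subset of it (the domains occur
separably), and reported if its support ratio — the fraction of the
source's EC-annotated CIDs carrying the whole tuple — equals 1 in at
least one evaluable source. Rejection is global across sources while
support is per source, so a tuple obligate in a small curated source
but separable in the bulk source is (correctly) discarded. The
proper-subset rejection rule for triplets and quadruplets is the
natural generalisation of the pair rule and is applied as such. Tuples
whose domain names contain both an "N-terminal" and a "C-terminal"
token are flagged as likely interface enzymes. By default all arities
are reported (a flag collapses to maximal tuples), and reporting is
restricted to domains in the final accepted set — unaccepted domains
never form tuples.

# The synthetic world

Real source databases are release-scale downloads, so validation runs on
a generated world (`world_spec()` / `generate_world()`) whose default —
200 EC numbers, 300 Pfam entries, 5000 clusters split over four sources,
5% base annotation noise, seed 7 — is the package's standard study
condition, small enough that the full pipeline (two calibrations of
14,641 weight combinations each) completes in seconds on one CPU.

The generator plants families of five architectural archetypes
(one-domain/one-function; two-domain/two-function chains also observed
as single-domain chains; one domain with two activities; a base domain
plus an interface/co-factor partner, which creates obligate pairs by
construction; and hierarchy families of sibling enzymes sharing one
domain across serial digits, some with a sparsely annotated sibling that
only 3-digit rescue can recover). Around them it adds enzyme-free
clusters with decoy domains, accessory domains that ride on enzyme-free
chains everywhere and on widespread families in the bulk source — never
on *all* chains of a family, since an accessory domain is precisely one
the activity does not require — and per-source noise: annotation drops,
stray annotations, and systematic transfer errors that propagate one
wrong EC across a whole family. Noise draws copy annotations already
common in the source rather than inventing unseen ones, which is how
real mis-transfer behaves. Source reliability is modelled structurally:
the curated sequence source is noise-free but misses nothing; the
rule-based source only covers families with a curated rule (60%); the
bulk source is large, complete and three times noisier than the base
rate; the structure source is small. A configurable share of families
exists only in the curated source, mirroring newly curated enzymes that
have not propagated to the bulk databases — this is what gives the
weight calibration a genuine optimum rather than a flat surface.

The curated positive reference is a seeded 70% subsample of the planted
ground truth, excluding the rare hierarchy siblings (under-curated by
construction). Generation is a pure function of the spec: identical
specs give byte-identical TSV output.

What the world does *not* emulate — and hence what passing tests do not
show about real data: actual sequences and the behaviour of real
identity clustering; Pfam motifs/repeats and clan structure; the heavy
skew of real database growth (our cluster counts per family are
gamma-distributed, real ones are far more extreme); correlated errors
*between* sources (our sources err independently, SIFTS/UniProt
annotations share provenance in reality); and release-scale candidate
counts, so absolute counts from the synthetic study are not comparable
to database-scale results.

# Numerical and degenerate-input choices

* Empty datasets score to empty tables; labels with zero support are
  dropped before normalisation rather than dividing by zero.
* `combine_scores` requires a strictly positive total weight; the
  all-zero grid point is never evaluated.
* ROC and F computations refuse empty classes rather than returning
  conventional values.
* Negative sampling is rejection sampling over a bounded number of
  shuffle rounds (50) and reports the attainable count when a request
  cannot be met — on toy inputs the non-candidate space can be
  exhausted.
* `K = 0` co-occurrence gives a hypergeometric tail of exactly 1;
  invalid count configurations are errors, not NA.
* All user-facing randomness flows through explicit seeds, and package
  functions restore the caller's RNG state.

# Known limitations

* The weight grid is coarse by design (matching the calibration recipe);
  no continuous optimisation or cross-validation is attempted.
* With sampled negatives that never co-occur, the scanned threshold
  lands on the smallest grid value whenever training positives separate
  cleanly; on messier references the scan is doing real work.
* Obligate-tuple mining is exponential in the per-EC accepted domain
  count and therefore capped (default 25 domains); real promiscuous hubs
  would need the cap raised or the maximal-only mode.
* p-values are conditional on the candidate universe and are not
  adjusted across sources jointly; Bonferroni within source follows the
  method's design, not a claim of optimality.
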