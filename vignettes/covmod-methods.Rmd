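---
title: "Covariance-model RNA homology search: models, filters and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-model RNA homology search: models, filters and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covmod)
```

Structural RNAs conserve a base-paired secondary structure as well as a
sequence, and homology search tools that model both are substantially more
sensitive than sequence-only profiles. `covmod` implements the full stack of
such a search tool at desk scale: covariance models (profile stochastic
context-free grammars) built from structure-annotated alignments, a staged
profile-HMM filter pipeline, HMM-banded CYK/Inside scoring, E-value
calibration by simulated search, and a pseudo-genome benchmark harness.
This vignette is the package's own account of the underlying methods, the
parameters that matter, and the choices made where the design was open.

## The model

A covariance model (CM) is built from a `structured_alignment`: aligned RNA
rows plus a consensus secondary-structure line in bracket notation
(`parse_wuss()` accepts `<>`, `()`, `[]`, `{}` as equivalent pair brackets
and `.,:_-~` as unpaired; letter-coded pseudoknot layers are outside the
nested grammar and are dropped with a warning).

Model construction proceeds in four steps:

1. **Consensus columns** (`select_consensus_columns`): a column is a match
   column iff its fraction of residues is at least `gap_threshold`
   (default 0.5). A paired column whose partner is dropped survives as an
   unpaired match column.
2. **Guide tree** (`build_guide_tree`): each interval of consensus columns
   is consumed from the outside in — a pair spanning the interval gives a
   MATP node, an unpaired left end a MATL (the left option is always taken
   first when both ends are unpaired, which fixes the construction
   deterministically), an unpaired right end under a paired left end a
   MATR, and a left end paired inside the interval a BIF with BEGL/BEGR
   subtrees. Branches end in END nodes.
3. **State layout** (`layout_states`): ROOT expands to {S, IL, IR}, MATP to
   {MP, ML, MR, D, IL, IR}, MATL to {ML, D, IL}, MATR to {MR, D, IR}, BIF
   to {B}, BEGL to {S}, BEGR to {S, IL}, END to {E}. Transitions connect a
   node's split and insert states to its own later inserts and the next
   node's split states; B connects to its two BEG children with
   probability one.
4. **Parameterization** (`parameterize`): every row is traced through the
   guide tree — residues in match columns feed MP/ML/MR emission counts,
   gaps feed D, residues in non-consensus columns feed the insert state
   that owns the surrounding inter-column slot (outer nodes claim slots
   first), and the induced state path feeds transition counts. Laplace
   pseudocounts are added, distributions normalized and converted to
   log-odds in bits against the null model (uniform 0.25 by default).
   Scores are rounded to five decimals, the model file's precision, so a
   written and re-read model is field-for-field identical to the built one.

**Pseudocount default.** The pseudocount is 0.5 per cell (configurable).
At this package's training depths (5–15 sequences) a +1-per-cell prior
flattens the 3–6-way transition distributions by roughly 0.7 bits per
node; over a 60-node model that erases ~40 bits of signal and pushes
genuine family members down to null-level scores. Halving the prior keeps
distributions proper while preserving the training signal. Mixture
Dirichlet priors and sequence weighting are out of scope; the prior
specification is pluggable.

**Insert emissions** are fixed at the null (score 0), so inserted residues
are penalized only through transition probabilities. This keeps several
expectations analytic and matches common practice.

## Scoring: CYK, Inside, and local mode

`cyk()` computes the maximum log-odds parse and its parse tree; `inside()`
computes the log-sum over all parses (always ≥ CYK). Both run on the same
triangular dynamic-programming core with the state's subsequence `[i, j]`
indexed by end position and length. Scores are bits throughout.

Glocal mode requires the full model; local mode adds uniform-probability
begins into any match-type state and local ends from any consensus state
into an EL sink that emits the remaining residues at the null. Both
penalties are configurable. Their defaults are *uniform-probability
costs* — `log2(1/n_begin_targets)` per begin, `log2(0.05)` per end —
rather than zero: with literal zero-cost begins and ends the *summed*
(Inside) score of a 150-nt random window is dominated by thousands of one-
and two-residue parses and sits within a bit of a genuine hit's score,
making detection statistically impossible. With the uniform costs, the
zero-cost construction is still available (and is used in the test suite
to verify that the local parse ensemble contains the glocal one).

Degenerate IUPAC codes are scored as the marginal over their compatible
bases (the log of the mean likelihood ratio).

Numerics: the log-sum is computed exactly (`log1p`/`exp2`, used wherever a
1e-9 oracle agreement is asserted) or through a fast approximation — a
resolution-1/256 lookup table in the scalar paths and a short polynomial in
the vectorized float paths, both accurate to ~1e-4 bits — used by the
scanning pipeline and calibration, which only ever compare scores produced
by the same arithmetic. "Minus infinity" is a finite sentinel (−1e30 bits)
so arithmetic stays total; bands that exclude every parse return it rather
than raising an error. CYK tie-breaking prefers the lower-indexed child
state and, at bifurcations, the smaller left-child interval, so tracebacks
are deterministic.

## The filter pipeline

Searching every window of a database with the CM is quadratic in window
length per state and far too slow; the pipeline therefore discards almost
everything with a sequence-only profile HMM first.

`cm_to_hmm()` derives the filter HMM: match state *k* emits the CM's
marginal distribution at consensus column *k* (pair emissions marginalized
over the partner); transitions are projected from the CM where the node
consuming column *k* leads directly to the node consuming column *k + 1*,
and take declared defaults elsewhere (M: 0.94/0.04/0.02, I: 0.50/0.45/0.05,
D: 0.70/0.05/0.25).

The cascade (`run_filter_cascade`) tiles each strand into windows of
`2 * clen + 20` with overlap `clen` — so any hit of roughly consensus
length lies entirely inside some window — and runs four stages, each
slower and stricter:

1. local Viterbi, P ≤ 0.35;
2. local Forward on survivors, P ≤ 0.15;
3. glocal Forward on survivors, P ≤ 0.02;
4. envelope definition by Forward–Backward posterior decoding: maximal
   runs of positions with in-model posterior ≥ 0.7, padded by 5 and merged
   when closer than 10.

Ceilings must be non-increasing and scale with database size as
`min(1, 10 / Z_Mb)`, a single documented stringency rule. The local
Forward score is **multi-hit**: after a hit ends the model may re-enter
downstream (a free joining segment carries completed-hit mass), which is
what lets posterior decoding separate two family copies that fall into one
window. Every hit entry pays the uniform begin cost and every exit a
matching uniform end cost; without the exit cost, single-residue "hits"
give every position of random sequence an in-model posterior around 0.7
and envelope definition degenerates.

Surviving envelopes are scored by the CM: HMM-derived bands
(`derive_bands`, tail probability 1e-7 per column side, padded ±4 and
widened by the neighboring column against single deletions) restrict the
DP; banded CYK provides the reported hit interval and parse; banded Inside
provides the reported bit score and E-value. Envelopes are scored in
window-sized context so the score geometry matches the calibration null,
and the CM stages score **glocally**: a hit is a complete structure
(truncated-hit alignment is out of scope), and a full-model parse pays no
local begin/end cost, which is worth several bits of discrimination for
weakly conserved family members. Local CM scoring remains available
through `cyk()`/`inside()`.
`mode = "max"` bypasses filters and bands entirely (every window, unbanded
Inside) and `mode = "hmm"` scores windows with the filter HMM alone — the
two comparison points for filter safety and for the value of structure.

## E-value calibration

`calibrate_model()` performs a simulated search against random sequence
for each stage scorer and fits a Gumbel (type-I extreme value)
distribution by maximum likelihood (a one-dimensional profile-likelihood
root for λ; μ in closed form). `P(S) = 1 − exp(−exp(−λ(S − μ)))` and
`E = P · Z / L_cal`, with Z the searched length (both strands) and
`L_cal` the per-sequence calibration length.

Defaults: n = 1000 sequences per stage, drawn i.i.d. from the model's
null. The calibration length defaults to the *model's own window length*
`2 * clen + 20` rather than a fixed constant: the multi-hit Forward score
grows roughly linearly with sequence length (re-entry mass compounds), so
P-values calibrated at one length do not transfer to windows of another —
measured on a 65-column model, 200-nt nulls sit ~8 bits above 145-nt
nulls, enough to drive a true hit's stage-2 P-value to 1. Matching the
calibration geometry to the scored windows removes the problem at the
source. The CM-stage scorer is calibrated unbanded; at the default tail
probability the bands are designed not to change scores, so this only
avoids paying the band-derivation cost a thousand times.

The Gumbel family is used for all stages. For summed (Forward/Inside)
scores this is a deliberate approximation — their null tails are known to
be slightly heavier than the optimal-alignment theory that motivates the
Gumbel — and the package's own uniformity checks (Kolmogorov–Smirnov on
fresh null P-values) bound the practical error.

## The synthetic benchmark

`generate_family()` emulates an RNA family: a nested consensus structure
assembled from contiguous 3–7 bp helices (as real structures are, rather
than isolated pairs), a consensus sequence with Watson–Crick-heavy pair
sampling, and descendants evolved by per-column substitution and indels.
Two features matter for realism:

- **Rate heterogeneity**: per-column rates are Gamma(0.6)-distributed
  around the mean substitution rate (a base pair shares one rate), giving
  the conserved core / variable periphery every real family shows. With
  uniform rates a profile at benchmark-level divergence carries almost no
  information and nothing is findable — heterogeneity is what makes
  40–60% pairwise-identity families detectable at all, for this package
  exactly as in nature.
- **Compensatory pairing**: substitutions at paired columns are replaced
  by a different canonical pair with probability 0.9, so structure
  survives sequence divergence. This is precisely the signal a CM can
  exploit and a sequence profile cannot.

A third realism feature is **lineage rate variation**: each descendant
carries a per-sequence rate multiplier (uniform on 0.4–1.8 of the mean
substitution rate 0.25). Under the benchmark's ceilings this reproduces
the structure of curated families: training alignments are internally
well conserved (slow lineages are unconstrained among themselves), while
held-out test members — forced below 60% identity to every training
sequence — are the fast lineages. A star phylogeny with one global rate
cannot produce both a sharp profile and distant test members at once.

Remaining defaults (chosen once for the study conditions): consensus
length 50–80, pairing fraction 0.4, 32 candidate descendants per family,
indel rate 0.02 per column. Families whose candidates cannot satisfy the
split ceilings are rejected and regenerated, exactly as benchmark family
selection discards most curated families.

`split_train_test()` applies the benchmark's identity ceilings — no two
test sequences more than 70% identical, no train/test pair more than 60% —
with identity defined as matches over columns where both rows have
residues. Assignment is greedy with a shrinking test quota; families that
cannot meet the minimum sizes (5 train, 1 test) are rejected, which is a
value, not an error, mirroring how benchmark families are selected.

`build_pseudo_genome()` embeds the test sequences at uniform random
positions and strands into decoy chunks (i.i.d. uniform by default; an
order-k Markov decoy model trained on a supplied sequence is available
since "genome-like" composition is otherwise unspecified). Insertion
rather than overwriting guarantees disjoint truth intervals.
`score_roc()` walks the E-value-ranked merged hit list: a hit is a true
positive when it overlaps an unclaimed truth interval of its own family on
the same strand by at least half the truth's length; a hit overlapping a
different family's truth is ignored; everything else is a false positive,
reported per Mb of genome per query family.

The packaged study runs 10 accepted families against a 2 × 50 kb
pseudo-genome, with each model calibrated at n = 1000. What passing this
benchmark shows — and what it does not — should be kept in mind: the
generator produces idealized families (independent columns, no
composition bias, no repeats, decoys without genomic structure), so
success here demonstrates the *internal* correctness and calibration of
the pipeline and the structure-vs-sequence ordering, not field performance
on real genomes.

## Problem sizes and reproducibility

Every stochastic step takes an explicit seed and is bit-reproducible:
identical seeds give identical model files, calibrations, hit tables and
benchmark sets. The oracle tests run exhaustive parse/path enumeration on
toy models (≤ 6 consensus columns, sequences ≤ 6 nt) and require 1e-9
agreement; the benchmark-scale checks run the 10-family pseudo-genome
study described above. `scripts/acceptance.R` regenerates the whole study
from a seed and writes the headline numbers as JSON.

## Known limitations

- Pseudoknots are outside the grammar and are treated as unpaired.
- No truncated-hit alignment: a family copy cut by a sequence end is
  scored only through local mode's end states.
- No entropy weighting, effective-sequence numbers or mixture Dirichlet
  priors; deep or redundant training alignments will over-concentrate.
- The Gumbel family is an approximation for summed scores (above).
- Single-threaded; the O(L²·states) memory guard limits per-sequence
  alignment length to 10 kb by default.
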