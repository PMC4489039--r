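---
title: "Identity-equalized DCA for tandem-repeat proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity-equalized DCA for tandem-repeat proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Direct coupling analysis (DCA) infers a Potts model from a protein family
alignment and uses the inferred pairwise couplings — summarized as direct
information (DI) — to predict residue-residue contacts. Tandem-repeat
proteins (ankyrin, TPR, armadillo, HEAT, ...) break a silent assumption of
this program: their consecutive repeat units are often recent duplications
that have not yet diverged, so rows of a two-repeat alignment can carry
nearly identical halves. Equivalent positions `(i, i + L0)` in adjacent
units then co-vary almost perfectly for reasons that have nothing to do
with physical contact, and the DI matrix acquires a strong spurious
symmetric diagonal. `repeatdca` implements the full analysis chain for this
setting: assembly of tandem alignments from repeat-unit alignments,
mean-field DCA with a finite-size correction, the identity-equalized
variant DI_id that removes the duplication artifact, cluster-based hit
selection, structural evaluation, multi-repeat reconstruction, and a
subsampling convergence analysis — plus a synthetic-data module that
reproduces the artifact on demand and is the basis of the package's tests.

## Alignment assembly

Repeat-unit alignments (aligned FASTA or Stockholm, PFAM-style
`ID/start-end` headers) are first cleaned of gap-rich columns: a column is
dropped when its gap fraction strictly exceeds 0.70. The retained width
defines the unit length `L0` once per family, before any concatenation.
Units of the same protein are then joined into tandem rows; two units may
be joined when the residue separation between them (`start(next) -
end(prev) - 1`) is strictly below `L0 / 3`, and for rows of more than two
units, or for n-th-neighbour rows, the rule is enforced at every
consecutive step along the array, not just at the endpoints. Rows whose
headers carry no residue span are excluded from concatenation because their
separation is undefined. A floor of 1500 rows is treated as a data-quality
flag rather than a hard error, so that small synthetic alignments can run
through the identical code path.

Insert states (lowercase columns in PFAM alignments) are uppercased on
reading; the gap-fraction rule is then applied to all columns uniformly.
If insert columns should not participate in the 70 % rule they must be
removed upstream; in practice they are gap-rich and are removed by the
filter anyway.

## Sequence weighting and the identity equalization

Phylogenetic redundancy is corrected with Henikoff position-based weights,
`w_i = sum_j 1 / (r_j * s_j^i)`, where `r_j` counts distinct states in
column `j` (the gap counts as a state) and `s_j^i` counts the sequences
sharing sequence `i`'s state there. These raw weights sum to the alignment
width `L` identically — a property the tests exploit — which also means
their sum cannot serve as an effective sequence number. Before frequency
estimation the package therefore rescales so the largest weight is 1,
giving `M_eff = sum(w)` between 1 and `M` that decreases with redundancy; a
mean-one rescaling is available as an option. This normalization is a
design choice of the package: it produces effective sample sizes of the
expected order for redundant families, but any fixed rescaling leaves the
relative weighting — and hence the frequencies — unchanged except through
the pseudocount balance.

The equalization works on the percent identity between the two halves of
each tandem row, computed over columns not gapped in both halves (a gap
against a residue counts as a mismatch) and snapped to the discrete grid
`n / L0`. Two distributions over this grid are compared: `nu`, the
weight-weighted histogram of identities of natural consecutive-repeat
rows, and `nu_random`, the unweighted histogram of identities between
randomly assembled unit pairs drawn (with replacement, default
`max(10 M, 10000)` pairs) from *different* proteins of the family. Each
row's weight is multiplied by `nu_random / nu` at its identity bin.
Computing `nu` as the weighted histogram makes the correction exact: after
equalization the weighted identity histogram of the rows equals
`nu_random` on its supported bins to machine precision, which is tested.
Bins where `nu_random` is zero but natural rows exist zero out those rows
rather than extrapolating an unbounded ratio; optional Laplace smoothing
(+1 pseudo-pair per bin) is provided for thin tails. For rows of more than
two units the package applies the product of bin-ratio factors over all
constituent consecutive pairs — a natural multiplicative extension chosen
here, since each factor corrects one duplication event.

## Mean-field DCA and the finite-size correction

Frequencies use the standard pseudocount scheme,
`f_i(A) = (lambda/q + sum_m w_m [x_i^m = A]) / (lambda + M_eff)` and its
pair analogue with `lambda/q^2`, which preserves the marginalization
identity `sum_B f_ij(A,B) = f_i(A)` exactly for any `lambda`. The default
pseudocount is `lambda = M_eff`, the conventional mean-field choice;
couplings are read off as the negative inverse of the connected-correlation
matrix restricted to `q - 1` states per site, with the gap state (last in
the codebook) as the gauge. Gap-free synthetic alignments may instead be
encoded over their residue alphabet alone (`encode_msa(include_gap =
FALSE)`), in which case the last residue state is the gauge; with small
pseudocounts this avoids a near-singular direction along the essentially
unobserved gap dimension.

DI is computed per pair from the two-site direct model
`P_dir(A,B) ~ exp(e_ij(A,B)) h_i(A) h_j(B)`, with auxiliary fields fitted
by alternating marginal matching until both marginals agree with the
single-site frequencies to `1e-6` (maximum absolute deviation; iteration
cap 2000, raised from common practice because the alternating scheme slows
down markedly for near-deterministic couplings). DI is the KL divergence
of `P_dir` from the product of marginals, in nats.

Finite sampling alone produces positive DI. The correction subtracts the
DI of a column-scrambled version of the same alignment: each column is
permuted independently (seeded), preserving marginal compositions while
destroying correlations. Weights stay attached to their rows and are not
recomputed on the scramble, and the null for DI_id uses the same equalized
weights as its raw run — the null must be evaluated under the same
estimator whose finite-size bias it is meant to remove. A single scramble
replicate is used by default; on coupling-free synthetic data the
corrected DI is centred at zero within three standard errors over twenty
seeds, which is one of the acceptance checks.

## Hit selection

Corrected DI values concentrate in a dense background near zero with a
small number of high outliers. Pairs are clustered on the one-dimensional
distance `dDI_ab = |DI_a - DI_b|` with average-linkage hierarchical
clustering, and the dendrogram is partitioned by an adaptive gap cut
written for this package: descending from the root, a merge is split into
its two branches when its height stands clear of the mean internal merge
height (core scatter) of *both* branches by more than
`mean(h) + k sd(h)` over all merge heights, with `k` in 3.5-1.5 controlled
by `deep_split` (default 1, i.e. `k = 3`). Clusters smaller than
`min_cluster_size` (default 2) are dissolved into the nearest surviving
cluster by value. The most populous cluster is declared background, and
hits are the members of all other clusters whose DI strictly exceeds the
background maximum; clusters of negative outliers are thereby discarded.
The selection depends only on the DI values, so it is invariant under
relabeling of pairs and under adding a constant to the matrix — both
tested. A ranked top-k selection is provided alongside for true-positive
rate curves. Hit counts from any cut method are parameter-sensitive;
`min_cluster_size` and `deep_split` are exposed as flags.

## Structural evaluation

Contact maps score residue pairs whose closest heavy (non-hydrogen) atoms
lie strictly below 8 Å, on the first model and first alternate location of
a PDB file, with waters and hetero-residues excluded. Alignment columns
are mapped to structure residues through a global-local pairwise alignment
of one ungapped anchor row against the structure sequence (BLOSUM62;
mappings below 30 % anchor identity are refused). The true-positive rate
of a ranked pair list counts, among the top k pairs whose endpoints both
map, the fraction in contact; unmapped pairs are skipped and counted. No
minimum sequence separation is imposed by default, since near-diagonal
pairs are legitimate targets at the sub-domain scale; a flag exists.

## Long repeat arrays

A joint inversion over an n-unit array costs quadratically more per added
unit, so the package reconstructs an array DI matrix from two-unit
calculations: intra-repeat blocks from the first-neighbour matrix (the
largest alignment, hence the best-sampled estimate — used for every unit),
inter-repeat blocks at separation n from the n-th-neighbour matrix. The
reconstruction is exact bookkeeping, tested bit-for-bit, and on synthetic
three-unit families it correlates with the direct three-unit calculation
at r > 0.99. The fraction of inter-repeat hits as a function of neighbour
order is fitted to `y = A 2^(-n/h)` by Levenberg-Marquardt least squares,
reporting the half-length `h` in repeat units; amplitude and intercept are
left free. A non-decreasing series yields an infinite half-length and a
warning rather than a fit.

## Convergence under subsampling

Nested subsets (default fractions 0.01-1, one seeded permutation, each
subset contained in the next — mirroring recurrent removal of sequences)
are each run through the full pipeline, weights and equalization
recomputed per subset. A pair has converged at subset `s` when, at `s` and
every larger subset, (a) its deviation from the full-data DI is below 1 %
of the global DI range over all positions and subsets, and (b) the
standard deviation of its values over the remaining larger subsets is
below 1 % of the pooled standard deviation of DI values over all pairs and
subsets (the pooled reading of an ambiguous criterion; a per-pair
reference is available as a flag). Requiring both conditions from `s`
upward makes convergence monotone in subset size by construction, and the
full subset always converges.

## The synthetic generator

Synthetic families are sampled from a Potts model with planted topology:
intra-repeat pairs replicated identically in every unit (repeats share one
fold), interface pairs between adjacent units, and optionally the full
symmetric diagonal `(i, i + L0)` as true couplings — the architecture in
which equivalent-position pairs really touch, where an equalization must
*not* erase the diagonal. Fields are drawn at random per unit position and
replicated across units, mimicking a conserved family profile (this also
gives random cross-protein unit pairs a realistic baseline identity well
above `1/q`). Each planted pair receives a coupling matrix of the
configured strength on a random one-to-one pattern of state combinations,
shared across its replications. Sampling runs one independent Gibbs chain
per sequence, all chains updated in vectorised parallel sweeps with a
burn-in of 1000 full sweeps; independent chains give exactly independent
rows, which the downstream statistics assume, and vectorisation makes this
the fastest mode here. A thinned single-chain mode is retained as an
option. Coupling-free models are sampled exactly from the independent-site
distribution, and models small enough to enumerate can be sampled exactly
from their Boltzmann distribution (`sample_exact_msa`), which serves as
the oracle for pipeline-convergence tests. The generator never emits gaps:
gaps are an alignment artifact, not part of the evolutionary model.

The duplication bias operator then rewrites a fraction `phi` of rows,
replacing the second repeat by a copy of the first mutated per position
with probability `mu` — the minimal model of recent intragenic
duplication that produces the high-identity tail of natural consecutive
repeats.

The central validation (`bias_rescue_experiment`) uses `L0 = 8`, two
units, 6 intra-repeat and 3 interface couplings of strength 1.5, a
4-letter alphabet, `M = 4000` rows, `phi = 0.6`, `mu = 0.15`. The alphabet
size and topology density were chosen once as a realistic reduced-alphabet
compromise that keeps the full pipeline fast enough to run inside the test
suite; the bias parameters are deliberately aggressive so the artifact
dominates the uncorrected matrix. Under these conditions plain-weight DI
shows a symmetric diagonal far above the background's 95th percentile,
DI_id attenuates the diagonal median by well over half (in practice ~99 %),
planted first-unit couplings move by only ~10 %, and the tree-cut hits
recover the planted pairs with a true-positive rate at or near 1. What the
synthetic module does *not* emulate: phylogenetic correlation between
rows, gaps and alignment errors, and length variation between units — so
passing these tests validates the estimator and the correction, not the
upstream alignment quality of real families.

## Numerical and degenerate-input choices

- Pseudocount `lambda = M_eff` by default everywhere; tests that compare
  against enumeration use small fixed pseudocounts with gap-free encoding.
- The two-site solver raises an error naming the offending pair if the
  marginal residual has not reached `1e-6` within the iteration cap.
- Raw DI values are clipped at exactly zero where round-off produces tiny
  negative KL values; corrected (null-subtracted) values may be negative.
- Fewer than three distinct DI values make clustering degenerate: the hit
  set is empty and a warning is raised.
- An all-double-gap tandem row has undefined identity and is an error.
- Identity bins are matched after rounding to 10 decimals so that
  floating-point snapping cannot miss the `n / L0` grid.

## Problem sizes used in tests and the acceptance script

Unit tests run on alignments of tens to hundreds of rows and unit widths
of 2-8. The experiment-scale checks use the study conditions above
(`M = 4000` for bias-and-rescue), `M = 2500` three-unit families for
reconstruction, `M = 1500` for the equalization no-harm comparison,
twenty `M = 400` coupling-free families for the null-centring check, and
an `M = 1000` family for the subsampling analysis. These sizes were chosen
as the smallest at which the measured quantities are stable across seeds.

## Known limitations

- Mean-field inversion is the only inference backend; the equalized-weight
  interface is backend-agnostic by design, but no pseudolikelihood
  implementation is included.
- The multi-unit (n > 2) equalization formula is the package's
  multiplicative extension; only the two-unit form is canonical.
- Hit counts depend on the cut parameters, as any cluster-based selection
  does; report them together with `min_cluster_size` and `deep_split`.
- `M_eff` values depend on the max-one normalization convention and are
  not directly comparable across normalizations.
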