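# repeatdca

Identity-equalized direct coupling analysis (DCA) for tandem-repeat
proteins.

## The problem

Co-evolutionary contact prediction infers a Potts model from a family's
multiple sequence alignment and ranks residue pairs by direct information
(DI),

    DI_ij = sum_{A,B} P_dir_ij(A,B) ln[ P_dir_ij(A,B) / (f_i(A) f_j(B)) ],

the KL divergence of the two-site "direct" distribution from the product
of single-site marginals. In tandem-repeat proteins (ankyrin, TPR,
armadillo, ...) consecutive repeat units are frequently recent duplications
with very high mutual sequence identity. In a two-repeat alignment of
width `2 L0`, the equivalent-position pairs `(i, i + L0)` then co-vary
almost perfectly for genealogical rather than structural reasons, planting
a spurious symmetric diagonal in the DI matrix that swamps genuine
signals.

`repeatdca` removes this bias by reweighting sequences so that the
distribution of consecutive-repeat identity matches that of randomly
assembled cross-protein repeat pairs:

    w_c_i = w_i * nu_random(%Id) / nu(%Id),

where `w_i` is the sequence's Henikoff weight, `%Id` the identity between
its two repeats on the discrete grid `n / L0`, `nu` the (weighted)
identity distribution of natural consecutive pairs and `nu_random` that of
random cross-protein pairs. DCA run under these weights yields **DI_id**.
Both DI and DI_id are finite-size corrected by subtracting the DI of a
column-scrambled null alignment.

The package covers the full workflow: building n-th-neighbour tandem
alignments from repeat-unit alignments (70 % gap-column filter, `< L0/3`
separation rule), mean-field DCA with Henikoff weighting and pseudocounts,
the identity equalization, adaptive tree-cut selection of hit pairs,
evaluation against PDB contact maps (closest heavy atoms, strict 8 Å),
reconstruction of multi-repeat DI matrices from pairwise runs with an
exponential decay fit of inter-repeat signal (half-length in repeat
units), subsampling convergence analysis, and a Potts-model synthetic
generator with a duplication-bias operator used throughout the tests.

## Worked example

The packaged bias-and-rescue experiment samples a two-repeat family
(`L0 = 8`, 4-letter alphabet, 6 intra-repeat + 3 interface planted
couplings of strength 1.5, `M = 4000`), biases 60 % of rows by duplicating
the first repeat with 15 % per-position mutation, and compares corrected
DI under plain and equalized weights:

```r
library(repeatdca)
ex <- bias_rescue_experiment(seed = 42)
print(ex$di_id)
#> di_matrix: L = 16 stage = corrected weighting = equalized
print(ex$hits)
#> hit_set: 15 hits in 2 outlier cluster(s); background max DI = 0.008019
head(ex$hits$pairs, 5)
#>   i  j        di cluster        class
#> 1 1  2 0.1488126       2 intra_repeat
#> 2 1  4 0.1249785       2 intra_repeat
#> 3 9 10 0.1219105       2 intra_repeat
#> 4 2  4 0.1206236       2 intra_repeat
#> 5 9 12 0.0938817       3 intra_repeat
```

The summary metrics show the correction at work:

```r
cat(sprintf("diagonal median DI: %.3f -> %.5f (attenuation %.1f%%)\n",
  ex$metrics$diagonal_median_plain, ex$metrics$diagonal_median_equalized,
  100 * ex$metrics$diagonal_attenuation))
#> diagonal median DI: 0.140 -> 0.00081 (attenuation 99.4%)
cat(sprintf("hit TPR vs planted couplings: %.2f (%d hits)\n",
  ex$metrics$hit_tpr, ex$metrics$n_hits))
#> hit TPR vs planted couplings: 1.00 (15 hits)
```

Under plain weights the spurious `(i, i+8)` diagonal (median DI 0.140)
dwarfs the background (95th percentile ~0.005); equalization collapses it
by ~99 % while the planted first-unit couplings move by only ~10 %, and
the adaptive tree cut recovers exactly the 15 planted pairs.

For real families the same chain runs from files:

```r
units <- filter_gap_columns(read_unit_msa("family_units.sto"))
pairs <- build_tandem_msa(units, n_units = 2, neighbour_order = 1)
di_id <- repeat_dca(pairs, weighting = "equalized", null_seed = 11)
hits  <- cluster_hits(di_id, L0 = units$L0)
```

and contacts are scored with `contact_map_from_pdb()`,
`map_columns_to_structure()` and `tp_rate()`. A thin command-line wrapper
with the same steps ships at `inst/cli/repeatdca`
(subcommands `build-msa`, `dca`, `hits`, `contacts`, `simulate`, `decay`).

## Documentation

The methods vignette
(`vignettes/identity-equalized-dca.Rmd`) describes the model, the
equalization, the adaptive tree cut, numerical choices, what the synthetic
generator does and does not emulate, and known limitations.
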