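test_that("Henikoff weights match hand-computed values and sum to L", {
  msa <- tandem_from_rows(c("AB", "AB", "AC"), L0 = 1L,
                          alphabet = c("A", "B", "C", "-"))
  w <- henikoff_weights(encode_msa(msa), normalize = "none")
  expect_equal(w$weights, c(7 / 12, 7 / 12, 5 / 6))
  expect_equal(w$M_eff, 2)                       # equals L exactly
  expect_equal(w$kind, "raw_henikoff")

  # identical rows: each weight L/M; single row: weight L
  same <- tandem_from_rows(rep("AAAA", 5), L0 = 2L)
  ws <- henikoff_weights(encode_msa(same), normalize = "none")
  expect_equal(ws$weights, rep(4 / 5, 5))
  one <- henikoff_weights(encode_msa(tandem_from_rows("ACDE", L0 = 2L)),
                          normalize = "none")
  expect_equal(one$weights, 4)
})

test_that("max-one normalisation yields M_eff in [1, M] tracking redundancy", {
  redundant <- tandem_from_rows(c(rep("ACAC", 8), "GGGG", "TTTT"), L0 = 2L)
  w <- henikoff_weights(encode_msa(redundant))
  expect_true(w$M_eff >= 1 && w$M_eff <= 10)
  expect_equal(max(w$weights), 1)
  diverse <- random_encoded(10, 4, q = 8, seed = 3)
  expect_gt(henikoff_weights(diverse)$M_eff, w$M_eff)
})

test_that("pair identity counts matches with double-gap columns excluded", {
  enc <- encode_msa(tandem_from_rows(c("ABCDABCE"), L0 = 4L,
                                     alphabet = c(LETTERS[1:5], "-")))
  expect_equal(pair_identity(enc, 4L), 0.75)
  enc2 <- encode_msa(tandem_from_rows("ACGTACGT", L0 = 4L))
  expect_equal(pair_identity(enc2, 4L), 1.0)
  # double gap at column 2 of both halves: denominator 3, matches 2
  enc3 <- encode_msa(tandem_from_rows("A-CDA-CE", L0 = 4L))
  expect_equal(pair_identity(enc3, 4L), 2 / 3)
  # all-double-gap row is undefined
  enc4 <- encode_msa(tandem_from_rows("----", L0 = 2L))
  expect_error(pair_identity(enc4, 2L), "undefined identity")
})

test_that("identity distributions are normalised, seeded, and detect the bias tail", {
  topo <- planted_topology(L0 = 6L)
  cfg <- generator_config(q = 4, coupling_strength = 0.8, M = 600, seed = 9)
  msa <- sample_msa(make_planted_model(topo, cfg), cfg)
  w <- henikoff_weights(encode_msa(msa))
  idd <- identity_distributions(msa, w, n_random_pairs = 4000, seed = 21)
  expect_equal(sum(idd$nu), 1)
  expect_equal(sum(idd$nu_random), 1)
  expect_equal(idd$bins, (0:6) / 6)
  # determinism
  idd2 <- identity_distributions(msa, w, n_random_pairs = 4000, seed = 21)
  expect_identical(idd$nu_random, idd2$nu_random)
  # duplication bias raises the natural mean above the random-pair mean
  biased <- apply_duplication_bias(msa, phi = 0.5, mu = 0.1, seed = 4)
  iddb <- identity_distributions(biased, henikoff_weights(encode_msa(biased)),
                                 n_random_pairs = 4000, seed = 21)
  expect_gt(sum(iddb$bins * iddb$nu), sum(iddb$bins * iddb$nu_random))
  # degenerate family: every repeat identical -> both point masses at 1
  const <- tandem_from_rows(rep("AAAA", 4), L0 = 2L,
                            protein_id = c("P1", "P1", "P2", "P2"))
  iddc <- identity_distributions(const, henikoff_weights(encode_msa(const)),
                                 n_random_pairs = 500, seed = 1)
  expect_equal(iddc$nu[length(iddc$bins)], 1)
  expect_equal(iddc$nu_random[length(iddc$bins)], 1)
})

test_that("equalization applies the bin ratio and reproduces nu_random", {
  # direct substitution: w = 0.5, nu_random/nu = 0.10/0.25 -> 0.2
  iddist <- structure(list(bins = c(0, 0.5, 1), nu = c(0.25, 0.5, 0.25),
                           nu_random = c(0.10, 0.8, 0.10),
                           identities = c(0, 0.5, 1),
                           n_random_pairs = 100L, seed = 1L),
                      class = "identity_distribution")
  base <- repeatdca:::new_weight_vector(c(0.5, 1, 0.3), "normalized")
  eq <- equalize_weights(base, iddist)
  expect_equal(eq$weights[1], 0.2)
  expect_equal(eq$kind, "equalized")
  expect_equal(eq$M_eff, sum(eq$weights))

  # nu == nu_random leaves weights unchanged
  idd_same <- iddist
  idd_same$nu_random <- idd_same$nu
  expect_equal(equalize_weights(base, idd_same)$weights, base$weights)

  # algebraic invariant: equalized weighted identity histogram == nu_random
  topo <- planted_topology(L0 = 5L)
  cfg <- generator_config(q = 3, coupling_strength = 0.5, M = 400, seed = 2)
  msa <- sample_msa(make_planted_model(topo, cfg), cfg)
  msa <- apply_duplication_bias(msa, phi = 0.4, mu = 0.2, seed = 3)
  w0 <- henikoff_weights(encode_msa(msa))
  idd <- identity_distributions(msa, w0, n_random_pairs = 5000, seed = 5)
  weq <- equalize_weights(w0, idd)
  hist_eq <- repeatdca:::weighted_bin_hist(idd$identities, weq$weights,
                                           idd$bins)
  supported <- idd$nu > 0
  expected <- idd$nu_random * supported
  expected <- expected / sum(expected)
  expect_equal(hist_eq, expected, tolerance = 1e-12)

  # ordering is preserved within each identity bin
  for (b in which(supported)) {
    members <- which(abs(idd$identities - idd$bins[b]) < 1e-9)
    if (length(members) > 1)
      expect_equal(order(weq$weights[members]), order(w0$weights[members]))
  }

  # length mismatch caught
  expect_error(equalize_weights(base, iddist, identities = c(0, 0.5)),
               "length")
})
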