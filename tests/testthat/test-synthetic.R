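test_that("planted models replicate pairs across units deterministically", {
  topo <- planted_topology(L0 = 5L, n_units = 2L,
                           intra_pairs = cbind(c(1, 2, 3), c(3, 4, 5)),
                           interface_pairs = cbind(c(1, 4), c(2, 5)))
  cfg <- generator_config(q = 3, coupling_strength = 1, seed = 10)
  mod <- make_planted_model(topo, cfg)
  expect_equal(nrow(mod$ground_truth), 3L * 2L + 2L)
  expect_true(all(mod$ground_truth$i < mod$ground_truth$j))
  # replicated intra pairs share one coupling matrix
  key <- vapply(mod$J, function(cp) paste(cp$i, cp$j), character(1))
  m13 <- mod$J[[which(key == "1 3")]]$mat
  m68 <- mod$J[[which(key == "6 8")]]$mat
  expect_identical(m13, m68)
  # fields are replicated across units
  expect_identical(mod$h[1:5, ], mod$h[6:10, ])
  # determinism
  mod2 <- make_planted_model(topo, cfg)
  expect_identical(mod$h, mod2$h)
  expect_identical(mod$J, mod2$J)
  # zero strength leaves pair structure but no interactions
  cfg0 <- generator_config(q = 3, coupling_strength = 0, seed = 10)
  mod0 <- make_planted_model(topo, cfg0)
  expect_true(all(vapply(mod0$J, function(cp) max(abs(cp$mat)), numeric(1)) == 0))
  # symmetric-diagonal planting adds one pair per unit position
  topo_d <- planted_topology(L0 = 4L, include_symmetric_diagonal = TRUE)
  mod_d <- make_planted_model(topo_d, cfg)
  expect_equal(mod_d$ground_truth$j - mod_d$ground_truth$i, rep(4L, 4L))
})

test_that("Gibbs samples agree with exact enumeration on a small model", {
  topo <- planted_topology(L0 = 2L, intra_pairs = cbind(1L, 2L),
                           interface_pairs = cbind(2L, 1L))
  cfg <- generator_config(q = 2, coupling_strength = 1.2, M = 4000,
                          burn_in = 300, seed = 8)
  mod <- make_planted_model(topo, cfg)
  en <- enumerate_potts(mod)
  expect_equal(sum(en$prob), 1)
  msa <- sample_msa(mod, cfg)
  X <- encode_msa(msa, include_gap = FALSE)$matrix
  # every pairwise joint frequency within 3 binomial standard errors
  for (i in 1:3) for (j in (i + 1):4) {
    for (a in 0:1) for (b in 0:1) {
      p_exact <- sum(en$prob[en$states[, i] == a + 1 & en$states[, j] == b + 1])
      p_emp <- mean(X[, i] == a & X[, j] == b)
      se <- sqrt(p_exact * (1 - p_exact) / nrow(X))
      expect_lt(abs(p_emp - p_exact), 3.5 * se)
    }
  }
})

test_that("mutual information shrinks without couplings and flags planted pairs", {
  topo <- planted_topology(L0 = 3L)
  max_mi <- vapply(c(500, 5000), function(M) {
    cfg <- generator_config(q = 3, coupling_strength = 0, M = M, seed = 31)
    msa <- sample_msa(make_planted_model(topo, cfg), cfg)
    mi <- pairwise_mi(encode_msa(msa, include_gap = FALSE))
    max(mi)
  }, numeric(1))
  expect_lt(max_mi[2], max_mi[1])

  # planted pairs dominate the MI ranking at moderate coupling strength
  ranks_ok <- vapply(1:3, function(s) {
    set.seed(s)
    topo <- random_topology(L0 = 5L, n_intra = 3L, n_interface = 2L)
    cfg <- generator_config(q = 3, coupling_strength = 1.5, M = 1500,
                            seed = s, burn_in = 500)
    mod <- make_planted_model(topo, cfg)
    msa <- sample_msa(mod, cfg)
    mi <- pairwise_mi(encode_msa(msa, include_gap = FALSE))
    gt <- as.matrix(mod$ground_truth[, c("i", "j")])
    planted_min <- min(mi[gt])
    other <- mi
    other[gt] <- NA; other[gt[, 2:1]] <- NA
    planted_min > max(other[upper.tri(other)], na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(ranks_ok), 2L)
})

test_that("duplication bias copies and mutates the second repeat only", {
  topo <- planted_topology(L0 = 6L)
  cfg <- generator_config(q = 4, coupling_strength = 0.5, M = 400, seed = 12)
  msa <- sample_msa(make_planted_model(topo, cfg), cfg)
  # phi = 1, mu = 0: every row becomes a perfect duplication
  dup <- apply_duplication_bias(msa, phi = 1, mu = 0, seed = 2)
  expect_true(all(pair_identity(encode_msa(dup), 6L) == 1))
  # first repeat untouched
  expect_equal(substr(dup$rows, 1, 6), substr(msa$rows, 1, 6))
  # phi = 0 is the identity
  expect_identical(apply_duplication_bias(msa, phi = 0, mu = 0.5)$rows,
                   msa$rows)
  # bias raises mean identity at moderate mutation rates, across seeds
  gains <- vapply(1:5, function(s) {
    b <- apply_duplication_bias(msa, phi = 0.5, mu = 0.1, seed = s)
    mean(pair_identity(encode_msa(b), 6L)) -
      mean(pair_identity(encode_msa(msa), 6L))
  }, numeric(1))
  expect_true(all(gains > 0))
  # determinism
  expect_identical(apply_duplication_bias(msa, 0.3, 0.2, seed = 9)$rows,
                   apply_duplication_bias(msa, 0.3, 0.2, seed = 9)$rows)
})

test_that("overlapping planted pairs collapse with a warning", {
  topo <- planted_topology(L0 = 4L, intra_pairs = rbind(c(1, 3), c(1, 3)))
  cfg <- generator_config(q = 3, seed = 2)
  # one warning per unit replication of the duplicated pair
  expect_warning(expect_warning(mod <- make_planted_model(topo, cfg),
                                "overlapping"))
  expect_equal(nrow(mod$ground_truth), 2L)   # one per unit, not two
})
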