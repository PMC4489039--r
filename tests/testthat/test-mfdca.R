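test_that("frequency estimates obey counting, pseudocount limits and marginalisation", {
  enc <- encode_msa(tandem_from_rows(c("AA", "AA", "AA"), L0 = 1L,
                                     alphabet = c("A", "C", "-")))
  w <- henikoff_weights(enc)
  f0 <- empirical_frequencies(enc, w, lambda = 0)
  expect_equal(f0$f1[1, ], c(1, 0, 0))
  # large-lambda limit pulls everything to 1/q
  finf <- empirical_frequencies(enc, w, lambda = 1e12)
  expect_equal(finf$f1[1, ], rep(1 / 3, 3), tolerance = 1e-9)
  # row sums of f1 are always 1
  enc2 <- random_encoded(50, 6, q = 5, seed = 7)
  f <- empirical_frequencies(enc2, henikoff_weights(enc2), lambda = 3.7)
  expect_equal(rowSums(f$f1), rep(1, 6))
  # marginalisation identity, machine precision, i != j
  q <- f$q
  for (i in c(1, 3)) for (j in c(2, 6)) {
    blk <- f$f2[(i - 1) * q + seq_len(q), (j - 1) * q + seq_len(q)]
    expect_lt(max(abs(rowSums(blk) - f$f1[i, ])), 1e-14)
  }
})

test_that("coupling inversion is symmetric and detects a correlated pair", {
  # correlated binary columns against independent ones
  set.seed(11)
  M <- 300L
  x <- sample(c("A", "C"), M, replace = TRUE)
  y <- sample(c("A", "C"), M, replace = TRUE)
  rows <- paste0(x, x, y)                          # col2 copies col1; col3 free
  enc <- encode_msa(tandem_from_rows(rows, L0 = 1L, n_units = 3L,
                                     alphabet = c("A", "C", "-")),
                    include_gap = FALSE)
  f <- empirical_frequencies(enc, henikoff_weights(enc), lambda = 10)
  cm <- infer_couplings(f)
  # e_ij(A,B) == e_ji(B,A)
  expect_equal(coupling_block(cm, 1, 2), t(coupling_block(cm, 2, 1)))
  expect_equal(coupling_block(cm, 1, 3), t(coupling_block(cm, 3, 1)))
  # the duplicated pair carries the dominant coupling on the matched state
  e12 <- coupling_block(cm, 1, 2)
  expect_gt(max(abs(e12)), max(abs(coupling_block(cm, 1, 3))))
  expect_equal(which.max(abs(e12)), 1L)            # (A,A) entry
  # singular C (no pseudocount, perfect correlation) names the remedy
  f_sing <- empirical_frequencies(enc, henikoff_weights(enc), lambda = 0)
  expect_error(infer_couplings(f_sing), "pseudocount")
})

test_that("two-site solver matches the q=2 closed form and honours marginals", {
  # closed form: with fixed marginals the 2x2 joint has one free parameter,
  # pinned by the odds-ratio constraint; solve the quadratic directly
  closed_form_q2 <- function(e, fi, fj) {
    R <- exp(e[1, 1] + e[2, 2] - e[1, 2] - e[2, 1])
    a <- fi[1]; b <- fj[1]
    if (abs(R - 1) < 1e-14) return(outer(fi, fj))
    # R-1) t^2 - (1 + (a+b)(R-1)) t + Rab = 0
    A <- R - 1; B <- -(1 + (a + b) * (R - 1)); C <- R * a * b
    t <- (-B - sqrt(B^2 - 4 * A * C)) / (2 * A)
    matrix(c(t, b - t, a - t, 1 - a - b + t), 2, 2)
  }
  set.seed(5)
  for (rep in 1:20) {
    e <- matrix(rnorm(4), 2, 2)
    fi <- runif(2, 0.1, 0.9); fi <- fi / sum(fi)
    fj <- runif(2, 0.1, 0.9); fj <- fj / sum(fj)
    P <- solve_two_site(e, fi, fj, tol = 1e-12, max_iter = 20000)
    expect_equal(P, closed_form_q2(e, fi, fj), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # zero coupling factorises exactly
  fi <- c(0.2, 0.3, 0.5)
  expect_equal(solve_two_site(matrix(0, 3, 3), fi, rev(fi)),
               outer(fi, rev(fi)), ignore_attr = TRUE)
  # marginal residuals meet tol on random q=4 blocks
  for (rep in 1:10) {
    e <- matrix(rnorm(16, sd = 0.8), 4, 4)
    fi <- runif(4, 0.05, 1); fi <- fi / sum(fi)
    fj <- runif(4, 0.05, 1); fj <- fj / sum(fj)
    P <- solve_two_site(e, fi, fj, tol = 1e-6)
    expect_lt(max(abs(rowSums(P) - fi), abs(colSums(P) - fj)), 1e-6)
    expect_equal(sum(P), 1)
  }
})

test_that("direct information is a KL divergence: zero when independent, ln 2 when locked", {
  # independent product distribution gives DI = 0 through the pipeline path
  fi <- c(0.3, 0.7)
  P <- solve_two_site(matrix(0, 2, 2), fi, fi)
  expect_equal(sum(P * log(P / outer(fi, fi))), 0, tolerance = 1e-12)
  # a near-deterministic direct coupling between uniform binary sites gives
  # DI -> ln 2, the mutual information of perfect correlation
  P2 <- solve_two_site(diag(20, 2), c(0.5, 0.5), c(0.5, 0.5), tol = 1e-10)
  expect_equal(sum(P2 * log(P2 / 0.25)), log(2), tolerance = 1e-3)
  # strongly correlated binary data through the whole pipeline: large,
  # symmetric, non-negative DI with a zero diagonal
  set.seed(19)
  x <- sample(c("A", "C"), 400, replace = TRUE)
  flip <- runif(400) < 0.05
  y <- ifelse(flip, chartr("AC", "CA", x), x)
  enc <- encode_msa(tandem_from_rows(paste0(x, y), L0 = 1L,
                                     alphabet = c("A", "C", "-")),
                    include_gap = FALSE)
  w <- henikoff_weights(enc)
  f <- empirical_frequencies(enc, w, lambda = w$M_eff / 100)
  di <- direct_information(infer_couplings(f), f)
  expect_gt(di$values[1, 2], 0.3)
  expect_lt(di$values[1, 2], log(2))
  expect_true(all(di$values >= 0))
  expect_equal(di$values, t(di$values))
  expect_equal(diag(di$values), rep(0, 2))
})

test_that("scrambled null preserves column composition and is seeded", {
  enc <- random_encoded(80, 8, q = 4, seed = 13)
  w <- henikoff_weights(enc)
  null1 <- scrambled_null_di(enc, w, lambda = "meff", seed = 3)
  null2 <- scrambled_null_di(enc, w, lambda = "meff", seed = 3)
  null3 <- scrambled_null_di(enc, w, lambda = "meff", seed = 4)
  expect_identical(null1$values, null2$values)
  expect_false(identical(null1$values, null3$values))
  expect_equal(null1$stage, "null")
  expect_true(all(null1$values[upper.tri(null1$values)] > 0))
  # column marginals of the scramble equal the originals exactly
  set.seed(3)                       # same seed path as scrambled_null_di
  Xs <- apply(enc$matrix, 2, sample)
  for (j in seq_len(ncol(Xs)))
    expect_equal(tabulate(Xs[, j] + 1L, 4), tabulate(enc$matrix[, j] + 1L, 4))
})

test_that("null subtraction validates inputs and zeroes a self-difference", {
  enc <- random_encoded(60, 6, q = 4, seed = 17)
  w <- henikoff_weights(enc)
  f <- empirical_frequencies(enc, w)
  raw <- direct_information(infer_couplings(f), f)
  null <- scrambled_null_di(enc, w, seed = 9)
  corr <- subtract_null(raw, null)
  expect_equal(corr$stage, "corrected")
  expect_equal(corr$values, raw$values - null$values)
  expect_equal(corr$values, t(corr$values))
  # raw == null gives the zero matrix
  null_as_raw <- raw
  null_as_raw$stage <- "null"
  expect_equal(max(abs(subtract_null(raw, null_as_raw)$values)), 0)
  # weighting flavour mismatch refused
  null_eq <- null
  null_eq$weighting <- "equalized"
  expect_error(subtract_null(raw, null_eq), "weighting mismatch")
})
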