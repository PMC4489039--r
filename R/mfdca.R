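#' Weighted empirical frequencies with pseudocounts
#'
#' Single-site and pair frequencies under sequence weights `w` and a
#' pseudocount mass `lambda`:
#' `f_i(A) = (lambda/q + sum_m w_m d(x_i^m = A)) / (lambda + M_eff)` and
#' `f_ij(A,B) = (lambda/q^2 + sum_m w_m dd) / (lambda + M_eff)`.
#' This scheme makes the marginalisation identity
#' `sum_B f_ij(A,B) = f_i(A)` hold exactly for any `lambda`.
#'
#' @param msa An `encoded_msa`.
#' @param weights A `weight_vector` of matching length.
#' @param lambda Pseudocount mass; the string `"meff"` (default) uses
#'   `lambda = M_eff`, the standard mean-field choice.
#' @return A `frequency_model`: `f1` (L x q), `f2` (Lq x Lq dense matrix of
#'   pair frequencies, diagonal site blocks unused), `lambda`, `M_eff`, `q`,
#'   `L`.
#' @export
empirical_frequencies <- function(msa, weights, lambda = "meff") {
  stopifnot(inherits(msa, "encoded_msa"), inherits(weights, "weight_vector"))
  X <- msa$matrix
  M <- nrow(X); L <- ncol(X); q <- msa$q
  w <- weights$weights
  stopifnot(length(w) == M)
  M_eff <- weights$M_eff
  if (identical(lambda, "meff")) lambda <- M_eff
  stopifnot(is.numeric(lambda), lambda >= 0)

  # one-hot indicator, M x (L*q); column block l holds site l's states
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(M), L),
    j = as.integer(rep((seq_len(L) - 1L) * q, each = M) + as.vector(X) + 1L),
    x = 1, dims = c(M, L * q))
  cnt1 <- as.vector(Matrix::crossprod(ind, w))          # weighted site counts
  f1 <- matrix((lambda / q + cnt1) / (lambda + M_eff), nrow = L, ncol = q,
               byrow = TRUE)
  cnt2 <- as.matrix(Matrix::crossprod(ind, ind * w))    # weighted pair counts
  f2 <- (lambda / q^2 + cnt2) / (lambda + M_eff)

  structure(list(f1 = f1, f2 = f2, lambda = lambda, M_eff = M_eff,
                 q = q, L = L),
            class = "frequency_model")
}

#' Infer Potts couplings by covariance inversion
#'
#' Mean-field inference: the connected-correlation matrix
#' `C_ij(A,B) = f_ij(A,B) - f_i(A) f_j(B)`, restricted to `q - 1` states per
#' site (the gap state, last in the codebook, is the gauge state), is
#' inverted and couplings read off as `e_ij(A,B) = -(C^-1)_ij(A,B)`.
#' Couplings involving the gauge state are implicitly zero.
#'
#' @param freqs A `frequency_model` with `lambda > 0` (a zero pseudocount
#'   generally leaves `C` singular).
#' @return A `coupling_model` holding the `L(q-1)` square matrix of negative
#'   inverse correlations plus accessors via [coupling_block()].
#' @export
infer_couplings <- function(freqs) {
  stopifnot(inherits(freqs, "frequency_model"))
  q <- freqs$q; L <- freqs$L; qr <- q - 1L
  keep <- as.vector(outer(seq_len(qr), (seq_len(L) - 1L) * q, `+`))
  f1v <- as.vector(t(freqs$f1))               # site-major flattening, length L*q
  C <- freqs$f2[keep, keep] - tcrossprod(f1v[keep])
  # within-site blocks: f_ii(A,B) = f_i(A) d(A,B) by convention
  for (l in seq_len(L)) {
    bl <- (l - 1L) * qr + seq_len(qr)
    fl <- freqs$f1[l, seq_len(qr)]
    C[bl, bl] <- diag(fl, qr) - tcrossprod(fl)
  }
  invC <- tryCatch(solve(C), error = function(e)
    stop("connected-correlation matrix is singular; use a pseudocount lambda > 0 (",
         conditionMessage(e), ")"))
  structure(list(e = -invC, q = q, L = L, gauge_state = q - 1L),
            class = "coupling_model")
}

#' Extract one coupling block as a q x q matrix
#'
#' @param cm A `coupling_model`.
#' @param i,j Site indices (1-based, `i != j`).
#' @return q x q coupling matrix; gauge-state row and column are zero.
#' @export
coupling_block <- function(cm, i, j) {
  stopifnot(inherits(cm, "coupling_model"), i != j)
  qr <- cm$q - 1L
  e <- matrix(0, cm$q, cm$q)
  e[seq_len(qr), seq_len(qr)] <-
    cm$e[(i - 1L) * qr + seq_len(qr), (j - 1L) * qr + seq_len(qr)]
  e
}

#' Fit the two-site direct model by marginal matching
#'
#' Solves for `P_dir(A,B) = exp(e_ij(A,B)) h_i(A) h_j(B) / Z` with auxiliary
#' fields fitted by alternating iteration so that both marginals of `P_dir`
#' match the single-site frequencies `f_i`, `f_j` to within `tol` (maximum
#' absolute deviation).
#'
#' @param e_block q x q coupling matrix.
#' @param f_i,f_j Strictly positive site marginals (length q).
#' @param tol Convergence tolerance on the marginal residual (default 1e-6).
#' @param max_iter Iteration cap (default 2000).
#' @return q x q matrix `P_dir`, summing to 1, with attribute `"residual"`.
#' @export
solve_two_site <- function(e_block, f_i, f_j, tol = 1e-6, max_iter = 2000L) {
  q <- length(f_i)
  stopifnot(nrow(e_block) == q, ncol(e_block) == q, length(f_j) == q,
            all(f_i > 0), all(f_j > 0))
  W <- exp(e_block)
  mu_i <- rep(1 / q, q); mu_j <- rep(1 / q, q)
  for (it in seq_len(max_iter)) {
    mu_i <- f_i / as.vector(W %*% mu_j);  mu_i <- mu_i / sum(mu_i)
    mu_j <- f_j / as.vector(crossprod(W, mu_i)); mu_j <- mu_j / sum(mu_j)
    P <- W * tcrossprod(mu_i, mu_j)
    P <- P / sum(P)
    res <- max(abs(rowSums(P) - f_i), abs(colSums(P) - f_j))
    if (res < tol) {
      attr(P, "residual") <- res
      return(P)
    }
  }
  stop(sprintf("two-site solver did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Direct information matrix
#'
#' For every site pair, fits the two-site direct model and evaluates the
#' Kullback-Leibler divergence of `P_dir` from the product of single-site
#' marginals, in nats:
#' `DI_ij = sum_AB P_dir(A,B) ln( P_dir(A,B) / (f_i(A) f_j(B)) )`.
#'
#' @param couplings A `coupling_model`.
#' @param freqs The matching `frequency_model`.
#' @param tol,max_iter Passed to [solve_two_site()].
#' @return A `di_matrix` with `stage = "raw"`: symmetric L x L, zero
#'   diagonal, non-negative entries.
#' @export
direct_information <- function(couplings, freqs, tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(couplings, "coupling_model"),
            inherits(freqs, "frequency_model"),
            couplings$L == freqs$L, couplings$q == freqs$q)
  L <- freqs$L
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    f_i <- freqs$f1[i, ]
    for (j in (i + 1L):L) {
      f_j <- freqs$f1[j, ]
      P <- tryCatch(
        solve_two_site(coupling_block(couplings, i, j), f_i, f_j,
                       tol = tol, max_iter = max_iter),
        error = function(e) stop("pair (", i, ", ", j, "): ",
                                 conditionMessage(e)))
      ref <- tcrossprod(f_i, f_j)
      v <- sum(P * log(P / ref))
      di[i, j] <- di[j, i] <- max(v, 0)   # clip KL round-off at exactly 0
    }
  }
  new_di_matrix(di, stage = "raw",
                meta = list(lambda = freqs$lambda, M_eff = freqs$M_eff))
}

new_di_matrix <- function(values, stage, weighting = "plain", meta = list()) {
  stopifnot(isSymmetric(values), all(diag(values) == 0))
  structure(list(values = values, stage = stage, weighting = weighting,
                 meta = meta),
            class = "di_matrix")
}

#' @export
print.di_matrix <- function(x, ...) {
  cat("di_matrix: L =", nrow(x$values), "stage =", x$stage,
      "weighting =", x$weighting, "\n")
  invisible(x)
}

#' Scrambled-column null DI (finite-size correction baseline)
#'
#' Permutes the entries of every column independently, preserving each
#' column's marginal composition but destroying all inter-column
#' correlation, then runs the full DI pipeline on the scrambled alignment.
#' Weights stay attached to their rows and are not recomputed, isolating the
#' finite-sample effect at fixed weighting.
#'
#' @param msa An `encoded_msa`.
#' @param weights The `weight_vector` used for the raw DI.
#' @param lambda Pseudocount mass (or `"meff"`).
#' @param seed Integer seed controlling the per-column permutations.
#' @return A `di_matrix` with `stage = "null"`.
#' @export
scrambled_null_di <- function(msa, weights, lambda = "meff", seed = 1L) {
  stopifnot(inherits(msa, "encoded_msa"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  Xs <- apply(msa$matrix, 2L, sample)
  scr <- msa
  scr$matrix <- Xs
  freqs <- empirical_frequencies(scr, weights, lambda)
  di <- direct_information(infer_couplings(freqs), freqs)
  di$stage <- "null"
  di$meta$seed <- as.integer(seed)
  di
}

#' Subtract the scrambled null from a raw DI matrix
#'
#' @param raw A `di_matrix` with `stage = "raw"`.
#' @param null A `di_matrix` with `stage = "null"`, same size and weighting
#'   flavour.
#' @return A `di_matrix` with `stage = "corrected"`; entries may be
#'   negative.
#' @export
subtract_null <- function(raw, null) {
  stopifnot(inherits(raw, "di_matrix"), inherits(null, "di_matrix"),
            raw$stage == "raw", null$stage == "null")
  if (!identical(dim(raw$values), dim(null$values)))
    stop("shape mismatch between raw and null DI matrices")
  if (!identical(raw$weighting, null$weighting))
    stop("weighting mismatch between raw and null DI matrices")
  new_di_matrix(raw$values - null$values, stage = "corrected",
                weighting = raw$weighting,
                meta = c(raw$meta, list(null_seed = null$meta$seed)))
}

#' Corrected DI / DI_id pipeline on a tandem alignment
#'
#' Convenience wrapper running the full chain: encode, Henikoff weights,
#' optional identity equalization (giving DI_id), weighted frequencies with
#' pseudocount, coupling inversion, direct information, scrambled-column
#' null, and null subtraction.
#'
#' @param msa A `tandem_msa`.
#' @param weighting `"plain"` for DI or `"equalized"` for DI_id.
#' @param lambda Pseudocount mass or `"meff"`.
#' @param null_seed Seed for the scrambled null.
#' @param pair_seed Seed for the random cross-protein pairs of the identity
#'   distribution (equalized weighting only).
#' @param n_random_pairs Random pairs for `nu_random` (equalized only).
#' @return A `di_matrix` with `stage = "corrected"`; the weights and (for
#'   DI_id) the identity distribution are attached in `meta`.
#' @export
repeat_dca <- function(msa, weighting = c("plain", "equalized"),
                       lambda = "meff", null_seed = 1L, pair_seed = 1L,
                       n_random_pairs = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(msa, "tandem_msa"))
  enc <- encode_msa(msa)
  w <- henikoff_weights(enc)
  iddist <- NULL
  if (weighting == "equalized") {
    if (msa$n_units == 2L) {
      iddist <- identity_distributions(msa, w, n_random_pairs = n_random_pairs,
                                       seed = pair_seed)
      w <- equalize_weights(w, iddist)
    } else {
      # multi-repeat form: product of bin-ratio factors over all
      # constituent consecutive-pair identities
      w <- equalize_weights_multi(msa, enc, w, pair_seed, n_random_pairs)
    }
  }
  freqs <- empirical_frequencies(enc, w, lambda)
  raw <- direct_information(infer_couplings(freqs), freqs)
  raw$weighting <- weighting
  null <- scrambled_null_di(enc, w, lambda = freqs$lambda, seed = null_seed)
  null$weighting <- weighting
  out <- subtract_null(raw, null)
  out$meta$weights <- w
  out$meta$iddist <- iddist
  out$meta$L0 <- msa$L0
  out$meta$n_units <- msa$n_units
  out
}

# Equalization for n_units > 2: each row is reweighted by the product of
# nu_random/nu ratio factors of its consecutive unit pairs; nu is the
# base-weighted histogram over all consecutive pairs pooled.
equalize_weights_multi <- function(msa, enc, base, pair_seed, n_random_pairs) {
  L0 <- msa$L0; n <- msa$n_units
  bins <- (0:L0) / L0
  gap <- enc$q - 1L
  per_pair_ids <- matrix(0, nrow(enc$matrix), n - 1L)
  for (k in seq_len(n - 1L)) {
    block <- enc$matrix[, ((k - 1L) * L0 + 1L):((k + 1L) * L0), drop = FALSE]
    per_pair_ids[, k] <- snap_identity_bins(pair_identity_mat(block, L0, gap), L0)
  }
  nu <- weighted_bin_hist(as.vector(per_pair_ids),
                          rep(base$weights, n - 1L), bins)
  # nu_random from a two-unit view: pool all units, pair across proteins
  pair_view <- new_tandem_msa(
    rows = substr(msa$rows, 1L, 2L * L0), n_units = 2L, L0 = L0,
    protein_id = msa$protein_id, spans = msa$spans,
    alphabet = msa$alphabet)
  idd <- identity_distributions(pair_view, base,
                                n_random_pairs = n_random_pairs,
                                seed = pair_seed)
  ratio_at <- function(idv) {
    idx <- match(round(idv, 10), round(bins, 10))
    ifelse(nu[idx] > 0, idd$nu_random[idx] / nu[idx], 0)
  }
  fac <- apply(per_pair_ids, 2L, ratio_at)
  new_weight_vector(base$weights * apply(fac, 1L, prod), kind = "equalized")
}

pair_identity_mat <- function(X, L0, gap) {
  A <- X[, seq_len(L0), drop = FALSE]
  B <- X[, L0 + seq_len(L0), drop = FALSE]
  both_gap <- (A == gap) & (B == gap)
  denom <- pmax(L0 - rowSums(both_gap), 1L)
  rowSums((A == B) & !both_gap) / denom
}

#' Write a DI matrix as a TSV edge list
#'
#' Columns `i`, `j` (1-based, `i < j`) and `di`.
#'
#' @param di A `di_matrix`.
#' @param path Output path.
#' @export
write_di_tsv <- function(di, path) {
  stopifnot(inherits(di, "di_matrix"))
  L <- nrow(di$values)
  ut <- which(upper.tri(di$values), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], di = di$values[ut])
  write.table(df[order(df$i, df$j), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
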