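#' Henikoff position-based sequence weights
#'
#' Computes the Henikoff & Henikoff weight of each sequence,
#' `w_i = sum_j 1 / (r_j * s_j^i)`, where `r_j` is the number of distinct
#' states in column j and `s_j^i` the number of sequences sharing sequence
#' i's state there. The gap state counts as a state. Raw weights satisfy
#' `sum(w) = L` identically; because that tie to the alignment width makes
#' the weight sum useless as an effective sample size, the default
#' normalisation rescales so the largest weight is 1, giving
#' `M_eff = sum(w) in [1, M]` that shrinks with redundancy. A mean-one
#' rescaling is available as an alternative.
#'
#' @param msa An `encoded_msa`.
#' @param normalize `"max_one"` (default), `"mean_one"`, or `"none"` for the
#'   raw weights.
#' @return A `weight_vector`: list with `weights`, `kind`
#'   (`"raw_henikoff"` or `"normalized"`) and `M_eff = sum(weights)`.
#' @export
henikoff_weights <- function(msa, normalize = c("max_one", "mean_one", "none")) {
  stopifnot(inherits(msa, "encoded_msa"))
  normalize <- match.arg(normalize)
  X <- msa$matrix
  M <- nrow(X); L <- ncol(X)
  w <- numeric(M)
  for (j in seq_len(L)) {
    counts <- tabulate(X[, j] + 1L, nbins = msa$q)
    r_j <- sum(counts > 0L)
    s_ji <- counts[X[, j] + 1L]
    w <- w + 1 / (r_j * s_ji)
  }
  if (normalize == "max_one") {
    w <- w / max(w)
    kind <- "normalized"
  } else if (normalize == "mean_one") {
    w <- w / mean(w)
    kind <- "normalized"
  } else {
    kind <- "raw_henikoff"
  }
  new_weight_vector(w, kind)
}

new_weight_vector <- function(weights, kind) {
  stopifnot(all(weights >= 0))
  structure(list(weights = weights, kind = kind, M_eff = sum(weights)),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("weight_vector (", x$kind, "): M = ", length(x$weights),
      ", M_eff = ", format(x$M_eff, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Percent identity between the two repeats of a tandem row
#'
#' For a row of width `2 * L0`, the fraction of columns `c` in `1..L0` whose
#' state equals the state at `c + L0`. Columns gapped in both repeats are
#' excluded from numerator and denominator; a gap against a residue counts
#' as a mismatch. The value lies on the discrete grid `n / L0` (up to the
#' double-gap exclusion, which shrinks the effective denominator).
#'
#' @param enc An `encoded_msa` of width `2 * L0` (or an integer row vector).
#' @param L0 Repeat-unit width.
#' @return Numeric vector of per-row identities.
#' @export
pair_identity <- function(enc, L0) {
  X <- if (inherits(enc, "encoded_msa")) enc$matrix else
    matrix(enc, nrow = 1L)
  stopifnot(ncol(X) == 2L * L0)
  gap <- if (inherits(enc, "encoded_msa")) enc$q - 1L else max(X)
  A <- X[, seq_len(L0), drop = FALSE]
  B <- X[, L0 + seq_len(L0), drop = FALSE]
  both_gap <- (A == gap) & (B == gap)
  denom <- L0 - rowSums(both_gap)
  if (any(denom == 0L)) stop("undefined identity: a row is all double-gap columns")
  rowSums((A == B) & !both_gap) / denom
}

# Snap identities onto the n/L0 grid used for histogramming.
snap_identity_bins <- function(id, L0) round(id * L0) / L0

#' Consecutive-repeat vs random-pair identity distributions
#'
#' `nu` is the base-weight-weighted histogram of pairwise repeat identity
#' over the natural tandem rows. `nu_random` is the unweighted histogram of
#' identity between randomly assembled pairs of repeat units drawn (with
#' replacement) from different proteins of the family. Both live on the
#' discrete grid `n / L0`.
#'
#' @param msa A `tandem_msa` with `n_units = 2`.
#' @param base_weights A `weight_vector` computed on the same alignment.
#' @param n_random_pairs Number of random cross-protein unit pairs
#'   (default `max(10 * M, 10000)`).
#' @param seed Integer seed for the random pairing.
#' @return An `identity_distribution`: `bins` (values n/L0), `nu`,
#'   `nu_random` (both sum to 1), per-row `identities`, and the sampling
#'   metadata.
#' @export
identity_distributions <- function(msa, base_weights, n_random_pairs = NULL,
                                   seed = 1L) {
  stopifnot(inherits(msa, "tandem_msa"), msa$n_units == 2L,
            inherits(base_weights, "weight_vector"))
  enc <- encode_msa(msa)
  M <- nrow(enc$matrix)
  stopifnot(length(base_weights$weights) == M)
  L0 <- msa$L0
  if (is.null(n_random_pairs)) n_random_pairs <- max(10L * M, 10000L)
  bins <- (0:L0) / L0

  ids <- snap_identity_bins(pair_identity(enc, L0), L0)
  nu <- weighted_bin_hist(ids, base_weights$weights, bins)

  # pool of single units tagged by source protein
  units <- rbind(enc$matrix[, seq_len(L0), drop = FALSE],
                 enc$matrix[, L0 + seq_len(L0), drop = FALSE])
  unit_prot <- rep(msa$protein_id, 2L)
  if (length(unique(unit_prot)) < 2L)
    stop("cannot build random pairs: fewer than 2 distinct proteins")
  gap <- enc$q - 1L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  i1 <- sample.int(nrow(units), n_random_pairs, replace = TRUE)
  i2 <- sample.int(nrow(units), n_random_pairs, replace = TRUE)
  clash <- unit_prot[i1] == unit_prot[i2]
  while (any(clash)) {
    i2[clash] <- sample.int(nrow(units), sum(clash), replace = TRUE)
    clash <- unit_prot[i1] == unit_prot[i2]
  }
  A <- units[i1, , drop = FALSE]; B <- units[i2, , drop = FALSE]
  both_gap <- (A == gap) & (B == gap)
  denom <- pmax(L0 - rowSums(both_gap), 1L)
  rid <- snap_identity_bins(rowSums((A == B) & !both_gap) / denom, L0)
  nu_random <- weighted_bin_hist(rid, rep(1, n_random_pairs), bins)

  structure(list(bins = bins, nu = nu, nu_random = nu_random,
                 identities = ids, n_random_pairs = n_random_pairs,
                 seed = as.integer(seed)),
            class = "identity_distribution")
}

weighted_bin_hist <- function(values, weights, bins) {
  idx <- match(round(values, 10), round(bins, 10))
  stopifnot(!anyNA(idx))
  h <- numeric(length(bins))
  agg <- tapply(weights, idx, sum)
  h[as.integer(names(agg))] <- agg
  h / sum(h)
}

#' Identity-equalized sequence weights
#'
#' Reweights each tandem row by the ratio of random-pair to natural
#' consecutive-pair identity frequency at the row's identity bin:
#' `w_c = w * nu_random(%Id) / nu(%Id)`. With `nu` defined as the
#' base-weight-weighted histogram, the equalized weighted identity histogram
#' equals `nu_random` exactly. Rows falling in bins where `nu_random = 0`
#' receive weight zero; optional Laplace smoothing adds one pseudo-pair to
#' every bin of `nu_random` before forming the ratio.
#'
#' @param base A `weight_vector` (normalized Henikoff weights).
#' @param iddist An `identity_distribution` computed from the same rows with
#'   the same base weights.
#' @param identities Optional per-row identities (defaults to those stored
#'   in `iddist`).
#' @param smooth Logical; Laplace-smooth `nu_random` (default FALSE).
#' @return A `weight_vector` with `kind = "equalized"` and recomputed
#'   `M_eff`.
#' @export
equalize_weights <- function(base, iddist, identities = NULL, smooth = FALSE) {
  stopifnot(inherits(base, "weight_vector"),
            inherits(iddist, "identity_distribution"))
  if (is.null(identities)) identities <- iddist$identities
  if (length(identities) != length(base$weights))
    stop("identities vector length != number of weights")
  nu_r <- iddist$nu_random
  if (smooth) {
    counts <- nu_r * iddist$n_random_pairs + 1
    nu_r <- counts / sum(counts)
  }
  idx <- match(round(identities, 10), round(iddist$bins, 10))
  stopifnot(!anyNA(idx))
  ratio <- ifelse(iddist$nu[idx] > 0, nu_r[idx] / iddist$nu[idx], 0)
  new_weight_vector(base$weights * ratio, kind = "equalized")
}

# Save/restore the global RNG so seeded helpers do not perturb user state.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
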