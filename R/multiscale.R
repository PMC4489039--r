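#' Reconstruct a multi-repeat DI matrix from pairwise calculations
#'
#' Assembles an `n_units * L0` DI matrix from corrected two-repeat DI
#' matrices computed on n-th-neighbour alignments: every intra-repeat
#' (diagonal) block is the first-repeat block of the order-1 matrix (the
#' largest alignment), and the block coupling repeats `a` and `a + n` is the
#' inter-repeat block of the order-n matrix. This makes joint analysis of
#' arbitrarily long arrays affordable: the cost of a single inversion grows
#' quadratically with total length, whereas the pairwise route stays at
#' `2 * L0`.
#'
#' @param pairwise Named list mapping neighbour order (`"1"`, `"2"`, ...) to
#'   corrected `di_matrix` objects of width `2 * L0`.
#' @param n_units Number of repeats in the reconstructed array.
#' @param L0 Repeat-unit width.
#' @return A corrected `di_matrix` of width `n_units * L0`.
#' @export
reconstruct_array_di <- function(pairwise, n_units, L0) {
  stopifnot(n_units >= 2L)
  orders <- as.character(seq_len(n_units - 1L))
  missing_orders <- setdiff(orders, names(pairwise))
  if (length(missing_orders))
    stop("missing neighbour order(s): ", paste(missing_orders, collapse = ", "))
  for (o in orders) {
    if (!inherits(pairwise[[o]], "di_matrix") ||
        nrow(pairwise[[o]]$values) != 2L * L0)
      stop("pairwise matrix for order ", o, " must be a di_matrix of width 2*L0")
  }
  if (n_units == 2L) return(pairwise[["1"]])
  L <- n_units * L0
  out <- matrix(0, L, L)
  intra <- pairwise[["1"]]$values[seq_len(L0), seq_len(L0)]
  for (a in seq_len(n_units)) {
    idx <- (a - 1L) * L0 + seq_len(L0)
    out[idx, idx] <- intra
  }
  for (n in seq_len(n_units - 1L)) {
    inter <- pairwise[[as.character(n)]]$values[seq_len(L0),
                                                L0 + seq_len(L0)]
    for (a in seq_len(n_units - n)) {
      ia <- (a - 1L) * L0 + seq_len(L0)
      ib <- (a + n - 1L) * L0 + seq_len(L0)
      out[ia, ib] <- inter
      out[ib, ia] <- t(inter)
    }
  }
  diag(out) <- 0
  new_di_matrix(out, stage = "corrected",
                weighting = pairwise[["1"]]$weighting,
                meta = list(L0 = L0, n_units = n_units,
                            reconstructed = TRUE))
}

#' Decompose a reconstructed array DI matrix into its blocks
#'
#' Inverse bookkeeping of [reconstruct_array_di()]: returns the intra-repeat
#' block and one inter-repeat block per neighbour order.
#'
#' @param di A `di_matrix` of width `n_units * L0`.
#' @param n_units,L0 Array geometry.
#' @return List with `intra` and `inter` (named by order).
#' @export
decompose_array_di <- function(di, n_units, L0) {
  stopifnot(inherits(di, "di_matrix"), nrow(di$values) == n_units * L0)
  inter <- lapply(seq_len(n_units - 1L), function(n) {
    di$values[seq_len(L0), n * L0 + seq_len(L0)]
  })
  names(inter) <- as.character(seq_len(n_units - 1L))
  list(intra = di$values[seq_len(L0), seq_len(L0)], inter = inter)
}

#' Fraction of inter-repeat hits per neighbour order
#'
#' @param hits_by_order Named list mapping neighbour order to `hit_set`
#'   objects computed on matching `L0`.
#' @return data.frame with columns `n` (order) and `fraction` (inter-repeat
#'   share of hits, `NA` for empty hit sets).
#' @export
inter_repeat_hit_fraction <- function(hits_by_order) {
  n <- as.integer(names(hits_by_order))
  frac <- vapply(hits_by_order, function(h) {
    stopifnot(inherits(h, "hit_set"))
    if (!nrow(h$pairs)) return(NA_real_)
    mean(h$pairs$class != "intra_repeat")
  }, numeric(1))
  data.frame(n = n, fraction = unname(frac))[order(n), ]
}

#' Fit an exponential decay of inter-repeat signal with repeat separation
#'
#' Least-squares fit of `y = A * 2^(-n / h)` to the per-order inter-repeat
#' hit fractions; `h` is the half-length in repeat units (the separation
#' over which the signal halves; e-folding length `h / ln 2`). The fitted
#' half-length is invariant under uniform scaling of the amplitudes.
#'
#' @param series data.frame with columns `n` and `fraction`
#'   (from [inter_repeat_hit_fraction()]); rows with `NA` are dropped.
#' @return List with `amplitude`, `half_length`, `residual` (residual norm)
#'   and the `fit` object. A non-decreasing series triggers a warning and
#'   returns `half_length = Inf`.
#' @export
fit_interaction_decay <- function(series) {
  series <- series[!is.na(series$fraction), , drop = FALSE]
  if (nrow(series) < 3L) stop("need at least 3 points to fit the decay")
  stopifnot(all(series$fraction >= 0 & series$fraction <= 1))
  y <- series$fraction; n <- series$n
  if (all(diff(y[order(n)]) >= 0)) {
    warning("series is non-decreasing: no decay to fit (half-length = Inf)")
    return(list(amplitude = mean(y), half_length = Inf,
                residual = sqrt(sum((y - mean(y))^2)), fit = NULL))
  }
  # log-linear start values on the positive part
  pos <- y > 0
  start_h <- if (sum(pos) >= 2) {
    sl <- coef(lm(log2(y[pos]) ~ n[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else 1
  } else 1
  start_A <- max(y) * 2^(min(n) / start_h)
  fit <- minpack.lm::nlsLM(
    fraction ~ A * 2^(-n / h), data = series,
    start = list(A = as.numeric(start_A), h = as.numeric(start_h)),
    lower = c(A = 0, h = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  list(amplitude = unname(est["A"]), half_length = unname(est["h"]),
       residual = sqrt(sum(residuals(fit)^2)), fit = fit)
}

#' Extract an n-th-neighbour pair alignment from an array alignment
#'
#' From a tandem alignment of `n_units` repeats, builds the two-unit
#' alignment whose rows concatenate unit `a` with unit `a + n` for every
#' admissible `a` — the input for a pairwise DI calculation at neighbour
#' order `n`.
#'
#' @param msa A `tandem_msa` with `n_units > n`.
#' @param neighbour_order Separation n between the paired units.
#' @return A `tandem_msa` with `n_units = 2` and the given
#'   `neighbour_order`.
#' @export
tandem_pairs_from_array <- function(msa, neighbour_order = 1L) {
  stopifnot(inherits(msa, "tandem_msa"), neighbour_order >= 1L,
            msa$n_units > neighbour_order)
  L0 <- msa$L0
  n_pairs <- msa$n_units - neighbour_order
  rows <- character(0); prot <- character(0)
  for (a in seq_len(n_pairs)) {
    u1 <- substr(msa$rows, (a - 1L) * L0 + 1L, a * L0)
    u2 <- substr(msa$rows, (a + neighbour_order - 1L) * L0 + 1L,
                 (a + neighbour_order) * L0)
    rows <- c(rows, paste0(u1, u2))
    prot <- c(prot, msa$protein_id)
  }
  new_tandem_msa(rows = rows, n_units = 2L, L0 = L0, protein_id = prot,
                 spans = rep("", length(rows)),
                 neighbour_order = neighbour_order, alphabet = msa$alphabet)
}
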