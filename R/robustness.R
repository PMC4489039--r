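#' DI on nested subsamples of an alignment
#'
#' Builds nested row subsets (each smaller subset contained in the next) by
#' a single seeded permutation and runs the full corrected-DI pipeline —
#' weights recomputed per subset, optional identity equalization, scrambled
#' null subtraction — on each. The full set (`fraction = 1`) reproduces the
#' full-data result exactly.
#'
#' @param msa A `tandem_msa`.
#' @param fractions Ascending row fractions ending in 1.0
#'   (default `c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)`).
#' @param seed Seed for the subset draw.
#' @param weighting `"plain"` or `"equalized"` (DI vs DI_id).
#' @param lambda,null_seed,pair_seed Passed to [repeat_dca()].
#' @return A `convergence_report` skeleton: `fractions`, `sizes`, per-subset
#'   `M_eff`, and `di_by_subset` (list of corrected `di_matrix`, ordered by
#'   subset size).
#' @export
subsample_di_series <- function(msa, fractions = c(0.01, 0.02, 0.05, 0.1,
                                                   0.2, 0.5, 1),
                                seed = 1L,
                                weighting = c("equalized", "plain"),
                                lambda = "meff", null_seed = 1L,
                                pair_seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(msa, "tandem_msa"),
            !is.unsorted(fractions, strictly = TRUE),
            abs(fractions[length(fractions)] - 1) < 1e-12)
  M <- length(msa$rows)
  old <- get_rng_state()
  set.seed(as.integer(seed))
  perm <- sample.int(M)
  restore_rng_state(old)
  sizes <- pmax(ceiling(fractions * M), 1L)
  if (any(sizes == 0L)) stop("subset with zero rows")
  di_by_subset <- vector("list", length(sizes))
  m_eff <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    idx <- sort(perm[seq_len(sizes[s])])
    sub <- new_tandem_msa(rows = msa$rows[idx], n_units = msa$n_units,
                          L0 = msa$L0, protein_id = msa$protein_id[idx],
                          spans = msa$spans[idx],
                          neighbour_order = msa$neighbour_order,
                          alphabet = msa$alphabet)
    di <- repeat_dca(sub, weighting = weighting, lambda = lambda,
                     null_seed = null_seed, pair_seed = pair_seed)
    m_eff[s] <- di$meta$weights$M_eff
    di$meta$weights <- NULL
    di_by_subset[[s]] <- di
  }
  structure(list(fractions = fractions, sizes = sizes, M_eff = m_eff,
                 di_by_subset = di_by_subset, weighting = weighting,
                 seed = as.integer(seed)),
            class = "convergence_report")
}

#' Per-pair convergence of DI across subset sizes
#'
#' A pair (i, j) is converged at subset `s` when, for `s` and every larger
#' subset `t`: (a) `|DI_ij^t - DI_ij| < tol * (max(DI) - min(DI))`, where
#' `DI_ij` is the full-data value and the range runs over all positions and
#' all subsets; and (b) the standard deviation of the pair's DI over subsets
#' `>= t` is below `tol` times the reference standard deviation — by default
#' the DI values pooled over all pairs and subsets (`sd_reference =
#' "pooled"`), with the per-pair across-subset alternative available. The
#' smallest such `s` is `converged_at`; requiring the criteria from `s`
#' upward makes convergence monotone in subset size by construction, and the
#' full subset always converges (zero deviation, single-point sd).
#'
#' @param report A `convergence_report` from [subsample_di_series()].
#' @param tol_fraction Convergence tolerance as a fraction of the reference
#'   scale (default 0.01).
#' @param sd_reference `"pooled"` (default) or `"per_pair"`.
#' @return The report with `converged_at` (matrix of subset indices, NA =
#'   never), `fraction_converged` (per subset size), `tol_fraction`.
#' @export
convergence_report <- function(report, tol_fraction = 0.01,
                               sd_reference = c("pooled", "per_pair")) {
  stopifnot(inherits(report, "convergence_report"))
  sd_reference <- match.arg(sd_reference)
  S <- length(report$di_by_subset)
  if (S < 2L) stop("need at least 2 subsets")
  L <- nrow(report$di_by_subset[[1]]$values)
  ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  # pairs x subsets matrix of DI values
  V <- vapply(report$di_by_subset, function(d) d$values[ut],
              numeric(nrow(ut)))
  full <- V[, S]
  rng <- max(V) - min(V)
  sd_ref <- if (sd_reference == "pooled") sd(as.vector(V)) else
    apply(V, 1L, sd)
  dev_ok <- abs(V - full) < tol_fraction * rng
  tail_sd_ok <- matrix(FALSE, nrow(V), S)
  for (s in seq_len(S)) {
    tail_sd <- apply(V[, s:S, drop = FALSE], 1L, function(x)
      if (length(x) > 1L) sd(x) else 0)
    tail_sd_ok[, s] <- tail_sd < tol_fraction * sd_ref
  }
  ok <- dev_ok & tail_sd_ok
  # converged at s iff ok holds at every t >= s
  ok_from <- ok
  for (s in rev(seq_len(S - 1L))) ok_from[, s] <- ok[, s] & ok_from[, s + 1L]
  converged_at <- apply(ok_from, 1L, function(x)
    if (any(x)) which(x)[1] else NA_integer_)
  frac <- vapply(seq_len(S), function(s)
    mean(!is.na(converged_at) & converged_at <= s), numeric(1))
  report$converged_at <- data.frame(i = ut[, 1], j = ut[, 2],
                                    converged_at = converged_at)
  report$fraction_converged <- frac
  report$tol_fraction <- tol_fraction
  report
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence_report:", length(x$sizes), "nested subsets, sizes",
      paste(x$sizes, collapse = "/"), "\n")
  if (!is.null(x$fraction_converged))
    cat("  fraction converged:",
        paste(sprintf("%.2f", x$fraction_converged), collapse = " "), "\n")
  invisible(x)
}

#' TSV summary of a convergence report
#'
#' @param report A completed `convergence_report`.
#' @param path Output path.
#' @export
write_convergence_tsv <- function(report, path) {
  stopifnot(!is.null(report$fraction_converged))
  df <- data.frame(fraction = report$fractions, size = report$sizes,
                   M_eff = report$M_eff,
                   fraction_converged = report$fraction_converged)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
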