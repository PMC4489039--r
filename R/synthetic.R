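#' Planted coupling topology for a synthetic repeat family
#'
#' Describes where true couplings live on a repeat array: intra-repeat pairs
#' (replicated identically in every unit, as repeats share one fold),
#' interface pairs between adjacent units, and optionally the full symmetric
#' diagonal `(i, i + L0)` of true contacts (the architecture in which every
#' equivalent-position pair really touches).
#'
#' @param L0 Repeat-unit width.
#' @param n_units Number of units.
#' @param intra_pairs 2-column matrix of within-unit pairs (1-based,
#'   `i < j <= L0`).
#' @param interface_pairs 2-column matrix of pairs `(i, j)` meaning position
#'   `i` of unit a couples to position `j` of unit a+1.
#' @param include_symmetric_diagonal Plant `(i, i + L0)` couplings for every
#'   `i` (default FALSE).
#' @return A `planted_topology`.
#' @export
planted_topology <- function(L0, n_units = 2L,
                             intra_pairs = NULL, interface_pairs = NULL,
                             include_symmetric_diagonal = FALSE) {
  intra_pairs <- as_pair_matrix(intra_pairs)
  interface_pairs <- as_pair_matrix(interface_pairs)
  stopifnot(L0 >= 2L, n_units >= 2L,
            all(intra_pairs <= L0), all(interface_pairs <= L0))
  if (nrow(intra_pairs) && any(intra_pairs[, 1] >= intra_pairs[, 2]))
    stop("intra pairs must satisfy i < j")
  structure(list(L0 = L0, n_units = n_units, intra_pairs = intra_pairs,
                 interface_pairs = interface_pairs,
                 include_symmetric_diagonal = include_symmetric_diagonal),
            class = "planted_topology")
}

as_pair_matrix <- function(x) {
  if (is.null(x)) return(matrix(integer(0), 0, 2))
  x <- matrix(as.integer(x), ncol = 2)
  x
}

#' Generator configuration for synthetic repeat alignments
#'
#' @param q Alphabet size (number of residue states, gap excluded; the
#'   emitted alignment uses the first `q` amino-acid letters).
#' @param coupling_strength Magnitude of planted couplings.
#' @param field_scale Standard deviation of the random site fields
#'   (replicated across units, mimicking a conserved family profile).
#' @param M Number of sequences.
#' @param burn_in Gibbs burn-in sweeps.
#' @param thinning Sweeps between retained samples (single-chain mode).
#' @param bias_fraction Fraction phi of rows receiving the duplication bias.
#' @param mutation_rate Per-position mutation probability mu of the
#'   duplicated repeat.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(q = 4L, coupling_strength = 1.5,
                             field_scale = 0.3, M = 4000L,
                             burn_in = 1000L, thinning = 10L,
                             bias_fraction = 0, mutation_rate = 0.1,
                             seed = 1L) {
  stopifnot(q >= 2L, q <= 20L, M >= 1L, burn_in > 0L, thinning > 0L,
            bias_fraction >= 0, bias_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(q = as.integer(q), coupling_strength = coupling_strength,
                 field_scale = field_scale, M = as.integer(M),
                 burn_in = as.integer(burn_in), thinning = as.integer(thinning),
                 bias_fraction = bias_fraction, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Build Potts parameters with planted couplings
#'
#' Fields are drawn at random per unit position and replicated across units.
#' Each planted base pair gets a coupling matrix of the configured strength
#' favouring a random one-to-one subset of state combinations (a random
#' permutation pattern), shared across its replications. Overlapping planted
#' pairs collapse to a single entry with a warning.
#'
#' @param topology A `planted_topology`.
#' @param config A `generator_config`.
#' @return A `potts_model`: `L`, `q`, `h` (L x q fields), `J` (list of
#'   couplings `list(i, j, mat)` in tandem coordinates) and `ground_truth`
#'   (data.frame `i`, `j`, `type` of all planted pairs).
#' @export
make_planted_model <- function(topology, config) {
  stopifnot(inherits(topology, "planted_topology"),
            inherits(config, "generator_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  L0 <- topology$L0; nu <- topology$n_units
  L <- L0 * nu; q <- config$q
  h_unit <- matrix(rnorm(L0 * q, sd = config$field_scale), L0, q)
  h <- h_unit[rep(seq_len(L0), nu), , drop = FALSE]

  perm_coupling <- function() {
    P <- matrix(0, q, q)
    P[cbind(seq_len(q), sample.int(q))] <- config$coupling_strength
    P
  }
  J <- list(); gt <- list()
  add_pair <- function(i, j, mat, type) {
    key <- paste(i, j)
    if (key %in% names(J)) {
      warning("overlapping planted pair (", i, ", ", j, "): collapsed")
      return(invisible(NULL))
    }
    J[[key]] <<- list(i = i, j = j, mat = mat)
    gt[[key]] <<- data.frame(i = i, j = j, type = type)
  }
  if (nrow(topology$intra_pairs)) {
    for (p in seq_len(nrow(topology$intra_pairs))) {
      mat <- perm_coupling()
      for (u in seq_len(nu)) {
        off <- (u - 1L) * L0
        add_pair(topology$intra_pairs[p, 1] + off,
                 topology$intra_pairs[p, 2] + off, mat, "intra")
      }
    }
  }
  if (nrow(topology$interface_pairs)) {
    for (p in seq_len(nrow(topology$interface_pairs))) {
      mat <- perm_coupling()
      for (u in seq_len(nu - 1L)) {
        off <- (u - 1L) * L0
        add_pair(topology$interface_pairs[p, 1] + off,
                 topology$interface_pairs[p, 2] + off + L0, mat, "interface")
      }
    }
  }
  if (isTRUE(topology$include_symmetric_diagonal)) {
    for (i in seq_len(L0)) {
      mat <- perm_coupling()
      for (u in seq_len(nu - 1L)) {
        off <- (u - 1L) * L0
        add_pair(i + off, i + off + L0, mat, "symmetric_diagonal")
      }
    }
  }
  gt <- if (length(gt)) do.call(rbind, unname(gt)) else
    data.frame(i = integer(0), j = integer(0), type = character(0))
  rownames(gt) <- NULL
  structure(list(L = L, L0 = L0, n_units = nu, q = q, h = h,
                 J = unname(J), ground_truth = gt, seed = config$seed),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat("potts_model: L =", x$L, "(", x$n_units, "x", x$L0, "), q =", x$q,
      ",", length(x$J), "planted couplings\n")
  invisible(x)
}

#' Sample a synthetic tandem alignment from a Potts model
#'
#' Gibbs sampling with single-site updates. The default mode runs one
#' independent chain per sequence, all chains updated in vectorised
#' parallel sweeps; rows are then independent draws, which matters for the
#' downstream statistics. `mode = "single_chain"` instead thins one long
#' chain (`burn_in` plus `thinning` sweeps between samples). A model with
#' no couplings is sampled exactly from the independent-site distribution.
#' Rows get distinct synthetic protein identifiers so that cross-protein
#' random repeat pairs are well defined; the gap state is never emitted.
#'
#' @param model A `potts_model`.
#' @param config A `generator_config` (supplies `M`, `burn_in`, `thinning`,
#'   `seed`).
#' @param mode `"independent"` (default) or `"single_chain"`.
#' @return A `tandem_msa` of `M` rows and width `n_units * L0`, carrying the
#'   reduced alphabet of the model.
#' @export
sample_msa <- function(model, config, mode = c("independent", "single_chain")) {
  stopifnot(inherits(model, "potts_model"), inherits(config, "generator_config"))
  mode <- match.arg(mode)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  L <- model$L; q <- model$q; M <- config$M
  if (mode == "independent") {
    S <- matrix(sample.int(q, M * L, replace = TRUE), M, L)
    adj <- build_adjacency(model)
    coupled <- which(lengths(adj) > 0L)
    # uncoupled sites are independent: draw them exactly from softmax(h)
    for (i in setdiff(seq_len(L), coupled)) {
      p <- exp(model$h[i, ] - max(model$h[i, ]))
      S[, i] <- sample.int(q, M, replace = TRUE, prob = p)
    }
    if (length(coupled)) {
      for (sweep in seq_len(config$burn_in))
        S <- gibbs_sweep(S, model, adj, sites = coupled)
    }
  } else {
    adj <- build_adjacency(model)
    S <- matrix(0L, M, L)
    chain <- matrix(sample.int(q, L, replace = TRUE), 1L, L)
    for (sweep in seq_len(config$burn_in)) chain <- gibbs_sweep(chain, model, adj)
    for (m in seq_len(M)) {
      for (sweep in seq_len(config$thinning)) chain <- gibbs_sweep(chain, model, adj)
      S[m, ] <- chain
    }
  }
  encoded_states_to_tandem(S, model)
}

# Adjacency with row-indexable coupling matrices: contribution of partner j
# in state b to site i's state-a logit is tmat[b, a].
build_adjacency <- function(model) {
  adj <- vector("list", model$L)
  for (cp in model$J) {
    adj[[cp$i]] <- c(adj[[cp$i]], list(list(j = cp$j, tmat = t(cp$mat))))
    adj[[cp$j]] <- c(adj[[cp$j]], list(list(j = cp$i, tmat = cp$mat)))
  }
  adj
}

# One full vectorised Gibbs sweep; only coupled sites need resampling given
# the others (uncoupled sites are handled by the caller's init/fast path),
# but sweeping all sites keeps the update a proper kernel for any state.
gibbs_sweep <- function(S, model, adj, sites = seq_len(model$L)) {
  M <- nrow(S); q <- model$q
  for (i in sites) {
    logits <- matrix(model$h[i, ], M, q, byrow = TRUE)
    for (nb in adj[[i]]) logits <- logits + nb$tmat[S[, nb$j], , drop = FALSE]
    p <- exp(logits)
    for (k in 2:q) p[, k] <- p[, k] + p[, k - 1L]   # in-place row cumsum
    u <- runif(M) * p[, q]
    s <- rep.int(1L, M)
    for (k in seq_len(q - 1L)) s <- s + (p[, k] < u)
    S[, i] <- s
  }
  S
}

encoded_states_to_tandem <- function(S, model) {
  letters_q <- AA_LETTERS[seq_len(model$q)]
  rows <- apply(S, 1L, function(r) paste(letters_q[r], collapse = ""))
  M <- nrow(S)
  new_tandem_msa(rows = rows, n_units = model$n_units, L0 = model$L0,
                 protein_id = sprintf("SYN%06d", seq_len(M)),
                 spans = rep(paste(sprintf("%d-%d",
                                           (seq_len(model$n_units) - 1L) * model$L0 + 1L,
                                           seq_len(model$n_units) * model$L0),
                                   collapse = "+"), M),
                 alphabet = c(letters_q, GAP_CHAR))
}

#' Inject the consecutive-repeat duplication bias
#'
#' For a random `phi`-fraction of rows of a two-unit alignment, replaces the
#' second repeat by a copy of the first in which every position is mutated,
#' independently with probability `mu`, to a uniformly chosen different
#' state. This reproduces the inflated high-identity tail of natural
#' consecutive repeat pairs that the identity equalization is designed to
#' remove.
#'
#' @param msa A `tandem_msa` with `n_units = 2`.
#' @param phi Fraction of rows biased, in `[0, 1]`.
#' @param mu Per-position mutation probability, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The biased `tandem_msa`.
#' @export
apply_duplication_bias <- function(msa, phi, mu, seed = 1L) {
  stopifnot(inherits(msa, "tandem_msa"), msa$n_units == 2L,
            phi >= 0, phi <= 1, mu >= 0, mu <= 1)
  if (phi == 0) return(msa)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  enc <- encode_msa(msa)
  X <- enc$matrix
  q_states <- enc$q - 1L   # residue states, gap excluded
  L0 <- msa$L0
  M <- nrow(X)
  rows <- sample.int(M, round(phi * M))
  for (m in rows) {
    copy <- X[m, seq_len(L0)]
    mut <- which(runif(L0) < mu)
    for (p in mut) {
      alt <- setdiff(seq_len(q_states) - 1L, copy[p])
      copy[p] <- if (length(alt)) alt[sample.int(length(alt), 1L)] else copy[p]
    }
    X[m, L0 + seq_len(L0)] <- copy
  }
  enc$matrix <- X
  out <- msa
  out$rows <- decode_msa(enc)
  out
}

#' Exact distribution of a small Potts model
#'
#' Enumerates all `q^L` states and their Boltzmann probabilities. Intended
#' as an oracle for small systems (`q^L` capped at 2^20).
#'
#' @param model A `potts_model`.
#' @return List with `states` (q^L x L matrix, states 1..q) and `prob`.
#' @export
enumerate_potts <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  if (model$q^model$L > 2^20) stop("state space too large to enumerate")
  states <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L)))
  dimnames(states) <- NULL
  E <- numeric(nrow(states))
  for (i in seq_len(model$L)) E <- E + model$h[i, ][states[, i]]
  for (cp in model$J) E <- E + cp$mat[cbind(states[, cp$i], states[, cp$j])]
  p <- exp(E - max(E))
  list(states = states, prob = p / sum(p))
}

#' Exact single-site and pair marginals of a small Potts model
#'
#' @param model A `potts_model`.
#' @return List with `f1` (L x q) and `f2` (Lq x Lq, site-major blocks),
#'   in the layout used by [empirical_frequencies()].
#' @export
exact_frequencies <- function(model) {
  en <- enumerate_potts(model)
  L <- model$L; q <- model$q
  f1 <- matrix(0, L, q)
  for (i in seq_len(L))
    f1[i, ] <- vapply(seq_len(q), function(a)
      sum(en$prob[en$states[, i] == a]), numeric(1))
  f2 <- matrix(0, L * q, L * q)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    blk <- matrix(0, q, q)
    if (i == j) {
      diag(blk) <- f1[i, ]
    } else {
      for (a in seq_len(q))
        blk[a, ] <- vapply(seq_len(q), function(b)
          sum(en$prob[en$states[, i] == a & en$states[, j] == b]), numeric(1))
    }
    f2[(i - 1L) * q + seq_len(q), (j - 1L) * q + seq_len(q)] <- blk
  }
  list(f1 = f1, f2 = f2)
}

#' Sample an alignment directly from the enumerated distribution
#'
#' Exact multinomial sampling for small models; bypasses Gibbs entirely.
#'
#' @param model A `potts_model` small enough for [enumerate_potts()].
#' @param M Number of rows.
#' @param seed Integer seed.
#' @return A `tandem_msa`.
#' @export
sample_exact_msa <- function(model, M, seed = 1L) {
  en <- enumerate_potts(model)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(en$states), M, replace = TRUE, prob = en$prob)
  encoded_states_to_tandem(en$states[idx, , drop = FALSE], model)
}

#' Mean-field DI of the exact model distribution
#'
#' Runs the coupling inversion and two-site computation on the *exact*
#' enumerated marginals (no sampling, no pseudocount), giving the
#' infinite-data limit the empirical pipeline should approach.
#'
#' @param model A small `potts_model`.
#' @return A `di_matrix` with `stage = "raw"`.
#' @export
exact_mean_field_di <- function(model) {
  ef <- exact_frequencies(model)
  freqs <- structure(list(f1 = ef$f1, f2 = ef$f2, lambda = 0,
                          M_eff = Inf, q = model$q, L = model$L),
                     class = "frequency_model")
  direct_information(infer_couplings(freqs), freqs)
}

#' Weighted (or plain) pairwise mutual information of an alignment
#'
#' Simple empirical mutual information per column pair, used as an
#' independent check on generator output.
#'
#' @param enc An `encoded_msa`.
#' @return Symmetric L x L matrix of MI in nats.
#' @export
pairwise_mi <- function(enc) {
  stopifnot(inherits(enc, "encoded_msa"))
  X <- enc$matrix
  L <- ncol(X); M <- nrow(X)
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    tab <- table(X[, i], X[, j]) / M
    pi_ <- rowSums(tab); pj <- colSums(tab)
    nz <- tab > 0
    mi[i, j] <- mi[j, i] <- sum(tab[nz] * log(tab[nz] / outer(pi_, pj)[nz]))
  }
  mi
}

#' Write a synthetic family to disk
#'
#' Aligned FASTA plus a ground-truth TSV of planted pairs.
#'
#' @param msa A `tandem_msa` from [sample_msa()].
#' @param model The `potts_model` that produced it.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_family <- function(msa, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tandem_fasta(msa, file.path(dir, "alignment.fasta"))
  write.table(model$ground_truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
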