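#' Binary contact map from a PDB structure
#'
#' Two residues are in contact when the minimum distance over their heavy
#' (non-hydrogen) atom pairs is strictly below `cutoff` Angstrom.
#' Hetero-residues and waters are excluded; for multi-model files the first
#' model is used and only the first alternate location of each atom is
#' kept. Residues in the requested range that are absent from the model
#' yield all-zero rows and are flagged.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param chain Chain identifier.
#' @param residue_range Length-2 inclusive span of author residue numbers,
#'   or `NULL` for the whole chain.
#' @param cutoff Contact distance in Angstrom (default 8.0, strict `<`).
#' @return A `contact_map`: symmetric binary matrix with zero diagonal,
#'   `residue_ids` (author numbering), `chain`, `cutoff` and
#'   `missing_residues`.
#' @export
contact_map_from_pdb <- function(pdb, chain, residue_range = NULL,
                                 cutoff = 8.0) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = FALSE)
  at <- pdb$atom
  sel <- at$chain == chain & at$type == "ATOM" &
    toupper(at$elesy) != "H" & at$resid != "HOH"
  if ("alt" %in% names(at)) sel <- sel & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[sel, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' absent or has no heavy atoms")
  if (is.null(residue_range)) residue_range <- range(at$resno)
  stopifnot(length(residue_range) == 2L, residue_range[1] <= residue_range[2])
  at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ,
           drop = FALSE]
  if (!nrow(at)) stop("no atoms in residue range ",
                      paste(residue_range, collapse = ":"))
  resnos <- residue_range[1]:residue_range[2]
  present <- resnos %in% unique(at$resno)
  R <- length(resnos)
  cmap <- matrix(0L, R, R, dimnames = list(resnos, resnos))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  res_idx <- match(at$resno, resnos)
  for (a in seq_len(R - 1L)) {
    ia <- which(res_idx == a)
    if (!length(ia)) next
    for (b in (a + 1L):R) {
      ib <- which(res_idx == b)
      if (!length(ib)) next
      d2 <- min(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                      rowSums(xyz[ib, , drop = FALSE]^2), `+`) -
                  2 * tcrossprod(xyz[ia, , drop = FALSE],
                                 xyz[ib, , drop = FALSE]))
      if (sqrt(max(d2, 0)) < cutoff) cmap[a, b] <- cmap[b, a] <- 1L
    }
  }
  structure(list(matrix = cmap, residue_ids = resnos, chain = chain,
                 cutoff = cutoff, missing_residues = resnos[!present]),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map: chain", x$chain, "-", length(x$residue_ids), "residues,",
      sum(x$matrix) / 2, "contacts at <", x$cutoff, "A\n")
  invisible(x)
}

#' Map tandem-alignment columns to structure residues
#'
#' Globally aligns the ungapped sequence of one alignment row (the anchor)
#' to the structure's one-letter sequence and propagates the correspondence
#' back to alignment columns. Columns that are gapped in the anchor, or that
#' align opposite a gap in the structure sequence, are reported unmapped.
#'
#' @param msa A `tandem_msa`.
#' @param structure_sequence One-letter amino-acid string of the structure
#'   region.
#' @param residue_ids Residue numbers parallel to `structure_sequence`.
#' @param anchor_row Row index of the anchor sequence (default 1).
#' @param min_identity Minimum fractional identity of the anchor alignment
#'   below which the mapping is refused (default 0.30).
#' @return A `column_structure_map`: integer vector `column_to_residue`
#'   (NA = unmapped) of length `ncol(msa)`, plus `unmapped` and the anchor
#'   alignment identity.
#' @export
map_columns_to_structure <- function(msa, structure_sequence, residue_ids,
                                     anchor_row = 1L, min_identity = 0.30) {
  stopifnot(inherits(msa, "tandem_msa"),
            nchar(structure_sequence) == length(residue_ids))
  row <- msa$rows[anchor_row]
  cols <- strsplit(row, "")[[1]]
  ungapped_cols <- which(cols != GAP_CHAR)
  anchor_seq <- paste(cols[ungapped_cols], collapse = "")
  if (!nzchar(anchor_seq)) stop("anchor row is all gaps")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(anchor_seq), Biostrings::AAString(structure_sequence),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pid <- Biostrings::pid(aln) / 100
  if (!is.finite(pid)) pid <- 0
  if (pid < min_identity)
    stop(sprintf("anchor-to-structure identity %.2f below %.2f: refusing mapping",
                 pid, min_identity))
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  col_to_res <- rep(NA_integer_, nchar(row))
  ai <- 0L  # position in anchor_seq
  # subject may be clipped on the left in global-local alignment
  si <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") ai <- ai + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-")
      col_to_res[ungapped_cols[ai]] <- residue_ids[si]
  }
  structure(list(column_to_residue = col_to_res,
                 unmapped = which(is.na(col_to_res)),
                 anchor_row = anchor_row, identity = pid),
            class = "column_structure_map")
}

#' @export
print.column_structure_map <- function(x, ...) {
  cat("column_structure_map:", sum(!is.na(x$column_to_residue)), "of",
      length(x$column_to_residue), "columns mapped (anchor identity",
      sprintf("%.2f)", x$identity), "\n")
  invisible(x)
}

#' One-letter sequence of a PDB chain region
#'
#' Helper extracting the (author-numbered) sequence and residue ids of a
#' chain from a structure, for use with [map_columns_to_structure()].
#'
#' @param pdb Path to a PDB file or a `bio3d` `pdb` object.
#' @param chain Chain identifier.
#' @param residue_range Optional length-2 inclusive span.
#' @return List with `sequence` (string) and `residue_ids`.
#' @export
structure_sequence <- function(pdb, chain, residue_range = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = FALSE)
  sel <- bio3d::atom.select(pdb, "calpha", chain = chain)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (!is.null(residue_range))
    at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ,
             drop = FALSE]
  if (!nrow(at)) stop("no residues found for chain ", chain)
  list(sequence = paste(bio3d::aa321(at$resid), collapse = ""),
       residue_ids = at$resno)
}

#' True-positive rate of ranked pairs against a contact map
#'
#' Fraction of the top-`k` ranked pairs, both of whose endpoints map to
#' structure residues, that are contacts. Pairs with an unmapped endpoint
#' are skipped (and counted) rather than scored.
#'
#' @param ranked_pairs data.frame with columns `i`, `j` (alignment columns),
#'   ordered by decreasing score, e.g. from [rank_hits()] or a
#'   `hit_set$pairs`.
#' @param cmap A `contact_map`.
#' @param colmap A `column_structure_map` onto the same structure.
#' @param k Number of top pairs to evaluate (defaults to all).
#' @param min_separation Minimum `|j - i|` in alignment columns for a pair
#'   to be scored (default 1, i.e. no exclusion).
#' @return Scalar TPR in `[0, 1]`, with attributes `n_scored` and
#'   `n_skipped`.
#' @export
tp_rate <- function(ranked_pairs, cmap, colmap, k = nrow(ranked_pairs),
                    min_separation = 1L) {
  stopifnot(k >= 1, inherits(cmap, "contact_map"),
            inherits(colmap, "column_structure_map"))
  rp <- ranked_pairs[abs(ranked_pairs$j - ranked_pairs$i) >= min_separation, ,
                     drop = FALSE]
  rp <- rp[seq_len(min(k, nrow(rp))), , drop = FALSE]
  ri <- colmap$column_to_residue[rp$i]
  rj <- colmap$column_to_residue[rp$j]
  mapped <- !is.na(ri) & !is.na(rj)
  n_skipped <- sum(!mapped)
  ri <- as.character(ri[mapped]); rj <- as.character(rj[mapped])
  ok <- ri %in% rownames(cmap$matrix) & rj %in% rownames(cmap$matrix)
  n_skipped <- n_skipped + sum(!ok)
  ri <- ri[ok]; rj <- rj[ok]
  if (!length(ri)) stop("no scorable pairs: all endpoints unmapped")
  hits <- cmap$matrix[cbind(ri, rj)]
  structure(mean(hits == 1L), n_scored = length(ri), n_skipped = n_skipped)
}
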