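# Fixtures are built in code at test time; nothing binary is stored.

# Write a small Stockholm alignment and return its path.
write_test_stockholm <- function(headers, rows) {
  path <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-20s %s", headers, rows),
               "//"), path)
  path
}

write_test_fasta <- function(headers, rows) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), rows)), path)
  path
}

# Tandem alignment straight from row strings (bypasses unit concatenation).
tandem_from_rows <- function(rows, L0, n_units = 2L,
                             protein_id = sprintf("P%03d", seq_along(rows)),
                             alphabet = NULL) {
  repeatdca:::new_tandem_msa(rows = rows, n_units = n_units, L0 = L0,
                             protein_id = protein_id,
                             spans = rep("", length(rows)),
                             alphabet = alphabet)
}

# Random encoded alignment over q states (gap-free unless gap_frac > 0).
random_encoded <- function(M, L, q = 4L, gap_frac = 0, seed = 1L) {
  set.seed(seed)
  letters_q <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][seq_len(q)]
  chars <- matrix(sample(letters_q, M * L, replace = TRUE), M, L)
  if (gap_frac > 0) chars[runif(M * L) < gap_frac] <- "-"
  rows <- apply(chars, 1L, paste, collapse = "")
  encode_msa(tandem_from_rows(rows, L0 = L / 2L,
                              alphabet = c(letters_q, "-")))
}

# Corrected-stage DI matrix from an upper-triangle value vector.
di_from_values <- function(vals, L) {
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  repeatdca:::new_di_matrix(m, stage = "corrected")
}

# Minimal PDB text: one CB atom per residue at the given coordinates.
write_test_pdb <- function(coords, chain = "A",
                           resno = seq_len(nrow(coords)), resid = "ALA") {
  path <- tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d  CB  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), resid, chain, resno,
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "END"), path)
  path
}

# Hit set fixture with a prescribed intra/inter composition.
hit_set_fixture <- function(n_inter, n_total, L0 = 7L) {
  intra <- which(upper.tri(matrix(0, L0, L0)), arr.ind = TRUE)
  inter <- as.matrix(expand.grid(i = seq_len(L0), j = L0 + seq_len(L0)))
  inter <- inter[inter[, 2] - inter[, 1] != L0, , drop = FALSE]
  stopifnot(n_inter <= nrow(inter), n_total - n_inter <= nrow(intra))
  pick_intra <- intra[seq_len(n_total - n_inter), , drop = FALSE]
  pick_inter <- inter[seq_len(n_inter), , drop = FALSE]
  pairs <- data.frame(
    i = c(pick_intra[, 1], pick_inter[, 1]),
    j = c(pick_intra[, 2], pick_inter[, 2]),
    di = seq_len(n_total) / 10, cluster = 2L,
    class = repeatdca:::classify_pair(
      c(pick_intra[, 1], pick_inter[, 1]),
      c(pick_intra[, 2], pick_inter[, 2]), L0),
    stringsAsFactors = FALSE)
  repeatdca:::new_hit_set(pairs, background_cluster = 1L, n_clusters = 2L,
                          background_max = 0)
}
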