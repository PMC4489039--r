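#' @importFrom stats hclust dist sd median quantile rnorm runif setNames coef cor lm residuals
#' @importFrom utils read.table write.table
NULL

# Canonical amino-acid alphabet; the gap state is always last.
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP_CHAR <- "-"
AMBIGUITY_CODES <- c("B", "Z", "X", "U", "O", "J")

#' Read a repeat-unit multiple sequence alignment
#'
#' Parses an aligned set of repeat units from a Stockholm or aligned-FASTA
#' file. Sequence names are expected in the PFAM style `"ID/start-end"`;
#' units whose header carries no residue span are kept but flagged, and are
#' later excluded from tandem concatenation (their separation to neighbours
#' is undefined). Rows are uppercased and `.` gaps normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"stockholm"` or `"fasta"`. Defaults to guessing from the
#'   file extension (`.sto`/`.stk` vs anything else).
#' @return A `repeat_unit_msa` object: a list with `units` (data.frame with
#'   `protein_id`, `start`, `end`), `rows` (gapped strings), `columns`
#'   (retained column indices into the original alignment) and `L0` (width).
#' @export
read_unit_msa <- function(path, format = c("auto", "stockholm", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    rec <- read_stockholm(path)
  } else {
    aln <- Biostrings::readBStringSet(path)
    rec <- list(names = names(aln), rows = as.character(aln))
  }
  if (length(rec$rows) == 0L) stop("alignment file contains no sequences: ", path)
  rows <- unname(toupper(gsub(".", "-", rec$rows, fixed = TRUE)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("format error: unequal row widths (", paste(unique(widths), collapse = ", "),
         ") in ", path)
  }
  hdr <- parse_unit_headers(rec$names)
  new_repeat_unit_msa(units = hdr, rows = rows, columns = seq_len(widths[1]),
                      L0 = widths[1])
}

new_repeat_unit_msa <- function(units, rows, columns, L0) {
  structure(list(units = units, rows = rows, columns = columns, L0 = L0),
            class = "repeat_unit_msa")
}

#' @export
print.repeat_unit_msa <- function(x, ...) {
  cat("repeat_unit_msa:", length(x$rows), "units, width L0 =", x$L0, "\n")
  invisible(x)
}

# Minimal Stockholm reader (sequence lines only; multi-block files supported).
# No installed R package parses Stockholm, so this is authored here.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  keep <- !grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))
  seqs <- list()
  for (ln in lines[keep]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
    nm <- parts[1]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], parts[2])
  }
  list(names = names(seqs), rows = unlist(seqs, use.names = FALSE))
}

# "P12345/10-42" -> protein_id, start, end; spanless headers get NA bounds.
parse_unit_headers <- function(names) {
  m <- regmatches(names, regexec("^(\\S+?)/(\\d+)-(\\d+)\\s*$", names))
  protein_id <- character(length(names))
  start <- end <- rep(NA_integer_, length(names))
  for (k in seq_along(names)) {
    if (length(m[[k]]) == 4L) {
      protein_id[k] <- m[[k]][2]
      start[k] <- as.integer(m[[k]][3])
      end[k] <- as.integer(m[[k]][4])
      if (start[k] > end[k]) stop("invalid span (start > end) in header: ", names[k])
    } else {
      protein_id[k] <- sub("\\s.*$", "", names[k])
    }
  }
  data.frame(protein_id = protein_id, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Remove gap-rich columns from a repeat-unit alignment
#'
#' Drops every column whose gap fraction is strictly greater than
#' `max_gap_fraction` (a column with exactly the threshold fraction of gaps
#' is retained). The retained-column map is kept so filtered coordinates can
#' be traced back to the original alignment. Idempotent.
#'
#' @param msa A `repeat_unit_msa`.
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.70).
#' @return A filtered `repeat_unit_msa` with updated `L0` and `columns`.
#' @export
filter_gap_columns <- function(msa, max_gap_fraction = 0.70) {
  stopifnot(inherits(msa, "repeat_unit_msa"),
            max_gap_fraction > 0, max_gap_fraction < 1)
  chars <- do.call(rbind, strsplit(msa$rows, ""))
  gap_frac <- colMeans(chars == GAP_CHAR)
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("empty alignment: all columns exceed the gap threshold")
  rows <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  new_repeat_unit_msa(units = msa$units, rows = rows,
                      columns = msa$columns[keep], L0 = sum(keep))
}

#' Assemble a concatenated n-neighbour tandem alignment
#'
#' Concatenates repeat units of the same protein into tandem rows. For
#' `neighbour_order` n, unit i is joined with unit i+n provided every
#' consecutive step along the intervening array satisfies the separation
#' rule: `start(next) - end(prev) - 1 < L0/3` residues between units. For
#' `n_units > 2` the rule is enforced between every consecutive pair of the
#' concatenated stretch.
#'
#' @param msa A gap-filtered `repeat_unit_msa`.
#' @param n_units Number of units per row (>= 2).
#' @param neighbour_order Neighbour order n; 1 joins consecutive units.
#' @param min_rows Data-quality floor on the number of rows; fewer rows sets
#'   the `below_floor` flag (a warning, not an error) so that small synthetic
#'   alignments remain usable.
#' @return A `tandem_msa`: rows of width `n_units * L0`, per-row provenance
#'   (protein and unit spans), `neighbour_order`, and the `below_floor` flag.
#' @export
build_tandem_msa <- function(msa, n_units = 2L, neighbour_order = 1L,
                             min_rows = 1500L) {
  stopifnot(inherits(msa, "repeat_unit_msa"), n_units >= 2L, neighbour_order >= 1L)
  known <- !is.na(msa$units$start) & !is.na(msa$units$end)
  units <- msa$units[known, , drop = FALSE]
  rows <- msa$rows[known]
  ord <- order(units$protein_id, units$start)
  units <- units[ord, , drop = FALSE]
  rows <- rows[ord]
  L0 <- msa$L0
  max_sep <- L0 / 3

  out_rows <- character(0)
  out_prot <- character(0)
  out_spans <- character(0)
  for (pid in unique(units$protein_id)) {
    idx <- which(units$protein_id == pid)
    if (length(idx) < 2L) next
    st <- units$start[idx]; en <- units$end[idx]
    # adjacency along the sorted array: TRUE when step k -> k+1 is tight
    ok_step <- (st[-1] - en[-length(en)] - 1) < max_sep
    # offsets of the n_units constituent units: i, i+n, i+2n, ...
    span_units <- (n_units - 1L) * neighbour_order
    if (length(idx) <= span_units) next
    for (i in seq_len(length(idx) - span_units)) {
      steps <- i:(i + span_units - 1L)
      if (all(ok_step[steps])) {
        members <- idx[seq(i, i + span_units, by = neighbour_order)]
        out_rows <- c(out_rows, paste(rows[members], collapse = ""))
        out_prot <- c(out_prot, pid)
        out_spans <- c(out_spans,
                       paste(sprintf("%d-%d", units$start[members],
                                     units$end[members]), collapse = "+"))
      }
    }
  }
  if (!length(out_rows)) stop("empty alignment: no unit pairs satisfy the separation rule")
  new_tandem_msa(rows = out_rows, n_units = n_units, L0 = L0,
                 protein_id = out_prot, spans = out_spans,
                 neighbour_order = neighbour_order,
                 below_floor = length(out_rows) < min_rows)
}

new_tandem_msa <- function(rows, n_units, L0, protein_id, spans,
                           neighbour_order = 1L, below_floor = FALSE,
                           alphabet = NULL) {
  stopifnot(all(nchar(rows) == n_units * L0))
  structure(list(rows = rows, n_units = n_units, L0 = L0,
                 protein_id = protein_id, spans = spans,
                 neighbour_order = neighbour_order,
                 below_floor = below_floor, alphabet = alphabet),
            class = "tandem_msa")
}

#' @export
print.tandem_msa <- function(x, ...) {
  cat("tandem_msa:", length(x$rows), "rows,", x$n_units, "units of L0 =",
      x$L0, "(neighbour order", paste0(x$neighbour_order, ")"),
      if (isTRUE(x$below_floor)) "[below sequence floor]" else "", "\n")
  invisible(x)
}

#' Write a tandem alignment as aligned FASTA
#'
#' Headers take the form `proteinID/s1-e1+s2-e2`.
#'
#' @param msa A `tandem_msa`.
#' @param path Output file path.
#' @export
write_tandem_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "tandem_msa"))
  x <- Biostrings::BStringSet(msa$rows)
  names(x) <- paste0(msa$protein_id, "/", msa$spans)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Encode a tandem alignment as an integer matrix
#'
#' Maps residues to integers in `[0, q-1]` with a deterministic codebook:
#' the 20 amino acids in alphabetical one-letter order, gap last. Ambiguity
#' codes (B, Z, X, U, O, J) map to the gap state and are counted. Synthetic
#' alignments generated over a reduced alphabet carry their own codebook in
#' `msa$alphabet` and are encoded against it.
#'
#' @param msa A `tandem_msa` (or a character vector of equal-width rows).
#' @param include_gap Keep the gap state in the codebook (default TRUE).
#'   `FALSE` encodes a gap-free alignment over the residue alphabet only
#'   (the last residue state then serves as the inference gauge); any gap or
#'   ambiguity character is an error in that mode.
#' @return An `encoded_msa`: list with `matrix` (M x L, values in 0..q-1),
#'   `q`, `alphabet`, and `ambiguity_count`.
#' @export
encode_msa <- function(msa, include_gap = TRUE) {
  if (inherits(msa, "tandem_msa")) {
    rows <- msa$rows
    alphabet <- msa$alphabet
  } else {
    rows <- msa
    alphabet <- NULL
  }
  if (is.null(alphabet)) alphabet <- c(AA_LETTERS, GAP_CHAR)
  stopifnot(alphabet[length(alphabet)] == GAP_CHAR)
  if (!include_gap) alphabet <- alphabet[-length(alphabet)]
  q <- length(alphabet)
  code <- setNames(seq_len(q) - 1L, alphabet)
  gap_code <- q - 1L
  chars <- do.call(rbind, strsplit(rows, ""))
  amb <- chars %in% AMBIGUITY_CODES & !(chars %in% alphabet)
  n_amb <- sum(amb)
  chars[amb] <- GAP_CHAR
  enc <- code[chars]
  if (anyNA(enc)) {
    bad <- which(is.na(matrix(enc, nrow(chars), ncol(chars))), arr.ind = TRUE)[1, ]
    stop("encoding error: unmappable character '",
         chars[bad[1], bad[2]], "' at row ", bad[1], ", column ", bad[2])
  }
  structure(list(matrix = matrix(as.integer(enc), nrow(chars), ncol(chars)),
                 q = q, alphabet = alphabet, ambiguity_count = n_amb),
            class = "encoded_msa")
}

#' Decode an encoded alignment back to strings
#'
#' @param enc An `encoded_msa`.
#' @return Character vector of rows.
#' @export
decode_msa <- function(enc) {
  stopifnot(inherits(enc, "encoded_msa"))
  apply(enc$matrix, 1L, function(r) paste(enc$alphabet[r + 1L], collapse = ""))
}
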