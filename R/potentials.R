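# Amino-acid alphabet and knowledge-based contact potentials.
#
# The pairwise interaction energy U is a symmetric 20x20 table of contact
# energies between the canonical amino acids (RT-scale, dimensionless as
# published). The default is the Miyazawa-Jernigan 1996 e_ij table; any
# other 20x20 symmetric table can be loaded from a plain-text file.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes of the canonical amino acids, in alphabetical
#' order. This is the only residue alphabet the package accepts in strict
#' mode; B, J, O, U, X, Z and the gap character are not part of it.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residue order used by the Miyazawa-Jernigan 1996 publication; the
# embedded constant below is the upper triangle of their e_ij table read
# row-wise in this order.
MJ_ORDER <- "CMFILVWYAGTSNQDEHRKP"
MJ1996_UPPER <- c(
  -5.44, -4.99, -5.80, -5.50, -5.83, -4.96, -4.95, -4.16, -3.57, -3.16,
  -3.11, -2.86, -2.59, -2.85, -2.41, -2.27, -3.60, -2.57, -1.95, -3.07,
  -5.46, -6.56, -6.02, -6.41, -5.32, -5.55, -4.91, -3.94, -3.39, -3.51,
  -3.03, -2.95, -3.30, -2.57, -2.89, -3.98, -3.12, -2.48, -3.45, -7.26,
  -6.84, -7.28, -6.29, -6.16, -5.66, -4.81, -4.13, -4.28, -4.02, -3.75,
  -4.10, -3.48, -3.56, -4.77, -3.98, -3.36, -4.25, -6.54, -7.04, -6.05,
  -5.78, -5.25, -4.58, -3.78, -4.03, -3.52, -3.24, -3.67, -3.17, -3.27,
  -4.14, -3.63, -3.01, -3.76, -7.37, -6.48, -6.14, -5.67, -4.91, -4.16,
  -4.34, -3.92, -3.74, -4.04, -3.40, -3.59, -4.54, -4.03, -3.37, -4.20,
  -5.52, -5.18, -4.62, -4.04, -3.38, -3.46, -3.05, -2.83, -3.07, -2.48,
  -2.67, -3.58, -3.07, -2.49, -3.32, -5.06, -4.66, -3.82, -3.42, -3.22,
  -2.99, -3.07, -3.11, -2.84, -2.99, -3.98, -3.41, -2.69, -3.73, -4.17,
  -3.36, -3.01, -3.01, -2.78, -2.76, -2.97, -2.76, -2.79, -3.52, -3.16,
  -2.60, -3.19, -2.72, -2.31, -2.32, -2.01, -1.84, -1.89, -1.70, -1.51,
  -2.41, -1.83, -1.31, -2.03, -2.24, -2.08, -1.82, -1.74, -1.66, -1.59,
  -1.22, -2.15, -1.72, -1.15, -1.87, -2.12, -1.96, -1.88, -1.90, -1.80,
  -1.74, -2.42, -1.90, -1.31, -1.90, -1.67, -1.58, -1.49, -1.63, -1.48,
  -2.11, -1.62, -1.05, -1.57, -1.68, -1.71, -1.68, -1.51, -2.08, -1.64,
  -1.21, -1.53, -1.54, -1.46, -1.42, -1.98, -1.80, -1.29, -1.73, -1.21,
  -1.02, -2.32, -2.29, -1.68, -1.33, -0.91, -2.15, -2.27, -1.80, -1.26,
  -3.05, -2.16, -1.35, -2.25, -1.55, -0.59, -1.70, -0.12, -0.97, -1.75
)

#' Validate and normalize one-letter residue codes
#'
#' Uppercases the input and checks every symbol against the canonical
#' 20-letter alphabet. In strict mode (the default) any other symbol is an
#' error; in lenient mode unknown symbols become `NA` so that downstream
#' computations can mask the affected positions instead of silently
#' substituting an energy.
#'
#' @param codes Character vector of single-letter codes, or a single string
#'   which is split into characters.
#' @param strict Reject non-canonical symbols (`TRUE`, default) or map them
#'   to `NA` (`FALSE`).
#' @return Character vector of uppercase codes, with `NA` for unknown
#'   symbols in lenient mode.
#' @export
as_residue_codes <- function(codes, strict = TRUE) {
  if (length(codes) == 1L && nchar(codes[1]) > 1L)
    codes <- strsplit(codes, "")[[1]]
  codes <- toupper(as.character(codes))
  bad <- !(codes %in% aa_alphabet())
  if (any(bad)) {
    if (strict)
      stop_validation("invalid residue code(s) %s at position(s) %s",
                      paste(unique(codes[bad]), collapse = ", "),
                      paste(which(bad), collapse = ", "))
    codes[bad] <- NA_character_
  }
  codes
}

new_potential_table <- function(mat, provenance_label) {
  structure(list(energies = mat, provenance_label = provenance_label),
            class = "potential_table")
}

#' Miyazawa-Jernigan contact-energy table
#'
#' The embedded default pairwise interaction potential: the
#' Miyazawa-Jernigan 1996 contact energies e_ij, a symmetric 20x20 table in
#' RT units. The table is the `U` of the frustration energy model; any
#' alternative table in the same shape can be swapped in via
#' [read_potential_table()].
#'
#' @return A `potential_table`: list with `energies` (20x20 symmetric
#'   numeric matrix, dimnames the alphabetical one-letter codes) and
#'   `provenance_label`.
#' @export
mj_potential <- function() {
  mj <- strsplit(MJ_ORDER, "")[[1]]
  mat <- matrix(NA_real_, 20, 20, dimnames = list(mj, mj))
  k <- 1L
  for (i in seq_len(20)) for (j in i:20) {
    mat[i, j] <- MJ1996_UPPER[k]
    mat[j, i] <- MJ1996_UPPER[k]
    k <- k + 1L
  }
  ab <- aa_alphabet()
  new_potential_table(mat[ab, ab], "Miyazawa-Jernigan 1996 e_ij")
}

#' Load a contact-potential table from a text file
#'
#' Format: whitespace-delimited; the first non-comment row holds the 20
#' one-letter codes, each following row starts with its code and carries 20
#' energies. The matrix must be complete over the canonical alphabet and
#' symmetric to within `tol`.
#'
#' @param path File path.
#' @param provenance_label Label stored with the table; defaults to the
#'   file name.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return A `potential_table`.
#' @export
read_potential_table <- function(path, provenance_label = basename(path),
                                 tol = 1e-9) {
  if (!file.exists(path)) stop_io("potential table file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "\\s+")
  header <- toupper(fields[[1]])
  if (!setequal(header, aa_alphabet()))
    stop_validation("potential table header must list the 20 canonical codes")
  if (length(fields) != 21L)
    stop_validation("potential table must have 20 data rows, found %d",
                    length(fields) - 1L)
  mat <- matrix(NA_real_, 20, 20, dimnames = list(header, header))
  for (row in fields[-1]) {
    if (length(row) != 21L)
      stop_validation("potential table row for '%s' must have 20 energies",
                      row[1])
    mat[toupper(row[1]), ] <- as.numeric(row[-1])
  }
  if (anyNA(mat) || any(!is.finite(mat)))
    stop_validation("potential table contains missing or non-finite energies")
  if (max(abs(mat - t(mat))) > tol)
    stop_validation("potential table is not symmetric to within %g", tol)
  ab <- aa_alphabet()
  new_potential_table(mat[ab, ab], provenance_label)
}

#' Pairwise contact energy
#'
#' Looks up the interaction energy of an unordered residue pair; symmetric
#' by construction.
#'
#' @param table A `potential_table`.
#' @param a,b One-letter residue codes.
#' @return Numeric energy (RT units).
#' @export
contact_energy <- function(table, a, b) {
  stopifnot(inherits(table, "potential_table"))
  a <- as_residue_codes(a)
  b <- as_residue_codes(b)
  table$energies[a, b]
}

#' Sequence interaction-potential matrix
#'
#' Builds the n x n matrix `U` whose (i, j) entry is the contact energy of
#' the residues at sequence positions i and j. The diagonal is populated
#' (self-pair energies) but downstream totals only ever consume i < j.
#'
#' @param table A `potential_table`.
#' @param seq Residue codes (vector or single string).
#' @return Symmetric n x n numeric matrix.
#' @export
sequence_potential_matrix <- function(table, seq) {
  stopifnot(inherits(table, "potential_table"))
  codes <- as_residue_codes(seq)
  if (length(codes) < 2L)
    stop_validation("sequence must have length >= 2, got %d", length(codes))
  idx <- match(codes, aa_alphabet())
  m <- table$energies[idx, idx]
  dimnames(m) <- NULL
  m
}

#' @export
print.potential_table <- function(x, ...) {
  cat("Contact-potential table:", x$provenance_label, "\n")
  cat("  20x20 symmetric; energy range [",
      min(x$energies), ",", max(x$energies), "] RT\n")
  invisible(x)
}
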