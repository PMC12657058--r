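# Evolutionary coupling-score matrices.
#
# Coupling scores are consumed, never computed: the upstream toolchain
# (EVcouplings alignment + plmc pseudolikelihood inference) produces either
# a headerless flat text file or a headered CSV. Both are parsed into a
# dense symmetric n x n matrix with zero diagonal, indexed by 1-based
# query-sequence positions. Expected upstream parameters, recorded here as
# configuration metadata only: jackhmmer bit-score thresholds 0.8/0.5/0.5,
# 5 iterations, 50% query-alignment sequence filter, 30% gap column
# filter; plmc regularization 0.01, 100 iterations.

new_coupling_matrix <- function(scores) {
  structure(scores, class = "coupling_matrix")
}

#' Construct a coupling matrix from pair records
#'
#' @param n Sequence length.
#' @param i,j 1-based position indices with `i < j`.
#' @param score Coupling scores.
#' @return A `coupling_matrix`: n x n symmetric numeric matrix, zero
#'   diagonal, class attribute `coupling_matrix`.
#' @export
coupling_matrix <- function(n, i = integer(), j = integer(),
                            score = numeric()) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop_validation("n must be a positive integer")
  if (length(i) != length(j) || length(i) != length(score))
    stop_validation("i, j and score must have equal length")
  bad <- which(i < 1 | i > n | j < 1 | j > n)
  if (length(bad))
    stop_validation("pair indices outside [1, %d] at record(s) %s", n,
                    paste(bad, collapse = ", "))
  if (any(i == j))
    stop_validation("self-pair (i == j) at record(s) %s",
                    paste(which(i == j), collapse = ", "))
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key))
    stop_validation("duplicate pair(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(!is.finite(score)))
    stop_validation("non-finite coupling score(s)")
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- score
  m[cbind(j, i)] <- score
  new_coupling_matrix(m)
}

validate_coupling_matrix <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C))
    stop_validation("coupling matrix must be square")
  if (any(!is.finite(C))) stop_validation("coupling matrix has non-finite entries")
  if (any(diag(C) != 0)) stop_validation("coupling matrix diagonal must be zero")
  if (!isTRUE(all.equal(unclass(C), t(unclass(C)), tolerance = 0)))
    stop_validation("coupling matrix must be symmetric")
  invisible(C)
}

sniff_dialect <- function(lines) {
  first <- trimws(lines[1])
  if (grepl(",", first) && grepl("(^|,)\\s*i\\s*(,|$)", tolower(first)))
    "evcouplings-csv"
  else if (!grepl(",", first) &&
           length(strsplit(first, "\\s+")[[1]]) >= 6) "plmc-flat"
  else NA_character_
}

#' Read coupling scores
#'
#' Two dialects are supported. `plmc-flat`: headerless whitespace rows
#' `i a_i j a_j extra score` as written by plmc's coupling output.
#' `evcouplings-csv`: comma-separated with a header naming columns
#' `i, A_i, j, A_j, fn, cn` where `fn` is the raw score and `cn` the
#' APC-corrected score. `auto` sniffs by header presence. The default
#' score column is the APC-corrected one (the standard EVcouplings
#' ranking score); negative scores are kept as-is.
#'
#' @param path File path.
#' @param n Query sequence length; every record must satisfy
#'   `1 <= i < j <= n`.
#' @param dialect `"plmc-flat"`, `"evcouplings-csv"` or `"auto"`.
#' @param score_column `"apc-corrected"` (default) or `"raw"`; ignored for
#'   the single-score plmc flat dialect.
#' @return A `coupling_matrix` with both (i, j) and (j, i) populated and
#'   unlisted pairs zero.
#' @export
read_couplings <- function(path, n,
                           dialect = c("auto", "plmc-flat", "evcouplings-csv"),
                           score_column = c("apc-corrected", "raw")) {
  dialect <- match.arg(dialect)
  score_column <- match.arg(score_column)
  if (!file.exists(path)) stop_io("couplings file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_validation("couplings file is empty: %s", path)
  if (dialect == "auto") {
    dialect <- sniff_dialect(lines)
    if (is.na(dialect))
      stop_validation(paste("could not identify couplings dialect of %s;",
                            "tried evcouplings-csv (header with i, A_i, j,",
                            "A_j), plmc-flat (>= 6 whitespace fields)"), path)
  }
  if (dialect == "plmc-flat") {
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 6))
      stop_validation("plmc-flat line %d has %d fields, expected >= 6",
                      which(nf < 6)[1], nf[nf < 6][1])
    i <- as.integer(vapply(fields, `[`, "", 1L))
    j <- as.integer(vapply(fields, `[`, "", 3L))
    s <- as.numeric(mapply(function(f, k) f[k], fields, nf))
    lineno <- seq_along(lines)
  } else {
    df <- utils::read.csv(text = lines, check.names = FALSE,
                          strip.white = TRUE)
    names(df) <- tolower(names(df))
    want <- if (score_column == "apc-corrected") "cn" else "fn"
    miss <- setdiff(c("i", "j", want), names(df))
    if (length(miss))
      stop_validation("couplings CSV missing column(s): %s",
                      paste(miss, collapse = ", "))
    i <- as.integer(df$i)
    j <- as.integer(df$j)
    s <- as.numeric(df[[want]])
    lineno <- seq_len(nrow(df)) + 1L
  }
  if (anyNA(i) || anyNA(j) || anyNA(s))
    stop_validation("unparseable record at line %d",
                    lineno[which(is.na(i) | is.na(j) | is.na(s))[1]])
  oob <- which(i < 1 | i > n | j < 1 | j > n)
  if (length(oob))
    stop_validation("position index outside [1, %d] at line %d", n,
                    lineno[oob[1]])
  if (any(i == j))
    stop_validation("self-pair i == j at line %d", lineno[which(i == j)[1]])
  coupling_matrix(n, i, j, s)
}

#' Write coupling scores
#'
#' Emits the evcouplings-csv dialect: upper triangle only, rows ordered by
#' i then j ascending, both `fn` and `cn` columns set to the stored score.
#'
#' @param matrix A `coupling_matrix`.
#' @param path Output file path.
#' @export
write_couplings <- function(matrix, path) {
  validate_coupling_matrix(matrix)
  C <- unclass(matrix)
  ut <- which(upper.tri(C) & C != 0, arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  df <- data.frame(i = ut[, 1], A_i = rep("-", nrow(ut)),
                   j = ut[, 2], A_j = rep("-", nrow(ut)),
                   fn = format(C[ut], digits = 17),
                   cn = format(C[ut], digits = 17))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_io("cannot write couplings to %s: %s",
                                path, conditionMessage(e)))
  invisible(NULL)
}

#' Per-position coupling coverage
#'
#' A position is covered when it appears in at least one scored pair.
#' Positions dropped upstream (e.g. by the 30%-gap alignment column
#' filter) arrive with no couplings and are reported `FALSE` here; the
#' frustration profile masks them rather than scoring them zero.
#'
#' @param matrix A `coupling_matrix`.
#' @return Logical vector of length n.
#' @export
coverage_mask <- function(matrix) {
  validate_coupling_matrix(matrix)
  rowSums(unclass(matrix) != 0) > 0
}

#' @export
print.coupling_matrix <- function(x, ...) {
  C <- unclass(x)
  np <- sum(C[upper.tri(C)] != 0)
  cat(sprintf("Coupling matrix: n = %d, %d scored pairs, %d/%d covered positions\n",
              nrow(C), np, sum(coverage_mask(x)), nrow(C)))
  invisible(x)
}
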