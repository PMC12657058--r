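# Sequence-based frustration.
#
# The energy model: F = C (Hadamard) U, where C holds evolutionary coupling
# scores and U the contact potentials of the residue pairs. The total
# folded-state energy estimate is the strictly-upper-triangular sum
# gamma(sigma) = sum_{i<j} F[i,j]. For a point mutation at position k only
# row/column k of F changes, so the energy difference
#   delta_gamma = gamma(wt) - gamma(mut)
#             = sum_{j != k} C[k,j] * (e(sigma_k, sigma_j) - e(mut, sigma_j))
# is computed incrementally from row k alone. The per-position frustration
# scalar Gamma_k is the unweighted mean of delta_gamma over the 19
# non-wild-type canonical substitutions. Orientation: positive Gamma means
# mutations on average lower the predicted energy, i.e. the native residue
# is energetically frustrated.

check_lengths <- function(C, codes) {
  n <- nrow(C)
  if (length(codes) != n)
    stop_validation("sequence length (%d) does not match coupling matrix size (%d)",
                    length(codes), n)
  n
}

# Lenient-mode sequences may carry NA codes; their couplings are zeroed so
# no neighbour's energy ever consumes an undefined residue, and the
# positions themselves are masked downstream.
prepare_instance <- function(C, seq, table, strict = TRUE) {
  validate_coupling_matrix(C)
  codes <- as_residue_codes(seq, strict = strict)
  check_lengths(C, codes)
  idx <- match(codes, aa_alphabet())
  Cm <- unclass(C)
  if (anyNA(idx)) {
    Cm[is.na(idx), ] <- 0
    Cm[, is.na(idx)] <- 0
  }
  list(C = Cm, codes = codes, idx = idx)
}

#' Coupling-weighted pairwise energy matrix
#'
#' The Hadamard product F = C * U(seq): each pair potential weighted by its
#' coupling score.
#'
#' @param C A `coupling_matrix`.
#' @param seq Residue codes (vector or string), length equal to `nrow(C)`.
#' @param table A `potential_table` (default [mj_potential()]).
#' @return Symmetric n x n numeric matrix.
#' @export
pairwise_energy <- function(C, seq, table = mj_potential()) {
  inst <- prepare_instance(C, seq, table)
  idx <- inst$idx
  E <- table$energies
  U <- E[idx, idx, drop = FALSE]
  U[is.na(U)] <- 0  # masked positions carry zero couplings anyway
  F <- inst$C * U
  dimnames(F) <- NULL
  F
}

#' Total predicted energy of a sequence
#'
#' gamma(sigma): the sum of the coupling-weighted pair potentials over the
#' strict upper triangle (each pair counted once; diagonal excluded).
#'
#' @inheritParams pairwise_energy
#' @return Scalar energy.
#' @export
total_energy <- function(C, seq, table = mj_potential()) {
  F <- pairwise_energy(C, seq, table)
  sum(F[upper.tri(F)])
}

#' Energy difference of a point mutation
#'
#' delta_gamma = gamma(wild type) - gamma(mutant at k), computed
#' incrementally from row k of the coupling matrix. Positive values mean
#' the mutant lowers the predicted total energy.
#'
#' @inheritParams pairwise_energy
#' @param k 1-based sequence position.
#' @param mutant One-letter code of the substituted residue.
#' @return Scalar energy difference.
#' @export
mutation_delta <- function(C, seq, table = mj_potential(), k, mutant) {
  inst <- prepare_instance(C, seq, table)
  n <- length(inst$codes)
  if (length(k) != 1L || is.na(k) || k < 1 || k > n)
    stop_validation("position k must lie in [1, %d]", n)
  mutant <- as_residue_codes(mutant)
  if (is.na(inst$idx[k]))
    stop_validation("position %d has no defined wild-type residue", k)
  E <- table$energies
  row <- inst$C[k, ]
  live <- which(row != 0 & !is.na(inst$idx))
  if (!length(live)) return(0)
  sum(row[live] * (E[inst$idx[k], inst$idx[live]] -
                   E[match(mutant, aa_alphabet()), inst$idx[live]]))
}

#' Per-position frustration profile
#'
#' For every position with coupling coverage, Gamma_k is the mean of
#' delta_gamma over the 19 non-wild-type canonical substitutions. Positions
#' with no coverage (or, in lenient mode, an unknown residue) are masked as
#' undefined rather than reported as zero, since zero would be
#' indistinguishable from "perfectly neutral" in rank analyses.
#'
#' Implementation: with S = E[, sigma] (20 x n) and A = S C (so
#' A[a, k] = sum_j C[k, j] e(a, sigma_j)), Gamma_k falls out of column k of
#' A in closed form; the full profile costs one 20 x n x n matrix product.
#'
#' @inheritParams pairwise_energy
#' @param strict Reject unknown residues (`TRUE`) or mask them (`FALSE`).
#' @return A `frustration_profile`: list with `gamma_native` (total energy
#'   of the input sequence), `per_residue` (numeric length n, `NA` where
#'   masked), `defined_mask` (logical), `sequence` (codes), and
#'   `orientation_note`.
#' @export
frustration_profile <- function(C, seq, table = mj_potential(),
                                strict = TRUE) {
  inst <- prepare_instance(C, seq, table, strict = strict)
  n <- length(inst$codes)
  idx <- inst$idx
  E <- table$energies
  S <- E[, ifelse(is.na(idx), 1L, idx), drop = FALSE]  # 20 x n
  S[, is.na(idx)] <- 0                                 # dead columns
  A <- S %*% inst$C                                    # A[a, k]
  wt <- A[cbind(ifelse(is.na(idx), 1L, idx), seq_len(n))]
  gamma_k <- wt - (colSums(A) - wt) / 19
  covered <- rowSums(inst$C != 0) > 0
  defined <- covered & !is.na(idx)
  gamma_k[!defined] <- NA_real_
  gamma_native <- {
    U <- E[ifelse(is.na(idx), 1L, idx), ifelse(is.na(idx), 1L, idx)]
    F <- inst$C * U
    sum(F[upper.tri(F)])
  }
  structure(list(gamma_native = gamma_native,
                 per_residue = as.numeric(gamma_k),
                 defined_mask = defined,
                 sequence = inst$codes,
                 orientation_note = "higher = more frustrated"),
            class = "frustration_profile")
}

#' @export
print.frustration_profile <- function(x, ...) {
  cat(sprintf("Frustration profile: n = %d, %d defined positions (%s)\n",
              length(x$per_residue), sum(x$defined_mask),
              x$orientation_note))
  cat(sprintf("  gamma(native) = %.4f; Gamma range [%.4f, %.4f]\n",
              x$gamma_native,
              min(x$per_residue, na.rm = TRUE),
              max(x$per_residue, na.rm = TRUE)))
  invisible(x)
}

#' Write a per-residue profile as CSV
#'
#' Columns: `position` (1-based), `residue`, `gamma` (empty where masked),
#' `covered` (true/false). The same format is used for compressed
#' structure-based profiles so the two are directly comparable.
#'
#' @param profile A `frustration_profile`, or any list with `per_residue`,
#'   `defined_mask` and optionally `sequence`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  n <- length(profile$per_residue)
  seqs <- if (!is.null(profile$sequence)) profile$sequence else rep("", n)
  seqs[is.na(seqs)] <- "X"
  df <- data.frame(position = seq_len(n), residue = seqs,
                   gamma = ifelse(profile$defined_mask,
                                  format(profile$per_residue, digits = 17,
                                         trim = TRUE), ""),
                   covered = ifelse(profile$defined_mask, "true", "false"))
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop_io("cannot write profile to %s: %s",
                                       path, conditionMessage(e)))
  invisible(NULL)
}

#' Read a per-residue profile CSV
#'
#' @param path Path to a CSV written by [write_profile()].
#' @return List with `per_residue` (NA where masked), `defined_mask`,
#'   `sequence`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_io("profile file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(gamma = "character"))
  need <- c("position", "residue", "gamma", "covered")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("profile CSV missing column(s): %s",
                    paste(miss, collapse = ", "))
  ord <- order(df$position)
  df <- df[ord, ]
  vals <- suppressWarnings(as.numeric(df$gamma))
  mask <- df$covered %in% c("true", "TRUE") & !is.na(vals)
  vals[!mask] <- NA_real_
  list(per_residue = vals, defined_mask = mask,
       sequence = as.character(df$residue))
}
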