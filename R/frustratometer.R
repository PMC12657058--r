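# Frustratometer mutational-output handling.
#
# The Frustratometer's "mutational" output lists amino-acid contacts with
# the native interaction energy theta and the decoy-mean energy phi. We do
# not recompute any of those energies; we only compress the contact list
# to one scalar per residue:
#   nu_m  = theta_m - phi_m              (per contact)
#   eps_n = sum_{m in X_n} nu_m / h      (X_n = the h contacts containing
#                                         residue n, on either side)
# This mirrors the sequence-based Gamma (mean energy difference upon
# mutation), making the two readouts directly comparable.

# Column-name synonyms accepted in Frustratometer headers.
FRUSTRA_COLS <- list(
  res_i = c("res1", "res_i", "i", "resid1"),
  res_j = c("res2", "res_j", "j", "resid2"),
  chain_i = c("chainres1", "chain1", "chain_i", "chaini"),
  chain_j = c("chainres2", "chain2", "chain_j", "chainj"),
  theta = c("native_energy", "nativeenergy", "theta"),
  phi = c("decoy_energy", "decoyenergy", "phi", "mean_decoy_energy")
)

find_column <- function(names_lower, synonyms, what) {
  hit <- which(names_lower %in% synonyms)
  if (!length(hit))
    stop_validation("Frustratometer table missing required column '%s' (accepted names: %s)",
                    what, paste(synonyms, collapse = ", "))
  hit[1]
}

#' Read Frustratometer mutational output
#'
#' Parses the headered whitespace table of contacts. Required columns:
#' residue indices, chain identifiers, native energy, decoy-mean energy
#' (several header spellings accepted); extra columns such as the decoy
#' standard deviation or the frustration index are ignored.
#'
#' @param path File path.
#' @param chain If non-`NULL`, keep only records whose both chains match;
#'   cross-chain and other-chain contacts are dropped with a message.
#' @return Data frame of contact records with columns `res_i`, `res_j`,
#'   `chain_i`, `chain_j`, `theta`, `phi`.
#' @export
read_frustratometer <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_io("Frustratometer file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop_validation("Frustratometer file is empty: %s", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  hl <- tolower(header)
  cols <- vapply(names(FRUSTRA_COLS),
                 function(w) find_column(hl, FRUSTRA_COLS[[w]], w), 1L)
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  nf <- lengths(rows)
  if (any(nf < max(cols)))
    stop_validation("unparseable row at line %d: %d fields, expected >= %d",
                    which(nf < max(cols))[1] + 1L, min(nf), max(cols))
  pick <- function(k) vapply(rows, `[`, "", cols[[k]])
  rec <- data.frame(res_i = suppressWarnings(as.integer(pick("res_i"))),
                    res_j = suppressWarnings(as.integer(pick("res_j"))),
                    chain_i = pick("chain_i"), chain_j = pick("chain_j"),
                    theta = suppressWarnings(as.numeric(pick("theta"))),
                    phi = suppressWarnings(as.numeric(pick("phi"))))
  bad <- which(is.na(rec$res_i) | is.na(rec$res_j) |
               is.na(rec$theta) | is.na(rec$phi))
  if (length(bad))
    stop_validation("unparseable row at line %d", bad[1] + 1L)
  if (any(rec$res_i == rec$res_j))
    stop_validation("self-contact (res_i == res_j) at line %d",
                    which(rec$res_i == rec$res_j)[1] + 1L)
  if (!is.null(chain)) {
    keep <- rec$chain_i == chain & rec$chain_j == chain
    if (sum(!keep))
      message(sprintf("read_frustratometer: dropped %d record(s) not on chain %s",
                      sum(!keep), chain))
    rec <- rec[keep, , drop = FALSE]
  }
  rec
}

#' Write a Frustratometer-style mutational table
#'
#' Companion writer used by the synthetic generator; emits the headered
#' whitespace dialect [read_frustratometer()] parses.
#'
#' @param records Data frame of contact records.
#' @param path Output path.
#' @export
write_frustratometer <- function(records, path) {
  df <- data.frame(Res1 = records$res_i, Res2 = records$res_j,
                   ChainRes1 = records$chain_i, ChainRes2 = records$chain_j,
                   NativeEnergy = format(records$theta, digits = 17, trim = TRUE),
                   DecoyEnergy = format(records$phi, digits = 17, trim = TRUE))
  tryCatch(utils::write.table(df, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop_io("cannot write Frustratometer table to %s: %s",
                                       path, conditionMessage(e)))
  invisible(NULL)
}

#' Compress contact records to a per-residue profile
#'
#' For each residue, eps is the mean of (theta - phi) over every contact
#' in which the residue appears on either side; membership is bilateral,
#' so each record contributes to exactly two residues. Duplicate (i, j)
#' records (e.g. direct and water-mediated variants of one pair) are kept
#' and enter the mean individually. Residues in no contact are masked.
#'
#' @param records Data frame from [read_frustratometer()].
#' @param n Sequence length; all record indices must lie in `[1, n]`.
#' @return A `compressed_profile`: list with `per_residue` (eps, `NA` where
#'   masked), `contact_counts` (h per residue), `defined_mask`.
#' @export
compress_contacts <- function(records, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop_validation("n must be a positive integer")
  i <- records$res_i
  j <- records$res_j
  oob <- which(i < 1 | i > n | j < 1 | j > n)
  if (length(oob))
    stop_validation("contact index outside [1, %d] at record %d", n, oob[1])
  nu <- records$theta - records$phi
  sums <- numeric(n)
  h <- integer(n)
  ends <- c(i, j)
  contrib <- c(nu, nu)
  sums <- as.numeric(tapply(contrib, factor(ends, levels = seq_len(n)),
                            sum, default = 0))
  h <- as.integer(tapply(rep(1L, length(ends)),
                         factor(ends, levels = seq_len(n)),
                         sum, default = 0L))
  eps <- ifelse(h > 0, sums / pmax(h, 1L), NA_real_)
  structure(list(per_residue = eps, contact_counts = h,
                 defined_mask = h > 0),
            class = "compressed_profile")
}
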