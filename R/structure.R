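# Per-residue B-factor extraction from PDB files.
#
# B-factors (temperature factors, A^2) are the paper-facing external
# comparator for frustration: the per-residue value is the arithmetic mean
# of the isotropic B over all of a residue's atoms (hydrogens included when
# present), after resolving alternate locations to the highest-occupancy
# conformer. PDB parsing itself is delegated to bio3d.

#' Per-residue mean B-factors from a PDB file
#'
#' One entry per polymer residue of the selected chain: the mean isotropic
#' B-factor over the residue's ATOM-record atoms. HETATM records (waters,
#' ligands) are excluded. Alternate locations are resolved per atom name to
#' the highest-occupancy conformer (ties: first encountered); hydrogens are
#' kept when present, with a message reporting their count.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier.
#' @return Data frame with columns `chain`, `resnum`, `insert` (insertion
#'   code, `""` if none), `resname` (three-letter), `mean_b` (A^2),
#'   `n_atoms`; rows in file order of first atom.
#' @export
residue_bfactors <- function(pdb_path, chain) {
  if (!file.exists(pdb_path)) stop_io("PDB file not found: %s", pdb_path)
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) stop_io("cannot parse PDB %s: %s",
                                              pdb_path, conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop_validation("no ATOM records in %s", pdb_path)
  avail <- sort(unique(at$chain))
  if (!chain %in% avail)
    stop_validation("chain '%s' not present; available chains: %s",
                    chain, paste(avail, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  nh <- sum(at$elesy == "H", na.rm = TRUE)
  if (nh) message(sprintf("residue_bfactors: %d hydrogen atoms included", nh))
  reskey <- paste(at$resno, at$insert, sep = "|")
  # altloc resolution: within each residue x atom-name group keep the
  # highest-occupancy record (first on ties); blank altloc always kept
  keep <- rep(TRUE, nrow(at))
  multi <- at$alt != ""
  if (any(multi)) {
    grp <- paste(reskey, at$elety, sep = "|")
    for (g in unique(grp[multi])) {
      rows <- which(grp == g)
      if (length(rows) > 1L) {
        occ <- at$o[rows]
        occ[is.na(occ)] <- 1
        keep[rows[-which.max(occ)]] <- FALSE
      }
    }
  }
  at <- at[keep, , drop = FALSE]
  reskey <- reskey[keep]
  first <- !duplicated(reskey)
  out <- data.frame(chain = chain,
                    resnum = at$resno[first],
                    insert = at$insert[first],
                    resname = at$resid[first],
                    mean_b = as.numeric(tapply(at$b, factor(reskey, levels = unique(reskey)), mean)),
                    n_atoms = as.integer(table(factor(reskey, levels = unique(reskey)))))
  if (any(!is.finite(out$mean_b)))
    stop_validation("non-finite B-factor(s) in %s", pdb_path)
  rownames(out) <- NULL
  out
}

#' Align per-residue B-factors to a query sequence
#'
#' Maps author residue numbering onto 1-based sequence positions via
#' `position = resnum - offset`. Positions with no structural residue are
#' masked; residues mapping outside the sequence are dropped with a
#' message. Residue identities are checked (three-letter names translated
#' to one-letter) and a mismatch rate above 50% is an error, since it
#' usually means the wrong chain or offset. Insertion-code residues cannot
#' be placed by plain numbering and are skipped with a warning.
#'
#' @param bfactors Data frame from [residue_bfactors()].
#' @param seq Residue codes (vector or string).
#' @param offset Integer offset, or `"auto"` to pick the offset in
#'   [-500, 500] maximizing sequence identity.
#' @return List with `values` (numeric length n, `NA` where masked),
#'   `defined_mask`, `offset` (the offset used), `n_mismatch`.
#' @export
align_bfactors <- function(bfactors, seq, offset = 0) {
  codes <- as_residue_codes(seq)
  n <- length(codes)
  ins <- bfactors$insert != ""
  if (any(ins)) {
    warning(sprintf("align_bfactors: skipping %d insertion-code residue(s)",
                    sum(ins)))
    bfactors <- bfactors[!ins, , drop = FALSE]
  }
  one <- suppressWarnings(bio3d::aa321(bfactors$resname))
  if (identical(offset, "auto")) {
    best <- 0L; best_hits <- -1L
    for (off in -500:500) {
      pos <- bfactors$resnum - off
      inside <- pos >= 1 & pos <= n
      hits <- sum(one[inside] == codes[pos[inside]], na.rm = TRUE)
      if (hits > best_hits) { best_hits <- hits; best <- off }
    }
    offset <- best
  }
  pos <- bfactors$resnum - offset
  inside <- pos >= 1 & pos <= n
  if (sum(!inside))
    message(sprintf("align_bfactors: dropped %d residue(s) mapping outside [1, %d]",
                    sum(!inside), n))
  values <- rep(NA_real_, n)
  values[pos[inside]] <- bfactors$mean_b[inside]
  mism <- sum(one[inside] != codes[pos[inside]], na.rm = TRUE)
  if (sum(inside) > 0 && mism / sum(inside) > 0.5)
    stop_validation("%d/%d residue identity mismatches (> 50%%): wrong chain or offset?",
                    mism, sum(inside))
  if (mism)
    message(sprintf("align_bfactors: %d residue identity mismatch(es)", mism))
  list(values = values, defined_mask = !is.na(values),
       offset = offset, n_mismatch = mism)
}
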