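# Synthetic benchmark instances.
#
# The generator emulates everything the pipeline consumes — a protein
# sequence, a sparse symmetric coupling matrix, a consistent
# Frustratometer-style contact table, and noisy per-residue B-factors —
# with a planted set of frustrated positions, so parameter recovery can be
# measured without any external data. Construction:
#   1. contact topology: random long-range pairs at the requested density;
#      chain-adjacent pairs (|i - j| == 1) carry no couplings, mirroring
#      the coevolution-analysis practice of discounting trivial neighbours;
#   2. coupling magnitudes ~ Exponential(1/coupling_scale);
#   3. residues by a two-pass greedy sweep: non-planted positions take the
#      residue minimizing the coupling-weighted mean contact energy
#      against current neighbours, planted positions the one maximizing it
#      (so mutations there mostly lower the energy: frustrated);
#   4. B-factors: affine in the planted indicator and the instance's own
#      Gamma, plus Gaussian noise;
#   5. one Frustratometer-style record per coupled pair with theta the
#      native pair energy and phi the mean over the 38 single-end
#      substitutions.
# Random streams are split per concern so changing one parameter does not
# reshuffle unrelated draws.

#' Synthetic instance parameters
#'
#' Defaults are the package's reference study conditions: 100 residues,
#' 5% long-range contact density, unit-scale couplings, 20% planted
#' frustrated positions, noise-free B-factors.
#'
#' @param n Sequence length (>= 20).
#' @param seed Integer random seed.
#' @param contact_density Expected fraction of eligible pairs coupled.
#' @param coupling_scale Mean magnitude of nonzero couplings.
#' @param frustrated_fraction Fraction of positions planted frustrated
#'   (in [0, 0.5]).
#' @param bfactor_noise_sd Gaussian noise s.d. added to the B-factor
#'   signal (A^2).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n = 100, seed = 1, contact_density = 0.05,
                           coupling_scale = 1, frustrated_fraction = 0.2,
                           bfactor_noise_sd = 0) {
  if (n < 20) stop_validation("n must be >= 20, got %d", n)
  if (contact_density <= 0 || contact_density > 1)
    stop_validation("contact_density must be in (0, 1]")
  if (frustrated_fraction < 0 || frustrated_fraction > 0.5)
    stop_validation("frustrated_fraction must be in [0, 0.5]")
  if (frustrated_fraction > 0 && round(frustrated_fraction * n) == 0)
    stop_validation("frustrated_fraction %g with n = %d plants no positions",
                    frustrated_fraction, n)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 contact_density = contact_density,
                 coupling_scale = coupling_scale,
                 frustrated_fraction = frustrated_fraction,
                 bfactor_noise_sd = bfactor_noise_sd),
            class = "synthetic_spec")
}

# per-concern substream seeds, kept within 32-bit integer range
stream_seed <- function(seed, stream) {
  (as.numeric(seed) * 131 + stream * 7919) %% 2147483647
}

#' Generate a synthetic protein instance
#'
#' Deterministic given the spec's seed. See the package vignette for what
#' the construction emulates and what it does not.
#'
#' @param spec A `synthetic_spec`.
#' @param table Contact-potential table (default [mj_potential()]).
#' @return A `synthetic_protein`: list with `sequence`, `couplings`
#'   (a `coupling_matrix`), `planted_mask`, `bfactors`,
#'   `frustratometer_records`, `spec`.
#' @export
generate_synthetic_protein <- function(spec, table = mj_potential()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  ab <- aa_alphabet()
  E <- table$energies

  # (1) topology: eligible pairs are |i - j| >= 2
  set.seed(stream_seed(spec$seed, 1))
  eligible <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  eligible <- eligible[eligible[, 2] - eligible[, 1] >= 2, , drop = FALSE]
  on <- stats::runif(nrow(eligible)) < spec$contact_density
  pairs <- eligible[on, , drop = FALSE]

  # (2) magnitudes
  set.seed(stream_seed(spec$seed, 2))
  mag <- stats::rexp(nrow(pairs), rate = 1 / spec$coupling_scale)
  C <- coupling_matrix(n, pairs[, 1], pairs[, 2], mag)

  # (3) residues: random start, then two greedy sweeps
  set.seed(stream_seed(spec$seed, 3))
  k_planted <- round(spec$frustrated_fraction * n)
  planted <- rep(FALSE, n)
  planted[sample.int(n, k_planted)] <- TRUE
  idx <- sample.int(20, n, replace = TRUE)
  Cm <- unclass(C)
  for (pass in 1:2) {
    for (k in seq_len(n)) {
      nb <- which(Cm[k, ] != 0)
      if (!length(nb)) next
      local <- as.numeric(E[, idx[nb], drop = FALSE] %*% Cm[k, nb])
      idx[k] <- if (planted[k]) which.max(local) else which.min(local)
    }
  }
  sequence <- ab[idx]

  # (4) B-factors: affine in planted signal + Gamma, plus noise
  prof <- frustration_profile(C, sequence, table)
  gam <- prof$per_residue
  gam[is.na(gam)] <- 0
  set.seed(stream_seed(spec$seed, 4))
  bf <- 20 + 10 * planted + 2 * gam +
    stats::rnorm(n, sd = spec$bfactor_noise_sd)

  # (5) Frustratometer-style records: theta = native pair energy, phi =
  # mean over the 19 + 19 single-end substitutions
  theta <- E[cbind(idx[pairs[, 1]], idx[pairs[, 2]])]
  phi <- (colSums(E[, idx[pairs[, 2]], drop = FALSE]) - theta +
          colSums(E[, idx[pairs[, 1]], drop = FALSE]) - theta) / 38
  records <- data.frame(res_i = pairs[, 1], res_j = pairs[, 2],
                        chain_i = "A", chain_j = "A",
                        theta = theta, phi = phi)

  structure(list(sequence = sequence, couplings = C,
                 planted_mask = planted, bfactors = bf,
                 frustratometer_records = records, spec = spec),
            class = "synthetic_protein")
}

#' Write a synthetic instance as a fixture bundle
#'
#' Layout: `seq.fasta`, `couplings.csv`, `frustratometer.tsv`,
#' `bfactors.csv`, `manifest.json` (spec + generator version). Every file
#' round-trips through the package's corresponding reader.
#'
#' @param protein A `synthetic_protein`.
#' @param dir Output directory (created if absent).
#' @export
write_fixture_bundle <- function(protein, dir) {
  stopifnot(inherits(protein, "synthetic_protein"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_io("cannot create directory %s", dir)
  seqinr::write.fasta(list(protein$sequence), names = "synthetic",
                      file.out = file.path(dir, "seq.fasta"))
  write_couplings(protein$couplings, file.path(dir, "couplings.csv"))
  write_frustratometer(protein$frustratometer_records,
                       file.path(dir, "frustratometer.tsv"))
  bf <- data.frame(position = seq_along(protein$bfactors),
                   bfactor = format(protein$bfactors, digits = 17,
                                    trim = TRUE))
  utils::write.csv(bf, file.path(dir, "bfactors.csv"), row.names = FALSE,
                   quote = FALSE)
  manifest <- c(protein$spec,
                list(generator = paste0("seqfrust ",
                                        as.character(utils::packageVersion("seqfrust")))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a per-position B-factor CSV
#'
#' Columns `position`, `bfactor`; missing positions are masked.
#'
#' @param path File path.
#' @param n Optional sequence length (default: max position present).
#' @return List with `values` and `defined_mask`.
#' @export
read_bfactor_csv <- function(path, n = NULL) {
  if (!file.exists(path)) stop_io("B-factor file not found: %s", path)
  df <- utils::read.csv(path)
  miss <- setdiff(c("position", "bfactor"), names(df))
  if (length(miss))
    stop_validation("B-factor CSV missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (is.null(n)) n <- max(df$position)
  values <- rep(NA_real_, n)
  values[df$position] <- df$bfactor
  list(values = values, defined_mask = !is.na(values))
}
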