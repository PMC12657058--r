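# Shared fixture builders: random instances, brute-force oracles, and a
# programmatic PDB writer. All randomness is seeded by the caller.

random_sequence <- function(n) sample(aa_alphabet(), n, replace = TRUE)

random_coupling_matrix <- function(n, density = 0.2) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on <- runif(nrow(ut)) < density
  coupling_matrix(n, ut[on, 1], ut[on, 2], rnorm(sum(on)))
}

# Brute-force frustration oracle: rebuild every mutant sequence and call
# total_energy; independent of the incremental row-k path under test.
brute_profile <- function(C, seq, table = mj_potential()) {
  n <- length(seq)
  g0 <- total_energy(C, seq, table)
  vapply(seq_len(n), function(k) {
    alts <- setdiff(aa_alphabet(), seq[k])
    mean(vapply(alts, function(a) {
      mut <- seq
      mut[k] <- a
      g0 - total_energy(C, mut, table)
    }, numeric(1)))
  }, numeric(1))
}

# Brute-force per-residue compression oracle.
brute_compress <- function(records, n) {
  eps <- rep(NA_real_, n)
  h <- integer(n)
  for (res in seq_len(n)) {
    hit <- records$res_i == res | records$res_j == res
    h[res] <- sum(hit)
    if (h[res] > 0)
      eps[res] <- mean(records$theta[hit] - records$phi[hit])
  }
  list(eps = eps, h = h)
}

pdb_atom_line <- function(serial, name, alt, resname, chain, resno, icode,
                          b, occ = 1, elem = substr(name, 1, 1),
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resname, chain,
          resno, icode, serial * 1.0, 0, 0, occ, b, elem)
}

# Minimal PDB writer: one line per row of `atoms` (data frame with name,
# alt, resname, chain, resno, icode, b, occ, record columns).
write_pdb_fixture <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (r in seq_len(nrow(atoms))) {
    a <- atoms[r, ]
    lines[r] <- pdb_atom_line(r, a$name, a$alt, a$resname, a$chain, a$resno,
                              a$icode, a$b, a$occ, record = a$record)
  }
  writeLines(c(lines, "END"), path)
}

# Default atom rows for a residue: N, CA, C with the given B-factors.
backbone_rows <- function(resname, chain, resno, b, icode = "") {
  data.frame(name = c("N", "CA", "C"), alt = "", resname = unname(resname),
             chain = chain, resno = resno, icode = icode, b = b,
             occ = 1, record = "ATOM")
}
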