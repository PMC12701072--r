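# Shared fixture builders (everything generated in code; no binary files).

# minimal PDB text with one carbon atom
minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# CA-only chain of n residues
ca_chain_pdb <- function(n = 5, path = tempfile(fileext = ".pdb")) {
  writeLines(c(sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), seq_len(n) * 3.8, 0, 0), "END"), path)
  path
}

# brute-force all-pairs contact count (independent oracle)
brute_contacts <- function(xyz, setA, setB, cutoff = 4) {
  A <- xyz[setA, , drop = FALSE]
  B <- xyz[setB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(d2 <= cutoff^2 + 1e-12)
}

# brute-force minimum cross distance
brute_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(d2), 0))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# interface template: a slice of a circular duplex plus a protein stub shared
# with the tetramer (emulates a symmetry-expanded crystal interface)
circle_slice_template <- function(tet, circ, bps) {
  bm <- attr(circ, "bp_map")
  a <- circ$atoms
  keep <- (a$chain == bm$chain1[1] & a$resno %in% bm$resno1[bps]) |
    (a$chain == bm$chain2[1] & a$resno %in% bm$resno2[bps])
  prot <- tet$atoms[tet$atoms$resno %in% c(1, 2, 3), ]
  wk_structure(rbind(prot, a[keep, ]))
}
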