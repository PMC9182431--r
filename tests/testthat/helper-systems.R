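# shared fixture builders (all generated in code; no stored data)

# two beads joined by a single native contact of given strength
two_bead_contact <- function(eps = 1.0, r0 = 5) {
  m <- bead_model(rbind(c(0, 0, 0), c(r0, 0, 0)), chain = c("A", "B"),
                  fixed = c(TRUE, FALSE))
  tb <- interaction_table(substrate_intra = eps)
  list(model = m, topology = build_native_contacts(m, tb))
}

# a hand-written 3-residue PDB text with known coordinates
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.234   2.000  -0.500  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.100   2.500   0.750  0.50  0.00           C",
    "ATOM      4  CA AGLY A   2       4.000   2.400   0.700  0.30  0.00           C",
    "ATOM      5  CA  SER A   3       7.000   3.000   1.250  1.00  0.00           C",
    "END"), path)
  invisible(path)
}

# synthetic force trace with two rupture peaks (ramp 300, drop, ramp 500, drop)
two_peak_trace <- function() {
  f <- c(seq(0, 300, by = 10), seq(290, 100, by = -10),
         seq(110, 500, by = 10), seq(490, 50, by = -10))
  tibble::tibble(time = seq_along(f) * 10, extension = seq_along(f) * 0.1,
                 force_pN = f)
}

# a hand-made topology over explicit contacts (for observable hand counts)
manual_topology <- function(coords, contacts, chain = rep(1L, nrow(coords))) {
  structure(list(
    bonds = tibble::tibble(i = integer(), j = integer(), r0 = numeric()),
    contacts = contacts, n_beads = nrow(coords),
    chain_idx = as.integer(chain),
    seqpos = as.integer(stats::ave(seq_len(nrow(coords)), chain,
                                   FUN = seq_along)),
    fene_k = 20, fene_R0 = 2, table = interaction_table()),
    class = "sop_topology")
}
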