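test_that("toy lattice has the documented bead census and annotations", {
  m <- make_toy_lattice(3, 3, 4, seed = 1)
  expect_equal(nrow(m), 3 * 3 * 2 * 4 + 9) # 72 core beads + 9 beta tails
  expect_equal(sum(m$domain == "HBD_tail"), 9)
  expect_equal(length(unique(m$subunit)), 18)
  expect_true(all(grepl("^pf0[1-3]:d0[1-3]:[ab]$", m$subunit)))
  # one chain per monomer; beta chains carry the extra tail bead
  sizes <- table(m$chain)
  expect_true(all(sizes %in% c(4, 5)))
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(bead_coords(make_toy_lattice(3, 2, 4, seed = 9)),
                   bead_coords(make_toy_lattice(3, 2, 4, seed = 9)))
  expect_identical(bead_coords(make_toy_hexamer(TRUE, 8, 10, seed = 5)),
                   bead_coords(make_toy_hexamer(TRUE, 8, 10, seed = 5)))
  expect_identical(bead_coords(make_toy_globule(4, 5, 3, seed = 2)),
                   bead_coords(make_toy_globule(4, 5, 3, seed = 2)))
  # and different seeds jitter the coordinates
  expect_false(identical(bead_coords(make_toy_lattice(3, 2, 4, seed = 1)),
                         bead_coords(make_toy_lattice(3, 2, 4, seed = 2))))
})

test_that("no generated lattice contains bead pairs closer than 1 A", {
  for (s in 1:3) {
    m <- make_toy_lattice(4, 3, 3, seed = s)
    expect_gt(min(dist(bead_coords(m))), 1)
  }
})

test_that("a 13-protofilament cylindrical lattice has exactly one seam interface", {
  m <- make_toy_lattice(13, 2, 3, seam = TRUE, seed = 1)
  expect_equal(attr(m, "seam"), c("pf13", "pf01"))
  topo <- build_native_contacts(m, interaction_table())
  seam_ct <- topo$contacts[topo$contacts$class == "seam", ]
  expect_gt(nrow(seam_ct), 0)
  pf_pairs <- unique(paste(sub(":.*", "", m$subunit[seam_ct$i]),
                           sub(":.*", "", m$subunit[seam_ct$j])))
  expect_true(all(pf_pairs %in% c("pf13 pf01", "pf01 pf13")))
  expect_equal(unname(topo$table$eps_h_by_class["seam"]), 0.9)
  # planar lattices cannot have a seam
  expect_warning(make_toy_lattice(3, 2, 4, seam = TRUE, seed = 1), "seam")
})

test_that("toy hexamer geometry: chains, arms, pore symmetry", {
  hx <- make_toy_hexamer(with_arms = FALSE, pore_radius = 8, seed = 1)
  expect_equal(length(unique(hx$chain)), 6)
  expect_equal(sum(hx$domain == "MIT"), 0)
  base_per_chain <- as.integer(table(hx$chain)[1])

  hxa <- make_toy_hexamer(with_arms = TRUE, pore_radius = 8,
                          linker_beads = 10, seed = 1)
  expect_true(all(table(hxa$chain) == base_per_chain + 13)) # 10 linker + 3 MIT
  expect_equal(sum(hxa$domain == "MIT"), 18)

  # pore-loop centroid on the symmetry axis
  pl <- bead_coords(hx)[hx$domain == "pore_loop", ]
  expect_equal(nrow(pl), 6)
  expect_lt(max(abs(colMeans(pl)[1:2])), 1e-6)
  expect_equal(unname(sqrt(rowSums(pl[, 1:2]^2))), rep(8, 6), tolerance = 1e-9)

  expect_error(make_toy_hexamer(pore_radius = 1), "excluded volume")
})

test_that("toy globule bead counts and terminal-strand contact pattern", {
  g <- make_toy_globule(4, 5, 3, seed = 1)
  expect_equal(nrow(g), 4 * 5 + 3)
  expect_equal(sum(g$domain == "substrate_tail"), 3)

  strand_of <- function(model, tail_len, strand_len, order) {
    n <- nrow(model)
    s <- rep(NA_integer_, n)
    for (k in seq_along(order))
      s[tail_len + (k - 1) * strand_len + seq_len(strand_len)] <- order[k]
    s
  }
  neighbour_strands <- function(terminal_strand) {
    order <- if (terminal_strand == 1) 1:4 else c(2:1, 3:4)
    g <- make_toy_globule(4, 5, 3, terminal_strand = terminal_strand, seed = 1)
    topo <- build_native_contacts(g, interaction_table(contact_cutoff = 6))
    s <- strand_of(g, 3, 5, order)
    ct <- topo$contacts
    term <- which(s == terminal_strand)
    cross <- (ct$i %in% term) != (ct$j %in% term)
    other <- ifelse(ct$i[cross] %in% term, ct$j[cross], ct$i[cross])
    sort(unique(s[other[!is.na(s[other])]]))
  }
  expect_equal(neighbour_strands(1), 2L)        # edge: one neighbour
  expect_equal(neighbour_strands(2), c(1L, 3L)) # core: two neighbours
})

test_that("PDB round trip preserves beads, tags and coordinates", {
  m <- make_toy_lattice(3, 2, 3, seed = 4)
  path <- tempfile(fileext = ".pdb")
  write_calpha_pdb(m, path)
  m2 <- read_calpha_pdb(path)
  expect_equal(bead_coords(m2), bead_coords(m), tolerance = 1e-3)
  expect_identical(m2$chain, m$chain)
  expect_identical(m2$subunit, m$subunit)
  expect_identical(m2$domain, m$domain)
  expect_identical(m2$fixed, m$fixed)
})

test_that("reading a fabricated PDB reproduces hand-read ATOM fields", {
  path <- tempfile(fileext = ".pdb")
  write_tiny_pdb(path)
  m <- read_calpha_pdb(path, sidecar = FALSE)
  expect_equal(nrow(m), 3) # one bead per residue
  expect_equal(m$resid, 1:3)
  # altloc resolved to highest occupancy (0.50 beats 0.30)
  expect_equal(bead_coords(m),
               cbind(x = c(1.234, 4.100, 7.000), y = c(2.0, 2.5, 3.0),
                     z = c(-0.5, 0.75, 1.25)),
               tolerance = 1e-3)
})

test_that("chain_map tags selected chains, leaves others as 'none', and errors on unknowns", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA B   1       0.000   6.000   0.000  1.00  0.00           C",
    "END"), path)
  m <- read_calpha_pdb(path, chain_map = c(A = "protomer:A"))
  expect_equal(unique(m$subunit[m$chain == "A"]), "protomer:A")
  expect_equal(unique(m$subunit[m$chain == "B"]), "none")
  expect_error(read_calpha_pdb(path, chain_map = c(Z = "protomer:A")),
               "not present")
})

test_that("a residue without a CA atom is reported by name", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   2       3.800   0.000   0.000  1.00  0.00           N",
    "END"), path)
  expect_error(read_calpha_pdb(path), "A/2")
})

test_that("written PDB coordinates agree with an independent PDB parser", {
  skip_if_not_installed("bio3d")
  m <- make_toy_lattice(3, 2, 3, seed = 6)
  path <- tempfile(fileext = ".pdb")
  write_calpha_pdb(m, path, sidecar = FALSE)
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  expect_equal(nrow(ca), nrow(m))
  expect_equal(cbind(ca$x, ca$y, ca$z), unname(bead_coords(m)),
               tolerance = 1e-3)
})
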