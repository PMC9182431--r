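test_that("contact cutoff and sequence-separation rules are enforced", {
  # two beads 20 A apart: no contacts under the 13 A cutoff
  m <- bead_model(rbind(c(0, 0, 0), c(20, 0, 0)), chain = c("A", "B"))
  expect_equal(nrow(build_native_contacts(m, interaction_table())$contacts), 0)

  # linear 6-bead chain at 3.8 A spacing: only |i-j| >= 3 pairs inside 13 A
  xyz <- cbind(3.8 * (0:5), 0, 0)
  m6 <- bead_model(xyz, chain = "A")
  topo <- build_native_contacts(m6, interaction_table())
  expect_true(all(abs(topo$contacts$i - topo$contacts$j) >= 3))
  expect_equal(nrow(topo$contacts), 3) # (1,4), (2,5), (3,6) at 11.4 A
  expect_equal(nrow(topo$bonds), 5)
})

test_that("contact list matches a brute-force O(N^2) enumeration", {
  set.seed(31)
  xyz <- matrix(runif(50 * 3, 0, 25), ncol = 3)
  xyz <- xyz[order(xyz[, 1]), ]
  # keep the chain bondable: rescale consecutive gaps into FENE reach
  for (i in 2:50) {
    d <- xyz[i, ] - xyz[i - 1, ]
    xyz[i, ] <- xyz[i - 1, ] + d / sqrt(sum(d^2)) * runif(1, 3.4, 4.2)
  }
  m <- bead_model(xyz, chain = "A")
  topo <- build_native_contacts(m, interaction_table())
  # independent brute force
  expected <- list()
  for (i in 1:49) for (j in (i + 1):50) {
    if (j - i < 3) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 13)
      expected[[length(expected) + 1]] <- c(i, j)
  }
  expected <- do.call(rbind, expected)
  got <- as.matrix(topo$contacts[, c("i", "j")])
  dimnames(got) <- NULL
  expect_equal(got[order(got[, 1], got[, 2]), ],
               expected[order(expected[, 1], expected[, 2]), ])
})

test_that("interface classification matches the GDP-lattice strength table", {
  m <- make_toy_lattice(3, 2, 3, seed = 1)
  pick <- function(sub) which(m$subunit == sub)[1]
  tb <- interaction_table()
  cls <- function(a, b) classify_interface(m, pick(a), pick(b))
  expect_equal(cls("pf02:d01:a", "pf02:d01:b"), "intra_dimer")
  expect_equal(unname(tb$eps_h_by_class["intra_dimer"]), 1.9)
  expect_equal(cls("pf02:d01:b", "pf02:d02:a"), "longitudinal")
  expect_equal(unname(tb$eps_h_by_class["longitudinal"]), 1.0)
  expect_equal(cls("pf02:d01:b", "pf03:d01:b"), "lateral")
  expect_equal(unname(tb$eps_h_by_class["lateral"]), 0.9)
  # symmetry under argument exchange
  subs <- unique(m$subunit)
  for (k in 1:10) {
    ij <- sample(nrow(m), 2)
    expect_equal(classify_interface(m, ij[1], ij[2]),
                 classify_interface(m, ij[2], ij[1]))
  }
  expect_error(classify_interface(bead_model(rbind(c(0, 0, 0)), chain = "A"),
                                  1, 1), "unannotated")
})

test_that("machine and machine-lattice interfaces classify by domain", {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0), c(4, 5, 0))
  m <- bead_model(xyz, chain = c("A", "B", "L", "L"),
                  subunit = c("protomer:A", "protomer:B",
                              "pf01:d01:a", "pf01:d01:a"),
                  domain = c("MIT", "NBD", "none", "none"))
  expect_equal(classify_interface(m, 1, 2), "inter_protomer")
  expect_equal(classify_interface(m, 1, 3), "mit_mt")
  expect_equal(classify_interface(m, 2, 3), "mt_protomer")
  # pore-loop against a tail bead is the handle interface
  m$domain <- c("pore_loop", "NBD", "HBD_tail", "none")
  expect_equal(classify_interface(m, 1, 3), "protomer_e15")
})

test_that("set_mit_interaction rescales exactly the MIT-lattice contacts", {
  xyz <- rbind(c(0, 0, 0), c(4.5, 0, 0), c(0, 4.5, 0), c(4.5, 4.5, 1))
  m <- bead_model(xyz, chain = c("A", "A", "L", "L"),
                  subunit = c("protomer:A", "protomer:A",
                              "pf01:d01:a", "pf01:d01:a"),
                  domain = c("MIT", "MIT", "none", "none"))
  topo <- build_native_contacts(m, interaction_table())
  n_mit <- sum(topo$contacts$class == "mit_mt")
  expect_gt(n_mit, 0)

  t2 <- set_mit_interaction(topo, 2.5)
  expect_equal(nrow(t2$contacts), nrow(topo$contacts))
  expect_true(all(t2$contacts$eps[t2$contacts$class == "mit_mt"] == 2.5))
  expect_equal(t2$contacts$eps[t2$contacts$class != "mit_mt"],
               topo$contacts$eps[topo$contacts$class != "mit_mt"])
  # identity when eps equals the current value
  expect_identical(set_mit_interaction(topo, 1.0)$contacts, topo$contacts)
  # the sweep yields topologies differing only in the MIT strength
  sweep <- lapply(c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0),
                  function(e) set_mit_interaction(topo, e))
  mits <- vapply(sweep, function(t) unique(t$contacts$eps[t$contacts$class == "mit_mt"]),
                 numeric(1))
  expect_equal(mits, c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0))
  others <- lapply(sweep, function(t) t$contacts[t$contacts$class != "mit_mt", ])
  for (k in 2:7) expect_identical(others[[k]], others[[1]])
})

test_that("native/bonded/repulsive bookkeeping is exclusive and exhaustive", {
  m <- make_toy_lattice(3, 2, 3, seed = 2)
  topo <- build_native_contacts(m, interaction_table())
  ct_key <- paste(topo$contacts$i, topo$contacts$j)
  bd_key <- paste(topo$bonds$i, topo$bonds$j)
  expect_equal(anyDuplicated(ct_key), 0)
  expect_equal(length(intersect(ct_key, bd_key)), 0)
  expect_true(all(topo$contacts$i < topo$contacts$j))
  expect_true(all(topo$contacts$r0 <= topo$table$contact_cutoff))
})

test_that("interior monomers keep lateral and longitudinal connectivity", {
  m <- make_toy_lattice(3, 3, 4, seed = 1)
  topo <- build_native_contacts(m, interaction_table())
  ct <- topo$contacts
  interior <- "pf02:d02:a"
  touch <- m$subunit[ct$i] == interior | m$subunit[ct$j] == interior
  expect_gt(sum(touch & ct$class == "lateral"), 0)
  expect_gt(sum(touch & ct$class == "longitudinal"), 0)
})

test_that("declared fusion bonds join chains and leave the contact list", {
  m <- bead_model(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11, 0, 0)),
                  chain = c("A", "A", "B", "B"))
  topo <- build_native_contacts(m, interaction_table(),
                                extra_bonds = cbind(2, 3))
  expect_equal(nrow(topo$bonds), 3)
  fb <- topo$bonds[topo$bonds$i == 2 & topo$bonds$j == 3, ]
  expect_equal(fb$r0, 3.8) # native distance
  expect_false(any(topo$contacts$i == 2 & topo$contacts$j == 3))
})

test_that("topology survives a TSV round trip", {
  m <- make_toy_lattice(3, 2, 3, seed = 7)
  topo <- build_native_contacts(m, interaction_table())
  base <- tempfile()
  write_topology(topo, base)
  t2 <- read_topology(base, m)
  expect_equal(t2$contacts$i, topo$contacts$i)
  expect_equal(t2$contacts$eps, topo$contacts$eps)
  expect_equal(t2$contacts$class, topo$contacts$class)
  expect_equal(t2$bonds$r0, topo$bonds$r0, tolerance = 1e-9)
})
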