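# Deterministic toy-system generators. These emulate the connectivity of the
# real assemblies (a multi-protofilament tubulin-like lattice, a hexameric
# AAA+ ring with pore loops and MIT-like arms, a small beta-sheet globule
# with a pulling tail) at desk scale; they do not reproduce real geometry.

# zig-zag monomer template along +x: compact, consecutive spacing < 3.8 A
.monomer_template <- function(n_beads, spacing = 3.6, wiggle = 1.0) {
  t <- seq_len(n_beads) - 1
  cbind(t * spacing, wiggle * (t %% 2), 0)
}

.check_overlap <- function(xyz, min_dist = 1) {
  d <- stats::dist(xyz)
  if (any(d < min_dist))
    stop("geometric overlap: beads closer than ", min_dist, " A", call. = FALSE)
  invisible(TRUE)
}

#' Generate a toy multi-protofilament lattice
#'
#' Builds a microtubule-like lattice of `n_pf` protofilaments, each a row of
#' `n_dimers` two-monomer (alpha/beta) subunits. Each monomer is a compact
#' zig-zag cluster of `beads_per_monomer` beads and its own chain; beta
#' monomers carry a terminal tail bead tagged `HBD_tail` (the pulled handle).
#' Lateral and longitudinal spacings are comparable so that interface
#' strength is set by the interaction table, not geometry. With `n_pf >= 5`
#' protofilaments sit on a cylinder and the wrap interface between the last
#' and first protofilament is labelled the seam when `seam = TRUE`; smaller
#' lattices are planar sheets.
#'
#' @param n_pf,n_dimers,beads_per_monomer lattice dimensions.
#' @param radius cylinder radius (Angstrom); `NULL` picks the radius giving a
#'   6 A lateral chord. Ignored for planar lattices.
#' @param seam label the wrap interface as the seam (cylindrical only).
#' @param seed integer seed for the (tiny) symmetry-breaking jitter.
#' @return a [bead_model()] with a `"seam"` attribute when applicable.
#' @export
make_toy_lattice <- function(n_pf = 3, n_dimers = 3, beads_per_monomer = 4,
                             radius = NULL, seam = FALSE, seed = 1) {
  stopifnot(n_pf >= 1, n_dimers >= 1, beads_per_monomer >= 2)
  tmpl <- .monomer_template(beads_per_monomer)
  mono_len <- max(tmpl[, 1])
  pitch <- mono_len + 4.2      # gap between consecutive monomers along a PF
  lat_spacing <- 8.0 # adjacent rows contact under 13 A, next-nearest do not
  cylindrical <- n_pf >= 5
  if (cylindrical && is.null(radius)) {
    radius <- lat_spacing / (2 * sin(pi / n_pf))
  }

  rows <- list()
  for (pf in seq_len(n_pf)) {
    for (d in seq_len(n_dimers)) {
      for (mono in c("a", "b")) {
        im <- (d - 1) * 2 + (mono == "b")
        xyz <- tmpl
        xyz[, 1] <- xyz[, 1] + im * pitch
        n_here <- beads_per_monomer
        dom <- rep("none", n_here)
        if (mono == "b") { # C-terminal tail bead on beta monomers
          tail <- xyz[n_here, ] + c(1.5, 0, 3.8)
          xyz <- rbind(xyz, tail)
          dom <- c(dom, "HBD_tail")
          n_here <- n_here + 1
        }
        if (cylindrical) {
          ang <- 2 * pi * (pf - 1) / n_pf
          r <- radius + xyz[, 2]
          xyz <- cbind(xyz[, 1], r * cos(ang) - xyz[, 3] * sin(ang),
                       r * sin(ang) + xyz[, 3] * cos(ang))
        } else {
          xyz[, 2] <- xyz[, 2] + (pf - 1) * lat_spacing
        }
        lab <- sprintf("pf%02d:d%02d:%s", pf, d, mono)
        rows[[length(rows) + 1]] <- list(xyz = xyz, chain = lab, subunit = lab,
                                         domain = dom)
      }
    }
  }
  xyz <- do.call(rbind, lapply(rows, `[[`, "xyz"))
  chain <- unlist(lapply(rows, function(r) rep(r$chain, nrow(r$xyz))))
  domain <- unlist(lapply(rows, `[[`, "domain"))

  set.seed(seed)
  xyz <- xyz + matrix(runif(length(xyz), -0.05, 0.05), ncol = 3)
  .check_overlap(xyz)

  seam_attr <- NULL
  if (seam) {
    if (!cylindrical) {
      warning("seam requires a cylindrical lattice (n_pf >= 5); ignored")
    } else {
      seam_attr <- c(sprintf("pf%02d", n_pf), "pf01")
    }
  }
  bead_model(xyz, chain = chain, subunit = chain, domain = domain,
             seam = seam_attr)
}

#' Generate a toy hexameric ring machine
#'
#' Six protomers (chains A-F) around a central pore. Each protomer carries
#' one bead tagged `pore_loop` at exactly `pore_radius` from the symmetry
#' axis plus a compact 8-bead `NBD` core. With `with_arms = TRUE`, each
#' protomer extends a flexible linker chain of `linker_beads` beads ending
#' in a 3-bead MIT-like cluster tagged `MIT` (the lattice-anchoring arms).
#' The pore-loop and core geometry is exactly six-fold symmetric; the seeded
#' jitter only perturbs the arms.
#'
#' @param with_arms attach linker + MIT arms.
#' @param pore_radius pore-loop distance from the axis (Angstrom).
#' @param linker_beads beads per linker.
#' @param seed integer seed (arm jitter only).
#' @return a [bead_model()].
#' @export
make_toy_hexamer <- function(with_arms = FALSE, pore_radius = 8,
                             linker_beads = 10, seed = 1) {
  stopifnot(pore_radius > 0, linker_beads >= 0)
  if (pore_radius < 2)
    stop("pore_radius smaller than the bead excluded volume (2 A)", call. = FALSE)
  # local protomer: pore loop at x = pore_radius, core cube behind it
  corner <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
                  c(0, 3.8, 3.8), c(3.8, 3.8, 3.8), c(3.8, 0, 3.8), c(0, 0, 3.8))
  core <- sweep(corner, 2, c(pore_radius + 3.4, -1.9, -1.9), `+`)
  set.seed(seed)
  rows <- list()
  for (k in 1:6) {
    loc <- rbind(c(pore_radius, 0, 0), core)
    dom <- c("pore_loop", rep("NBD", 8))
    if (with_arms) {
      arm_start <- loc[nrow(loc), ]
      lk <- NULL
      if (linker_beads > 0) {
        t <- seq_len(linker_beads)
        lk <- cbind(arm_start[1] + 3.2 * t, arm_start[2] + 0.8 * (t %% 2),
                    arm_start[3] - 1.5 * t)
      }
      mit_org <- if (is.null(lk)) arm_start else lk[nrow(lk), ]
      mit <- rbind(mit_org + c(3.2, 0, -1.5),
                   mit_org + c(6.0, 1.9, -2.5),
                   mit_org + c(6.0, -1.9, -3.5))
      arm <- rbind(lk, mit)
      arm <- arm + matrix(runif(length(arm), -0.05, 0.05), ncol = 3)
      loc <- rbind(loc, arm)
      dom <- c(dom, rep("linker", linker_beads), rep("MIT", 3))
    }
    ang <- 2 * pi * (k - 1) / 6
    rot <- cbind(loc[, 1] * cos(ang) - loc[, 2] * sin(ang),
                 loc[, 1] * sin(ang) + loc[, 2] * cos(ang), loc[, 3])
    rows[[k]] <- list(xyz = rot, chain = LETTERS[k], domain = dom)
  }
  xyz <- do.call(rbind, lapply(rows, `[[`, "xyz"))
  chain <- unlist(lapply(rows, function(r) rep(r$chain, nrow(r$xyz))))
  domain <- unlist(lapply(rows, `[[`, "domain"))
  .check_overlap(xyz)
  bead_model(xyz, chain = chain,
             subunit = paste0("protomer:", chain), domain = domain)
}

#' Generate a toy anisotropic beta-sheet globule with a pulling tail
#'
#' A planar sheet of `n_strands` strands (4.8 A apart, 3.8 A bead spacing)
#' connected by a serpentine bonded path, with `tail_len` tail beads
#' (tagged `substrate_tail`) prepended at the chain terminal. The terminal
#' strand -- the one carrying the tail -- is selectable: `terminal_strand = 1`
#' gives an edge terminal (native contacts with one neighbouring strand,
#' unzipping-prone), an interior index gives a core terminal (contacts with
#' two neighbours, shearing-prone), emulating wild-type versus
#' circular-permutant terminals. `sheet_parallel` staggers alternate strands
#' by half a bead spacing to emulate a parallel-like contact registry; the
#' bonded path is serpentine in both cases.
#'
#' @param n_strands,strand_len,tail_len sheet dimensions.
#' @param topology `"sheet_antiparallel"` (in register) or `"sheet_parallel"`
#'   (staggered registry).
#' @param terminal_strand index of the strand carrying the tail.
#' @param seed integer seed for symmetry-breaking jitter.
#' @return a [bead_model()] (single chain `"S"`, subunit `"sp"`).
#' @export
make_toy_globule <- function(n_strands = 4, strand_len = 5, tail_len = 3,
                             topology = c("sheet_antiparallel", "sheet_parallel"),
                             terminal_strand = 1, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_strands >= 2, strand_len >= 2, tail_len >= 0)
  if (terminal_strand < 1 || terminal_strand > n_strands)
    stop("terminal_strand out of range", call. = FALSE)
  s <- terminal_strand
  order <- if (s == 1) seq_len(n_strands) else c(s:1, if (s < n_strands) (s + 1):n_strands)

  stagger <- if (topology == "sheet_parallel") 1.9 else 0
  xb <- (seq_len(strand_len) - 1) * 3.8
  xyz <- NULL
  dirs <- rep(c(1, -1), length.out = length(order))
  for (k in seq_along(order)) {
    str <- order[k]
    xs <- if (dirs[k] == 1) xb else rev(xb)
    xs <- xs + (str %% 2) * stagger
    xyz <- rbind(xyz, cbind(xs, (str - 1) * 4.8, 0))
  }
  # tail extends away from the first bead of the terminal strand
  if (tail_len > 0) {
    first <- xyz[1, ]
    step <- if (dirs[1] == 1) -3.8 else 3.8
    t <- rev(seq_len(tail_len))
    tail_xyz <- cbind(first[1] + step * t, first[2], first[3] + 2.0)
    xyz <- rbind(tail_xyz, xyz)
  }
  set.seed(seed)
  xyz <- xyz + matrix(runif(length(xyz), -0.05, 0.05), ncol = 3)
  .check_overlap(xyz)
  domain <- c(rep("substrate_tail", tail_len),
              rep("substrate_core", n_strands * strand_len))
  bead_model(xyz, chain = "S", subunit = "sp", domain = domain)
}
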