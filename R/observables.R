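#' Fraction of native contacts retained
#'
#' `Q_N = (1/N_C) sum_ij theta(eta - |r_ij - r0_ij|)`: the fraction of
#' native pairs currently within tolerance `eta` of their native distance.
#' Restricting to a contact-class subset implements the longitudinal /
#' lateral split of severing analyses.
#'
#' @param coords n x 3 coordinate matrix (or a [bead_model()]).
#' @param topology an `sop_topology`.
#' @param eta tolerance, Angstrom (default 2).
#' @param classes optional character vector of interface classes to keep.
#' @param subunits optional character vector: keep only contacts touching
#'   these subunit labels (needs `model`).
#' @param model bead model, required with `subunits`.
#' @return Q_N in `[0, 1]`.
#' @export
fraction_native_contacts <- function(coords, topology, eta = 2,
                                     classes = NULL, subunits = NULL,
                                     model = NULL) {
  if (inherits(coords, "bead_model")) {
    model <- model %||% coords
    coords <- bead_coords(coords)
  }
  ct <- topology$contacts
  if (!is.null(classes)) ct <- ct[ct$class %in% classes, ]
  if (!is.null(subunits)) {
    stopifnot(!is.null(model))
    ct <- ct[model$subunit[ct$i] %in% subunits |
               model$subunit[ct$j] %in% subunits, ]
  }
  if (nrow(ct) == 0) stop("no native contacts after filtering", call. = FALSE)
  d <- sqrt(rowSums((coords[ct$i, , drop = FALSE] -
                       coords[ct$j, , drop = FALSE])^2))
  mean(abs(d - ct$r0) <= eta)
}

#' Fraction of non-native contacts
#'
#' `f_NN = N_NC / N_C`: the number of currently formed non-native pairs
#' (within `cutoff`, not in the native list, not bonded, sequence
#' separation >= 3 within a chain) relative to the native-contact count.
#' May exceed 1.
#'
#' @inheritParams fraction_native_contacts
#' @param cutoff formation cutoff, Angstrom (default 6).
#' @return f_NN >= 0.
#' @export
fraction_nonnative <- function(coords, topology, cutoff = 6) {
  if (inherits(coords, "bead_model")) coords <- bead_coords(coords)
  nc <- nrow(topology$contacts)
  if (nc == 0) stop("topology has no native contacts", call. = FALSE)
  D <- as.matrix(stats::dist(coords))
  within <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  i <- within[, 1]; j <- within[, 2]
  chain <- topology$chain_idx; sq <- topology$seqpos
  eligible <- chain[i] != chain[j] | abs(sq[i] - sq[j]) >= 3
  key <- paste(i, j)
  native_key <- paste(topology$contacts$i, topology$contacts$j)
  bond_key <- paste(topology$bonds$i, topology$bonds$j)
  n_nn <- sum(eligible & !(key %in% native_key) & !(key %in% bond_key))
  n_nn / nc
}

#' Detect first and critical breaking forces in a force trace
#'
#' Rupture events are local maxima of the moving-average-smoothed force
#' followed by a drop of at least `min_drop` before the force recovers.
#' FBF is the force at the first event; CBF the global maximum of the
#' smoothed force. A monotone rising trace yields FBF = CBF = the final
#' maximum; a trace with no events and no net rise leaves FBF undefined
#' (NA) with CBF = the maximum.
#'
#' @param trace tibble with `time` and `force_pN` (an `sop_pulling` works
#'   too).
#' @param smooth_window moving-average window, frames (1 = no smoothing).
#' @param min_drop minimum post-peak drop, pN.
#' @return list with `fbf`, `cbf` (pN) and `events` (tibble: time,
#'   force_pN).
#' @export
detect_breaking_forces <- function(trace, smooth_window = 50, min_drop = 50) {
  if (inherits(trace, "sop_pulling")) trace <- trace$trace
  f <- trace$force_pN
  t <- trace$time
  stopifnot(length(f) > smooth_window)
  if (smooth_window > 1) {
    fs <- as.numeric(stats::filter(f, rep(1 / smooth_window, smooth_window),
                                   sides = 2))
    ok <- !is.na(fs)
    fs <- fs[ok]; ts <- t[ok]
  } else {
    fs <- f; ts <- t
  }
  n <- length(fs)
  ev_idx <- integer()
  i <- 2
  while (i < n) {
    if (fs[i] >= fs[i - 1] && fs[i] > fs[i + 1]) { # local max
      j <- i + 1
      drop_ok <- FALSE
      while (j <= n && fs[j] <= fs[i]) {
        if (fs[i] - fs[j] >= min_drop) { drop_ok <- TRUE }
        j <- j + 1
      }
      if (drop_ok) ev_idx <- c(ev_idx, i)
      i <- max(j - 1, i + 1)
    } else {
      i <- i + 1
    }
  }
  cbf <- max(fs)
  if (length(ev_idx) > 0) {
    fbf <- fs[ev_idx[1]]
  } else if (fs[n] >= cbf - 1e-9 && (cbf - fs[1]) >= min_drop) {
    # monotone ramp ending at its maximum: single terminal event
    fbf <- fs[n]
    ev_idx <- n
  } else {
    fbf <- NA_real_
  }
  list(fbf = fbf, cbf = cbf,
       events = tibble::tibble(time = ts[ev_idx], force_pN = fs[ev_idx]))
}

#' Fragment and oligomer census of a configuration
#'
#' Builds a graph over subunits with an edge wherever at least one
#' inter-subunit native contact is still formed (`|r - r0| <=
#' break_tolerance`), and reports its connected components. The pathway
#' label counts tubulin dimers in lattice fragments detached from the
#' anchored component (e.g. `"6"`, `"6 + 2"`, `"0"` for intact); the
#' oligomer string gives the ring-machine decomposition (`"0"` intact,
#' else protomer counts such as `"3;3"`).
#'
#' @param coords n x 3 coordinates (or a [bead_model()]).
#' @param topology an `sop_topology`.
#' @param model the [bead_model()] (subunit annotations).
#' @param break_tolerance contact-formed tolerance, Angstrom (the Q_N
#'   tolerance by default).
#' @return an `event_report`: list with `fragments` (tibble: component,
#'   subunits, n_subunits, n_dimers), `oligomers`, `pathway` and
#'   `dimers_lost`.
#' @export
fragment_census <- function(coords, topology, model, break_tolerance = 2) {
  if (inherits(coords, "bead_model")) coords <- bead_coords(coords)
  stopifnot(!is.null(model$subunit))
  subs <- unique(model$subunit)
  ct <- topology$contacts
  d <- sqrt(rowSums((coords[ct$i, , drop = FALSE] -
                       coords[ct$j, , drop = FALSE])^2))
  formed <- abs(d - ct$r0) <= break_tolerance
  si <- model$subunit[ct$i]; sj <- model$subunit[ct$j]
  inter <- si != sj & formed
  edges <- unique(data.frame(a = pmin(si[inter], sj[inter]),
                             b = pmax(si[inter], sj[inter])))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = subs))
  comp <- igraph::components(g)$membership
  frag <- tibble::tibble(subunit = names(comp), component = unname(comp))
  frag <- dplyr::summarise(
    dplyr::group_by(frag, .data$component),
    subunits = paste(sort(.data$subunit), collapse = ","),
    n_subunits = dplyr::n(),
    n_dimers = length(unique(sub(":[ab]$", "",
                                 grep("^pf", .data$subunit, value = TRUE)))),
    .groups = "drop")

  # anchored lattice component: contains a fixed lattice bead, else the
  # largest lattice-containing component
  lattice_subs <- subs[grepl("^pf", subs)]
  pathway <- "0"
  dimers_lost <- integer()
  if (length(lattice_subs) > 0) {
    fixed_subs <- unique(model$subunit[model$fixed & grepl("^pf", model$subunit)])
    comp_of <- function(s) unname(comp[s])
    anchored <- if (length(fixed_subs) > 0) unique(comp_of(fixed_subs)) else {
      lat_comp <- table(comp[lattice_subs])
      as.integer(names(lat_comp)[which.max(lat_comp)])
    }
    lost <- frag[!(frag$component %in% anchored) & frag$n_dimers > 0, ]
    dimers_lost <- sort(lost$n_dimers, decreasing = TRUE)
    pathway <- if (length(dimers_lost) == 0) "0" else
      paste(dimers_lost, collapse = " + ")
  }

  oligomers <- "0"
  prot_subs <- subs[grepl("^protomer", subs)]
  if (length(prot_subs) > 0) {
    sizes <- table(comp[prot_subs])
    sizes <- sort(as.integer(sizes), decreasing = TRUE)
    oligomers <- if (length(sizes) == 1) "0" else paste(sizes, collapse = ";")
  }
  structure(list(fragments = frag, oligomers = oligomers, pathway = pathway,
                 dimers_lost = dimers_lost, fbf = NA_real_, cbf = NA_real_),
            class = "event_report")
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf("<event_report> pathway '%s', oligomers '%s', FBF %.1f, CBF %.1f pN\n",
              x$pathway, x$oligomers, x$fbf, x$cbf))
  print(x$fragments)
  invisible(x)
}

#' Protofilament long axis from dimer centres of mass
#'
#' Unit vector from the centre of mass of `from_dimer` to that of
#' `to_dimer` (e.g. the plus-end dimer to the pulled dimer) of one
#' protofilament.
#'
#' @param model a [bead_model()].
#' @param coords coordinates (defaults to the model's).
#' @param from_dimer,to_dimer subunit-label prefixes such as `"pf02:d01"`.
#' @return unit 3-vector.
#' @export
pf_axis <- function(model, coords = NULL, from_dimer, to_dimer) {
  if (is.null(coords)) coords <- bead_coords(model)
  com <- function(pref) {
    idx <- startsWith(model$subunit, pref)
    if (!any(idx)) stop("no beads in dimer ", pref, call. = FALSE)
    colMeans(coords[idx, , drop = FALSE])
  }
  unit_vec(com(to_dimer) - com(from_dimer))
}

#' Machine orientation angles relative to a protofilament axis
#'
#' theta: angle between `axis` and the principal axis of the full machine
#' (motor + linkers + MIT); phi: same against the motor-only selection
#' (NBD + pore-loop beads); psi: against the unit vector joining the two
#' designated pore-loop beads. Axis semantics fold all angles to
#' `[0, 90]` degrees; `fold = FALSE` keeps `[0, 180]`.
#'
#' @param model a [bead_model()] containing the machine.
#' @param coords coordinates (defaults to the model's).
#' @param axis reference (protofilament) axis.
#' @param loop_pair indices of the two pore-loop beads defining psi.
#' @param fold fold to axis semantics.
#' @return list with `theta`, `phi`, `psi` in degrees.
#' @export
orientation_angles <- function(model, coords = NULL, axis, loop_pair,
                               fold = TRUE) {
  if (is.null(coords)) coords <- bead_coords(model)
  mach <- grepl("^protomer", model$subunit)
  if (!any(mach)) stop("no machine beads (subunit 'protomer:*')", call. = FALSE)
  motor <- mach & model$domain %in% c("NBD", "pore_loop")
  theta <- angle_deg(axis, principal_axis(coords[mach, , drop = FALSE]), fold)
  phi <- angle_deg(axis, principal_axis(coords[motor, , drop = FALSE]), fold)
  lv <- coords[loop_pair[2], ] - coords[loop_pair[1], ]
  psi <- angle_deg(axis, lv, fold)
  list(theta = theta, phi = phi, psi = psi)
}

#' Substrate orientation at the pore lumen
#'
#' Polar angle theta between the substrate's first principal axis and the
#' pore axis (folded to `[0, 90]`); azimuthal angle phi between the
#' projections, onto the plane perpendicular to the pore axis, of the
#' principal axis and of the position vector of a reference ring subunit's
#' centre of mass (in `[0, 180]`).
#'
#' @param coords substrate coordinates (untranslocated selection).
#' @param ring_com centre of mass of the reference ring subunit.
#' @param pore_axis pore axis (default +z).
#' @return list with `theta` and `phi` in degrees.
#' @export
sp_orientation <- function(coords, ring_com, pore_axis = c(0, 0, 1)) {
  ax <- unit_vec(pore_axis)
  pa <- principal_axis(coords)
  theta <- angle_deg(ax, pa, fold = TRUE)
  proj <- function(v) v - sum(v * ax) * ax
  p1 <- proj(pa); p2 <- proj(ring_com)
  if (sqrt(sum(p1^2)) < 1e-10 || sqrt(sum(p2^2)) < 1e-10)
    stop("degenerate projection for azimuthal angle", call. = FALSE)
  phi <- angle_deg(p1, p2, fold = FALSE)
  list(theta = theta, phi = phi)
}

#' Translocation progress metrics
#'
#' From a frame series: `x(t)` the fraction of substrate beads beyond
#' `z_trans`; `I(t)` the sequence position of the most recently
#' translocated residue (non-decreasing ratchet convention by default);
#' `w(I)` the per-residue waiting time, i.e. total residence time with
#' `z >= z_lumen` before that residue translocates.
#'
#' @param frames n x 3 x T coordinate array (substrate beads, sequence
#'   order) or an `sop_translocation` (its substrate beads are used).
#' @param time frame times, ps.
#' @param z_trans,z_lumen thresholds, Angstrom.
#' @param axis pore axis.
#' @param ratchet keep `I(t)` non-decreasing.
#' @return list of tibbles `x` (time, x), `I` (time, I) and `w`
#'   (residue, w_ps).
#' @export
translocation_metrics <- function(frames, time = NULL, z_trans = 12,
                                  z_lumen = -8, axis = c(0, 0, 1),
                                  ratchet = TRUE) {
  if (inherits(frames, "sop_translocation")) {
    tr <- frames
    n_sub <- nrow(tr$substrate)
    time <- tr$log$time_ps
    z_trans <- tr$protocol$z_trans
    z_lumen <- tr$protocol$z_lumen
    axis <- tr$protocol$force_axis
    frames <- tr$frames[seq_len(n_sub), , , drop = FALSE]
  }
  n <- dim(frames)[1]; nt <- dim(frames)[3]
  if (is.null(time)) time <- seq_len(nt)
  axis <- unit_vec(axis)
  z <- vapply(seq_len(nt), function(k) as.numeric(frames[, , k] %*% axis),
              numeric(n))
  z <- matrix(z, nrow = n) # n x T
  trans <- z > z_trans
  x <- colMeans(trans)
  I_raw <- apply(trans, 2, function(v) if (any(v)) max(which(v)) else 0L)
  I_t <- if (ratchet) cummax(I_raw) else I_raw
  # waiting time: frames with z >= z_lumen before first translocation
  dt_frame <- if (nt > 1) diff(time) else 1
  dt_frame <- c(dt_frame, dt_frame[length(dt_frame)])
  w <- vapply(seq_len(n), function(i) {
    first <- which(trans[i, ])[1]
    upto <- if (is.na(first)) nt else first - 1
    if (upto < 1) return(0)
    sum(dt_frame[seq_len(upto)][z[i, seq_len(upto)] >= z_lumen])
  }, numeric(1))
  list(x = tibble::tibble(time = time, x = x),
       I = tibble::tibble(time = time, I = as.integer(I_t)),
       w = tibble::tibble(residue = seq_len(n), w_ps = w))
}

#' Two-dimensional free-energy landscape
#'
#' Histograms paired observables, converts to probabilities and reports
#' `-kBT ln P` with the global minimum shifted to zero; empty bins are NA
#' (undefined), never an infinite sentinel.
#'
#' @param obs1,obs2 numeric sample vectors (equal length).
#' @param kBT thermal energy, kcal/mol.
#' @param bins bin count per axis (scalar or length 2).
#' @param limits optional list of two range vectors.
#' @return an `sop_fel`: tibble with bin centres `x`, `y` and free energy
#'   `F`, plus break attributes.
#' @export
free_energy_landscape <- function(obs1, obs2, kBT = 0.6, bins = 30,
                                  limits = NULL) {
  stopifnot(length(obs1) == length(obs2), length(obs1) >= 1, all(bins >= 2))
  bins <- rep_len(bins, 2)
  r1 <- if (is.null(limits)) range(obs1) else limits[[1]]
  r2 <- if (is.null(limits)) range(obs2) else limits[[2]]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  r1 <- pad(r1); r2 <- pad(r2)
  b1 <- seq(r1[1], r1[2], length.out = bins[1] + 1)
  b2 <- seq(r2[1], r2[2], length.out = bins[2] + 1)
  i1 <- findInterval(obs1, b1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(obs2, b2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins[1], bins[2])
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  P <- counts / length(obs1)
  F <- ifelse(P > 0, -kBT * log(P), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  ctr <- function(b) (b[-1] + b[-length(b)]) / 2
  grid <- tidyr::expand_grid(y = ctr(b2), x = ctr(b1))[, c("x", "y")]
  grid$F <- as.vector(F) # column-major: x fastest, matching row order
  structure(tibble::new_tibble(grid, class = "sop_fel"),
            breaks_x = b1, breaks_y = b2, kBT = kBT)
}

#' Write a free-energy landscape as a TSV matrix
#'
#' Rows are x bins, columns y bins; bin centres in the header/first column.
#'
#' @param fel an `sop_fel`.
#' @param path output path.
#' @export
write_fel <- function(fel, path) {
  xs <- unique(fel$x); ys <- unique(fel$y)
  M <- matrix(fel$F, nrow = length(xs))
  df <- data.frame(x = xs, M)
  names(df) <- c("x", sprintf("y_%g", ys))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' First-passage time for detachment of a bead set
#'
#' The first frame at which every native contact crossing the boundary of
#' `beads` (one endpoint inside, one outside) is broken
#' (`|r - r0| > tolerance`). Used e.g. for the extraction time of the
#' terminal strand of a substrate during pore translocation -- the
#' engaged-terminal unfolding step whose barrier carries the mechanical
#' anisotropy.
#'
#' @param frames n x 3 x T coordinate array or an `sop_translocation`.
#' @param topology the `sop_topology` the contacts come from.
#' @param beads integer bead indices of the detaching unit.
#' @param tolerance broken-contact tolerance, Angstrom.
#' @return the frame (cycle) index, or `NA` if never detached.
#' @export
detachment_time <- function(frames, topology, beads, tolerance = 2) {
  if (inherits(frames, "sop_translocation")) frames <- frames$frames
  ct <- topology$contacts
  sel <- which((ct$i %in% beads) != (ct$j %in% beads))
  if (length(sel) == 0) stop("no boundary-crossing native contacts", call. = FALSE)
  for (k in seq_len(dim(frames)[3])) {
    d <- sqrt(rowSums((frames[ct$i[sel], , k, drop = FALSE] -
                         frames[ct$j[sel], , k, drop = FALSE])^2))
    if (all(abs(d - ct$r0[sel]) > tolerance)) return(k)
  }
  NA_integer_
}
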