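#' Repetitive pore-force cycle protocol
#'
#' The ClpY-style allosteric cycle at C-alpha resolution: each cycle of
#' duration `tau` comprises two hemicycles (open->close, close->open) of six
#' sequential protomer transitions each. During the open->close hemicycle a
#' force of Gaussian magnitude (`mean_force`, `sd_force`, truncated at zero)
#' is distributed uniformly over the substrate beads inside the pore window
#' (`|z - <z_loop>| < window_half_width`, evaluated at cycle start) and
#' applied along `force_axis`. `z_trans` / `z_lumen` are the translocation
#' and lumen thresholds of the progress metrics.
#'
#' @param tau cycle duration, ps.
#' @param n_transitions_per_cycle protomer transitions per full cycle
#'   (6 open->close + 6 close->open).
#' @param loop_excursion pore-loop axial excursion, Angstrom.
#' @param mean_force,sd_force Gaussian force magnitude, pN. Defaults are the
#'   wild-type N-C values (700, 50); see [pore_force_preset()].
#' @param window_half_width pore-window half width, Angstrom.
#' @param z_trans,z_lumen translocation / lumen thresholds, Angstrom.
#' @param force_axis pore axis (normalised; + side is trans).
#' @return a `cycle_protocol`.
#' @export
cycle_protocol <- function(tau = 120, n_transitions_per_cycle = 12,
                           loop_excursion = 10, mean_force = 700,
                           sd_force = 50, window_half_width = 5,
                           z_trans = 12, z_lumen = -8,
                           force_axis = c(0, 0, 1)) {
  stopifnot(tau > 0, sd_force >= 0, window_half_width > 0,
            n_transitions_per_cycle >= 2, loop_excursion > 0)
  structure(list(tau = tau,
                 n_transitions_per_cycle = as.integer(n_transitions_per_cycle),
                 loop_excursion = loop_excursion, mean_force = mean_force,
                 sd_force = sd_force, window_half_width = window_half_width,
                 z_trans = z_trans, z_lumen = z_lumen,
                 force_axis = unit_vec(force_axis)),
            class = "cycle_protocol")
}

#' Per-variant pore-force presets
#'
#' Mean/sd of the Gaussian pore force: wild-type N-C 700/50 pN, wild-type
#' C-N 400/20 pN, circular permutant P25 400/20 pN, circular permutant K38
#' 600/20 pN.
#'
#' @param variant one of `"wt_nc"`, `"wt_cn"`, `"cp_p25"`, `"cp_k38"`.
#' @param ... passed to [cycle_protocol()].
#' @return a `cycle_protocol`.
#' @export
pore_force_preset <- function(variant = c("wt_nc", "wt_cn", "cp_p25", "cp_k38"),
                              ...) {
  variant <- match.arg(variant)
  f <- switch(variant,
              wt_nc = c(700, 50), wt_cn = c(400, 20),
              cp_p25 = c(400, 20), cp_k38 = c(600, 20))
  cycle_protocol(mean_force = f[1], sd_force = f[2], ...)
}

#' Schedule protomer transitions for one hemicycle
#'
#' A cyclic permutation of the ring: the first protomer is drawn uniformly
#' at random (or forced via `start`), subsequent transitions follow the
#' clockwise ring order.
#'
#' @param n_protomers ring size (6).
#' @param seed optional integer seed.
#' @param start optional forced start index (1-based).
#' @param labels protomer labels (default `LETTERS`).
#' @return character vector of protomer labels in transition order.
#' @export
schedule_transitions <- function(n_protomers = 6, seed = NULL, start = NULL,
                                 labels = LETTERS[seq_len(n_protomers)]) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- sample.int(n_protomers, 1)
  idx <- ((start - 1 + seq_len(n_protomers) - 1) %% n_protomers) + 1
  labels[idx]
}

#' Select substrate beads inside the pore window
#'
#' Beads with `|z - <z_loop>| < window_half_width`, where `<z_loop>` is the
#' mean axial coordinate of the pore-loop beads; evaluated at cycle start
#' and held for the hemicycle.
#'
#' @param coords n x 3 coordinate matrix.
#' @param loop_beads indices of the pore-loop beads.
#' @param candidates indices of substrate beads eligible for selection.
#' @param protocol a [cycle_protocol()].
#' @return integer vector of selected bead indices (possibly empty, with a
#'   warning).
#' @export
select_pore_atoms <- function(coords, loop_beads, candidates, protocol) {
  stopifnot(length(loop_beads) > 0)
  axis <- protocol$force_axis
  zc <- as.numeric(coords %*% axis)
  z_loop <- mean(zc[loop_beads])
  sel <- candidates[abs(zc[candidates] - z_loop) < protocol$window_half_width]
  if (length(sel) == 0)
    warning("empty pore-window selection: no force applied this hemicycle")
  sel
}

#' Sample the pore force and distribute it over selected beads
#'
#' The total magnitude is drawn from `Normal(mean_force, sd_force)`
#' truncated at zero; each selected bead receives `total/|selected|` along
#' the pore axis.
#'
#' @param selected integer vector of selected bead indices.
#' @param protocol a [cycle_protocol()].
#' @param seed optional integer seed.
#' @return list with `total_pN`, `per_bead_pN` and `forces` (a tibble:
#'   bead, fx, fy, fz in pN).
#' @export
sample_and_distribute_force <- function(selected, protocol, seed = NULL) {
  stopifnot(length(selected) > 0)
  if (!is.null(seed)) set.seed(seed)
  total <- max(0, rnorm(1, protocol$mean_force, protocol$sd_force))
  per <- total / length(selected)
  v <- protocol$force_axis * per
  list(total_pN = total, per_bead_pN = per,
       forces = tibble::tibble(bead = selected, fx = v[1], fy = v[2], fz = v[3]))
}

#' Effective pore-loop pulling speed
#'
#' `loop_excursion / (tau / n_transitions_per_cycle)`: 10 A over 120 ps and
#' 12 transitions gives 1 A/ps.
#'
#' @param protocol a [cycle_protocol()].
#' @return speed in A/ps.
#' @export
effective_loop_speed <- function(protocol) {
  protocol$loop_excursion / (protocol$tau / protocol$n_transitions_per_cycle)
}

#' Thread a substrate below a ring machine
#'
#' Positions the substrate for translocation: the machine is centred at the
#' origin with its pore axis along +z (cis side z < 0), the substrate is
#' rotated so its tail points to +z and translated so the tail terminal
#' bead sits at `z_offset` inside the pore.
#'
#' @param substrate a [bead_model()] with `substrate_tail` beads at the
#'   chain start.
#' @param z_offset axial position of the tail terminal bead, Angstrom.
#' @return the repositioned substrate model.
#' @export
thread_substrate <- function(substrate, z_offset = 2) {
  xyz <- bead_coords(substrate)
  tail_idx <- which(substrate$domain == "substrate_tail")
  anchor <- if (length(tail_idx) > 0) tail_idx[1] else 1L
  com <- colMeans(xyz)
  dirv <- unit_vec(xyz[anchor, ] - com)
  target <- c(0, 0, 1)
  # rotation taking dirv -> +z (Rodrigues)
  v <- c(dirv[2] * target[3] - dirv[3] * target[2],
         dirv[3] * target[1] - dirv[1] * target[3],
         dirv[1] * target[2] - dirv[2] * target[1])
  c0 <- sum(dirv * target)
  if (sqrt(sum(v^2)) < 1e-10) {
    R <- if (c0 > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx / (1 + c0)
  }
  xyz <- sweep(xyz, 2, com) %*% t(R)
  shift <- c(-xyz[anchor, 1], -xyz[anchor, 2], z_offset - xyz[anchor, 3])
  xyz <- sweep(xyz, 2, shift, `+`)
  set_bead_coords(substrate, xyz)
}

#' Run a repetitive-force translocation simulation
#'
#' Alternates open->close hemicycles (pore force applied to the beads
#' selected at cycle start) and close->open hemicycles (no applied force),
#' propagating the substrate with Brownian dynamics. The machine ring is
#' static: it interacts with the substrate through excluded-volume
#' repulsion only, unless `grip_contacts = TRUE` adds pore-loop/tail native
#' contacts (class `protomer_e15`). Hemicycles tile the nominal step
#' exactly: the integrator substep is derived from `tau` (see the methods
#' vignette).
#'
#' @param substrate a threaded [bead_model()] (see [thread_substrate()]).
#' @param machine a ring [bead_model()] with `pore_loop` beads.
#' @param protocol a [cycle_protocol()].
#' @param table an [interaction_table()] for the substrate topology.
#' @param params an [sop_params()].
#' @param n_cycles cycles to run.
#' @param seed integer seed.
#' @param grip_contacts add native pore-loop/tail contacts.
#' @return an `sop_translocation`: `frames` (substrate+machine coordinates,
#'   one frame per cycle), `log` (per-cycle tibble: cycle, start_protomer,
#'   n_selected, total_force_pN, x, I, time_ps), models and protocol.
#' @export
run_translocation <- function(substrate, machine, protocol = cycle_protocol(),
                              table = interaction_table(contact_cutoff = 6),
                              params = sop_params(), n_cycles = 100, seed = 1,
                              grip_contacts = FALSE) {
  n_sub <- nrow(substrate)
  combined <- dplyr::bind_rows(substrate, machine)
  combined$bead <- seq_len(nrow(combined))
  combined$fixed <- c(rep(FALSE, n_sub), rep(TRUE, nrow(machine)))
  combined <- new_bead_model(combined)
  topo <- build_native_contacts(combined, table)
  if (!grip_contacts) {
    keep <- !(topo$contacts$class %in% c("protomer_e15", "mt_protomer",
                                         "mit_mt", "inter_protomer",
                                         "intra_protomer"))
    # machine is a static wall: drop machine-internal and, unless gripping,
    # machine-substrate native contacts (pure repulsion remains)
    topo$contacts <- topo$contacts[keep, ]
  } else {
    keep <- !(topo$contacts$class %in% c("mt_protomer", "mit_mt",
                                         "inter_protomer", "intra_protomer"))
    topo$contacts <- topo$contacts[keep, ]
  }

  loop_beads <- which(combined$domain == "pore_loop")
  candidates <- seq_len(n_sub)
  axis <- protocol$force_axis
  # integrator substep chosen so hemicycles tile exactly
  hemi_steps <- max(1L, as.integer(ceiling(protocol$tau / (2 * params$dt))))
  p_hemi <- params
  p_hemi$dt <- protocol$tau / (2 * hemi_steps)

  coords <- bead_coords(combined)
  fixed <- combined$fixed
  tcpp <- .topo_cpp(topo)
  pcpp <- .params_cpp(topo, p_hemi)
  seq_order <- seq_len(n_sub) # substrate beads in sequence order
  set.seed(seed)

  log <- vector("list", n_cycles)
  frames <- array(NA_real_, dim = c(nrow(combined), 3, n_cycles))
  impulse_applied <- 0
  for (cyc in seq_len(n_cycles)) {
    start_prot <- schedule_transitions(6)[1]
    sel <- suppressWarnings(
      select_pore_atoms(coords, loop_beads, candidates, protocol))
    if (length(sel) > 0) {
      fs <- sample_and_distribute_force(sel, protocol)
      ext <- matrix(0, nrow(combined), 3)
      ext[sel, ] <- matrix(rep(axis * pN_to_kcal(fs$per_bead_pN),
                               each = length(sel)), ncol = 3)
      total_f <- fs$total_pN
    } else {
      ext <- NULL
      total_f <- 0
    }
    res <- cpp_run_bd(coords, tcpp, pcpp, fixed, hemi_steps, hemi_steps,
                      ext, NULL, NULL, p_hemi$n_sub, p_hemi$max_disp)
    coords <- res$coords
    impulse_applied <- impulse_applied + total_f * protocol$tau / 2
    res <- cpp_run_bd(coords, tcpp, pcpp, fixed, hemi_steps, hemi_steps,
                      NULL, NULL, NULL, p_hemi$n_sub, p_hemi$max_disp)
    coords <- res$coords
    zc <- as.numeric(coords[seq_order, , drop = FALSE] %*% axis)
    translocated <- zc > protocol$z_trans
    frames[, , cyc] <- coords
    log[[cyc]] <- tibble::tibble(
      cycle = cyc, start_protomer = start_prot, n_selected = length(sel),
      total_force_pN = total_f, x = mean(translocated),
      I = if (any(translocated)) max(which(translocated)) else 0L,
      time_ps = cyc * protocol$tau)
  }
  structure(list(frames = frames, coords = coords,
                 log = dplyr::bind_rows(log),
                 impulse_applied_pN_ps = impulse_applied,
                 substrate = substrate, machine = machine,
                 combined = combined, topology = topo, protocol = protocol,
                 params = p_hemi, seed = seed),
            class = "sop_translocation")
}
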