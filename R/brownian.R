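#' Constant-loading-rate cantilever protocol
#'
#' The cantilever anchor starts at the pulled bead and advances by `dx`
#' along `direction` every `n_av` integration steps; the bead feels the
#' harmonic spring `k_trans` towards the anchor. The pulling speed is
#' `v_f = dx / (n_av * dt)`: the defaults (`dx = 0.0008` A,
#' `n_av = 1000`, `dt = 40` ps) give 2 um/s.
#'
#' @param pulled_bead index of the pulled bead.
#' @param direction pulling direction (normalised internally).
#' @param k_trans cantilever spring constant, kcal/(mol A^2).
#' @param dx anchor displacement per update, Angstrom.
#' @param n_av steps between anchor updates.
#' @return a `cantilever_protocol`.
#' @export
cantilever_protocol <- function(pulled_bead, direction = c(0, 0, 1),
                                k_trans = 0.025, dx = 0.0008, n_av = 1000) {
  stopifnot(k_trans > 0, dx > 0, n_av >= 1, pulled_bead >= 1)
  structure(list(pulled_bead = as.integer(pulled_bead),
                 direction = unit_vec(direction), k_trans = k_trans,
                 dx = dx, n_av = as.integer(n_av)),
            class = "cantilever_protocol")
}

#' Pulling speed of a cantilever protocol
#'
#' @param protocol a [cantilever_protocol()].
#' @param dt integration step, ps.
#' @return list with the speed in `A_per_ps` and `um_per_s`
#'   (1 A/ps = 100 m/s).
#' @export
pulling_speed <- function(protocol, dt = 40) {
  v <- protocol$dx / (protocol$n_av * dt) # A/ps
  list(A_per_ps = v, um_per_s = v * 1e8)
}

#' One overdamped Brownian step
#'
#' Advances every non-fixed bead by `F dt / zeta_eff` plus Gaussian noise
#' with per-component variance `2 kBT dt / zeta_eff`
#' (fluctuation-dissipation); fixed beads do not move. Reproducible given
#' `seed`.
#'
#' @param coords n x 3 coordinate matrix (or a [bead_model()]).
#' @param topology an `sop_topology`.
#' @param params an [sop_params()].
#' @param external_forces optional n x 3 force matrix, kcal/(mol A).
#' @param fixed logical vector (default: none fixed).
#' @param seed optional integer seed.
#' @return the new n x 3 coordinate matrix.
#' @export
brownian_step <- function(coords, topology, params = sop_params(),
                          external_forces = NULL, fixed = NULL, seed = NULL) {
  if (inherits(coords, "bead_model")) {
    if (is.null(fixed)) fixed <- coords$fixed
    coords <- bead_coords(coords)
  }
  if (is.null(fixed)) fixed <- rep(FALSE, nrow(coords))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_bd(coords, .topo_cpp(topology), .params_cpp(topology, params),
                    fixed, 1L, 1L, external_forces, NULL, NULL,
                    params$n_sub, params$max_disp)
  res$coords
}

#' Free Brownian dynamics (no cantilever)
#'
#' @inheritParams brownian_step
#' @param n_steps number of nominal steps.
#' @param output_every record a frame every so many steps.
#' @param traps optional harmonic restraints: list with `idx` (bead
#'   indices), `centers` (matrix) and `k` (kcal/(mol A^2)).
#' @return an `sop_trajectory`: list with `frames` (n x 3 x T array),
#'   `time` (ps), `coords` (final) and an `energies` tibble.
#' @export
run_brownian <- function(coords, topology, params = sop_params(),
                         n_steps = 1000, seed = 1, output_every = 10,
                         external_forces = NULL, fixed = NULL, traps = NULL) {
  if (inherits(coords, "bead_model")) {
    if (is.null(fixed)) fixed <- coords$fixed
    coords <- bead_coords(coords)
  }
  if (is.null(fixed)) fixed <- rep(FALSE, nrow(coords))
  set.seed(seed)
  res <- cpp_run_bd(coords, .topo_cpp(topology), .params_cpp(topology, params),
                    fixed, as.integer(n_steps), as.integer(output_every),
                    external_forces, NULL, traps, params$n_sub, params$max_disp)
  .as_trajectory(res, params)
}

.as_trajectory <- function(res, params) {
  frames <- aperm(res$frames, c(2, 1, 3)) # -> n x 3 x T
  structure(list(
    frames = frames, time = res$time, coords = res$coords,
    energies = tibble::tibble(time = res$time, v_fene = res$v_fene,
                              v_att = res$v_att, v_rep = res$v_rep,
                              v_total = res$v_fene + res$v_att + res$v_rep),
    params = params), class = "sop_trajectory")
}

#' Run a constant-loading-rate pulling simulation
#'
#' Brownian dynamics with the cantilever of `protocol` attached to the
#' pulled bead; the anchor starts at the bead's initial position. Returns
#' the trajectory plus the force-extension record (extension = displacement
#' of the pulled bead along the pulling direction; force = axial component
#' of the cantilever spring, pN).
#'
#' @param model a [bead_model()] (its `fixed` column marks immobile beads
#'   unless `fixed_beads` is given).
#' @param topology an `sop_topology`.
#' @param params an [sop_params()].
#' @param protocol a [cantilever_protocol()].
#' @param fixed_beads optional integer indices of fixed beads.
#' @param n_steps nominal steps to run.
#' @param seed integer seed.
#' @param output_every frame/trace stride (nominal steps).
#' @return an `sop_pulling`: trajectory fields plus `trace`
#'   (tibble: time, extension, force_pN), the protocol and the model.
#' @export
run_pulling <- function(model, topology, params = sop_params(), protocol,
                        fixed_beads = NULL, n_steps = 5000, seed = 1,
                        output_every = 10) {
  stopifnot(inherits(protocol, "cantilever_protocol"))
  fixed <- model$fixed
  if (!is.null(fixed_beads)) {
    fixed <- rep(FALSE, nrow(model))
    fixed[fixed_beads] <- TRUE
  }
  # a fixed pulled bead is allowed: it records the pure loading ramp
  coords <- bead_coords(model)
  cant <- list(pulled_bead = protocol$pulled_bead,
               direction = protocol$direction, k_trans = protocol$k_trans,
               dx = protocol$dx, n_av = protocol$n_av,
               anchor0 = coords[protocol$pulled_bead, ])
  set.seed(seed)
  res <- cpp_run_bd(coords, .topo_cpp(topology), .params_cpp(topology, params),
                    fixed, as.integer(n_steps), as.integer(output_every),
                    NULL, cant, NULL, params$n_sub, params$max_disp)
  out <- .as_trajectory(res, params)
  out$trace <- tibble::tibble(time = res$time, extension = res$extension,
                              force_pN = res$force_pN)
  out$protocol <- protocol
  out$model <- model
  out$topology <- topology
  out$seed <- seed
  class(out) <- c("sop_pulling", "sop_trajectory")
  out
}

#' Write a force trace as TSV
#'
#' Columns `step`, `time_ps`, `extension_A`, `force_pN`.
#'
#' @param pulling an `sop_pulling` result.
#' @param path output path.
#' @export
write_force_trace <- function(pulling, path) {
  tr <- pulling$trace
  utils::write.table(
    data.frame(step = seq_len(nrow(tr)), time_ps = tr$time,
               extension_A = tr$extension, force_pN = tr$force_pN),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
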