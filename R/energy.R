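#' SOP model parameters
#'
#' Energies in kcal/mol, lengths in Angstrom, times in ps. The friction
#' coefficient is the dimensionless `zeta = 50` times `zeta_unit`
#' (kcal mol^-1 ps A^-2), giving the overdamped mobility
#' `1/(zeta*zeta_unit)` A^2 mol kcal^-1 ps^-1. The nominal integration step
#' `dt = 40` ps sets the time axis and the pulling-speed bookkeeping; for
#' numerical stability of the stiff FENE term each nominal step is
#' subdivided into `n_sub` Euler-Maruyama substeps (see the methods
#' vignette).
#'
#' @param fene_k FENE spring constant, kcal/(mol A^2).
#' @param fene_R0 FENE extensibility limit, Angstrom.
#' @param eps_l repulsive amplitude, kcal/mol.
#' @param sigma repulsive range, Angstrom.
#' @param zeta dimensionless friction multiplier.
#' @param zeta_unit friction unit scale, kcal mol^-1 ps A^-2.
#' @param dt nominal integration step, ps (warns above 100).
#' @param n_sub integration substeps per nominal step.
#' @param kBT thermal energy, kcal/mol (0.6 is ~300 K).
#' @param rep_cutoff_mult repulsive-pair cutoff in units of sigma.
#' @param max_disp per-substep displacement cap, Angstrom (guards the FENE
#'   wall).
#' @return an `sop_params` list.
#' @export
sop_params <- function(fene_k = 20, fene_R0 = 2.0, eps_l = 1.0, sigma = 3.8,
                       zeta = 50, zeta_unit = 1.0, dt = 40, n_sub = 40,
                       kBT = 0.6, rep_cutoff_mult = 3, max_disp = 0.5) {
  stopifnot(fene_k > 0, fene_R0 > 0, eps_l > 0, sigma > 0, zeta > 0,
            dt > 0, n_sub >= 1, kBT >= 0)
  if (dt > 100)
    warning("dt > 100 ps: integration stability is your responsibility")
  structure(list(fene_k = fene_k, fene_R0 = fene_R0, eps_l = eps_l,
                 sigma = sigma, zeta = zeta, zeta_unit = zeta_unit,
                 zeta_eff = zeta * zeta_unit, dt = dt, n_sub = as.integer(n_sub),
                 kBT = kBT, rep_cutoff = rep_cutoff_mult * sigma,
                 max_disp = max_disp),
            class = "sop_params")
}

#' FENE backbone bond energy
#'
#' `V(r) = -(k/2) R0^2 ln(1 - (r - r0)^2 / R0^2)`: zero at the native
#' length, diverging at the extensibility limit `|r - r0| = R0`.
#'
#' @param r,r0 current and native bond lengths (Angstrom); vectorized.
#' @param params an [sop_params()].
#' @return energies in kcal/mol.
#' @export
fene_energy <- function(r, r0, params = sop_params()) {
  d2 <- (r - r0)^2
  if (any(d2 >= params$fene_R0^2)) {
    k <- which(d2 >= params$fene_R0^2)[1]
    stop(sprintf("bond %d overstretched: |r - r0| = %.3f >= R0 = %.3f",
                 k, abs(r - r0)[k], params$fene_R0), call. = FALSE)
  }
  -0.5 * params$fene_k * params$fene_R0^2 * log(1 - d2 / params$fene_R0^2)
}

#' Native (attractive) Lennard-Jones contact energy
#'
#' `V(r) = eps_h [ (r0/r)^12 - 2 (r0/r)^6 ]`, minimum `-eps_h` at `r = r0`.
#'
#' @param r,r0 current and native pair distances (Angstrom); vectorized.
#' @param eps_h contact strength, kcal/mol.
#' @return energies in kcal/mol.
#' @export
native_lj_energy <- function(r, r0, eps_h) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  q6 <- (r0 / r)^6
  eps_h * (q6^2 - 2 * q6)
}

#' Repulsive (non-native) Lennard-Jones energy
#'
#' `V(r) = eps_l (sigma/r)^6`: strictly positive and monotonically
#' decreasing.
#'
#' @param r pair distances (Angstrom); vectorized.
#' @param params an [sop_params()].
#' @return energies in kcal/mol.
#' @export
repulsive_lj_energy <- function(r, params = sop_params()) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  params$eps_l * (params$sigma / r)^6
}

# marshal an sop_topology into the flat 0-based lists the C++ core expects
.topo_cpp <- function(topology) {
  list(bond_i = as.integer(topology$bonds$i - 1L),
       bond_j = as.integer(topology$bonds$j - 1L),
       bond_r0 = as.numeric(topology$bonds$r0),
       con_i = as.integer(topology$contacts$i - 1L),
       con_j = as.integer(topology$contacts$j - 1L),
       con_r0 = as.numeric(topology$contacts$r0),
       con_eps = as.numeric(topology$contacts$eps),
       chain = as.integer(topology$chain_idx),
       seq = as.integer(topology$seqpos))
}

.params_cpp <- function(topology, params) {
  list(fene_k = topology$fene_k %||% params$fene_k,
       fene_R0 = topology$fene_R0 %||% params$fene_R0,
       eps_l = params$eps_l, sigma = params$sigma, kBT = params$kBT,
       zeta_eff = params$zeta_eff, rep_cutoff = params$rep_cutoff,
       dt = params$dt)
}

#' Total SOP energy and analytic forces
#'
#' Evaluates `V_T = V_FENE + V_NBATT + V_NBREP` and its exact negative
#' gradient for one configuration. Native pairs come from the fixed contact
#' list (no cutoff); repulsion acts on every non-native, non-bonded pair
#' (the intra-chain `|i - j| = 2` term always, others within
#' `rep_cutoff_mult * sigma`).
#'
#' @param coords n x 3 coordinate matrix (or a [bead_model()]).
#' @param topology an `sop_topology`.
#' @param params an [sop_params()].
#' @return list with `v_fene`, `v_att`, `v_rep`, `v_total` (kcal/mol) and
#'   `forces` (n x 3, kcal/(mol A)).
#' @export
sop_energy_forces <- function(coords, topology, params = sop_params()) {
  if (inherits(coords, "bead_model")) coords <- bead_coords(coords)
  stopifnot(nrow(coords) == topology$n_beads)
  cpp_energy_forces(coords, .topo_cpp(topology), .params_cpp(topology, params))
}
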