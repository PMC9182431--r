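#' Declarative experiment configuration
#'
#' Bundles a system, interaction table, protocol and run settings into a
#' reproducible multi-trajectory experiment. Fixed beads are chosen by
#' `fixed_selector(model)`, returning bead indices (so presets can say
#' "first bead of the first and last dimer" without hard-coding indices).
#'
#' @param model a [bead_model()] (the native system).
#' @param table an [interaction_table()].
#' @param protocol a [cantilever_protocol()] or [cycle_protocol()].
#' @param params an [sop_params()].
#' @param fixed_selector function(model) -> integer indices, or an integer
#'   vector, or `NULL` (use the model's `fixed` column).
#' @param n_steps nominal steps (cantilever runs).
#' @param n_cycles cycles (pore runs).
#' @param n_trajectories independent trajectories.
#' @param seed base seed; per-trajectory seeds are derived from it.
#' @param mit_eps optional MIT-lattice strength applied via
#'   [set_mit_interaction()].
#' @param output_every trace/frame stride.
#' @param extra_bonds declared fusions passed to [build_native_contacts()].
#' @param machine companion ring model (pore runs).
#' @param label experiment label carried into the aggregate table.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(model, table = interaction_table(), protocol,
                              params = sop_params(), fixed_selector = NULL,
                              n_steps = 5000, n_cycles = 100,
                              n_trajectories = 3, seed = 1, mit_eps = NULL,
                              output_every = 10, extra_bonds = NULL,
                              machine = NULL, label = "experiment") {
  stopifnot(n_trajectories >= 1)
  structure(list(model = model, table = table, protocol = protocol,
                 params = params, fixed_selector = fixed_selector,
                 n_steps = n_steps, n_cycles = n_cycles,
                 n_trajectories = n_trajectories, seed = seed,
                 mit_eps = mit_eps, output_every = output_every,
                 extra_bonds = extra_bonds, machine = machine, label = label),
            class = "experiment_config")
}

.resolve_fixed <- function(config) {
  fs <- config$fixed_selector
  model <- config$model
  idx <- if (is.null(fs)) which(model$fixed)
  else if (is.function(fs)) fs(model)
  else as.integer(fs)
  if (!is.null(fs) && length(idx) == 0)
    stop("fixed-bead selector resolved to an empty set", call. = FALSE)
  idx
}

#' Run a configured multi-trajectory experiment
#'
#' Runs `n_trajectories` with seeds derived from the base seed. Cantilever
#' runs yield per-trajectory force traces plus an event report (breaking
#' forces and final-frame census); pore runs yield translocation logs. The
#' aggregate table mirrors the severing-outcome summaries: one row per
#' trajectory with eps_MIT, FBF, CBF, oligomer decomposition and the
#' fragments-lost pathway label.
#'
#' @param config an [experiment_config()].
#' @param smooth_window,min_drop passed to [detect_breaking_forces()].
#' @return an `sop_experiment`: list with `runs` (per-trajectory results),
#'   `reports` (event reports) and `aggregate` (tibble).
#' @export
run_experiment <- function(config, smooth_window = 25, min_drop = 50) {
  model <- config$model
  topo <- build_native_contacts(model, config$table,
                                extra_bonds = config$extra_bonds)
  if (!is.null(config$mit_eps))
    topo <- set_mit_interaction(topo, config$mit_eps)
  fixed_idx <- .resolve_fixed(config)
  model$fixed <- seq_len(nrow(model)) %in% fixed_idx
  is_cant <- inherits(config$protocol, "cantilever_protocol")

  runs <- vector("list", config$n_trajectories)
  reports <- vector("list", config$n_trajectories)
  rows <- vector("list", config$n_trajectories)
  for (k in seq_len(config$n_trajectories)) {
    sk <- derive_seed(config$seed, k)
    if (is_cant) {
      run <- run_pulling(model, topo, config$params, config$protocol,
                         fixed_beads = fixed_idx, n_steps = config$n_steps,
                         seed = sk, output_every = config$output_every)
      bf <- detect_breaking_forces(run$trace, smooth_window, min_drop)
      rep <- fragment_census(run$coords, topo, model)
      rep$fbf <- bf$fbf; rep$cbf <- bf$cbf
      rows[[k]] <- tibble::tibble(
        label = config$label, trajectory = k, seed = sk,
        eps_mit = config$mit_eps %||% NA_real_,
        fbf_pN = rep$fbf, cbf_pN = rep$cbf,
        oligomers = rep$oligomers, pathway = rep$pathway)
    } else {
      run <- run_translocation(model, config$machine, config$protocol,
                               config$table, config$params,
                               n_cycles = config$n_cycles, seed = sk)
      rep <- NULL
      lg <- run$log
      rows[[k]] <- tibble::tibble(
        label = config$label, trajectory = k, seed = sk,
        eps_mit = NA_real_, fbf_pN = NA_real_, cbf_pN = NA_real_,
        oligomers = NA_character_,
        pathway = NA_character_,
        x_final = lg$x[nrow(lg)], I_final = lg$I[nrow(lg)])
    }
    runs[[k]] <- run
    reports[[k]] <- rep
  }
  structure(list(runs = runs, reports = reports,
                 aggregate = dplyr::bind_rows(rows), config = config),
            class = "sop_experiment")
}

#' Pathway frequency census over event reports
#'
#' Frequency of each (fragments-lost label, oligomer decomposition) pair
#' across trajectories, with counts (tiny-n statistics are reported as
#' counts, not only percentages).
#'
#' @param reports a list of `event_report`s, an `sop_experiment`, or a
#'   tibble with `pathway` (and optionally `oligomers`) columns.
#' @param by group by `"pathway"` (default) or `c("pathway", "oligomers")`.
#' @return tibble with `pathway` (and `oligomers`), `n` and `pct`.
#' @export
pathway_census <- function(reports, by = "pathway") {
  tbl <- if (inherits(reports, "sop_experiment")) reports$aggregate
  else if (is.data.frame(reports)) reports
  else tibble::tibble(
    pathway = vapply(reports, `[[`, "", "pathway"),
    oligomers = vapply(reports, `[[`, "", "oligomers"))
  stopifnot(nrow(tbl) >= 1)
  out <- dplyr::count(tbl, dplyr::across(dplyr::all_of(by)), name = "n")
  out$pct <- 100 * out$n / sum(out$n)
  out
}

#' Toy severing experiment preset
#'
#' A desk-scale analogue of the lattice-severing setups: a 3 x 3 toy
#' lattice with the machine replaced by a direct cantilever pull on a
#' central beta-monomer tail bead, lumen-side beads of the first and last
#' dimer of each protofilament held fixed. The pulling speed is scaled up
#' relative to the 2 um/s reference so rupture happens within desk-scale
#' step counts.
#'
#' @param n_pf,n_dimers,beads_per_monomer lattice size.
#' @param mit_eps optional MIT strength (kept for sweep plumbing).
#' @param n_steps,n_trajectories,seed run settings.
#' @param dx_scale anchor-step multiplier relative to the 0.0008 A
#'   reference.
#' @return an [experiment_config()].
#' @export
toy_severing_config <- function(n_pf = 3, n_dimers = 3, beads_per_monomer = 4,
                                mit_eps = NULL, n_steps = 4000,
                                n_trajectories = 3, seed = 1,
                                dx_scale = 5000) {
  model <- make_toy_lattice(n_pf, n_dimers, beads_per_monomer, seed = seed)
  # fix the first bead of every end monomer (both lattice ends)
  fixer <- function(m) {
    end_sub <- grepl(":d01:a$", m$subunit) |
      grepl(sprintf(":d%02d:b$", n_dimers), m$subunit)
    which(end_sub & !duplicated(m$subunit))
  }
  # pull the tail of the central beta monomer, perpendicular to the sheet
  mid_pf <- (n_pf + 1) %/% 2
  mid_d <- (n_dimers + 1) %/% 2
  tail_bead <- which(model$domain == "HBD_tail" &
                       model$subunit == sprintf("pf%02d:d%02d:b", mid_pf, mid_d))
  prot <- cantilever_protocol(pulled_bead = tail_bead,
                              direction = c(0, 0, 1),
                              dx = 0.0008 * dx_scale, n_av = 10)
  experiment_config(model, interaction_table(), prot,
                    sop_params(), fixed_selector = fixer,
                    n_steps = n_steps, n_trajectories = n_trajectories,
                    seed = seed, mit_eps = mit_eps, output_every = 5,
                    label = sprintf("toy_severing_pf%d", n_pf))
}

#' Toy translocation experiment preset
#'
#' A toy globule threaded through the toy hexamer pore under the
#' repetitive-force protocol, with an edge- or core-terminal tail to probe
#' the unzipping/shearing anisotropy of the engaged terminal. The pore
#' (radius 4.5 A) only passes an extended chain, so progress requires
#' extraction of the terminal strand from the sheet; the sheet strength
#' (1.5 kcal/mol) and the default 90 pN mean force put the chain tension
#' between the one-rung and two-rung rupture scales, the regime where the
#' edge/core contrast is resolved (see the methods vignette).
#'
#' @param terminal `"edge"` or `"core"`.
#' @param mean_force,sd_force Gaussian pore-force parameters, pN.
#' @param n_cycles,n_trajectories,seed run settings.
#' @return an [experiment_config()].
#' @export
toy_translocation_config <- function(terminal = c("edge", "core"),
                                     mean_force = 90, sd_force = 5,
                                     n_cycles = 150,
                                     n_trajectories = 3, seed = 1) {
  terminal <- match.arg(terminal)
  glob <- make_toy_globule(n_strands = 4, strand_len = 6, tail_len = 6,
                           terminal_strand = if (terminal == "edge") 1 else 2,
                           seed = 1)
  glob <- thread_substrate(glob, z_offset = 6)
  machine <- make_toy_hexamer(with_arms = FALSE, pore_radius = 4.5, seed = 1)
  experiment_config(glob,
                    interaction_table(substrate_intra = 1.5,
                                      contact_cutoff = 6),
                    cycle_protocol(mean_force = mean_force,
                                   sd_force = sd_force),
                    sop_params(),
                    n_cycles = n_cycles, n_trajectories = n_trajectories,
                    seed = seed, machine = machine,
                    label = sprintf("toy_translocation_%s", terminal))
}
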