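#' Interface interaction table
#'
#' Per-interface native contact strengths (kcal/mol) plus the repulsive
#' amplitude/range and the native-contact cutoff. Defaults are the standard
#' GDP-lattice values: intra-dimer 1.9, longitudinal 1.0, lateral and seam
#' 0.9, intra- and inter-protomer 1.3, machine-lattice 1.0, pore-loop/handle
#' (protomer-E15) 1.0; the MIT-lattice strength `mit_mt` is the sweep
#' variable (1.0-4.0 kcal/mol). Contacts within one lattice monomer reuse
#' the intra-dimer scale; a globular substrate's internal contacts have
#' their own scale `substrate_intra`.
#'
#' @param intra_monomer,intra_dimer,longitudinal,lateral,seam,intra_protomer,inter_protomer,mt_protomer,mit_mt,protomer_e15,substrate_intra
#'   native contact strengths by interface class (kcal/mol).
#' @param eps_l repulsive amplitude (kcal/mol).
#' @param sigma repulsive range (Angstrom).
#' @param contact_cutoff native-contact distance cutoff (Angstrom; 13 for
#'   C-alpha lattice systems, 6 recommended for the toy globules).
#' @return an `interaction_table`.
#' @export
interaction_table <- function(intra_monomer = 1.9, intra_dimer = 1.9,
                              longitudinal = 1.0, lateral = 0.9, seam = 0.9,
                              intra_protomer = 1.3, inter_protomer = 1.3,
                              mt_protomer = 1.0, mit_mt = 1.0,
                              protomer_e15 = 1.0, substrate_intra = 1.0,
                              eps_l = 1.0, sigma = 3.8, contact_cutoff = 13) {
  eps <- c(intra_monomer = intra_monomer, intra_dimer = intra_dimer,
           longitudinal = longitudinal, lateral = lateral, seam = seam,
           intra_protomer = intra_protomer, inter_protomer = inter_protomer,
           mt_protomer = mt_protomer, mit_mt = mit_mt,
           protomer_e15 = protomer_e15, substrate_intra = substrate_intra)
  if (any(eps <= 0) || eps_l <= 0 || sigma <= 0)
    stop("all energies and sigma must be positive", call. = FALSE)
  if (contact_cutoff <= sigma)
    stop("contact_cutoff must exceed sigma", call. = FALSE)
  structure(list(eps_h_by_class = eps, eps_l = eps_l, sigma = sigma,
                 contact_cutoff = contact_cutoff),
            class = "interaction_table")
}

.subunit_body <- function(subunit) {
  dplyr::case_when(
    grepl("^pf", subunit) ~ "lattice",
    grepl("^protomer", subunit) ~ "machine",
    subunit %in% c("none", "", NA) ~ "unknown",
    TRUE ~ "substrate"
  )
}

#' Classify the interface of bead pairs
#'
#' Deterministic interface class from subunit and domain annotations:
#' within one lattice monomer `intra_monomer`; alpha-beta of one dimer
#' `intra_dimer`; same protofilament, different dimer `longitudinal`;
#' adjacent protofilaments `lateral` (or `seam` at the declared seam);
#' within/between ring protomers `intra_protomer`/`inter_protomer`;
#' machine-lattice `mt_protomer`, or `mit_mt` when the machine bead is an
#' MIT bead; a pore-loop bead against a substrate/HBD tail bead
#' `protomer_e15`; within a globular substrate `substrate_intra`.
#' Classification is symmetric in `i`, `j`.
#'
#' @param model a [bead_model()].
#' @param i,j bead indices (vectors of equal length).
#' @return character vector of interface classes.
#' @export
classify_interface <- function(model, i, j) {
  si <- model$subunit[i]; sj <- model$subunit[j]
  if (any(si %in% c("none", "", NA)) || any(sj %in% c("none", "", NA)))
    stop("unannotated bead(s): subunit_id required for classification",
         call. = FALSE)
  di <- model$domain[i]; dj <- model$domain[j]
  bi <- .subunit_body(si); bj <- .subunit_body(sj)
  seam <- attr(model, "seam")

  tail_tags <- c("HBD_tail", "substrate_tail")
  pore_pair <- (di == "pore_loop" & dj %in% tail_tags) |
    (dj == "pore_loop" & di %in% tail_tags)

  pf_i <- sub(":.*", "", si); pf_j <- sub(":.*", "", sj)
  dim_i <- sub("^(pf[0-9]+:d[0-9]+).*", "\\1", si)
  dim_j <- sub("^(pf[0-9]+:d[0-9]+).*", "\\1", sj)
  is_seam <- if (is.null(seam)) rep(FALSE, length(pf_i)) else
    (pf_i == seam[1] & pf_j == seam[2]) | (pf_i == seam[2] & pf_j == seam[1])

  cls <- dplyr::case_when(
    pore_pair ~ "protomer_e15",
    si == sj & bi == "lattice" ~ "intra_monomer",
    si == sj & bi == "machine" ~ "intra_protomer",
    si == sj ~ "substrate_intra",
    bi == "lattice" & bj == "lattice" & dim_i == dim_j ~ "intra_dimer",
    bi == "lattice" & bj == "lattice" & pf_i == pf_j ~ "longitudinal",
    bi == "lattice" & bj == "lattice" & is_seam ~ "seam",
    bi == "lattice" & bj == "lattice" ~ "lateral",
    bi == "machine" & bj == "machine" ~ "inter_protomer",
    xor(bi == "machine", bj == "machine") &
      ((bi == "machine" & di == "MIT") | (bj == "machine" & dj == "MIT")) &
      (bi == "lattice" | bj == "lattice") ~ "mit_mt",
    TRUE ~ "mt_protomer"
  )
  cls
}

#' Build the SOP topology from a native-configuration bead model
#'
#' Native contacts are all pairs within `contact_cutoff` in the native
#' configuration, with sequence separation >= 3 within a chain and no
#' separation rule between chains; each pair stores its native distance and
#' the interface strength of its class. Bonds are all consecutive
#' intra-chain pairs plus declared cross-links (e.g. the covalent
#' handle-tail fusion), each at its native length. Pairs are either native
#' or subject to repulsion, never both.
#'
#' @param model a [bead_model()] in its native configuration.
#' @param table an [interaction_table()].
#' @param extra_bonds optional two-column matrix/data frame of bead index
#'   pairs to bond covalently (declared fusions).
#' @param min_seq_sep minimum intra-chain sequence separation for a native
#'   contact (default 3).
#' @return an `sop_topology` (list with `bonds` and `contacts` tibbles).
#' @export
build_native_contacts <- function(model, table = interaction_table(),
                                  extra_bonds = NULL, min_seq_sep = 3) {
  xyz <- bead_coords(model)
  n <- nrow(xyz)
  chain_idx <- match(model$chain, unique(model$chain))
  seqpos <- stats::ave(seq_len(n), chain_idx, FUN = seq_along)

  # bonds: consecutive within each chain + declared fusions
  same_next <- which(chain_idx[-n] == chain_idx[-1])
  bonds <- tibble::tibble(i = same_next, j = same_next + 1L)
  if (!is.null(extra_bonds)) {
    eb <- as.matrix(extra_bonds)
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      i = as.integer(pmin(eb[, 1], eb[, 2])),
      j = as.integer(pmax(eb[, 1], eb[, 2]))))
  }
  bonds$r0 <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                              xyz[bonds$j, , drop = FALSE])^2))
  if (any(!is.finite(bonds$r0)) || any(bonds$r0 <= 0))
    stop("invalid bond length", call. = FALSE)
  if (any(bonds$r0 > 12)) {
    k <- which.max(bonds$r0)
    stop(sprintf("bond %d-%d has native length %.1f A: chain break?",
                 bonds$i[k], bonds$j[k], bonds$r0[k]), call. = FALSE)
  }

  D <- as.matrix(stats::dist(xyz))
  within <- which(upper.tri(D) & D <= table$contact_cutoff, arr.ind = TRUE)
  i <- within[, 1]; j <- within[, 2]
  eligible <- chain_idx[i] != chain_idx[j] |
    abs(seqpos[i] - seqpos[j]) >= min_seq_sep
  i <- i[eligible]; j <- j[eligible]
  # exclude declared fusion bonds from the contact list
  bond_key <- paste(bonds$i, bonds$j)
  keep <- !(paste(pmin(i, j), pmax(i, j)) %in% bond_key)
  i <- i[keep]; j <- j[keep]

  ann <- !(model$subunit %in% c("none", "", NA))
  cls <- character(length(i))
  if (length(i) > 0) {
    both <- ann[i] & ann[j]
    cls[both] <- classify_interface(model, i[both], j[both])
    cls[!both] <- "substrate_intra" # unannotated beads: generic scale
  }
  contacts <- tibble::tibble(
    i = as.integer(i), j = as.integer(j),
    r0 = D[cbind(i, j)],
    eps = unname(table$eps_h_by_class[cls]),
    class = cls)

  structure(list(
    bonds = bonds, contacts = contacts, n_beads = n,
    chain_idx = chain_idx, seqpos = as.integer(seqpos),
    fene_k = 20, fene_R0 = 2, table = table), class = "sop_topology")
}

#' @export
print.sop_topology <- function(x, ...) {
  cat(sprintf("<sop_topology> %d beads, %d bonds, %d native contacts\n",
              x$n_beads, nrow(x$bonds), nrow(x$contacts)))
  print(dplyr::count(x$contacts, .data$class))
  invisible(x)
}

#' Set the MIT-lattice interaction strength
#'
#' Rescales every `mit_mt` native contact to `eps` kcal/mol, leaving all
#' other contacts unchanged (the sweep variable of the severing
#' experiments).
#'
#' @param topology an `sop_topology`.
#' @param eps new strength (kcal/mol, > 0).
#' @return the modified topology.
#' @export
set_mit_interaction <- function(topology, eps) {
  stopifnot(eps > 0)
  topology$contacts$eps[topology$contacts$class == "mit_mt"] <- eps
  topology$table$eps_h_by_class["mit_mt"] <- eps
  topology
}

#' Serialize / load a topology as plain-text tables
#'
#' Writes `<path>.contacts.tsv` (i, j, r0, eps_h, class) and
#' `<path>.bonds.tsv` (i, j, r0).
#'
#' @param topology an `sop_topology`.
#' @param path base path.
#' @return `path` (write) or the topology (read), invisibly for write.
#' @export
write_topology <- function(topology, path) {
  ct <- topology$contacts
  names(ct) <- c("i", "j", "r0", "eps_h", "class")
  utils::write.table(ct, paste0(path, ".contacts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(topology$bonds, paste0(path, ".bonds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @param model the bead model the topology belongs to (annotations are not
#'   stored in the pair lists).
#' @param table the interaction table to attach.
#' @export
read_topology <- function(path, model, table = interaction_table()) {
  ct <- utils::read.table(paste0(path, ".contacts.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  bd <- utils::read.table(paste0(path, ".bonds.tsv"), header = TRUE, sep = "\t")
  chain_idx <- match(model$chain, unique(model$chain))
  structure(list(
    bonds = tibble::as_tibble(bd),
    contacts = tibble::tibble(i = as.integer(ct$i), j = as.integer(ct$j),
                              r0 = ct$r0, eps = ct$eps_h, class = ct$class),
    n_beads = nrow(model), chain_idx = chain_idx,
    seqpos = as.integer(stats::ave(seq_len(nrow(model)), chain_idx,
                                   FUN = seq_along)),
    fene_k = 20, fene_R0 = 2, table = table), class = "sop_topology")
}
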