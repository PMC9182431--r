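#' Annotated C-alpha bead models
#'
#' A `bead_model` is a tibble with one row per C-alpha bead and columns
#' `bead` (index), `chain`, `resid`, `subunit`, `domain`, `fixed`,
#' `x`, `y`, `z` (Angstrom). Subunit labels encode the body a bead belongs
#' to: `"pfPP:dDD:a"`/`"pfPP:dDD:b"` for lattice monomers, `"protomer:A"` ...
#' `"protomer:F"` for ring-machine protomers and `"sp"` for a globular
#' substrate. Domain tags are one of `NBD`, `HBD_tail`, `pore_loop`,
#' `linker`, `MIT`, `substrate_core`, `substrate_tail`, `none`.
#'
#' @param chain,resid,subunit,domain,fixed per-bead annotations (recycled
#'   where length 1).
#' @param xyz numeric matrix of bead coordinates (n x 3, Angstrom).
#' @param seam optional character pair of protofilament labels whose lateral
#'   interface is the seam.
#' @return a `bead_model` tibble.
#' @export
bead_model <- function(xyz, chain, resid = NULL, subunit = "none",
                       domain = "none", fixed = FALSE, seam = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  n <- nrow(xyz)
  chain <- rep_len(as.character(chain), n)
  if (is.null(resid)) {
    resid <- stats::ave(seq_len(n), chain, FUN = seq_along)
  }
  m <- tibble::tibble(
    bead = seq_len(n),
    chain = chain,
    resid = as.integer(rep_len(resid, n)),
    subunit = rep_len(as.character(subunit), n),
    domain = rep_len(as.character(domain), n),
    fixed = rep_len(as.logical(fixed), n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  new_bead_model(m, seam = seam)
}

.domain_levels <- c("NBD", "HBD_tail", "pore_loop", "linker", "MIT",
                    "substrate_core", "substrate_tail", "none")

new_bead_model <- function(tbl, seam = NULL) {
  stopifnot(all(c("bead", "chain", "resid", "subunit", "domain", "fixed",
                  "x", "y", "z") %in% names(tbl)))
  if (nrow(tbl) < 1) stop("a bead model needs at least one bead", call. = FALSE)
  if (!all(is.finite(tbl$x) & is.finite(tbl$y) & is.finite(tbl$z)))
    stop("non-finite coordinates in bead model", call. = FALSE)
  bad <- setdiff(unique(tbl$domain), .domain_levels)
  if (length(bad) > 0)
    stop("unknown domain tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- tibble::new_tibble(tbl, class = "bead_model")
  attr(out, "seam") <- seam
  out
}

#' Extract bead coordinates as a matrix
#'
#' @param model a [bead_model()].
#' @return numeric n x 3 matrix (Angstrom).
#' @export
bead_coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

#' Replace bead coordinates
#'
#' @param model a [bead_model()].
#' @param xyz numeric n x 3 matrix.
#' @return the model with new coordinates.
#' @export
set_bead_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model))
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Read a C-alpha bead model from a PDB file
#'
#' Extracts one bead per residue from the CA records of a standard PDB file,
#' ordered by chain then residue number. Alternate locations are resolved to
#' the highest occupancy. If a sidecar annotation table written by
#' [write_calpha_pdb()] sits next to the file (`<path>.beads.tsv`) it is used
#' to restore subunit/domain/fixed annotations and full chain labels.
#'
#' @param path PDB file path.
#' @param chain_map optional named character vector mapping chain IDs to
#'   subunit labels; unmapped chains get subunit `"none"`. Unknown names
#'   error.
#' @param sidecar path of the annotation TSV, `NULL` to auto-detect,
#'   `FALSE` to ignore.
#' @return a [bead_model()].
#' @export
read_calpha_pdb <- function(path, chain_map = NULL, sidecar = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(atoms) == 0) stop("no ATOM records in ", path, call. = FALSE)
  rec <- tibble::tibble(
    name = trimws(substr(atoms, 13, 16)),
    altloc = substr(atoms, 17, 17),
    chain = trimws(substr(atoms, 22, 22)),
    resid = as.integer(substr(atoms, 23, 26)),
    x = as.numeric(substr(atoms, 31, 38)),
    y = as.numeric(substr(atoms, 39, 46)),
    z = as.numeric(substr(atoms, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(atoms, 55, 60)))
  )
  rec$occ[is.na(rec$occ)] <- 1
  # every residue must contribute a CA bead
  per_res <- dplyr::summarise(dplyr::group_by(rec, .data$chain, .data$resid),
                              has_ca = any(.data$name == "CA"), .groups = "drop")
  miss <- dplyr::filter(per_res, !.data$has_ca)
  if (nrow(miss) > 0)
    stop("residue(s) without CA atom: ",
         paste(sprintf("%s/%d", miss$chain, miss$resid), collapse = ", "),
         call. = FALSE)
  ca <- dplyr::filter(rec, .data$name == "CA")
  ca <- dplyr::slice_max(dplyr::group_by(ca, .data$chain, .data$resid),
                         .data$occ, n = 1, with_ties = FALSE)
  ca <- dplyr::arrange(dplyr::ungroup(ca), .data$chain, .data$resid)

  if (!is.null(chain_map)) {
    unknown <- setdiff(names(chain_map), unique(ca$chain))
    if (length(unknown) > 0)
      stop("chain_map names not present in PDB: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  subunit <- rep("none", nrow(ca))
  if (!is.null(chain_map)) {
    hit <- ca$chain %in% names(chain_map)
    subunit[hit] <- unname(chain_map[ca$chain[hit]])
  }
  model <- bead_model(cbind(ca$x, ca$y, ca$z), chain = ca$chain,
                      resid = ca$resid, subunit = subunit)

  side_path <- if (is.null(sidecar)) paste0(path, ".beads.tsv") else sidecar
  if (!isFALSE(side_path) && is.character(side_path) && file.exists(side_path)) {
    ann <- utils::read.table(side_path, header = TRUE, sep = "\t",
                             colClasses = c("integer", "character", "integer",
                                            "character", "character", "logical"))
    if (nrow(ann) == nrow(model)) {
      model$chain <- ann$chain
      model$resid <- ann$resid
      model$subunit <- ann$subunit_id
      model$domain <- ann$domain_tag
      model$fixed <- ann$fixed
      seam_attr <- readLines(side_path, n = 1)
      if (startsWith(seam_attr, "#seam")) {
        attr(model, "seam") <- strsplit(sub("^#seam\\s+", "", seam_attr), ",")[[1]]
      }
    }
  }
  model
}

#' Write a bead model to PDB plus a sidecar annotation table
#'
#' Standard PDB columns cannot carry subunit/domain tags or multi-character
#' chain labels, so annotations go to `<path>.beads.tsv` (columns
#' `bead_index`, `chain`, `resid`, `subunit_id`, `domain_tag`, `fixed`).
#' Chains are mapped to single PDB characters in order of appearance.
#'
#' @param model a [bead_model()].
#' @param path output PDB path.
#' @param sidecar write the annotation TSV (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(model, path, sidecar = TRUE) {
  chains <- unique(model$chain)
  pool <- c(LETTERS, letters, as.character(0:9))
  pdb_chain <- setNames(rep_len(pool, length(chains)), chains)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    (seq_len(nrow(model)) - 1L) %% 99999L + 1L,
    pdb_chain[model$chain],
    (model$resid - 1L) %% 9999L + 1L,
    model$x, model$y, model$z)
  writeLines(c(lines, "END"), path)
  if (sidecar) {
    sp <- paste0(path, ".beads.tsv")
    con <- file(sp, "w")
    seam <- attr(model, "seam")
    if (!is.null(seam)) writeLines(paste0("#seam ", paste(seam, collapse = ",")), con)
    utils::write.table(
      data.frame(bead_index = model$bead, chain = model$chain,
                 resid = model$resid, subunit_id = model$subunit,
                 domain_tag = model$domain, fixed = model$fixed),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' @export
print.bead_model <- function(x, ...) {
  seam <- attr(x, "seam")
  cat(sprintf("<bead_model> %d beads, %d chains, %d subunits%s\n",
              nrow(x), length(unique(x$chain)), length(unique(x$subunit)),
              if (is.null(seam)) "" else sprintf(", seam %s|%s", seam[1], seam[2])))
  NextMethod()
}
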