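#' Molecular structures as atom tables
#'
#' A structure is a tibble with one row per atom and columns `chain`, `resno`,
#' `ins`, `resid` (three-letter residue code), `elety` (atom name), `element`,
#' `x`, `y`, `z` (Angstrom), `occ` and `b`.  Optional columns `radius`
#' (van der Waals radius, Angstrom) and `charge` (elementary charges) are
#' added by [assign_biophys()] and consumed by the energy and electrostatics
#' stages.
#'
#' @param atoms A data frame with at least chain, resno, resid, elety, x, y, z.
#' @return A `mol_structure` tibble.
#' @export
new_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    abort(paste0("structure is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"element" %in% names(atoms)) atoms$element <- element_from_name(atoms$elety)
  atoms$ins[is.na(atoms$ins)] <- ""
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("structure has non-finite coordinates")
  }
  class(atoms) <- c("mol_structure", class(tibble()))
  atoms
}

#' Extract or replace the coordinate matrix of a structure
#'
#' @param x A `mol_structure`.
#' @param m An n x 3 matrix of coordinates in Angstrom.
#' @return `coords_matrix()` returns an n x 3 matrix; `set_coords()` returns
#'   the structure with replaced coordinates.
#' @export
coords_matrix <- function(x) {
  cbind(x$x, x$y, x$z)
}

#' @rdname coords_matrix
#' @export
set_coords <- function(x, m) {
  x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
  x
}

residue_keys <- function(x) {
  paste(x$chain, x$resno, x$ins, sep = "|")
}

#' Read a PDB file into an atom table
#'
#' Parsing is delegated to bio3d.  Alternate locations are resolved to the
#' highest-occupancy copy (first on ties).
#'
#' @param path Path to a PDB file.
#' @return A `mol_structure` tibble.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("no such PDB file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) abort(paste0("unreadable PDB file '", path, "': ", conditionMessage(e)))
  )
  a <- as_tibble(pdb$atom)
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  a <- a |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(desc(.data$o), .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$eleno)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) elem <- element_from_name(a$elety)
  elem[is.na(elem) | elem == ""] <- element_from_name(a$elety[is.na(elem) | elem == ""])
  new_structure(tibble(
    chain = a$chain, resno = a$resno, ins = a$insert, resid = a$resid,
    elety = a$elety, element = toupper(elem),
    x = a$x, y = a$y, z = a$z, occ = a$o, b = a$b
  ))
}

#' Write an atom table to a PDB file
#'
#' @param x A `mol_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  xyz <- as.vector(t(coords_matrix(x)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = x$resno, resid = x$resid, eleno = seq_len(nrow(x)),
    elety = x$elety, chain = ifelse(x$chain == " ", "", x$chain),
    insert = ifelse(x$ins == "", NA, x$ins),
    o = x$occ, b = x$b, elesy = x$element
  )
  invisible(path)
}

#' Attach van der Waals radii and partial charges
#'
#' Radii come from a bundled per-element table; partial charges from a compact
#' per-residue scheme in which backbone atoms sum to zero and side chains
#' carry the residue's formal charge.  Atoms with an unknown element raise an
#' error naming the atom.
#'
#' @param x A `mol_structure`.
#' @param charge_scale Multiplier applied to all charges.
#' @return `x` with `radius` and `charge` columns.
#' @export
assign_biophys <- function(x, charge_scale = 1) {
  if ("radius" %in% names(x) && !all(is.na(x$radius))) {
    x$radius[is.na(x$radius)] <- vdw_radius_of(x$element[is.na(x$radius)],
                                               x$elety[is.na(x$radius)])
  } else {
    x$radius <- vdw_radius_of(x$element, x$elety)
  }
  q <- unname(BACKBONE_CHARGES[x$elety])
  q[is.na(q)] <- 0
  for (res in names(SIDECHAIN_CHARGES)) {
    idx <- which(x$resid == res)
    if (!length(idx)) next
    sc <- SIDECHAIN_CHARGES[[res]]
    hit <- x$elety[idx] %in% names(sc)
    q[idx[hit]] <- sc[x$elety[idx[hit]]]
  }
  if ("charge" %in% names(x) && !all(is.na(x$charge))) {
    # explicit charges (e.g. toy fixtures) take precedence over the scheme
    x$charge[is.na(x$charge)] <- 0
  } else {
    x$charge <- q * charge_scale
  }
  x
}

#' Scan two chains for van der Waals clashes
#'
#' Reports inter-chain atom pairs closer than the sum of their van der Waals
#' radii minus `tolerance`.
#'
#' @param x A `mol_structure` with radii (added on the fly if absent).
#' @param chains Character vector of two chain identifiers.
#' @param tolerance Overlap tolerance in Angstrom.
#' @return Tibble with one row per clashing pair (atom indices, residues,
#'   distance and overlap).
#' @export
clash_scan <- function(x, chains, tolerance = 0.4) {
  if (!"radius" %in% names(x) || anyNA(x$radius)) x <- assign_biophys(x)
  missing <- setdiff(chains, unique(x$chain))
  if (length(missing)) abort(paste0("chain(s) not in structure: ", paste(missing, collapse = ", ")))
  a <- filter(x, .data$chain == chains[1])
  b <- filter(x, .data$chain == chains[2])
  pa <- coords_matrix(a); pb <- coords_matrix(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    d <- sqrt(colSums((t(pb) - pa[i, ])^2))
    hit <- which(d < a$radius[i] + b$radius - tolerance)
    if (length(hit)) {
      out[[length(out) + 1]] <- tibble(
        chain_i = a$chain[i], resno_i = a$resno[i], elety_i = a$elety[i],
        chain_j = b$chain[hit], resno_j = b$resno[hit], elety_j = b$elety[hit],
        distance = d[hit], overlap = a$radius[i] + b$radius[hit] - d[hit]
      )
    }
  }
  if (!length(out)) {
    return(tibble(chain_i = character(), resno_i = integer(), elety_i = character(),
                  chain_j = character(), resno_j = integer(), elety_j = character(),
                  distance = numeric(), overlap = numeric()))
  }
  bind_rows(out)
}

#' Select a biological dimer and report clashes
#'
#' Keeps only the requested chains and runs an inter-chain van der Waals clash
#' scan, emulating the choice of a clash-free dimer as the biological unit.
#'
#' @inheritParams clash_scan
#' @return List with `structure` (the selected chains) and `clashes` (tibble).
#' @export
select_biological_dimer <- function(x, chains = c("C", "D"), tolerance = 0.4) {
  missing <- setdiff(chains, unique(x$chain))
  if (length(missing)) abort(paste0("chain(s) not in structure: ", paste(missing, collapse = ", ")))
  sel <- filter(x, .data$chain %in% chains)
  class(sel) <- class(x)
  list(structure = sel, clashes = clash_scan(x, chains, tolerance))
}

#' Convert between crystal-structure and full-sequence residue numbering
#'
#' The engineered sites are conventionally quoted in crystal-structure
#' numbering; the full-length sequence numbering is offset by a constant
#' (+15 for the spermine synthase construct: S165 is S180 in the sequence).
#'
#' @param site Integer vector of residue numbers.
#' @param offset Numbering offset (sequence = structure + offset).
#' @param direction `"to_sequence"` or `"to_structure"`.
#' @return Integer vector of renumbered sites.
#' @export
renumber <- function(site, offset = 15, direction = c("to_sequence", "to_structure")) {
  direction <- match.arg(direction)
  if (direction == "to_sequence") site + offset else site - offset
}

#' Remove a residue range from every chain
#'
#' Used to drop the N-terminal dimerization domain (residues 2-109) before
#' energy calculations on the catalytic domain.
#'
#' @param x A `mol_structure`.
#' @param range Closed residue-number range to remove.
#' @return The truncated structure.
#' @export
truncate_domain <- function(x, range = c(2, 109)) {
  out <- filter(x, .data$resno < range[1] | .data$resno > range[2])
  class(out) <- class(x)
  out
}

#' Extract a three-residue segment around a site
#'
#' Returns residues `site - 1 .. site + 1` of one chain with coordinates as in
#' the parent structure (no re-fitting).  At a chain terminus the existing two
#' residues are returned and the result carries attribute `terminus = TRUE`.
#'
#' @param x A `mol_structure`.
#' @param chain Chain identifier.
#' @param site Residue number of the central residue.
#' @return A `mol_structure` of 2-3 residues.
#' @export
tripeptide_segment <- function(x, chain, site) {
  ch <- filter(x, .data$chain == !!chain)
  if (!nrow(ch)) abort(paste0("chain '", chain, "' not in structure"))
  present <- sort(unique(ch$resno))
  if (!site %in% present) abort(paste0("residue ", site, " not in chain ", chain))
  want <- intersect((site - 1):(site + 1), present)
  seg <- filter(ch, .data$resno %in% want)
  class(seg) <- class(x)
  attr(seg, "terminus") <- length(want) < 3
  seg
}
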