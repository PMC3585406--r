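#' Specification for a synthetic homolog alignment
#'
#' Describes a profile-driven alignment: a reference (acceptor) sequence over
#' a site window, per-site residue distributions for designated columns, a
#' jointly distributed (coevolving) column pair, and conserved background
#' columns.  Distributions may be given as counts or probabilities; they are
#' normalized internally.
#'
#' @param n_sequences Number of sequences to sample.
#' @param start_site Reference site number of the first column.
#' @param reference Named length-1 character vector: `c(id = sequence)`.
#' @param columns Named list: site (as character) -> named numeric vector of
#'   residue weights (`-` for gap, `X` for unspecified other residues).
#' @param coupled List with `sites` (length-2 integer) and `joint` (a named
#'   numeric matrix of weights, rows = first site's residues, columns =
#'   second site's residues).
#' @param background_conservation Probability of the reference residue in
#'   background columns; the remainder is spread over three fixed
#'   alternatives.
#' @return An `msa_spec` list.
#' @export
msa_spec <- function(n_sequences = 500, start_site = 1, reference,
                     columns = list(), coupled = NULL,
                     background_conservation = 0.97) {
  stopifnot(length(reference) == 1, !is.null(names(reference)))
  for (cw in columns) {
    if (any(cw < 0) || sum(cw) <= 0) abort("column weights must be non-negative and sum > 0")
  }
  if (!is.null(coupled)) {
    stopifnot(length(coupled$sites) == 2, is.matrix(coupled$joint))
  }
  structure(list(
    n_sequences = n_sequences, start_site = start_site,
    reference = reference, columns = columns, coupled = coupled,
    background_conservation = background_conservation
  ), class = "msa_spec")
}

sample_column <- function(n, weights) {
  p <- weights / sum(weights)
  sample(names(weights), n, replace = TRUE, prob = p)
}

#' Sample a synthetic homolog alignment
#'
#' A pure function of `(spec, seed)`: identical inputs give identical
#' alignments.  Column empirical frequencies converge to the specified
#' distributions; the coupled pair is drawn from its joint distribution, so
#' its mutual information reflects the specified coupling.  The reference
#' sequence is included as the first record.
#'
#' @param spec An [msa_spec()].
#' @param seed Integer seed.
#' @return An alignment tibble (see [new_alignment()]).
#' @export
synth_msa <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "msa_spec"))
  set.seed(seed)
  ref_id <- names(spec$reference)
  ref <- strsplit(unname(spec$reference), "")[[1]]
  n_col <- length(ref)
  n <- spec$n_sequences
  sites <- spec$start_site + seq_len(n_col) - 1L
  m <- matrix("", nrow = n, ncol = n_col)
  coupled_sites <- if (!is.null(spec$coupled)) spec$coupled$sites else integer()
  # fixed alternatives per background column, chosen deterministically
  alt_pool <- c("A", "G", "S", "T", "V", "L", "I", "N", "D", "E")
  for (j in seq_len(n_col)) {
    s <- sites[j]
    key <- as.character(s)
    if (s %in% coupled_sites) next
    if (key %in% names(spec$columns)) {
      m[, j] <- sample_column(n, spec$columns[[key]])
    } else {
      alts <- setdiff(alt_pool, ref[j])[1:3]
      p_alt <- (1 - spec$background_conservation) / 3
      m[, j] <- sample(c(ref[j], alts), n, replace = TRUE,
                       prob = c(spec$background_conservation, rep(p_alt, 3)))
    }
  }
  if (length(coupled_sites)) {
    J <- spec$coupled$joint
    p <- as.vector(J) / sum(J)
    cells <- expand.grid(a = rownames(J), b = colnames(J),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pick <- sample(nrow(cells), n, replace = TRUE, prob = p)
    m[, match(coupled_sites[1], sites)] <- cells$a[pick]
    m[, match(coupled_sites[2], sites)] <- cells$b[pick]
  }
  # reference sequence is one of the homologs
  m[1, ] <- ref
  ids <- c(ref_id, sprintf("homolog_%04d", seq_len(n - 1)))
  new_alignment(ids, apply(m, 1, paste, collapse = ""))
}

#' The bundled homolog-alignment scenario around the engineered sites
#'
#' Reproduces the study conditions of the published selection: a 500-sequence
#' alignment over sites 145-230 of the acceptor (human spermine synthase
#' numbering), with the four engineered sites following the printed homolog
#' frequency profiles (165: Asp 85.6%; 175: Glu 76.0%; 178: His 33.4%;
#' 206: Arg 77.2%), decoy candidate sites whose donor residue is in the
#' minority (160, 224), a gap-dominated column (223), a site excluded by
#' manual triage (149), and a jointly distributed 175/178 pair whose
#' marginals match the printed profiles while concentrating Glu175 with
#' His178.
#'
#' @return List with `spec` (an [msa_spec()]), `pair` (acceptor/donor
#'   alignment tibble), ids and `start_site`.
#' @export
table1_msa_spec <- function() {
  start <- 145L
  # invented acceptor window, sites 145..230 (86 residues); engineered sites
  # carry the documented wild-type residues (S165, L175, T178, C206)
  acc <- paste0(
    "GKVLNIGLGG", # 145-154
    "GALDMSLYEA", # 155-164  (site 160 = N-like decoy -> use N at 160)
    "SGAKVDLVEL", # 165-174  (site 165 = S)
    "LDSTAVGKRV", # 175-184  (site 175 = L, 178 = T)
    "GELFRDPRVN", # 185-194
    "VINGDACEVL", # 195-204
    "ECGRDLSQVD", # 205-214  (site 206 = C)
    "VIVGDSTEKM", # 215-224  (sites 223/224)
    "QELVKG"      # 225-230
  )
  chars <- strsplit(acc, "")[[1]]
  site_at <- function(s) s - start + 1L
  chars[site_at(160)] <- "N"
  chars[site_at(165)] <- "S"
  chars[site_at(175)] <- "L"
  chars[site_at(178)] <- "T"
  chars[site_at(206)] <- "C"
  chars[site_at(223)] <- "Q"
  chars[site_at(224)] <- "M"
  chars[site_at(149)] <- "N"
  acc <- paste(chars, collapse = "")
  don <- chars
  don[site_at(149)] <- "S"
  don[site_at(160)] <- "V"
  don[site_at(165)] <- "D"
  don[site_at(175)] <- "E"
  don[site_at(178)] <- "H"
  don[site_at(206)] <- "R"
  don[site_at(223)] <- "A"
  don[site_at(224)] <- "L"
  don <- paste(don, collapse = "")
  # printed homolog counts (out of 500); X = unlisted other residues
  columns <- list(
    `149` = c(N = 300, S = 150, D = 50),
    `160` = c(N = 300, V = 150, S = 50),
    `165` = c(D = 428, S = 57, N = 10, Y = 1, `-` = 4),
    `206` = c(R = 386, C = 45, Y = 38, W = 11, `-` = 1, X = 19),
    `223` = c(`-` = 400, Q = 60, A = 40),
    `224` = c(M = 275, L = 200, X = 25)
  )
  # joint counts for the coevolving 175/178 pair; row/column sums equal the
  # printed marginals (E380 L103 T4 I4 -2 X7 / Q203 H167 T114 D10 -2 X4)
  joint <- matrix(0, nrow = 6, ncol = 6,
                  dimnames = list(c("E", "L", "T", "I", "-", "X"),
                                  c("Q", "H", "T", "D", "-", "X")))
  joint["E", "Q"] <- 203; joint["E", "H"] <- 167; joint["E", "T"] <- 10
  joint["L", "T"] <- 103
  joint["T", "T"] <- 1;  joint["T", "D"] <- 3
  joint["I", "D"] <- 4
  joint["-", "D"] <- 2
  joint["X", "D"] <- 1;  joint["X", "-"] <- 2; joint["X", "X"] <- 4
  spec <- msa_spec(
    n_sequences = 500, start_site = start,
    reference = c(HsSMS = acc),
    columns = columns,
    coupled = list(sites = c(175L, 178L), joint = joint),
    background_conservation = 0.97
  )
  pair <- new_alignment(c("HsSMS", "TmSRM"), c(acc, don))
  list(spec = spec, pair = pair, acceptor_id = "HsSMS", donor_id = "TmSRM",
       start_site = start)
}

#' Toy structures for analytic tests
#'
#' Deterministic generators for desk-scale structures:
#' * `spring_chain(n, spacing)` - collinear C-alpha chain (x axis).
#' @param n Number of residues.
#' @param spacing Nearest-neighbor distance in Angstrom.
#' @param chain Chain identifier.
#' @return A `mol_structure`.
#' @export
spring_chain <- function(n = 10, spacing = 3.8, chain = "A") {
  new_structure(tibble(
    chain = chain, resno = seq_len(n), resid = "GLY", elety = "CA",
    element = "C", x = spacing * (seq_len(n) - 1), y = 0, z = 0
  ))
}

#' @rdname spring_chain
#' @param q Charge in elementary units.
#' @param a Radius in Angstrom.
#' @export
charged_sphere <- function(q = 1, a = 2) {
  s <- new_structure(tibble(
    chain = "A", resno = 1L, resid = "ION", elety = "Q", element = "C",
    x = 0, y = 0, z = 0
  ))
  s$radius <- a
  s$charge <- q
  s
}

#' @rdname spring_chain
#' @param sequence One-letter sequence for the helix (poly-Ala by default).
#' @export
toy_helix <- function(n = 8, sequence = NULL, chain = "A") {
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  build_backbone(sequence, phi = -57, psi = -47, chain = chain)
}

#' @rdname spring_chain
#' @param n_per_domain Residues per rigid body.
#' @param cleft Minimum inter-domain C-alpha distance in Angstrom.
#' @param charges Optional named numeric vector `c("C:5" = -1, ...)` placing
#'   point charges on the CB (or CA) atom of specific residues.
#' @export
two_domain_dimer <- function(n_per_domain = 8, cleft = 12, charges = NULL) {
  a <- toy_helix(n_per_domain, chain = "C")
  b <- toy_helix(n_per_domain, chain = "D")
  # translate D so the minimum CA-CA distance equals the cleft width
  ca_a <- coords_matrix(filter(a, .data$elety == "CA"))
  ca_b0 <- coords_matrix(filter(b, .data$elety == "CA"))
  shift0 <- max(ca_a[, 1]) - min(ca_b0[, 1])
  b <- set_coords(b, sweep(coords_matrix(b), 2, c(shift0, 0, 0), `+`))
  ca_b <- coords_matrix(filter(b, .data$elety == "CA"))
  dmin <- function(off) {
    bb <- sweep(ca_b, 2, c(off, 0, 0), `+`)
    min(sqrt(outer(rowSums(ca_a^2), rowSums(bb^2), `+`) - 2 * ca_a %*% t(bb)))
  }
  off <- stats::uniroot(function(o) dmin(o) - cleft, c(0, cleft + 50))$root
  b <- set_coords(b, sweep(coords_matrix(b), 2, c(off, 0, 0), `+`))
  dimer <- new_structure(bind_rows(a, b))
  dimer <- assign_biophys(dimer)
  if (!is.null(charges)) {
    for (key in names(charges)) {
      parts <- strsplit(key, ":")[[1]]
      res_idx <- which(dimer$chain == parts[1] & dimer$resno == as.integer(parts[2]))
      if (!length(res_idx)) abort(paste0("charge decoration references missing residue: ", key))
      idx <- res_idx[match(c("CB", "CA"), dimer$elety[res_idx])]
      idx <- idx[!is.na(idx)][1]
      dimer$charge[idx] <- dimer$charge[idx] + unname(charges[key])
    }
  }
  dimer
}
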