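# Hydrogen-bond geometry with on-the-fly polar hydrogen placement.

hydroxyl_antecedent <- c(OG = "CB", OG1 = "CB", OH = "CZ", SG = "CB")
hydroxyl_grandparent <- c(OG = "CA", OG1 = "CA", OH = "CE1", SG = "CA")

#' Measure hydrogen-bond geometry between a donor and an acceptor
#'
#' Places the donor's polar hydrogen by ideal geometry if it is absent
#' (bond length 0.96 A for O-H, 1.34 A for S-H, tetrahedral angle), scanning
#' the rotatable hydroxyl/thiol torsion on a 10 degree grid so the hydrogen
#' points toward the acceptor; amide/ring N-H hydrogens are placed in the
#' plane of the nitrogen's heavy neighbors.  Reports the H..acceptor
#' distance, the donor-H-acceptor angle, and a bonded classification under
#' the distance cutoff.
#'
#' @param x A `mol_structure`.
#' @param donor List `(chain, resno, atom)` naming the donor heavy atom.
#' @param acceptor List `(chain, resno, atom)` naming the acceptor atom.
#' @param cutoff H..acceptor distance (Angstrom) below which the contact is
#'   classified as hydrogen bonded.
#' @param torsion_step Grid for the hydroxyl torsion scan, degrees.
#' @return Tibble with `distance`, `angle`, `hbond` and the hydrogen position.
#' @export
hbond_geometry <- function(x, donor, acceptor, cutoff = 3.5, torsion_step = 10) {
  getp <- function(spec) {
    r <- filter(x, .data$chain == spec$chain, .data$resno == spec$resno,
                .data$elety == spec$atom)
    if (!nrow(r)) {
      abort(paste0("atom not found: ", spec$chain, ":", spec$resno, ":", spec$atom))
    }
    c(r$x[1], r$y[1], r$z[1])
  }
  D <- getp(donor)
  A <- getp(acceptor)
  res <- filter(x, .data$chain == donor$chain, .data$resno == donor$resno)
  heavy <- donor$atom
  hname <- paste0("H", sub("^[ONS]", "", heavy))
  existing <- filter(res, .data$elety %in% c(hname, paste0("H", heavy)))
  if (nrow(existing)) {
    H <- c(existing$x[1], existing$y[1], existing$z[1])
  } else if (heavy %in% names(hydroxyl_antecedent)) {
    ante <- hydroxyl_antecedent[[heavy]]
    grand <- hydroxyl_grandparent[[heavy]]
    getr <- function(nm) {
      r <- filter(res, .data$elety == nm)
      if (!nrow(r)) abort(paste0("cannot place hydrogen: missing ", nm))
      c(r$x[1], r$y[1], r$z[1])
    }
    B <- getr(ante); G <- getr(grand)
    bond <- if (startsWith(heavy, "S")) 1.34 else 0.96
    best <- NULL; bestd <- Inf
    for (tor in seq(-180 + torsion_step, 180, by = torsion_step)) {
      Htry <- place_atom(G, B, D, bond, 109.5, tor)
      d <- vnorm(Htry - A)
      if (d < bestd) { bestd <- d; best <- Htry }
    }
    H <- best
  } else if (startsWith(heavy, "N")) {
    # in-plane placement along the external bisector of the heavy neighbors
    others <- filter(res, .data$elety != heavy)
    pos <- coords_matrix(others)
    d <- sqrt(colSums((t(pos) - D)^2))
    nb <- order(d)[seq_len(min(2, nrow(others)))]
    dirs <- lapply(nb, function(i) unitv(pos[i, ] - D))
    H <- D + 1.01 * unitv(-Reduce(`+`, dirs))
  } else {
    abort(paste0("no hydrogen-placement rule for donor atom ", heavy))
  }
  dist <- vnorm(H - A)
  ang <- bond_angle(D, H, A)
  tibble(distance = dist, angle = ang, hbond = dist <= cutoff,
         hx = H[1], hy = H[2], hz = H[3])
}
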