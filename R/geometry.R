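# Internal-coordinate geometry: NeRF atom placement, torsions, and an ideal
# backbone builder used by the toy generators and the rotamer substituter.

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D given positions A, B, C, the C-D bond length, the B-C-D angle
# (degrees) and the A-B-C-D torsion (degrees); the standard NeRF construction
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(C - B, A - B)) # normal of the A-B-C plane
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  # sign convention: dihedral_angle(A, B, C, result) == torsion
  C + d2[1] * bc + d2[2] * m - d2[3] * n
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))) * 180 / pi
}

#' Build an ideal-geometry peptide backbone
#'
#' Constructs N, CA, C, O (and CB for non-glycine) atoms with standard bond
#' lengths and angles at the given backbone dihedrals.  Defaults give an
#' alpha helix.
#'
#' @param sequence One-letter amino acid sequence.
#' @param phi,psi,omega Backbone dihedrals in degrees (recycled).
#' @param chain Chain identifier.
#' @return A `mol_structure`.
#' @export
build_backbone <- function(sequence, phi = -57, psi = -47, omega = 180,
                           chain = "A") {
  aas <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aas)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  # ideal values: N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231
  rows <- list()
  # seed first residue
  Npos <- c(0, 0, 0)
  CApos <- c(1.458, 0, 0)
  Cpos <- CApos + 1.525 * c(cos(pi - 111 * pi / 180), sin(pi - 111 * pi / 180), 0)
  pos <- list(N = Npos, CA = CApos, C = Cpos)
  add <- function(resno, resid, elety, element, p) {
    rows[[length(rows) + 1]] <<- tibble(
      chain = chain, resno = resno, resid = resid, elety = elety,
      element = element, x = p[1], y = p[2], z = p[3]
    )
  }
  prev <- NULL
  for (i in seq_len(n)) {
    resid <- aa_three(aas[i])
    if (i > 1) {
      Npos <- place_atom(prev$N, prev$CA, prev$C, 1.329, 116.2, psi[i - 1])
      CApos <- place_atom(prev$CA, prev$C, Npos, 1.458, 121.7, omega[i])
      Cpos <- place_atom(prev$C, Npos, CApos, 1.525, 111.0, phi[i])
      pos <- list(N = Npos, CA = CApos, C = Cpos)
    }
    add(i, resid, "N", "N", pos$N)
    add(i, resid, "CA", "C", pos$CA)
    add(i, resid, "C", "C", pos$C)
    # carbonyl O roughly anti to the next N; use psi + 180
    Opos <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.8, psi[i] + 180)
    add(i, resid, "O", "O", Opos)
    if (resid != "GLY") {
      CBpos <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.5, 122.5)
      add(i, resid, "CB", "C", CBpos)
    }
    prev <- pos
  }
  new_structure(bind_rows(rows))
}
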