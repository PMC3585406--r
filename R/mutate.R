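# In-silico side-chain replacement: ideal-geometry rotamer substitution with
# a deterministic hard-sphere chi scan.  Backbone atoms are never moved.

# Side-chain internal-coordinate templates.  Each atom is placed by NeRF from
# three reference atoms already present in the residue.  `torsion` is either
# a number (degrees) or the string "chiK" / "chiK+OFFSET" tying the torsion
# to rotatable angle K.
sidechain_template <- function(resid) {
  t <- function(name, refs, bond, angle, torsion, element = substr(name, 1, 1)) {
    list(name = name, refs = refs, bond = bond, angle = angle,
         torsion = torsion, element = element)
  }
  base_cg <- t("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1")
  templates <- list(
    GLY = list(),
    ALA = list(),
    SER = list(t("OG", c("N", "CA", "CB"), 1.417, 110.8, "chi1", "O")),
    CYS = list(t("SG", c("N", "CA", "CB"), 1.808, 113.8, "chi1", "S")),
    THR = list(t("OG1", c("N", "CA", "CB"), 1.433, 109.6, "chi1", "O"),
               t("CG2", c("N", "CA", "CB"), 1.521, 110.5, "chi1-120")),
    VAL = list(t("CG1", c("N", "CA", "CB"), 1.527, 110.7, "chi1"),
               t("CG2", c("N", "CA", "CB"), 1.527, 110.7, "chi1+120")),
    ASP = list(base_cg,
               t("OD1", c("CA", "CB", "CG"), 1.25, 118.4, "chi2", "O"),
               t("OD2", c("CA", "CB", "CG"), 1.25, 118.4, "chi2+180", "O")),
    ASN = list(base_cg,
               t("OD1", c("CA", "CB", "CG"), 1.23, 120.8, "chi2", "O"),
               t("ND2", c("CA", "CB", "CG"), 1.33, 116.4, "chi2+180", "N")),
    GLU = list(base_cg,
               t("CD", c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
               t("OE1", c("CB", "CG", "CD"), 1.25, 118.4, "chi3", "O"),
               t("OE2", c("CB", "CG", "CD"), 1.25, 118.4, "chi3+180", "O")),
    GLN = list(base_cg,
               t("CD", c("CA", "CB", "CG"), 1.52, 112.6, "chi2"),
               t("OE1", c("CB", "CG", "CD"), 1.23, 120.8, "chi3", "O"),
               t("NE2", c("CB", "CG", "CD"), 1.33, 116.4, "chi3+180", "N")),
    LEU = list(t("CG", c("N", "CA", "CB"), 1.53, 116.3, "chi1"),
               t("CD1", c("CA", "CB", "CG"), 1.52, 110.7, "chi2"),
               t("CD2", c("CA", "CB", "CG"), 1.52, 110.7, "chi2+120")),
    ILE = list(t("CG1", c("N", "CA", "CB"), 1.53, 110.4, "chi1"),
               t("CG2", c("N", "CA", "CB"), 1.52, 110.5, "chi1-120"),
               t("CD1", c("CA", "CB", "CG1"), 1.51, 113.8, "chi2")),
    MET = list(base_cg,
               t("SD", c("CA", "CB", "CG"), 1.80, 112.7, "chi2", "S"),
               t("CE", c("CB", "CG", "SD"), 1.79, 100.9, "chi3")),
    LYS = list(base_cg,
               t("CD", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
               t("CE", c("CB", "CG", "CD"), 1.52, 111.3, "chi3"),
               t("NZ", c("CG", "CD", "CE"), 1.49, 111.9, "chi4", "N")),
    ARG = list(base_cg,
               t("CD", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
               t("NE", c("CB", "CG", "CD"), 1.46, 111.8, "chi3", "N"),
               t("CZ", c("CG", "CD", "NE"), 1.33, 124.0, "chi4"),
               t("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0, "N"),
               t("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180, "N")),
    HIS = list(t("CG", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
               t("ND1", c("CA", "CB", "CG"), 1.38, 122.7, "chi2", "N"),
               t("CD2", c("CA", "CB", "CG"), 1.36, 131.0, "chi2+180"),
               t("CE1", c("CB", "CG", "ND1"), 1.32, 109.0, 180),
               t("NE2", c("CG", "ND1", "CE1"), 1.32, 108.0, 0, "N")),
    PHE = list(t("CG", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
               t("CD1", c("CA", "CB", "CG"), 1.39, 120.7, "chi2"),
               t("CD2", c("CA", "CB", "CG"), 1.39, 120.7, "chi2+180"),
               t("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
               t("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
               t("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
    TRP = list(t("CG", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
               t("CD1", c("CA", "CB", "CG"), 1.37, 127.0, "chi2"),
               t("CD2", c("CA", "CB", "CG"), 1.43, 126.6, "chi2+180"),
               t("NE1", c("CB", "CG", "CD1"), 1.38, 110.2, 180, "N"),
               t("CE2", c("CG", "CD1", "NE1"), 1.37, 109.0, 0),
               t("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, 0),
               t("CZ2", c("CD1", "NE1", "CE2"), 1.40, 130.1, 180),
               t("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.8, 180),
               t("CH2", c("CD2", "CE3", "CZ3"), 1.37, 121.2, 0)),
    TYR = list(t("CG", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
               t("CD1", c("CA", "CB", "CG"), 1.39, 120.7, "chi2"),
               t("CD2", c("CA", "CB", "CG"), 1.39, 120.7, "chi2+180"),
               t("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
               t("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
               t("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
               t("OH", c("CD1", "CE1", "CZ"), 1.38, 119.9, 180, "O"))
  )
  if (resid == "PRO") abort("proline substitution is not supported (ring backbone)")
  tmpl <- templates[[resid]]
  if (is.null(tmpl)) abort(paste0("no side-chain template for ", resid))
  tmpl
}

n_chis <- function(resid) {
  c(GLY = 0, ALA = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, ASP = 2, ASN = 2,
    GLU = 3, GLN = 3, LEU = 2, ILE = 2, MET = 3, LYS = 4, ARG = 4, HIS = 2,
    PHE = 2, TRP = 2, TYR = 2)[[resid]]
}

resolve_torsion <- function(torsion, chis) {
  if (is.numeric(torsion)) return(torsion)
  m <- regmatches(torsion, regexec("^chi([0-9])([+-][0-9]+)?$", torsion))[[1]]
  val <- chis[as.integer(m[2])]
  if (m[3] != "") val <- val + as.numeric(m[3])
  val
}

build_sidechain_coords <- function(bb, tmpl, chis) {
  # bb: named list of backbone coordinate vectors (N, CA, CB, ...)
  pos <- bb
  placed <- list()
  for (atom in tmpl) {
    refs <- lapply(atom$refs, function(r) pos[[r]])
    if (any(vapply(refs, is.null, logical(1)))) {
      abort(paste0("missing reference atom for ", atom$name))
    }
    p <- place_atom(refs[[1]], refs[[2]], refs[[3]], atom$bond, atom$angle,
                    resolve_torsion(atom$torsion, chis))
    pos[[atom$name]] <- p
    placed[[atom$name]] <- list(p = p, element = atom$element)
  }
  placed
}

count_hard_clashes <- function(points, elements, env_coords, env_radii,
                               tolerance = 0.4) {
  if (!length(points) || !nrow(env_coords)) return(0L)
  r_new <- vdw_radius_of(elements)
  n <- 0L
  for (i in seq_along(points)) {
    d <- sqrt(colSums((t(env_coords) - points[[i]])^2))
    n <- n + sum(d < r_new[i] + env_radii - tolerance)
  }
  n
}

#' Replace a side chain in silico
#'
#' Ideal-geometry rotamer substitution: the target side chain is rebuilt from
#' bundled internal coordinates on the unchanged backbone (N, CA, C, O and a
#' re-idealized CB), and its rotatable chi angles are chosen by a
#' deterministic greedy scan (15 degree grid, ties to the smaller angle) that
#' minimizes hard-sphere clashes with all atoms outside the mutated residue.
#'
#' @param x A `mol_structure`.
#' @param chain Chain identifier.
#' @param site Residue number (structure numbering).
#' @param wt_aa Expected current residue (one-letter); mismatch is an error,
#'   guarding against numbering mistakes.
#' @param mut_aa Target residue (one-letter).
#' @param chi_step Chi-scan grid in degrees.
#' @param clash_tolerance Hard-sphere overlap tolerance in Angstrom.
#' @return The mutated structure; only atoms of the mutated residue change.
#' @export
mutate_residue <- function(x, chain, site, wt_aa, mut_aa, chi_step = 15,
                           clash_tolerance = 0.4) {
  idx <- which(x$chain == chain & x$resno == site)
  if (!length(idx)) abort(paste0("no residue ", site, " in chain ", chain))
  cur <- unique(x$resid[idx])
  if (length(cur) != 1 || aa_one(cur) != toupper(wt_aa)) {
    abort(sprintf("wild-type mismatch at %s:%d: structure has %s, expected %s",
                  chain, site, paste(cur, collapse = "/"), wt_aa))
  }
  target <- aa_three(mut_aa)
  bb_names <- c("N", "CA", "C", "O", "OXT")
  bb_idx <- idx[x$elety[idx] %in% bb_names]
  need <- c("N", "CA", "C")
  if (!all(need %in% x$elety[bb_idx])) {
    abort(paste0("backbone atoms missing at ", chain, ":", site))
  }
  res_bb <- x[bb_idx, ]
  getp <- function(name) {
    r <- res_bb[res_bb$elety == name, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  bb <- list(N = getp("N"), CA = getp("CA"), C = getp("C"))
  keep <- x[-setdiff(idx, bb_idx), ]
  # re-idealized CB for every non-glycine target
  new_atoms <- list()
  if (target != "GLY") {
    bb$CB <- place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, 122.5)
    new_atoms[["CB"]] <- list(p = bb$CB, element = "C")
  }
  tmpl <- sidechain_template(target)
  k <- n_chis(target)
  chis <- rep(180, 4)
  if (k > 0 && length(tmpl)) {
    env <- x[-idx, ]
    if (!"radius" %in% names(env)) env <- assign_biophys(env)
    env_coords <- coords_matrix(env)
    grid <- seq(-180 + chi_step, 180, by = chi_step)
    for (ci in seq_len(k)) {
      best <- c(Inf, NA)
      for (ang in grid) {
        trial <- chis; trial[ci] <- ang
        placed <- build_sidechain_coords(bb, tmpl, trial)
        score <- count_hard_clashes(lapply(placed, `[[`, "p"),
                                    vapply(placed, `[[`, "", "element"),
                                    env_coords, env$radius, clash_tolerance)
        if (score < best[1] || (score == best[1] && ang < best[2])) {
          best <- c(score, ang)
        }
      }
      chis[ci] <- best[2]
    }
  }
  placed <- c(new_atoms, build_sidechain_coords(bb, tmpl, chis))
  if (!length(placed)) placed <- NULL
  sc <- purrr::imap(placed %||% list(), function(v, nm) {
    tibble(chain = chain, resno = site, ins = res_bb$ins[1], resid = target,
           elety = nm, element = v$element,
           x = v$p[1], y = v$p[2], z = v$p[3], occ = 1, b = 0)
  }) |> list_rbind()
  res_new <- bind_rows(mutate(res_bb, resid = target), sc)
  # splice the rebuilt residue where the old one sat, leaving every other
  # atom row untouched
  first <- min(idx)
  pre <- x[seq_len(nrow(x)) < first & !seq_len(nrow(x)) %in% idx, ]
  post <- x[seq_len(nrow(x)) > first & !seq_len(nrow(x)) %in% idx, ]
  out <- bind_rows(pre, res_new, post)
  res <- new_structure(select(out, -any_of(c("radius", "charge"))))
  if ("radius" %in% names(x)) res <- assign_biophys(res)
  res
}
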