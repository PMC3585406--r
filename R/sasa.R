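# Shrake-Rupley solvent-accessible surface area.

golden_sphere <- function(n) {
  # deterministic quasi-uniform points on the unit sphere (golden spiral)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley: each atom's solvent-expanded sphere is sampled with a
#' deterministic golden-spiral point set; a point is accessible when it lies
#' outside every neighbor's expanded sphere.
#'
#' @param x A `mol_structure` (radii assigned on the fly if absent).
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-atom SASA in A^2.
#' @export
sasa_atoms <- function(x, probe = 1.4, n_points = 960) {
  if (!"radius" %in% names(x) || anyNA(x$radius)) x <- assign_biophys(x)
  pts <- golden_sphere(n_points)
  xyz <- coords_matrix(x)
  rs <- x$radius + probe
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    sp <- sweep(pts * rs[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        acc[acc] <- colSums((t(sp[acc, , drop = FALSE]) - xyz[j, ])^2) >= rs[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * rs[i]^2
  }
  out
}

#' Residue solvent exposure
#'
#' Sums atomic SASA per residue, divides by a bundled per-residue maximum
#' (Gly-X-Gly reference, see [max_sasa_table()]), and classifies residues
#' with relative SASA at or above `rsasa_threshold` as surface.
#'
#' @inheritParams sasa_atoms
#' @param rsasa_threshold Relative-SASA cutoff for the surface flag.
#' @return Tibble with `chain`, `site`, `resid`, `sasa`, `rsasa`, `surface`.
#' @export
residue_exposure <- function(x, probe = 1.4, n_points = 960,
                             rsasa_threshold = 0.25) {
  x$sasa_atom <- sasa_atoms(x, probe, n_points)
  maxima <- max_sasa_table()
  x |>
    group_by(chain = .data$chain, site = .data$resno, resid = .data$resid) |>
    summarise(sasa = sum(.data$sasa_atom), .groups = "drop") |>
    mutate(
      rsasa = .data$sasa / unname(maxima[.data$resid]),
      surface = !is.na(.data$rsasa) & .data$rsasa >= rsasa_threshold
    )
}
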