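# C-alpha anisotropic network model: Hessian, modes, GHz frequencies.

#' Anisotropic network model normal modes
#'
#' Builds the 3N x 3N ANM Hessian over C-alpha nodes (unit spring constant;
#' pairs within the cutoff interact, distance-weight exponent 0 meaning
#' uniform springs), diagonalizes it, and returns the smallest `n_modes`
#' eigenpairs.  Modes with eigenvalue below `1e-8 * max(eigenvalue)` are
#' flagged rigid-body; any valid 3-D structure has exactly six.
#'
#' @param x A `mol_structure` (C-alpha atoms are extracted, one per residue)
#'   or an N x 3 coordinate matrix.
#' @param cutoff Interaction cutoff, Angstrom.
#' @param gamma Spring force constant, kcal/(mol A^2).
#' @param n_modes Number of lowest modes to return (`NULL` = all).
#' @param mass Node mass in Da for the frequency conversion.
#' @return A `mode_set`: eigenvalues (ascending), eigenvectors, rigid-body
#'   flags, and non-zero-mode frequencies in GHz.
#' @export
enm_modes <- function(x, cutoff = 15, gamma = 1.0, n_modes = 36, mass = 110) {
  if (cutoff <= 0 || gamma <= 0) abort("cutoff and gamma must be positive")
  coords <- if (is.matrix(x)) x else {
    ca <- filter(x, .data$elety == "CA") |>
      distinct(.data$chain, .data$resno, .keep_all = TRUE)
    if (!nrow(ca)) abort("no C-alpha atoms in structure")
    coords_matrix(ca)
  }
  n <- nrow(coords)
  if (n < 2) abort("need at least 2 nodes")
  centered <- sweep(coords, 2, colMeans(coords))
  if (n >= 3 && qr(centered)$rank < 2) {
    # a perfectly collinear network has no transverse stiffness: the
    # rotation about the chain axis and all transverse motions are
    # zero modes, so the usual six-zero-mode bookkeeping does not apply
    warn("all nodes are collinear: rotational modes are degenerate and extra zero modes appear")
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- coords[j, ] - coords[i, ]
      d2 <- sum(dv^2)
      if (d2 > cutoff^2 || d2 == 0) next
      blk <- -outer(dv, dv) / d2 # unit-gamma super-element
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  if (is.null(n_modes)) n_modes <- 3 * n
  n_modes <- min(n_modes, 3 * n)
  values <- values[seq_len(n_modes)]
  vectors <- vectors[, seq_len(n_modes), drop = FALSE]
  lam_max <- max(eig$values)
  rigid <- values < 1e-8 * lam_max
  values[rigid & abs(values) < 1e-8 * lam_max] <- pmax(values[rigid], 0)
  freqs <- rep(NA_real_, n_modes)
  freqs[!rigid] <- mode_frequencies(values[!rigid], gamma = gamma, mass = mass)
  structure(list(values = values, vectors = vectors, rigid = rigid,
                 n_zero = sum(rigid), freq_ghz = freqs,
                 gamma = gamma, mass = mass, cutoff = cutoff, n_nodes = n),
            class = "mode_set")
}

#' Convert ANM eigenvalues to frequencies in GHz
#'
#' nu_i = (1 / 2 pi) sqrt(gamma lambda_i / m), with gamma lambda in
#' kcal/(mol A^2) converted via 1 kcal/(mol A^2) = 0.6947695 N/m and the node
#' mass via 1 Da = 1.66053907e-27 kg.
#'
#' @param lambda Non-negative eigenvalues of the unit-gamma Hessian.
#' @param gamma Spring constant, kcal/(mol A^2).
#' @param mass Node mass, Da.
#' @return Frequencies in GHz.
#' @export
mode_frequencies <- function(lambda, gamma = 1.0, mass = 110) {
  if (any(lambda < 0)) abort("negative eigenvalue passed to mode_frequencies")
  k_si <- gamma * lambda * KCALMOLA2_TO_NM
  m_si <- mass * DALTON_TO_KG
  sqrt(k_si / m_si) / (2 * pi) / 1e9
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("ANM mode set: %d nodes, %d modes (%d rigid-body), cutoff %.1f A\n",
              x$n_nodes, length(x$values), x$n_zero, x$cutoff))
  nz <- which(!x$rigid)[seq_len(min(3, sum(!x$rigid)))]
  cat("  first non-zero modes (GHz):",
      paste(sprintf("%.2f", x$freq_ghz[nz]), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mode_set <- function(x, ...) {
  tibble(mode = seq_along(x$values), eigenvalue = x$values,
         rigid_body = x$rigid, frequency_ghz = x$freq_ghz)
}

#' @exportS3Method generics::glance
glance.mode_set <- function(x, ...) {
  tibble(n_nodes = x$n_nodes, n_modes = length(x$values), n_zero = x$n_zero,
         cutoff = x$cutoff, gamma = x$gamma, mass = x$mass)
}

#' Wild-type versus mutant mode-frequency table
#'
#' Mirrors the published normal-mode bookkeeping: per-parameterization
#' frequencies for the selected modes, arithmetic means across
#' parameterizations, and mutant-minus-wild-type differences in MHz.
#'
#' @param freqs Tibble with columns `structure` (e.g. "WT"/"Fmut"), `label`
#'   (parameterization), `mode` (integer) and `ghz`.
#' @param modes Modes to tabulate.
#' @return Tibble with one row per mode: per-label columns, the mean, and
#'   the mutant - WT difference in MHz (when exactly two structures given).
#' @export
mode_table <- function(freqs, modes = 1:3) {
  freqs <- as_tibble(freqs) |> filter(.data$mode %in% modes)
  wide <- freqs |>
    tidyr::pivot_wider(names_from = "label", values_from = "ghz")
  labels <- setdiff(names(wide), c("structure", "mode"))
  wide$mean_ghz <- rowMeans(wide[labels])
  structures <- unique(wide$structure)
  out <- arrange(wide, .data$mode, .data$structure)
  if (length(structures) == 2) {
    diffs <- out |>
      select("structure", "mode", "mean_ghz") |>
      tidyr::pivot_wider(names_from = "structure", values_from = "mean_ghz")
    diffs$diff_mhz <- (diffs[[structures[2]]] - diffs[[structures[1]]]) * 1000
    out <- left_join(out, select(diffs, "mode", "diff_mhz"), by = "mode")
  }
  out
}

#' Export mode vectors in NMD format
#'
#' Minimal NMD (normal-mode data) writer for viewers: names, coordinates and
#' the requested mode vectors scaled by inverse square-root eigenvalue.
#'
#' @param modes A `mode_set`.
#' @param coords N x 3 coordinate matrix of the nodes.
#' @param path Output path.
#' @param which Mode indices to export (defaults to first three non-rigid).
#' @return `path`, invisibly.
#' @export
write_nmd <- function(modes, coords, path, which = NULL) {
  if (is.null(which)) which <- head(which(!modes$rigid), 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("title mutsmith ANM modes", con)
  writeLines(paste("coordinates", paste(sprintf("%.3f", t(coords)), collapse = " ")), con)
  for (m in which) {
    scale <- if (modes$values[m] > 0) 1 / sqrt(modes$values[m]) else 1
    writeLines(paste("mode", m, sprintf("%.4f", scale),
                     paste(sprintf("%.4f", modes$vectors[, m]), collapse = " ")), con)
  }
  invisible(path)
}
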