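# Simplified molecular-mechanics + generalized-Born energy function.
#
# Components (kcal/mol):
#   bonded   - harmonic bonds over detected covalent connectivity
#   vdw      - Lennard-Jones 12-6 with per-element parameters
#   coulomb  - pairwise Coulomb at internal dielectric (default 1.0)
#   gb       - Still-style generalized Born polar solvation with
#              Hawkins-Cramer-Truhlar pairwise descreening Born radii
#   nonpolar - surface-area-proportional term (gamma * SASA)
#
# Multiple bundled parameterizations play the role of independent force
# fields; predictions are averaged across them.

#' Bundled energy parameterizations
#'
#' Three parameterizations of the simplified energy function (differing in
#' Lennard-Jones radii/depths and the nonpolar surface coefficient) stand in
#' for independent force fields; downstream predictions are averaged across
#' the parameterizations used.
#'
#' @param id One of `"setA"`, `"setB"`, `"setC"`.
#' @return An `energy_params` list.
#' @export
energy_params <- function(id = c("setA", "setB", "setC")) {
  id <- match.arg(id)
  base_rmin <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  base_eps <- c(H = 0.02, C = 0.10, N = 0.16, O = 0.20, S = 0.25, P = 0.20)
  tweak <- switch(id,
    setA = list(r = 1.00, e = 1.0, gamma = 0.0050),
    setB = list(r = 1.03, e = 0.9, gamma = 0.0072),
    setC = list(r = 0.97, e = 1.1, gamma = 0.0060)
  )
  structure(list(
    id = id,
    lj_rmin = base_rmin * tweak$r,
    lj_eps = base_eps * tweak$e,
    dielectric = 1.0,
    gb = list(eps_solvent = 80, offset = 0, scale = 0.8),
    gamma_np = tweak$gamma,
    bond_k = 300,
    sasa_points = 240
  ), class = "energy_params")
}

#' @rdname energy_params
#' @param ids Parameterization ids to include.
#' @export
default_params_list <- function(ids = c("setA", "setB", "setC")) {
  lapply(ids, energy_params)
}

detect_bonds <- function(x) {
  # covalent bonds by distance: d < 1.25 * (sum of covalent radii)
  xyz <- coords_matrix(x)
  rc <- COV_RADII[x$element]
  rc[is.na(rc)] <- 0.77
  n <- nrow(x)
  pairs <- list()
  for (i in seq_len(max(n - 1, 0))) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    j <- which(d < 1.25 * (rc[i] + rc[(i + 1):n])) + i
    if (length(j)) pairs[[length(pairs) + 1]] <- cbind(i, j, d[j - i])
  }
  if (!length(pairs)) return(matrix(numeric(), ncol = 3))
  do.call(rbind, pairs)
}

exclusion_sets <- function(bonds, n) {
  # 1-2 and 1-3 pairs excluded from nonbonded terms
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  excl <- new.env()
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) mark(bonds[k, 1], bonds[k, 2])
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      if (length(nb) > 1) {
        cmb <- utils::combn(nb, 2)
        for (c2 in seq_len(ncol(cmb))) mark(cmb[1, c2], cmb[2, c2])
      }
    }
  }
  excl
}

is_excluded <- function(excl, i, j) {
  exists(paste(min(i, j), max(i, j)), envir = excl, inherits = FALSE)
}

build_topology <- function(x) {
  bonds <- detect_bonds(x)
  n <- nrow(x)
  excl <- exclusion_sets(bonds, n)
  # bonded equilibrium lengths from covalent radii
  rc <- COV_RADII[x$element]
  rc[is.na(rc)] <- 0.77
  b0 <- if (nrow(bonds)) rc[bonds[, 1]] + rc[bonds[, 2]] else numeric()
  list(bonds = bonds, b0 = b0, excl = excl)
}

born_radii <- function(xyz, radius, gb) {
  # Hawkins-Cramer-Truhlar pairwise descreening
  rho <- pmax(radius - gb$offset, 0.5)
  n <- nrow(xyz)
  inv_alpha <- 1 / rho
  if (n > 1) {
    s <- gb$scale
    for (i in seq_len(n)) {
      r <- sqrt(colSums((t(xyz[-i, , drop = FALSE]) - xyz[i, ])^2))
      sr <- s * rho[-i]
      L <- pmax(abs(r - sr), rho[i])
      U <- r + sr
      ok <- rho[i] < U
      term <- 0.5 * (1 / L - 1 / U +
                       0.25 * (1 / U^2 - 1 / L^2) * (r - sr^2 / r) +
                       0.5 * log(L / U) / r)
      inv_alpha[i] <- inv_alpha[i] - sum(term[ok])
    }
  }
  1 / pmax(inv_alpha, 1e-6)
}

gb_polar_energy <- function(xyz, charge, radius, gb, dielectric = 1) {
  if (all(charge == 0)) return(0)
  alpha <- born_radii(xyz, radius, gb)
  n <- nrow(xyz)
  pref <- -0.5 * COULOMB_KCAL * (1 / dielectric - 1 / gb$eps_solvent)
  e <- sum(pref * charge^2 / alpha) # self terms
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      r2 <- colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2)
      aa <- alpha[i] * alpha[j]
      f <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
      e <- e + sum(2 * pref * charge[i] * charge[j] / f)
    }
  }
  e
}

pairwise_nonbonded <- function(xyz, x, params, topo, what = c("vdw", "coulomb"),
                               soft_floor = NULL) {
  n <- nrow(xyz)
  e_vdw <- 0; e_coul <- 0
  if (n < 2) return(c(vdw = 0, coulomb = 0))
  rmin_i <- params$lj_rmin[x$element]
  eps_i <- params$lj_eps[x$element]
  rmin_i[is.na(rmin_i)] <- 1.7; eps_i[is.na(eps_i)] <- 0.1
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    keep <- !vapply(j, function(jj) is_excluded(topo$excl, i, jj), logical(1))
    j <- j[keep]
    if (!length(j)) next
    r <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    if ("vdw" %in% what) {
      rm <- (rmin_i[i] + rmin_i[j]) # rmin distance (sum of rmin/2 pairs)
      ep <- sqrt(eps_i[i] * eps_i[j])
      reff <- if (is.null(soft_floor)) r else pmax(r, soft_floor * rm)
      sr6 <- (rm / reff)^6
      e_vdw <- e_vdw + sum(ep * (sr6^2 - 2 * sr6))
    }
    if ("coulomb" %in% what) {
      e_coul <- e_coul + sum(COULOMB_KCAL * x$charge[i] * x$charge[j] /
                               (params$dielectric * r))
    }
  }
  c(vdw = e_vdw, coulomb = e_coul)
}

#' Total energy of a structure under one parameterization
#'
#' @param x A `mol_structure`; radii/charges assigned on the fly if absent.
#' @param params An [energy_params()] object.
#' @param terms Components to evaluate; others are reported as zero.
#' @param topo Optional precomputed topology (internal use).
#' @return An `energy_breakdown`: tibble with one row per component plus the
#'   total, and attribute `total`.
#' @export
total_energy <- function(x, params = energy_params("setA"),
                         terms = c("bonded", "vdw", "coulomb", "gb", "nonpolar"),
                         topo = NULL) {
  comps <- c(bonded = 0, vdw = 0, coulomb = 0, gb = 0, nonpolar = 0)
  if (nrow(x)) {
    x <- assign_biophys(x)
    xyz <- coords_matrix(x)
    if (is.null(topo)) topo <- build_topology(x)
    if ("bonded" %in% terms && nrow(topo$bonds)) {
      d <- sqrt(rowSums((xyz[topo$bonds[, 1], , drop = FALSE] -
                           xyz[topo$bonds[, 2], , drop = FALSE])^2))
      comps["bonded"] <- sum(params$bond_k * (d - topo$b0)^2)
    }
    nb <- pairwise_nonbonded(xyz, x, params, topo,
                             what = intersect(terms, c("vdw", "coulomb")))
    comps["vdw"] <- nb["vdw"]; comps["coulomb"] <- nb["coulomb"]
    if ("gb" %in% terms) {
      comps["gb"] <- gb_polar_energy(xyz, x$charge, x$radius, params$gb,
                                     params$dielectric)
    }
    if ("nonpolar" %in% terms) {
      comps["nonpolar"] <- params$gamma_np * sum(sasa_atoms(x, n_points = params$sasa_points))
    }
  }
  out <- tibble(component = c(names(comps), "total"),
                energy = c(unname(comps), sum(comps)))
  class(out) <- c("energy_breakdown", class(out))
  attr(out, "total") <- sum(comps)
  out
}

#' @exportS3Method generics::tidy
tidy.energy_breakdown <- function(x, ...) as_tibble(unclass(x))

#' Total of an energy breakdown
#'
#' @param x An `energy_breakdown` from [total_energy()].
#' @return The total energy in kcal/mol.
#' @export
energy_total <- function(x) attr(x, "total")

# analytic gradient of the differentiable terms (bonded, vdw, coulomb,
# harmonic positional restraints)
mm_energy_gradient <- function(coords, x, params, topo, terms, restraints,
                               soft_floor = NULL) {
  n <- nrow(x)
  xyz <- matrix(coords, ncol = 3, byrow = FALSE)
  e <- 0
  g <- matrix(0, n, 3)
  if ("bonded" %in% terms && nrow(topo$bonds)) {
    i <- topo$bonds[, 1]; j <- topo$bonds[, 2]
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    e <- e + sum(params$bond_k * (d - topo$b0)^2)
    f <- 2 * params$bond_k * (d - topo$b0) / d
    gi <- dv * f
    for (k in seq_along(i)) {
      g[i[k], ] <- g[i[k], ] + gi[k, ]
      g[j[k], ] <- g[j[k], ] - gi[k, ]
    }
  }
  rmin_i <- params$lj_rmin[x$element]; eps_i <- params$lj_eps[x$element]
  rmin_i[is.na(rmin_i)] <- 1.7; eps_i[is.na(eps_i)] <- 0.1
  do_vdw <- "vdw" %in% terms; do_coul <- "coulomb" %in% terms
  if ((do_vdw || do_coul) && n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      keep <- !vapply(j, function(jj) is_excluded(topo$excl, i, jj), logical(1))
      j <- j[keep]
      if (!length(j)) next
      dv <- sweep(xyz[j, , drop = FALSE], 2, xyz[i, ], `-`) # j - i
      r <- sqrt(rowSums(dv^2))
      if (do_vdw) {
        rm <- rmin_i[i] + rmin_i[j]
        ep <- sqrt(eps_i[i] * eps_i[j])
        if (is.null(soft_floor)) {
          reff <- r
          floored <- rep(FALSE, length(r))
        } else {
          reff <- pmax(r, soft_floor * rm)
          floored <- r < soft_floor * rm
        }
        sr6 <- (rm / reff)^6
        e <- e + sum(ep * (sr6^2 - 2 * sr6))
        dE_dr <- -12 * ep * (sr6^2 - sr6) / reff
        if (!is.null(soft_floor)) dE_dr[floored] <- 0
        gj <- dv * (dE_dr / r)
        g[i, ] <- g[i, ] - colSums(gj)
        g[j, ] <- g[j, ] + gj
      }
      if (do_coul) {
        qq <- COULOMB_KCAL * x$charge[i] * x$charge[j] / params$dielectric
        e <- e + sum(qq / r)
        dE_dr <- -qq / r^2
        gj <- dv * (dE_dr / r)
        g[i, ] <- g[i, ] - colSums(gj)
        g[j, ] <- g[j, ] + gj
      }
    }
  }
  if (!is.null(restraints)) {
    dv <- xyz - restraints$ref
    e <- e + sum(restraints$k * rowSums(dv^2))
    g <- g + 2 * restraints$k * dv
  }
  list(energy = e, gradient = as.vector(g))
}

#' Energy-minimize a structure
#'
#' Limited-memory BFGS minimization of the differentiable molecular-mechanics
#' terms (bonds, Lennard-Jones, Coulomb, optional harmonic restraints) with
#' analytic gradients.  Severe steric clashes are relaxed first with a
#' soft-core van der Waals floor before the full potential is applied.
#' Convergence is reached when the RMS per-atom gradient falls at or below
#' `rms_tol` (kcal/mol/A).
#'
#' @param x A `mol_structure`.
#' @param params An [energy_params()] object.
#' @param terms MM terms to include in the objective.
#' @param rms_tol RMS gradient convergence criterion, kcal/mol/A.
#' @param max_iter Iteration cap.
#' @param soft_steps Iterations of the initial soft-core phase.
#' @param restraints Optional list `(k, ref)`: harmonic restraints of force
#'   constant `k` (kcal/mol/A^2) to reference coordinates `ref` (n x 3).
#' @return List with `structure`, `energy`, `rms_gradient`, `iterations`,
#'   `converged`; class `minimization`.
#' @export
minimize <- function(x, params = energy_params("setA"),
                     terms = c("bonded", "vdw", "coulomb"),
                     rms_tol = 0.01, max_iter = 5000, soft_steps = 50,
                     restraints = NULL) {
  x <- assign_biophys(x)
  topo <- build_topology(x)
  n <- nrow(x)
  p0 <- as.vector(coords_matrix(x))
  obj <- function(soft_floor) {
    list(
      fn = function(p) mm_energy_gradient(p, x, params, topo, terms,
                                          restraints, soft_floor)$energy,
      gr = function(p) mm_energy_gradient(p, x, params, topo, terms,
                                          restraints, soft_floor)$gradient
    )
  }
  iters <- 0L
  # soft-core phase only if the start is clashed
  start_grad <- mm_energy_gradient(p0, x, params, topo, terms, restraints)$gradient
  if (soft_steps > 0 && sqrt(mean(start_grad^2) * 3) > 1e3) {
    o <- obj(0.8)
    fit <- optim(p0, o$fn, o$gr, method = "L-BFGS-B",
                 control = list(maxit = soft_steps))
    p0 <- fit$par
    iters <- iters + fit$counts[1]
  }
  o <- obj(NULL)
  fit <- optim(p0, o$fn, o$gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 10))
  iters <- iters + fit$counts[1]
  res <- mm_energy_gradient(fit$par, x, params, topo, terms, restraints)
  rms <- sqrt(mean(matrix(res$gradient, ncol = 3)^2) * 3)
  # polish until the gradient criterion is met or the cap is reached
  tries <- 0
  while (rms > rms_tol && iters < max_iter && tries < 5) {
    fit <- optim(fit$par, o$fn, o$gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter - iters, factr = 1))
    iters <- iters + fit$counts[1]
    res <- mm_energy_gradient(fit$par, x, params, topo, terms, restraints)
    rms <- sqrt(mean(matrix(res$gradient, ncol = 3)^2) * 3)
    tries <- tries + 1
  }
  out <- set_coords(x, matrix(fit$par, ncol = 3))
  structure(list(structure = out, energy = res$energy, rms_gradient = rms,
                 iterations = unname(iters), converged = rms <= rms_tol),
            class = "minimization")
}

#' @export
print.minimization <- function(x, ...) {
  cat(sprintf("minimization: E = %.4f kcal/mol, RMS grad = %.4g, %d iterations, %s\n",
              x$energy, x$rms_gradient, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
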