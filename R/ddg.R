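# Folding and binding free-energy changes, multi-parameterization averaging,
# the two-parameter affine calibration, additivity and effect classification,
# and pKa-shift bookkeeping.
#
# Sign conventions follow the published protocol: positive folding ddG means
# the mutant monomer is more stable than the wild type; positive binding
# dddG means the mutation increases dimer affinity.

eval_state_energy <- function(x, params, terms, do_minimize, max_iter) {
  if (do_minimize) {
    x <- minimize(x, params, terms = intersect(terms, c("bonded", "vdw", "coulomb")),
                  max_iter = max_iter)$structure
  }
  energy_total(total_energy(x, params, terms = terms))
}

#' Mutation-induced folding free-energy change
#'
#' For each parameterization and each monomer chain the folded-state energy
#' is compared against an unfolded-state proxy: the sum of energies of
#' three-residue segments centered on every mutated site (the
#' sequence-independent remainder of the unfolded state cancels between WT
#' and mutant and is never evaluated).  Positive values mean the mutant
#' monomer is more stable.
#'
#' @param wt,mut Wild-type and mutant structures (same chains).
#' @param sites Tibble with columns `chain` and `site` listing mutated sites.
#' @param params_list List of [energy_params()] parameterizations.
#' @param monomers Chains treated as independent monomers.
#' @param terms Energy components used.
#' @param minimize Minimize folded structures and segments before evaluation.
#' @param max_iter Minimizer iteration cap per state.
#' @return A `folding_ddg` tibble: one row per (parameterization, monomer)
#'   with column `ddg`.
#' @export
folding_ddg <- function(wt, mut, sites, params_list = default_params_list(),
                        monomers = intersect(unique(wt$chain), c("C", "D")),
                        terms = c("bonded", "vdw", "coulomb", "gb", "nonpolar"),
                        minimize = FALSE, max_iter = 200) {
  if (!nrow(sites)) abort("no mutated sites supplied")
  if (!length(monomers)) monomers <- unique(wt$chain)
  rows <- list()
  for (params in params_list) {
    for (mono in monomers) {
      wt_m <- filter(wt, .data$chain == mono); class(wt_m) <- class(wt)
      mut_m <- filter(mut, .data$chain == mono); class(mut_m) <- class(mut)
      site_list <- sites$site[sites$chain == mono]
      if (!length(site_list)) site_list <- sites$site
      g_fold_wt <- eval_state_energy(wt_m, params, terms, minimize, max_iter)
      g_fold_mut <- eval_state_energy(mut_m, params, terms, minimize, max_iter)
      g3_wt <- sum(vapply(site_list, function(s) {
        eval_state_energy(tripeptide_segment(wt_m, mono, s), params, terms,
                          minimize, max_iter)
      }, numeric(1)))
      g3_mut <- sum(vapply(site_list, function(s) {
        eval_state_energy(tripeptide_segment(mut_m, mono, s), params, terms,
                          minimize, max_iter)
      }, numeric(1)))
      dg_wt <- g_fold_wt - g3_wt
      dg_mut <- g_fold_mut - g3_mut
      rows[[length(rows) + 1]] <- tibble(
        param = params$id, monomer = mono, ddg = dg_wt - dg_mut
      )
    }
  }
  out <- list_rbind(rows)
  class(out) <- c("folding_ddg", class(out))
  out
}

#' Mutation-induced binding free-energy change
#'
#' Binding energy is the dimer energy minus the energies of the two
#' independently evaluated monomers; the reported value is the change in
#' binding energy caused by the mutation, positive when the mutant binds
#' tighter.
#'
#' @param wt_dimer,mut_dimer Dimer structures.
#' @param chains The two monomer chains.
#' @param params_list List of parameterizations.
#' @param split `"rigid"` evaluates monomers at their in-dimer geometry;
#'   `"minimize"` re-minimizes each monomer after extraction.
#' @inheritParams folding_ddg
#' @return A `binding_ddg` tibble with per-parameterization `wt_binding`,
#'   `mut_binding` and `ddd` columns.
#' @export
binding_ddg <- function(wt_dimer, mut_dimer, chains = c("C", "D"),
                        params_list = default_params_list(),
                        split = c("rigid", "minimize"),
                        terms = c("bonded", "vdw", "coulomb", "gb", "nonpolar"),
                        max_iter = 200) {
  split <- match.arg(split)
  do_min <- split == "minimize"
  binding_of <- function(dimer, params) {
    g_dimer <- eval_state_energy(dimer, params, terms, do_min, max_iter)
    g_mono <- vapply(chains, function(ch) {
      m <- filter(dimer, .data$chain == ch); class(m) <- class(dimer)
      if (!nrow(m)) abort(paste0("chain '", ch, "' not in structure"))
      eval_state_energy(m, params, terms, do_min, max_iter)
    }, numeric(1))
    g_dimer - sum(g_mono)
  }
  rows <- lapply(params_list, function(params) {
    wt_b <- binding_of(wt_dimer, params)
    mut_b <- binding_of(mut_dimer, params)
    tibble(param = params$id, wt_binding = wt_b, mut_binding = mut_b,
           ddd = wt_b - mut_b)
  })
  out <- list_rbind(rows)
  class(out) <- c("binding_ddg", class(out))
  out
}

#' Average energy records across parameterizations and monomers
#'
#' Reproduces the published bookkeeping: the arithmetic mean across
#' parameterizations per monomer, then the mean across monomers.
#'
#' @param records Tibble with columns `param`, a value column, and optionally
#'   `monomer`.
#' @param value Name of the value column.
#' @return List with `per_monomer` (mean over parameterizations for each
#'   monomer) and `overall` (mean over monomers, or over parameterizations
#'   when no monomer column is present).
#' @export
aggregate_ddg <- function(records, value = "ddg") {
  v <- rlang::sym(value)
  if ("monomer" %in% names(records)) {
    per <- records |>
      group_by(.data$monomer) |>
      summarise(mean_value = mean(!!v), .groups = "drop")
    list(per_monomer = per, overall = mean(per$mean_value))
  } else {
    list(per_monomer = NULL, overall = mean(records[[value]]))
  }
}

#' Fit the two-parameter calibration
#'
#' The raw energy-function predictions are calibrated against experimental
#' reference values with an affine (two-parameter) least-squares fit.
#'
#' @param pairs Tibble with columns `raw` and `adjusted`.
#' @return An `adjustment_model` wrapping the linear fit.
#' @export
fit_adjustment <- function(pairs) {
  pairs <- distinct(as_tibble(pairs))
  if (nrow(pairs) < 2) abort("need at least 2 distinct (raw, adjusted) pairs")
  fit <- lm(adjusted ~ raw, data = pairs)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "adjustment_model")
}

#' @rdname fit_adjustment
#' @param model An `adjustment_model`.
#' @param raw Numeric vector of raw predictions.
#' @export
apply_adjustment <- function(model, raw) {
  model$intercept + model$slope * raw
}

#' @exportS3Method generics::tidy
tidy.adjustment_model <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.adjustment_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         nobs = length(x$fit$residuals))
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("affine calibration: adjusted = %.5f * raw %+.5f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Check additivity of single-mutant effects
#'
#' @param single_ddgs Numeric vector of single-mutant (or mutant-group)
#'   energy changes.
#' @param combined_ddg Energy change of the combined mutant.
#' @param tolerance Relative deviation below which the effects count as
#'   additive.
#' @return One-row tibble with sum, combined value, deviations and verdict.
#' @export
additivity_check <- function(single_ddgs, combined_ddg, tolerance = 0.05) {
  s <- sum(single_ddgs)
  abs_dev <- abs(combined_ddg - s)
  rel_dev <- if (combined_ddg != 0) abs_dev / abs(combined_ddg) else ifelse(abs_dev == 0, 0, Inf)
  tibble(sum = s, combined = combined_ddg, abs_dev = abs_dev,
         rel_dev = rel_dev, additive = rel_dev <= tolerance)
}

#' Classify a binding energy change
#'
#' Changes smaller in magnitude than the neutral band are considered to have
#' no effect on dimer affinity.
#'
#' @param ddd Numeric vector of binding energy changes (kcal/mol, positive =
#'   tighter mutant dimer).
#' @param neutral_band Half-width of the no-effect band, kcal/mol.
#' @return Character vector: `"increase"`, `"decrease"`, or `"no-effect"`.
#' @export
classify_binding_effect <- function(ddd, neutral_band = 2.0) {
  ifelse(abs(ddd) < neutral_band, "no-effect",
         ifelse(ddd > 0, "increase", "decrease"))
}

#' Per-residue pKa shifts between two titration tables
#'
#' @param wt,mut Tibbles with columns `residue` and `pka`.
#' @return Tibble with `residue`, `pka_wt`, `pka_mut`, `delta_pka`, `status`;
#'   residues missing from either table are reported as absent, not zero.
#' @export
pka_shift_table <- function(wt, mut) {
  full_join(rename(as_tibble(wt), pka_wt = "pka"),
            rename(as_tibble(mut), pka_mut = "pka"),
            by = "residue") |>
    mutate(
      delta_pka = .data$pka_mut - .data$pka_wt,
      status = case_when(
        is.na(.data$pka_wt) & is.na(.data$pka_mut) ~ "absent_both",
        is.na(.data$pka_wt) ~ "absent_wt",
        is.na(.data$pka_mut) ~ "absent_mut",
        TRUE ~ "ok"
      )
    )
}
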