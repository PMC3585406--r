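#' Flag conservation context of candidate sites
#'
#' A site is `non_conserved` when its modal residue frequency (gap counted as
#' a category) is below `conservation_threshold`; it is `near_conserved` when
#' any other site within `window` positions is conserved.  Conserved
#' candidates are dropped; `near_conserved` is a ranking flag, not a filter.
#'
#' @param candidates Tibble from [pairwise_candidates()].
#' @param profiles Tibble from [column_profiles()] covering the candidate
#'   sites and their neighborhoods.
#' @param conservation_threshold Modal frequency at and above which a column
#'   counts as conserved.
#' @param window Neighborhood half-width in sites.
#' @param drop_conserved Drop candidates that are not `non_conserved`.
#' @return Candidates with `modal_freq`, `non_conserved`, `near_conserved`.
#' @export
conservation_context <- function(candidates, profiles,
                                 conservation_threshold = 0.95, window = 2,
                                 drop_conserved = TRUE) {
  if (window < 1) abort("window must be >= 1")
  modal <- profiles |>
    group_by(.data$site) |>
    summarise(modal_freq = max(.data$freq), .groups = "drop")
  missing <- setdiff(candidates$site, modal$site)
  if (length(missing)) {
    abort(paste0("profiles do not cover candidate site(s): ", paste(missing, collapse = ", ")))
  }
  conserved_sites <- modal$site[modal$modal_freq >= conservation_threshold]
  out <- candidates |>
    left_join(modal, by = "site") |>
    mutate(
      non_conserved = .data$modal_freq < conservation_threshold,
      near_conserved = purrr::map_lgl(.data$site, function(s) {
        any(abs(conserved_sites - s) <= window & conserved_sites != s)
      })
    )
  if (drop_conserved) out <- filter(out, .data$non_conserved)
  out
}

#' Majority-frequency rule over homolog profiles
#'
#' A candidate survives when the target residue's frequency in the homolog
#' alignment is at least `threshold` (the rule deletes substitutions seen in
#' strictly less than the threshold fraction).  The frequency denominator is
#' the full sequence count, gaps included.
#'
#' @param candidates Candidate tibble (needs `site`, `target_residue`).
#' @param profiles Profile tibble covering the candidate sites.
#' @param threshold Survival threshold in (0, 1].
#' @param keep_all Keep failing candidates (flagged) instead of dropping them.
#' @return Candidates with `target_freq` and `freq_pass` columns; failing
#'   rows removed unless `keep_all`.
#' @export
frequency_rule <- function(candidates, profiles, threshold = 0.5, keep_all = FALSE) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  missing <- setdiff(candidates$site, unique(profiles$site))
  if (length(missing)) {
    abort(paste0("profiles do not cover candidate site(s): ", paste(missing, collapse = ", ")))
  }
  freq <- candidates |>
    left_join(profiles, by = c("site", target_residue = "residue")) |>
    mutate(target_freq = ifelse(is.na(.data$freq), 0, .data$freq),
           freq_pass = .data$target_freq >= threshold) |>
    select(-any_of(c("count", "n_total", "freq")))
  if (keep_all) freq else filter(freq, .data$freq_pass)
}

mutual_information <- function(a, b) {
  # plug-in MI over observed symbol pairs, gap as a 21st symbol, in nats
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(pa, pb)[idx]))
}

apc_correction <- function(mi_matrix) {
  # average-product correction over a set of columns
  diag(mi_matrix) <- NA
  row_mean <- rowMeans(mi_matrix, na.rm = TRUE)
  overall <- mean(mi_matrix[upper.tri(mi_matrix)], na.rm = TRUE)
  outer(row_mean, row_mean) / overall
}

#' Detect coevolving partner columns of an anchor site
#'
#' Association is mutual information with average-product correction (APC),
#' gap treated as a 21st symbol.  Significance is assessed against a
#' column-shuffle permutation null: the finite-sample MI null is
#' right-skewed, so a gamma distribution is moment-fitted to the `n_perm`
#' shuffled values and a partner is significant when its score exceeds the
#' upper `alpha` gamma quantile (on the APC-corrected scale); a fixed
#' `mi_threshold` overrides the null.  With fewer than 30 sequences scores
#' are flagged unreliable.
#'
#' @inheritParams align_to_reference
#' @param anchor_site Reference site whose partners are sought.
#' @param partner_sites Candidate partner sites (the anchor itself is
#'   excluded from the output).
#' @param n_perm Number of column-shuffle permutations for the null.
#' @param alpha Per-test tail probability of the calibrated null.
#' @param mi_threshold Optional fixed threshold overriding the permutation null.
#' @return Tibble with `partner_site`, `score`, `threshold`, `significant`,
#'   `reliable`, sorted by descending score.
#' @export
correlated_pairs <- function(aln, reference_id, anchor_site, partner_sites,
                             start = 1, n_perm = 200, alpha = 1e-6,
                             mi_threshold = NULL) {
  map <- align_to_reference(aln, reference_id, start)
  if (!anchor_site %in% map$site) abort(paste0("anchor site ", anchor_site, " unmapped"))
  partner_sites <- setdiff(partner_sites, anchor_site)
  bad <- setdiff(partner_sites, map$site)
  if (length(bad)) abort(paste0("partner site(s) unmapped: ", paste(bad, collapse = ", ")))
  m <- aln_matrix(aln)
  reliable <- nrow(m) >= 30
  if (!reliable) warn("fewer than 30 sequences: coevolution scores are unreliable")
  cols <- c(anchor_site, partner_sites)
  cm <- m[, map$column[match(cols, map$site)], drop = FALSE]
  k <- ncol(cm)
  mi <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mi[i, j] <- mi[j, i] <- mutual_information(cm[, i], cm[, j])
  }
  scores <- if (k > 2) {
    (mi - apc_correction(mi))[1, -1]
  } else {
    mi[1, -1] # APC undefined for a single pair; raw MI
  }
  anchor_col <- cm[, 1]
  out <- purrr::map(seq_along(partner_sites), function(p) {
    obs <- scores[p]
    if (is.null(mi_threshold)) {
      null_mi <- vapply(seq_len(n_perm), function(.) {
        mutual_information(anchor_col, sample(cm[, p + 1]))
      }, numeric(1))
      # permutation destroys the joint signal; compare on the same corrected
      # scale by shifting the null by the pair's APC background
      apc_bg <- mi[1, p + 1] - obs
      m_null <- mean(null_mi); s_null <- sd(null_mi)
      if (!is.finite(s_null) || s_null < 1e-12 || m_null <= 0) {
        thr <- m_null + 1e-9 - apc_bg
      } else {
        shape <- (m_null / s_null)^2
        thr <- stats::qgamma(1 - alpha, shape = shape,
                             rate = shape / m_null) - apc_bg
      }
    } else {
      thr <- mi_threshold
    }
    tibble(partner_site = partner_sites[p], score = obs, threshold = thr,
           significant = obs > thr, reliable = reliable)
  }) |> list_rbind()
  arrange(out, desc(.data$score))
}

#' Assemble the final mutation list and stage report
#'
#' The final list is the union of frequency-rule survivors and their
#' significant coevolving partners, ordered by ascending site number.  Pure
#' filter stages can only shrink the candidate list; the partner stage can
#' only add.
#'
#' @param candidates Full candidate tibble (source of wt/target residues).
#' @param survivors Survivor tibble from [frequency_rule()].
#' @param pairs Partner tibble from [correlated_pairs()] (may be empty).
#' @param stages Optional named list of site vectors recording earlier stages.
#' @return A `selection_report` object.
#' @export
finalize_selection <- function(candidates, survivors, pairs = NULL, stages = list()) {
  partner_sites <- integer()
  if (!is.null(pairs) && nrow(pairs)) {
    partner_sites <- pairs$partner_site[pairs$significant]
  }
  final_sites <- sort(union(survivors$site, partner_sites))
  final <- candidates |>
    filter(.data$site %in% final_sites) |>
    distinct(.data$site, .keep_all = TRUE) |>
    mutate(from_correlation = .data$site %in% setdiff(partner_sites, survivors$site)) |>
    arrange(.data$site)
  stages <- c(stages, list(frequency_rule = sort(survivors$site),
                           correlated_partners = final_sites))
  stage_tbl <- tibble(
    stage = names(stages),
    n = purrr::map_int(stages, length),
    sites = purrr::map(stages, sort)
  )
  structure(list(stages = stage_tbl, final = final),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Mutation selection report\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-22s %3d sites\n", x$stages$stage[i], x$stages$n[i]))
  }
  muts <- paste0(x$final$wt_residue, x$final$site, x$final$target_residue)
  cat("  final mutations:", paste(muts, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.selection_report <- function(x, ...) x$final

#' @exportS3Method generics::glance
glance.selection_report <- function(x, ...) {
  tibble(n_stages = nrow(x$stages),
         n_final = nrow(x$final),
         n_from_correlation = sum(x$final$from_correlation))
}

#' Run the full candidate-selection cascade
#'
#' Chains [pairwise_candidates()], a manual exclusion list,
#' [conservation_context()], an optional surface filter, [frequency_rule()]
#' and [correlated_pairs()] into a [finalize_selection()] report.  This is the
#' homology-guided mutation-selection protocol: donor/acceptor differences on
#' the acceptor surface, restricted to non-conserved columns, kept when the
#' donor residue dominates the homolog alignment, plus coevolving partners of
#' the survivors.
#'
#' @param msa Homolog alignment tibble.
#' @param pair Two-sequence acceptor/donor alignment tibble.
#' @param acceptor_id,donor_id,reference_id Sequence ids (`reference_id`
#'   defaults to the acceptor).
#' @param start Reference site number of the first non-gap acceptor position.
#' @param exclude Sites removed by manual triage (active-site proximity).
#' @param surface Optional tibble (`site`, `surface`) from
#'   [residue_exposure()]; non-surface candidates are dropped when supplied.
#' @param conservation_threshold,window Passed to [conservation_context()].
#' @param freq_threshold Passed to [frequency_rule()].
#' @param n_perm,alpha,mi_threshold Passed to [correlated_pairs()].
#' @return A `selection_report`.
#' @export
select_mutations <- function(msa, pair, acceptor_id, donor_id,
                             reference_id = acceptor_id, start = 1,
                             exclude = 149, surface = NULL,
                             conservation_threshold = 0.95, window = 2,
                             freq_threshold = 0.5, n_perm = 200,
                             alpha = 1e-6, mi_threshold = NULL) {
  stages <- list()
  cand <- pairwise_candidates(pair, acceptor_id, donor_id, start)
  stages$differing <- cand$site
  cand <- filter(cand, !.data$site %in% exclude)
  stages$manual_exclusion <- cand$site
  profiles <- column_profiles(msa, reference_id, sites = NULL, start = start)
  cand <- conservation_context(cand, profiles, conservation_threshold, window)
  stages$non_conserved <- cand$site
  if (!is.null(surface)) {
    cand <- cand |>
      left_join(surface, by = "site") |>
      filter(!is.na(.data$surface) & .data$surface)
    stages$surface <- cand$site
  }
  survivors <- frequency_rule(cand, profiles, freq_threshold)
  dropped <- setdiff(cand$site, survivors$site)
  pairs <- NULL
  if (length(dropped) && nrow(survivors)) {
    pairs <- purrr::map(survivors$site, function(anchor) {
      correlated_pairs(msa, reference_id, anchor, dropped, start,
                       n_perm = n_perm, alpha = alpha,
                       mi_threshold = mi_threshold)
    }) |> list_rbind() |>
      group_by(.data$partner_site) |>
      arrange(desc(.data$score), .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  finalize_selection(cand, survivors, pairs, stages)
}
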