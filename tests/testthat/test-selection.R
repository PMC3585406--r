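table1_profiles <- fixture_bundle("table1_profiles")

table1_candidates <- tibble::tibble(
  site = c(165L, 175L, 178L, 206L),
  wt_residue = c("S", "L", "T", "C"),
  target_residue = c("D", "E", "H", "R")
)

test_that("printed homolog profiles reproduce the published percentages", {
  get_freq <- function(site, res) {
    p <- table1_profiles
    p$freq[p$site == site & p$residue == res]
  }
  expect_equal(get_freq(165, "D") * 100, 85.6)
  expect_equal(get_freq(165, "S") * 100, 11.4)
  expect_equal(get_freq(175, "E") * 100, 76.0)
  expect_equal(get_freq(178, "H") * 100, 33.4)
  expect_equal(get_freq(206, "R") * 100, 77.2)
  # every profile sums to the full sequence count (gaps included)
  sums <- tapply(table1_profiles$count, table1_profiles$site, sum)
  expect_true(all(sums == 500))
})

test_that("frequency rule keeps majority substitutions and drops the rest", {
  survivors <- frequency_rule(table1_candidates, table1_profiles, threshold = 0.5)
  expect_equal(survivors$site, c(165L, 175L, 206L))
  expect_true(all(survivors$freq_pass))

  # boundary: exactly 50% survives (the rule deletes strictly-below)
  prof <- tibble::tibble(site = 1L, residue = c("A", "B"), count = c(50L, 50L)) |>
    mutsmith:::profiles_from_counts()
  cand <- tibble::tibble(site = 1L, wt_residue = "B", target_residue = "A")
  expect_equal(nrow(frequency_rule(cand, prof, 0.5)), 1L)

  expect_error(frequency_rule(cand, prof, 0), "in \\(0, 1\\]")
  expect_error(frequency_rule(cand, prof, 1.2), "in \\(0, 1\\]")
})

test_that("frequency rule agrees with a brute-force threshold scan and is idempotent", {
  set.seed(21)
  sites <- 1:100
  profs <- purrr::map(sites, function(s) {
    k <- sample(2:5, 1)
    res <- sample(c(LETTERS[1:6], "-"), k)
    tibble::tibble(site = s, residue = res, count = as.integer(rmultinom(1, 500, runif(k))))
  }) |> purrr::list_rbind() |> mutsmith:::profiles_from_counts()
  cands <- tibble::tibble(
    site = sites, wt_residue = "Z",
    target_residue = purrr::map_chr(sites, function(s) {
      sample(c(profs$residue[profs$site == s], "Q"), 1)
    })
  )
  out <- frequency_rule(cands, profs, 0.5)
  # oracle: direct per-site frequency lookup
  expected <- vapply(seq_len(nrow(cands)), function(i) {
    p <- profs[profs$site == cands$site[i] & profs$residue == cands$target_residue[i], ]
    f <- if (nrow(p)) p$freq else 0
    f >= 0.5
  }, logical(1))
  expect_equal(out$site, cands$site[expected])
  # idempotence: filtering the survivors again changes nothing
  again <- frequency_rule(out, profs, 0.5)
  expect_equal(again$site, out$site)
})

test_that("conservation context drops invariant candidates and flags neighbors", {
  profs <- tibble::tibble(
    site = rep(1:5, each = 2),
    residue = rep(c("A", "B"), 5),
    count = c(100L, 0L,  60L, 40L,  95L, 5L,  50L, 50L,  99L, 1L)
  ) |> mutsmith:::profiles_from_counts()
  cands <- tibble::tibble(site = c(1L, 2L, 4L),
                          wt_residue = "B", target_residue = "A")
  out <- conservation_context(cands, profs, conservation_threshold = 0.9, window = 2)
  # site 1 is invariant -> dropped; sites 2 and 4 are variable
  expect_equal(out$site, c(2L, 4L))
  # both neighbors of a conserved column within the window get the flag
  expect_true(all(out$near_conserved))
  expect_error(conservation_context(cands, profs, window = 0), "window")

  # flags equal a brute-force frequency check over random columns
  set.seed(31)
  profs2 <- purrr::map(1:100, function(s) {
    tibble::tibble(site = s, residue = c("A", "B", "C"),
                   count = as.integer(rmultinom(1, 200, runif(3))))
  }) |> purrr::list_rbind() |> mutsmith:::profiles_from_counts()
  cands2 <- tibble::tibble(site = 1:100, wt_residue = "Z", target_residue = "A")
  out2 <- conservation_context(cands2, profs2, 0.9, 2, drop_conserved = FALSE)
  modal <- tapply(profs2$freq, profs2$site, max)
  expect_equal(out2$non_conserved, as.vector(modal < 0.9))
})

test_that("mutual information is symmetric and maximal for a column with itself", {
  aln <- random_alignment(100, 10, seed = 5)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  mi_ab <- mutsmith:::mutual_information(m[, 1], m[, 2])
  mi_ba <- mutsmith:::mutual_information(m[, 2], m[, 1])
  expect_equal(mi_ab, mi_ba, tolerance = 1e-12)
  mi_self <- mutsmith:::mutual_information(m[, 1], m[, 1])
  expect_gte(mi_self, mi_ab)
  # self-pairing is excluded from partner output
  out <- correlated_pairs(aln, "seq001", anchor_site = 3,
                          partner_sites = c(3, 4), n_perm = 20)
  expect_false(3 %in% out$partner_site)
})

test_that("coupled columns are detected and independent columns are not", {
  # jointly sampled pair: 70% E&H, 20% L&T, 10% independent noise
  set.seed(99)
  n <- 500
  draw <- runif(n)
  a <- ifelse(draw < 0.7, "E", ifelse(draw < 0.9, "L", sample(c("A", "G"), n, TRUE)))
  b <- ifelse(draw < 0.7, "H", ifelse(draw < 0.9, "T", sample(c("S", "V"), n, TRUE)))
  indep1 <- sample(LETTERS[1:8], n, TRUE)
  indep2 <- sample(LETTERS[1:8], n, TRUE)
  seqs <- paste0(a, b, indep1, indep2)
  aln <- new_alignment(sprintf("s%03d", 1:n), seqs)
  set.seed(1)
  out <- correlated_pairs(aln, "s001", anchor_site = 1, partner_sites = 2:4,
                          n_perm = 100)
  expect_true(out$significant[out$partner_site == 2])
  expect_equal(out$partner_site[1], 2L) # strongest score first
  # independent uniform columns stay below the permutation threshold
  expect_false(any(out$significant[out$partner_site %in% 3:4]))
})

test_that("finalize_selection unions survivors with partners without duplicates", {
  survivors <- table1_candidates[table1_candidates$site %in% c(165, 175, 206), ]
  pairs <- tibble::tibble(partner_site = 178L, score = 0.5, threshold = 0.1,
                          significant = TRUE, reliable = TRUE)
  rep <- finalize_selection(table1_candidates, survivors, pairs)
  expect_s3_class(rep, "selection_report")
  expect_equal(rep$final$site, c(165L, 175L, 178L, 206L))
  expect_equal(sum(rep$final$from_correlation), 1L)

  # no pairs: final equals survivors
  rep2 <- finalize_selection(table1_candidates, survivors, NULL)
  expect_equal(rep2$final$site, survivors$site)

  # partner already a survivor: no duplicate
  pairs3 <- tibble::tibble(partner_site = 175L, score = 0.5, threshold = 0.1,
                           significant = TRUE, reliable = TRUE)
  rep3 <- finalize_selection(table1_candidates, survivors, pairs3)
  expect_equal(rep3$final$site, survivors$site)

  # stage counts are monotone over filters; partner stage may add
  expect_true(all(diff(rep$stages$n[rep$stages$stage != "correlated_partners"]) <= 0))
  g <- glance(rep)
  expect_equal(g$n_final, 4L)
})

test_that("profile-based survivors equal a direct per-sequence tally", {
  scen <- table1_msa_spec()
  msa <- synth_msa(scen$spec, seed = 17)
  profiles <- column_profiles(msa, scen$acceptor_id, start = scen$start_site)
  cand <- pairwise_candidates(scen$pair, scen$acceptor_id, scen$donor_id,
                              start = scen$start_site)
  out <- frequency_rule(cand, profiles, 0.5)
  # oracle: count matching residues sequence by sequence
  m <- do.call(rbind, strsplit(msa$seq, ""))
  map <- align_to_reference(msa, scen$acceptor_id, scen$start_site)
  oracle_sites <- cand$site[vapply(seq_len(nrow(cand)), function(i) {
    col <- m[, map$column[map$site == cand$site[i]]]
    mean(col == cand$target_residue[i]) >= 0.5
  }, logical(1))]
  expect_equal(out$site, oracle_sites)
})
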