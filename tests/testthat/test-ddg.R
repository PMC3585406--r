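params2 <- default_params_list(c("setA", "setB"))

test_that("an identity mutation gives exactly zero folding change", {
  wt <- two_domain_dimer(6, 12)
  sites <- tibble::tibble(chain = c("C", "D"), site = 3L)
  f <- folding_ddg(wt, wt, sites, params2)
  expect_true(all(f$ddg == 0))
  expect_error(folding_ddg(wt, wt, sites[0, ], params2), "no mutated sites")
})

test_that("swapping wild type and mutant negates the folding change exactly", {
  wt <- two_domain_dimer(6, 12)
  mut <- mutate_residue(mutate_residue(wt, "C", 3, "A", "D"), "D", 3, "A", "D")
  sites <- tibble::tibble(chain = c("C", "D"), site = 3L)
  fwd <- folding_ddg(wt, mut, sites, params2)
  rev <- folding_ddg(mut, wt, sites, params2)
  expect_equal(rev$ddg, -fwd$ddg)
})

test_that("a far-away charge perturbation reduces to segment self-energy differences", {
  # chain long enough that residue 2 and residue 9 never interact beyond
  # the tripeptide window; perturb a single side-chain charge at residue 2
  ch <- spring_chain(12, spacing = 25)
  wt <- assign_biophys(ch)
  wt$charge <- 0
  mut <- wt
  mut$charge[mut$resno == 2] <- 1
  sites <- tibble::tibble(chain = "A", site = 2L)
  p <- energy_params("setA")
  f <- folding_ddg(wt, mut, sites, list(p), monomers = "A", terms = "coulomb")
  # oracle: the lone charge has no partner in the folded state or the
  # segment, so the folding ddG must vanish identically
  expect_equal(f$ddg, 0, tolerance = 1e-9)

  # now add an interaction OUTSIDE the segment (charge at residue 9):
  # the folded state sees the pair Coulomb term, the segments do not
  wt2 <- wt; wt2$charge[wt2$resno == 9] <- 1
  mut2 <- mut; mut2$charge[mut2$resno == 9] <- 1
  f2 <- folding_ddg(wt2, mut2, sites, list(p), monomers = "A",
                    terms = "coulomb")
  d29 <- 25 * 7
  oracle <- -(332.0637 * 1 * 1 / d29) # positive charge pair destabilizes mutant
  expect_equal(f2$ddg, oracle, tolerance = 1e-6)
})

test_that("a stabilizing contact present only in the folded state gives positive ddG", {
  # mutant gains an attractive charge pair far outside the tripeptide window
  ch <- spring_chain(12, spacing = 25)
  wt <- assign_biophys(ch)
  wt$charge <- 0
  mut <- wt
  mut$charge[mut$resno == 2] <- 1
  mut$charge[mut$resno == 9] <- -1
  sites <- tibble::tibble(chain = "A", site = 2L)
  f <- folding_ddg(wt, mut, sites, list(energy_params("setA")), monomers = "A",
                   terms = "coulomb")
  expect_gt(f$ddg, 0)
})

test_that("non-interacting monomers have zero binding energy", {
  a <- toy_helix(5, chain = "C")
  b <- toy_helix(5, chain = "D")
  b <- set_coords(b, sweep(coords_matrix(b), 2, c(200, 0, 0), `+`))
  dimer <- new_structure(dplyr::bind_rows(a, b))
  out <- binding_ddg(dimer, dimer, chains = c("C", "D"), params_list = params2,
                     terms = c("bonded", "vdw", "coulomb"))
  expect_true(all(abs(out$wt_binding) < 1e-3))
  expect_true(all(out$ddd == 0))
})

test_that("binding is symmetric in chain order and a salt bridge is recovered", {
  dimer <- two_domain_dimer(6, 8, charges = c("C:6" = 1, "D:1" = -1))
  mut <- two_domain_dimer(6, 8)
  out_cd <- binding_ddg(dimer, mut, chains = c("C", "D"),
                        params_list = list(energy_params("setA")),
                        terms = "coulomb")
  out_dc <- binding_ddg(dimer, mut, chains = c("D", "C"),
                        params_list = list(energy_params("setA")),
                        terms = "coulomb")
  expect_equal(out_cd$ddd, out_dc$ddd, tolerance = 1e-9)
  # oracle: binding energy equals the inter-chain Coulomb sum
  d <- assign_biophys(dimer)
  qa <- d[d$chain == "C", ]; qb <- d[d$chain == "D", ]
  oracle <- 0
  for (i in which(qa$charge != 0)) for (j in which(qb$charge != 0)) {
    r <- sqrt(sum((unlist(qa[i, c("x", "y", "z")]) - unlist(qb[j, c("x", "y", "z")]))^2))
    oracle <- oracle + 332.0637 * qa$charge[i] * qb$charge[j] / r
  }
  expect_equal(out_cd$wt_binding, oracle, tolerance = 1e-6)
})

test_that("averaging reproduces the published bookkeeping", {
  t3 <- fixture_bundle("table3_folding")
  sd <- t3[t3$mutant == "SDmut", ]
  agg <- aggregate_ddg(dplyr::rename(sd, param = forcefield), value = "ddg")
  expect_equal(round(agg$per_monomer$mean_value[agg$per_monomer$monomer == "C"], 2), 83.96)
  expect_equal(round(agg$overall, 2), 83.28)
  t5 <- fixture_bundle("table5_binding")
  fm <- t5[t5$mutant == "Fmut", ]
  expect_equal(round(mean(fm$ddd), 2), -0.61)
  # identical replicates average to themselves
  same <- tibble::tibble(param = c("a", "b"), monomer = "C", ddg = 4.2)
  expect_equal(aggregate_ddg(same)$overall, 4.2)
})

test_that("the affine calibration reproduces the published adjusted values", {
  model <- fit_adjustment(tibble::tibble(raw = c(83.28, 181.32),
                                         adjusted = c(6.66, 15.77)))
  # derived from the printed pairs by solving the 2x2 linear system:
  # slope 0.0929213..., intercept -1.0784...; the held-out value checks out
  expect_equal(round(apply_adjustment(model, 90.05), 2), 7.29)
  td <- tidy(model)
  expect_equal(td$term, c("intercept", "slope"))

  ident <- fit_adjustment(tibble::tibble(raw = c(1, 2, 5), adjusted = c(1, 2, 5)))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  coll <- fit_adjustment(tibble::tibble(raw = c(0, 1, 2, 3),
                                        adjusted = 2 + 3 * c(0, 1, 2, 3)))
  expect_lt(max(abs(residuals(coll$fit))), 1e-10)
  expect_error(fit_adjustment(tibble::tibble(raw = 1, adjusted = 1)), "at least 2")
})

test_that("additivity verdicts match the published sums and detect coupling", {
  chk <- additivity_check(c(83.28, 181.32, 90.05), 355.42, tolerance = 0.05)
  expect_equal(chk$sum, 354.65)
  expect_equal(round(chk$abs_dev, 2), 0.77)
  expect_true(chk$additive)

  exact <- additivity_check(c(1, 2), 3)
  expect_equal(exact$abs_dev, 0)

  coupled <- additivity_check(c(10, 10), 35, tolerance = 0.05)
  expect_false(coupled$additive)
})

test_that("interacting sites break additivity in a constructed toy", {
  # two charge perturbations close together: combined effect includes their
  # mutual Coulomb term, the singles do not
  ch <- spring_chain(12, spacing = 25)
  wt <- assign_biophys(ch)
  wt$charge <- 0
  m1 <- wt; m1$charge[m1$resno == 5] <- 1
  m2 <- wt; m2$charge[m2$resno == 9] <- 1
  m12 <- wt; m12$charge[m12$resno %in% c(5, 9)] <- 1
  p <- list(energy_params("setA"))
  s5 <- tibble::tibble(chain = "A", site = 5L)
  s9 <- tibble::tibble(chain = "A", site = 9L)
  d1 <- folding_ddg(wt, m1, s5, p, monomers = "A", terms = "coulomb")$ddg
  d2 <- folding_ddg(wt, m2, s9, p, monomers = "A", terms = "coulomb")$ddg
  d12 <- folding_ddg(wt, m12, dplyr::bind_rows(s5, s9), p, monomers = "A",
                     terms = "coulomb")$ddg
  chk <- additivity_check(c(d1, d2), d12, tolerance = 0.01)
  expect_false(chk$additive)
  # the deviation equals the pair interaction term exactly
  expect_equal(chk$abs_dev, 332.0637 / (25 * 4), tolerance = 1e-6)
})

test_that("binding effects are classified against the neutral band", {
  published <- c(-1.18, 1.99, -0.73, -0.61)
  expect_true(all(classify_binding_effect(published, 2.0) == "no-effect"))
  expect_equal(classify_binding_effect(5), "increase")
  expect_equal(classify_binding_effect(-5), "decrease")
})

test_that("pKa shifts subtract element-wise and report absences", {
  wt <- tibble::tibble(residue = c("Asp201", "Asp276"), pka = c(0, 9.7))
  mut <- tibble::tibble(residue = c("Asp201", "Asp276", "Glu175"),
                        pka = c(14, 9.4, 2.926))
  out <- pka_shift_table(wt, mut)
  expect_equal(out$delta_pka[out$residue == "Asp201"], 14)
  expect_equal(out$status[out$residue == "Glu175"], "absent_wt")
  # identical tables give all-zero shifts
  same <- pka_shift_table(wt, wt)
  expect_true(all(same$delta_pka == 0))
  # random tables match the subtraction oracle
  set.seed(4)
  a <- tibble::tibble(residue = letters[1:8], pka = runif(8, 0, 14))
  b <- tibble::tibble(residue = letters[1:8], pka = runif(8, 0, 14))
  out2 <- pka_shift_table(a, b)
  expect_equal(out2$delta_pka, b$pka - a$pka)
})
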