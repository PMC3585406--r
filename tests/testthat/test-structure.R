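toy_pdb_text <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.003   1.420   0.000  1.00  0.00           C",
  "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      5  CA  GLY A   2       4.214   2.682   0.123  1.00  0.00           C",
  "ATOM      6  C   GLY A   2       5.614   2.151   0.401  1.00  0.00           C",
  "ATOM      7  N   SER A   3       6.552   3.082   0.567  1.00  0.00           N",
  "ATOM      8  CA  SER A   3       7.962   2.741   0.711  1.00  0.00           C",
  "ATOM      9  C   SER A   3       8.712   3.998   1.141  1.00  0.00           C",
  "END"
)

test_that("PDB round-trip preserves atoms, names and coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text, path)
  s <- read_structure(path)
  expect_equal(nrow(s), 9L)
  expect_equal(length(unique(paste(s$chain, s$resno))), 3L)
  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(s2$elety, s$elety)
  expect_equal(s2$resid, s$resid)
  expect_equal(round(coords_matrix(s2), 3), round(coords_matrix(s), 3))
})

test_that("alternate locations resolve to the highest occupancy", {
  alt <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, path)
  s <- read_structure(path)
  expect_equal(sum(s$elety == "N"), 1L)
  expect_equal(s$x[s$elety == "N"], 9.0)
})

test_that("clash scan reports exactly the overlapping inter-chain pairs", {
  # two chains far apart: no clashes
  far <- new_structure(tibble::tibble(
    chain = c("A", "B"), resno = 1L, resid = "GLY", elety = "CA",
    element = "C", x = c(0, 100), y = 0, z = 0
  ))
  expect_equal(nrow(clash_scan(far, c("A", "B"))), 0L)

  # constructed overlaps: atoms 1A-1B overlap by ~1.4 A (d = 2, r_sum = 3.4)
  clashed <- new_structure(tibble::tibble(
    chain = rep(c("A", "B"), each = 2), resno = c(1L, 2L, 1L, 2L),
    resid = "GLY", elety = "CA", element = "C",
    x = c(0, 10, 2, 40), y = 0, z = 0
  ))
  rep <- clash_scan(clashed, c("A", "B"), tolerance = 0.4)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$distance, 2)
  expect_equal(rep$overlap, 1.4)

  # brute-force O(n^2) oracle on a random cloud
  set.seed(8)
  xyz <- matrix(runif(60, 0, 12), ncol = 3)
  cloud <- new_structure(tibble::tibble(
    chain = rep(c("A", "B"), each = 10), resno = rep(1:10, 2), resid = "GLY",
    elety = "CA", element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
  rep2 <- clash_scan(cloud, c("A", "B"), tolerance = 0.4)
  n_oracle <- 0L
  for (i in 1:10) for (j in 11:20) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 1.7 + 1.7 - 0.4) n_oracle <- n_oracle + 1L
  }
  expect_equal(nrow(rep2), n_oracle)
})

test_that("biological dimer selection keeps requested chains and flags the clashed pair", {
  mimic <- new_structure(tibble::tibble(
    chain = c("A", "B", "C", "D"), resno = 1L, resid = "GLY", elety = "CA",
    element = "C", x = c(0, 1.5, 100, 140), y = 0, z = 0
  ))
  ab <- select_biological_dimer(mimic, c("A", "B"))
  cd <- select_biological_dimer(mimic, c("C", "D"))
  expect_gt(nrow(ab$clashes), 0)
  expect_equal(nrow(cd$clashes), 0L)
  expect_setequal(unique(cd$structure$chain), c("C", "D"))
  expect_error(select_biological_dimer(mimic, c("C", "Z")), "not in structure")
})

test_that("numbering conversion applies the +15 offset both ways", {
  expect_equal(renumber(165), 180)
  expect_equal(renumber(206), 221)
  expect_equal(renumber(175), 190)
  expect_equal(renumber(178), 193)
  expect_equal(renumber(180, direction = "to_structure"), 165)
  sites <- c(150L, 165L, 300L)
  expect_equal(renumber(renumber(sites), direction = "to_structure"), sites)
})

test_that("domain truncation removes the closed residue range everywhere", {
  ch <- spring_chain(120)
  tr <- truncate_domain(ch, c(2, 109))
  expect_equal(sort(unique(tr$resno)), c(1L, 110:120))
  expect_equal(nrow(tr), 12L)
  # structures with no residues in range are untouched
  short <- spring_chain(5)
  expect_equal(nrow(truncate_domain(short, c(50, 60))), 5L)
  # coordinates of survivors unchanged
  expect_equal(tr$x, ch$x[ch$resno %in% c(1, 110:120)])
})

test_that("tripeptide segments keep parent coordinates and flag termini", {
  h <- toy_helix(6)
  seg <- tripeptide_segment(h, "A", 3)
  expect_equal(sort(unique(seg$resno)), 2:4)
  expect_false(attr(seg, "terminus"))
  # coordinates identical to the parent (no re-fitting)
  parent <- h[h$resno %in% 2:4, ]
  expect_equal(coords_matrix(seg), coords_matrix(parent))

  segN <- tripeptide_segment(h, "A", 1)
  expect_equal(sort(unique(segN$resno)), 1:2)
  expect_true(attr(segN, "terminus"))
  expect_error(tripeptide_segment(h, "A", 99), "not in chain")
})
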