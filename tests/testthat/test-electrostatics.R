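# Shared solver fixtures (computed once; solves are the slow part)
sphere <- charged_sphere(q = 1, a = 2)
uniform_spec <- grid_spec(scale = 1, fill = 14, eps_protein = 80,
                          eps_solvent = 80, ionic_strength = 0, stern = 0,
                          probe = 0)
uniform_grid <- solve_lpbe(sphere, uniform_spec)

grid_value_at <- function(g, p) {
  ax <- lapply(1:3, function(k) g$origin[k] + (seq_len(g$dims[k]) - 1) * g$spacing)
  ii <- vapply(1:3, function(k) which.min(abs(ax[[k]] - p[k])), integer(1))
  node <- vapply(1:3, function(k) ax[[k]][ii[k]], numeric(1))
  list(value = g$values[ii[1], ii[2], ii[3]], node = node)
}

test_that("zero charges give an identically zero potential", {
  s <- sphere
  s$charge <- 0
  g <- solve_lpbe(s, grid_spec(fill = 50, probe = 0, stern = 0))
  expect_true(all(g$values == 0))
})

test_that("a point charge in uniform dielectric recovers Coulomb off-axis", {
  lB <- mutsmith:::bjerrum_vacuum()
  for (p in list(c(5, 3, 2), c(-4, 4, 3), c(6, -5, 2), c(3, 3, 3))) {
    got <- grid_value_at(uniform_grid, p)
    r <- sqrt(sum(got$node^2))
    expect_equal(got$value, lB / (80 * r), tolerance = 0.03)
  }
})

test_that("a dielectric sphere in salt matches the Debye-Hueckel solution", {
  spec <- grid_spec(scale = 2, fill = 18, eps_protein = 2, eps_solvent = 80,
                    ionic_strength = 0.15, stern = 2, probe = 0)
  g <- solve_lpbe(sphere, spec)
  kap <- sqrt(mutsmith:::debye_kappa2(0.15, 80))
  a_eff <- 2 + 2 # radius + Stern layer bounds the ion-free region
  lB <- mutsmith:::bjerrum_vacuum()
  for (p in list(c(5, 2, 1), c(-5, -4, 2), c(6, 3, 3), c(4, 4, 4))) {
    got <- grid_value_at(g, p)
    r <- sqrt(sum(got$node^2))
    ana <- lB / 80 * exp(-kap * (r - a_eff)) / ((1 + kap * a_eff) * r)
    expect_equal(got$value, ana, tolerance = 0.05)
  }
})

test_that("the linearized solver is linear and scales with charge", {
  two <- point_structure(rbind(c(-2, 0, 0), c(2, 0, 0)), charge = c(1, -1),
                         radius = 1.5)
  spec <- grid_spec(scale = 1, fill = 30, probe = 0, stern = 0)
  g_both <- solve_lpbe(two, spec)
  one_a <- two; one_a$charge <- c(1, 0)
  one_b <- two; one_b$charge <- c(0, -1)
  g_a <- solve_lpbe(one_a, spec)
  g_b <- solve_lpbe(one_b, spec)
  expect_equal(g_both$values, g_a$values + g_b$values, tolerance = 1e-3)

  doubled <- two; doubled$charge <- doubled$charge * 2
  g2 <- solve_lpbe(doubled, spec)
  expect_equal(g2$values, 2 * g_both$values, tolerance = 1e-3)
})

test_that("a mirrored structure yields the mirrored potential", {
  two <- point_structure(rbind(c(-2, 1, 0), c(3, 0, 0)), charge = c(1, -1),
                         radius = 1.5)
  spec <- grid_spec(scale = 1, fill = 30, probe = 0, stern = 0)
  g <- solve_lpbe(two, spec)
  mir <- set_coords(two, coords_matrix(two) %*% diag(c(-1, 1, 1)))
  gm <- solve_lpbe(mir, spec)
  # x-mirroring reverses the first grid axis
  expect_equal(gm$values, g$values[rev(seq_len(g$dims[1])), , ], tolerance = 1e-6)
})

test_that("CUBE files round-trip and use bohr with z-fastest ordering", {
  set.seed(12)
  g <- mutsmith:::new_potential_grid(c(1, 0, -2), 0.5, array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, path)
  lines <- readLines(path)
  # header origin in bohr: 1 A -> 1.88973 bohr
  expect_equal(as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])[2],
               1.88973, tolerance = 1e-5)
  # 8 values, z-fastest: first data line holds grid[1, 1, 1:2]
  vals <- as.numeric(strsplit(trimws(lines[7]), "\\s+")[[1]])
  expect_equal(vals[1:2], g$values[1, 1, ], tolerance = 1e-4)
  back <- read_cube(path)
  expect_equal(back$dims, g$dims)
  expect_equal(back$origin, g$origin, tolerance = 1e-6)
  expect_equal(back$values, g$values, tolerance = 1e-4)
  # malformed files are rejected
  bad <- withr::local_tempfile(fileext = ".cube")
  writeLines(lines[1:3], bad)
  expect_error(read_cube(bad), "CUBE")
})

test_that("map subtraction is element-wise and refuses mismatched geometry", {
  g <- uniform_grid
  zero <- grid_subtract(g, g)
  expect_true(all(zero$values == 0))
  shifted <- mutsmith:::new_potential_grid(g$origin + 1, g$spacing, g$values)
  expect_error(grid_subtract(shifted, g), "geometries differ")
})

test_that("an added negative charge makes the nearby difference map negative", {
  dimer <- two_domain_dimer(5, 8)
  mut <- dimer
  idx <- which(mut$chain == "C" & mut$resno == 5 & mut$elety == "CB")
  mut$charge[idx] <- mut$charge[idx] - 1
  spec <- grid_spec(scale = 0.6, fill = 50)
  g_wt <- solve_lpbe(dimer, spec)
  g_mut <- solve_lpbe(mut, spec)
  diffm <- grid_subtract(g_mut, g_wt)
  # potential near the perturbed residue drops; the far end is barely moved
  near <- grid_value_at(diffm, unlist(mut[idx, c("x", "y", "z")]))
  far_atom <- dimer[dimer$chain == "D" & dimer$resno == 5 & dimer$elety == "CB", ]
  far <- grid_value_at(diffm, unlist(far_atom[1, c("x", "y", "z")]))
  expect_lt(near$value, 0)
  expect_lt(abs(far$value), abs(near$value))

  # patch statistics see the same contrast
  stats <- patch_stats(diffm, dimer, list(
    near = tibble::tibble(chain = "C", site = 4:5),
    far = tibble::tibble(chain = "D", site = 4:5)
  ))
  expect_lt(stats$mean[stats$patch == "near"], 0)
  expect_lt(abs(stats$mean[stats$patch == "far"]),
            abs(stats$mean[stats$patch == "near"]))

  # a uniformly zero map gives zero patch means
  zstats <- patch_stats(grid_subtract(g_wt, g_wt), dimer,
                        list(p = tibble::tibble(chain = "C", site = 1:5)))
  expect_equal(zstats$mean, 0)
})
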