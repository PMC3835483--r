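test_that("region assignment follows the hydroxyl-plus-ring rule", {
  g <- cholesterol_graph()
  # polar seeds: O, ring carbons C2, C3, C4 (hydrogens pulled in)
  o <- which(g$labels == "O3")
  seeds <- c(o, 2L, 3L, 4L)
  reg <- assign_regions(g, seeds)
  polar <- which(reg$region == "polar_head")
  # O + its H + C2 + 2H + C3 + 1H + C4 + 2H = 10 atoms
  expect_equal(length(polar), 10L)
  expect_setequal(g$elements[polar], c("O", "H", "C"))
  expect_equal(sum(g$elements[polar] == "H"), 6L)
  expect_equal(length(which(reg$region == "core")), 64L)

  expect_warning(reg0 <- assign_regions(g, integer(0)), "empty")
  expect_true(all(reg0$region == "core"))
  expect_warning(reg_all <- assign_regions(g, seq_len(n_atoms(g))), "empty")
  expect_true(all(reg_all$region == "polar_head"))
  expect_error(assign_regions(g, 999L), "out of range")
  expect_error(assign_regions(g, 1L, eps_core = 0.5), "dielectric")
})

test_that("surface sampling covers spheres at the stated density", {
  s1 <- structure3d("C", matrix(0, 1, 3))
  pts <- sample_surface(s1, radii = 2, scale = 1, density = 5)
  expect_equal(nrow(pts), ceiling(5 * 4 * pi * 4), tolerance = 0.1)
  r <- sqrt(rowSums(as.matrix(pts[, 1:3])^2))
  expect_lt(max(abs(r - 2)), 1e-9)

  # scale 1.1 scales point radii exactly
  pts11 <- sample_surface(s1, radii = 2, scale = 1.1, density = 5)
  r11 <- sqrt(rowSums(as.matrix(pts11[, 1:3])^2))
  expect_lt(max(abs(r11 - 2.2)), 1e-9)

  # two nearly coincident identical atoms: each sphere half-occluded,
  # total point count is about one full sphere
  s2 <- structure3d(c("C", "C"), rbind(c(0, 0, 0), c(0.02, 0, 0)))
  pts2 <- sample_surface(s2, radii = c(2, 2), scale = 1, density = 5)
  expect_equal(nrow(pts2), nrow(pts), tolerance = 0.05)
  # direct distance oracle: no surviving point is inside the other sphere
  for (i in 1:2) {
    own <- as.matrix(pts2[pts2$atom == i, 1:3])
    other <- s2$xyz[3 - i, ]
    expect_true(all(sqrt(rowSums(sweep(own, 2, other)^2)) >= 2 - 1e-9))
  }
  expect_error(sample_surface(s1, radii = -1), "radii")
  expect_error(sample_surface(s1, radii = 1, scale = 0.5), "scale")
})

test_that("screened Coulomb reproduces the worked point-charge value", {
  # +1 e at origin, uniform eps = 2, sample point at 10 Angstrom, 300 K
  s <- structure3d("C", matrix(0, 1, 3))
  cs <- charge_set(1, 1.7)
  g <- mol_graph("C", matrix(integer(0), ncol = 2), check = FALSE)
  reg <- suppressWarnings(assign_regions(g, integer(0), eps_core = 2))
  pts <- data.frame(x = 10, y = 0, z = 0, atom = 1L)
  esp <- esp_at_points(pts, s, cs, reg, temperature = 300)
  expect_equal(esp$phi, 27.85, tolerance = 5e-4)  # 4 significant figures
  expect_equal(esp$phi_clamped, 5)                # clamped at +5 kT/e
})

test_that("a centred charge gives a uniform surface potential k q/(eps R)", {
  s <- structure3d("C", matrix(0, 1, 3))
  cs <- charge_set(0.7, 1.5)
  g <- mol_graph("C", matrix(integer(0), ncol = 2), check = FALSE)
  reg <- suppressWarnings(assign_regions(g, integer(0), eps_core = 2.02))
  pts <- sample_surface(s, radii = 1.5, scale = 1.2, density = 4)
  esp <- esp_at_points(pts, s, cs, reg, temperature = 300)
  expect_lt(diff(range(esp$phi)) / abs(mean(esp$phi)), 1e-9)
  kT <- 8.617333262e-5 * 300
  expect_equal(mean(esp$phi), 14.3996 * 0.7 / (2.02 * 1.8) / kT,
               tolerance = 1e-9)
})

test_that("potentials are linear in charges and scale as 1/eps", {
  g <- cholesterol_graph()
  s <- cholesterol_structure()
  seeds <- c(which(g$labels == "O3"), 2L, 3L, 4L)
  reg <- assign_regions(g, seeds)
  pts <- sample_surface(s, density = 1)
  q1 <- generate_charges(g, "fixture-like")
  q0 <- generate_charges(g, "neutral")
  e1 <- esp_at_points(pts, s, q1, reg)
  e0 <- esp_at_points(pts, s, q0, reg)
  expect_true(all(e0$phi[!e0$masked] == 0))
  neg <- charge_set(-q1$charge, q1$radius)
  expect_equal(esp_at_points(pts, s, neg, reg)$phi, -e1$phi)
  twice <- charge_set(2 * q1$charge, q1$radius)
  expect_equal(esp_at_points(pts, s, twice, reg)$phi, 2 * e1$phi)

  # doubling both dielectric constants halves every potential
  reg2 <- assign_regions(g, seeds, eps_polar = 2 * 32.6, eps_core = 2 * 2.02)
  expect_equal(esp_at_points(pts, s, q1, reg2)$phi, e1$phi / 2)

  # polar-head screening: same charges, head dielectric vs core dielectric
  head_pts <- pts[reg$region[pts$atom] == "polar_head", ]
  reg_core_only <- suppressWarnings(
    assign_regions(g, integer(0), eps_core = 2.02))
  screened <- esp_at_points(head_pts, s, q1, reg)
  unscreened <- esp_at_points(head_pts, s, q1, reg_core_only)
  nz <- abs(unscreened$phi) > 1e-9
  expect_true(all(abs(screened$phi[nz]) < abs(unscreened$phi[nz])))
})

test_that("the hydroxyl-polarised fixture is most negative near oxygen", {
  g <- cholesterol_graph()
  s <- cholesterol_structure()
  o <- which(g$labels == "O3")
  pts <- sample_surface(s, density = 2)
  q <- generate_charges(g, "fixture-like")

  # with a uniform dielectric the most negative surface point sits on the
  # oxygen sphere itself
  reg_u <- suppressWarnings(assign_regions(g, integer(0), eps_core = 2.02))
  esp_u <- esp_at_points(pts, s, q, reg_u)
  expect_equal(g$elements[esp_u$atom[which.min(esp_u$phi)]], "O")

  # with the two-region map the strongly screened head group hands the
  # minimum to a core atom, but it stays on the hydroxyl side: closer to O
  # than the median surface point
  reg <- assign_regions(g, c(o, 2L, 3L, 4L))
  esp2 <- esp_at_points(pts, s, q, reg)
  d_o <- sqrt(rowSums(sweep(as.matrix(esp2[, c("x", "y", "z")]), 2,
                            s$xyz[o, ])^2))
  i <- which.min(esp2$phi)
  expect_lt(esp2$phi[i], 0)
  expect_lt(d_o[i], stats::median(d_o))
})
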