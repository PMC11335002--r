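test_that("constraint evaluation at neutral and at the closed-form strain", {
  j <- cylinder_joint(10, 2)
  r0 <- evaluate_constraints(j, 0, "z")
  expect_equal(r0$worst_disc_strain, 0)
  expect_equal(r0$worst_capsule_strain, 0)
  expect_false(r0$bone_contact)
  expect_length(r0$violated, 0)
  # locator fixture: strain = cos(theta/2) - 1; at 60 deg: -0.1340
  sj <- strain_joint()
  r <- evaluate_constraints(sj, 60, "z",
                            bending_config(max_angle = 120))
  expect_equal(r$worst_disc_strain, cos(pi / 6) - 1, tolerance = 1e-9)
  expect_equal(round(r$worst_disc_strain, 4), -0.1340)
  # bone contact appears just past the analytic disk-contact angle
  cfg <- no_strain_config()
  ang <- 2 * atan(2 / 20) * 180 / pi  # 11.42 deg for r = 10, g = 2
  expect_false(evaluate_constraints(j, ang - 0.4, "z", cfg)$bone_contact)
  expect_true(evaluate_constraints(j, ang + 0.1, "z", cfg)$bone_contact)
})

test_that("cylinder sweep matches the analytic contact oracle", {
  s <- sweep_direction(cylinder_joint(10, 2), "dorsoflexion",
                       no_strain_config())
  expect_equal(s$rom, 11)
  expect_equal(s$limiting, "bone")
})

test_that("strain-limited sweep matches the closed form", {
  s <- sweep_direction(strain_joint(), "dorsoflexion",
                       bending_config(strain_allowance = 0.1))
  expect_equal(s$rom, 51.5)  # floor(2*acos(0.9) / 0.5) * 0.5
  expect_equal(s$limiting, "disc")
})

test_that("a joint with no engaging constraints sweeps to the 90-degree cap", {
  for (d in bending_directions()$direction) {
    s <- sweep_direction(cap_joint(), d, bending_config())
    expect_equal(s$rom, 90)
    expect_equal(s$limiting, "cap")
  }
})

test_that("the variant grid is the full 3x3x3 factorial", {
  g <- variant_grid()
  expect_equal(nrow(g), 27)
  expect_equal(sort(unique(g$spacing_mult)), c(0.9, 1, 1.1))
  expect_equal(sort(unique(g$threshold)), c(0.0025, 0.005, 0.0075))
  expect_equal(sort(unique(g$strain_allow)), c(0.45, 0.5, 0.55))
})

test_that("a single-joint experiment yields 162 deterministic records", {
  col <- cylinder_column(radius = 10, gap = 2)
  res <- run_experiment(col)
  expect_equal(nrow(res), 6 * 27)
  expect_equal(nrow(unique(res[, c("direction", "spacing_mult", "threshold",
                                   "strain_allow")])), 162)
  res2 <- run_experiment(col)
  expect_identical(res, res2)
  # per-joint text export
  dir <- withr::local_tempdir()
  run_experiment(col, out_dir = dir)
  f <- file.path(dir, "joint_01_rom.txt")
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.delim(f)), 162)
})

test_that("ROM is monotone in threshold and strain allowance, and symmetric", {
  col <- generate_column(synthetic_column_spec(n_vertebrae = 2))
  res <- run_experiment(col)
  by_var <- split(res, list(res$direction, res$spacing_mult))
  for (chunk in by_var) {
    for (sa in unique(chunk$strain_allow)) {
      sub <- chunk[chunk$strain_allow == sa, ]
      sub <- sub[order(sub$threshold), ]
      expect_true(all(diff(sub$rom_deg) >= 0))
    }
    for (th in unique(chunk$threshold)) {
      sub <- chunk[chunk$threshold == th, ]
      sub <- sub[order(sub$strain_allow), ]
      expect_true(all(diff(sub$rom_deg) >= 0))
    }
  }
  # bilateral symmetry on a symmetric joint
  lat <- with(res, tapply(rom_deg, direction, mean))
  expect_equal(lat[["lateroflexion_left"]], lat[["lateroflexion_right"]])
  expect_equal(lat[["axial_left"]], lat[["axial_right"]])
})

test_that("cylinder ROM follows floor(2*atan(g/2r)/step)*step over the grid", {
  cfg <- no_strain_config()
  for (r in c(5, 10, 20)) for (g in c(1, 2, 4)) {
    s <- sweep_direction(cylinder_joint(r, g, nseg = 32), "ventroflexion",
                         cfg)
    oracle <- floor((2 * atan(g / (2 * r)) * 180 / pi) / 0.5) * 0.5
    expect_equal(s$rom, oracle,
                 info = sprintf("r=%g g=%g", r, g))
  }
})

test_that("bone-limited ROM does not decrease with wider spacing", {
  for (m in list(c(0.9, 1), c(1, 1.1))) {
    r1 <- sweep_direction(build_joint(cylinder_vertebra(10, -32, -2),
                                      cylinder_vertebra(10, 0, 30),
                                      optimal_spacing = 2,
                                      spacing_multiplier = m[1]),
                          "dorsoflexion", no_strain_config())
    r2 <- sweep_direction(build_joint(cylinder_vertebra(10, -32, -2),
                                      cylinder_vertebra(10, 0, 30),
                                      optimal_spacing = 2,
                                      spacing_multiplier = m[2]),
                          "dorsoflexion", no_strain_config())
    expect_gte(r2$rom, r1$rom)
  }
})

test_that("disarticulation flips at the closed-form separation angle", {
  fx <- facet_fixture(h = 10)
  expect_false(detect_disarticulation(fx))
  # rotate the prezygapophyseal facet about x through the origin
  posed <- function(theta) {
    f <- fx
    f$facet_pairs$left$prezyg <-
      rotate_points(f$facet_pairs$left$prezyg, c(1, 0, 0), theta, c(0, 0, 0))
    f
  }
  oracle <- 2 * atan(1 / 10) * 180 / pi  # 11.42 deg
  expect_false(detect_disarticulation(posed(floor(oracle / 0.5) * 0.5)))
  expect_true(detect_disarticulation(posed(ceiling(oracle / 0.5) * 0.5)))
  # fully translated apart
  f2 <- fx
  f2$facet_pairs$left$prezyg <-
    sweep(f2$facet_pairs$left$prezyg, 2, c(5, 0, 0), "+")
  expect_true(detect_disarticulation(f2))
  # joints without facet polygons are never flagged
  expect_false(detect_disarticulation(cylinder_joint(5, 2)))
})

test_that("constraint tallies preserve record counts", {
  col <- cylinder_column(radius = 10, gap = 2)
  res <- run_experiment(col)
  tab <- summarize_constraints(res)
  expect_equal(sum(tab$n), nrow(res))
  expect_true(all(tab$limiting %in% c("bone", "disc", "capsule", "cap")))
})
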