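test_that("generated vertebrae are watertight with finite landmarks", {
  spec <- synthetic_column_spec(n_vertebrae = 3)
  v <- generate_vertebra(spec, 1)
  expect_true(is_watertight(v$mesh))
  expect_gt(mesh_volume(v$mesh), 0)
  expect_true(all(is.finite(v$landmarks$points)))
  expect_gte(nrow(v$landmarks$points), 13)
  expect_error(generate_vertebra(synthetic_column_spec(mesh_segments = 4), 1),
               "resolution|multiple")
})

test_that("degenerate spine profile puts the mesh top at the arch roof", {
  spec <- synthetic_column_spec(n_vertebrae = 2, spine_height = 0)
  v <- generate_vertebra(spec, 1)
  apex <- v$landmarks$points["arch_apex", ]
  expect_equal(max(v$mesh$vertices[, 2]), apex[[2]], tolerance = 1e-9)
})

test_that("facet plate normals follow the angle profile", {
  norm_of <- function(angle) {
    v <- generate_vertebra(synthetic_column_spec(n_vertebrae = 2,
                                                 facet_angle = angle), 1)
    fp <- v$landmarks$points[paste0("facet_prezyg_left_", 1:4), ]
    e1 <- fp[2, ] - fp[1, ]; e2 <- fp[4, ] - fp[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    abs(n / sqrt(sum(n^2)))
  }
  expect_equal(norm_of(0)[2], 1, tolerance = 1e-9)   # horizontal: normal up
  expect_equal(norm_of(90)[2], 0, tolerance = 1e-9)  # vertical: normal lateral
})

test_that("columns count joints, inject damage, and are deterministic", {
  col <- generate_column(synthetic_column_spec(n_vertebrae = 8))
  expect_length(col$vertebrae, 8)
  expect_length(col$joints, 7)
  dmg <- generate_column(synthetic_column_spec(
    n_vertebrae = 4, damage = list(c(3, "left"))))
  expect_equal(dmg$vertebrae[[3]]$landmarks$side_damage, "left")
  expect_false(any(grepl("zyg_left",
                         rownames(dmg$vertebrae[[3]]$landmarks$points))))
  expect_lt(mesh_volume(dmg$vertebrae[[3]]$mesh),
            mesh_volume(dmg$vertebrae[[2]]$mesh))
  # damaged side drops its capsule pairs in the adjoining joints
  sides <- vapply(dmg$joints[[2]]$locator_pairs, `[[`, "", "side")
  expect_false("left" %in% sides[vapply(dmg$joints[[2]]$locator_pairs,
                                        `[[`, "", "tissue") == "capsule"])
  a <- generate_column(synthetic_column_spec(n_vertebrae = 3, seed = 7))
  b <- generate_column(synthetic_column_spec(n_vertebrae = 3, seed = 7))
  expect_identical(a$vertebrae[[2]]$mesh$vertices,
                   b$vertebrae[[2]]$mesh$vertices)
})

test_that("presets encode the intended comparative morphologies", {
  n <- 8
  mam <- preset_column_spec("mammal_like", n)
  mid <- ceiling(n / 2)
  expect_lt(max(mam$facet_angle[1:(mid - 1)]), 15)
  expect_gt(min(mam$facet_angle[(mid + 2):n]), 75)
  sail <- preset_column_spec("sailback", n)
  expect_gt(max(sail$spine_height) / sail$centrum_length, 10)
  tua <- preset_column_spec("tuatara_like", n)
  expect_false(is.null(tua$intercentra))
  col <- generate_column(preset_column_spec("tuatara_like", 3))
  expect_length(col$intercentra, 2)
  expect_true(all(vapply(col$intercentra, function(m) mesh_volume(m) > 0, TRUE)))
  expect_error(preset_column_spec("unicorn"), "mammal_like")
})
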