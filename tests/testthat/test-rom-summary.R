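# minimal raw table builder: one joint, all six directions, chosen variants
raw_table <- function(joint = 1, rom = NULL, grid = variant_grid()) {
  dirs <- bending_directions()$direction
  df <- expand.grid(direction = dirs, i = seq_len(nrow(grid)),
                    stringsAsFactors = FALSE)
  out <- data.frame(species = "toy", joint = joint, direction = df$direction,
                    spacing_mult = grid$spacing_mult[df$i],
                    threshold = grid$threshold[df$i],
                    strain_allow = grid$strain_allow[df$i],
                    rom_deg = NA_real_, limiting_constraint = "cap",
                    disarticulated_at = NA_real_, stringsAsFactors = FALSE)
  base <- c(dorsoflexion = 8, ventroflexion = 6, lateroflexion_left = 11,
            lateroflexion_right = 11, axial_left = 4, axial_right = 4)
  if (!is.null(rom)) base[names(rom)] <- rom
  out$rom_deg <- base[out$direction]
  out
}

test_that("processing rules: doubling, damage, 0.75% variant removal", {
  raw <- raw_table()
  pr <- process_rom(raw)
  expect_equal(pr$n_variants, 18)  # 27 - 9 dropped at the 0.75% threshold
  expect_equal(pr$lateral, 22)     # mean(11, 11) * 2
  expect_equal(pr$axial, 8)
  expect_equal(pr$sagittal, 14)    # dorso + ventro
  # asymmetric damage: intact side doubled
  raw2 <- raw_table(rom = c(lateroflexion_left = 9, lateroflexion_right = 12))
  pr2 <- process_rom(raw2, damage = c("1" = "left"))
  expect_equal(pr2$lateral, 24)    # right side only, doubled
  pr3 <- process_rom(raw2, damage = c("1" = "right"))
  expect_equal(pr3$lateral, 18)
  expect_message(pr4 <- process_rom(raw2, damage = c("1" = "both")), "excluded")
  expect_null(pr4)
})

test_that("dropping the 0.75% variants is idempotent; order-invariant", {
  raw <- raw_table()
  once <- process_rom(raw)
  twice <- process_rom(raw[abs(raw$threshold - 0.0075) > 1e-12, ])
  expect_equal(once$lateral, twice$lateral)
  shuffled <- raw[rev(seq_len(nrow(raw))), ]
  expect_equal(process_rom(shuffled)$sagittal, once$sagittal)
})

test_that("ternary proportions: normalization, class rule, tie, scaling", {
  pr <- data.frame(joint = 1:3,
                   lateral = c(30, 10, 20),
                   sagittal = c(30, 30, 20),
                   axial = c(60, 0, 20))
  tp <- ternary_proportions(pr)
  expect_equal(tp$p_lateral[1], 0.25)
  expect_equal(tp$p_sagittal[1], 0.25)
  expect_equal(tp$p_axial[1], 0.50)
  expect_equal(rowSums(tp[, c("p_lateral", "p_sagittal", "p_axial")]),
               rep(1, 3), tolerance = 1e-12)
  expect_equal(tp$class[2], "sagittal-dominant")  # 30/40 > 0.5
  expect_equal(tp$class[3], "lateral-dominant")   # exact tie -> lateral
  # scaling all ROM leaves proportions unchanged
  tp2 <- ternary_proportions(transform(pr, lateral = 3 * lateral,
                                       sagittal = 3 * sagittal,
                                       axial = 3 * axial))
  expect_equal(tp2$p_axial, tp$p_axial)
})

test_that("region assignment: diaphragmatic and mid-dorsal rules", {
  fake_col <- function(n_joints, group, pos = NA) {
    structure(list(joints = vector("list", n_joints), group = group,
                   region_pos = pos), class = "column_model")
  }
  r <- assign_regions(fake_col(20, "mammal", 11))
  expect_equal(sum(r$region == "anterior"), 11)
  expect_equal(sum(r$region == "posterior"), 9)
  r2 <- assign_regions(fake_col(20, "reptile"))
  expect_equal(sum(r2$region == "anterior"), 10)
  r3 <- assign_regions(fake_col(21, "reptile"))
  expect_equal(sum(r3$region == "anterior"), 10)
  expect_equal(sum(r3$region == "posterior"), 11)
  # labels form one contiguous anterior block then one posterior block
  expect_true(all(diff(r3$region == "anterior") <= 0))
  expect_error(assign_regions(fake_col(10, "mammal")), "diaphragmatic")
})

test_that("craniocaudal polynomial fits: exact line, constant, guard", {
  x <- 1:10
  lin <- craniocaudal_profile(x, 2 + 0.5 * x, degree = 3)
  expect_lt(max(abs(lin$residuals)), 1e-9)
  expect_equal(lin$fit$value[1], 2.5, tolerance = 1e-9)
  cst <- craniocaudal_profile(x, rep(4, 10), degree = 3)
  expect_equal(range(cst$fit$value), c(4, 4), tolerance = 1e-9)
  expect_warning(small <- craniocaudal_profile(1:3, c(1, 2, 5), degree = 5),
                 "reduced")
  expect_equal(small$degree, 2)
})

test_that("constraint tallies: all-cap input and conservation", {
  raw <- raw_table()
  tab <- summarize_constraints(raw)
  expect_equal(unique(tab$limiting), "cap")
  expect_equal(sum(tab$n), nrow(raw))
})
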