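test_that("amphicoelous COR is the midpoint of the intervertebral space", {
  mk <- function(x) cylinder_landmarks(1, x - 2, x)
  expect_equal(place_cor_amphicoelous(mk(0), cylinder_landmarks(1, 2, 4)),
               c(1, 0, 0))
  lm_a <- cylinder_landmarks(1, -2, 0)
  lm_b <- cylinder_landmarks(1, 0, 2)
  expect_warning(cor0 <- place_cor_amphicoelous(lm_a, lm_b), "zero")
  expect_equal(cor0, c(0, 0, 0))
})

test_that("procoelous COR by sphere fit recovers the centre", {
  set.seed(42)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(5 * u, 2, c(3, -1, 2), "+")
  fit <- place_cor_procoelous(pts)
  expect_equal(as.numeric(fit), c(3, -1, 2), tolerance = 1e-6)
  expect_equal(attr(fit, "radius"), 5, tolerance = 1e-6)
  noisy <- pts + matrix(rnorm(300, sd = 0.05), ncol = 3)
  fit2 <- place_cor_procoelous(noisy)
  expect_lt(sqrt(sum((as.numeric(fit2) - c(3, -1, 2))^2)), 0.05)
  flat <- cbind(matrix(rnorm(20), ncol = 2), 0)
  expect_error(place_cor_procoelous(flat), "ill-conditioned")
})

test_that("joint assembly sets spacing, frame and lever arms", {
  j1 <- cylinder_joint(10, 2)
  expect_equal(j1$spacing, 2, tolerance = 1e-9)
  j11 <- build_joint(cylinder_vertebra(10, -32, -2),
                     cylinder_vertebra(10, 0, 30),
                     optimal_spacing = 2, spacing_multiplier = 1.1)
  expect_equal(j11$spacing, 1.1 * j1$spacing, tolerance = 1e-12)
  gap <- function(j) endplate_centroid(j$landmarks_posterior, "cranial")[1] -
    endplate_centroid(j$landmarks_anterior, "caudal")[1]
  expect_equal(gap(j11), 2.2, tolerance = 1e-9)
  # frame orthonormal and right-handed
  A <- rbind(j1$frame$x_axis, j1$frame$y_axis, j1$frame$z_axis)
  expect_equal(A %*% t(A), diag(3), tolerance = 1e-12)
  expect_equal(det(A), 1, tolerance = 1e-12)
  # lever to an arch apex placed 20 mm above the COR
  va <- cylinder_vertebra(2, -10, -1)
  va$landmarks$points["arch_apex", ] <- c(-0.5, 20, 0) + c(0, 0, 0)
  vp <- cylinder_vertebra(2, 1, 10)
  j <- build_joint(va, vp, optimal_spacing = 2)
  expect_equal(j$lever_sagittal,
               sqrt(sum((c(-0.5, 20, 0) - j$frame$cor)^2)))
  # locator pairs span disc and capsule tissues on full landmark sets
  col <- generate_column(synthetic_column_spec(n_vertebrae = 2))
  tissues <- vapply(col$joints[[1]]$locator_pairs, `[[`, "", "tissue")
  expect_setequal(unique(tissues), c("disc", "capsule"))
})

test_that("hierarchical rotation matches a forward-kinematics oracle", {
  col <- column_model(lapply(0:4, function(k)
    cylinder_vertebra(3, k * 12, k * 12 + 10)),
    optimal_spacing = 2, species = "chain")
  # oracle: explicit sequential rigid maps applied to vertebra centroids
  centroid <- function(v) colMeans(v$mesh$vertices)
  rots <- list(c(joint = 1, ang = 10), c(joint = 3, ang = -7))
  posed <- col
  for (r in rots)
    posed <- apply_joint_rotation(posed, r["joint"], "z", r["ang"])
  oracle <- lapply(col$vertebrae, centroid)
  cors <- lapply(col$joints, function(j) j$frame$cor)
  for (r in rots) {
    j <- r[["joint"]]
    for (k in seq_along(oracle)) {
      if (k > j)
        oracle[[k]] <- rotate_points(oracle[[k]], c(0, 0, 1), r[["ang"]],
                                     cors[[j]])
    }
    for (q in seq_along(cors))
      if (q > j)
        cors[[q]] <- rotate_points(cors[[q]], c(0, 0, 1), r[["ang"]],
                                   cors[[j]])
  }
  for (k in 1:5)
    expect_equal(centroid(posed$vertebrae[[k]]), oracle[[k]],
                 tolerance = 1e-9)
  # identity and inverse
  same <- apply_joint_rotation(col, 2, "y", 0)
  expect_equal(same$vertebrae[[4]]$mesh$vertices,
               col$vertebrae[[4]]$mesh$vertices)
  back <- apply_joint_rotation(apply_joint_rotation(col, 2, "x", 23),
                               2, "x", -23)
  expect_equal(back$vertebrae[[4]]$mesh$vertices,
               col$vertebrae[[4]]$mesh$vertices, tolerance = 1e-9)
  expect_error(apply_joint_rotation(col, 99, "z", 1), "joint")
})

test_that("mirroring through the sagittal plane swaps sides, keeps distances", {
  col <- generate_column(synthetic_column_spec(n_vertebrae = 2))
  j <- col$joints[[1]]
  mirror <- function(v) {
    v$mesh$vertices[, 3] <- -v$mesh$vertices[, 3]
    lm <- v$landmarks
    lm$points[, 3] <- -lm$points[, 3]
    rn <- rownames(lm$points)
    rn <- gsub("left", "@@", rn)
    rn <- gsub("right", "left", rn)
    rownames(lm$points) <- gsub("@@", "right", rn)
    v$landmarks <- lm
    v
  }
  jm <- build_joint(mirror(col$vertebrae[[1]]), mirror(col$vertebrae[[2]]),
                    optimal_spacing = col$optimal_spacing[1],
                    check_neutral = FALSE)
  d <- function(x) sort(vapply(x$locator_pairs, `[[`, 0, "neutral"))
  expect_equal(d(jm), d(j), tolerance = 1e-9)
  left_m <- vapply(jm$locator_pairs, function(p) identical(p$side, "left"), TRUE)
  left_o <- vapply(j$locator_pairs, function(p) identical(p$side, "left"), TRUE)
  expect_equal(sum(left_m), sum(left_o))
})

test_that("landmark sidecars and column manifests round-trip", {
  dir <- withr::local_tempdir()
  lm <- cylinder_landmarks(3, 0, 10)
  save_landmarks(lm, file.path(dir, "lm.txt"))
  lm2 <- load_landmarks(file.path(dir, "lm.txt"))
  expect_equal(lm2$points, lm$points)
  expect_equal(lm2$centrum_length, 10)
  col <- generate_column(synthetic_column_spec(n_vertebrae = 3), dir = dir)
  col2 <- load_column(file.path(dir, "manifest.txt"))
  expect_equal(length(col2$vertebrae), 3)
  expect_equal(col2$optimal_spacing, col$optimal_spacing)
  expect_equal(max(col2$vertebrae[[2]]$mesh$comp),
               max(col$vertebrae[[2]]$mesh$comp))
  expect_equal(mesh_volume(col2$vertebrae[[2]]$mesh),
               mesh_volume(col$vertebrae[[2]]$mesh), tolerance = 1e-4)
})
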