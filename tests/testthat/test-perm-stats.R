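# toy multivariate dataset with a group structure
toy_data <- function(n = 40, shift = 0, seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("A", "B"), each = n / 2))
  r <- factor(rep(c("ant", "post"), times = n / 2))
  sp <- factor(paste0(g, rep(1:2, each = n / 4)))
  Y <- matrix(rnorm(3 * n), n, 3)
  Y[r == "post", 1] <- Y[r == "post", 1] + shift
  data.frame(y1 = Y[, 1], y2 = Y[, 2], y3 = Y[, 3], Group = g, Region = r,
             Species = sp)
}

test_that("observed sequential SS and R2 match vegan::adonis2 (Euclidean)", {
  skip_if_not_installed("vegan")
  d <- toy_data(n = 40, shift = 1.5, seed = 3)
  fit <- rrpp_manova(cbind(y1, y2, y3) ~ Group * Region, d, n_perm = 99,
                     seed = 1)
  ref <- vegan::adonis2(d[, 1:3] ~ Group * Region, data = d,
                        method = "euclidean", by = "terms",
                        permutations = 49)
  expect_equal(fit$SS, ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(fit$R2, ref$R2[1:3], tolerance = 1e-9)
  expect_equal(fit$F, ref$F[1:3], tolerance = 1e-9)
})

test_that("observed statistics are invariant to row order", {
  d <- toy_data(n = 32, shift = 1, seed = 5)
  f1 <- rrpp_manova(cbind(y1, y2, y3) ~ Group * Region, d, n_perm = 19,
                    seed = 2)
  d2 <- d[sample(nrow(d)), ]
  f2 <- rrpp_manova(cbind(y1, y2, y3) ~ Group * Region, d2, n_perm = 19,
                    seed = 2)
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
  expect_equal(f1$SS, f2$SS, tolerance = 1e-10)
})

test_that("nested species-within-group terms fit and are sequential", {
  d <- toy_data(n = 40, shift = 1, seed = 7)
  fit <- rrpp_manova(cbind(y1, y2, y3) ~ Group / Species * Region, d,
                     n_perm = 99, seed = 1)
  expect_true("Group:Species" %in% fit$term)
  expect_equal(sum(fit$SS) + attr(fit, "SS_residual"),
               sum(scale(as.matrix(d[, 1:3]), scale = FALSE)^2),
               tolerance = 1e-9)
  expect_true(all(fit$R2 >= 0) && sum(fit$R2) <= 1)
  expect_true(all(fit$p > 0 & fit$p <= 1))
})

test_that("a strong region effect is detected with high power", {
  hits <- 0
  for (i in 1:40) {
    d <- toy_data(n = 80, shift = 2, seed = 100 + i)
    fit <- rrpp_manova(cbind(y1, y2, y3) ~ Group * Region, d, n_perm = 199,
                       seed = i)
    if (fit$p[fit$term == "Region"] < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("single-response F values reproduce a univariate permutation ANOVA", {
  d <- toy_data(n = 24, shift = 1, seed = 11)
  fit <- rrpp_manova(cbind(y1) ~ Region, d, n_perm = 499, seed = 9)
  # univariate oracle on the same permutation set
  a <- stats::anova(stats::lm(y1 ~ Region, d))
  expect_equal(fit$F[1], a$`F value`[1], tolerance = 1e-9)
  mu <- mean(d$y1)
  set.seed(9)
  count <- 0
  for (p in seq_len(499)) {
    idx <- sample.int(24)
    yp <- mu + (d$y1 - mu)[idx]
    Fp <- stats::anova(stats::lm(yp ~ d$Region))$`F value`[1]
    if (Fp >= a$`F value`[1]) count <- count + 1
  }
  expect_equal(fit$p[1], (1 + count) / 500, tolerance = 1e-12)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- toy_data(n = 24)
  d$Dup <- d$Group
  expect_error(rrpp_manova(cbind(y1, y2) ~ Group + Dup, d, n_perm = 9),
               "aliased")
  d$flat <- 1
  expect_error(rrpp_manova(cbind(y1, flat) ~ Group, d, n_perm = 9),
               "zero-variance")
  d$one <- factor("x", levels = c("x", "y"))
  expect_error(rrpp_manova(cbind(y1, y2) ~ one, d, n_perm = 9), "levels")
})

test_that("results are reproducible given the seed and recorded in text", {
  d <- toy_data(n = 32, shift = 0.5, seed = 13)
  f1 <- rrpp_manova(cbind(y1, y2) ~ Group * Region, d, n_perm = 199, seed = 4)
  f2 <- rrpp_manova(cbind(y1, y2) ~ Group * Region, d, n_perm = 199, seed = 4)
  expect_identical(f1$p, f2$p)
  path <- file.path(withr::local_tempdir(), "manova.txt")
  write_manova(f1, path)
  lines <- readLines(path)
  expect_true(any(grepl("#n_perm 199", lines)))
  expect_true(any(grepl("#seed 4", lines)))
})
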