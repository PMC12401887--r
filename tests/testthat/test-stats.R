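test_that("ANOVA effect sums of squares vanish when cell means are equal", {
  cells <- expand.grid(tr = c("benign", "high"),
    bio = c("alpine", "temperate", "desert"))
  dat <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(tr = cells$tr[i], bio = cells$bio[i], y = c(-1, 0, 1) + 5)
  }))
  tab <- two_way_anova(dat$y, dat$tr, dat$bio)
  eff <- tab[tab$term != "residuals", ]
  expect_equal(eff$sum_sq, rep(0, 3), tolerance = 1e-10)
  expect_equal(eff$f, rep(0, 3), tolerance = 1e-10)
  expect_equal(eff$df, c(1, 2, 2))
})

test_that("Type III ANOVA matches the reference implementation on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- c(4, 7, 5, 9, 6, 8)
  cells <- expand.grid(tr = c("benign", "high"),
    bio = c("alpine", "temperate", "desert"))
  dat <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(tr = cells$tr[i], bio = cells$bio[i],
      y = rnorm(n[i], mean = i * 0.5, sd = 1))
  }))
  tab <- two_way_anova(dat$y, dat$tr, dat$bio)

  fit <- lm(y ~ tr * bio, data = dat,
    contrasts = list(tr = "contr.sum", bio = "contr.sum"))
  ref <- car::Anova(fit, type = 3)
  ref <- ref[c("tr", "bio", "tr:bio", "Residuals"), ]
  expect_equal(tab$sum_sq, ref$`Sum Sq`, tolerance = 1e-6)
  expect_equal(tab$f[1:3], ref$`F value`[1:3], tolerance = 1e-6)
  expect_equal(tab$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-6)
  expect_equal(attr(tab, "r_squared"), summary(fit)$r.squared, tolerance = 1e-8)
})

test_that("ANOVA F statistics are location and scale invariant", {
  set.seed(13)
  dat <- data.frame(
    tr = sample(c("benign", "high"), 40, replace = TRUE),
    bio = sample(c("alpine", "temperate", "desert"), 40, replace = TRUE),
    y = rnorm(40)
  )
  base <- two_way_anova(dat$y, dat$tr, dat$bio)
  shifted <- two_way_anova(dat$y + 100, dat$tr, dat$bio)
  scaled <- two_way_anova(dat$y * -3.7, dat$tr, dat$bio)
  expect_equal(shifted$f, base$f, tolerance = 1e-9)
  expect_equal(scaled$f, base$f, tolerance = 1e-9)
  expect_error(two_way_anova(dat$y, rep("benign", 40), dat$bio), "single level")
})

test_that("Type III and sequential sums of squares coincide for balanced designs", {
  set.seed(14)
  cells <- expand.grid(tr = c("benign", "high"),
    bio = c("alpine", "temperate", "desert"))
  dat <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(tr = cells$tr[i], bio = cells$bio[i], y = rnorm(6, i, 1))
  }))
  t3 <- two_way_anova(dat$y, dat$tr, dat$bio)
  t1 <- anova(lm(y ~ tr * bio, data = dat)) # sequential (Type I)
  expect_equal(t3$sum_sq[1:3], t1$`Sum Sq`[1:3], tolerance = 1e-9)
})

test_that("Tukey contrasts reduce to the t test for two groups", {
  set.seed(15)
  y <- c(rnorm(8, 0), rnorm(10, 1))
  g <- rep(c("a", "b"), c(8, 10))
  out <- pairwise_contrasts(y, g)
  ref <- t.test(y[g == "b"], y[g == "a"], var.equal = TRUE)
  expect_equal(out$p_adj, ref$p.value, tolerance = 1e-9)
  expect_equal(out$diff, unname(diff(rev(ref$estimate))), tolerance = 1e-12)
})

test_that("three identical groups give adjusted p of 1", {
  y <- rep(c(3, 5, 7, 9), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  out <- pairwise_contrasts(y, g)
  expect_equal(out$p_adj, rep(1, 3), tolerance = 1e-9)
  expect_equal(out$diff, rep(0, 3))
})

test_that("Tukey-Kramer contrasts match TukeyHSD on six unbalanced groups", {
  set.seed(16)
  g <- rep(paste0(rep(c("alpine", "temperate", "desert"), each = 2),
    ".", c("benign", "high")), times = c(7, 9, 8, 10, 6, 11))
  y <- rnorm(length(g), mean = as.integer(factor(g)) * 0.4)
  out <- pairwise_contrasts(y, g)

  ref <- TukeyHSD(aov(y ~ g2, data.frame(y = y, g2 = factor(g))))$g2
  key <- paste(out$group_2, out$group_1, sep = "-")
  ref <- ref[key, ]
  expect_equal(out$diff, unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(out$p_adj, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(out$lo, unname(ref[, "lwr"]), tolerance = 1e-9)
  expect_equal(out$hi, unname(ref[, "upr"]), tolerance = 1e-9)

  # Holm alternative is monotone in the unadjusted p and bounded by 1
  holm <- pairwise_contrasts(y, g, method = "holm")
  expect_true(all(holm$p_adj >= 0 & holm$p_adj <= 1))
})

test_that("singleton groups are excluded from contrasts with a warning", {
  y <- c(rnorm(5), rnorm(5, 1), 2.5)
  g <- c(rep("a", 5), rep("b", 5), "c")
  expect_warning(out <- pairwise_contrasts(y, g), "c")
  expect_equal(nrow(out), 1)
})

test_that("bootstrap CI is degenerate for constants and reproducible by seed", {
  out <- bootstrap_mean_ci(rep(4.2, 10), seed = 1)
  expect_equal(out$mean, 4.2)
  expect_equal(out$lo, 4.2)
  expect_equal(out$hi, 4.2)

  x <- rnorm(30, sd = 2)
  a <- bootstrap_mean_ci(x, seed = 77)
  b <- bootstrap_mean_ci(x, seed = 77)
  expect_identical(a, b)
  c2 <- bootstrap_mean_ci(x, seed = 78)
  expect_false(identical(a$lo, c2$lo))
  expect_true(a$lo < a$mean && a$mean < a$hi)
  expect_error(bootstrap_mean_ci(5), "at least two")
})

test_that("bootstrap seeding does not disturb the caller's RNG stream", {
  set.seed(123)
  invisible(bootstrap_mean_ci(rnorm(10) + 10, seed = 5))
  # the outer stream continues as if the bootstrap never drew from it
  x <- rnorm(10)
  set.seed(123)
  rnorm(10)
  expect_identical(rnorm(10), x)
})

test_that("group summaries carry one bootstrap CI row per biome x treatment", {
  set.seed(18)
  d <- tibble::tibble(
    biome = rep(c("alpine", "temperate", "desert"), each = 10),
    treatment = rep(c("benign", "high"), 15),
    y = rnorm(30)
  )
  out <- group_summaries(d, "y", n_boot = 200, seed = 9)
  expect_equal(nrow(out), 6)
  expect_true(all(out$n == 5))
  expect_true(all(out$lo <= out$mean & out$mean <= out$hi))
  expect_identical(out, group_summaries(d, "y", n_boot = 200, seed = 9))
})
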