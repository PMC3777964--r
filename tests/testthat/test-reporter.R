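test_that("the ratio-of-ratios efficiency behaves as forced by its formula", {
  ctrl <- data.frame(beta_gal = c(100, 120, 90), luciferase = c(50, 60, 45))
  test1 <- ctrl
  test1$luciferase <- ctrl$luciferase * 0.01
  expect_equal(efficiency(test1, ctrl)$percent, 1.0)
  expect_equal(efficiency(ctrl, ctrl)$percent, 100)

  # scale invariance in either reporter channel
  t2 <- data.frame(beta_gal = c(80, 100), luciferase = c(2, 3))
  c2 <- data.frame(beta_gal = c(90, 95), luciferase = c(200, 260))
  base <- efficiency(t2, c2)
  for (cc in c(0.1, 7)) {
    scaled_luc <- list(
      test = transform(t2, luciferase = luciferase * cc),
      ctrl = transform(c2, luciferase = luciferase * cc)
    )
    expect_equal(efficiency(scaled_luc$test, scaled_luc$ctrl)$percent,
                 base$percent)
    scaled_bg <- list(
      test = transform(t2, beta_gal = beta_gal * cc),
      ctrl = transform(c2, beta_gal = beta_gal * cc)
    )
    expect_equal(efficiency(scaled_bg$test, scaled_bg$ctrl)$percent,
                 base$percent)
  }
  bad <- data.frame(beta_gal = c(10, 0), luciferase = c(1, 1))
  expect_error(efficiency(bad, ctrl), "replicate\\(s\\) 2")
})

test_that("exact Mann-Whitney matches hand counts and the direct-U oracle", {
  r <- mann_whitney_exact(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(mann_whitney_exact(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(mann_whitney_exact(c(1, 2), c(1, 2))$p_value, 1)

  withr::with_seed(8, {
    for (k in 1:40) {
      nx <- sample(1:6, 1)
      ny <- sample(1:6, 1)
      with_ties <- k %% 2 == 0
      x <- if (with_ties) sample(1:4, nx, replace = TRUE) else
        stats::rnorm(nx)
      y <- if (with_ties) sample(1:4, ny, replace = TRUE) else
        stats::rnorm(ny)
      got <- mann_whitney_exact(x, y)
      want <- oracle_mw(x, y)
      expect_equal(got$U, want$U)
      expect_equal(got$p_value, want$p, info = paste(nx, ny, with_ties))
      # swap symmetry
      swapped <- mann_whitney_exact(y, x)
      expect_equal(swapped$U, nx * ny - got$U)
      expect_equal(swapped$p_value, got$p_value)
      # tie-free case: agreement with the reference implementation
      if (!with_ties) {
        ref <- stats::wilcox.test(x, y, exact = TRUE)
        expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
        expect_equal(got$U, unname(ref$statistic))
      }
    }
  })
})

test_that("the exact test is valid (super-uniform) under the null at 6+6", {
  # deterministic: the null distribution of p over all C(12,6) labelings of a
  # fixed tie-free pool satisfies P(p <= alpha) <= alpha for every alpha
  pool <- 1:12
  labelings <- utils::combn(12, 6)
  pvals <- apply(labelings, 2, function(idx) {
    mann_whitney_exact(pool[idx], pool[-idx])$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5, 1)) {
    expect_lte(mean(pvals <= alpha), alpha)
  }
  expect_lte(mean(pvals <= 0.05), 0.05)
})

test_that("normal approximation is flagged for large samples", {
  withr::with_seed(2, {
    x <- stats::rnorm(15)
    y <- stats::rnorm(15)
  })
  r <- mann_whitney_exact(x, y)
  expect_equal(r$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("the efficiency estimator recovers the truth within its sampling error", {
  n_trials <- 300
  cv <- 0.1
  reps <- 6
  # exact sampling error implied by the generator's noise model: both ratio
  # means carry a relative SE of cv/sqrt(n), propagated to first order
  se_truth <- 1 * cv * sqrt(2 / reps)
  hits_truth <- 0
  hits_data <- 0
  for (s in seq_len(n_trials)) {
    d <- make_reporter(1, n_replicates = reps, cv = cv, seed = 20000 + s)
    est <- efficiency(d[d$construct == "test", ],
                      d[d$construct == "control", ])
    if (abs(est$percent - 1) <= 3 * se_truth) hits_truth <- hits_truth + 1
    if (abs(est$percent - 1) <= 3 * est$se_percent) hits_data <- hits_data + 1
  }
  expect_gte(hits_truth / n_trials, 0.99)
  # the data-estimated SE replaces sigma by a six-replicate estimate, so its
  # 3-SE interval has t-like tails (about 98.5-99% coverage)
  expect_gte(hits_data / n_trials, 0.97)
})

test_that("reporter_fit ties everything together with tidy and glance", {
  d <- dplyr::bind_rows(
    make_reporter(1, cv = 0.05, seed = 1, test = "Podo-1",
                  control = "Podo0"),
    make_reporter(0.3, cv = 0.05, seed = 2, test = "IBV-Podo0",
                  control = "drop") %>% dplyr::filter(construct != "drop")
  )
  fit <- reporter_fit(d, control = "Podo0")
  td <- tidy(fit)
  expect_setequal(td$construct, c("Podo-1", "IBV-Podo0"))
  expect_true(all(c("percent", "se_percent", "U", "p_value", "p_holm") %in%
                    names(td)))
  expect_true(all(td$p_holm >= td$p_value))
  g <- glance(fit)
  expect_equal(g$n_constructs, 2)
  expect_error(reporter_fit(d, control = "nope"), "control")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
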