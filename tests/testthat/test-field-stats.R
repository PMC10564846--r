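test_that("enrichment factors reproduce worked station values and invariances", {
  # Station 8 VLP: 3.4e7 over 1.9e7 displays as 1.8; Station 5: 0.7
  expect_equal(enrichment_factor(3.4e7, 1.9e7)$ef_display, 1.8)
  expect_equal(enrichment_factor(1.3e7, 1.9e7)$ef_display, 0.7)
  # identity and scale invariance
  x <- c(1.5, 2e7, 3.3e3)
  expect_equal(enrichment_factor(x, x)$ef, rep(1, 3))
  expect_equal(enrichment_factor(5 * x, 5 * 2 * x)$ef,
               enrichment_factor(x, 2 * x)$ef)
  # n.d. propagation and zero denominator flagged, not thrown
  res <- enrichment_factor(c(NA, 2), c(1, 0))
  expect_true(is.na(res$ef[1]) && is.na(res$ef[2]))
  expect_true(res$undefined[2])
  expect_error(enrichment_factor(-1, 1), ">= 0")
})

test_that("virus-host ratios match printed station cells within rounding", {
  expect_equal(virus_host_ratio(3.4e7, 9.9e5), 34.3434, tolerance = 1e-4)
  expect_equal(virus_host_ratio(0, 5), 0)
  expect_true(is.na(virus_host_ratio(3, 0)))
  # full table recomputation: printed 2-s.f. inputs reproduce printed ratios
  counts <- read_station_counts(
    system.file("extdata", "station_counts.csv", package = "aerovirome"))
  rt <- station_ratio_table(counts)
  printed <- c(counts$printed_ratio_foam, counts$printed_ratio_sml,
               counts$printed_ratio_ssw, counts$printed_ratio_prc)
  recomputed <- c(
    rt$ratio[rt$compartment == "foam"], rt$ratio[rt$compartment == "sml"],
    rt$ratio[rt$compartment == "ssw"], rt$ratio[rt$compartment == "prc"])
  ok <- !is.na(printed)
  # Inputs are printed at 2 significant figures, so each recomputed ratio
  # can drift by up to ~2% of its magnitude (the 127.8 cell recomputes to
  # 125.9); tolerate the larger of 1.5 absolute or 2% relative.
  tol <- pmax(1.5, 0.02 * printed[ok])
  expect_true(all(abs(recomputed[ok] - printed[ok]) <= tol))
})

test_that("correlate reports r, t, df and p and is symmetric", {
  d <- data.frame(x = c(1, 2, 4, 3, 6, 5, 8), y = c(2, 1, 5, 4, 7, 5, 9))
  r1 <- correlate(d, x, y, method = "pearson")
  r2 <- correlate(d, y, x, method = "pearson")
  expect_equal(r1$estimate, r2$estimate)
  expect_equal(r1$df, nrow(d) - 2)
  expect_equal(r1$t, r1$estimate * sqrt(r1$df) / sqrt(1 - r1$estimate^2))
  # perfect linear relation
  d2 <- data.frame(x = 1:6, y = 1:6)
  expect_equal(correlate(d2, x, y, method = "pearson")$estimate, 1)
  expect_equal(correlate(d2, x, y, method = "spearman")$estimate, 1)
  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), x, y,
                         method = "pearson"), "zero variance")
})

test_that("spearman equals the brute-force average-rank oracle on ties", {
  set.seed(11)
  for (i in 1:5) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- correlate(data.frame(x = x, y = y), x, y, method = "spearman")$estimate
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # invariance under a monotone transform
  x <- c(0.3, 2, 5, 1, 9, 4); y <- c(1, 3, 2, 5, 8, 6)
  a <- correlate(data.frame(x = x, y = y), x, y, method = "spearman")$estimate
  b <- correlate(data.frame(x = exp(x), y = y), x, y, method = "spearman")$estimate
  expect_equal(a, b)
})

test_that("interaction model recovers exact and noisy coefficients", {
  a <- c(1, 2, 3, 4, 5, 6, 2, 4); b <- c(2, 1, 4, 3, 6, 5, 5, 2)
  y <- 1 + a + b + a * b
  fit <- fit_interaction_model(data.frame(y = y, a = a, b = b), y, a, b)
  g <- glance(fit)
  expect_equal(g$adjusted_r2, 1)
  expect_equal(unname(residuals(fit$fit)), rep(0, 8), tolerance = 1e-10)
  expect_equal(g$df_error, 8L - 4L)

  # parameter recovery within 3 standard errors, sigma = 0.1, n = 10;
  # with 6 error df the joint 3-SE event holds for roughly 90% of draws
  set.seed(21)
  ok <- replicate(100, {
    a <- rnorm(10); b <- rnorm(10)
    y <- 0.5 + 1.2 * a - 0.7 * b + 0.4 * a * b + rnorm(10, 0, 0.1)
    td <- tidy(fit_interaction_model(data.frame(y = y, a = a, b = b), y, a, b))
    all(abs(td$estimate - c(0.5, 1.2, -0.7, 0.4)) <= 3 * td$std_error)
  })
  expect_gte(mean(ok), 0.8)
})

test_that("AIC penalizes the spurious interaction on interaction-free data", {
  # AIC adds the interaction only when |t| > sqrt(2); under the null that
  # happens for ~17% of fits at this sample size, so the reduced model
  # should win at least 80% of the time
  set.seed(31)
  worse <- replicate(500, {
    a <- rnorm(40); b <- rnorm(40)
    y <- 1 + a + b + rnorm(40, 0, 0.5)
    full <- AIC(lm(y ~ a * b))
    reduced <- AIC(lm(y ~ a + b))
    full > reduced
  })
  expect_gte(mean(worse), 0.8)
})

test_that("interaction model AIC follows the Gaussian stats::AIC convention", {
  set.seed(5)
  a <- rnorm(10); b <- rnorm(10); y <- a + b + rnorm(10)
  fit <- fit_interaction_model(data.frame(y = y, a = a, b = b), y, a, b)
  ll <- logLik(fit$fit)
  expect_equal(glance(fit)$aic, -2 * as.numeric(ll) + 2 * attr(ll, "df"))
  expect_equal(attr(ll, "df"), 5)  # 4 coefficients + error variance
})

test_that("degenerate interaction designs error clearly", {
  expect_error(fit_interaction_model(data.frame(y = 1:4, a = 1:4, b = 4:1),
                                     y, a, b), "n > 4")
  d <- data.frame(y = rnorm(8), a = 1:8, b = 2 * (1:8))
  expect_error(fit_interaction_model(d, y, a, b), "Singular")
})
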