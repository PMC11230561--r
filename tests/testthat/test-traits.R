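test_that("the three-block worked example yields the forced trait vector", {
  p <- toy_three_block()
  tv <- compute_traits(p, segment_bars(p))
  expect_equal(unname(tv["darkest_intensity"]), 50)
  expect_equal(unname(tv["lightest_intensity"]), 200)
  expect_equal(unname(tv["range_intensity"]), 150)
  expect_equal(unname(tv["avg_bar_intensity"]), 50)
  expect_equal(unname(tv["avg_interbar_intensity"]), 200)
  expect_equal(unname(tv["differential_intensity"]), 150)
  expect_equal(unname(tv["n_bars"]), 1)
  expect_equal(unname(tv["percent_barring"]), 1 / 3)
  expect_equal(unname(tv["avg_bar_width_cm"]), 0.10)
  expect_equal(unname(tv["avg_interbar_width_cm"]), 0.10)
})

test_that("the position covariance trait is cov(position, value)", {
  p <- intensity_profile(0:99)
  tv <- compute_traits(p, segment_bars(p))
  expect_equal(unname(tv["covariance"]), var(0:99))  # cov(x, x) = var(x)
  expect_equal(unname(tv["covariance"]), 841 + 2 / 3, tolerance = 1e-12)
})

test_that("constant profiles leave bar-dependent traits missing, not zero", {
  p <- intensity_profile(rep(99, 70))
  tv <- compute_traits(p, segment_bars(p))
  expect_equal(unname(tv["range_intensity"]), 0)
  expect_equal(unname(tv["n_bars"]), 0)
  expect_equal(unname(tv["percent_barring"]), 0)
  expect_true(is.na(tv["avg_bar_intensity"]))
  expect_true(is.na(tv["differential_intensity"]))
  expect_true(is.na(tv["avg_bar_width_cm"]))
})

test_that("trait identities hold on random profiles", {
  set.seed(31)
  for (rep in 1:100) {
    p <- random_profile(sample(30:400, 1))
    s <- segment_bars(p)
    tv <- compute_traits(p, s)
    expect_equal(unname(tv["range_intensity"]),
                 unname(tv["lightest_intensity"] - tv["darkest_intensity"]))
    # partition of the profile
    expect_equal(sum(s$segments$end_px - s$segments$start_px), p$length_px)
    # percent barring from bar count and mean width (Sigma = n * mean)
    if (tv["n_bars"] > 0) {
      expect_equal(unname(tv["percent_barring"]),
                   unname(tv["n_bars"] * (tv["avg_bar_width_cm"] /
                                            p$scale_cm_per_px) / p$length_px),
                   tolerance = 1e-12)
      expect_equal(unname(tv["differential_intensity"]),
                   unname(tv["avg_interbar_intensity"] -
                            tv["avg_bar_intensity"]), tolerance = 1e-12)
      # exact pixel identity
      expect_equal(tv["percent_barring"] * p$length_px,
                   unname(sum(bars(s)$end_px - bars(s)$start_px)),
                   ignore_attr = TRUE)
    }
    expect_gte(unname(tv["percent_barring"]), 0)
    expect_lte(unname(tv["percent_barring"]), 1)
  }
})

test_that("mismatched profile and segmentation lengths are rejected", {
  p <- toy_three_block()
  s <- segment_bars(rep(1:2, 20))
  expect_error(compute_traits(p, s), "match")
})

make_sl_table <- function(n = 60, seed = 2) {
  set.seed(seed)
  sl <- runif(n, 3, 6)
  df <- data.frame(id = as.character(seq_len(n)), group = "F2",
                   standard_length_cm = sl,
                   n_bars = rpois(n, 6) + 0.0,
                   range_intensity = 100 + 12 * sl + rnorm(n, 0, 5),
                   percent_barring = pmin(1, pmax(0, 0.4 + rnorm(n, 0, 0.1))),
                   stringsAsFactors = FALSE)
  df
}

test_that("residualization removes allometry exactly and is idempotent", {
  df <- make_sl_table()
  df$range_intensity <- 2 * df$standard_length_cm + 1  # perfectly allometric
  out <- residualize(df, columns = c("range_intensity", "n_bars"))
  expect_equal(out$range_intensity_resid, rep(0, nrow(df)),
               tolerance = 1e-10)
  # OLS orthogonality
  expect_lt(abs(cor(out$n_bars_resid, out$standard_length_cm)), 1e-10)
  # idempotence: residualizing the residuals changes nothing
  df2 <- df
  df2$n_bars <- out$n_bars_resid
  out2 <- residualize(df2, columns = "n_bars")
  expect_equal(out2$n_bars_resid, out$n_bars_resid, tolerance = 1e-10)
})

test_that("degenerate allometry inputs are rejected", {
  df <- make_sl_table()
  df$standard_length_cm <- 4.2
  expect_error(residualize(df, columns = "n_bars"), "zero variance")
  df2 <- make_sl_table()[1:2, ]
  expect_error(residualize(df2, columns = "n_bars"), "fewer than 3")
})

test_that("missing traits or lengths give missing residuals without breaking the fit", {
  df <- make_sl_table()
  df$n_bars[c(3, 9)] <- NA
  df$standard_length_cm[5] <- NA
  out <- residualize(df, columns = "n_bars")
  expect_true(all(is.na(out$n_bars_resid[c(3, 5, 9)])))
  expect_true(all(!is.na(out$n_bars_resid[-c(3, 5, 9)])))
})

test_that("group comparison handles degenerate and two-group cases", {
  # identical constant data: F = 0, p = 1
  gc <- group_compare(rep(5, 30), rep(c("a", "b", "c"), each = 10))
  expect_equal(gc$f, 0)
  expect_equal(gc$p, 1)
  expect_true(all(gc$tukey$p_adj == 1))

  # two groups: the single Tukey contrast reproduces the ANOVA p
  set.seed(12)
  v <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  gc2 <- group_compare(v, g)
  expect_equal(gc2$tukey$p_adj, gc2$p, tolerance = 1e-6)

  expect_error(group_compare(rnorm(3), c("a", "a", "b")), "at least 2")
  expect_error(group_compare(rnorm(10), rep("a", 10)), "2 groups")
})

test_that("the ANOVA rejects at its nominal level under the null", {
  set.seed(99)
  rej <- mean(replicate(2000, {
    group_compare(rnorm(30), rep(c("a", "b", "c"), each = 10))$p < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("trait correlations behave like Pearson r", {
  set.seed(41)
  n <- 300
  df <- data.frame(id = as.character(1:n), group = "F2",
                   standard_length_cm = runif(n, 3, 6),
                   stringsAsFactors = FALSE)
  for (tr in c("n_bars", "range_intensity", "percent_barring",
               "avg_bar_width_cm")) df[[tr]] <- rnorm(n)
  cm <- trait_correlations(df, use_residuals = FALSE)
  expect_equal(unname(diag(cm$r)), rep(1, ncol(cm$r)))
  # independent traits: small correlations
  off <- cm$r[upper.tri(cm$r)]
  expect_gt(mean(abs(off) < 0.2, na.rm = TRUE), 0.9)
  # affine invariance
  df2 <- df
  df2$n_bars <- 3 * df$n_bars + 7
  cm2 <- trait_correlations(df2, use_residuals = FALSE)
  expect_equal(cm2$r, cm$r, tolerance = 1e-12)
  # degenerate trait warns and yields missing cells
  df3 <- df
  df3$n_bars <- 1
  expect_warning(cm3 <- trait_correlations(df3, use_residuals = FALSE),
                 "zero-variance")
  expect_true(is.na(cm3$r["n_bars", "range_intensity"]))
})

test_that("correlations use residual traits except against standard length", {
  set.seed(42)
  n <- 200
  sl <- runif(n, 3, 6)
  df <- data.frame(id = as.character(1:n), group = "F2",
                   standard_length_cm = sl,
                   n_bars = 5 * sl + rnorm(n),
                   range_intensity = -2 * sl + rnorm(n),
                   stringsAsFactors = FALSE)
  df <- residualize(df, columns = c("n_bars", "range_intensity"))
  cm <- trait_correlations(df)
  # trait-vs-trait on residuals: the shared size signal is gone
  expect_lt(abs(cm$r["n_bars", "range_intensity"]), 0.25)
  # trait-vs-length on raw values: the allometry is visible
  expect_gt(cm$r["n_bars", "standard_length_cm"], 0.9)
  expect_lt(cm$r["range_intensity", "standard_length_cm"], -0.85)
})
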