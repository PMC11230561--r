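make_test_cross <- function(n = 150, seed = 1, qtl = NULL, ...) {
  map <- sim_map(3, 10, 10)
  cr <- simulate_f2_cross(map, n, qtl = qtl, seed = seed, ...)
  gp <- genotype_probabilities(cr, step_cM = 5, error_rate = 0)
  list(cr = cr, gp = gp)
}

test_that("Haley-Knott LOD equals the regression oracle at typed markers", {
  tc <- make_test_cross(n = 150, seed = 21, qtl = data.frame(
    lg = "2", pos_cM = 40, trait = "y", a = 0.6, d = 0.3))
  sc <- scan_hk(tc$gp, tc$cr$pheno$y)
  at_marker <- !is.na(sc$marker)
  for (i in which(at_marker)) {
    want <- oracle_marker_lod(tc$cr$pheno$y, tc$cr$geno[, sc$marker[i]])
    expect_equal(sc$lod[i], want, tolerance = 1e-8)
  }
})

test_that("the LOD curve is invariant to affine phenotype transforms", {
  tc <- make_test_cross(seed = 22)
  y <- tc$cr$pheno$pheno
  s1 <- scan_hk(tc$gp, y)
  s2 <- scan_hk(tc$gp, 3 * y + 7)
  expect_equal(s2$lod, s1$lod, tolerance = 1e-9)
})

test_that("LOD is non-negative and missing phenotypes are dropped", {
  tc <- make_test_cross(seed = 23)
  y <- tc$cr$pheno$pheno
  y[1:5] <- NA
  sc <- scan_hk(tc$gp, y)
  expect_true(all(sc$lod >= 0))
  expect_equal(attr(sc, "n"), 145L)
  expect_error(scan_hk(tc$gp, rep(1, 150)), "zero variance")
  expect_error(scan_hk(tc$gp, c(y[1:12], rep(NA, 138))), "at least 10")
})

test_that("a strong planted QTL is found on its linkage group", {
  set.seed(24)
  hits <- 0
  for (i in 1:25) {
    tc <- make_test_cross(n = 250, seed = 300 + i, qtl = data.frame(
      lg = "2", pos_cM = 35, trait = "y", a = sqrt(0.5), d = 0))
    sc <- scan_hk(tc$gp, tc$cr$pheno$y)
    if (sc$lg[which.max(sc$lod)] == "2") hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("permutation thresholds are ordered, seeded, and stable", {
  tc <- make_test_cross(seed = 25)
  y <- tc$cr$pheno$pheno
  t1 <- permutation_thresholds(tc$gp, y, n_perm = 200, seed = 9)
  t2 <- permutation_thresholds(tc$gp, y, n_perm = 200, seed = 9)
  expect_identical(t1, t2)
  expect_gte(t1[["5%"]], t1[["10%"]])
  # threshold grows as alpha shrinks
  t3 <- permutation_thresholds(tc$gp, y, n_perm = 200,
                               alphas = c(0.01, 0.05, 0.2), seed = 9)
  expect_true(all(diff(unname(t3)) <= 0))
  # stability across seeds at 1000 permutations
  a <- permutation_thresholds(tc$gp, y, n_perm = 1000, seed = 1)
  b <- permutation_thresholds(tc$gp, y, n_perm = 1000, seed = 2)
  expect_lt(abs(a[[1]] - b[[1]]), 0.2)
  expect_error(permutation_thresholds(tc$gp, y, n_perm = 50), "100")
})

test_that("PVE matches the oracle regression R-squared at the peak marker", {
  tc <- make_test_cross(n = 200, seed = 26, qtl = data.frame(
    lg = "1", pos_cM = 50, trait = "y", a = 0.7, d = 0))
  sc <- scan_hk(tc$gp, tc$cr$pheno$y)
  mk <- sc[!is.na(sc$marker), ]
  i <- which.max(mk$lod)
  want <- 100 * oracle_marker_r2(tc$cr$pheno$y, tc$cr$geno[, mk$marker[i]])
  expect_equal(pve(mk$lod[i], attr(sc, "n")), want, tolerance = 1e-6)
  expect_equal(pve(0, 100), 0)
  expect_true(all(diff(pve(seq(0, 10, 0.5), 100)) > 0))
  expect_error(pve(-1, 100), "non-negative")
})

test_that("allelic effects follow the genotype class means", {
  g <- rep(1:3, each = 4)
  eff <- qtl_effects(g, rep(c(10, 15, 20), each = 4))
  expect_equal(unname(eff$a), 5)
  expect_equal(unname(eff$d), 0)
  # underdominance direction
  eff2 <- qtl_effects(g, rep(c(10, 20, 10), each = 4))
  expect_equal(unname(eff2$a), 0)
  expect_equal(unname(eff2$d), 10)
  # label swap negates a, keeps d
  eff3 <- qtl_effects(4L - g, rep(c(10, 15, 20), each = 4))
  expect_equal(unname(eff3$a), -5)
  expect_equal(unname(eff3$d), 0)
  # empty class warns and yields missing effects
  expect_warning(eff4 <- qtl_effects(c(1, 1, 2, 2), c(1, 2, 3, 4)), "empty")
  expect_true(is.na(eff4$a))
})

test_that("Bayes intervals cover the peak and respect the coverage knob", {
  tc <- make_test_cross(n = 200, seed = 27, qtl = data.frame(
    lg = "2", pos_cM = 45, trait = "y", a = 0.8, d = 0))
  sc <- scan_hk(tc$gp, tc$cr$pheno$y)
  ci <- bayes_interval(sc, "2")
  pk <- attr(ci, "peak_cM")
  expect_lte(ci[1], pk)
  expect_gte(ci[2], pk)
  # coverage 1: the whole group
  ci1 <- bayes_interval(sc, "2", coverage = 1)
  s2 <- sc[sc$lg == "2", ]
  expect_equal(as.vector(ci1), range(s2$pos_cM))
  expect_error(bayes_interval(sc, "2", coverage = 1.5), "coverage")

  # a single dominant spike collapses the interval to one grid step
  fake <- sc[sc$lg == "1", ]
  fake$lod <- 0
  fake$lod[7] <- 20
  ci2 <- bayes_interval(fake, "1")
  expect_equal(as.vector(ci2), rep(fake$pos_cM[7], 2))
})

test_that("flanking markers are reported alongside interval endpoints", {
  tc <- make_test_cross(n = 200, seed = 28, qtl = data.frame(
    lg = "3", pos_cM = 50, trait = "y", a = 0.7, d = 0))
  sc <- scan_hk(tc$gp, tc$cr$pheno$y)
  ci <- bayes_interval(sc, "3")
  fl <- attr(ci, "flank_markers")
  expect_length(fl, 2L)
  expect_true(all(fl %in% tc$cr$map$marker))
})
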