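test_that("the Haldane map function matches its closed form", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_gt(haldane_r(1000), 0.4999)
  expect_error(haldane_r(-1), "non-negative")
  # composition over three loci: r13 = r12(1 - r23) + r23(1 - r12)
  for (d in list(c(5, 12), c(20, 20), c(1, 80))) {
    r12 <- haldane_r(d[1]); r23 <- haldane_r(d[2])
    expect_equal(haldane_r(sum(d)), r12 * (1 - r23) + r23 * (1 - r12),
                 tolerance = 1e-12)
  }
})

test_that("linkage map validation catches malformed maps", {
  expect_error(linkage_map(c("a", "a"), c("1", "1"), c(0, 5)), "unique")
  expect_error(linkage_map("a", "1", -2), "non-negative")
  m <- sim_map(2, 5, 10)
  expect_equal(nrow(m), 10L)
  expect_true(all(tapply(m$pos_cM, m$lg, function(p) !is.unsorted(p))))
})

test_that("cross CSV dialect round-trips exactly", {
  map <- sim_map(2, 6, 8)
  cr <- simulate_f2_cross(map, 25, qtl = data.frame(
    lg = "1", pos_cM = 16, trait = "y", a = 1, d = 0.5),
    missing_rate = 0.1, seed = 4)
  cr$pheno$y[3] <- NA  # a missing phenotype cell
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_csv(cr, path)
  back <- read_cross_csv(path)
  expect_identical(back$geno, cr$geno)
  expect_equal(back$map$marker, cr$map$marker)
  expect_equal(back$map$lg, cr$map$lg)
  expect_equal(back$map$pos_cM, cr$map$pos_cM)
  expect_equal(back$pheno$y, cr$pheno$y)
  expect_equal(back$pheno$standard_length_cm, cr$pheno$standard_length_cm)
  expect_equal(back$pheno$id, cr$pheno$id)

  # genotype codes on disk are the A/H/B/- dialect
  row4 <- strsplit(readLines(path)[4], ",")[[1]]
  expect_true(all(row4[-(1:3)] %in% c("A", "H", "B", "-")))

  expect_error(read_cross_csv("no/such/file.csv"), "not found")
})

test_that("segregation QC flags distorted markers and keeps clean ones", {
  g <- matrix(c(rep(1L, 25), rep(2L, 50), rep(3L, 25)), ncol = 1)
  colnames(g) <- "m1"
  qc <- segregation_qc(g)
  expect_equal(qc$chisq, 0)
  expect_equal(qc$p, 1)
  expect_true(qc$keep)

  # maximal distortion is always dropped
  g2 <- cbind(m1 = rep(1L, 100), m2 = c(rep(1L, 25), rep(2L, 50), rep(3L, 25)))
  qc2 <- segregation_qc(g2)
  expect_false(qc2$keep[qc2$marker == "m1"])
  expect_true(qc2$keep[qc2$marker == "m2"])

  # all-missing marker: untestable, kept, with a warning
  g3 <- cbind(m1 = rep(NA_integer_, 50), m2 = rep(c(1L, 2L, 2L, 3L), 13)[1:50])
  expect_warning(qc3 <- segregation_qc(g3), "untestable")
  expect_true(qc3$keep[qc3$marker == "m1"])
})

test_that("a clean simulated cross keeps nearly all markers", {
  map <- sim_map(5, 100, 2)
  cr <- simulate_f2_cross(map, 200, seed = 6)
  qc <- segregation_qc(cr)
  expect_gte(mean(qc$keep), 0.95)
})

test_that("adjacent markers 0 cM apart carry identical genotypes", {
  map <- linkage_map(c("a", "b", "c"), "1", c(0, 0, 25))
  cr <- simulate_f2_cross(map, 300, seed = 7)
  expect_identical(cr$geno[, "a"], cr$geno[, "b"])
  expect_false(identical(cr$geno[, "a"], cr$geno[, "c"]))
})

test_that("single-marker segregation is 1:2:1", {
  map <- linkage_map("m", "1", 0)
  cr <- simulate_f2_cross(map, 4000, seed = 8)
  counts <- tabulate(cr$geno[, 1], 3)
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.01)
})

test_that("empirical recombination matches the Haldane fraction at 20 cM", {
  map <- linkage_map(c("L", "R"), "1", c(0, 20))
  cr <- simulate_f2_cross(map, 5000, seed = 9)
  g1 <- cr$geno[, "L"]; g2 <- cr$geno[, "R"]
  # homozygotes at the left locus have two gametes of known allele; the
  # B-allele (or A-allele) dose at the right locus counts recombinant gametes
  rec <- sum(g2[g1 == 1L] - 1L) + sum(3L - g2[g1 == 3L])
  gametes <- 2 * sum(g1 %in% c(1L, 3L))
  r_hat <- rec / gametes
  r_true <- (1 - exp(-0.4)) / 2
  se <- sqrt(r_true * (1 - r_true) / gametes)
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("null crosses have no marker-phenotype correlation beyond noise", {
  map <- sim_map(2, 15, 10)
  cr <- simulate_f2_cross(map, 400, qtl = NULL, allometry_slope = 0, seed = 10)
  rs <- apply(cr$geno, 2, function(g) abs(cor(g, cr$pheno$pheno)))
  # null envelope for n = 400 over 30 markers
  expect_lt(max(rs), 4 / sqrt(400))
})

test_that("cross simulation is deterministic and validates planted QTL", {
  map <- sim_map(2, 10, 10)
  a <- simulate_f2_cross(map, 50, seed = 11)
  b <- simulate_f2_cross(map, 50, seed = 11)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
  expect_error(simulate_f2_cross(map, 50, qtl = data.frame(
    lg = "9", pos_cM = 5, trait = "y", a = 1, d = 0)), "absent")
  expect_error(simulate_f2_cross(map, 50, qtl = data.frame(
    lg = "1", pos_cM = 500, trait = "y", a = 1, d = 0)), "outside")
})

test_that("planted effects shift genotype class means as coded", {
  map <- sim_map(1, 5, 10)
  cr <- simulate_f2_cross(map, 3000, qtl = data.frame(
    lg = "1", pos_cM = 20, trait = "y", a = 2, d = 1),
    residual_sd = 0.5, seed = 12)
  g <- cr$geno[, "M1_03"]
  mAA <- mean(cr$pheno$y[g == 1]); mAB <- mean(cr$pheno$y[g == 2])
  mBB <- mean(cr$pheno$y[g == 3])
  expect_equal((mBB - mAA) / 2, 2, tolerance = 0.1)
  expect_equal(mAB - (mAA + mBB) / 2, 1, tolerance = 0.1)
})

test_that("missing-genotype masking hits the requested rate", {
  map <- sim_map(2, 20, 5)
  cr <- simulate_f2_cross(map, 300, missing_rate = 0.15, seed = 13)
  expect_lt(abs(mean(is.na(cr$geno)) - 0.15), 0.02)
})
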