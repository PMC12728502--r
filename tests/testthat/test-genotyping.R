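test_that("a fully homozygous sample has F_IS exactly 1", {
  gt <- cbind(c(0L, 2L, 0L, 2L, 0L, 2L),
              c(1L, 1L, 0L, 1L, 1L, 0L),
              c(0L, 1L, 1L, 2L, 0L, 1L),
              c(1L, 0L, 1L, 1L, 2L, 1L))
  gm <- make_gm(gt)
  expect_equal(unname(compute_fis(gm, "s01")), 1)
})

test_that("F_IS matches the spreadsheet-style oracle on a hand-built 4x6 matrix", {
  gt <- cbind(c(0L, 1L, 2L, NA, 0L, 1L),
              c(1L, 1L, 1L, 1L, 0L, 0L),
              c(0L, 0L, 2L, 2L, NA, 1L),
              c(2L, 1L, 0L, 1L, 1L, 2L))
  gm <- make_gm(gt)
  f <- compute_fis(gm)
  for (s in gm$samples) {
    expect_equal(unname(f[s]), naive_fis(gm, s), tolerance = 1e-12,
                 info = s)
  }
})

test_that("F_IS matches the brute-force oracle on random 5x10 matrices", {
  for (s in 1:20) {
    gm <- random_gm(10, 5, miss = runif(1, 0, 0.3), seed = 300 + s)
    f <- suppressWarnings(compute_fis(gm))
    for (id in gm$samples) {
      expect_equal(unname(f[id]), naive_fis(gm, id), tolerance = 1e-12,
                   info = paste(300 + s, id))
    }
  }
})

test_that("simulated M/P workers fall below -0.5 and M/M workers above", {
  co <- simulate_cohort(small_cohort_config(seed = 30L))
  f <- compute_fis(filter_sites(co$gm))
  cls <- co$truth$classes[names(f)]
  expect_true(all(f[cls == "MP"] < -0.5))
  expect_true(all(f[cls == "MM"] > -0.5))
})

test_that("the F_IS carrier threshold is strict", {
  fis <- c(a = -0.5, b = -0.51, c = 0.2, d = -0.4999)
  expect_identical(classify_by_fis(fis), "b")
})

test_that("window tiling puts boundary sites in the stated windows", {
  gt <- matrix(1L, 3, 2)
  gm <- make_gm(gt, pos = c(1L, 20000L, 20001L))
  scan <- window_het_scan(gm, "s01", window_size = 20000L)
  expect_identical(scan$counts[, "s01"], c(2L, 1L))
  expect_identical(scan$window_start, c(1L, 20001L))
  ## zero het sites -> all-zero profile
  gm0 <- make_gm(matrix(0L, 3, 2), pos = c(1L, 20000L, 20001L))
  scan0 <- window_het_scan(gm0, "s01", window_size = 20000L)
  expect_true(all(scan0$mean == 0))
  expect_error(window_het_scan(gm, "s01", window_size = 0), "positive")
})

make_scan <- function(values, w = 20000L) {
  structure(list(chrom = "chr1", window_size = w,
                 window_start = (seq_along(values) - 1L) * w + 1L,
                 window_end = seq_along(values) * w,
                 counts = matrix(values, ncol = 1), mean = values),
            class = "region_scan")
}

test_that("delimitation recovers a planted plateau and obeys the longest-run rule", {
  v <- rep(2, 300); v[101:200] <- 20    # 100-window plateau at 10x background
  reg <- delimit_region(make_scan(v))
  expect_equal(reg, c(100 * 20000 + 1, 200 * 20000))
  ## flat profile -> empty with warning
  expect_warning(reg0 <- delimit_region(make_scan(rep(3, 100))), "empty")
  expect_length(reg0, 0)
  ## two plateaus, lengths 50 and 10 -> the longer one wins
  v2 <- rep(1, 200); v2[21:70] <- 30; v2[150:159] <- 30
  reg2 <- delimit_region(make_scan(v2))
  expect_equal(reg2, c(20 * 20000 + 1, 70 * 20000))
})

test_that("region recovery is window-exact on simulated cohorts", {
  co <- simulate_cohort(small_cohort_config(seed = 31L))
  mp <- names(co$truth$classes)[co$truth$classes == "MP"]
  scan <- window_het_scan(filter_sites(co$gm), mp, 20000L,
                          co$config$chrom_length)
  reg <- delimit_region(scan)
  expect_lte(abs(reg[1] - co$truth$region[1]), 20000L)
  expect_lte(abs(reg[2] - co$truth$region[2]), 20000L)
})

test_that("trans-specific extraction enforces the strict missingness bound", {
  ## 5 carriers; site 2 has exactly 20% carriers missing -> removed
  gt <- rbind(rep(1L, 5),
              c(1L, 1L, 1L, 1L, NA),
              c(1L, 1L, 1L, NA, NA),
              c(1L, 1L, 1L, 1L, 0L),
              rep(2L, 5))
  gm <- make_gm(gt)
  hs <- extract_trans_specific(gm, gm$samples, max_missing = 0.2)
  expect_identical(hs$positions, gm$pos[1])
  ## and is invariant under permutation of sample order
  perm <- sample(ncol(gm$gt))
  gmp <- gm_subset(gm, samples = perm)
  expect_identical(extract_trans_specific(gmp, gmp$samples)$positions,
                   hs$positions)
  expect_error(extract_trans_specific(gm, character(0)), "empty")
})

test_that("extraction equals planted truth exactly on a clean cohort", {
  co <- simulate_cohort(small_cohort_config(seed = 32L,
                                            genotype_error_rate = 0,
                                            missing_rate = 0))
  mp <- names(co$truth$classes)[co$truth$classes == "MP"]
  hs <- extract_trans_specific(co$gm, mp)
  expect_identical(hs$positions, co$truth$hset_pos)
})

test_that("proportion-based assignment follows the majority rule", {
  ## 100 hset sites: 97 ref-hom, 2 het, 1 alt-hom -> MM for a diploid
  gt <- matrix(c(rep(0L, 97), 1L, 1L, 2L), ncol = 1)
  gm <- make_gm(cbind(gt, gt), samples = c("x", "y"))
  hs <- structure(list(positions = gm$pos, carriers = "y",
                       max_missing = 0.2),
                  class = "haplotype_specific_set")
  call <- classify_by_proportions(gm, hs, "x", ploidy = 2L)
  expect_identical(call$assigned_class, "MM")
  expect_equal(call$p00, 0.97)
  ## haploid with p11 ~ 1 -> hapP
  gt2 <- matrix(c(rep(2L, 96), rep(0L, 4)), ncol = 1)
  gm2 <- make_gm(cbind(gt2, gt2), samples = c("x", "y"))
  hs2 <- structure(list(positions = gm2$pos, carriers = "y",
                        max_missing = 0.2),
                   class = "haplotype_specific_set")
  expect_identical(classify_by_proportions(gm2, hs2, "x", 1L)$assigned_class,
                   "hapP")
  ## haploid with heterozygous majority -> hapP with duplication flag
  gt3 <- matrix(c(rep(1L, 95), rep(0L, 5)), ncol = 1)
  gm3 <- make_gm(cbind(gt3, gt3), samples = c("x", "y"))
  hs3 <- structure(list(positions = gm3$pos, carriers = "y",
                        max_missing = 0.2),
                   class = "haplotype_specific_set")
  call3 <- classify_by_proportions(gm3, hs3, "x", 1L)
  expect_identical(call3$assigned_class, "hapP")
  expect_true(call3$dup_flag)
  ## mostly-missing sample -> ambiguous with a reason
  gt4 <- matrix(c(rep(NA, 60), rep(0L, 40)), ncol = 1)
  gm4 <- make_gm(cbind(gt4, gt4), samples = c("x", "y"))
  hs4 <- structure(list(positions = gm4$pos, carriers = "y",
                        max_missing = 0.2),
                   class = "haplotype_specific_set")
  call4 <- classify_by_proportions(gm4, hs4, "x", 2L)
  expect_identical(call4$assigned_class, "ambiguous")
  expect_match(call4$reason, "missing")
})

test_that("the full genotyping stage recovers every planted class", {
  co <- simulate_cohort(small_cohort_config(seed = 33L))
  sg <- genotype_after_qc(co)
  truth <- co$truth$classes[sg$calls$sample_id]
  expect_identical(unname(truth), sg$calls$assigned_class)
  ## F_IS carriers and proportion-based MP agree on diploids
  prop_mp <- sg$calls$sample_id[sg$calls$p01 > 0.8 & sg$calls$ploidy == 2]
  expect_setequal(prop_mp, sg$carriers)
  ## S3 surface
  expect_s3_class(sg, "supergene_calls")
  expect_output(print(sg), "M/P carriers")
  expect_output(print(summary(sg)), "classes by species")
  expect_identical(as.data.frame(sg), sg$calls)
})

test_that("no P/P diploid call arises when none was planted", {
  st <- default_species_table()
  st$PP <- 0L
  for (s in 1:5) {
    co <- simulate_cohort(small_cohort_config(seed = 400 + s,
                                              species_table = st,
                                              load = FALSE))
    sg <- genotype_after_qc(co)
    expect_false(any(sg$calls$assigned_class == "PP"))
  }
})
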