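test_that("each site rule removes exactly the sites it should (12-site toy)", {
  ## 12 sites, 10 samples; one rule violated per site, plus passing sites
  n <- 10L
  th <- filter_thresholds()
  pass_het <- c(rep(1L, 5), rep(0L, 2), rep(2L, 3))       # ac 11, mac 9
  gt <- rbind(
    pass_het,                                             # 1 keep
    pass_het,                                             # 2 low QUAL
    c(rep(1L, 4), rep(0L, 6)),                            # 3 ac 4 < 5
    c(rep(1L, 5), rep(0L, 5)),                            # 4 ac 5 keep
    c(rep(2L, 8), 1L, 0L),                                # 5 mac 3 < 5
    c(rep(1L, 5), rep(NA, 5)),                            # 6 missing 50% > 40%
    c(rep(1L, 10)),                                       # 7 het 100% > 90%
    c(rep(1L, 9), 0L),                                    # 8 het 90% keep
    pass_het,                                             # 9 low-depth -> missing
    c(rep(1L, 6), rep(0L, 4)),                            # 10 keep
    pass_het,                                             # 11 multiallelic
    pass_het                                              # 12 not a SNP
  )
  qual <- rep(50, 12); qual[2] <- 19
  dp <- matrix(20L, 12, n); dp[9, ] <- 2L
  alt <- rep("G", 12); alt[11] <- "G,T"
  ref <- rep("A", 12); ref[12] <- "AT"
  gm <- make_gm(gt, dp = dp, qual = qual, ref = ref, alt = alt)

  out <- filter_sites(gm, th)
  expect_identical(out$pos, gm$pos[c(1, 4, 8, 10)])
  ## independent per-rule brute-force checker agrees
  expect_identical(out$pos, gm$pos[naive_filter_sites(gm, th)])
  rep <- attr(out, "qc_report")
  expect_identical(rep$low_qual, 1L)
  expect_identical(rep$not_biallelic_snp, 2L)
  expect_identical(rep$excess_heterozygosity, 1L)
})

test_that("threshold boundaries behave as specified", {
  n <- 20L
  base <- c(rep(1L, 10), rep(0L, 5), rep(2L, 5))
  ## QUAL 19 removed, 20 kept
  gm <- make_gm(rbind(base, base), qual = c(19, 20))
  out <- filter_sites(gm, filter_thresholds())
  expect_identical(out$pos, gm$pos[2])
  ## het in 91% of samples removed, 90% kept (strict >90%)
  n <- 100L
  het91 <- c(rep(1L, 91), rep(0L, 5), rep(2L, 4))
  het90 <- c(rep(1L, 90), rep(0L, 6), rep(2L, 4))
  gm <- make_gm(rbind(het91, het90))
  out <- filter_sites(gm, filter_thresholds())
  expect_identical(out$pos, gm$pos[2])
})

test_that("samples missing at exactly 10% of sites are excluded (inclusive bound)", {
  gt <- matrix(1L, 20, 4)
  gt[1:2, 2] <- NA          # exactly 10%
  gt[1, 3] <- NA            # 5%
  gt[1:9, 4] <- NA          # 45%
  gt[, 1] <- c(rep(0L, 8), rep(2L, 6), rep(1L, 6))
  gm <- make_gm(gt)
  th <- filter_thresholds(min_nonref_allele_count = 0,
                          min_minor_allele_count = 0,
                          min_nonmissing_fraction = 0,
                          max_het_sample_fraction = 1)
  fs <- filter_samples(gm, th)
  expect_identical(fs$excluded, c("s02", "s04"))
  expect_identical(fs$gm$samples, c("s01", "s03"))
  ## complete samples: identity
  gm2 <- make_gm(matrix(1L, 5, 3))
  fs2 <- filter_samples(gm2, filter_thresholds())
  expect_identical(fs2$gm$gt, gm2$gt)
  expect_identical(fs2$excluded, character(0))
})

test_that("a planted high-missingness sample is the only one excluded from a simulated cohort", {
  cfg <- small_cohort_config(seed = 20L, load = FALSE)
  n_samp <- sum(cfg$species_table$MM, cfg$species_table$MP,
                cfg$species_table$PP, cfg$species_table$hapM,
                cfg$species_table$hapP)
  rates <- rep(0, n_samp); rates[7] <- 0.2
  co <- simulate_cohort(small_cohort_config(seed = 20L, load = FALSE,
                                            missing_rate = rates))
  fs <- filter_samples(co$gm, filter_thresholds())
  expect_identical(fs$excluded, co$meta$id[7])
})

test_that("site filtering is idempotent and matches the oracle on random matrices", {
  th <- filter_thresholds()
  for (s in 1:25) {
    gm <- random_gm(n_sites = sample(1:20, 1), n_samples = sample(4:12, 1),
                    miss = runif(1, 0, 0.4), seed = 1000 + s)
    once <- filter_sites(gm, th)
    twice <- filter_sites(once, th)
    expect_identical(twice$pos, once$pos)
    expect_identical(twice$gt, once$gt)
    expect_identical(once$pos, gm$pos[naive_filter_sites(gm, th)],
                     info = paste("seed", 1000 + s))
    expect_identical(filter_samples(once, th)$excluded,
                     naive_filter_samples(once, th))
  }
})

test_that("tightening any single threshold never grows the survivor set", {
  gm <- random_gm(60, 10, miss = 0.25, seed = 77)
  th <- filter_thresholds()
  base <- filter_sites(gm, th)$pos
  tighter <- list(
    filter_thresholds(min_site_qual = 40),
    filter_thresholds(min_genotype_depth = 10),
    filter_thresholds(min_nonref_allele_count = 8),
    filter_thresholds(min_minor_allele_count = 8),
    filter_thresholds(min_nonmissing_fraction = 0.8),
    filter_thresholds(max_het_sample_fraction = 0.5)
  )
  for (t2 in tighter) {
    expect_true(all(filter_sites(gm, t2)$pos %in% base))
  }
})

test_that("degenerate inputs are handled", {
  ## empty input -> empty output, not an error
  gm <- make_gm(matrix(integer(0), 0, 3))
  out <- filter_sites(gm, filter_thresholds())
  expect_identical(nrow(out$gt), 0L)
  ## matrix lacking depth errors naming the field
  expect_error(genotype_matrix(matrix(1L, 2, 2), dp = NULL, "c", c(1L, 2L),
                               c("A", "A"), c("G", "G"), c(50, 50),
                               c("a", "b")),
               "dp")
})
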