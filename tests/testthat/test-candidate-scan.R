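## shared small cohort for scan tests: clean genotypes, planted duplication
scan_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      co <<- simulate_cohort(small_cohort_config(seed = 50L,
                                                 genotype_error_rate = 0,
                                                 missing_rate = 0))
    }
    co
  }
})

truth_hset <- function(co) {
  structure(list(positions = co$truth$hset_pos,
                 carriers = names(co$truth$classes)[co$truth$classes == "MP"],
                 max_missing = 0.2),
            class = "haplotype_specific_set")
}

test_that("P-specific counts are zero for an all-reference sample and conserved overall", {
  co <- scan_cohort()
  hs <- truth_hset(co)
  counts <- count_p_specific(co$gm, hs, co$genes)
  ## a non-carrier M/M worker of a socially polymorphic species: all zero
  cls <- co$truth$classes
  sp_mm <- setdiff(names(cls)[cls == "MM"], co$truth$dup_carriers)
  sp_mm <- sp_mm[grepl("lugubris|pratensis|rufa", sp_mm)][1]
  expect_true(all(counts[, sp_mm] == 0L))
  ## conservation: column sums equal the direct per-sample total
  idx <- supergeneR:::build_cds_index(co$genes)
  cds_sites <- hs$positions[hs$positions %in% idx$site$pos]
  g <- co$gm$gt[match(cds_sites, co$gm$pos), , drop = FALSE]
  direct <- colSums(!is.na(g) & g >= 1L)
  expect_identical(unname(colSums(counts)), unname(direct))
})

test_that("a dup-block carrier M/M worker scores only at the two planted genes", {
  co <- scan_cohort()
  hs <- truth_hset(co)
  cls <- co$truth$classes
  op_mm <- intersect(names(cls)[cls == "MM"], co$truth$dup_carriers)[1]
  counts <- count_p_specific(co$gm, hs, co$genes, samples = op_mm)
  nz <- rownames(counts)[counts[, 1] > 0]
  expect_setequal(nz, co$truth$dup_genes)
  expect_identical(unname(counts[co$truth$dup_genes, 1]),
                   co$config$dup_block$n_pseudo_het_sites)
})

test_that("the group contrast matches the pooled-t formula and stats::t.test", {
  x <- c(20.4, 21.9, 19.7); y <- c(0.4, 1.1, 0.2)
  counts <- matrix(c(x, y), nrow = 1,
                   dimnames = list("g1", letters[1:6]))
  attr(counts, "n_sites") <- c(g1 = 10L)
  species <- letters[1:6]
  form <- setNames(c("OP", "OP", "OP", "SP", "SP", "SP"), species)
  res <- contrast_groups(counts, species, form, n_tests = 1)
  ## brute-force pooled t
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 4
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)
  ## the established implementation agrees
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("Bonferroni over 283 tests sends raw p = 0.026 to 1, and never lowers p", {
  ## construct species means whose pooled t gives p ~ 0.026, then adjust
  counts <- matrix(c(3.457, 2, 2.543, 1, 0, -1) + 10, nrow = 1,
                   dimnames = list("g1", letters[1:6]))
  attr(counts, "n_sites") <- c(g1 = 27L)
  form <- setNames(c("OP", "OP", "OP", "SP", "SP", "SP"), letters[1:6])
  res <- contrast_groups(counts, letters[1:6], form, n_tests = 283)
  expect_lt(res$p, 0.05)
  expect_identical(res$p_adj, 1)
  expect_gte(res$p_adj, res$p)
})

test_that("degenerate groups give t = 0, p = 1 on equal means", {
  counts <- matrix(rep(5, 6), nrow = 1, dimnames = list("g1", letters[1:6]))
  attr(counts, "n_sites") <- c(g1 = 3L)
  form <- setNames(c("OP", "OP", "OP", "SP", "SP", "SP"), letters[1:6])
  res <- contrast_groups(counts, letters[1:6], form, n_tests = 1)
  expect_identical(res$t, 0)
  expect_identical(res$p, 1)
})

test_that("gene order does not change the p-values", {
  co <- scan_cohort()
  hs <- truth_hset(co)
  cls <- co$truth$classes
  mm <- names(cls)[cls == "MM"]
  counts <- count_p_specific(co$gm, hs, co$genes, samples = mm)
  sf <- setNames(co$meta$social_form, co$meta$species)
  sf <- sf[!duplicated(names(sf))]
  species <- co$meta$species[match(mm, co$meta$id)]
  res1 <- contrast_groups(counts, species, sf)
  perm <- sample(nrow(counts))
  counts2 <- counts[perm, , drop = FALSE]
  attr(counts2, "n_sites") <- attr(counts, "n_sites")[perm]
  res2 <- contrast_groups(counts2, species, sf)
  expect_equal(res2$p[match(res1$gene_id, res2$gene_id)], res1$p)
})

test_that("depth normalization fixes every sample mean at exactly 1", {
  co <- scan_cohort()
  nd <- normalize_depth(co$depth)
  expect_equal(unname(colMeans(nd$values)),
               rep(1, ncol(nd$values)), tolerance = 1e-12)
  ## constant-depth sample -> all values 1; a doubled gene -> 2 vs 1
  parts <- data.frame(part_id = c("a", "b", "c"),
                      gene_id = c("g1", "g2", "g3"),
                      start = c(1L, 100L, 200L), end = c(50L, 150L, 250L))
  vals <- matrix(30, 3, 2, dimnames = list(parts$part_id, c("s1", "s2")))
  vals[2, 2] <- 60
  d <- structure(list(values = vals, parts = parts), class = "cds_depth")
  nd2 <- normalize_depth(d)
  expect_equal(unname(nd2$values[, "s1"]), rep(1, 3))
  expect_equal(unname(nd2$values[, "s2"]), c(0.75, 1.5, 0.75))
  expect_equal(unname(nd2$values[2, "s2"] / nd2$values[1, "s2"]), 2)
})

test_that("planted duplication depth is recovered near the multiplier", {
  co <- scan_cohort()
  nd <- normalize_depth(co$depth)
  gd <- gene_depth(nd)
  carrier <- co$meta$id %in% co$truth$dup_carriers
  ratio <- mean(gd[co$truth$dup_genes, carrier]) /
    mean(gd[co$truth$dup_genes, !carrier])
  ## normalization divides carriers by their own (dup-inflated) mean: with
  ## d of n CDS parts duplicated at multiplier m the expected ratio is
  ## m * n / (n + d (m - 1))
  mult <- co$config$dup_block$depth_multiplier
  n_parts <- nrow(co$depth$parts)
  d_parts <- sum(co$depth$parts$gene_id %in% co$truth$dup_genes)
  expected <- mult * n_parts / (n_parts + d_parts * (mult - 1))
  expect_lt(abs(ratio - expected) / expected, 0.1)
})

test_that("depth contrasts behave under null, planted effect and label swap", {
  set.seed(60)
  parts <- data.frame(part_id = paste0("p", 1:4),
                      gene_id = rep("g1", 4),
                      start = c(1L, 400L, 800L, 1200L),
                      end = c(300L, 700L, 1100L, 1500L))
  n <- 20
  ids <- c(paste0("mm", 1:n), paste0("mp", 1:n))
  ## null: identical distributions
  v0 <- matrix(rgamma(4 * 2 * n, 50, 50), 4,
               dimnames = list(parts$part_id, ids))
  d0 <- structure(list(values = v0, parts = parts), class = "cds_depth")
  r0 <- depth_contrast(d0, paste0("mm", 1:n), paste0("mp", 1:n))
  expect_gt(r0$p, 0.05)
  ## planted 1.5x in the MP group, small dispersion
  v1 <- v0
  v1[, paste0("mp", 1:n)] <- 1.5 * matrix(rgamma(4 * n, 400, 400), 4)
  d1 <- structure(list(values = v1, parts = parts), class = "cds_depth")
  r1 <- depth_contrast(d1, paste0("mm", 1:n), paste0("mp", 1:n))
  expect_lt(r1$p, 0.001)
  ## two-sided symmetry under label swap
  r1b <- depth_contrast(d1, paste0("mp", 1:n), paste0("mm", 1:n))
  expect_equal(r1$p, r1b$p, tolerance = 1e-12)
  expect_error(depth_contrast(d1, character(0), ids), "non-empty")
})

test_that("haploid pseudo-heterozygosity flags duplications and nothing else", {
  co <- scan_cohort()
  hs <- truth_hset(co)
  cls <- co$truth$classes
  males <- co$meta$id[co$meta$ploidy == 1L]
  ph <- haploid_pseudo_het(co$gm, hs, co$genes, males)
  hap_p <- males[cls[males] == "hapP"]
  hap_m <- males[cls[males] == "hapM"]
  ## P males are fully pseudo-het at both planted genes
  expect_true(all(ph$fractions[co$truth$dup_genes, hap_p] == 1))
  expect_true(all(ph$flags[co$truth$dup_genes, hap_p]))
  ## zero false flags anywhere else at error 0
  other <- setdiff(rownames(ph$flags), co$truth$dup_genes)
  expect_false(any(ph$flags[other, ]))
  expect_false(any(ph$flags[, hap_m]))
  ## a male hom-alt at every site of a gene has fraction 0, no flag
  expect_true(all(ph$fractions[other, hap_p] %in% c(0, NA)))
})

test_that("pairwise identity follows the stated gap policy", {
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("acgt", "ACGT"), 100)
  ## gap-vs-base is a mismatch, the column still counts
  expect_equal(pairwise_identity("AC-T", "ACGT"), 75)
  ## both-gap columns are dropped from the denominator
  expect_equal(pairwise_identity("AC--T", "AC--A"), 2 / 3 * 100)
  expect_error(pairwise_identity("ACG", "ACGT"), "equal length")
})

test_that("TPM follows the printed formula and the atlas cutoffs", {
  r <- tpm(10, 1000, 1e6)
  expect_equal(r$tpm, 0.01)
  expect_identical(r$expression_class, "below")
  expect_equal(tpm(0, 500, 1e6)$tpm, 0)
  ## doubling the library size halves every value
  counts <- c(g1 = 100, g2 = 5000, g3 = 0)
  lens <- c(1000, 2000, 1500)
  a <- tpm(counts, lens, 1e6)
  b <- tpm(counts, lens, 2e6)
  expect_equal(b$tpm, a$tpm / 2)
  ## class boundaries
  x <- tpm(c(0.4, 0.5, 10, 10.1, 1000, 1001), rep(1, 6), 1e6)
  expect_identical(x$expression_class,
                   c("below", "low", "low", "medium", "medium", "high"))
  expect_error(tpm(1, 0, 1e6), "positive")
  expect_error(tpm(1, 100, 0), "positive")
})
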