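test_that("site filter applies the median-depth window per sample", {
  # Dbar = 30: window is [9, 90]
  depth <- c(8L, 9L, 30L, 90L, 95L, 30L, 30L)
  snv <- snv_from_vectors(depth, rep(1L, 7), gene_id = c(rep("g1", 5), "g2", "g3"))
  expect_equal(unname(snv$median_depth), 30)
  filt <- filter_sites(snv, core = c("g1", "g2", "g3"), blacklist = "g3")
  expect_false("x00007" %in% filt$sites$site_id)      # blacklisted gene dropped
  d <- filt$depth[, 1]
  expect_identical(unname(d[c("x00001", "x00005")]), c(0L, 0L))  # 8 < 9, 95 > 90
  expect_identical(unname(d[c("x00002", "x00003", "x00004")]), c(9L, 30L, 90L))
  # non-core and high-copy genes dropped site-wise
  filt2 <- filter_sites(snv, core = "g1", high_copy = character())
  expect_true(all(filt2$sites$gene_id == "g1"))
})

test_that("sample filter uses the strict median-depth rule", {
  mk <- function(md) {
    s <- snv_from_vectors(rep(1L, 10), rep(0L, 10))
    s$median_depth[] <- md
    s
  }
  expect_identical(filter_samples(mk(4.9)), character())
  expect_identical(filter_samples(mk(5)), "s1")
  # a sample with no covered site has median depth 0: excluded
  empty <- snv_from_vectors(rep(0L, 10), rep(0L, 10))
  expect_identical(filter_samples(empty), character())
})

test_that("species eligibility needs marker coverage 10 in 10 samples", {
  mc <- matrix(0, 12, 2, dimnames = list(sprintf("s%d", 1:12), c("a", "b")))
  mc[1:10, "a"] <- 12
  mc[1:9, "b"] <- 12
  cohort <- list(marker_coverage = mc)
  expect_identical(eligible_species(cohort), "a")
  empty <- list(marker_coverage = mc[, 0, drop = FALSE])
  expect_identical(eligible_species(empty), character())
})

test_that("polymorphism rate counts intermediate-frequency sites inclusively", {
  n <- 1000
  alt <- rep(0L, n)
  alt[1:3] <- 50L                       # f = 0.5
  snv <- snv_from_vectors(rep(100L, n), alt)
  r <- polymorphism_rate(snv, "s1", "synonymous")
  expect_equal(r$rate, 0.003)
  expect_equal(r$n_sites_passing, n)
  # bounds inclusive at both ends: f = 0.2 and f = 0.8 count
  snv2 <- snv_from_vectors(rep(100L, 4), c(20L, 80L, 19L, 81L))
  expect_equal(polymorphism_rate(snv2, "s1")$n_intermediate, 2)
  # all fixed sites: rate 0; empty class: undefined record
  snv3 <- snv_from_vectors(rep(100L, 5), c(0L, 0L, 100L, 100L, 0L))
  expect_equal(polymorphism_rate(snv3, "s1")$rate, 0)
  expect_true(is.na(polymorphism_rate(snv3, "s1", "nonsynonymous")$rate))
})

test_that("widening the frequency window never decreases the rate", {
  set.seed(11)
  for (i in 1:5) {
    depth <- rpois(200, 60)
    alt <- rbinom(200, depth, runif(200))
    snv <- snv_from_vectors(depth, alt)
    r1 <- polymorphism_rate(snv, "s1", f_lo = 0.3, f_hi = 0.7)$rate
    r2 <- polymorphism_rate(snv, "s1", f_lo = 0.2, f_hi = 0.8)$rate
    r3 <- polymorphism_rate(snv, "s1", f_lo = 0.1, f_hi = 0.9)$rate
    expect_true(r1 <= r2 && r2 <= r3)
  }
})

test_that("rate is invariant under allele relabelling", {
  set.seed(12)
  depth <- rpois(300, 50)
  alt <- rbinom(300, depth, 0.3)
  a <- polymorphism_rate(snv_from_vectors(depth, alt), "s1")$rate
  b <- polymorphism_rate(snv_from_vectors(depth, depth - alt), "s1")$rate
  expect_equal(a, b)
})

test_that("two-strain mixtures recover the divergence as the rate", {
  d <- 0.01
  ss <- simulate_strain_sample(2, c(.5, .5), d, 20000, 10000, 0, seed = 5)
  snv <- snv_from_vectors(ss$depth, ss$alt)
  r <- polymorphism_rate(snv, "s1")
  se <- sqrt(d * (1 - d) / 20000)
  expect_lt(abs(r$rate - d), 3 * se)
})

test_that("single-strain samples sit below the error floor", {
  rates <- vapply(1:10, function(i) {
    ss <- simulate_strain_sample(1, 1, 0.1, 1000, 60, 0.01, seed = 40 + i)
    polymorphism_rate(snv_from_vectors(ss$depth, ss$alt), "s1")$rate
  }, numeric(1))
  expect_lt(median(rates), 1e-3)
})

test_that("rate ranks samples like mean heterozygosity", {
  set.seed(13)
  stats <- t(vapply(1:40, function(i) {
    d <- runif(1, 0.002, 0.08)
    ss <- simulate_strain_sample(2, c(.6, .4), d, 500, 100, 0.002, seed = 300 + i)
    f <- ss$alt / pmax(ss$depth, 1)
    het <- mean(2 * f * (1 - f))
    rate <- polymorphism_rate(snv_from_vectors(ss$depth, ss$alt), "s1")$rate
    c(rate, het)
  }, numeric(2)))
  expect_gt(cor(stats[, 1], stats[, 2], method = "spearman"), 0.9)
})

test_that("polymorphism change differences within-host rates", {
  tb <- make_test_cohort()
  r1 <- data.frame(species_id = "spA01", sample_id = "s1", class = "synonymous",
                   n_sites_passing = 500, n_intermediate = 2, rate = 0.004)
  r2 <- r1; r2$sample_id <- "s2"; r2$rate <- 0.006
  ch <- polymorphism_change(r1, r2, tb$samples)
  expect_equal(ch$delta, 0.002)
  expect_equal(ch$delta_days, 180)
  expect_equal(ch$host_id, "h1")
  # identical rates: zero change
  expect_equal(polymorphism_change(r1, within(r1, sample_id <- "s2"),
                                   tb$samples)$delta, 0)
  # undefined endpoint: pair skipped with a message, not an error
  r1na <- within(r1, rate <- NA_real_)
  expect_message(out <- polymorphism_change(r1na, r2, tb$samples), "skipping")
  expect_null(out)
})

test_that("host pairing supports consecutive, first-anchor and all-pairs", {
  sm <- data.frame(sample_id = c("a", "b", "c"), host_id = "h",
                   time_point = 0:2, collection_day = c(0, 10, 30),
                   read_count = 1)
  expect_equal(nrow(microdiv:::host_pairs(c("a", "b", "c"), sm, "consecutive")), 2)
  fa <- microdiv:::host_pairs(c("a", "b", "c"), sm, "first_anchor")
  expect_true(all(fa$t1 == "a"))
  expect_equal(nrow(microdiv:::host_pairs(c("a", "b", "c"), sm, "all_pairs")), 3)
  expect_null(microdiv:::host_pairs("a", sm, "consecutive"))
})

test_that("the cohort-level polymorphism table runs the full filter stack", {
  sim <- simulate_cohort(sim_params(n_hosts = 10, n_focal_species = 2, seed = 17))
  pt <- polymorphism_table(sim$tables, run_config())
  expect_true(all(pt$rates$rate >= 0 & pt$rates$rate <= 1, na.rm = TRUE))
  expect_true(all(pt$rates$class %in% c("synonymous", "nonsynonymous")))
  expect_true(all(pt$changes$delta_days > 0))
  # change records difference the matching rate records
  i <- 1
  ch <- pt$changes[i, ]
  r1 <- pt$rates$rate[pt$rates$sample_id == ch$t1 & pt$rates$class == ch$class &
                        pt$rates$species_id == ch$species_id]
  r2 <- pt$rates$rate[pt$rates$sample_id == ch$t2 & pt$rates$class == ch$class &
                        pt$rates$species_id == ch$species_id]
  expect_equal(ch$delta, r2 - r1)
})
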