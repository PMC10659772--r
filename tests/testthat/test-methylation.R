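test_that("rate calling corrects for non-conversion and enforces coverage", {
  expect_equal(call_rate(90, 10, 0, min_cov = 10), 0.9)
  expect_equal(call_rate(5, 95, 0.05, min_cov = 10), 0)
  expect_true(is.na(call_rate(2, 1, 0, min_cov = 10)))
  expect_error(call_rate(1, 1, 1), "nonconversion")
  expect_error(call_rate(-1, 1, 0), "negative")
  # correction is the identity at b = 0 and clamps into [0, 1]
  set.seed(43)
  meth <- rbinom(100, 200, 0.3); conv <- 200 - meth
  expect_equal(call_rate(meth, conv, 0, 1), meth / 200)
  r <- call_rate(meth, conv, 0.4, 1)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("called rates converge to the planted rate with coverage", {
  set.seed(47)
  truth <- 0.85; b <- 0.01; cov <- 1e4
  meth <- rbinom(50, cov, truth + (1 - truth) * b)
  est <- call_rate(meth, cov - meth, b, 10)
  expect_lt(max(abs(est - truth)), 0.02)
})

test_that("site calling joins region and canonical labels", {
  trnas <- toy_trna(labels = c(`4` = "C48"))
  sc <- site_rows("Leu-CAA-1-1", c(2L, 4L), "vector", c(80L, 90L), c(20L, 10L))
  sites <- call_sites(sc, trnas)
  expect_identical(sites$region, c("ACC_STEM", "V_LOOP"))
  expect_identical(sites$canonical_label, c("", "C48"))
  expect_equal(sites$rate, c(0.8, 0.9))
  expect_error(call_sites(site_rows("nope", 0L, "vector", 1L, 1L), trnas),
               "unannotated")
})

test_that("isodecoder summaries follow the candidate-site rule", {
  trnas <- toy_trna()
  sc <- rbind(site_rows("Leu-CAA-1-1", c(3L, 4L, 5L), "vector",
                        c(90L, 70L, 1L), c(10L, 30L, 99L)),
              site_rows("Leu-CAA-1-1", c(3L, 4L, 5L), "shN",
                        c(85L, 75L, 2L), c(15L, 25L, 98L)))
  lev <- summarize_isodecoder(call_sites(sc, trnas))
  v <- lev[lev$condition == "vector", ]
  expect_equal(v$level, 0.8)     # (0.9 + 0.7)/2; the 0.01 site is excluded
  expect_identical(v$n_sites, 2L)

  # single candidate site
  one <- call_sites(site_rows("Leu-CAA-1-1", 3L, "vector", 80L, 20L), trnas)
  expect_equal(summarize_isodecoder(one)$level, 0.8)

  # all sites below the candidate threshold: undefined level
  low <- call_sites(rbind(
    site_rows("Leu-CAA-1-1", 3L, "vector", 2L, 98L),
    site_rows("Leu-CAA-1-1", 3L, "shN", 1L, 99L)), trnas)
  ll <- summarize_isodecoder(low)
  expect_true(all(is.na(ll$level)))
  expect_identical(ll$n_sites, c(0L, 0L))
})

test_that("region densities partition called sites and negate on swap", {
  trnas <- toy_trna()
  sc <- rbind(site_rows("Leu-CAA-1-1", c(3L, 4L), "vector",
                        c(90L, 80L), c(10L, 20L)),
              site_rows("Leu-CAA-1-1", c(3L, 4L), "shN",
                        c(5L, 10L), c(95L, 90L)),
              site_rows("Leu-CAA-1-1", 8L, "vector", 1L, 99L),
              site_rows("Leu-CAA-1-1", 8L, "shN", 2L, 98L))
  sites <- call_sites(sc, trnas)
  dens <- region_density(sites, ref = "vector", alt = "shN")
  expect_equal(sum(dens$summary$n_ref) + sum(dens$summary$n_alt),
               sum(!is.na(sites$rate)))
  vl <- dens$summary[dens$summary$region == "V_LOOP", ]
  expect_equal(vl$mean_delta, mean(c(0.05, 0.1)) - mean(c(0.9, 0.8)))
  swapped <- region_density(sites, ref = "shN", alt = "vector")
  expect_equal(swapped$summary$mean_delta, -dens$summary$mean_delta)
  # an all-V_LOOP site set leaves other regions empty
  only_v <- call_sites(site_rows("Leu-CAA-1-1", 4L, "vector", 9L, 1L), trnas)
  expect_identical(region_density(only_v)$summary$region, "V_LOOP")
})

test_that("condition comparison computes deltas and loss flags", {
  trnas <- toy_trna()
  sc <- rbind(site_rows("Leu-CAA-1-1", 4L, "vector", 85L, 15L),
              site_rows("Leu-CAA-1-1", 4L, "shN", 2L, 98L))
  cmp <- compare_conditions(call_sites(sc, trnas), "vector", "shN")
  expect_equal(cmp$sites$delta, -0.83)
  expect_true(cmp$isodecoders$lost)

  # mismatched key is skipped with a message
  sc2 <- rbind(sc, site_rows("Leu-CAA-1-1", 6L, "vector", 50L, 50L))
  expect_message(cmp2 <- compare_conditions(call_sites(sc2, trnas),
                                            "vector", "shN"),
                 "1 site key")
  expect_identical(nrow(cmp2$sites), 1L)
})

test_that("context PFM is one-hot for a single site and consensus-correct", {
  trnas <- toy_trna(seq = "GGCACGTTCA")  # cytosine at 0-based position 4
  sites <- call_sites(site_rows("Leu-CAA-1-1", 4L, "vector", 95L, 5L), trnas)
  pfm <- context_pfm(sites, trnas, flank = 2)
  expect_equal(pfm$n_sites, 1L)
  expect_true(all(apply(pfm$pfm, 2, max) == 1))
  expect_identical(pfm$consensus, codon_to_rna(substr("GGCACGTTCA", 3, 7)))
  expect_equal(pfm$information, rep(2, 5))

  # duplicated windows normalise to the same PFM
  sites2 <- call_sites(rbind(
    site_rows("Leu-CAA-1-1", 4L, "vector", 95L, 5L),
    site_rows("Leu-CAA-1-1", 4L, "shN", 95L, 5L)), trnas)
  pfm2 <- context_pfm(sites2, trnas, flank = 2, condition = "vector")
  expect_equal(pfm2$pfm, pfm$pfm)

  # window running off the 5' end is N-padded
  edge <- call_sites(site_rows("Leu-CAA-1-1", 0L, "vector", 95L, 5L), trnas)
  pe <- context_pfm(edge, trnas, flank = 2)
  expect_identical(substr(pe$consensus, 1, 2), "NN")
  expect_error(context_pfm(call_sites(
    site_rows("Leu-CAA-1-1", 3L, "vector", 1L, 99L), trnas), trnas),
    "no site")
})
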