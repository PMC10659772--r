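test_that("designs validate their inputs and require a seed", {
  expect_error(sim_design(), "seed")
  expect_error(sim_design(seed = 1, nb_dispersion = 0))
  expect_error(sim_design(seed = 1, frac_uug_rich = 1.2))
  d <- sim_design(seed = 1)
  expect_s3_class(d, "sim_design")
  expect_identical(d$n_genes, 2000L)
})

test_that("generators are pure functions of (design, seed)", {
  d <- small_design(seed = 5L)
  a <- generate_cds(d); b <- generate_cds(d)
  expect_identical(a, b)
  e1 <- generate_expression(d, a$truth)
  e2 <- generate_expression(d, a$truth)
  expect_identical(e1$mrna$counts, e2$mrna$counts)
  expect_identical(generate_bisulfite(d)$site_counts,
                   generate_bisulfite(d)$site_counts)
  expect_identical(generate_qpcr(d)$qpcr, generate_qpcr(d)$qpcr)
  # a different seed changes the data
  expect_false(identical(generate_cds(small_design(seed = 6L))$sequences,
                         a$sequences))
})

test_that("generated CDS are valid and the UUG tilt is recovered downstream", {
  d <- sim_design(n_genes = 300L, seed = 13L)
  cds <- generate_cds(d)
  expect_identical(length(cds$sequences), 300L)
  for (i in sample(300, 10))
    expect_silent(validate_cds(cds$sequences[[i]], names(cds$sequences)[i]))
  usage <- codon_usage_profile(cds$sequences)
  uug <- usage$rscu[, "UUG"]
  rich <- cds$truth$uug_rich
  m_rich <- mean(uug[rich], na.rm = TRUE)
  expect_gt(m_rich, 1.6)
  expect_lt(m_rich, 3.0)
  # without the tilt the family is symmetric: mean RSCU(UUG) near 1
  d0 <- sim_design(n_genes = 300L, frac_uug_rich = 0, seed = 13L)
  u0 <- codon_usage_profile(generate_cds(d0)$sequences)$rscu[, "UUG"]
  expect_lt(abs(mean(u0, na.rm = TRUE) - 1), 0.15)
})

test_that("a gene of pure UUG leucines has RSCU(UUG) = 6", {
  r <- compute_rscu(count_codons(strrep("TTG", 40)))
  expect_equal(unname(r["UUG"]), 6)
})

test_that("planted TE effects are recovered within tolerance", {
  d <- sim_design(n_genes = 600L, seed = 17L)  # default 15% UUG-rich
  cds_truth <- data.frame(gene_id = sprintf("g%04d", 1:600),
                          uug_rich = c(rep(TRUE, 90), rep(FALSE, 510)))
  expr <- generate_expression(d, cds_truth)
  rec <- te_profile(expr$mrna, expr$ribo, "vector", "shN")
  med <- median(rec$log2fc_te[cds_truth$uug_rich])
  expect_lt(abs(med - (-2)), 0.3)
  expect_lt(abs(median(rec$log2fc_te[!cds_truth$uug_rich])), 0.3)
})

test_that("TE ratios cancel the shared biological replicate factors", {
  # the paired libraries of a replicate share their biological abundance
  # draw, so TE noise reflects only the technical dispersion
  d <- sim_design(n_genes = 1000L, frac_uug_rich = 0, frac_mrna_de = 0,
                  seed = 61L)
  ct <- data.frame(gene_id = sprintf("g%04d", 1:1000), uug_rich = FALSE)
  expr <- generate_expression(d, ct)
  te <- compute_te(normalize_counts(expr$ribo), normalize_counts(expr$mrna))
  mrna_cpm <- normalize_counts(expr$mrna)
  keep <- rowMeans(mrna_cpm) > 100  # genes where count noise is negligible
  sd_te <- apply(log(te[keep, ]), 1, sd)
  sd_mrna <- apply(log(mrna_cpm[keep, ] + 0.5), 1, sd)
  # mRNA carries the full marginal dispersion (sd ~ sqrt(0.1)); TE carries
  # the technical parts of two libraries (sd ~ sqrt(2 * 0.02)); under
  # independent noise the ratio would be sqrt(2) instead of ~0.7
  expect_lt(median(sd_te), 0.8 * median(sd_mrna))
  expect_lt(median(sd_te), sqrt(2 * (d$tech_dispersion + 0.01)) * 1.5)
  expect_gt(median(sd_mrna), sqrt(d$nb_dispersion) * 0.7)
})

test_that("bisulphite counts honour the planted rates", {
  d <- sim_design(seed = 19L, nonconversion = 0, background_rate = 0,
                  control_rate = 0, spared_kd_rate = 0)
  b <- generate_bisulfite(d)
  expect_true(all(b$site_counts$meth == 0))

  d2 <- sim_design(seed = 23L)
  b2 <- generate_bisulfite(d2)
  planted <- merge(b2$site_counts, b2$truth_rates,
                   by = c("isodecoder", "position", "condition"))
  est <- planted$meth / (planted$meth + planted$conv)
  q <- planted$true_rate + (1 - planted$true_rate) * d2$nonconversion
  sd3 <- 3 * sqrt(q * (1 - q) / d2$coverage)
  expect_true(all(abs(est - q) <= pmax(sd3, 1e-3) + 3e-3))
})

test_that("the spared and untouched isodecoders behave as planted", {
  d <- sim_design(seed = 29L)
  b <- generate_bisulfite(d)
  sites <- call_sites(b$site_counts, b$trnas, d$nonconversion, 10)
  cmp <- compare_conditions(sites, "vector", "shN")
  cag <- cmp$sites[cmp$sites$isodecoder == "Leu-CAG-1-1" &
                     cmp$sites$canonical_label == "C48", ]
  expect_lt(abs(cag$delta), 0.05)
  iso <- cmp$isodecoders
  leu_caa <- iso[grepl("^Leu-CAA", iso$isodecoder), ]
  expect_identical(sum(leu_caa$lost), 5L)
  expect_false(iso$lost[iso$isodecoder == "Leu-CAA-4-1"])
})

test_that("qPCR generation recovers planted ratios", {
  d0 <- sim_design(seed = 31L, qpcr_sd = 0)
  q0 <- generate_qpcr(d0)
  ch0 <- charging_summary(q0$qpcr)
  merged <- merge(ch0, q0$truth$charging, by = c("target", "condition"))
  expect_equal(merged$charged_ratio, merged$charged_fraction, tolerance = 1e-9)
  fr0 <- fragment_summary(q0$qpcr, "vector", "shN")
  m0 <- merge(fr0, q0$truth$fragments, by = "target")
  expect_equal(m0$rel_quantity.x, m0$rel_quantity.y, tolerance = 1e-9)

  # with Ct noise (sd 0.15 on each of 4 channels, 3 replicates) the
  # geometric-mean estimate has standard error 2 * 0.15 / sqrt(3) = 0.17
  # on the log2 scale; every planted charged fraction must sit within
  # three of those standard errors
  d <- sim_design(seed = 37L)
  q <- generate_qpcr(d)
  ch <- charging_summary(q$qpcr)
  m <- merge(ch, q$truth$charging, by = c("target", "condition"))
  log2_err <- abs(log2(m$charged_ratio / m$charged_fraction))
  expect_true(all(log2_err < 3 * 2 * d$qpcr_sd / sqrt(d$n_replicates)))

  # a table without the reference channel errors downstream
  broken <- q$qpcr[q$qpcr$channel != "ref_ox", ]
  expect_error(charging_summary(broken), "ref_ox")
})

test_that("fragment rank order reflects the planted 3'-tRF increase", {
  d <- sim_design(seed = 41L)
  q <- generate_qpcr(d)
  fr <- fragment_summary(q$qpcr, "vector", "shN")
  trf <- fr$rel_quantity[grepl("^tRF", fr$target)]
  mature <- fr$rel_quantity[fr$target == "tRNA-Leu-CAA"]
  expect_true(all(trf > 1))
  expect_lt(mature, 1)
  expect_true(all(trf > mature))
})
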