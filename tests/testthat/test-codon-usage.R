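test_that("codon counting is exact on hand-checked sequences", {
  cc <- count_codons("ATGTTGTAA")
  expect_identical(unname(cc[c("AUG", "UUG", "UAA")]), c(1L, 1L, 1L))
  expect_identical(sum(cc), 3L)

  linker <- count_codons("TTGTTGTTGTTGTTGTTG")
  expect_identical(unname(linker["UUG"]), 6L)
  expect_identical(sum(linker), 6L)

  # concatenation property for in-frame fusion
  s1 <- "ATGGCCGCA"; s2 <- "TTGCTGGGT"
  expect_identical(as.integer(count_codons(paste0(s1, s2))),
                   as.integer(count_codons(s1)) + as.integer(count_codons(s2)))
})

test_that("RSCU matches hand evaluation and marks absent families", {
  # every leucine codon once -> RSCU 1 across the family
  leu6 <- "TTATTGCTTCTCCTACTG"
  r <- compute_rscu(count_codons(leu6))
  expect_equal(unname(r[c("UUA", "UUG", "CUU", "CUC", "CUA", "CUG")]),
               rep(1, 6))
  # all other families absent
  expect_true(all(is.na(r[c("GCU", "AAA", "GGG")])))

  # 6X-TTG linker: family mean = 1, RSCU(UUG) = 6
  rl <- compute_rscu(count_codons("TTGTTGTTGTTGTTGTTG"))
  expect_equal(unname(rl["UUG"]), 6)
  expect_equal(unname(rl[c("UUA", "CUU", "CUC", "CUA", "CUG")]), rep(0, 5))

  # Ala GCC=6, GCA=2: mean 2 -> 3.0 and 1.0
  ala <- paste0(strrep("GCC", 6), strrep("GCA", 2))
  ra <- compute_rscu(count_codons(ala))
  expect_equal(unname(ra[c("GCC", "GCA", "GCG", "GCU")]), c(3, 1, 0, 0))
})

test_that("per-family RSCU sums equal family size on random counts", {
  fams <- m5Ccodon:::.degenerate_families()
  set.seed(11)
  for (i in 1:50) {
    counts <- random_counts(500L)
    r <- compute_rscu(counts)
    for (fam in fams) {
      vals <- r[codon_to_rna(fam)]
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(fam), tolerance = 1e-12)
    }
  }
})

test_that("RSCU is invariant to synonymous-preserving codon shuffles", {
  set.seed(3)
  fams <- m5Ccodon:::.degenerate_families()
  codons <- unlist(lapply(fams, function(f) sample(f, 30, replace = TRUE)))
  r1 <- compute_rscu(count_codons(paste(codons, collapse = "")))
  r2 <- compute_rscu(count_codons(paste(sample(codons), collapse = "")))
  expect_equal(r1, r2)
})

test_that("codon classes follow the published cut-offs at the boundaries", {
  expect_identical(
    classify_codon(c(1.61, 1.6, 1.0001, 1.0, 0.6, 0.5999, 0, NA)),
    c("overrepresented", "abundant", "abundant", "typical", "typical",
      "underrepresented", "underrepresented", "absent"))
  expect_error(classify_codon(-0.1), "nonnegative")
})

test_that("GC3s counts third positions of degenerate families only", {
  expect_equal(compute_gc3s(count_codons(strrep("GCC", 10))), 1)
  expect_equal(compute_gc3s(count_codons("TTGTTGTTGTTGTTGTTG")), 1)
  expect_equal(compute_gc3s(count_codons("TTAGCC")), 0.5)
  # AUG and UGG do not contribute
  expect_equal(compute_gc3s(count_codons("ATGTGGGCC")), 1)
  expect_true(is.na(compute_gc3s(count_codons("ATGTGG"))))
})

test_that("ENC reaches its analytic limits", {
  fams <- m5Ccodon:::.degenerate_families()
  biased <- paste(rep(vapply(fams, `[[`, "", 1L), 60), collapse = "")
  expect_equal(compute_enc(count_codons(biased)), 20, tolerance = 1e-12)
  uniform <- paste(rep(unlist(fams), 60), collapse = "")
  expect_equal(compute_enc(count_codons(uniform)), 61, tolerance = 1e-12)
})

test_that("ENC equals an independently coded evaluation on random genes", {
  # independent oracle: recompute Wright's statistic from the raw codon
  # string with data-frame bookkeeping rather than the package's tables
  oracle_enc <- function(seq) {
    gc <- Biostrings::GENETIC_CODE
    cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
    df <- data.frame(codon = cods, aa = gc[cods])
    df <- df[df$aa != "*", ]
    fam_size <- table(gc[gc != "*"])
    df <- df[fam_size[df$aa] >= 2, ]
    Fs <- sapply(split(df$codon, df$aa), function(cs) {
      n <- length(cs)
      if (n < 2) return(NA_real_)
      p <- as.numeric(table(cs)) / n
      (n * sum(p^2) - 1) / (n - 1)
    })
    deg <- fam_size[names(Fs)]
    Fbar <- sapply(c(2, 3, 4, 6), function(k) mean(Fs[deg == k], na.rm = TRUE))
    if (is.nan(Fbar[2])) Fbar[2] <- mean(Fbar[c(1, 3)])
    if (any(is.nan(Fbar)) || any(Fbar <= 0)) return(NA_real_)
    min(2 + 9 / Fbar[1] + 1 / Fbar[2] + 5 / Fbar[3] + 3 / Fbar[4], 61)
  }
  set.seed(21)
  fams <- m5Ccodon:::.degenerate_families()
  for (i in 1:20) {
    codons <- unlist(lapply(fams, function(f)
      sample(f, sample(2:12, 1), replace = TRUE, prob = runif(length(f)))))
    seq <- paste(sample(codons), collapse = "")
    expect_equal(compute_enc(count_codons(seq)), oracle_enc(seq),
                 tolerance = 1e-10)
  }
})

test_that("ENC never increases when within-family skew increases", {
  set.seed(5)
  base <- random_counts(600L)
  fams <- m5Ccodon:::.degenerate_families()
  for (i in 1:20) {
    fam <- codon_to_rna(fams[[sample(length(fams), 1)]])
    skewed <- base
    # move all of one family's mass onto a single codon
    tot <- sum(base[fam])
    skewed[fam] <- 0L
    skewed[fam[1]] <- tot
    e0 <- compute_enc(base); e1 <- compute_enc(skewed)
    if (!is.na(e0) && !is.na(e1)) expect_lte(e1, e0 + 1e-9)
  }
})

test_that("the expected-ENC curve evaluates and peaks where it should", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "0, 1")
  grid <- seq(0, 1, by = 0.001)
  peak <- grid[which.max(enc_expected(grid))]
  expect_gt(peak, 0.45)
  expect_lt(peak, 0.55)
})

test_that("the ENC-plot table flags genes below the null curve", {
  seqs <- c(g_biased = strrep("GCC", 60),
            g_even = paste(rep(unlist(m5Ccodon:::.degenerate_families()), 4),
                           collapse = ""))
  tab <- enc_plot_table(lapply(seqs, count_codons))
  expect_identical(tab$gene_id, names(seqs))
  expect_true(is.na(tab$enc[1]))        # single family: classes missing
  expect_identical(tab$below_curve[1], NA)
  expect_false(tab$below_curve[2])      # uniform usage sits above the curve
})

test_that("unbiased synthetic genes hug the expected-ENC curve", {
  set.seed(9)
  fams <- m5Ccodon:::.degenerate_families()
  seqs <- replicate(60, paste(unlist(lapply(fams, function(f)
    sample(f, 25, replace = TRUE))), collapse = ""))
  names(seqs) <- sprintf("g%02d", 1:60)
  tab <- enc_plot_table(lapply(seqs, count_codons))
  ok <- abs(tab$enc - tab$enc_expected) <= 5
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
})

test_that("correspondence analysis matches an independent eigen solver", {
  set.seed(17)
  X <- matrix(rpois(9, 20) + 1, 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  ca <- correspondence_analysis(X)
  P <- X / sum(X); r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ca$inertia, ev[seq_along(ca$inertia)], tolerance = 1e-10)
  # reconstruction: total inertia == chi-square statistic / grand total
  expd <- outer(rowSums(X), colSums(X)) / sum(X)
  chi2 <- sum((X - expd)^2 / expd)
  expect_equal(ca$total_inertia, chi2 / sum(X), tolerance = 1e-9)
  expect_equal(sum(ca$inertia_fractions), 1, tolerance = 1e-9)
})

test_that("correspondence analysis agrees with MASS::corresp", {
  skip_if_not_installed("MASS")
  set.seed(19)
  X <- matrix(rpois(50, 15) + 1, 5, 10)
  dimnames(X) <- list(paste0("g", 1:5), paste0("c", 1:10))
  ca <- correspondence_analysis(X)
  mc <- MASS::corresp(X, nf = 2)
  expect_equal(ca$inertia[1:2], mc$cor[1:2]^2, tolerance = 1e-8)
  # principal coordinates agree up to sign
  expect_equal(abs(ca$row_coords[, 1]),
               abs(mc$rscore[, 1] * mc$cor[1]), tolerance = 1e-8)
})

test_that("rank-1 input yields zero inertia; axes are mass-orthogonal", {
  r1 <- outer(1:4, c(2, 3, 5, 7, 11))
  dimnames(r1) <- list(paste0("g", 1:4), paste0("c", 1:5))
  ca <- correspondence_analysis(r1)
  expect_true(ca$zero_inertia)
  expect_lt(ca$total_inertia, 1e-12)

  set.seed(23)
  X <- matrix(rpois(40, 10) + 1, 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  ca <- correspondence_analysis(X)
  r <- rowSums(X) / sum(X)
  G <- ca$row_coords
  gram <- t(G) %*% (G * r)
  off <- gram[upper.tri(gram)]
  expect_true(all(abs(off) < 1e-9))
})

test_that("sparse genes are dropped from CA and reported", {
  set.seed(29)
  full <- matrix(runif(3 * 59, 0.5, 2), 3, 59,
                 dimnames = list(paste0("g", 1:3), informative_codons()))
  sparse <- rep(NA_real_, 59)
  sparse[1:20] <- 1
  m <- rbind(full, g_sparse = sparse)
  ca <- correspondence_analysis(m, max_absent = 30)
  expect_identical(ca$dropped_genes, "g_sparse")
  expect_identical(nrow(ca$row_coords), 3L)
})
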