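# Seeded synthetic-data generators emulating the data structure the
# pipeline assumes: coding sequences with a UUG-rich subset, paired
# negative-binomial mRNA/Ribo-seq counts with planted TE loss in that
# subset, binomial bisulphite site counts with condition-dependent m5C at
# variable-loop/T-arm positions, and qPCR Ct tables for charging and
# fragment assays. Every generator is a pure function of (design, seed):
# truth tables accompany every dataset so downstream estimators can be
# benchmarked by parameter recovery.

#' Simulation design
#'
#' Bundles every tunable of the synthetic-data generators with validated
#' defaults. The defaults describe the emulated study conditions: 2000
#' genes of 100-500 codons, 15\% with a leucine-family tilt towards UUG
#' (Dirichlet weight 3, expected RSCU(UUG) = 2.25), planted TE log2 fold
#' change of -2 in the knockdown for UUG-rich genes, negative-binomial
#' counts with dispersion 0.1 at a library size of 1e6 over 3 replicates
#' per condition, bisulphite coverage 1000 with 1\% non-conversion, and a
#' ten-isodecoder panel in which five of six Leu-CAA isodecoders lose their
#' m5C entirely in the knockdown, one (Leu-CAA-4-1) is partially spared,
#' and Leu-CAG is untouched.
#'
#' @param n_genes number of coding sequences.
#' @param frac_uug_rich proportion of genes given the UUG tilt.
#' @param uug_tilt Dirichlet weight on UUG within the leucine family
#'   (others 1); expected RSCU(UUG) for tilted genes is
#'   \code{6 * uug_tilt / (uug_tilt + 5)}.
#' @param te_effect_log2fc planted TE log2 fold change (knockdown vs
#'   control) for UUG-rich genes.
#' @param frac_mrna_de proportion of genes with a planted mRNA-only shift.
#' @param mrna_de_log2fc magnitude of that shift (random sign).
#' @param nb_dispersion marginal negative-binomial dispersion alpha of each
#'   assay (variance \eqn{\mu + \alpha \mu^2}).
#' @param tech_dispersion the technical (library-level) share of
#'   \code{nb_dispersion}: paired mRNA and ribosome libraries are prepared
#'   from the same biological sample, so the biological component of the
#'   overdispersion is shared between the two assays of a replicate and
#'   cancels in the TE ratio, while this technical component stays
#'   independent.
#' @param lib_size expected counts per sample.
#' @param n_replicates replicates per condition.
#' @param coverage bisulphite read depth per cytosine.
#' @param nonconversion bisulphite non-conversion error rate.
#' @param control_rate true m5C rate at planted sites in the control.
#' @param spared_kd_rate knockdown rate retained by the spared isodecoder.
#' @param background_rate methylation floor at non-target cytosines.
#' @param qpcr_sd Gaussian Ct noise standard deviation.
#' @param conditions two condition labels (control first).
#' @param seed integer seed; mandatory, every generator derives its random
#'   stream from it.
#' @return an object of class \code{sim_design} (a validated list).
#' @export
sim_design <- function(n_genes = 2000L, frac_uug_rich = 0.15, uug_tilt = 3,
                       te_effect_log2fc = -2, frac_mrna_de = 0.05,
                       mrna_de_log2fc = 1, nb_dispersion = 0.1,
                       tech_dispersion = 0.02,
                       lib_size = 1e6, n_replicates = 3L, coverage = 1000L,
                       nonconversion = 0.01, control_rate = 0.85,
                       spared_kd_rate = 0.25, background_rate = 0.02,
                       qpcr_sd = 0.15, conditions = c("vector", "shN"),
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for the stochastic generators")
  stopifnot(n_genes >= 1, frac_uug_rich >= 0, frac_uug_rich <= 1,
            uug_tilt > 0, nb_dispersion > 0,
            tech_dispersion > 0, tech_dispersion <= nb_dispersion,
            lib_size > 0,
            n_replicates >= 1, coverage >= 1,
            nonconversion >= 0, nonconversion < 1,
            control_rate >= 0, control_rate <= 1,
            length(conditions) == 2L)
  structure(as.list(environment()), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(paste0("<sim_design> %d genes (%.0f%% UUG-rich, tilt %.3g), ",
                     "TE effect %+.3g log2, %d reps, lib %.3g, seed %d\n"),
              x$n_genes, 100 * x$frac_uug_rich, x$uug_tilt,
              x$te_effect_log2fc, x$n_replicates, x$lib_size, x$seed))
  invisible(x)
}

# each generator gets an independent, design-derived stream
.with_seed <- function(design, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed((design$seed + offset) %% .Machine$integer.max)
  expr
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate coding sequences with a UUG-rich subset
#'
#' Per gene: an amino-acid sequence drawn uniformly over the 20 amino
#' acids with length uniform in 100-500 codons; codons drawn per family
#' from a Dirichlet-multinomial (symmetric concentration 1, except the
#' leucine family of UUG-rich genes, which is tilted towards UUG); a
#' terminal stop appended.
#'
#' @param design a \code{\link{sim_design}}.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth}: data.frame (gene_id, uug_rich, n_codons, true RSCU of
#'   UUG and CUG) with the full genes x 59 matrix of true RSCU values as
#'   attribute \code{true_rscu}.
#' @export
generate_cds <- function(design) .with_seed(design, 1L, {
  fams <- .degenerate_families()
  single <- .code()$families[vapply(.code()$families, length, 1L) == 1L]
  all_fams <- c(fams, single)
  aas <- names(all_fams)
  n <- design$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  uug_rich <- seq_len(n) <= round(design$frac_uug_rich * n)
  cods59 <- informative_codons()
  true_rscu <- matrix(NA_real_, n, length(cods59),
                      dimnames = list(ids, cods59))
  lens <- sample(100:500, n, replace = TRUE)
  seqs <- character(n)
  leu <- fams[["L"]]
  for (i in seq_len(n)) {
    aa_seq <- sample(aas, lens[i], replace = TRUE)
    codons <- character(lens[i])
    for (aa in unique(aa_seq)) {
      fam <- all_fams[[aa]]
      pos <- which(aa_seq == aa)
      if (length(fam) == 1L) {
        codons[pos] <- fam
        next
      }
      alpha <- rep(1, length(fam))
      if (aa == "L" && uug_rich[i]) alpha[fam == "TTG"] <- design$uug_tilt
      p <- .rdirichlet1(alpha)
      true_rscu[i, codon_to_rna(fam)] <- length(fam) * p
      codons[pos] <- sample(fam, length(pos), replace = TRUE, prob = p)
    }
    seqs[i] <- paste0(paste(codons, collapse = ""), "TAA")
  }
  names(seqs) <- ids
  truth <- data.frame(gene_id = ids, uug_rich = uug_rich, n_codons = lens,
                      true_rscu_uug = true_rscu[, "UUG"],
                      true_rscu_cug = true_rscu[, "CUG"],
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(truth, "true_rscu") <- true_rscu
  list(sequences = seqs, truth = truth)
})

#' Generate paired mRNA / Ribo-seq count matrices
#'
#' Gene base abundances are log-normal; each biological replicate draws a
#' per-gene abundance factor (gamma, mean 1) shared by the paired mRNA and
#' ribosome libraries of that sample, and each library then adds
#' independent technical negative-binomial noise, so each assay's marginal
#' dispersion equals \code{nb_dispersion} while the biological component
#' cancels in the TE ratio, as it does in a paired profiling design. mRNA
#' means are equal across conditions except a small random mRNA-DE subset;
#' ribosome-footprint means are the replicate's mRNA level times the
#' gene's TE, with the planted TE log2 fold change applied to UUG-rich
#' genes in the knockdown condition only. Replicates are i.i.d.
#'
#' @param design a \code{\link{sim_design}}.
#' @param truth truth table from \code{\link{generate_cds}}.
#' @return list with \code{mrna} and \code{ribo} (\code{expr_matrix}
#'   objects) and \code{truth}: per-gene true TE log2FC and mRNA log2FC.
#' @export
generate_expression <- function(design, truth) .with_seed(design, 2L, {
  n <- nrow(truth)
  rel <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  rel <- rel / sum(rel)
  te_fc <- ifelse(truth$uug_rich, design$te_effect_log2fc, 0)
  de <- stats::runif(n) < design$frac_mrna_de
  mrna_fc <- ifelse(de, sample(c(-1, 1), n, replace = TRUE) *
                      design$mrna_de_log2fc, 0)
  conds <- design$conditions
  samples <- sort(as.vector(outer(seq_len(design$n_replicates), conds,
                                  function(r, cd) paste0(cd, "_", r))))
  cond_of <- sub("_[^_]*$", "", samples)
  # split marginal dispersion: alpha = a_bio (1 + a_tech) + a_tech
  a_tech <- design$tech_dispersion
  a_bio <- (design$nb_dispersion - a_tech) / (1 + a_tech)
  base <- function(cd) {
    fc <- if (cd == conds[2L]) 2^mrna_fc else rep(1, n)
    rel * fc * design$lib_size
  }
  mu <- vapply(cond_of, base, numeric(n))
  bio <- matrix(stats::rgamma(n * length(samples), shape = 1 / a_bio,
                              scale = a_bio), nrow = n)
  lambda <- mu * bio
  te_mult <- vapply(cond_of, function(cd)
    if (cd == conds[2L]) 2^te_fc else rep(1, n), numeric(n))
  draw <- function(mu_mat) matrix(
    stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / a_tech),
    nrow = n, dimnames = list(truth$gene_id, samples))
  tr <- data.frame(gene_id = truth$gene_id, true_te_log2fc = te_fc,
                   true_mrna_log2fc = mrna_fc, stringsAsFactors = FALSE)
  list(mrna = expression_matrix(draw(lambda), assay = "mrna"),
       ribo = expression_matrix(draw(lambda * te_mult), assay = "ribo"),
       truth = tr)
})

#' Default tRNA isodecoder panel
#'
#' Ten isodecoders: six Leu-CAA (substrates; five fully demethylated in
#' the knockdown, Leu-CAA-4-1 partially spared), one Leu-CAG (methylated
#' but untouched by the knockdown), and the further substrate families
#' Gly-GCC, Glu-UUC and Val-AAC (demethylated).
#'
#' @param design a \code{\link{sim_design}} supplying the rate parameters.
#' @return data.frame with \code{isodecoder}, \code{substrate},
#'   \code{control_rate}, \code{kd_rate}.
#' @export
default_isodecoder_panel <- function(design) {
  iso <- c(sprintf("Leu-CAA-%d-1", 1:6), "Leu-CAG-1-1",
           "Gly-GCC-1-1", "Glu-UUC-1-1", "Val-AAC-1-1")
  kd <- c(rep(0, 3), design$spared_kd_rate, rep(0, 2),  # Leu-CAA-4-1 spared
          design$control_rate,                          # Leu-CAG unchanged
          rep(0, 3))
  data.frame(isodecoder = iso,
             substrate = iso != "Leu-CAG-1-1",
             control_rate = design$control_rate,
             kd_rate = kd, stringsAsFactors = FALSE)
}

# synthetic 76-nt isodecoder with cloverleaf-style region blocks and two
# planted cytosines: position 47 (V_LOOP, "C48") in a C-A-C context and
# position 49 (T_ARM, "C49")
.make_trna <- function(name) {
  L <- 76L
  region <- c(rep("ACC_STEM", 7), rep("D_ARM", 19), rep("AC_ARM", 18),
              rep("V_LOOP", 5), rep("T_ARM", 17), rep("OTHER", 10))
  stopifnot(length(region) == L)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.3, 0.2, 0.3, 0.2))
  base[47L + 1L] <- "C"; base[48L + 1L] <- "A"; base[49L + 1L] <- "C"
  lab <- character(L)
  lab[47L + 1L] <- "C48"; lab[49L + 1L] <- "C49"
  list(name = name, seq = paste(base, collapse = ""),
       region = region, canonical_label = lab)
}

#' Generate bisulphite site counts for the isodecoder panel
#'
#' Builds synthetic 76-nt isodecoder sequences with structural regions and
#' planted m5C sites at a variable-loop position (canonical label
#' \code{C48}) and a T-arm position (\code{C49}); every cytosine then gets
#' a methylated count drawn from
#' \eqn{Binomial(coverage, q)} with \eqn{q = rate + (1 - rate) b} for
#' non-conversion \eqn{b}. Planted sites carry the panel's per-condition
#' true rates; other cytosines sit at the background rate. A per-isodecoder
#' truth table also carries a planted log2 expression change, a linear
#' function of retained knockdown methylation (spared isodecoder up,
#' demethylated ones down) plus Gaussian noise, emulating the link between
#' m5C and tRNA stability.
#'
#' @param design a \code{\link{sim_design}}.
#' @param panel isodecoder panel; default
#'   \code{\link{default_isodecoder_panel}}.
#' @return list with \code{site_counts} (data.frame), \code{trnas}
#'   (annotation list), \code{truth_rates} (per planted site) and
#'   \code{isodecoder_truth} (rates + \code{expr_log2fc}).
#' @export
generate_bisulfite <- function(design, panel = default_isodecoder_panel(design)) {
  .with_seed(design, 3L, {
    trnas <- lapply(panel$isodecoder, .make_trna)
    names(trnas) <- panel$isodecoder
    conds <- design$conditions
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(panel))) {
      t <- trnas[[i]]
      cpos <- which(strsplit(t$seq, "")[[1L]] == "C") - 1L
      planted <- c(47L, 49L)
      for (cond in conds) {
        rate <- ifelse(cpos %in% planted,
                       if (cond == conds[1L]) panel$control_rate[i]
                       else panel$kd_rate[i],
                       design$background_rate)
        q <- rate + (1 - rate) * design$nonconversion
        meth <- stats::rbinom(length(cpos), design$coverage, q)
        rows[[length(rows) + 1L]] <-
          data.frame(isodecoder = panel$isodecoder[i], position = cpos,
                     condition = cond, meth = meth,
                     conv = design$coverage - meth,
                     stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <-
          data.frame(isodecoder = panel$isodecoder[i], position = planted,
                     condition = cond,
                     true_rate = ifelse(cond == conds[1L],
                                        panel$control_rate[i],
                                        panel$kd_rate[i]),
                     stringsAsFactors = FALSE)
      }
    }
    iso_truth <- panel
    iso_truth$expr_log2fc <- 2.5 * panel$kd_rate - 1 +
      stats::rnorm(nrow(panel), 0, 0.2)
    list(site_counts = do.call(rbind, rows), trnas = trnas,
         truth_rates = unique(do.call(rbind, truth)),
         isodecoder_truth = iso_truth)
  })
}

#' Generate qPCR Ct tables for charging and fragment assays
#'
#' Ct values follow \eqn{Ct = base - \log_2(quantity) + noise} with
#' Gaussian noise. The charging assay plants a halved charged fraction for
#' Leu-CAA in the knockdown (Leu-CAG unchanged) with a spike-in reference
#' measured in both channels; the fragment assay plants a depleted mature
#' Leu-CAA and three enriched 3'-tRFs against a flat U6 reference.
#'
#' @param design a \code{\link{sim_design}}.
#' @return list with \code{qpcr} (long Ct table) and \code{truth}
#'   (\code{charging}: per family/condition charged fraction;
#'   \code{fragments}: per target relative quantity, knockdown vs
#'   control).
#' @export
generate_qpcr <- function(design) .with_seed(design, 4L, {
  conds <- design$conditions
  reps <- seq_len(design$n_replicates)
  charged <- data.frame(target = rep(c("Leu-CAA", "Leu-CAG"), each = 2L),
                        condition = rep(conds, 2L),
                        charged_fraction = c(0.8, 0.4, 0.8, 0.8),
                        stringsAsFactors = FALSE)
  frag <- data.frame(target = c("tRNA-Leu-CAA", "tRF-3a", "tRF-3b", "tRF-3c"),
                     rel_quantity = c(0.5, 4, 4, 4),
                     stringsAsFactors = FALSE)
  noise <- function(n) stats::rnorm(n, 0, design$qpcr_sd)
  rows <- list()
  add <- function(assay, target, condition, channel, replicate, ct)
    rows[[length(rows) + 1L]] <<- data.frame(
      assay = assay, target = target, condition = condition,
      channel = channel, replicate = replicate, ct = ct,
      stringsAsFactors = FALSE)
  base_ct <- 20; ref_ct <- 15
  for (i in seq_len(nrow(charged))) for (r in reps) {
    total <- 1
    ch <- charged$charged_fraction[i] * total
    add("charging", charged$target[i], charged$condition[i], "ox", r,
        base_ct - log2(ch) + noise(1))
    add("charging", charged$target[i], charged$condition[i], "nonox", r,
        base_ct - log2(total) + noise(1))
    add("charging", charged$target[i], charged$condition[i], "ref_ox", r,
        ref_ct + noise(1))
    add("charging", charged$target[i], charged$condition[i], "ref_nonox", r,
        ref_ct + noise(1))
  }
  for (i in seq_len(nrow(frag))) for (r in reps) for (cond in conds) {
    qty <- if (cond == conds[2L]) frag$rel_quantity[i] else 1
    add("fragment", frag$target[i], cond, "target", r,
        base_ct - log2(qty) + noise(1))
  }
  for (r in reps) for (cond in conds)
    add("fragment", "U6", cond, "u6", r, ref_ct + noise(1))
  list(qpcr = do.call(rbind, rows),
       truth = list(charging = charged, fragments = frag))
})

#' Generate a complete synthetic dataset
#'
#' Runs all four generators under the design's seed and optionally writes
#' every table (plus truth tables) to a directory in the pipeline's input
#' formats.
#'
#' @param design a \code{\link{sim_design}}.
#' @param out_dir optional output directory; created if missing.
#' @return list with components \code{cds}, \code{expression},
#'   \code{bisulfite}, \code{qpcr} (each a generator's return value).
#' @export
generate_dataset <- function(design, out_dir = NULL) {
  cds <- generate_cds(design)
  expr <- generate_expression(design, cds$truth)
  bsq <- generate_bisulfite(design)
  qpcr <- generate_qpcr(design)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    write_fasta_sequences(cds$sequences, file.path(out_dir, "cds.fasta"))
    write_counts_table(expr$mrna, file.path(out_dir, "mrna_counts.tsv"))
    write_counts_table(expr$ribo, file.path(out_dir, "ribo_counts.tsv"))
    write_tsv(bsq$site_counts, file.path(out_dir, "bsq_sites.tsv"))
    write_trna_annotation(bsq$trnas, file.path(out_dir, "trna_annotation.tsv"))
    write_tsv(qpcr$qpcr, file.path(out_dir, "qpcr.tsv"))
    write_tsv(cds$truth, file.path(out_dir, "truth", "cds_truth.tsv"))
    write_tsv(expr$truth, file.path(out_dir, "truth", "te_truth.tsv"))
    write_tsv(bsq$truth_rates, file.path(out_dir, "truth", "meth_truth.tsv"))
    write_tsv(bsq$isodecoder_truth,
              file.path(out_dir, "truth", "isodecoder_truth.tsv"))
    write_tsv(qpcr$truth$charging, file.path(out_dir, "truth", "charging_truth.tsv"))
    write_tsv(qpcr$truth$fragments, file.path(out_dir, "truth", "fragment_truth.tsv"))
  }
  list(cds = cds, expression = expr, bisulfite = bsq, qpcr = qpcr)
}
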