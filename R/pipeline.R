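# End-to-end orchestration: run the TE, codon-usage, methylation and
# integration stages over synthetic (or file-based) inputs, write every
# backing table, and emit a run report with the resolved configuration.

#' Pipeline configuration
#'
#' Resolves all thresholds and paths for \code{\link{run_pipeline}}. With
#' \code{input_dir = NULL} the pipeline generates its inputs from
#' \code{design}; otherwise it reads the tables a previous
#' \code{\link{generate_dataset}} call (or external preparation in the
#' same formats) wrote there.
#'
#' @param seed integer seed; mandatory.
#' @param out_dir directory for all stage outputs.
#' @param input_dir optional directory of pre-generated inputs.
#' @param design a \code{\link{sim_design}}; defaults to the standard
#'   design under \code{seed}.
#' @param fc_gate,p_gate differential significance gates (1, 0.05).
#' @param pseudocount TE stabiliser in CPM.
#' @param n_top size of the TE-down set fed to the codon-usage stage.
#' @param min_cov,candidate_min,lost_high,lost_low methylation thresholds.
#' @param nonconversion bisulphite non-conversion used for rate correction
#'   (defaults to the design's value).
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(seed, out_dir, input_dir = NULL,
                       design = sim_design(seed = seed),
                       fc_gate = 1, p_gate = 0.05, pseudocount = 0.5,
                       n_top = 1000L, min_cov = 10L, candidate_min = 0.1,
                       lost_high = 0.5, lost_low = 0.1,
                       nonconversion = design$nonconversion) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(is.finite(fc_gate), is.finite(p_gate), is.finite(pseudocount),
            is.finite(min_cov))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: synthetic-data generation (or input loading), TE
#' profiling, codon usage over the TE-down set, tRNA methylation, and the
#' integrative statistics (UUG/CUG cluster grid with explained fraction,
#' charging and fragment quantification, expression-methylation
#' correlation). All backing tables are written under
#' \code{config$out_dir} along with a JSON run report recording the
#' resolved configuration; runs are byte-identical for a fixed seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return an object of class \code{pipeline_report} (invisibly a list of
#'   all stage outputs plus provenance).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  design <- config$design

  # --- stage 0: inputs --------------------------------------------------
  if (is.null(config$input_dir)) {
    data <- generate_dataset(design, out_dir = file.path(out, "inputs"))
  } else {
    ind <- config$input_dir
    seqs <- read_fasta_sequences(file.path(ind, "cds.fasta"))
    data <- list(
      cds = list(sequences = seqs, truth = NULL),
      expression = list(
        mrna = read_counts_table(file.path(ind, "mrna_counts.tsv"), "mrna"),
        ribo = read_counts_table(file.path(ind, "ribo_counts.tsv"), "ribo"),
        truth = NULL),
      bisulfite = list(
        site_counts = read_site_counts(file.path(ind, "bsq_sites.tsv")),
        trnas = read_trna_annotation(file.path(ind, "trna_annotation.tsv")),
        isodecoder_truth = NULL),
      qpcr = list(qpcr = read_qpcr_table(file.path(ind, "qpcr.tsv"))))
  }
  conds <- design$conditions

  # --- stage 1: TE profiling -------------------------------------------
  te_rec <- te_profile(data$expression$mrna, data$expression$ribo,
                       ref = conds[1L], alt = conds[2L],
                       pseudocount = config$pseudocount,
                       fc_gate = config$fc_gate, p_gate = config$p_gate)
  te_down <- select_te_down(te_rec, n_top = config$n_top,
                            fc_gate = config$fc_gate, p_gate = config$p_gate)
  write_tsv(te_rec, file.path(out, "te_records.tsv"))
  write_tsv(te_down, file.path(out, "te_down_top.tsv"))

  # --- stage 2: codon usage over the TE-down set -----------------------
  seqs <- vapply(names(data$cds$sequences), function(id)
    validate_cds(data$cds$sequences[[id]], id), character(1L))
  usage <- codon_usage_profile(seqs)
  down_ids <- te_down$gene_id
  rscu_down <- usage$rscu[down_ids, , drop = FALSE]
  ca <- if (nrow(rscu_down) >= 2L)
    correspondence_analysis(rscu_down) else NULL
  write_tsv(data.frame(gene_id = rownames(usage$rscu), usage$rscu,
                       check.names = FALSE), file.path(out, "rscu.tsv"))
  write_tsv(usage$enc_table, file.path(out, "enc.tsv"))
  if (!is.null(ca)) {
    write_tsv(data.frame(gene_id = rownames(ca$row_coords),
                         ca$row_coords[, 1:2, drop = FALSE],
                         check.names = FALSE),
              file.path(out, "ca_rows.tsv"))
    write_tsv(data.frame(codon = rownames(ca$col_coords),
                         ca$col_coords[, 1:2, drop = FALSE],
                         check.names = FALSE),
              file.path(out, "ca_cols.tsv"))
    write_tsv(data.frame(axis = seq_along(ca$inertia),
                         inertia = ca$inertia,
                         fraction = ca$inertia_fractions),
              file.path(out, "ca_inertia.tsv"))
  }

  # --- stage 3: tRNA methylation ---------------------------------------
  sites <- call_sites(data$bisulfite$site_counts, data$bisulfite$trnas,
                      nonconversion = config$nonconversion,
                      min_cov = config$min_cov)
  meth_cmp <- compare_conditions(sites, ref = conds[1L], alt = conds[2L],
                                 lost_high = config$lost_high,
                                 lost_low = config$lost_low,
                                 candidate_min = config$candidate_min)
  dens <- region_density(sites, ref = conds[1L], alt = conds[2L])
  pfm <- context_pfm(sites, data$bisulfite$trnas, flank = 2L,
                     condition = conds[1L])
  write_tsv(sites, file.path(out, "rates.tsv"))
  write_tsv(summarize_isodecoder(sites, config$candidate_min),
            file.path(out, "isodecoder_levels.tsv"))
  write_tsv(dens$summary, file.path(out, "region_density.tsv"))
  write_tsv(meth_cmp$sites, file.path(out, "comparisons.tsv"))
  write_tsv(data.frame(base = rownames(pfm$pfm), pfm$pfm,
                       check.names = FALSE), file.path(out, "pfm.tsv"))

  # --- stage 4: integration --------------------------------------------
  cluster <- cluster_by_codon(down_ids, usage$rscu)
  expl <- explained_fraction(cluster)
  truth_fraction <- NA_real_
  if (!is.null(data$cds$truth)) {
    # ground truth: same cell rule over the genes actually planted with a
    # TE effect, using their (exactly known) realised codon usage
    planted <- data$cds$truth$gene_id[data$cds$truth$uug_rich]
    if (length(planted))
      truth_fraction <-
        explained_fraction(cluster_by_codon(planted, usage$rscu))$fraction
  }
  charging <- charging_summary(data$qpcr$qpcr)
  fragments <- fragment_summary(data$qpcr$qpcr, ref = conds[1L],
                                alt = conds[2L])
  vloop <- meth_cmp$sites[meth_cmp$sites$region == "V_LOOP" &
                            !is.na(meth_cmp$sites$canonical_label) &
                            nzchar(meth_cmp$sites$canonical_label), ]
  vdelta <- stats::setNames(vloop$delta, vloop$isodecoder)
  correlation <- NULL
  if (!is.null(data$bisulfite$isodecoder_truth)) {
    expr_fc <- stats::setNames(data$bisulfite$isodecoder_truth$expr_log2fc,
                               data$bisulfite$isodecoder_truth$isodecoder)
    correlation <- correlate_expr_meth(expr_fc, vdelta, method = "pearson")
  }
  write_tsv(data.frame(uug = rep(rownames(cluster$grid), 4L),
                       cug = rep(colnames(cluster$grid), each = 4L),
                       count = as.vector(cluster$grid)),
            file.path(out, "cluster_grid.tsv"))
  write_tsv(charging, file.path(out, "charging.tsv"))
  write_tsv(fragments, file.path(out, "fragments.tsv"))
  jsonlite::write_json(
    list(fraction = expl$fraction, explained_count = expl$explained_count,
         total_count = expl$total_count),
    file.path(out, "explained_fraction.json"), auto_unbox = TRUE, digits = NA)

  # --- report -----------------------------------------------------------
  resolved <- config[!vapply(config, is.null, logical(1L))]
  resolved$design <- unclass(design)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("m5Ccodon")),
                 thresholds = list(fc_gate = config$fc_gate,
                                   p_gate = config$p_gate,
                                   pseudocount = config$pseudocount,
                                   min_cov = config$min_cov,
                                   candidate_min = config$candidate_min,
                                   lost_high = config$lost_high,
                                   lost_low = config$lost_low),
                 n_te_down = nrow(te_down),
                 explained_fraction = expl$fraction,
                 truth_explained_fraction = truth_fraction)
  jsonlite::write_json(c(report, list(resolved_config = resolved[
    setdiff(names(resolved), c("design", "out_dir", "input_dir"))])),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)

  structure(list(config = config, data = data, te_records = te_rec,
                 te_down = te_down, usage = usage, ca = ca, sites = sites,
                 methylation = meth_cmp, region_density = dens, pfm = pfm,
                 cluster = cluster, explained = expl, charging = charging,
                 fragments = fragments, correlation = correlation,
                 report = report),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  seed: %d\n", x$config$seed))
  cat(sprintf("  TE-down genes selected: %d\n", nrow(x$te_down)))
  if (!is.null(x$ca) && !x$ca$zero_inertia)
    cat(sprintf("  CA axis 1/2 shares: %.2f%% / %.2f%%\n",
                100 * x$ca$inertia_fractions[1L],
                100 * x$ca$inertia_fractions[2L]))
  cat(sprintf("  isodecoders lost: %d of %d\n",
              sum(x$methylation$isodecoders$lost),
              nrow(x$methylation$isodecoders)))
  cat(sprintf("  explained fraction (UUG rule): %.3f (%d/%d)\n",
              x$explained$fraction, x$explained$explained_count,
              x$explained$total_count))
  invisible(x)
}
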