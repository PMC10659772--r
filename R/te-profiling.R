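# Translation-efficiency profiling: CPM normalisation of paired mRNA-seq /
# Ribo-seq counts, per-sample TE, Welch differential calls on log2 values
# with |log2FC| and p gates, direction-concordance classification and
# ranked selection of TE-down genes.

#' Counts-per-million normalisation
#'
#' \eqn{CPM_{gs} = 10^6 x_{gs} / \sum_g x_{gs}}. Scale-free per sample, so
#' downstream TE ratios cancel library size exactly.
#'
#' @param x an \code{expr_matrix} or a plain counts matrix.
#' @return numeric matrix of CPM values with the input's dimnames.
#' @export
normalize_counts <- function(x) {
  m <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  libs <- colSums(m)
  if (any(libs == 0)) stop("zero library size in sample(s): ",
                           paste(colnames(m)[libs == 0], collapse = ", "))
  sweep(m, 2L, libs, "/") * 1e6
}

#' Translation efficiency per gene and sample pair
#'
#' TE is the ratio of normalised translation to normalised mRNA level,
#' stabilised with a pseudo-count:
#' \eqn{TE = (ribo + \epsilon) / (mrna + \epsilon)} with \eqn{\epsilon}
#' 0.5 CPM by default. Gene sets and sample sets must match.
#'
#' @param ribo_norm,mrna_norm matched CPM matrices (genes x samples).
#' @param pseudocount stabiliser in CPM units.
#' @return matrix of TE values; attribute \code{low_evidence} marks entries
#'   where both assays were zero (TE pinned at 1 by the pseudo-count).
#' @export
compute_te <- function(ribo_norm, mrna_norm, pseudocount = 0.5) {
  if (!identical(dim(ribo_norm), dim(mrna_norm)) ||
      !identical(rownames(ribo_norm), rownames(mrna_norm)))
    stop("ribo and mrna matrices must share genes and samples")
  te <- (ribo_norm + pseudocount) / (mrna_norm + pseudocount)
  attr(te, "low_evidence") <- ribo_norm == 0 & mrna_norm == 0
  te
}

# Welch two-sample test on (optionally log2) values; explicit zero-variance
# branch because stats::t.test() refuses essentially-constant data, while
# the limiting p-values (1 for identical constants, 0 for separated
# constants) are well defined here.
.welch <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    return(c(diff = mean(b) - mean(a), p = NA_real_))
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(b) - mean(a)
  if (va < 1e-20 && vb < 1e-20)
    return(c(diff = d, p = if (abs(d) < 1e-12) 1 else 0))
  se2 <- va / length(a) + vb / length(b)
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1L) +
                 (vb / length(b))^2 / (length(b) - 1L))
  c(diff = d, p = 2 * stats::pt(-abs(t), df))
}

#' Differential change between two conditions
#'
#' Per gene: \code{log2fc} is the mean log2 of condition B minus the mean
#' log2 of condition A, and \code{p} a two-sided Welch t-test on the log2
#' values (on the raw values when \code{on_log_scale = FALSE}). With fewer
#' than two replicates in a group the fold change is still reported and the
#' p-value is \code{NA}.
#'
#' @param values genes x samples matrix of positive values (CPM or TE).
#' @param condition per-sample condition tags.
#' @param ref,alt condition labels: change is \code{alt} relative to
#'   \code{ref}.
#' @param on_log_scale test on log2-transformed values (default TRUE).
#' @return data.frame with \code{gene_id}, \code{log2fc}, \code{p}.
#' @export
differential <- function(values, condition, ref, alt, on_log_scale = TRUE) {
  ia <- which(condition == ref)
  ib <- which(condition == alt)
  if (!length(ia) || !length(ib))
    stop("conditions not found: ", ref, " / ", alt)
  v <- if (on_log_scale) log2(values) else values
  res <- t(apply(v, 1L, function(row) .welch(row[ia], row[ib])))
  fc <- res[, "diff"]
  if (!on_log_scale) fc <- apply(values, 1L, function(row)
    log2(mean(row[ib]) / mean(row[ia])))
  data.frame(gene_id = rownames(values), log2fc = unname(fc),
             p = unname(res[, "p"]), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify mRNA / TE direction concordance
#'
#' A change is significant when \code{|log2fc| >= fc_gate} and
#' \code{p < p_gate}. Both significant with the same sign:
#' \code{homo_direction}; both significant with opposite signs:
#' \code{opposite}; exactly one significant: \code{mrna_only} or
#' \code{te_only}; otherwise \code{ns}.
#'
#' @param log2fc_mrna,p_mrna,log2fc_te,p_te vectors of differential results.
#' @param fc_gate,p_gate significance gates (defaults 1 and 0.05).
#' @return character vector of direction classes.
#' @export
classify_direction <- function(log2fc_mrna, p_mrna, log2fc_te, p_te,
                               fc_gate = 1, p_gate = 0.05) {
  sig_m <- !is.na(p_mrna) & abs(log2fc_mrna) >= fc_gate & p_mrna < p_gate
  sig_t <- !is.na(p_te) & abs(log2fc_te) >= fc_gate & p_te < p_gate
  out <- rep("ns", length(log2fc_mrna))
  out[sig_m & !sig_t] <- "mrna_only"
  out[!sig_m & sig_t] <- "te_only"
  both <- sig_m & sig_t
  out[both & sign(log2fc_mrna) == sign(log2fc_te)] <- "homo_direction"
  out[both & sign(log2fc_mrna) != sign(log2fc_te)] <- "opposite"
  out
}

#' Full TE profiling of a paired mRNA / Ribo-seq experiment
#'
#' Runs CPM normalisation, TE computation, Welch differentials for mRNA and
#' TE, Benjamini-Hochberg adjusted p-values (reported, not used for
#' gating) and direction classification.
#'
#' @param mrna,ribo paired \code{expr_matrix} objects over identical genes
#'   and samples.
#' @param ref,alt condition labels (change is \code{alt} vs \code{ref}).
#' @param pseudocount TE stabiliser in CPM (default 0.5).
#' @param fc_gate,p_gate significance gates for direction classes.
#' @return data.frame of TE records: per-gene log2 fold changes, p-values,
#'   BH-adjusted p-values and direction class, with the TE matrix attached
#'   as attribute \code{te}.
#' @export
te_profile <- function(mrna, ribo, ref, alt, pseudocount = 0.5,
                       fc_gate = 1, p_gate = 0.05) {
  stopifnot(inherits(mrna, "expr_matrix"), inherits(ribo, "expr_matrix"))
  if (!identical(rownames(mrna$counts), rownames(ribo$counts)))
    stop("mRNA and ribo matrices must cover the same genes in the same order")
  if (!identical(mrna$condition, ribo$condition))
    stop("mRNA and ribo matrices must share the condition design")
  mrna_cpm <- normalize_counts(mrna)
  ribo_cpm <- normalize_counts(ribo)
  te <- compute_te(ribo_cpm, mrna_cpm, pseudocount)
  d_m <- differential(mrna_cpm + pseudocount, mrna$condition, ref, alt)
  d_t <- differential(te, mrna$condition, ref, alt)
  rec <- data.frame(gene_id = d_m$gene_id,
                    log2fc_mrna = d_m$log2fc, p_mrna = d_m$p,
                    log2fc_te = d_t$log2fc, p_te = d_t$p,
                    padj_mrna = stats::p.adjust(d_m$p, "BH"),
                    padj_te = stats::p.adjust(d_t$p, "BH"),
                    stringsAsFactors = FALSE)
  rec$direction <- classify_direction(rec$log2fc_mrna, rec$p_mrna,
                                      rec$log2fc_te, rec$p_te,
                                      fc_gate, p_gate)
  attr(rec, "te") <- te
  rec
}

#' Select top TE-down-regulated genes
#'
#' Filters records to \code{log2fc_te <= -fc_gate} and \code{p_te < p_gate},
#' ranks by ascending TE log2 fold change (ties broken by gene ID for
#' determinism) and returns the top \code{n_top}. If fewer genes pass the
#' gates than requested, the whole pool is returned with a message.
#'
#' @param records TE record data.frame from \code{\link{te_profile}}.
#' @param n_top number of genes to keep.
#' @param fc_gate,p_gate significance gates.
#' @return data.frame of selected records in rank order.
#' @export
select_te_down <- function(records, n_top = 1000L, fc_gate = 1, p_gate = 0.05) {
  pool <- records[!is.na(records$p_te) &
                    records$log2fc_te <= -fc_gate &
                    records$p_te < p_gate, , drop = FALSE]
  pool <- pool[order(pool$log2fc_te, pool$gene_id), , drop = FALSE]
  if (nrow(pool) < n_top)
    message("only ", nrow(pool), " genes pass the TE-down gates (requested ",
            n_top, ")")
  utils::head(pool, n_top)
}
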