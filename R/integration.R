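# Linking analyses: the UUG x CUG cluster grid over TE-down genes with the
# explained-fraction statistic, delta-delta-Ct quantification for tRNA
# charging and fragment assays, and isodecoder expression vs m5C
# correlation.

.CLASS_ORDER <- c("underrepresented", "typical", "abundant", "overrepresented")

#' Cluster TE-down genes by UUG and CUG usage
#'
#' Classifies each gene's RSCU(UUG) and RSCU(CUG) with
#' \code{\link{classify_codon}} and fills a 4 x 4 grid of counts over the
#' classes (under / typical / abundant / over). Genes with an absent
#' leucine family are excluded and counted.
#'
#' @param gene_ids gene IDs of the TE-down set.
#' @param rscu genes x 59 RSCU matrix from \code{\link{rscu_matrix}} (must
#'   cover all listed genes).
#' @return an object of class \code{cluster_table}: list with
#'   \code{per_gene} (gene_id, rscu_uug, rscu_cug, class_uug, class_cug),
#'   \code{grid} (4 x 4 count matrix, UUG classes in rows),
#'   \code{total_count} and \code{n_excluded}.
#' @export
cluster_by_codon <- function(gene_ids, rscu) {
  if (!length(gene_ids)) stop("empty gene list")
  miss <- setdiff(gene_ids, rownames(rscu))
  if (length(miss)) stop("no RSCU profile for gene(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  uug <- rscu[gene_ids, "UUG"]
  cug <- rscu[gene_ids, "CUG"]
  keep <- !is.na(uug) & !is.na(cug)
  n_excluded <- sum(!keep)
  if (n_excluded)
    message(n_excluded, " gene(s) with no leucine codons excluded from the grid")
  per_gene <- data.frame(gene_id = gene_ids[keep],
                         rscu_uug = unname(uug[keep]),
                         rscu_cug = unname(cug[keep]),
                         class_uug = classify_codon(unname(uug[keep])),
                         class_cug = classify_codon(unname(cug[keep])),
                         stringsAsFactors = FALSE)
  grid <- table(factor(per_gene$class_uug, levels = .CLASS_ORDER),
                factor(per_gene$class_cug, levels = .CLASS_ORDER))
  grid <- unclass(grid)
  names(dimnames(grid)) <- c("UUG", "CUG")
  structure(list(per_gene = per_gene, grid = grid,
                 total_count = nrow(per_gene), n_excluded = n_excluded),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d genes (%d excluded, absent Leu family)\n",
              x$total_count, x$n_excluded))
  print(x$grid)
  invisible(x)
}

# default cell rule: UUG at least abundant and strictly above the CUG class
.default_cells <- function() {
  cells <- expand.grid(uug = .CLASS_ORDER, cug = .CLASS_ORDER,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- function(cl) match(cl, .CLASS_ORDER)
  cells[ord(cells$uug) >= ord("abundant") &
          ord(cells$uug) > ord(cells$cug), , drop = FALSE]
}

#' Fraction of TE-down-regulation explained by UUG bias
#'
#' The explained fraction is the share of grid genes falling in the
#' selected cells. The default selection operationalises "down-regulation
#' attributable to UUG usage": cells where the UUG class is at least
#' abundant and strictly exceeds the CUG class (class order under < typical
#' < abundant < over). Can also be evaluated directly on printed cell
#' counts via the numeric method.
#'
#' @param x a \code{cluster_table}, or a numeric vector of selected cell
#'   counts.
#' @param ... passed to methods.
#' @return list with \code{fraction}, \code{explained_count},
#'   \code{total_count} and (for the table method) the selected
#'   \code{cells} with their counts.
#' @examples
#' explained_fraction(c(133, 15, 536), total = 1917)$fraction  # 0.3568
#' @export
explained_fraction <- function(x, ...) UseMethod("explained_fraction")

#' @rdname explained_fraction
#' @param total total gene count (numeric method).
#' @export
explained_fraction.numeric <- function(x, total, ...) {
  if (total <= 0) stop("total count must be positive")
  list(fraction = sum(x) / total, explained_count = sum(x),
       total_count = total)
}

#' @rdname explained_fraction
#' @param cells data.frame with columns \code{uug}, \code{cug} naming the
#'   selected grid cells; default rule described above.
#' @export
explained_fraction.cluster_table <- function(x, cells = NULL, ...) {
  if (is.null(cells)) cells <- .default_cells()
  if (!all(cells$uug %in% .CLASS_ORDER) || !all(cells$cug %in% .CLASS_ORDER))
    stop("cells must name classes among: ", paste(.CLASS_ORDER, collapse = ", "))
  if (x$total_count == 0) stop("empty cluster table")
  cells$count <- if (nrow(cells)) as.numeric(
    mapply(function(u, c) x$grid[u, c], cells$uug, cells$cug)) else numeric(0)
  list(fraction = sum(cells$count) / x$total_count,
       explained_count = sum(cells$count),
       total_count = x$total_count,
       cells = cells)
}

#' Charged-tRNA ratio from a periodate protection assay
#'
#' Delta-delta-Ct quantification of the charged fraction: periodate
#' destroys the 3' end of uncharged tRNA, so the oxidised channel
#' amplifies only charged molecules. The ratio is
#' \eqn{2^{-[(Ct_{ox} - Ct_{ref,ox}) - (Ct_{nonox} - Ct_{ref,nonox})]}}
#' against a spike-in reference. Scale-free in Ct: adding a constant to
#' every Ct leaves the ratio unchanged.
#'
#' @param ct_ox,ct_nonox target Ct in the oxidised / non-oxidised channel.
#' @param ct_ref_ox,ct_ref_nonox reference (spike-in) Ct values.
#' @return charged ratio (vectors allowed).
#' @export
charging_ratio <- function(ct_ox, ct_nonox, ct_ref_ox, ct_ref_nonox) {
  2^(-((ct_ox - ct_ref_ox) - (ct_nonox - ct_ref_nonox)))
}

#' Relative quantity of a tRNA or fragment by delta-delta-Ct
#'
#' Standard \eqn{2^{-\Delta\Delta Ct}} against a U6 internal control and a
#' control condition.
#'
#' @param ct_target,ct_u6 Ct values in the test condition.
#' @param ct_target_ctrl,ct_u6_ctrl Ct values in the control condition.
#' @return relative quantity (vectors allowed).
#' @export
fragment_quantification <- function(ct_target, ct_u6, ct_target_ctrl,
                                    ct_u6_ctrl) {
  2^(-((ct_target - ct_u6) - (ct_target_ctrl - ct_u6_ctrl)))
}

#' Summarise a charging qPCR table
#'
#' Computes the per-replicate charged ratio for each target and condition,
#' then the geometric mean over replicates.
#'
#' @param qpcr long Ct table from \code{\link{read_qpcr_table}} (charging
#'   assay rows).
#' @return data.frame with \code{target}, \code{condition},
#'   \code{charged_ratio}, \code{n_reps}.
#' @export
charging_summary <- function(qpcr) {
  q <- qpcr[qpcr$assay == "charging", , drop = FALSE]
  need <- c("ox", "nonox", "ref_ox", "ref_nonox")
  if (!all(need %in% q$channel))
    stop("charging assay requires channels: ", paste(need, collapse = ", "))
  key <- unique(q[, c("target", "condition")])
  res <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- q[q$target == key$target[i] & q$condition == key$condition[i], ]
    reps <- sort(unique(sub$replicate))
    ratios <- vapply(reps, function(r) {
      ch <- function(x) {
        v <- sub$ct[sub$channel == x & sub$replicate == r]
        if (length(v) != 1L) stop("missing channel '", x, "' for ",
                                  key$target[i], " / ", key$condition[i],
                                  " replicate ", r)
        v
      }
      charging_ratio(ch("ox"), ch("nonox"), ch("ref_ox"), ch("ref_nonox"))
    }, numeric(1L))
    data.frame(target = key$target[i], condition = key$condition[i],
               charged_ratio = exp(mean(log(ratios))),
               n_reps = length(reps), stringsAsFactors = FALSE)
  }))
  res
}

#' Summarise a fragment qPCR table
#'
#' Per-target relative quantity in the test condition versus the control
#' condition by delta-delta-Ct against the U6 channel, geometric-averaged
#' over replicates.
#'
#' @param qpcr long Ct table (fragment assay rows, channels \code{target}
#'   and \code{u6}).
#' @param ref,alt control / test condition labels.
#' @return data.frame with \code{target}, \code{rel_quantity},
#'   \code{n_reps}.
#' @export
fragment_summary <- function(qpcr, ref, alt) {
  q <- qpcr[qpcr$assay == "fragment", , drop = FALSE]
  if (!"u6" %in% q$channel) stop("fragment assay requires a u6 reference channel")
  targets <- setdiff(unique(q$target), "U6")
  do.call(rbind, lapply(targets, function(tg) {
    reps <- sort(unique(q$replicate))
    rq <- vapply(reps, function(r) {
      ct <- function(cond, chan, tgt) {
        v <- q$ct[q$condition == cond & q$channel == chan &
                    q$replicate == r & q$target == tgt]
        if (length(v) != 1L) stop("missing ", chan, " Ct for ", tgt,
                                  " / ", cond, " replicate ", r)
        v
      }
      fragment_quantification(ct(alt, "target", tg), ct(alt, "u6", "U6"),
                              ct(ref, "target", tg), ct(ref, "u6", "U6"))
    }, numeric(1L))
    data.frame(target = tg, rel_quantity = exp(mean(log(rq))),
               n_reps = length(reps), stringsAsFactors = FALSE)
  }))
}

#' Correlate isodecoder expression change with m5C change
#'
#' Spearman (default) or Pearson correlation between per-isodecoder log2
#' expression changes and methylation deltas (e.g. at the variable loop),
#' with a two-sided p-value. Pairs with uncalled (NA) methylation are
#' dropped and counted.
#'
#' @param expr_log2fc named numeric vector of expression changes.
#' @param meth_delta named numeric vector of methylation deltas (matched
#'   by name when names are present, by position otherwise).
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return list with \code{estimate}, \code{p_value}, \code{method},
#'   \code{n_used}, \code{n_dropped}.
#' @export
correlate_expr_meth <- function(expr_log2fc, meth_delta,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.null(names(expr_log2fc)) && !is.null(names(meth_delta)))
    meth_delta <- meth_delta[names(expr_log2fc)]
  ok <- !is.na(expr_log2fc) & !is.na(meth_delta)
  if (sum(ok) < 3L) stop("need at least 3 complete isodecoder pairs")
  ct <- stats::cor.test(expr_log2fc[ok], meth_delta[ok], method = method,
                        alternative = "two.sided", exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n_used = sum(ok), n_dropped = sum(!ok))
}
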