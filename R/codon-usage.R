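# Codon usage statistics: codon counts, RSCU with over/under-representation
# classes, GC3s, Wright's effective number of codons (ENC) with the expected
# null curve, and correspondence analysis of the genes x 59-codon RSCU
# matrix.

#' Count codons in a coding sequence
#'
#' Frame-0 triplet counting over the 64 codons. Stops are tallied under
#' their own codon (a terminal stop is counted) but are excluded from all
#' downstream statistics.
#'
#' @param seq a validated CDS (DNA or RNA alphabet).
#' @param gene_id optional identifier attached to the result.
#' @return named integer vector of length 64 (RNA codon labels), with
#'   attribute \code{gene_id}.
#' @examples
#' count_codons("ATGTTGTAA")[c("AUG", "UUG", "UAA")]
#' @export
count_codons <- function(seq, gene_id = NULL) {
  seq <- chartr("U", "T", toupper(seq))
  if (nchar(seq) %% 3L != 0L) stop("sequence length is not a multiple of 3")
  cods <- .split_codons(seq)
  tab <- .code()
  counts <- integer(length(tab$codons))
  names(counts) <- tab$codons
  obs <- table(cods)
  bad <- setdiff(names(obs), tab$codons)
  if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "))
  counts[names(obs)] <- as.integer(obs)
  names(counts) <- codon_to_rna(names(counts))
  attr(counts, "gene_id") <- gene_id
  counts
}

#' Relative synonymous codon usage
#'
#' For each synonymous family with \eqn{n_k} codons, RSCU of codon \eqn{m}
#' is the observed count \eqn{a_{km}} divided by the family mean
#' \eqn{(1/n_k)\sum_m a_{km}}; 1 means no bias and the per-family RSCU sum
#' equals the family size. Families with zero observations are \code{NA}
#' ("absent"). AUG, UGG and stop codons are excluded, leaving the 59
#' informative codons.
#'
#' @param counts a 64-codon count vector from \code{\link{count_codons}},
#'   or any named numeric vector covering the informative codons.
#' @return named numeric vector over the 59 informative codons (RNA
#'   labels), \code{NA} for absent families; attribute \code{gene_id}
#'   carried through.
#' @export
compute_rscu <- function(counts) {
  fams <- .degenerate_families()
  nm_dna <- codon_to_dna(names(counts))
  rscu <- stats::setNames(rep(NA_real_, length(.code()$informative)),
                          codon_to_rna(.code()$informative))
  for (fam in fams) {
    idx <- match(fam, nm_dna)
    if (anyNA(idx)) stop("count vector is missing codon(s): ",
                         paste(fam[is.na(idx)], collapse = ", "))
    a <- as.numeric(counts[idx])
    tot <- sum(a)
    if (tot > 0) rscu[codon_to_rna(fam)] <- a / (tot / length(fam))
  }
  attr(rscu, "gene_id") <- attr(counts, "gene_id")
  rscu
}

#' Classify an RSCU value
#'
#' Class cut-offs: RSCU > 1.6 overrepresented; 1 < RSCU <= 1.6 abundant;
#' 0.6 <= RSCU <= 1 typical; RSCU < 0.6 underrepresented; \code{NA}
#' (unobserved family) maps to \code{"absent"}.
#'
#' @param rscu numeric vector of RSCU values (nonnegative or NA).
#' @return character vector of classes.
#' @export
classify_codon <- function(rscu) {
  if (any(rscu < 0, na.rm = TRUE)) stop("RSCU values must be nonnegative")
  out <- rep("absent", length(rscu))
  ok <- !is.na(rscu)
  out[ok & rscu > 1.6] <- "overrepresented"
  out[ok & rscu > 1 & rscu <= 1.6] <- "abundant"
  out[ok & rscu >= 0.6 & rscu <= 1] <- "typical"
  out[ok & rscu < 0.6] <- "underrepresented"
  names(out) <- names(rscu)
  out
}

#' GC content at synonymous third positions
#'
#' Fraction of third codon positions that are G or C, over codons of
#' synonymously degenerate families only (AUG, UGG and stops excluded).
#'
#' @param counts a 64-codon count vector.
#' @return a value in [0, 1], or \code{NA} if no eligible codon was
#'   observed.
#' @export
compute_gc3s <- function(counts) {
  elig <- unlist(.degenerate_families(), use.names = FALSE)
  nm_dna <- codon_to_dna(names(counts))
  idx <- match(elig, nm_dna)
  a <- as.numeric(counts[idx])
  tot <- sum(a)
  if (tot == 0) return(NA_real_)
  third <- substr(elig, 3L, 3L)
  sum(a[third %in% c("G", "C")]) / tot
}

#' Wright's effective number of codons (ENC)
#'
#' Per-family codon homozygosity \eqn{F = (n \sum p^2 - 1)/(n - 1)} for
#' families observed at least twice; class averages over families of
#' degeneracy 2, 3, 4 and 6; then
#' \eqn{ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6},
#' capped at 61. A missing 3-fold class (isoleucine unobserved) is imputed
#' as the mean of the 2- and 4-fold averages, following the conventions of
#' the classic CodonW implementation. \code{NA} if any other class average
#' is missing or nonpositive. ENC ranges from 20 (one codon per amino
#' acid) to 61 (uniform synonymous usage).
#'
#' @param counts a 64-codon count vector.
#' @return ENC in [20, 61], or \code{NA} when undefined.
#' @export
compute_enc <- function(counts) {
  fams <- .degenerate_families()
  nm_dna <- codon_to_dna(names(counts))
  deg <- vapply(fams, length, integer(1L))
  Fhat <- rep(NA_real_, length(fams))
  for (i in seq_along(fams)) {
    a <- as.numeric(counts[match(fams[[i]], nm_dna)])
    n <- sum(a)
    if (n >= 2) {
      p <- a / n
      Fhat[i] <- (n * sum(p^2) - 1) / (n - 1)
    }
  }
  classes <- c(2L, 3L, 4L, 6L)
  n_fam <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- vapply(classes, function(k) {
    v <- Fhat[deg == k & !is.na(Fhat)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  names(Fbar) <- classes
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (any(is.na(Fbar)) || any(Fbar <= 0)) return(NA_real_)
  enc <- 2 + sum(n_fam / Fbar)
  min(enc, 61)
}

#' Expected ENC under GC3s-driven mutational bias
#'
#' The null ENC-plot curve: \eqn{ENC_{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)}
#' with \eqn{s} the GC3s value. Genes falling well below the curve show
#' codon bias beyond what base composition alone predicts.
#'
#' @param gc3s numeric vector in [0, 1].
#' @return expected ENC values.
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.na(gc3s) & (gc3s < 0 | gc3s > 1)))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Per-gene ENC / GC3s table for the ENC plot
#'
#' One row per gene with GC3s, ENC, expected ENC and a below-curve flag;
#' rows with undefined ENC are retained with a missing flag so the plot
#' table accounts for every input gene.
#'
#' @param counts_list named list of 64-codon count vectors (names are gene
#'   IDs) as from \code{\link{count_codons}}.
#' @return data.frame with columns \code{gene_id}, \code{gc3s}, \code{enc},
#'   \code{enc_expected}, \code{below_curve}.
#' @export
enc_plot_table <- function(counts_list) {
  gc3s <- vapply(counts_list, compute_gc3s, numeric(1L))
  enc <- vapply(counts_list, compute_enc, numeric(1L))
  expd <- ifelse(is.na(gc3s), NA_real_, enc_expected(gc3s))
  data.frame(gene_id = names(counts_list),
             gc3s = gc3s, enc = enc, enc_expected = expd,
             below_curve = ifelse(is.na(enc) | is.na(expd), NA, enc < expd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the genes x 59-codon RSCU matrix
#'
#' @param rscu_list named list of RSCU vectors from
#'   \code{\link{compute_rscu}}.
#' @return numeric matrix, genes in rows, the 59 informative codons in
#'   columns (RNA labels); absent families are \code{NA}.
#' @export
rscu_matrix <- function(rscu_list) {
  cods <- informative_codons()
  m <- do.call(rbind, lapply(rscu_list, function(r) r[cods]))
  rownames(m) <- names(rscu_list)
  colnames(m) <- cods
  m
}

#' Correspondence analysis of an RSCU matrix
#'
#' Chi-square-metric decomposition of the genes x codons matrix: with
#' correspondence matrix \eqn{P = X / \sum X}, row/column masses \eqn{r, c}
#' and standardised residuals
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}, the SVD of \eqn{S} gives
#' principal inertias \eqn{\lambda_i = \sigma_i^2} and mass-scaled principal
#' coordinates. Absent (NA) entries are imputed as 0; genes with more than
#' \code{max_absent} absent codons are dropped (and reported), as are
#' all-zero rows or columns.
#'
#' @param x nonnegative genes x codons matrix (NAs allowed).
#' @param max_absent drop genes with more NA entries than this (default 30).
#' @return an object of class \code{ca_result}: list with
#'   \code{row_coords}, \code{col_coords}, \code{inertia},
#'   \code{inertia_fractions}, \code{total_inertia}, \code{zero_inertia}
#'   flag and \code{dropped_genes}.
#' @export
correspondence_analysis <- function(x, max_absent = 30L) {
  x <- as.matrix(x)
  n_abs <- rowSums(is.na(x))
  dropped <- rownames(x)[n_abs > max_absent]
  x <- x[n_abs <= max_absent, , drop = FALSE]
  x[is.na(x)] <- 0
  if (any(x < 0)) stop("correspondence analysis needs a nonnegative matrix")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 rows and 2 columns with positive mass")
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  lambda <- sv$d^2
  total <- sum(lambda)
  zero <- total < 1e-12
  k <- min(nrow(x), ncol(x)) - 1L
  keep <- seq_len(max(k, 0L))
  lambda <- lambda[keep]
  frac <- if (zero) rep(NA_real_, length(keep)) else lambda / sum(sv$d^2)
  rowc <- sweep(sv$u[, keep, drop = FALSE] * rep(sv$d[keep], each = nrow(x)),
                1L, sqrt(r), "/")
  colc <- sweep(sv$v[, keep, drop = FALSE] * rep(sv$d[keep], each = ncol(x)),
                1L, sqrt(cc), "/")
  dimnames(rowc) <- list(rownames(x), paste0("Axis", seq_along(keep)))
  dimnames(colc) <- list(colnames(x), paste0("Axis", seq_along(keep)))
  structure(list(row_coords = rowc, col_coords = colc,
                 inertia = lambda, inertia_fractions = frac,
                 total_inertia = total, zero_inertia = zero,
                 dropped_genes = dropped),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d genes x %d codons, total inertia %.4g\n",
              nrow(x$row_coords), nrow(x$col_coords), x$total_inertia))
  if (x$zero_inertia) {
    cat("  zero total inertia (rows proportional: independence model exact)\n")
  } else {
    k <- min(4L, length(x$inertia_fractions))
    cat("  axis shares:",
        paste(sprintf("%.2f%%", 100 * x$inertia_fractions[seq_len(k)]),
              collapse = ", "), "\n")
  }
  if (length(x$dropped_genes))
    cat("  dropped", length(x$dropped_genes), "gene(s) with sparse RSCU\n")
  invisible(x)
}

#' Per-gene codon usage profile
#'
#' Convenience wrapper computing counts, RSCU, classes, GC3s and ENC for a
#' set of coding sequences, plus a pooled ("concatenate") RSCU obtained by
#' summing counts over all genes before the RSCU step.
#'
#' @param seqs named character vector of validated CDS.
#' @return list with \code{counts} (list), \code{rscu} (genes x 59 matrix),
#'   \code{classes} (genes x 59 character matrix), \code{enc_table}
#'   (data.frame) and \code{pooled_rscu} (length-59 vector).
#' @export
codon_usage_profile <- function(seqs) {
  counts <- lapply(seq_along(seqs),
                   function(i) count_codons(seqs[[i]], gene_id = names(seqs)[i]))
  names(counts) <- names(seqs)
  rscu <- rscu_matrix(lapply(counts, compute_rscu))
  classes <- rscu
  classes[] <- classify_codon(as.numeric(rscu))
  pooled_counts <- Reduce(`+`, lapply(counts, as.integer))
  names(pooled_counts) <- names(counts[[1L]])
  pooled <- compute_rscu(pooled_counts)
  list(counts = counts, rscu = rscu, classes = classes,
       enc_table = enc_plot_table(counts), pooled_rscu = pooled)
}
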