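# tRNA m5C quantification from bisulphite site counts: per-cytosine rate
# calling with non-conversion correction, isodecoder-level summaries,
# structural-region densities, condition comparisons with loss flags, and
# sequence-context position frequency matrices.

#' Call a per-cytosine methylation rate
#'
#' Raw rate is \code{meth / (meth + conv)} (unconverted over total reads);
#' the bisulphite non-conversion floor \code{b} is removed as
#' \code{(raw - b) / (1 - b)}, clamped to [0, 1]. Sites below the minimum
#' coverage are uncalled (\code{NA}).
#'
#' @param meth,conv unconverted / converted read counts (vectors allowed).
#' @param nonconversion non-conversion error rate in [0, 1).
#' @param min_cov minimum coverage for a called site (default 10).
#' @return numeric vector of corrected rates in [0, 1], \code{NA} where
#'   uncalled.
#' @export
call_rate <- function(meth, conv, nonconversion = 0, min_cov = 10L) {
  if (nonconversion >= 1 || nonconversion < 0)
    stop("nonconversion must lie in [0, 1)")
  if (any(meth < 0) || any(conv < 0)) stop("negative read count")
  cov <- meth + conv
  raw <- ifelse(cov > 0, meth / cov, NA_real_)
  rate <- pmin(pmax((raw - nonconversion) / (1 - nonconversion), 0), 1)
  rate[cov < min_cov] <- NA_real_
  rate
}

#' Call rates for a bisulphite site table
#'
#' Joins per-cytosine counts with the isodecoder annotation (structural
#' region and canonical label per position) and calls corrected rates.
#'
#' @param site_counts data.frame from \code{\link{read_site_counts}}.
#' @param trnas annotation list from \code{\link{read_trna_annotation}}.
#' @inheritParams call_rate
#' @return data.frame of methylation sites with \code{isodecoder},
#'   \code{position}, \code{canonical_label}, \code{region},
#'   \code{condition}, \code{meth}, \code{conv}, \code{coverage},
#'   \code{rate} (NA = uncalled).
#' @export
call_sites <- function(site_counts, trnas, nonconversion = 0, min_cov = 10L) {
  unknown <- setdiff(unique(site_counts$isodecoder), names(trnas))
  if (length(unknown))
    stop("site table references unannotated isodecoder(s): ",
         paste(unknown, collapse = ", "))
  idx <- match(site_counts$isodecoder, names(trnas))
  region <- mapply(function(i, pos) trnas[[i]]$region[pos + 1L],
                   idx, site_counts$position)
  label <- mapply(function(i, pos) trnas[[i]]$canonical_label[pos + 1L],
                  idx, site_counts$position)
  data.frame(isodecoder = site_counts$isodecoder,
             position = site_counts$position,
             canonical_label = label, region = region,
             condition = site_counts$condition,
             meth = site_counts$meth, conv = site_counts$conv,
             coverage = site_counts$meth + site_counts$conv,
             rate = call_rate(site_counts$meth, site_counts$conv,
                              nonconversion, min_cov),
             stringsAsFactors = FALSE)
}

# candidate sites: rate >= candidate_min in at least one condition
.candidate_keys <- function(sites, candidate_min) {
  key <- paste(sites$isodecoder, sites$position)
  ok <- !is.na(sites$rate) & sites$rate >= candidate_min
  unique(key[ok])
}

#' Summarised m5C level per isodecoder
#'
#' Unweighted mean of called rates over candidate sites (sites reaching
#' \code{candidate_min} in at least one condition), per isodecoder and
#' condition. Isodecoders with no candidate site get \code{NA} with zero
#' site count.
#'
#' @param sites called site table from \code{\link{call_sites}}.
#' @param candidate_min candidate-site rate threshold (default 0.1).
#' @return data.frame with \code{isodecoder}, \code{condition},
#'   \code{level}, \code{n_sites}.
#' @export
summarize_isodecoder <- function(sites, candidate_min = 0.1) {
  cand <- .candidate_keys(sites, candidate_min)
  key <- paste(sites$isodecoder, sites$position)
  grid <- expand.grid(isodecoder = unique(sites$isodecoder),
                      condition = unique(sites$condition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(iso, cond) {
    sel <- sites$isodecoder == iso & sites$condition == cond &
      key %in% cand & !is.na(sites$rate)
    c(level = if (any(sel)) mean(sites$rate[sel]) else NA_real_,
      n = sum(sel))
  }, grid$isodecoder, grid$condition)
  grid$level <- res["level", ]
  grid$n_sites <- as.integer(res["n", ])
  grid
}

#' Methylation-rate density by structural region
#'
#' Groups called sites by secondary-structure region and condition,
#' returning the per-region rate vectors (backing a ridge/density plot)
#' and a per-region summary with the mean rate difference between two
#' conditions.
#'
#' @param sites called site table.
#' @param ref,alt condition labels for the delta (\code{alt - ref});
#'   defaults to the two conditions present, in sorted order.
#' @return list with \code{rates} (data.frame: region, condition, rate) and
#'   \code{summary} (data.frame: region, mean and n per condition,
#'   \code{mean_delta}).
#' @export
region_density <- function(sites, ref = NULL, alt = NULL) {
  bad <- setdiff(unique(sites$region), .REGIONS)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  conds <- sort(unique(sites$condition))
  if (is.null(ref)) ref <- conds[1L]
  if (is.null(alt)) alt <- conds[min(2L, length(conds))]
  called <- sites[!is.na(sites$rate), , drop = FALSE]
  rates <- data.frame(region = called$region, condition = called$condition,
                      rate = called$rate, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(intersect(.REGIONS, unique(called$region)),
                                function(rg) {
    a <- called$rate[called$region == rg & called$condition == ref]
    b <- called$rate[called$region == rg & called$condition == alt]
    data.frame(region = rg,
               mean_ref = if (length(a)) mean(a) else NA_real_, n_ref = length(a),
               mean_alt = if (length(b)) mean(b) else NA_real_, n_alt = length(b),
               mean_delta = if (length(a) && length(b)) mean(b) - mean(a)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(rates = rates, summary = summ)
}

#' Compare site-level methylation between conditions
#'
#' Per-site delta (knockdown minus control) over matching site keys, plus
#' an isodecoder-level "lost" flag: summarised control level at least
#' \code{lost_high} and knockdown level at most \code{lost_low}.
#'
#' @param sites called site table covering both conditions.
#' @param ref,alt control / knockdown condition labels.
#' @param lost_high,lost_low isodecoder loss thresholds (defaults 0.5, 0.1).
#' @param candidate_min candidate-site rule for the isodecoder summary.
#' @return list with \code{sites} (per-site comparison: rates, delta,
#'   called flags) and \code{isodecoders} (levels per condition + lost
#'   flag). Site keys present in only one condition are dropped and
#'   counted in attribute \code{n_unmatched}.
#' @export
compare_conditions <- function(sites, ref, alt, lost_high = 0.5,
                               lost_low = 0.1, candidate_min = 0.1) {
  a <- sites[sites$condition == ref, , drop = FALSE]
  b <- sites[sites$condition == alt, , drop = FALSE]
  ka <- paste(a$isodecoder, a$position)
  kb <- paste(b$isodecoder, b$position)
  common <- intersect(ka, kb)
  n_unmatched <- length(setdiff(union(ka, kb), common))
  if (n_unmatched)
    message(n_unmatched, " site key(s) present in only one condition; skipped")
  ia <- match(common, ka); ib <- match(common, kb)
  cmp <- data.frame(isodecoder = a$isodecoder[ia], position = a$position[ia],
                    canonical_label = a$canonical_label[ia],
                    region = a$region[ia],
                    rate_control = a$rate[ia], rate_kd = b$rate[ib],
                    called_control = !is.na(a$rate[ia]),
                    called_kd = !is.na(b$rate[ib]),
                    stringsAsFactors = FALSE)
  cmp$delta <- cmp$rate_kd - cmp$rate_control
  lev <- summarize_isodecoder(sites, candidate_min)
  iso <- unique(lev$isodecoder)
  lc <- lev$level[match(paste(iso, ref), paste(lev$isodecoder, lev$condition))]
  lk <- lev$level[match(paste(iso, alt), paste(lev$isodecoder, lev$condition))]
  isodecoders <- data.frame(isodecoder = iso, level_control = lc,
                            level_kd = lk,
                            lost = !is.na(lc) & !is.na(lk) &
                              lc >= lost_high & lk <= lost_low,
                            stringsAsFactors = FALSE)
  structure(list(sites = cmp, isodecoders = isodecoders),
            n_unmatched = n_unmatched, class = "meth_comparison")
}

#' @export
print.meth_comparison <- function(x, ...) {
  cat(sprintf("<meth_comparison> %d matched sites, %d isodecoders (%d lost)\n",
              nrow(x$sites), nrow(x$isodecoders), sum(x$isodecoders$lost)))
  invisible(x)
}

#' Sequence context around methylated sites
#'
#' Extracts windows of \code{[-flank, +flank]} around sites methylated in
#' the reference condition (rate at least \code{min_rate}), pads windows
#' running off the sequence with \code{N}, and builds a position frequency
#' matrix with a majority-base consensus (\code{N} on ties) and per-column
#' information content (2 - Shannon entropy over observed A/C/G/U).
#'
#' @param sites called site table (reference condition rows are used).
#' @param trnas annotation list providing sequences.
#' @param flank window half-width in nucleotides.
#' @param min_rate qualifying site threshold (default 0.5).
#' @param condition which condition's rates qualify sites; default the
#'   lexicographically first.
#' @return list with \code{pfm} (4 x width frequency matrix, rows
#'   A/C/G/U), \code{consensus} string, \code{information} per column and
#'   \code{n_sites}.
#' @export
context_pfm <- function(sites, trnas, flank = 2L, min_rate = 0.5,
                        condition = NULL) {
  if (is.null(condition)) condition <- sort(unique(sites$condition))[1L]
  sel <- sites[sites$condition == condition & !is.na(sites$rate) &
                 sites$rate >= min_rate, , drop = FALSE]
  if (!nrow(sel)) stop("no site reaches rate ", min_rate,
                       " in condition ", condition)
  windows <- mapply(function(iso, pos) {
    s <- trnas[[iso]]$seq
    idx <- (pos - flank):(pos + flank) + 1L
    ch <- rep("N", length(idx))
    ok <- idx >= 1L & idx <= nchar(s)
    ch[ok] <- strsplit(s, "")[[1L]][idx[ok]]
    paste(ch, collapse = "")
  }, sel$isodecoder, sel$position)
  width <- 2L * flank + 1L
  bases <- c("A", "C", "G", "T")
  cnt <- matrix(0, 4L, width, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (w in windows) {
    ch <- strsplit(w, "")[[1L]]
    for (j in seq_len(width)) if (ch[j] %in% bases)
      cnt[match(ch[j], bases), j] <- cnt[match(ch[j], bases), j] + 1
  }
  tot <- colSums(cnt)
  pfm <- sweep(cnt, 2L, pmax(tot, 1), "/")
  consensus <- vapply(seq_len(width), function(j) {
    if (tot[j] == 0) return("N")
    mx <- max(cnt[, j])
    top <- rownames(cnt)[cnt[, j] == mx]
    if (length(top) == 1L) top else "N"
  }, character(1L))
  info <- vapply(seq_len(width), function(j) {
    if (tot[j] == 0) return(0)
    f <- pfm[, j][pfm[, j] > 0]
    2 + sum(f * log2(f))
  }, numeric(1L))
  colnames(pfm) <- as.character(seq_len(width) - flank - 1L)
  list(pfm = pfm, consensus = paste(consensus, collapse = ""),
       information = info, n_sites = nrow(sel))
}
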