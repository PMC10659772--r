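# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA coding sequences, TSV count tables (condition encoded in the sample
# name as <condition>_<replicate>), TSV tRNA annotations, TSV bisulphite
# site counts and qPCR Ct tables.

#' Read coding (or tRNA) sequences from FASTA
#'
#' Sequences are uppercased and RNA \code{U} is mapped to \code{T} (with a
#' message), so both DNA and RNA FASTA inputs are accepted. Record IDs are
#' the first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record IDs).
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence ID(s) in FASTA: ",
                        paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    message("RNA alphabet detected: mapping U -> T")
    seqs <- chartr("U", "T", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Validate a coding sequence
#'
#' Checks the CDS invariants: alphabet restricted to ACGT, length a multiple
#' of 3, and (unless \code{allow_internal_stop}) no stop codon before the
#' final position. A terminal stop is permitted and retained.
#'
#' @param seq a single nucleotide string.
#' @param gene_id identifier used in error messages.
#' @param allow_internal_stop keep sequences with internal stop codons.
#' @return the validated (uppercased, DNA-alphabet) sequence, invisibly
#'   usable downstream.
#' @export
validate_cds <- function(seq, gene_id = "<unnamed>", allow_internal_stop = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("U", "T", toupper(seq))
  if (grepl("[^ACGT]", seq))
    stop("gene ", gene_id, ": non-ACGT character in sequence")
  if (nchar(seq) %% 3L != 0L)
    stop("gene ", gene_id, ": length ", nchar(seq), " is not a multiple of 3")
  if (!allow_internal_stop && nchar(seq) >= 6L) {
    cods <- .split_codons(seq)
    internal <- cods[-length(cods)]
    if (any(internal %in% .code()$stops))
      stop("gene ", gene_id, ": internal stop codon at codon position ",
           which(internal %in% .code()$stops)[1L])
  }
  seq
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Construct a paired expression matrix
#'
#' A thin container for a genes-by-samples count matrix with a condition tag
#' per sample. Conditions are taken from sample names of the form
#' \code{<condition>_<replicate>} unless given explicitly.
#'
#' @param counts nonnegative integer matrix with gene rownames and sample
#'   colnames.
#' @param assay \code{"mrna"} or \code{"ribo"}.
#' @param condition optional character vector of per-sample condition tags.
#' @return an object of class \code{expr_matrix}.
#' @export
expression_matrix <- function(counts, assay = c("mrna", "ribo"), condition = NULL) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample name in counts")
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(condition)) {
    if (!all(grepl("_", colnames(counts))))
      stop("cannot infer condition: sample names must look like <condition>_<rep>")
    condition <- sub("_[^_]*$", "", colnames(counts))
  }
  if (length(condition) != ncol(counts))
    stop("condition must have one entry per sample")
  structure(list(assay = assay, counts = counts,
                 condition = as.character(condition)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> assay=%s: %d genes x %d samples (%s)\n",
              x$assay, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$condition)),
                            as.integer(table(x$condition))), collapse = ", ")))
  invisible(x)
}

#' Read a gene-by-sample count table
#'
#' Expects a TSV with a \code{gene_id} column followed by one column per
#' sample, named \code{<condition>_<replicate>}. Row and column order is
#' preserved exactly as in the file.
#'
#' @param path TSV path.
#' @inheritParams expression_matrix
#' @return an \code{expr_matrix}.
#' @export
read_counts_table <- function(path, assay = c("mrna", "ribo")) {
  assay <- match.arg(assay)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("counts table must have a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count in ", path)
  if (any(m < 0)) stop("negative count in ", path)
  rownames(m) <- df$gene_id
  expression_matrix(m, assay = assay)
}

#' Write a count table as TSV
#'
#' Inverse of \code{\link{read_counts_table}}: round-trips values exactly.
#'
#' @param x an \code{expr_matrix}.
#' @param path output TSV path.
#' @export
write_counts_table <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# deterministic TSV writer used for all tabular outputs
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

.REGIONS <- c("ACC_STEM", "D_ARM", "AC_ARM", "V_LOOP", "T_ARM", "OTHER")

#' Read a tRNA isodecoder annotation table
#'
#' TSV with columns \code{isodecoder}, \code{position} (0-based),
#' \code{base}, \code{region} and optional \code{canonical_label} (e.g.
#' \code{"C48"}; Sprinzl-style labels are carried as opaque strings, never
#' used as indices). Positions must be contiguous from 0 within each
#' isodecoder.
#'
#' @param path TSV path.
#' @return named list of isodecoder records, each a list with \code{name},
#'   \code{seq}, \code{region} (per-position) and \code{canonical_label}.
#' @export
read_trna_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(canonical_label = "character"))
  need <- c("isodecoder", "position", "base", "region")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (!"canonical_label" %in% names(df)) df$canonical_label <- ""
  bad <- setdiff(unique(df$region), .REGIONS)
  if (length(bad)) stop("unknown region code(s): ", paste(bad, collapse = ", "))
  out <- lapply(split(df, df$isodecoder), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d)) - 1L))
      stop("isodecoder ", d$isodecoder[1L], ": positions are not contiguous 0..L-1")
    lab <- d$canonical_label
    lab[is.na(lab)] <- ""
    if (anyDuplicated(lab[nzchar(lab)]))
      stop("isodecoder ", d$isodecoder[1L], ": duplicate canonical labels")
    list(name = d$isodecoder[1L],
         seq = paste(toupper(chartr("U", "T", d$base)), collapse = ""),
         region = d$region,
         canonical_label = lab)
  })
  out[unique(df$isodecoder)]
}

#' Write a tRNA annotation table
#'
#' @param trnas list of isodecoder records as from
#'   \code{\link{read_trna_annotation}}.
#' @param path output TSV path.
#' @export
write_trna_annotation <- function(trnas, path) {
  rows <- lapply(trnas, function(t) {
    data.frame(isodecoder = t$name,
               position = seq_len(nchar(t$seq)) - 1L,
               base = strsplit(t$seq, "")[[1L]],
               region = t$region,
               canonical_label = t$canonical_label,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read per-cytosine bisulphite site counts
#'
#' TSV with columns \code{isodecoder}, \code{position} (0-based),
#' \code{condition}, \code{meth} (unconverted reads) and \code{conv}
#' (converted reads).
#'
#' @param path TSV path.
#' @return data.frame of site counts.
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("isodecoder", "position", "condition", "meth", "conv")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (any(df$meth < 0) || any(df$conv < 0)) stop("negative read count")
  df
}

#' Read a qPCR Ct table
#'
#' Long-format TSV with columns \code{assay} (\code{charging} or
#' \code{fragment}), \code{target}, \code{condition}, \code{channel} and
#' \code{replicate}, plus the \code{ct} value. Charging channels are
#' \code{ox}/\code{nonox}/\code{ref_ox}/\code{ref_nonox}; fragment channels
#' are \code{target}/\code{u6}.
#'
#' @param path TSV path.
#' @return data.frame of Ct values.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("assay", "target", "condition", "channel", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$ct) || any(!is.finite(df$ct))) stop("non-finite Ct value")
  df
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}
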