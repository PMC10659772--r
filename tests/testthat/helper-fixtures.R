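# Small designs and hand-built fixtures shared across test files.

small_design <- function(seed = 42L, ...) {
  sim_design(n_genes = 80L, lib_size = 2e5, seed = seed, ...)
}

# a minimal annotated isodecoder: 10 nt, one V_LOOP block
toy_trna <- function(name = "Leu-CAA-1-1", seq = "GGCACGTTCA",
                     region = c(rep("ACC_STEM", 3), rep("V_LOOP", 4),
                                rep("T_ARM", 3)),
                     labels = NULL) {
  lab <- character(nchar(seq))
  if (!is.null(labels)) lab[as.integer(names(labels)) + 1L] <- labels
  out <- list(list(name = name, seq = seq, region = region,
                   canonical_label = lab))
  names(out) <- name
  out
}

# site table row builder
site_rows <- function(isodecoder, position, condition, meth, conv) {
  data.frame(isodecoder = isodecoder, position = position,
             condition = condition, meth = meth, conv = conv,
             stringsAsFactors = FALSE)
}

# random 64-codon count vector (RNA names), uniform over codons
random_counts <- function(n_codons = 300L) {
  cods <- names(count_codons("ATG"))
  tab <- table(factor(sample(cods, n_codons, replace = TRUE), levels = cods))
  counts <- as.integer(tab)
  names(counts) <- cods
  counts
}
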