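# Independent brute-force oracles, deliberately not sharing code paths with
# the package: the IUPAC table is restated here and translation goes through
# seqinr rather than Biostrings.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# 64-codon translation table via seqinr (stop = "*")
oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      aa <- vapply(codons, function(cdn)
        seqinr::translate(strsplit(cdn, "")[[1]]), "")
      tab <<- stats::setNames(aa, codons)
    }
    tab
  }
})

oracle_expand_codon <- function(codon_str) {
  letters3 <- strsplit(codon_str, "")[[1]]
  sets <- lapply(letters3, function(l) ORACLE_IUPAC[[l]])
  g <- expand.grid(sets[[1]], sets[[2]], sets[[3]], stringsAsFactors = FALSE)
  sort(paste0(g[[1]], g[[2]], g[[3]]))
}

oracle_aa_distribution <- function(codon_str, mode = "standard") {
  codons <- oracle_expand_codon(codon_str)
  tab <- oracle_codon_table()
  if (mode == "amber_suppressed") tab["TAG"] <- "Q"
  aas <- tab[codons]
  tt <- table(aas)
  stats::setNames(as.numeric(tt) / length(codons), names(tt))
}

# distinct stop-free peptides of a cassette by full enumeration
oracle_protein_diversity <- function(codon_strs, mode = "standard") {
  tab <- oracle_codon_table()
  if (mode == "amber_suppressed") tab["TAG"] <- "Q"
  peptide_sets <- lapply(codon_strs, function(cs) tab[oracle_expand_codon(cs)])
  peps <- Reduce(function(acc, aas)
    as.vector(outer(acc, aas, paste0)), peptide_sets, accumulate = FALSE)
  length(unique(peps[!grepl("*", peps, fixed = TRUE)]))
}

all_degenerate_codons <- function() {
  letters15 <- names(ORACLE_IUPAC)
  as.vector(outer(outer(letters15, letters15, paste0), letters15, paste0))
}

total_variation <- function(p, q) {
  keys <- union(names(p), names(q))
  p <- stats::setNames(p[keys], keys); p[is.na(p)] <- 0
  q <- stats::setNames(q[keys], keys); q[is.na(q)] <- 0
  sum(abs(p / sum(p) - q / sum(q))) / 2
}
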