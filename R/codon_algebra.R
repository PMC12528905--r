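# Degenerate-codon algebra: IUPAC expansion, translation, exact diversity.

#' Expand an IUPAC nucleotide ambiguity code to its base set
#'
#' Maps a single IUPAC ambiguity letter to the set of unambiguous bases it
#' represents (e.g. `N` is any base, `K` is G or T, `D` is A, G or T).
#' Unambiguous letters map to singletons. The mapping is the IUPAC standard
#' as provided by [Biostrings::IUPAC_CODE_MAP].
#'
#' @param code A single IUPAC nucleotide letter (case-insensitive).
#' @return Character vector of bases from A/C/G/T, sorted.
#' @examples
#' expand_code("N") # A C G T
#' expand_code("K") # G T
#' @export
expand_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- toupper(code)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    stop(errorCondition(
      sprintf("invalid IUPAC nucleotide code: '%s'", code),
      class = c("scfvlib_invalid_alphabet", "error")))
  }
  sort(strsplit(map[[code]], "")[[1]])
}

#' Degenerate codon
#'
#' A codon written in IUPAC ambiguity letters, representing an equimolar
#' mixture of concrete codons (one base drawn uniformly and independently
#' from each position's base set). `NNK`, `DRC` and `RRY` are typical
#' library-design codons; a codon of three unambiguous letters is "fixed".
#'
#' @param codes A 3-letter IUPAC string (e.g. `"NNK"`), or a character
#'   vector of three single letters.
#' @return Object of class `degenerate_codon` with elements `codes`
#'   (three letters), `base_sets` (list of base vectors) and
#'   `expansion_count` (product of base-set sizes).
#' @examples
#' degenerate_codon("NNK")$expansion_count # 32
#' @export
degenerate_codon <- function(codes) {
  if (inherits(codes, "degenerate_codon")) return(codes)
  if (length(codes) == 1L) codes <- strsplit(toupper(codes), "")[[1]]
  if (length(codes) != 3L)
    stop("a degenerate codon needs exactly three IUPAC letters")
  sets <- lapply(codes, expand_code)
  structure(list(
    codes = toupper(codes),
    base_sets = sets,
    expansion_count = as.integer(prod(lengths(sets)))
  ), class = "degenerate_codon")
}

#' @export
#' @method print degenerate_codon
print.degenerate_codon <- function(x, ...) {
  cat(sprintf("<degenerate codon %s: %d concrete codon%s>\n",
              paste(x$codes, collapse = ""), x$expansion_count,
              if (x$expansion_count == 1L) "" else "s"))
  invisible(x)
}

#' Enumerate the concrete codons of a degenerate codon
#'
#' @param dc A [degenerate_codon()] (or a 3-letter IUPAC string).
#' @return Character vector of concrete codons, lexicographically sorted,
#'   duplicate-free; its length equals `expansion_count`.
#' @examples
#' length(expand_codon("NNK")) # 32
#' expand_codon("DRC")
#' @export
expand_codon <- function(dc) {
  dc <- degenerate_codon(dc)
  g <- expand.grid(p3 = dc$base_sets[[3]], p2 = dc$base_sets[[2]],
                   p1 = dc$base_sets[[1]], stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' Genetic code table by mode
#'
#' `standard` is the NCBI standard code (table 1). `amber_suppressed`
#' translates the amber stop TAG as glutamine, matching readthrough in
#' amber-suppressor display hosts such as E. coli TG1 (supE); TAA and TGA
#' remain stops.
#'
#' @param mode `"standard"` or `"amber_suppressed"`.
#' @return Named character vector mapping codons to one-letter residues
#'   (`*` = stop).
#' @export
genetic_code <- function(mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  code <- Biostrings::GENETIC_CODE
  if (mode == "amber_suppressed") code[["TAG"]] <- "Q"
  code
}

#' Amino-acid distribution induced by a degenerate codon
#'
#' Each concrete codon in the expansion carries uniform weight
#' 1/`expansion_count` (equimolar base mixing); weights are summed per
#' translated residue. The support is exactly the set of residues (and
#' possibly stop, `*`) reachable from the expansion under the chosen
#' genetic-code mode.
#'
#' @inheritParams expand_codon
#' @inheritParams genetic_code
#' @return Named numeric probability vector (class `aa_distribution`),
#'   names are one-letter residues with `*` for stop; sums to 1.
#' @examples
#' d <- aa_distribution("NNK")
#' d["*"]          # 1/32: TAG is the sole stop in the NNK expansion
#' length(d)       # 21: all 20 residues plus stop
#' @export
aa_distribution <- function(dc, mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  dc <- degenerate_codon(dc)
  codons <- expand_codon(dc)
  aas <- unname(genetic_code(mode)[codons])
  tab <- table(aas)
  probs <- as.numeric(tab) / length(codons)
  names(probs) <- names(tab)
  structure(probs[order(names(probs))], class = "aa_distribution", mode = mode)
}

#' @export
#' @method print aa_distribution
print.aa_distribution <- function(x, ...) {
  cat(sprintf("<amino-acid distribution, %s code>\n", attr(x, "mode")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Stop-codon probability of a degenerate codon
#'
#' @inheritParams aa_distribution
#' @return Probability in \[0, 1\] that one realization of the codon is a
#'   stop under the given genetic-code mode.
#' @examples
#' stop_probability("NNK")                      # 1/32
#' stop_probability("NNK", "amber_suppressed")  # 0
#' @export
stop_probability <- function(dc, mode = c("standard", "amber_suppressed")) {
  d <- aa_distribution(dc, mode)
  if ("*" %in% names(d)) unname(d[["*"]]) else 0
}

as_codon_list <- function(codons) {
  if (inherits(codons, "degenerate_codon")) return(list(codons))
  if (is.character(codons) && length(codons) == 1L && nchar(codons) %% 3 == 0) {
    codons <- substring(codons, seq(1, nchar(codons), 3), seq(3, nchar(codons), 3))
  }
  lapply(codons, degenerate_codon)
}

#' Exact DNA diversity of a degenerate cassette
#'
#' Number of distinct nucleotide realizations of an ordered run of
#' degenerate codons: the product of per-codon expansion counts, computed
#' in exact arbitrary-precision arithmetic (long NNK runs overflow doubles).
#'
#' @param codons A list of [degenerate_codon()]s, a character vector of
#'   3-letter IUPAC strings, or one IUPAC string with length a multiple of 3.
#' @return A [big_integer()].
#' @examples
#' cassette_dna_diversity(c("NNK", "NNK"))   # 1024
#' format(cassette_dna_diversity(rep("NNK", 28)))
#' @export
cassette_dna_diversity <- function(codons) {
  bi_prod(vapply(as_codon_list(codons), function(d) d$expansion_count, 1))
}

#' Exact stop-free protein diversity of a degenerate cassette
#'
#' Number of distinct stop-free peptides encoded by the cassette. Positions
#' are independent, so this is the product over positions of the number of
#' distinct non-stop residues reachable at that position.
#'
#' @inheritParams cassette_dna_diversity
#' @inheritParams genetic_code
#' @return A [big_integer()].
#' @examples
#' cassette_protein_diversity("NNK")          # 20
#' cassette_protein_diversity(c("DRC", "RRY"))
#' @export
cassette_protein_diversity <- function(codons,
                                       mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  counts <- vapply(as_codon_list(codons), function(d) {
    aa <- aa_distribution(d, mode)
    length(setdiff(names(aa), "*"))
  }, 1L)
  bi_prod(counts)
}

#' Stop-free fraction of a degenerate cassette
#'
#' Probability that a uniform realization of the cassette encodes no stop
#' codon; for a run of k NNK codons under the standard code this is
#' (31/32)^k.
#'
#' @inheritParams cassette_protein_diversity
#' @return Numeric in \[0, 1\].
#' @export
cassette_stop_free_fraction <- function(codons,
                                        mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  prod(vapply(as_codon_list(codons),
              function(d) 1 - stop_probability(d, mode), 1))
}

#' Write an amino-acid distribution as TSV
#'
#' @param d An [aa_distribution()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aa_distribution <- function(d, path) {
  df <- data.frame(residue = names(d), probability = as.numeric(d))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
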