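# The unmutated scFv template backbone and its CDR3 interval annotation.
# Coordinates are 0-based half-open internally; Kabat labels appear only in
# reports.

# Synthetic framework segments (not a natural V-gene): fixed literals chosen
# so that SacI/NheI occur exactly once each, inside the designated CDR3
# interval, and the 12-nt extraction anchors are unique in the template even
# under one mismatch.
TEMPLATE_FR_L1 <- "CCTCGTGAGGTGCATCCATGCACCATTCTCGCTGACAACGTTACTCCGCGTTTCAGGAATGCG"
TEMPLATE_VL_CDR3 <- "TATGAGCTCAGTCCTACG"  # Y E L S P T; SacI GAGCTC inside
TEMPLATE_MID <- "GCAACGAAAATAGATTAGATGGGAAATGAACCGTTGGGAATCCGGTAGCGTTTATGCTTGGGTCCAGCGGCCGCAGGAATGGCACTAGTGTGGAAA"
TEMPLATE_VH_CDR3 <- "CGTGCTAGCTATGGTTCGACTTACCCTGAT"  # R A S Y G S T Y P D; NheI
TEMPLATE_FR_H2 <- "GCTGATATTAAGTTTTACGCGCCTAGGCCATACAAAATAGGCTCTATCTAATGTATCGTTCTA"

#' The synthetic scFv template with annotated CDR3 intervals
#'
#' A compact synthetic stand-in for the unmutated parental scFv: framework
#' segments flanking a VL CDR3 (Kabat 91-96, carrying the unique SacI site
#' GAGCTC) and a VH CDR3 (anchors Arg94/Asp101, carrying the unique NheI
#' site GCTAGC). The framework sequences are synthetic literals, not a
#' natural V-gene; they exist to give mutagenesis cassettes and clone reads
#' a fixed, anchor-unique context. A custom template can be supplied
#' instead.
#'
#' @param sequence Template nucleotide sequence (A/C/G/T).
#' @param intervals Data.frame with columns `region` ("VL"/"VH"), `start`,
#'   `end` (0-based half-open) delimiting the CDR3 cassette-replacement
#'   intervals.
#' @return Object of class `scfv_template`.
#' @examples
#' tm <- scfv_template()
#' check_template_sites(tm)
#' @export
scfv_template <- function(sequence = NULL, intervals = NULL) {
  if (is.null(sequence)) {
    segs <- c(TEMPLATE_FR_L1, TEMPLATE_VL_CDR3, TEMPLATE_MID,
              TEMPLATE_VH_CDR3, TEMPLATE_FR_H2)
    sequence <- paste(segs, collapse = "")
    offs <- cumsum(c(0L, nchar(segs)))
    intervals <- data.frame(region = c("VL", "VH"),
                            start = offs[c(2L, 4L)], end = offs[c(3L, 5L)])
  }
  stopifnot(grepl("^[ACGT]+$", sequence))
  if (!is.null(intervals)) {
    stopifnot(all(c("region", "start", "end") %in% names(intervals)),
              all(intervals$start >= 0), all(intervals$end <= nchar(sequence)),
              all(intervals$start < intervals$end))
  }
  structure(list(sequence = sequence, intervals = intervals),
            class = "scfv_template")
}

#' @export
#' @method print scfv_template
print.scfv_template <- function(x, ...) {
  cat(sprintf("<scFv template, %d nt>\n", nchar(x$sequence)))
  if (!is.null(x$intervals)) {
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  %s CDR3: [%d, %d)\n", x$intervals$region[i],
                  x$intervals$start[i], x$intervals$end[i]))
  } else cat("  (no CDR3 interval annotation)\n")
  invisible(x)
}

template_interval <- function(template, region) {
  iv <- template$intervals[template$intervals$region == region, ]
  if (nrow(iv) != 1L)
    stop(errorCondition(
      sprintf("template lacks a %s CDR3 interval annotation", region),
      class = c("scfvlib_annotation_required", "error")))
  iv
}

#' Template CDR3 nucleotides for one region
#'
#' @param template An [scfv_template()].
#' @param region `"VL"` or `"VH"`.
#' @return Nucleotide string of the annotated interval.
#' @export
template_region <- function(template, region = c("VL", "VH")) {
  region <- match.arg(region)
  iv <- template_interval(template, region)
  substr(template$sequence, iv$start + 1L, iv$end)
}

#' Framework arms / extraction anchors flanking each CDR3 interval
#'
#' @param template An [scfv_template()].
#' @param flank Arm length in nt (at least 6).
#' @return List with `VL` and `VH`, each holding `upstream` and
#'   `downstream` framework strings of length `flank`.
#' @export
template_arms <- function(template, flank = 12L) {
  if (flank < 6L)
    stop(errorCondition("anchors shorter than 6 nt are not reliable",
                        class = c("scfvlib_configuration_error", "error")))
  out <- lapply(c(VL = "VL", VH = "VH"), function(region) {
    iv <- template_interval(template, region)
    stopifnot(iv$start >= flank, iv$end + flank <= nchar(template$sequence))
    list(upstream = substr(template$sequence, iv$start - flank + 1L, iv$start),
         downstream = substr(template$sequence, iv$end + 1L, iv$end + flank))
  })
  out
}

#' Write the template as FASTA plus BED interval annotation
#'
#' @param template An [scfv_template()].
#' @param fasta_path,bed_path Output files. BED is 0-based half-open.
#' @param name Sequence name used in both files.
#' @return `fasta_path`, invisibly.
#' @export
write_template <- function(template, fasta_path, bed_path,
                           name = "scfv_template") {
  dss <- Biostrings::DNAStringSet(stats::setNames(template$sequence, name))
  Biostrings::writeXStringSet(dss, fasta_path)
  bed <- data.frame(chrom = name, start = template$intervals$start,
                    end = template$intervals$end,
                    name = paste0(template$intervals$region, "_CDR3"))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(fasta_path)
}

#' Read a template from FASTA plus BED annotation
#'
#' @param fasta_path FASTA with one template record.
#' @param bed_path BED file (0-based half-open) whose name column starts
#'   with `VL` or `VH`.
#' @return An [scfv_template()].
#' @export
read_template <- function(fasta_path, bed_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  stopifnot(length(dss) == 1L)
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  scfv_template(as.character(dss[[1L]]),
                data.frame(region = substr(bed$name, 1L, 2L),
                           start = bed$start, end = bed$end))
}
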