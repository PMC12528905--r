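# Sequenced-repertoire QC: CDR3 extraction by framework anchors, length and
# per-position amino-acid diversity, residual-template detection,
# natural-repertoire comparison, and library-size estimation from colony
# counts.

#' Extract a CDR3 region from one clone sequence
#'
#' Locates the upstream and then the downstream framework anchor and
#' returns the enclosed region. Each anchor is sought exactly first; an
#' anchor with no exact occurrence is re-sought allowing up to
#' `max_mismatch` mismatches (so a mutated anchor still extracts, while a
#' chance near-copy of an anchor inside a randomized loop cannot displace
#' an exact framework match). If either anchor is missing, or the valid
#' placements (downstream after upstream) are ambiguous, the clone is
#' reported unanchored.
#'
#' @param sequence Clone nucleotide string.
#' @param anchors List with `upstream` and `downstream` anchor strings
#'   (at least 6 nt each), e.g. one element of [template_arms()].
#' @param max_mismatch Mismatches tolerated per anchor (default 1).
#' @return List with `found` (logical), `nt` (enclosed nucleotides) and
#'   `start`/`end` (0-based half-open coordinates), or
#'   `found = FALSE` with reason `"unanchored"`.
#' @export
extract_cdr3 <- function(sequence, anchors, max_mismatch = 1L) {
  res <- extract_cdr3_batch(sequence, anchors, max_mismatch)
  list(found = res$found[1L], nt = res$nt[1L],
       start = res$start[1L], end = res$end[1L],
       reason = if (res$found[1L]) NA_character_ else "unanchored")
}

# Vectorized anchor search over many clones. Each anchor is located first
# by exact match; only if an anchor has no exact occurrence is the
# mismatch-tolerant search used for it. A unique valid placement
# (downstream anchor strictly after the upstream one) is required at the
# tolerance level in force; anything else is unanchored.
extract_cdr3_batch <- function(sequences, anchors, max_mismatch = 1L) {
  if (nchar(anchors$upstream) < 6L || nchar(anchors$downstream) < 6L)
    stop(errorCondition("extraction anchors must be at least 6 nt",
                        class = c("scfvlib_configuration_error", "error")))
  dss <- if (inherits(sequences, "DNAStringSet")) sequences
         else Biostrings::DNAStringSet(sequences)
  up0 <- Biostrings::vmatchPattern(anchors$upstream, dss)
  dn0 <- Biostrings::vmatchPattern(anchors$downstream, dss)
  need_up <- which(lengths(up0) == 0L)
  need_dn <- which(lengths(dn0) == 0L)
  up1 <- if (length(need_up) && max_mismatch > 0L)
    Biostrings::vmatchPattern(anchors$upstream, dss[need_up],
                              max.mismatch = max_mismatch)
  dn1 <- if (length(need_dn) && max_mismatch > 0L)
    Biostrings::vmatchPattern(anchors$downstream, dss[need_dn],
                              max.mismatch = max_mismatch)
  n <- length(dss)
  found <- logical(n); s0 <- e0 <- rep(NA_integer_, n); nt <- rep(NA_character_, n)
  seqs <- as.character(dss)
  for (i in seq_len(n)) {
    u <- if (i %in% need_up) {
      if (is.null(up1)) next else up1[[match(i, need_up)]]
    } else up0[[i]]
    d <- if (i %in% need_dn) {
      if (is.null(dn1)) next else dn1[[match(i, need_dn)]]
    } else dn0[[i]]
    if (length(u) == 0L || length(d) == 0L) next
    combos <- expand.grid(ue = IRanges::end(u), ds = IRanges::start(d))
    combos <- combos[combos$ds > combos$ue, , drop = FALSE]
    if (nrow(combos) != 1L) next     # missing or ambiguous placement
    found[i] <- TRUE
    s0[i] <- combos$ue[1L]           # 0-based start of enclosed region
    e0[i] <- combos$ds[1L] - 1L      # 0-based end (half-open)
    nt[i] <- substr(seqs[i], combos$ue[1L] + 1L, combos$ds[1L] - 1L)
  }
  data.frame(found = found, nt = nt, start = s0, end = e0)
}

translate_inframe <- function(nts, mode = "standard") {
  out <- rep(NA_character_, length(nts))
  ok <- !is.na(nts) & nchar(nts) > 0L & nchar(nts) %% 3L == 0L
  if (any(ok)) {
    pep <- Biostrings::translate(Biostrings::DNAStringSet(nts[ok]),
                                 genetic.code = genetic_code(mode))
    out[ok] <- as.character(pep)
  }
  out
}

#' Process sequenced clones against a library template
#'
#' Extracts both CDR3 regions by framework anchors, translates in-frame
#' extractions, and sets per-clone flags (`unanchored`, `frameshift`,
#' `internal_stop`, `template`).
#'
#' @param sequences Named character vector, `DNAStringSet`, or path
#'   handled upstream by [read_clones_fasta()].
#' @param template An [scfv_template()] (anchor source).
#' @param flank Anchor length in nt (default 12).
#' @param max_mismatch Mismatches tolerated per anchor.
#' @inheritParams genetic_code
#' @return Data.frame of class `clone_records`: per clone, per region, the
#'   extracted nucleotides/peptide and flags.
#' @export
process_clones <- function(sequences, template, flank = 12L, max_mismatch = 1L,
                           mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  arms <- template_arms(template, flank)
  dss <- if (inherits(sequences, "DNAStringSet")) sequences
         else Biostrings::DNAStringSet(sequences)
  ids <- names(dss)
  if (is.null(ids)) ids <- sprintf("clone_%05d", seq_along(dss))
  out <- data.frame(id = ids)
  for (region in c("vl", "vh")) {
    ex <- extract_cdr3_batch(dss, arms[[toupper(region)]], max_mismatch)
    pep <- translate_inframe(ex$nt, mode)
    out[[paste0(region, "_found")]] <- ex$found
    out[[paste0(region, "_nt")]] <- ex$nt
    out[[paste0(region, "_pep")]] <- pep
    out[[paste0(region, "_frameshift")]] <- ex$found & nchar(ex$nt) %% 3L != 0L
    out[[paste0(region, "_stop")]] <- !is.na(pep) & grepl("*", pep, fixed = TRUE)
  }
  tmplt <- detect_template(out, template)
  out$template <- tmplt$is_template
  out$template_evidence <- tmplt$evidence
  unanchored <- !(out$vl_found & out$vh_found)
  frameshift <- out$vl_frameshift | out$vh_frameshift
  has_stop <- out$vl_stop | out$vh_stop
  out$flags <- vapply(seq_len(nrow(out)), function(i)
    paste(c(if (unanchored[i]) "unanchored",
            if (frameshift[i]) "frameshift",
            if (has_stop[i]) "internal_stop",
            if (out$template[i]) "template"), collapse = ","), "")
  attr(out, "mode") <- mode
  class(out) <- c("clone_records", "data.frame")
  out
}

#' Detect residual parental template among sequenced clones
#'
#' A clone is called template if, in either region, its extracted CDR3
#' nucleotides equal the template CDR3 exactly, or contain the depletion
#' restriction site assigned to that region (SacI GAGCTC in VL, NheI
#' GCTAGC in VH). Site evidence can in principle also arise from a mutant
#' clone that regenerated the site by chance (such clones would likewise
#' be cut by the depletion digest); the evidence string names the trigger
#' so the two cases can be distinguished.
#'
#' @param clones A `clone_records` data.frame from [process_clones()], or
#'   a list/one-row data.frame with `vl_nt` and `vh_nt`.
#' @param template An [scfv_template()].
#' @param sites Named (VL/VH) recognition sequences.
#' @return Data.frame with `is_template` and `evidence` per clone.
#' @export
detect_template <- function(clones, template,
                            sites = c(VL = "GAGCTC", VH = "GCTAGC")) {
  if (!is.data.frame(clones)) clones <- as.data.frame(clones)
  vl_ref <- template_region(template, "VL")
  vh_ref <- template_region(template, "VH")
  vl <- clones$vl_nt; vh <- clones$vh_nt
  ev <- cbind(
    VL_exact = !is.na(vl) & vl == vl_ref,
    VL_site  = !is.na(vl) & grepl(sites[["VL"]], vl, fixed = TRUE),
    VH_exact = !is.na(vh) & vh == vh_ref,
    VH_site  = !is.na(vh) & grepl(sites[["VH"]], vh, fixed = TRUE))
  data.frame(
    is_template = rowSums(ev) > 0L,
    evidence = apply(ev, 1L, function(r)
      paste(colnames(ev)[r], collapse = ",")))
}

kabat_sort_key <- function(labels) {
  num <- as.integer(sub("[a-z]+$", "", labels))
  ins <- sub("^[0-9]+", "", labels)
  num * 100L + ifelse(ins == "", 0L, match(ins, letters))
}

AA_LEVELS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
               "S","T","V","W","Y","*")

#' Summarize a sequenced repertoire
#'
#' Computes, per region: the number of usable clones (extracted, in-frame,
#' stop-free), the CDR3 length histogram (randomized residues only: VH
#' anchors Arg94/Asp101 are excluded; VL counts its full 91-96 loop), the
#' per-Kabat-position amino-acid count matrix (VH positions across loop
#' lengths are binned by Kabat insertion label), per-position Shannon
#' entropy in bits, and the residual-template count.
#'
#' @param clones Clone sequences or a `clone_records` data.frame from
#'   [process_clones()].
#' @param design A [library_design()] (template/anchor source).
#' @inheritParams genetic_code
#' @param include_stops Count stop-containing clones in the matrices
#'   (default FALSE: they cannot be displayed on phage).
#' @param by_length Also return per-length VH count matrices.
#' @return Object of class `repertoire_summary`.
#' @export
summarize_repertoire <- function(clones, design,
                                 mode = c("standard", "amber_suppressed"),
                                 include_stops = FALSE, by_length = FALSE) {
  mode <- match.arg(mode)
  if (!inherits(clones, "clone_records"))
    clones <- process_clones(clones, design$template, mode = mode)
  n_total <- nrow(clones)
  usable <- list()
  for (region in c("vl", "vh")) {
    ok <- clones[[paste0(region, "_found")]] &
      !clones[[paste0(region, "_frameshift")]]
    if (!include_stops) ok <- ok & !clones[[paste0(region, "_stop")]]
    usable[[region]] <- ok
  }
  vl_len <- nchar(clones$vl_nt) %/% 3L
  vh_len <- pmax(nchar(clones$vh_nt) %/% 3L - 2L, 0L)

  hist_of <- function(lens, ok) {
    if (!any(ok)) return(table(integer(0)))
    table(lens[ok])
  }
  count_matrix <- function(peps, labels_fun) {
    mat <- NULL
    tab <- new.env()
    peps <- peps[!is.na(peps)]
    if (length(peps) == 0L)
      return(matrix(0L, nrow = length(AA_LEVELS), ncol = 0L,
                    dimnames = list(AA_LEVELS, NULL)))
    labs_all <- unique(unlist(lapply(nchar(peps), labels_fun)))
    labs_all <- labs_all[order(kabat_sort_key(labs_all))]
    mat <- matrix(0L, nrow = length(AA_LEVELS), ncol = length(labs_all),
                  dimnames = list(AA_LEVELS, labs_all))
    for (p in peps) {
      labs <- labels_fun(nchar(p))
      aas <- strsplit(p, "")[[1]]
      for (j in seq_along(labs)) {
        mat[aas[j], labs[j]] <- mat[aas[j], labs[j]] + 1L
      }
    }
    mat
  }
  vl_labels <- function(len) as.character(seq(91L, length.out = len))
  vh_labels <- function(len) c("94", kabat_vh_labels(len - 2L), "101")

  vl_mat <- count_matrix(clones$vl_pep[usable$vl], vl_labels)
  vh_mat <- count_matrix(clones$vh_pep[usable$vh], vh_labels)

  entropy_bits <- function(mat) apply(mat, 2L, function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  })

  vh_by_length <- NULL
  if (by_length) {
    lens <- sort(unique(vh_len[usable$vh]))
    vh_by_length <- lapply(stats::setNames(lens, lens), function(k)
      count_matrix(clones$vh_pep[usable$vh & vh_len == k], vh_labels))
  }

  structure(list(
    n_total = n_total,
    n_usable = c(VL = sum(usable$vl), VH = sum(usable$vh)),
    length_histogram = list(VL = hist_of(vl_len, usable$vl),
                            VH = hist_of(vh_len, usable$vh)),
    aa_count_matrix = list(VL = vl_mat, VH = vh_mat),
    entropy_bits = list(VL = entropy_bits(vl_mat), VH = entropy_bits(vh_mat)),
    template_count = sum(clones$template),
    vh_by_length = vh_by_length,
    mode = mode, include_stops = include_stops
  ), class = "repertoire_summary")
}

#' @export
#' @method print repertoire_summary
print.repertoire_summary <- function(x, ...) {
  cat(sprintf("<repertoire summary: %d clones (%d usable VL, %d usable VH)>\n",
              x$n_total, x$n_usable[["VL"]], x$n_usable[["VH"]]))
  cat(sprintf("  residual template detected: %d (%.2f%%)\n",
              x$template_count, 100 * x$template_count / max(x$n_total, 1L)))
  vh <- x$length_histogram$VH
  if (length(vh))
    cat("  VH loop lengths:", paste(sprintf("%s:%d", names(vh), vh), collapse = " "),
        "\n")
  invisible(x)
}

#' Jensen-Shannon divergence (base 2) of two distributions
#'
#' Symmetric, bounded in \[0, 1\] bit; 0 for identical distributions, 1 for
#' disjoint supports.
#'
#' @param p,q Named or aligned non-negative vectors (normalized internally).
#' @return Divergence in bits.
#' @export
js_divergence <- function(p, q) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    keys <- union(names(p), names(q))
    p <- stats::setNames(p[keys], keys); p[is.na(p)] <- 0
    q <- stats::setNames(q[keys], keys); q[is.na(q)] <- 0
  }
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0),
            sum(p) > 0, sum(q) > 0)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) { i <- a > 0; sum(a[i] * log2(a[i] / b[i])) }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Compare observed per-position residue frequencies with a reference
#'
#' Per shared Kabat position, the base-2 Jensen-Shannon divergence between
#' the observed frequencies and a (user-supplied) natural-repertoire
#' reference; the overall mean is attached as an attribute.
#'
#' @param summary A [summarize_repertoire()] result.
#' @param reference Matrix or data.frame of reference frequencies,
#'   positions in rows (row names = Kabat labels), residues in columns;
#'   see [read_reference_tsv()]. Each row should sum to 1.
#' @param region `"VL"` or `"VH"`.
#' @return Data.frame (`position`, `jsd_bits`) with attribute `mean_jsd`.
#' @export
compare_to_reference <- function(summary, reference, region = c("VL", "VH")) {
  region <- match.arg(region)
  obs <- summary$aa_count_matrix[[region]]
  reference <- as.matrix(reference)
  shared <- intersect(colnames(obs), rownames(reference))
  if (length(shared) == 0L) stop("no shared Kabat positions with the reference")
  jsd <- vapply(shared, function(pos) {
    o <- obs[, pos]
    if (sum(o) == 0) return(NA_real_)
    js_divergence(o, stats::setNames(as.numeric(reference[pos, ]),
                                     colnames(reference)))
  }, 1)
  out <- data.frame(position = shared, jsd_bits = jsd, row.names = NULL)
  attr(out, "mean_jsd") <- mean(jsd, na.rm = TRUE)
  out
}

#' Position-frequency matrix for sequence-logo tools
#'
#' Converts the per-position residue counts of a repertoire summary into a
#' frequency matrix (positions in rows, residues in columns; rows sum to
#' 1) and optionally writes it as TSV consumable by standard logo tools.
#'
#' @param summary A [summarize_repertoire()] result.
#' @param region `"VL"` or `"VH"`.
#' @param path Optional TSV output path.
#' @param drop_stop Drop the stop column before normalizing (default TRUE).
#' @return The frequency matrix, invisibly if `path` is given.
#' @export
export_logo_matrix <- function(summary, region = c("VL", "VH"), path = NULL,
                               drop_stop = TRUE) {
  region <- match.arg(region)
  counts <- t(summary$aa_count_matrix[[region]])   # positions x residues
  if (drop_stop) counts <- counts[, colnames(counts) != "*", drop = FALSE]
  covered <- rowSums(counts) > 0
  freq <- counts
  freq[covered, ] <- counts[covered, , drop = FALSE] / rowSums(counts)[covered]
  if (!is.null(path)) {
    utils::write.table(data.frame(position = rownames(freq), freq,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(freq))
  }
  freq
}

#' Estimate library size from serial-dilution colony counts
#'
#' Each technical replicate estimates `count * dilution_factor /
#' plated_fraction` transformants; the mean and standard deviation across
#' replicates are reported.
#'
#' @param colony_counts Counts per replicate plate.
#' @param dilution_factors Dilution factor per replicate (scalar recycled).
#' @param plated_fraction Fraction of the transformation plated (scalar
#'   recycled; default 1).
#' @return List of class `library_size_estimate`: `estimate` (mean), `sd`,
#'   `per_replicate`.
#' @examples
#' estimate_library_size(c(100, 100, 100), 1e6)
#' @export
estimate_library_size <- function(colony_counts, dilution_factors,
                                  plated_fraction = 1) {
  n <- length(colony_counts)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n)
      stop(sprintf("%s must have length 1 or length(colony_counts)", what))
    x
  }
  dilution_factors <- expand(dilution_factors, "dilution_factors")
  plated_fraction <- expand(plated_fraction, "plated_fraction")
  stopifnot(all(colony_counts >= 0), all(dilution_factors > 0),
            all(plated_fraction > 0), all(plated_fraction <= 1))
  per <- colony_counts * dilution_factors / plated_fraction
  structure(list(estimate = mean(per),
                 sd = if (n > 1L) stats::sd(per) else 0,
                 per_replicate = per),
            class = "library_size_estimate")
}

#' @export
#' @method print library_size_estimate
print.library_size_estimate <- function(x, ...) {
  cat(sprintf("<library size: %.3g +/- %.2g (n = %d replicates)>\n",
              x$estimate, x$sd, length(x$per_replicate)))
  invisible(x)
}

#' Read clone sequences from FASTA or FASTQ
#'
#' FASTQ qualities, if present, are ignored (Sanger-style one sequence per
#' clone).
#'
#' @param path FASTA or FASTQ file.
#' @return A `DNAStringSet`.
#' @export
read_clones_fasta <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@")) Biostrings::readDNAStringSet(path, format = "fastq")
  else Biostrings::readDNAStringSet(path)
}

#' Read a per-position residue-frequency reference table
#'
#' TSV with a `position` column (Kabat labels) and one column per residue.
#'
#' @param path TSV file.
#' @return Matrix, positions in rows.
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "position"), drop = FALSE])
  rownames(m) <- as.character(df$position)
  m
}
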