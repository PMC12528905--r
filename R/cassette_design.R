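# CDR3 mutagenesis-cassette construction: Kabat-labelled position specs,
# VL variants, VH length series (S/L sublibraries), template restriction-site
# checks for parental-template depletion, and theoretical diversity tables.

#' A single Kabat-labelled cassette position
#'
#' @param kabat_label Kabat position label, e.g. `"91"`, `"95"`, `"100a"`
#'   (insertion letters for long loops).
#' @param codon A [degenerate_codon()] or 3-letter IUPAC string.
#' @param fixed_aa Optional one-letter residue; if given, every concrete
#'   codon in the expansion must translate to it (standard code).
#' @return Object of class `position_spec`.
#' @export
position_spec <- function(kabat_label, codon, fixed_aa = NA_character_) {
  codon <- degenerate_codon(codon)
  if (!is.na(fixed_aa)) {
    aas <- unique(unname(genetic_code("standard")[expand_codon(codon)]))
    if (!identical(aas, fixed_aa))
      stop(sprintf("codon %s does not encode fixed residue %s",
                   paste(codon$codes, collapse = ""), fixed_aa))
  }
  structure(list(kabat_label = as.character(kabat_label),
                 codon = codon, fixed_aa = fixed_aa),
            class = "position_spec")
}

is_fixed_position <- function(p) !is.na(p$fixed_aa)

#' CDR3 mutagenesis cassette
#'
#' An ordered run of Kabat-labelled (possibly degenerate) codons flanked by
#' framework-complementary arms. VH cassettes must start with the conserved
#' arginine anchor (Kabat 94) and end with the conserved aspartate anchor
#' (Kabat 101), the salt-bridge pair that holds the VH CDR3 conformation;
#' VL cassettes span Kabat 91-96 with the conserved proline fixed at 95.
#'
#' @param region `"VH"` or `"VL"`.
#' @param positions List of [position_spec()]s in Kabat order.
#' @param upstream_arm,downstream_arm Unambiguous framework-complementary
#'   nucleotide strings.
#' @param name Cassette name.
#' @return Object of class `cdr3_cassette`.
#' @export
cdr3_cassette <- function(region = c("VH", "VL"), positions,
                          upstream_arm, downstream_arm, name) {
  region <- match.arg(region)
  stopifnot(length(positions) > 0L)
  for (arm in list(upstream_arm, downstream_arm)) {
    if (!grepl("^[ACGT]*$", arm))
      stop(errorCondition(
        "cassette arms must be unambiguous A/C/G/T sequences",
        class = c("scfvlib_invalid_arm", "error")))
  }
  labels <- vapply(positions, `[[`, "", "kabat_label")
  if (anyDuplicated(labels)) stop("duplicated Kabat labels in cassette")
  if (region == "VH") {
    first <- positions[[1L]]; last <- positions[[length(positions)]]
    stopifnot(identical(first$fixed_aa, "R"), identical(first$kabat_label, "94"),
              identical(last$fixed_aa, "D"), identical(last$kabat_label, "101"))
  } else {
    stopifnot(identical(labels[1L], "91"),
              identical(labels[length(labels)], "96"),
              identical(positions[[which(labels == "95")]]$fixed_aa, "P"))
  }
  structure(list(region = region, positions = positions, name = name,
                 upstream_arm = upstream_arm, downstream_arm = downstream_arm),
            class = "cdr3_cassette")
}

#' @export
#' @method print cdr3_cassette
print.cdr3_cassette <- function(x, ...) {
  lab <- vapply(x$positions, `[[`, "", "kabat_label")
  cod <- vapply(x$positions, function(p) paste(p$codon$codes, collapse = ""), "")
  fx <- vapply(x$positions, function(p)
    if (is_fixed_position(p)) paste0(" (", p$fixed_aa, ")") else "", "")
  cat(sprintf("<%s CDR3 cassette '%s', %d positions>\n", x$region, x$name,
              length(x$positions)))
  cat(paste0("  ", lab, ": ", cod, fx, collapse = "\n"), "\n")
  invisible(x)
}

cassette_codons <- function(cassette) lapply(cassette$positions, `[[`, "codon")

cassette_iupac <- function(cassette) {
  paste(vapply(cassette$positions,
               function(p) paste(p$codon$codes, collapse = ""), ""),
        collapse = "")
}

#' Number of randomized (non-anchor) residues in a cassette
#'
#' CDR3 "length" throughout the package counts randomized residues only;
#' the fixed VH anchors (Arg94/Asp101) are excluded.
#' @param cassette A [cdr3_cassette()].
#' @return Integer count.
#' @export
cassette_loop_length <- function(cassette) {
  if (cassette$region == "VH")
    sum(!vapply(cassette$positions, is_fixed_position, TRUE))
  else
    length(cassette$positions)
}

#' Default design configuration
#'
#' Tunables for the cassette builders: fixed-position codons (human-common
#' choices by default), the codon used at VL position 91 in variant B, the
#' mixing weights of the two VL variants, and the framework arms (taken
#' from [scfv_template()] when not supplied).
#'
#' @param fixed_codons Named codons for fixed residues Y, P, R, D.
#' @param vl_variant_b_91 Degenerate codon randomizing VL position 91 in
#'   variant B (default NNK).
#' @param vl_variant_weights Mixing weights of VL variants A (Tyr91-fixed)
#'   and B; equimolar by default, giving roughly 50% Tyr at position 91
#'   plus the small Tyr mass of NNK, mimicking the ~50% natural frequency.
#' @param template An [scfv_template()]; source of the cassette arms.
#' @param arm_length Arm length in nt copied from the template framework.
#' @return A list of class `design_config`.
#' @export
design_config <- function(fixed_codons = c(Y = "TAT", P = "CCT",
                                           R = "CGT", D = "GAT"),
                          vl_variant_b_91 = "NNK",
                          vl_variant_weights = c(A = 0.5, B = 0.5),
                          template = scfv_template(),
                          arm_length = 21L) {
  stopifnot(all(c("Y", "P", "R", "D") %in% names(fixed_codons)),
            arm_length >= 6L)
  arms <- template_arms(template, arm_length)
  structure(list(fixed_codons = fixed_codons,
                 vl_variant_b_91 = vl_variant_b_91,
                 vl_variant_weights = vl_variant_weights / sum(vl_variant_weights),
                 template = template, arms = arms),
            class = "design_config")
}

#' Build the two VL CDR3 cassettes
#'
#' The VL loop spans Kabat 91-96. Variant A fixes tyrosine at 91 (it is
#' the majority residue there in natural kappa repertoires); variant B
#' randomizes 91 (NNK by default). Both variants use DRC at 92 and RRY at
#' 93 (limited, tailored diversity), NNK at 94 and 96 (full diversity),
#' and keep the conserved proline fixed at 95.
#'
#' @param config A [design_config()].
#' @return List of two [cdr3_cassette()]s named `A` and `B`.
#' @export
build_vl_cassettes <- function(config = design_config()) {
  fc <- config$fixed_codons
  common <- function(p91) list(
    p91,
    position_spec("92", "DRC"),
    position_spec("93", "RRY"),
    position_spec("94", "NNK"),
    position_spec("95", fc[["P"]], fixed_aa = "P"),
    position_spec("96", "NNK"))
  arms <- config$arms$VL
  list(
    A = cdr3_cassette("VL", common(position_spec("91", fc[["Y"]], fixed_aa = "Y")),
                      arms$upstream, arms$downstream, "VL-A"),
    B = cdr3_cassette("VL", common(position_spec("91", config$vl_variant_b_91)),
                      arms$upstream, arms$downstream, "VL-B"))
}

#' Kabat labels for randomized VH CDR3 positions
#'
#' Positions between the anchors are labelled 95..100 and then 100a..100z
#' for longer loops (Kabat insertion-letter convention).
#'
#' @param k Number of randomized residues (1-32).
#' @return Character vector of labels.
#' @export
kabat_vh_labels <- function(k) {
  if (k < 1L || k > 32L)
    stop(errorCondition(
      sprintf("VH loop length %d outside the supported Kabat labelling (1-32)", k),
      class = c("scfvlib_unsupported_length", "error")))
  base <- as.character(95:100)
  c(base[seq_len(min(k, 6L))],
    if (k > 6L) paste0("100", letters[seq_len(k - 6L)]))
}

#' Build the VH CDR3 cassette series for a sublibrary
#'
#' One cassette per loop length k: fixed Arg at Kabat 94, k NNK positions
#' labelled 95..100z, fixed Asp at 101.
#'
#' @param sublibrary_name `"S"` or `"L"` (used in cassette names).
#' @param loop_lengths Integer vector of randomized-residue counts.
#' @param config A [design_config()].
#' @return Named list of [cdr3_cassette()]s, one per length.
#' @export
build_vh_cassettes <- function(sublibrary_name, loop_lengths,
                               config = design_config()) {
  fc <- config$fixed_codons
  arms <- config$arms$VH
  out <- lapply(loop_lengths, function(k) {
    mids <- lapply(kabat_vh_labels(k), position_spec, codon = "NNK")
    positions <- c(list(position_spec("94", fc[["R"]], fixed_aa = "R")), mids,
                   list(position_spec("101", fc[["D"]], fixed_aa = "D")))
    cdr3_cassette("VH", positions, arms$upstream, arms$downstream,
                  sprintf("VH-%s-%02d", sublibrary_name, k))
  })
  names(out) <- sprintf("%02d", loop_lengths)
  out
}

#' Full library design: VL variants plus S and L VH sublibraries
#'
#' The short (S) sublibrary covers VH CDR3 loop lengths 5-22 and the long
#' (L) sublibrary 9-28 (randomized residues, anchors excluded); together
#' they cover lengths 5-28. Each clone combines one VL cassette realization
#' with one VH cassette realization on the scFv template backbone.
#'
#' @param config A [design_config()].
#' @param s_lengths,l_lengths Loop-length ranges of the two sublibraries.
#' @return Object of class `library_design`.
#' @export
library_design <- function(config = design_config(),
                           s_lengths = 5:22, l_lengths = 9:28) {
  structure(list(
    vl_cassettes = build_vl_cassettes(config),
    sublibraries = list(
      S = list(name = "S", loop_lengths = s_lengths,
               cassettes = build_vh_cassettes("S", s_lengths, config)),
      L = list(name = "L", loop_lengths = l_lengths,
               cassettes = build_vh_cassettes("L", l_lengths, config))),
    template = config$template,
    config = config), class = "library_design")
}

#' @export
#' @method print library_design
print.library_design <- function(x, ...) {
  cat("<scFv CDR3 library design>\n")
  cat(sprintf("  VL cassettes: %s\n",
              paste(vapply(x$vl_cassettes, `[[`, "", "name"), collapse = ", ")))
  for (sub in x$sublibraries)
    cat(sprintf("  %s sublibrary: VH loop lengths %d-%d (%d cassettes)\n",
                sub$name, min(sub$loop_lengths), max(sub$loop_lengths),
                length(sub$cassettes)))
  cat(sprintf("  template: %d nt, CDR3 intervals annotated\n",
              nchar(x$template$sequence)))
  invisible(x)
}

all_vh_cassettes <- function(design)
  unlist(lapply(design$sublibraries, `[[`, "cassettes"), recursive = FALSE)

#' Check template-depletion restriction sites
#'
#' The unmutated parental template must carry a SacI site (GAGCTC) inside
#' its VL CDR3 and an NheI site (GCTAGC) inside its VH CDR3, each unique in
#' the whole template, so that parental plasmid can be excised by digestion
#' while mutant clones (whose CDR3s no longer contain the sites) are spared.
#' Both recognition sequences are palindromic, so forward-strand scanning
#' covers both strands; the report records this.
#'
#' @param template An [scfv_template()].
#' @param sites Named recognition sequences.
#' @param assignment Region assigned to each enzyme.
#' @return A data.frame of class `template_site_report` with one row per
#'   enzyme: occurrences inside the assigned CDR3 interval, total
#'   occurrences, uniqueness, and pass flags.
#' @export
check_template_sites <- function(template,
                                 sites = c(SacI = "GAGCTC", NheI = "GCTAGC"),
                                 assignment = c(SacI = "VL", NheI = "VH")) {
  if (is.null(template$intervals))
    stop(errorCondition("template CDR3 interval annotation is required",
                        class = c("scfvlib_annotation_required", "error")))
  seq <- Biostrings::DNAString(template$sequence)
  rows <- lapply(names(sites), function(enz) {
    site <- sites[[enz]]
    fwd <- Biostrings::matchPattern(site, seq)
    rev <- Biostrings::matchPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(site))), seq)
    palindromic <- identical(Biostrings::start(fwd), Biostrings::start(rev))
    starts0 <- Biostrings::start(fwd) - 1L   # 0-based
    region <- assignment[[enz]]
    iv <- template$intervals[template$intervals$region == region, ]
    inside <- sum(starts0 >= iv$start & (starts0 + nchar(site)) <= iv$end)
    n_total <- length(starts0)
    data.frame(enzyme = enz, site = site, region = region,
               n_in_region = inside, n_total = n_total,
               palindromic = palindromic,
               unique_in_template = n_total == 1L,
               pass = inside == 1L && n_total == 1L)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("template_site_report", "data.frame")
  out
}

#' @export
#' @method print template_site_report
print.template_site_report <- function(x, ...) {
  cat("<template restriction-site report>\n")
  print.data.frame(x)
  for (i in seq_len(nrow(x))) {
    if (x$n_in_region[i] == 0L)
      cat(sprintf("  FAIL: %s site (%s) absent from the %s CDR3 interval\n",
                  x$enzyme[i], x$site[i], x$region[i]))
    else if (!x$unique_in_template[i])
      cat(sprintf("  WARNING: %s site (%s) is not unique in the template\n",
                  x$enzyme[i], x$site[i]))
  }
  invisible(x)
}

# per-position base probability table (rows A,C,G,T) of a realized cassette
# with its fixed arms
cassette_base_profile <- function(x, upstream_arm = NULL, downstream_arm = NULL) {
  if (inherits(x, "cdr3_cassette")) {
    codons <- cassette_codons(x)
    if (is.null(upstream_arm)) upstream_arm <- x$upstream_arm
    if (is.null(downstream_arm)) downstream_arm <- x$downstream_arm
  } else {
    codons <- as_codon_list(x)
    if (is.null(upstream_arm)) upstream_arm <- ""
    if (is.null(downstream_arm)) downstream_arm <- ""
  }
  point <- function(b) { p <- c(A = 0, C = 0, G = 0, T = 0); p[b] <- 1; p }
  cols <- c(
    lapply(strsplit(upstream_arm, "")[[1]], point),
    unlist(lapply(codons, function(d) lapply(d$base_sets, function(s) {
      p <- c(A = 0, C = 0, G = 0, T = 0); p[s] <- 1 / length(s); p
    })), recursive = FALSE),
    lapply(strsplit(downstream_arm, "")[[1]], point))
  do.call(cbind, cols)
}

#' Probability that a cassette realization regenerates a restriction site
#'
#' Scans every window of `nchar(site)` nt over the realized cassette,
#' including windows overlapping the fixed arms. Positions are mutually
#' independent (each degenerate position is an independent uniform draw),
#' so each window's match probability is an exact product; windows are
#' combined as if independent (`1 - prod(1 - p_w)`), which is exact
#' whenever at most one window has positive probability and a close upper
#' approximation otherwise. A regenerated site would make a genuine mutant
#' clone susceptible to the depletion digest.
#'
#' @param cassette A [cdr3_cassette()] or a character vector of degenerate
#'   codon strings.
#' @param site Recognition sequence (unambiguous).
#' @param upstream_arm,downstream_arm Override the cassette arms (defaults:
#'   the cassette's own arms; empty for bare codon vectors).
#' @return Probability in \[0, 1\].
#' @export
cassette_site_regeneration_risk <- function(cassette, site,
                                            upstream_arm = NULL,
                                            downstream_arm = NULL) {
  stopifnot(grepl("^[ACGT]+$", site))
  prof <- cassette_base_profile(cassette, upstream_arm, downstream_arm)
  sbases <- strsplit(site, "")[[1]]
  w <- length(sbases)
  n <- ncol(prof)
  if (n < w) return(0)
  rows <- match(sbases, rownames(prof))
  p_window <- vapply(seq_len(n - w + 1L), function(i) {
    prod(prof[cbind(rows, i:(i + w - 1L))])
  }, 1)
  1 - prod(1 - p_window)
}

#' Theoretical diversity table of a library design
#'
#' Per cassette: exact DNA diversity, exact stop-free protein diversity and
#' the stop-containing fraction; exact totals per sublibrary and for the
#' whole design (VL total x VH total, since a clone pairs one VL with one
#' VH realization). Exact values are decimal strings; `*_num` columns are
#' double approximations for convenience.
#'
#' @param design A [library_design()].
#' @inheritParams genetic_code
#' @return List of class `library_stats` with elements `per_cassette`
#'   (data.frame) and `totals`.
#' @export
theoretical_library_stats <- function(design,
                                      mode = c("standard", "amber_suppressed")) {
  mode <- match.arg(mode)
  cassette_row <- function(cassette, sub) {
    codons <- cassette_codons(cassette)
    dna <- cassette_dna_diversity(codons)
    prot <- cassette_protein_diversity(codons, mode)
    sf <- cassette_stop_free_fraction(codons, mode)
    data.frame(name = cassette$name, region = cassette$region,
               sublibrary = sub, loop_length = cassette_loop_length(cassette),
               dna_diversity = format(dna), dna_diversity_num = as.numeric(dna),
               protein_diversity = format(prot),
               protein_diversity_num = as.numeric(prot),
               stop_free_fraction = sf, stop_fraction = 1 - sf)
  }
  rows <- c(lapply(design$vl_cassettes, cassette_row, sub = "VL"),
            lapply(design$sublibraries$S$cassettes, cassette_row, sub = "S"),
            lapply(design$sublibraries$L$cassettes, cassette_row, sub = "L"))
  per_cassette <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  sum_big <- function(rows_sub, col)
    Reduce(bi_add, lapply(rows_sub[[col]], big_integer), big_integer(0))
  totals <- list()
  for (sub in c("VL", "S", "L")) {
    rs <- per_cassette[per_cassette$sublibrary == sub, ]
    totals[[sub]] <- list(n_cassettes = nrow(rs),
                          dna_diversity = sum_big(rs, "dna_diversity"),
                          protein_diversity = sum_big(rs, "protein_diversity"))
  }
  vh_dna <- bi_add(totals$S$dna_diversity, totals$L$dna_diversity)
  vh_prot <- bi_add(totals$S$protein_diversity, totals$L$protein_diversity)
  totals$combined <- list(
    dna_diversity = bi_mul(totals$VL$dna_diversity, vh_dna),
    protein_diversity = bi_mul(totals$VL$protein_diversity, vh_prot))
  structure(list(per_cassette = per_cassette, totals = totals, mode = mode),
            class = "library_stats")
}

#' @export
#' @method print library_stats
print.library_stats <- function(x, ...) {
  cat(sprintf("<theoretical library diversity, %s code>\n", x$mode))
  for (sub in c("VL", "S", "L")) {
    t <- x$totals[[sub]]
    cat(sprintf("  %s: %d cassettes, DNA %s, stop-free protein %s\n",
                sub, t$n_cassettes, format_sci(t$dna_diversity),
                format_sci(t$protein_diversity)))
  }
  cat(sprintf("  combined (VL x VH): DNA %s, protein %s\n",
              format_sci(x$totals$combined$dna_diversity),
              format_sci(x$totals$combined$protein_diversity)))
  invisible(x)
}

#' Export cassettes as degenerate-oligo FASTA plus a TSV manifest
#'
#' @param design A [library_design()].
#' @param fasta_path,manifest_path Output files.
#' @return Invisibly, the manifest data.frame.
#' @export
export_cassettes <- function(design, fasta_path, manifest_path) {
  cassettes <- c(design$vl_cassettes, all_vh_cassettes(design))
  oligos <- vapply(cassettes, function(cs)
    paste0(cs$upstream_arm, cassette_iupac(cs), cs$downstream_arm), "")
  names(oligos) <- vapply(cassettes, `[[`, "", "name")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(oligos), fasta_path)
  manifest <- data.frame(
    name = names(oligos),
    region = vapply(cassettes, `[[`, "", "region"),
    loop_length = vapply(cassettes, cassette_loop_length, 1L),
    core_iupac = vapply(cassettes, cassette_iupac, ""),
    oligo_length = nchar(oligos))
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
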