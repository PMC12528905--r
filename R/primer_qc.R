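# Mutagenesis-primer QC: arm GC balance, melting temperature, equimolar
# pooling. Rules follow the arm-composition optimization used to cut
# parental-template carryover in Kunkel mutagenesis: balanced GC between the
# two framework-complementary arms (difference at most 5 points), each arm
# GC below 50%, and arm Tm close to 45 degrees C.

AVOGADRO <- 6.02214076e23

#' A mutagenesis primer
#'
#' A degenerate-core oligo with unambiguous upstream and downstream
#' framework-complementary arms. The arms must be the literal prefix and
#' suffix of `sequence`.
#'
#' @param name Primer name.
#' @param sequence Full oligo sequence (IUPAC letters allowed in the core).
#' @param upstream_arm,downstream_arm Unambiguous A/C/G/T arm sequences.
#' @param concentration_uM Stock concentration in micromolar (needed for
#'   pooling).
#' @return Object of class `primer`.
#' @export
primer <- function(name, sequence, upstream_arm, downstream_arm,
                   concentration_uM = NA_real_) {
  sequence <- toupper(sequence)
  upstream_arm <- toupper(upstream_arm); downstream_arm <- toupper(downstream_arm)
  for (arm in c(upstream_arm, downstream_arm)) {
    if (nchar(arm) == 0L)
      stop(errorCondition("primer arm is missing/empty",
                          class = c("scfvlib_missing_arm", "error")))
    if (!grepl("^[ACGT]+$", arm))
      stop(errorCondition("primer arms must be unambiguous A/C/G/T",
                          class = c("scfvlib_ambiguous_sequence", "error")))
  }
  stopifnot(startsWith(sequence, upstream_arm), endsWith(sequence, downstream_arm))
  structure(list(name = name, sequence = sequence,
                 upstream_arm = upstream_arm, downstream_arm = downstream_arm,
                 concentration_uM = concentration_uM), class = "primer")
}

#' GC content of an unambiguous sequence
#'
#' @param seq Nucleotide string (A/C/G/T only; ambiguity codes have no
#'   defined GC fraction and raise an error).
#' @return Percentage, `100 * (G + C) / length`.
#' @examples
#' gc_content("ATGC") # 50
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq))
    stop(errorCondition(
      "gc_content needs an unambiguous A/C/G/T sequence",
      class = c("scfvlib_ambiguous_sequence", "error")))
  b <- strsplit(seq, "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# Unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K),
# 5'->3' dinucleotides; complements share values.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Melting temperature of an unambiguous oligo
#'
#' Two methods are provided and the one used is recorded as an attribute:
#' the Wallace rule `2(A+T) + 4(G+C)` for short oligos, and a
#' nearest-neighbor calculation with the unified thermodynamic parameter
#' set (two-state model, `Tm = dH / (dS + R ln(CT/4))` with terminal
#' initiation terms and a `0.368 (N-1) ln[Na+]` entropy salt correction).
#' `method = "auto"` (the default) uses Wallace for lengths up to 14 nt and
#' nearest-neighbor beyond.
#'
#' @param seq Unambiguous nucleotide string.
#' @param method `"auto"`, `"wallace"` or `"nearest_neighbor"`.
#' @param primer_nM Total single-strand concentration in nM
#'   (nearest-neighbor only).
#' @param na_mM Monovalent cation concentration in mM (nearest-neighbor
#'   only).
#' @return Tm in degrees C, with attribute `method`.
#' @examples
#' melting_temp("ATGCATGC") # Wallace: 24
#' @export
melting_temp <- function(seq, method = c("auto", "wallace", "nearest_neighbor"),
                         primer_nM = 500, na_mM = 50) {
  method <- match.arg(method)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("cannot compute Tm of an empty sequence")
  if (!grepl("^[ACGT]+$", seq))
    stop(errorCondition("Tm needs an unambiguous A/C/G/T sequence",
                        class = c("scfvlib_ambiguous_sequence", "error")))
  if (method == "auto") method <- if (nchar(seq) <= 14L) "wallace" else "nearest_neighbor"
  b <- strsplit(seq, "")[[1]]
  if (method == "wallace") {
    tm <- 2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  } else {
    if (length(b) < 2L) stop("nearest-neighbor Tm needs at least 2 nt")
    steps <- paste0(b[-length(b)], b[-1L])
    dH <- sum(NN_DH[steps])
    dS <- sum(NN_DS[steps])
    for (term in b[c(1L, length(b))]) {     # initiation terms
      if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
      else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
    }
    dS <- dS + 0.368 * (length(b) - 1L) * log(na_mM / 1000)
    ct <- primer_nM * 1e-9
    tm <- 1000 * dH / (dS + 1.987 * log(ct / 4)) - 273.15
  }
  structure(tm, method = method)
}

#' Primer QC rule set
#'
#' @param gc_max Each arm's GC must be strictly below this percentage.
#' @param delta_gc_max Maximum allowed |GC difference| between arms, in
#'   percentage points (boundary passes).
#' @param tm_target,tm_tol Arm Tm must lie within `tm_target +/- tm_tol`
#'   degrees C. The target reflects the low-temperature annealing regime
#'   of the mutagenesis protocol; the tolerance is configurable because
#'   only "close to 45" is prescribed.
#' @param tm_method Passed to [melting_temp()].
#' @return A list of class `primer_rules`.
#' @export
primer_rules <- function(gc_max = 50, delta_gc_max = 5,
                         tm_target = 45, tm_tol = 3, tm_method = "auto") {
  structure(list(gc_max = gc_max, delta_gc_max = delta_gc_max,
                 tm_target = tm_target, tm_tol = tm_tol,
                 tm_method = tm_method), class = "primer_rules")
}

#' QC one mutagenesis primer against the arm-composition rules
#'
#' Evaluates, on the two unambiguous arms only (the degenerate core has no
#' defined GC or Tm): GC below `gc_max` per arm, |deltaGC| at most
#' `delta_gc_max`, and Tm within the configured window per arm.
#'
#' @param p A [primer()].
#' @param rules A [primer_rules()].
#' @return Object of class `primer_qc_report`: arm statistics, one row per
#'   rule with pass flags, the Tm method used, and overall `pass`.
#' @export
qc_primer <- function(p, rules = primer_rules()) {
  stopifnot(inherits(p, "primer"))
  arms <- c(upstream = p$upstream_arm, downstream = p$downstream_arm)
  gc <- vapply(arms, gc_content, 1)
  tm <- lapply(arms, melting_temp, method = rules$tm_method)
  tm_val <- vapply(tm, as.numeric, 1)
  delta_gc <- abs(diff(gc))
  checks <- data.frame(
    rule = c("GC<50", "dGC<=5", "Tm~45"),
    description = c(
      sprintf("each arm GC strictly below %g%%", rules$gc_max),
      sprintf("arm GC difference at most %g points", rules$delta_gc_max),
      sprintf("each arm Tm within %g +/- %g C", rules$tm_target, rules$tm_tol)),
    value = c(max(gc), delta_gc, max(abs(tm_val - rules$tm_target))),
    pass = c(all(gc < rules$gc_max),
             delta_gc <= rules$delta_gc_max,
             all(abs(tm_val - rules$tm_target) <= rules$tm_tol)))
  structure(list(name = p$name, arm_gc = gc, delta_gc = delta_gc,
                 arm_tm = tm_val,
                 tm_method = vapply(tm, attr, "", "method"),
                 checks = checks, rules = rules,
                 pass = all(checks$pass)), class = "primer_qc_report")
}

#' @export
#' @method print primer_qc_report
print.primer_qc_report <- function(x, ...) {
  cat(sprintf("<primer QC: %s — %s>\n", x$name, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  arm GC: %.1f%% / %.1f%% (d = %.1f)   arm Tm: %.1f / %.1f C (%s)\n",
              x$arm_gc[1], x$arm_gc[2], x$delta_gc,
              x$arm_tm[1], x$arm_tm[2], paste(unique(x$tm_method), collapse = "+")))
  print.data.frame(x$checks, row.names = FALSE)
  invisible(x)
}

#' QC a table of primers
#'
#' @param primers List of [primer()]s, or a data.frame with columns `name`,
#'   `sequence`, `upstream_arm`, `downstream_arm` (and optionally
#'   `concentration_uM`).
#' @param rules A [primer_rules()].
#' @return Data.frame with one row per primer: arm GC/Tm values and the
#'   per-rule and overall pass flags.
#' @export
qc_primers <- function(primers, rules = primer_rules()) {
  if (is.data.frame(primers)) {
    primers <- lapply(seq_len(nrow(primers)), function(i)
      primer(primers$name[i], primers$sequence[i], primers$upstream_arm[i],
             primers$downstream_arm[i],
             if ("concentration_uM" %in% names(primers))
               primers$concentration_uM[i] else NA_real_))
  }
  rows <- lapply(primers, function(p) {
    r <- qc_primer(p, rules)
    data.frame(name = r$name,
               gc_upstream = r$arm_gc[["upstream"]],
               gc_downstream = r$arm_gc[["downstream"]],
               delta_gc = r$delta_gc,
               tm_upstream = r$arm_tm[["upstream"]],
               tm_downstream = r$arm_tm[["downstream"]],
               pass_gc = r$checks$pass[1], pass_delta_gc = r$checks$pass[2],
               pass_tm = r$checks$pass[3], pass = r$pass)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Equimolar pooling of primers
#'
#' Computes per-primer volumes so that each primer contributes the same
#' molar amount to the pool (volumes inversely proportional to
#' concentration; equal concentrations give equal volumes), and reports
#' molecule counts via `N = c * N_A * v`. With concentrations in uM, a
#' volume in uL contributes `conc * volume` pmol.
#'
#' @param concentrations_uM Named numeric vector (or list of [primer()]s
#'   with concentrations) of stock concentrations in uM.
#' @param amount_pmol Molar amount each primer contributes (pmol).
#' @return Data.frame of class `primer_pool`: per-primer volume (uL),
#'   amount (pmol) and molecule count; total volume and pool concentration
#'   as attributes.
#' @examples
#' equimolar_pool(c(p1 = 100, p2 = 100, p3 = 100), amount_pmol = 100)
#' @export
equimolar_pool <- function(concentrations_uM, amount_pmol = 100) {
  if (is.list(concentrations_uM) && all(vapply(concentrations_uM, inherits, TRUE, "primer"))) {
    concentrations_uM <- stats::setNames(
      vapply(concentrations_uM, `[[`, 1, "concentration_uM"),
      vapply(concentrations_uM, `[[`, "", "name"))
  }
  conc <- unlist(concentrations_uM)
  if (any(is.na(conc)) || any(conc <= 0))
    stop("every primer needs a positive concentration for pooling")
  vol <- amount_pmol / conc                 # uL: pmol / (pmol/uL)
  out <- data.frame(
    name = if (is.null(names(conc))) paste0("primer_", seq_along(conc)) else names(conc),
    concentration_uM = as.numeric(conc),
    volume_uL = as.numeric(vol),
    amount_pmol = amount_pmol,
    molecules = amount_pmol * 1e-12 * AVOGADRO)
  attr(out, "total_volume_uL") <- sum(vol)
  attr(out, "pool_concentration_uM") <- length(conc) * amount_pmol / sum(vol)
  class(out) <- c("primer_pool", "data.frame")
  out
}

#' Read primers from TSV
#'
#' Expected columns: `name`, `sequence`, `upstream_arm`, `downstream_arm`,
#' optional `concentration_uM`.
#'
#' @param path TSV file.
#' @return List of [primer()]s.
#' @export
read_primers_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    primer(df$name[i], df$sequence[i], df$upstream_arm[i], df$downstream_arm[i],
           if ("concentration_uM" %in% names(df)) df$concentration_uM[i]
           else NA_real_))
}
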