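# Seeded synthetic-data generator: repertoires realized from the cassette
# design (with configurable residual-template fraction and sequencing
# error), ELISA plates with planted binders, and panning titer
# trajectories — each with a ground-truth table.

#' Generator configuration
#'
#' @param seed Integer seed; one PRNG stream per run.
#' @param n_clones Number of clones to emit (default 190, one sequencing
#'   plate's worth of colonies).
#' @param sublibrary_mix Weights over sources `S`, `L` and `VL_only`
#'   (normalized internally). `VL_only` clones mutate only the VL loop and
#'   keep the template VH CDR3.
#' @param length_weights Optional per-loop-length weights within a
#'   sublibrary (named by length); uniform when NULL.
#' @param template_fraction Probability a clone is the unmutated parental
#'   template (residual template carryover).
#' @param substitution_rate,indel_rate Per-base sequencing error
#'   probabilities applied after realization (substitutions first, then
#'   indels).
#' @param genetic_code_mode Passed to [genetic_code()].
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_clones = 190L,
                             sublibrary_mix = c(S = 0.5, L = 0.5, VL_only = 0),
                             length_weights = NULL,
                             template_fraction = 0,
                             substitution_rate = 0, indel_rate = 0,
                             genetic_code_mode = "standard") {
  stopifnot(template_fraction >= 0, template_fraction <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, n_clones >= 0)
  mix <- c(S = 0, L = 0, VL_only = 0)
  mix[names(sublibrary_mix)] <- sublibrary_mix
  stopifnot(sum(mix) > 0)
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 sublibrary_mix = mix / sum(mix),
                 length_weights = length_weights,
                 template_fraction = template_fraction,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 genetic_code_mode = genetic_code_mode),
            class = "generator_config")
}

# n independent uniform realizations of a cassette's degenerate core
realize_cassette_n <- function(cassette, n) {
  if (n == 0L) return(character(0))
  sets <- unlist(lapply(cassette_codons(cassette), `[[`, "base_sets"),
                 recursive = FALSE)
  mat <- vapply(sets, function(s) {
    if (length(s) == 1L) rep(s, n) else sample(s, n, replace = TRUE)
  }, character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  apply(mat, 1L, paste, collapse = "")
}

# substitutions then indels, per base; returns sequences and error counts
apply_sequencing_errors <- function(seqs, sub_rate, indel_rate) {
  n_sub <- n_ins <- n_del <- integer(length(seqs))
  if (sub_rate == 0 && indel_rate == 0)
    return(list(seqs = seqs, n_sub = n_sub, n_ins = n_ins, n_del = n_del))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[i], "")[[1]]
    if (sub_rate > 0) {
      hit <- which(stats::runif(length(b)) < sub_rate)
      for (j in hit) b[j] <- sample(setdiff(bases, b[j]), 1L)
      n_sub[i] <- length(hit)
    }
    if (indel_rate > 0) {
      u <- stats::runif(length(b))
      del <- u < indel_rate / 2
      ins <- u >= indel_rate / 2 & u < indel_rate
      n_del[i] <- sum(del); n_ins[i] <- sum(ins)
      pieces <- ifelse(del, "", b)
      if (any(ins))
        pieces[ins] <- paste0(pieces[ins], sample(bases, sum(ins), replace = TRUE))
      b <- pieces
    }
    seqs[i] <- paste(b, collapse = "")
  }
  list(seqs = seqs, n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

#' Generate a synthetic sequenced repertoire with ground truth
#'
#' Each clone is, with probability `template_fraction`, the unmutated
#' parental template; otherwise a source is drawn from `sublibrary_mix`, a
#' VH cassette from the sublibrary's loop lengths (uniform unless
#' `length_weights` is given), a VL variant (A/B) from the design's
#' variant weights, each degenerate position is realized uniformly over
#' its expansion, the realizations are embedded in the template framework,
#' and sequencing errors are applied (substitutions, then indels).
#' Deterministic given the config seed.
#'
#' @param design A [library_design()].
#' @param config A [generator_config()].
#' @return List of class `synthetic_repertoire`: `sequences`
#'   (`DNAStringSet`), `truth` (data.frame, one row per clone), `config`.
#' @export
generate_repertoire <- function(design, config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_clones
  tm <- design$template
  vl_iv <- template_interval(tm, "VL"); vh_iv <- template_interval(tm, "VH")
  seg_pre <- substr(tm$sequence, 1L, vl_iv$start)
  seg_mid <- substr(tm$sequence, vl_iv$end + 1L, vh_iv$start)
  seg_post <- substr(tm$sequence, vh_iv$end + 1L, nchar(tm$sequence))
  tmpl_vl <- template_region(tm, "VL"); tmpl_vh <- template_region(tm, "VH")

  ids <- sprintf("clone_%05d", seq_len(n))
  if (n == 0L) {
    return(structure(list(
      sequences = Biostrings::DNAStringSet(),
      truth = data.frame(id = character(0)), config = config),
      class = "synthetic_repertoire"))
  }

  is_template <- stats::runif(n) < config$template_fraction
  source <- rep("template", n)
  idx_mut <- which(!is_template)
  mix <- config$sublibrary_mix
  source[idx_mut] <- sample(names(mix), length(idx_mut), replace = TRUE,
                            prob = mix)

  # VH cassette per clone
  vh_name <- rep(NA_character_, n)
  for (sub in c("S", "L")) {
    idx <- which(source == sub)
    if (!length(idx)) next
    lens <- design$sublibraries[[sub]]$loop_lengths
    w <- rep(1, length(lens))
    if (!is.null(config$length_weights)) {
      hit <- as.character(lens) %in% names(config$length_weights)
      w[hit] <- config$length_weights[as.character(lens)[hit]]
    }
    pick <- sample(seq_along(lens), length(idx), replace = TRUE, prob = w)
    vh_name[idx] <- vapply(design$sublibraries[[sub]]$cassettes[pick],
                           `[[`, "", "name")
  }

  # VL variant per mutant clone
  vl_variant <- rep(NA_character_, n)
  vw <- design$config$vl_variant_weights
  vl_variant[idx_mut] <- sample(names(vw), length(idx_mut), replace = TRUE,
                                prob = vw)

  vl_nt <- rep(NA_character_, n); vh_nt <- rep(NA_character_, n)
  vl_nt[is_template] <- tmpl_vl; vh_nt[is_template] <- tmpl_vh
  vh_nt[source == "VL_only"] <- tmpl_vh
  for (v in names(design$vl_cassettes)) {
    idx <- which(vl_variant == v)
    vl_nt[idx] <- realize_cassette_n(design$vl_cassettes[[v]], length(idx))
  }
  all_vh <- all_vh_cassettes(design)
  names(all_vh) <- vapply(all_vh, `[[`, "", "name")
  for (nm in names(all_vh)) {
    idx <- which(vh_name == nm)
    if (length(idx))
      vh_nt[idx] <- realize_cassette_n(all_vh[[nm]], length(idx))
  }

  mode <- config$genetic_code_mode
  vl_pep <- translate_inframe(vl_nt, mode)
  vh_pep <- translate_inframe(vh_nt, mode)
  seqs <- paste0(seg_pre, vl_nt, seg_mid, vh_nt, seg_post)
  err <- apply_sequencing_errors(seqs, config$substitution_rate,
                                 config$indel_rate)

  truth <- data.frame(
    id = ids, is_template = is_template, source = source,
    vl_variant = vl_variant, vh_cassette = vh_name,
    vl_nt = vl_nt, vl_pep = vl_pep,
    vh_nt = vh_nt, vh_pep = vh_pep,
    vh_loop_length = ifelse(source %in% c("S", "L"),
                            nchar(vh_nt) %/% 3L - 2L, NA_integer_),
    n_sub = err$n_sub, n_ins = err$n_ins, n_del = err$n_del)
  sequences <- Biostrings::DNAStringSet(stats::setNames(err$seqs, ids))
  structure(list(sequences = sequences, truth = truth, config = config),
            class = "synthetic_repertoire")
}

#' @export
#' @method print synthetic_repertoire
print.synthetic_repertoire <- function(x, ...) {
  cat(sprintf("<synthetic repertoire: %d clones (seed %d)>\n",
              length(x$sequences), x$config$seed))
  if (nrow(x$truth)) print(table(x$truth$source))
  invisible(x)
}

#' Write a synthetic repertoire as FASTA plus a truth-table TSV
#'
#' The seed is recorded in both outputs (FASTA description of the first
#' record, TSV comment header) so a run can be reproduced byte-for-byte.
#'
#' @param rep A [generate_repertoire()] result.
#' @param fasta_path,truth_path Output files.
#' @return `fasta_path`, invisibly.
#' @export
write_repertoire <- function(rep, fasta_path, truth_path) {
  dss <- rep$sequences
  if (length(dss))
    names(dss)[1L] <- paste0(names(dss)[1L], " seed=", rep$config$seed)
  Biostrings::writeXStringSet(dss, fasta_path)
  con <- file(truth_path, "w")
  writeLines(sprintf("# seed=%d n_clones=%d template_fraction=%g",
                     rep$config$seed, rep$config$n_clones,
                     rep$config$template_fraction), con)
  utils::write.table(rep$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(fasta_path)
}

#' Generate an ELISA plate with planted binders
#'
#' Binder and non-binder/control absorbances are drawn from lognormal
#' high/low components. The defaults give a strongly separated plate
#' (negative controls near 0.08 absorbance units, binders near 1.0, i.e.
#' roughly 12-fold over control).
#'
#' @param n_clones Number of clone wells (default 50).
#' @param n_binders Number of planted binders (default 12).
#' @param signal_params List with `low_meanlog`, `low_sdlog`,
#'   `high_meanlog`, `high_sdlog` of the lognormal components.
#' @param n_controls Number of negative-control wells.
#' @param seed Integer seed.
#' @return List: `plate` (an [elisa_plate()]) and `truth` (data.frame with
#'   `id`, `is_binder`).
#' @export
generate_elisa_fixture <- function(n_clones = 50L, n_binders = 12L,
                                   signal_params = list(
                                     low_meanlog = log(0.08), low_sdlog = 0.2,
                                     high_meanlog = log(1.0), high_sdlog = 0.25),
                                   n_controls = 4L, seed = 1L) {
  stopifnot(n_binders <= n_clones)
  set.seed(seed)
  ids <- sprintf("clone_%02d", seq_len(n_clones))
  binder <- rep(FALSE, n_clones)
  binder[sample(n_clones, n_binders)] <- TRUE
  a450 <- numeric(n_clones)
  a450[binder] <- stats::rlnorm(n_binders, signal_params$high_meanlog,
                                signal_params$high_sdlog)
  a450[!binder] <- stats::rlnorm(n_clones - n_binders,
                                 signal_params$low_meanlog,
                                 signal_params$low_sdlog)
  nc_ids <- sprintf("NC%d", seq_len(n_controls))
  nc <- stats::rlnorm(n_controls, signal_params$low_meanlog,
                      signal_params$low_sdlog)
  plate <- elisa_plate(data.frame(id = c(ids, nc_ids), a450 = c(a450, nc)),
                       nc_ids)
  list(plate = plate, truth = data.frame(id = ids, is_binder = binder))
}

#' Generate a panning titer trajectory
#'
#' The output/input recovery ratio multiplies by `enrichment_factor` each
#' round, with optional lognormal noise.
#'
#' @param n_rounds Number of rounds.
#' @param enrichment_factor Multiplicative per-round gain of the recovery
#'   ratio.
#' @param input_titer Input titer per round (pfu; recycled).
#' @param initial_ratio Recovery ratio of round 1.
#' @param noise_sdlog Lognormal noise sd on the ratios (0 = none).
#' @param seed Integer seed.
#' @return A [panning_rounds()] data.frame.
#' @export
generate_panning_fixture <- function(n_rounds = 3L, enrichment_factor = 10,
                                     input_titer = 1e12, initial_ratio = 1e-8,
                                     noise_sdlog = 0, seed = 1L) {
  set.seed(seed)
  input <- rep_len(input_titer, n_rounds)
  ratio <- initial_ratio * enrichment_factor^(seq_len(n_rounds) - 1L)
  if (noise_sdlog > 0)
    ratio <- ratio * stats::rlnorm(n_rounds, 0, noise_sdlog)
  panning_rounds(input, input * ratio)
}

#' Read a generator configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of
#'   [generator_config()].
#' @return A [generator_config()].
#' @export
generator_config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$sublibrary_mix)) cfg$sublibrary_mix <- unlist(cfg$sublibrary_mix)
  if (!is.null(cfg$length_weights)) cfg$length_weights <- unlist(cfg$length_weights)
  do.call(generator_config, cfg)
}

#' Build a library design from a JSON parameter file
#'
#' Recognized keys: `fixed_codons` (named Y/P/R/D), `vl_variant_b_91`,
#' `vl_variant_weights`, `s_lengths`, `l_lengths` (2-element ranges).
#'
#' @param path JSON file.
#' @return A [library_design()].
#' @export
design_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- list()
  if (!is.null(j$fixed_codons)) cfg_args$fixed_codons <- unlist(j$fixed_codons)
  if (!is.null(j$vl_variant_b_91)) cfg_args$vl_variant_b_91 <- j$vl_variant_b_91
  if (!is.null(j$vl_variant_weights))
    cfg_args$vl_variant_weights <- unlist(j$vl_variant_weights)
  cfg <- do.call(design_config, cfg_args)
  rng <- function(x, default) if (is.null(x)) default else seq(x[1], x[2])
  library_design(cfg, s_lengths = rng(j$s_lengths, 5:22),
                 l_lengths = rng(j$l_lengths, 9:28))
}
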