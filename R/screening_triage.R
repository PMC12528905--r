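# Panning enrichment trajectories and ELISA hit calling by the
# fold-over-negative-control rule.

#' Panning rounds
#'
#' @param input_titer,output_titer Phage titers (pfu) per selection round,
#'   both strictly positive.
#' @return Data.frame of class `panning_rounds` with a `round` index.
#' @export
panning_rounds <- function(input_titer, output_titer) {
  stopifnot(length(input_titer) == length(output_titer),
            all(input_titer > 0), all(output_titer > 0))
  structure(data.frame(round = seq_along(input_titer),
                       input_titer = input_titer,
                       output_titer = output_titer),
            class = c("panning_rounds", "data.frame"))
}

#' Per-round enrichment trajectory
#'
#' The recovery ratio `output/input` per panning round, and the fold
#' change of that ratio between consecutive rounds (NA for the first). A
#' rising ratio across rounds indicates enrichment of target binders.
#'
#' @param rounds A [panning_rounds()] data.frame (or one with
#'   `input_titer`/`output_titer` columns).
#' @return Data.frame with `round`, `input_titer`, `output_titer`,
#'   `ratio`, `fold_change`.
#' @examples
#' enrichment_trajectory(panning_rounds(rep(1e12, 3), c(1e4, 1e6, 1e8)))
#' @export
enrichment_trajectory <- function(rounds) {
  stopifnot(all(c("input_titer", "output_titer") %in% names(rounds)))
  ratio <- rounds$output_titer / rounds$input_titer
  data.frame(round = seq_along(ratio),
             input_titer = rounds$input_titer,
             output_titer = rounds$output_titer,
             ratio = ratio,
             fold_change = c(NA, ratio[-1] / ratio[-length(ratio)]))
}

#' An ELISA plate with negative controls
#'
#' @param wells Data.frame with `id` and `a450` (absorbance at 450 nm,
#'   non-negative) columns, or a named numeric vector.
#' @param negative_controls Character vector of well ids serving as
#'   negative controls (at least one, all present in `wells`).
#' @return Object of class `elisa_plate`.
#' @export
elisa_plate <- function(wells, negative_controls) {
  if (!is.data.frame(wells))
    wells <- data.frame(id = names(wells), a450 = as.numeric(wells))
  stopifnot(all(c("id", "a450") %in% names(wells)), all(wells$a450 >= 0),
            !anyDuplicated(wells$id))
  if (length(negative_controls) == 0L ||
      !all(negative_controls %in% wells$id))
    stop(errorCondition("at least one negative-control well is required",
                        class = c("scfvlib_no_controls", "error")))
  structure(list(wells = wells, negative_controls = negative_controls),
            class = "elisa_plate")
}

#' Call ELISA hits by fold over negative controls
#'
#' A clone is a hit iff its A450 is at least `fold_threshold` times the
#' negative-control summary (arithmetic mean by default); equality at the
#' boundary counts as a hit. Hit calls are invariant to a common scaling
#' of all absorbances and monotone in each clone's absorbance.
#'
#' @param plate An [elisa_plate()].
#' @param fold_threshold Positive fold cutoff (default 4).
#' @param control_stat `"mean"` or `"median"` summary of the negative
#'   controls.
#' @return List of class `elisa_hits`: `hits` (clone ids),
#'   `report` (per-clone fold and call), `control_level`.
#' @export
call_hits <- function(plate, fold_threshold = 4,
                      control_stat = c("mean", "median")) {
  stopifnot(inherits(plate, "elisa_plate"), fold_threshold > 0)
  control_stat <- match.arg(control_stat)
  w <- plate$wells
  is_ctrl <- w$id %in% plate$negative_controls
  ctrl <- if (control_stat == "mean") mean(w$a450[is_ctrl])
          else stats::median(w$a450[is_ctrl])
  if (ctrl <= 0)
    stop("negative-control level is zero; fold over control is undefined")
  clones <- w[!is_ctrl, , drop = FALSE]
  fold <- clones$a450 / ctrl
  report <- data.frame(id = clones$id, a450 = clones$a450, fold = fold,
                       hit = fold >= fold_threshold)
  structure(list(hits = report$id[report$hit], report = report,
                 control_level = ctrl, control_stat = control_stat,
                 fold_threshold = fold_threshold), class = "elisa_hits")
}

#' @export
#' @method print elisa_hits
print.elisa_hits <- function(x, ...) {
  cat(sprintf("<ELISA hits: %d of %d clones at >= %g-fold over control (%s = %.3g)>\n",
              length(x$hits), nrow(x$report), x$fold_threshold,
              x$control_stat, x$control_level))
  if (length(x$hits)) print(rank_candidates(x))
  invisible(x)
}

#' Rank called hits
#'
#' Descending by fold over control; ties broken by clone id
#' (lexicographic) for determinism.
#'
#' @param hits An [call_hits()] result (or its `report` data.frame).
#' @return Data.frame of hits in rank order.
#' @export
rank_candidates <- function(hits) {
  report <- if (inherits(hits, "elisa_hits")) hits$report else hits
  h <- report[report$hit, , drop = FALSE]
  h <- h[order(-h$fold, h$id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Read a titer table as panning rounds
#'
#' TSV with `input_titer` and `output_titer` columns (one row per round).
#'
#' @param path TSV file.
#' @return A [panning_rounds()] data.frame.
#' @export
read_titers_tsv <- function(path) {
  df <- utils::read.delim(path)
  panning_rounds(df$input_titer, df$output_titer)
}

#' Read an ELISA plate table
#'
#' TSV with `id` and `a450` columns; wells whose id appears in
#' `control_ids` (or, by default, ids starting with `"NC"`) are the
#' negative controls.
#'
#' @param path TSV file.
#' @param control_ids Optional explicit control ids.
#' @return An [elisa_plate()].
#' @export
read_elisa_tsv <- function(path, control_ids = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(control_ids)) control_ids <- df$id[startsWith(df$id, "NC")]
  elisa_plate(df, control_ids)
}
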