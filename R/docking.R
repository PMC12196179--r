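#' Best-scoring compound per docking target
#'
#' Docking scores are binding free energies in kcal/mol; more negative is
#' more favorable, so the best pose per target is the minimum.
#'
#' @param scores long-format data frame with columns `compound`, `target`,
#'   `score` (kcal/mol); `NA` marks missing pairs. See
#'   [docking_matrix_to_long()] for wide matrices.
#' @return tibble with one row per (target, tied best compound):
#'   `target`, `compound`, `score`, `n_tied`. Targets with no finite score
#'   appear with `NA` compound and score.
#' @export
best_per_target <- function(scores) {
  scores <- validate_docking_long(scores)
  scores |>
    dplyr::group_by(.data$target) |>
    dplyr::group_modify(function(df, key) {
      ok <- is.finite(df$score)
      if (!any(ok)) {
        return(tibble::tibble(compound = NA_character_, score = NA_real_, n_tied = 0L))
      }
      best <- min(df$score[ok])
      hits <- df[ok & df$score == best, , drop = FALSE]
      tibble::tibble(
        compound = sort(hits$compound),
        score = best,
        n_tied = nrow(hits)
      )
    }) |>
    dplyr::ungroup()
}

validate_docking_long <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0 ||
    !all(c("compound", "target", "score") %in% names(scores))) {
    stop_validation("`scores` must be a nonempty data frame with compound, target, score")
  }
  if (any(is.infinite(scores$score), na.rm = TRUE)) {
    stop_validation("docking scores must be finite or NA")
  }
  tibble::as_tibble(scores)
}

#' Convert a wide compound-by-target score matrix to long format
#'
#' @param m data frame whose first column names the compounds and whose
#'   remaining columns are targets (the layout of a score-matrix CSV).
#' @return long tibble with columns `compound`, `target`, `score`.
#' @export
docking_matrix_to_long <- function(m) {
  if (!is.data.frame(m) || ncol(m) < 2) {
    stop_validation("`m` must be a data frame with a compound column plus target columns")
  }
  names(m)[1] <- "compound"
  tidyr::pivot_longer(
    tibble::as_tibble(m), -"compound",
    names_to = "target", values_to = "score"
  )
}

#' Flag biologically relevant docking interactions
#'
#' Applies the conventional relevance cutoff for docking scores (default
#' -5.00 kcal/mol): a compound-target pair is relevant when its score is at
#' or below the cutoff, and a compound is relevant when it has at least one
#' relevant target.
#'
#' @inheritParams best_per_target
#' @param cutoff relevance threshold in kcal/mol (negative; default -5).
#' @return list with `pairs` (long tibble plus logical `relevant`) and
#'   `compounds` (per-compound tibble with `n_relevant_targets` and
#'   `relevant`).
#' @export
relevance_flags <- function(scores, cutoff = -5.0) {
  scores <- validate_docking_long(scores)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff >= 0) {
    stop_validation("`cutoff` must be a single negative number (kcal/mol)")
  }
  pairs <- dplyr::mutate(scores, relevant = !is.na(.data$score) & .data$score <= cutoff)
  compounds <- pairs |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      best_score = ifelse(all(is.na(.data$score)), NA_real_,
        min(.data$score, na.rm = TRUE)
      ),
      n_relevant_targets = sum(.data$relevant),
      relevant = any(.data$relevant),
      .groups = "drop"
    )
  list(pairs = pairs, compounds = compounds)
}

#' Select the optimal docking pose
#'
#' From a pose list, the optimal conformation is the lowest binding energy
#' among poses with acceptable RMSD; if no pose satisfies the RMSD limit,
#' the overall lowest-energy pose is returned with a warning.
#'
#' @param poses data frame with columns `energy` (kcal/mol) and `rmsd`
#'   (Angstrom).
#' @param rmsd_max RMSD acceptability limit (default 2.0 A, the usual
#'   pose-clustering convention).
#' @return single-row tibble: the selected pose plus `rmsd_ok`.
#' @export
select_best_pose <- function(poses, rmsd_max = 2.0) {
  if (!is.data.frame(poses) || nrow(poses) == 0 ||
    !all(c("energy", "rmsd") %in% names(poses))) {
    stop_validation("`poses` must be a nonempty data frame with energy and rmsd")
  }
  poses <- tibble::as_tibble(poses)
  ok <- poses$rmsd <= rmsd_max
  if (any(ok)) {
    sel <- poses[ok, , drop = FALSE]
    out <- sel[which.min(sel$energy), , drop = FALSE]
    out$rmsd_ok <- TRUE
  } else {
    warn("no pose within the RMSD limit; returning the lowest-energy pose")
    out <- poses[which.min(poses$energy), , drop = FALSE]
    out$rmsd_ok <- FALSE
  }
  out
}
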