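#' Count Lipinski rule-of-five violations
#'
#' The four oral drug-likeness limits: molecular weight <= 500 Da,
#' logP <= 5, H-bond donors <= 5, H-bond acceptors <= 10. Violations are
#' strict exceedances, so a compound sitting exactly on a limit does not
#' violate it.
#'
#' @param descriptors data frame with numeric columns `mw`, `logp`, `hbd`,
#'   `hba` (one row per compound).
#' @return integer vector of violation counts (0-4), one per row.
#' @export
lipinski_violations <- function(descriptors) {
  validate_descriptors(descriptors)
  with(descriptors, {
    (mw > 500) + (logp > 5) + (hbd > 5) + (hba > 10)
  }) |> as.integer()
}

validate_descriptors <- function(d, need_bio = FALSE) {
  if (!is.data.frame(d) || nrow(d) == 0) {
    stop_validation("`descriptors` must be a nonempty data frame")
  }
  needed <- c("mw", "logp", "hbd", "hba", if (need_bio) "bioavailability_score")
  missing <- setdiff(needed, names(d))
  if (length(missing) > 0) {
    stop_validation(paste0("missing descriptor column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in needed) {
    if (!is.numeric(d[[col]]) || anyNA(d[[col]])) {
      stop_validation(sprintf("descriptor column `%s` must be numeric without NA", col))
    }
  }
  if (any(d$mw <= 0)) stop_validation("mw must be positive")
  if (any(d$hbd < 0) || any(d$hba < 0)) stop_validation("hbd/hba must be nonnegative")
  if (need_bio && (any(d$bioavailability_score < 0) || any(d$bioavailability_score > 1))) {
    stop_validation("bioavailability_score must lie in [0, 1]")
  }
  invisible(d)
}

#' Screen compounds for drug-likeness
#'
#' A compound passes when its Lipinski violation count is at most
#' `max_violations` and its predicted oral bioavailability score is at least
#' `min_bioavailability`. The defaults (one allowed violation, score >= 0.5)
#' follow the original rule-of-five allowance and the conventional Abbott
#' bioavailability cutoff.
#'
#' @param descriptors data frame with columns `name`, `mw`, `logp`, `hbd`,
#'   `hba`, `bioavailability_score`.
#' @param max_violations maximum allowed rule-of-five violations (default 1;
#'   set 0 for strict compliance).
#' @param min_bioavailability minimum bioavailability score (default 0.5).
#' @return tibble with per-rule outcomes (`viol_mw`, `viol_logp`,
#'   `viol_hbd`, `viol_hba`), the violation count, `bio_ok` and `pass`.
#' @export
screen_druglikeness <- function(descriptors, max_violations = 1,
                                min_bioavailability = 0.5) {
  validate_descriptors(descriptors, need_bio = TRUE)
  tibble::as_tibble(descriptors) |>
    dplyr::mutate(
      viol_mw = .data$mw > 500,
      viol_logp = .data$logp > 5,
      viol_hbd = .data$hbd > 5,
      viol_hba = .data$hba > 10,
      violations = as.integer(.data$viol_mw + .data$viol_logp +
        .data$viol_hbd + .data$viol_hba),
      bio_ok = .data$bioavailability_score >= min_bioavailability,
      pass = .data$violations <= max_violations & .data$bio_ok
    )
}
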