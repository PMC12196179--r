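#' Kovats/van den Dool retention index against an n-alkane ladder
#'
#' Converts analyte retention times to retention indices on the scale
#' anchored by a homologous n-alkane series (carbon number n maps to index
#' 100 n), interpolating linearly between the bracketing alkanes as is
#' standard for temperature-programmed GC.
#'
#' @param rt numeric vector of analyte retention times (minutes).
#' @param ladder data frame with columns `carbon` (integer carbon numbers,
#'   strictly increasing) and `rt` (minutes, strictly increasing), e.g. from
#'   [gen_alkane_ladder()].
#' @return numeric vector of retention indices (index units).
#' @details Retention times outside the ladder span are an error: the
#'   calibration is not extrapolated.
#' @examples
#' ladder <- tibble::tibble(carbon = c(10, 11), rt = c(10, 12))
#' retention_index(10.5, ladder) # 1025
#' @export
retention_index <- function(rt, ladder) {
  validate_ladder(ladder)
  if (!is.numeric(rt) || any(!is.finite(rt))) {
    stop_validation("`rt` must be finite numeric")
  }
  lo <- min(ladder$rt)
  hi <- max(ladder$rt)
  if (any(rt < lo | rt > hi)) {
    stop_validation(sprintf(
      "retention time outside the alkane ladder span [%.3f, %.3f]; no extrapolation",
      lo, hi
    ))
  }
  vapply(rt, function(t) {
    i <- findInterval(t, ladder$rt, rightmost.closed = TRUE)
    cn <- ladder$carbon[i]
    cn1 <- ladder$carbon[i + 1]
    tn <- ladder$rt[i]
    tn1 <- ladder$rt[i + 1]
    100 * (cn + (cn1 - cn) * (t - tn) / (tn1 - tn))
  }, numeric(1))
}

validate_ladder <- function(ladder) {
  if (!is.data.frame(ladder) || !all(c("carbon", "rt") %in% names(ladder))) {
    stop_validation("`ladder` must be a data frame with columns `carbon` and `rt`")
  }
  if (nrow(ladder) < 2) stop_validation("ladder needs at least two alkanes")
  if (any(diff(ladder$carbon) <= 0) || any(diff(ladder$rt) <= 0)) {
    stop_validation("ladder carbon numbers and retention times must be strictly increasing")
  }
  invisible(ladder)
}

#' Confirm peak identities by retention-index agreement
#'
#' Compares experimental against literature retention indices and flags each
#' peak whose absolute deviation is within `tolerance` index units, the usual
#' confirmation step alongside mass-spectral matching.
#'
#' @param peaks data frame with columns `ri_exp` and `ri_lit` (index units).
#' @param tolerance acceptance window in index units (default 10, a common
#'   choice for 5%-phenyl columns; the matching window is method-dependent).
#' @return `peaks` with `ri_deviation` (signed, experimental minus
#'   literature) and `ri_confirmed` (logical) columns appended.
#' @export
confirm_identity <- function(peaks, tolerance = 10) {
  if (!is.data.frame(peaks) || !all(c("ri_exp", "ri_lit") %in% names(peaks))) {
    stop_validation("`peaks` must contain `ri_exp` and `ri_lit` columns")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance <= 0) {
    stop_validation("`tolerance` must be a single positive number")
  }
  dplyr::mutate(
    tibble::as_tibble(peaks),
    ri_deviation = .data$ri_exp - .data$ri_lit,
    ri_confirmed = abs(.data$ri_deviation) <= tolerance
  )
}

# Controlled class vocabulary used for subtotals.
terpene_classes <- c(
  "monoterpene hydrocarbon", "oxygenated monoterpene",
  "sesquiterpene hydrocarbon", "oxygenated sesquiterpene", "other"
)

#' Map free-text chemical class labels to the subtotal vocabulary
#'
#' Peak tables carry descriptive classes ("Bicyclic monoterpene hydrocarbon",
#' "Tricyclic sesquiterpene alcohol", ...). Subtotals are computed over five
#' groups: monoterpene hydrocarbons (aromatic monoterpene hydrocarbons
#' included), oxygenated monoterpenes (alcohols/oxides/aldehydes/ketones),
#' sesquiterpene hydrocarbons, oxygenated sesquiterpenes, and "other" for
#' non-terpenoids such as fatty acid esters.
#'
#' @param x character vector of class labels.
#' @return character vector over the controlled vocabulary.
#' @export
normalize_chemical_class <- function(x) {
  lx <- tolower(trimws(x))
  out <- dplyr::case_when(
    lx %in% terpene_classes ~ lx,
    grepl("sesquiterpene", lx) & grepl("alcohol|oxide|ol$|one|al$|ether", lx) ~
      "oxygenated sesquiterpene",
    grepl("sesquiterpene", lx) ~ "sesquiterpene hydrocarbon",
    grepl("monoterpene", lx) & grepl("alcohol|oxide|ol$|one|al$|ether", lx) ~
      "oxygenated monoterpene",
    grepl("monoterpene", lx) ~ "monoterpene hydrocarbon",
    grepl("ester|acid|alkane|aldehyde|ketone", lx) ~ "other",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    stop_validation(paste0(
      "unrecognized chemical class label(s): ",
      paste(unique(x[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Summarize an identified-peak table into class totals
#'
#' Computes area-percent subtotals per chemical class group and two grand
#' totals: the terpenoid total (the four terpene subtotals, excluding
#' non-terpenoid "other" peaks) and the total over all identified peaks.
#'
#' @param peaks data frame with columns `name`, `chemical_class` and
#'   `area_pct`; classes may be free text (see [normalize_chemical_class()]).
#' @return An object of class `composition_summary` with elements `peaks`
#'   (per-peak tibble with the normalized `class_group`), `class_totals`
#'   (tibble of per-group sums with 2-decimal display values), and scalars
#'   `total_identified` (all peaks) and `total_terpenoid` (terpene groups
#'   only). `tidy()` returns the class totals, `glance()` the grand totals.
#' @export
summarize_composition <- function(peaks) {
  if (!is.data.frame(peaks) || nrow(peaks) == 0) {
    stop_validation("`peaks` must be a nonempty data frame")
  }
  needed <- c("name", "chemical_class", "area_pct")
  if (!all(needed %in% names(peaks))) {
    stop_validation("`peaks` must contain columns name, chemical_class, area_pct")
  }
  if (any(peaks$area_pct < 0)) stop_validation("area_pct must be nonnegative")
  per_peak <- dplyr::mutate(
    tibble::as_tibble(peaks),
    class_group = normalize_chemical_class(.data$chemical_class)
  )
  class_totals <- per_peak |>
    dplyr::group_by(class_group = factor(.data$class_group, levels = terpene_classes)) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      area_pct = sum(.data$area_pct),
      .groups = "drop"
    ) |>
    tidyr::complete(
      class_group,
      fill = list(n_peaks = 0L, area_pct = 0)
    ) |>
    dplyr::mutate(
      class_group = as.character(.data$class_group),
      area_pct_2dp = round_half_up(.data$area_pct, 2)
    )
  total_identified <- sum(per_peak$area_pct)
  total_terpenoid <- sum(class_totals$area_pct[class_totals$class_group != "other"])
  structure(
    list(
      peaks = per_peak,
      class_totals = class_totals,
      total_identified = total_identified,
      total_terpenoid = total_terpenoid
    ),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("GC/MS composition summary:", nrow(x$peaks), "identified peaks\n")
  tot <- x$class_totals[x$class_totals$n_peaks > 0, c("class_group", "n_peaks", "area_pct_2dp")]
  print(as.data.frame(tot), row.names = FALSE)
  cat(sprintf("Total terpenoid:  %.2f%%\n", round_half_up(x$total_terpenoid, 2)))
  cat(sprintf("Total identified: %.2f%%\n", round_half_up(x$total_identified, 2)))
  invisible(x)
}

#' @rdname summarize_composition
#' @param x a `composition_summary`.
#' @param ... unused.
#' @export
tidy.composition_summary <- function(x, ...) x$class_totals

#' @rdname summarize_composition
#' @export
glance.composition_summary <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x$peaks),
    total_identified = x$total_identified,
    total_terpenoid = x$total_terpenoid
  )
}

normalize_compound_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  # common typographic synonyms
  x <- gsub("eucalyptol", "1,8-cineole", x, fixed = TRUE)
  x
}

#' Compare a composition profile against a reference profile
#'
#' Per-compound area-percent deltas between the current profile and a
#' reference (for instance an earlier analysis of the same species), with
#' optional grouped rows that pool isomers before comparison. Compounds are
#' matched case-insensitively after synonym normalization; compounds present
#' on only one side are flagged rather than dropped.
#'
#' @param current data frame with columns `name` and `area_pct`, or a
#'   `composition_summary`.
#' @param reference data frame with columns `name` and `area_pct`.
#' @param groups optional named list; each element pools the named current
#'   compounds into one row, e.g.
#'   `list("alpha-Pinene" = c("1R-alpha-Pinene", "1S-alpha-Pinene"))`.
#' @return tibble with columns `name`, `current`, `reference`, `delta`
#'   (current minus reference) and `status` (`"shared"`,
#'   `"absent_in_current"`, `"absent_in_reference"`).
#' @export
compare_profiles <- function(current, reference, groups = NULL) {
  if (inherits(current, "composition_summary")) current <- current$peaks
  for (nm in list(current, reference)) {
    if (!is.data.frame(nm) || !all(c("name", "area_pct") %in% names(nm))) {
      stop_validation("profiles must be data frames with `name` and `area_pct`")
    }
  }
  cur <- tibble::tibble(name = current$name, current = current$area_pct)
  if (!is.null(groups)) {
    for (gname in names(groups)) {
      members <- normalize_compound_name(groups[[gname]])
      in_group <- normalize_compound_name(cur$name) %in% members
      if (any(in_group)) {
        cur <- dplyr::bind_rows(
          cur[!in_group, ],
          tibble::tibble(name = gname, current = sum(cur$current[in_group]))
        )
      }
    }
  }
  cur$key <- normalize_compound_name(cur$name)
  ref <- tibble::tibble(
    key = normalize_compound_name(reference$name),
    ref_name = reference$name,
    reference = reference$area_pct
  )
  dplyr::full_join(cur, ref, by = "key") |>
    dplyr::transmute(
      name = dplyr::coalesce(.data$name, .data$ref_name),
      current = .data$current,
      reference = .data$reference,
      delta = .data$current - .data$reference,
      status = dplyr::case_when(
        is.na(.data$current) ~ "absent_in_current",
        is.na(.data$reference) ~ "absent_in_reference",
        TRUE ~ "shared"
      )
    ) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$delta)), dplyr::desc(abs(.data$delta)))
}
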