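#' Bundled reference datasets for Melaleuca quinquenervia leaf essential oil
#'
#' Small published-measurement tables for an Egyptian *Melaleuca
#' quinquenervia* leaf essential oil (MQLEO), bundled as plain-text CSV so
#' every stage of the pipeline has a real worked example:
#'
#' * `mq_peak_table()` — the 19 identified GC/MS peaks with retention time
#'   (min), experimental and literature retention indices, chemical class and
#'   chromatogram area percent.
#' * `mq_cytotoxicity()` — MTT assay CC50/IC50 values (mean, sd; ug/mL) for
#'   the oil and a staurosporine positive control on Vero, MCF-7, HepG-2 and
#'   A-549 cells.
#' * `mq_hub_centralities()` — the 19 core protein targets retained by the
#'   two-tier hub screen with their betweenness (bc), closeness (cc) and
#'   degree (dc) centralities.
#' * `mq_compound_degrees()` — the 19 oil constituents ranked by degree in
#'   the compound-target bipartite network.
#' * `mq_reference_profile_1991()` — major-constituent area percentages from
#'   a 1991 analysis of the same species in the same region, used as the
#'   historical comparison profile.
#'
#' @return A tibble; see each description for columns.
#' @name mq_data
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phytonet", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname mq_data
#' @export
mq_peak_table <- function() read_extdata("mq_leaf_oil_peaks.csv")

#' @rdname mq_data
#' @export
mq_cytotoxicity <- function() read_extdata("mq_cytotoxicity.csv")

#' @rdname mq_data
#' @export
mq_hub_centralities <- function() read_extdata("mq_hub_centralities.csv")

#' @rdname mq_data
#' @export
mq_compound_degrees <- function() read_extdata("mq_compound_degrees.csv")

#' @rdname mq_data
#' @export
mq_reference_profile_1991 <- function() {
  tibble::tribble(
    ~name,             ~area_pct,
    "1,8-Cineole",     57.2,
    "alpha-Terpineol", 13.2,
    "alpha-Pinene",    6.2
  )
}
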