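#' Hypergeometric over-representation tail probability
#'
#' Probability of observing at least `k` annotated genes when drawing a
#' query of size `n` without replacement from a background of `N` genes of
#' which `K` carry the annotation. The tail is evaluated in log space for
#' numerical stability at extreme enrichments.
#'
#' @param k observed hits in the query (vectorized).
#' @param K annotated genes in the background (term size).
#' @param n query size.
#' @param N background size.
#' @return numeric vector of tail probabilities `P[X >= k]`.
#' @examples
#' hypergeom_p(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_p <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
    any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop_validation("inconsistent hypergeometric counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  pmin(exp(lp), 1)
}

# recycle scalar arguments against the longest one
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == len) a else rep_len(a, len)
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control: with `m` tests and sorted p-values
#' `p_(i)`, the adjusted value is `min over j >= i of p_(j) * m / j`, capped
#' at 1 and returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_validation("`pvals` must be numeric in [0, 1] without NA")
  }
  p.adjust(pvals, method = "BH")
}

validate_catalog <- function(catalog) {
  if (!is.data.frame(catalog) ||
    !all(c("term", "category", "genes") %in% names(catalog))) {
    stop_validation("`catalog` must have columns term, category, genes (list-column)")
  }
  if (!is.list(catalog$genes)) stop_validation("`genes` must be a list-column")
  tibble::as_tibble(catalog)
}

#' Over-representation analysis of a gene set against an annotation catalog
#'
#' For every catalog term sharing at least one gene with the query, computes
#' the hypergeometric tail probability of the overlap and applies
#' Benjamini-Hochberg correction. Adjustment is done within each annotation
#' category separately (the convention of GO/KEGG reporting tools); set
#' `per_category = FALSE` to pool all terms into one family.
#'
#' @param query character vector of query gene symbols (must lie within the
#'   background).
#' @param catalog annotation catalog: tibble with columns `term`, `category`
#'   and list-column `genes` (see [gen_annotations()] and [read_gmt()]).
#' @param background background gene universe; defaults to the union of all
#'   catalog genes. Term genes outside the background are dropped with a
#'   warning.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param per_category adjust within category (default) or pooled.
#' @param ease if `TRUE`, use the conservative EASE variant that discounts
#'   one hit (tail probability of `k - 1`).
#' @return tibble with one row per term with `k >= 1`: `term`, `category`,
#'   `k`, `K`, `n`, `N`, `gene_ratio`, `p`, `p_adj`, `significant`; sorted
#'   by `p_adj` then term.
#' @export
enrich <- function(query, catalog, background = NULL, alpha = 0.05,
                   per_category = TRUE, ease = FALSE) {
  catalog <- validate_catalog(catalog)
  query <- unique(toupper(query))
  genes_by_term <- lapply(catalog$genes, function(g) unique(toupper(g)))
  if (is.null(background)) {
    background <- sort(unique(unlist(genes_by_term, use.names = FALSE)))
  } else {
    background <- unique(toupper(background))
  }
  if (!all(query %in% background)) {
    stop_validation("query genes must be a subset of the background")
  }
  n_outside <- sum(vapply(
    genes_by_term,
    function(g) sum(!(g %in% background)), integer(1)
  ))
  if (n_outside > 0) {
    warn(sprintf("%d term gene(s) outside the background were dropped", n_outside))
    genes_by_term <- lapply(genes_by_term, function(g) g[g %in% background])
  }
  N <- length(background)
  n <- length(query)
  res <- tibble::tibble(
    term = catalog$term,
    category = catalog$category,
    k = vapply(genes_by_term, function(g) length(intersect(g, query)), integer(1)),
    K = lengths(genes_by_term)
  ) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n,
      N = N,
      gene_ratio = .data$k / .data$K,
      p = hypergeom_p(if (ease) pmax(.data$k - 1, 0) else .data$k, .data$K, n, N)
    )
  if (nrow(res) == 0) {
    return(dplyr::mutate(res, p_adj = numeric(0), significant = logical(0)))
  }
  if (per_category) {
    res <- res |>
      dplyr::group_by(.data$category) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
      dplyr::ungroup()
  } else {
    res <- dplyr::mutate(res, p_adj = bh_adjust(.data$p))
  }
  res |>
    dplyr::mutate(significant = .data$p_adj < alpha) |>
    dplyr::arrange(.data$p_adj, .data$term)
}

#' Read / write gene-set catalogs in GMT format
#'
#' GMT is the tab-delimited gene-set exchange format: one set per line as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Reading uses
#' `fgsea::gmtPathways()` for the membership lists; the description field is
#' used to carry the annotation category.
#'
#' @param path file path.
#' @return `read_gmt()`: a catalog tibble (`term`, `category`, `genes`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 2]
  categories <- setNames(
    vapply(fields, `[[`, character(1), 2),
    vapply(fields, `[[`, character(1), 1)
  )
  tibble::tibble(
    term = names(sets),
    category = unname(categories[names(sets)]),
    genes = unname(sets)
  )
}

#' @rdname read_gmt
#' @param catalog catalog tibble with columns `term`, `category`, `genes`.
#' @return `write_gmt()`: `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  lines <- mapply(
    function(term, category, genes) {
      paste(c(term, category, genes), collapse = "\t")
    },
    catalog$term, catalog$category, catalog$genes
  )
  writeLines(unname(lines), path)
  invisible(path)
}
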