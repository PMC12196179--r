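#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be emulated with a known ground
#' truth, so each analysis stage is testable without live databases or
#' instruments. All generators are deterministic given their seed and leave
#' the caller's RNG stream untouched.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Bundles the sizes and noise levels of a full synthetic study; see
#' [simulate_study()]. One root seed fans out to fixed per-generator child
#' seeds, so regenerating one piece never perturbs the others.
#'
#' @param seed root integer seed.
#' @param n_genes gene universe size.
#' @param n_compounds number of compounds.
#' @param n_terms number of random annotation terms.
#' @param noise_sd replicate noise, percent viability.
#' @param replicate_count replicates per concentration.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_genes = 2000, n_compounds = 19,
                              n_terms = 100, noise_sd = 3, replicate_count = 3) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0),
    n_genes = check_count(n_genes, "n_genes"),
    n_compounds = check_count(n_compounds, "n_compounds"),
    n_terms = check_count(n_terms, "n_terms", min = 0),
    noise_sd = noise_sd,
    replicate_count = check_count(replicate_count, "replicate_count")
  )
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(cfg, class = "simulation_config")
}

synthetic_gene_symbols <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free PPI-like network
#'
#' Preferential attachment: `attach_m` initially isolated seed nodes, then
#' each new node attaches to `attach_m` distinct existing nodes chosen with
#' probability proportional to degree + 1 (the +1 lets the isolated seed
#' nodes be chosen, which also makes the graph connected). The construction
#' forces exactly `attach_m * (n_nodes - attach_m)` edges. Each edge carries
#' a confidence score drawn uniformly on \[0.15, 1\].
#'
#' Optionally, `n_hubs` planted mega-hubs are wired to a fraction
#' `hub_frac` of all nodes, providing ground truth for hub-recovery tests;
#' their labels are attached as the `planted_hubs` attribute.
#'
#' @param n_nodes number of nodes (> `attach_m`).
#' @param attach_m edges added per new node (>= 1).
#' @param seed integer seed.
#' @param n_hubs number of planted mega-hubs (default 0).
#' @param hub_frac fraction of all nodes each planted hub connects to
#'   (default 0.25).
#' @return a [ppi_network()] with synthetic gene-symbol labels
#'   (`"G0001"`, ...) and, when hubs are planted, attribute `planted_hubs`.
#' @export
gen_ppi_network <- function(n_nodes, attach_m, seed, n_hubs = 0, hub_frac = 0.25) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  attach_m <- check_count(attach_m, "attach_m")
  if (n_nodes <= attach_m) stop_config("need n_nodes > attach_m")
  labels <- synthetic_gene_symbols(n_nodes)
  with_seed(seed, {
    deg <- integer(n_nodes)
    n_new <- n_nodes - attach_m
    from <- integer(n_new * attach_m)
    to <- integer(n_new * attach_m)
    k <- 0L
    for (v in seq.int(attach_m + 1L, n_nodes)) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing,
        size = attach_m, replace = FALSE,
        prob = deg[existing] + 1
      )
      for (t in targets) {
        k <- k + 1L
        from[k] <- v
        to[k] <- t
        deg[v] <- deg[v] + 1L
        deg[t] <- deg[t] + 1L
      }
    }
    edges <- tibble::tibble(
      from = labels[from], to = labels[to],
      confidence = runif(k, 0.15, 1)
    )
    hubs <- character(0)
    if (n_hubs > 0) {
      # planted hubs attach preferentially, like the growth process itself,
      # so they sit in the dense part of the graph rather than its periphery
      hubs <- sample(labels, n_hubs)
      extra <- lapply(hubs, function(h) {
        others <- which(labels != h)
        n_extra <- max(1L, round(hub_frac * n_nodes))
        tibble::tibble(
          from = h,
          to = labels[sample(others, n_extra, prob = deg[others] + 1)],
          confidence = runif(n_extra, 0.15, 1)
        )
      })
      edges <- dplyr::bind_rows(edges, dplyr::bind_rows(extra))
    }
    net <- ppi_network(edges)
    attr(net, "planted_hubs") <- sort(hubs)
    net
  })
}

#' Generate compound target sets with a planted disease overlap
#'
#' Each compound receives a shared core of genes plus random fill from the
#' universe; the disease gene set is a random subset of the universe forced
#' to contain the core, guaranteeing a non-trivial intersection with the
#' compound target union.
#'
#' @param n_compounds number of compounds.
#' @param universe character vector of gene symbols.
#' @param core_size size of the shared core (<= `per_compound`).
#' @param per_compound targets per compound (<= universe size).
#' @param disease_frac fraction of the universe in the disease set
#'   (0 < frac <= 1).
#' @param seed integer seed.
#' @return list with `targets` (named list per compound), `disease`
#'   (character), and ground truth `core` (character).
#' @export
gen_target_sets <- function(n_compounds, universe, core_size, per_compound,
                            disease_frac, seed) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  universe <- unique(toupper(universe))
  if (core_size > per_compound || per_compound > length(universe)) {
    stop_config("need core_size <= per_compound <= length(universe)")
  }
  if (!is.numeric(disease_frac) || disease_frac <= 0 || disease_frac > 1) {
    stop_config("disease_frac must lie in (0, 1]")
  }
  with_seed(seed, {
    core <- sort(sample(universe, core_size))
    rest <- setdiff(universe, core)
    targets <- lapply(seq_len(n_compounds), function(i) {
      sort(c(core, sample(rest, per_compound - core_size)))
    })
    names(targets) <- sprintf("compound_%02d", seq_len(n_compounds))
    n_disease <- round(disease_frac * length(universe))
    n_disease <- max(n_disease, core_size)
    disease <- sort(unique(c(core, sample(rest, max(0, n_disease - core_size)))))
    list(targets = targets, disease = disease, core = core)
  })
}

#' Generate an annotation catalog with planted enriched terms
#'
#' The catalog contains the planted terms verbatim plus `n_terms` random
#' terms whose sizes are uniform on \[10, 200\] (clamped to the universe).
#' Categories cycle over BP/CC/MF/KEGG. Serializable via [write_gmt()].
#'
#' @param universe character vector of gene symbols.
#' @param n_terms number of random terms.
#' @param planted named list of gene sets to embed verbatim (must be
#'   subsets of the universe).
#' @param seed integer seed.
#' @return catalog tibble (`term`, `category`, `genes`) with attribute
#'   `planted_terms` naming the embedded terms.
#' @export
gen_annotations <- function(universe, n_terms, planted = list(), seed) {
  n_terms <- check_count(n_terms, "n_terms", min = 0)
  universe <- unique(toupper(universe))
  planted <- lapply(planted, toupper)
  outside <- unlist(lapply(planted, setdiff, y = universe), use.names = FALSE)
  if (length(outside) > 0) {
    stop_validation(paste0(
      "planted gene(s) outside the universe: ",
      paste(utils::head(outside, 5), collapse = ", ")
    ))
  }
  if (length(planted) > 0 && is.null(names(planted))) {
    names(planted) <- sprintf("PLANTED%02d", seq_along(planted))
  }
  cats <- c("BP", "CC", "MF", "KEGG")
  with_seed(seed, {
    sizes <- pmin(sample(10:200, n_terms, replace = TRUE), length(universe))
    random_terms <- lapply(sizes, function(s) sort(sample(universe, s)))
    terms <- c(names(planted), sprintf("T%04d", seq_len(n_terms)))
    genes <- c(unname(lapply(planted, sort)), random_terms)
    catalog <- tibble::tibble(
      term = terms,
      category = rep_len(cats, length(terms)),
      genes = genes
    )
    attr(catalog, "planted_terms") <- names(planted)
    catalog
  })
}

#' Default two-fold serial dilution ladder (ug/mL)
#'
#' Nine concentrations from a 100 ug/mL stock by 1:2 serial dilution, the
#' usual MTT design: 100, 50, 25, 12.5, 6.25, 3.13, 1.56, 0.78, 0.39.
#' Values below 25 carry the conventional 2-3 significant-figure rounding
#' of a pipetted dilution series.
#'
#' @return numeric vector of 9 concentrations.
#' @export
serial_dilution_ladder <- function() {
  c(100, 50, 25, 12.5, 6.25, 3.13, 1.56, 0.78, 0.39)
}

#' Generate replicate viability data from a 4PL curve
#'
#' Replicate viabilities are the 4PL mean response plus Gaussian noise,
#' truncated at zero.
#'
#' @param top,bottom asymptotes (percent viability).
#' @param hill hill slope (positive for a decreasing viability curve).
#' @param ic50 midpoint concentration (ug/mL, positive).
#' @param concentrations positive concentration vector (default
#'   [serial_dilution_ladder()]).
#' @param noise_sd replicate noise sd in percent viability.
#' @param reps replicates per concentration.
#' @param seed integer seed.
#' @return tibble (`concentration`, `replicate`, `viability`) with
#'   attribute `truth` (the generating parameters).
#' @export
gen_dose_response <- function(top = 100, bottom = 0, hill = 1, ic50,
                              concentrations = serial_dilution_ladder(),
                              noise_sd = 0, reps = 3, seed = 1) {
  if (ic50 <= 0) stop_config("ic50 must be positive")
  if (any(concentrations <= 0)) stop_config("concentrations must be positive")
  reps <- check_count(reps, "reps")
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      concentration = concentrations,
      replicate = seq_len(reps)
    )
    mu <- fourpl_mean(grid$concentration, top, bottom, hill, ic50)
    out <- dplyr::mutate(
      grid,
      viability = pmax(mu + rnorm(nrow(grid), 0, noise_sd), 0)
    )
    attr(out, "truth") <- list(top = top, bottom = bottom, hill = hill, ic50 = ic50)
    out
  })
}

#' Generate Annexin V / PI flow-cytometry event clouds
#'
#' Events are drawn from four bivariate Gaussian clusters on the log10
#' intensity scale (log-normal in linear intensity), one per quadrant, with
#' centers placed on known sides of the gating thresholds so the generating
#' quadrant weights are recoverable.
#'
#' @param weights length-4 nonnegative vector summing to 1:
#'   (viable, early apoptotic, late apoptotic, necrotic).
#' @param n_events number of events.
#' @param seed integer seed.
#' @param cluster_sd within-cluster sd on the log10 scale (default 0.15).
#' @return list with `events` (tibble `annexin`, `pi`, `quadrant_true`),
#'   `annexin_gate`, `pi_gate` and `weights`.
#' @export
gen_flow_events <- function(weights, n_events, seed, cluster_sd = 0.15) {
  if (length(weights) != 4 || any(weights < 0)) {
    stop_validation("`weights` must be 4 nonnegative fractions")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop_validation("`weights` must sum to 1")
  n_events <- check_count(n_events, "n_events")
  gate <- 2.5
  centers <- list(
    viable = c(1.8, 1.8),
    early_apoptotic = c(3.2, 1.8),
    late_apoptotic = c(3.2, 3.2),
    necrotic = c(1.8, 3.2)
  )
  with_seed(seed, {
    q <- sample(names(centers), n_events, replace = TRUE, prob = weights)
    mu <- do.call(rbind, centers[q])
    events <- tibble::tibble(
      annexin = rnorm(n_events, mu[, 1], cluster_sd),
      pi = rnorm(n_events, mu[, 2], cluster_sd),
      quadrant_true = q
    )
    list(events = events, annexin_gate = gate, pi_gate = gate, weights = weights)
  })
}

#' Generate a temperature-programmed n-alkane retention ladder
#'
#' Strictly increasing retention times with nondecreasing spacing between
#' successive carbon numbers, mimicking elution under a linear oven ramp.
#'
#' @param c_min,c_max carbon-number range (8 <= c_min < c_max <= 28).
#' @param seed integer seed.
#' @return tibble (`carbon`, `rt` in minutes).
#' @export
gen_alkane_ladder <- function(c_min = 8, c_max = 28, seed = 1) {
  if (!(c_min >= 8 && c_min < c_max && c_max <= 28)) {
    stop_config("need 8 <= c_min < c_max <= 28")
  }
  with_seed(seed, {
    k <- c_max - c_min
    spacing <- sort(runif(k, 0.8, 1.8)) # nondecreasing gaps
    rt0 <- runif(1, 2.5, 4)
    tibble::tibble(
      carbon = seq.int(c_min, c_max),
      rt = rt0 + c(0, cumsum(spacing))
    )
  })
}

#' Generate a uniform compound-by-target docking score matrix
#'
#' @param compounds,targets character vectors of names.
#' @param score_range numeric length-2 interval of binding energies in
#'   kcal/mol; both endpoints negative, lower < upper. Default matches the
#'   span typical of small terpenoids against protein targets,
#'   \[-6.9, -4.0\].
#' @param seed integer seed.
#' @return long tibble (`compound`, `target`, `score`).
#' @export
gen_docking_matrix <- function(compounds, targets,
                               score_range = c(-6.9, -4.0), seed = 1) {
  if (length(score_range) != 2 || any(score_range >= 0) ||
    score_range[1] >= score_range[2]) {
    stop_config("`score_range` must be two negative values with lower < upper")
  }
  if (length(compounds) == 0 || length(targets) == 0) {
    stop_config("compounds and targets must be nonempty")
  }
  with_seed(seed, {
    grid <- tidyr::expand_grid(compound = compounds, target = targets)
    dplyr::mutate(grid, score = runif(nrow(grid), score_range[1], score_range[2]))
  })
}

#' Generate a full synthetic study from one configuration
#'
#' Fans the root seed out to fixed per-generator child seeds and produces
#' every input the pipeline consumes: a scale-free confidence-scored PPI
#' network with planted hubs, compound target sets with a planted disease
#' overlap, an annotation catalog with a planted enriched term, replicate
#' dose-response data, apoptosis event clouds, an alkane ladder, and a
#' docking matrix.
#'
#' @param config a [simulation_config()].
#' @return named list of generated pieces, each carrying its own ground
#'   truth.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  s <- function(k) derive_seed(config$seed, k)
  universe <- synthetic_gene_symbols(config$n_genes)
  targets <- gen_target_sets(
    n_compounds = config$n_compounds, universe = universe,
    core_size = 50, per_compound = 80, disease_frac = 0.9, seed = s(2)
  )
  planted_term <- list(PLANTED01 = targets$core[1:20])
  list(
    network = gen_ppi_network(300, 5, seed = s(1), n_hubs = 5),
    targets = targets,
    catalog = gen_annotations(universe, config$n_terms,
      planted = planted_term, seed = s(3)
    ),
    dose_response = gen_dose_response(
      top = 100, bottom = 0, hill = 1.5, ic50 = 18.09,
      noise_sd = config$noise_sd, reps = config$replicate_count, seed = s(4)
    ),
    flow = gen_flow_events(c(0.7239, 0.1502, 0.093, 0.0329), 50000, seed = s(5)),
    ladder = gen_alkane_ladder(8, 28, seed = s(6)),
    docking = gen_docking_matrix(
      sprintf("compound_%02d", seq_len(config$n_compounds)),
      c("ESR1", "CASP3", "PPARG", "PTGS2"),
      seed = s(7)
    )
  )
}
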