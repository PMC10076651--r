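#' Configuration for a full pipeline run
#'
#' Collects every stage parameter (with its seed) so a run is reproducible
#' from the config alone. Either `input` (a response matrix or CSV path) or
#' `generator` (a [generator_config()]) must be supplied.
#'
#' @param input item response matrix, or path to a response CSV.
#' @param generator optional [generator_config()] used when `input` is NULL.
#' @param out_dir directory for artifacts.
#' @param gamma EBIC hyperparameter.
#' @param redundancy_threshold,redundancy_alpha redundancy-screen settings.
#' @param run_stability,run_nct stage toggles for the expensive stages.
#' @param nboot_edges,nboot_cs bootstrap sizes.
#' @param n_perm NCT permutations.
#' @param group optional two-level grouping vector (or column name when the
#'   input CSV carries a grouping column) enabling the NCT stage.
#' @param seed master seed; stage seeds are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            out_dir = tempfile("symptomnet_run_"),
                            gamma = 0.5,
                            redundancy_threshold = 0.25,
                            redundancy_alpha = 0.05,
                            run_stability = FALSE, run_nct = FALSE,
                            nboot_edges = 1000, nboot_cs = 2000,
                            n_perm = 1000, group = NULL, seed = 1L) {
  if (is.null(input) && is.null(generator)) {
    stop("either input data or a generator config is required")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 9973L) %% 2147483647L

#' Run the full symptom-network pipeline
#'
#' Executes preprocess (nonparanormal transform + redundancy screen),
#' network estimation, Walktrap communities, centrality, and optionally the
#' stability bootstraps and the network comparison test; writes diff-able
#' artifacts (weight matrix CSV, edge-list CSV, centrality CSV, JSON for
#' nested results) plus a run manifest with parameters, seeds and summary
#' counts.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- config$input
  truth <- NULL
  if (is.null(x)) {
    sim <- simulate_survey(config$generator)
    x <- sim$responses
    truth <- sim$truth
    write_survey(sim, file.path(config$out_dir, "responses.csv"),
                 file.path(config$out_dir, "truth.json"))
  } else if (is.character(x)) {
    x <- read_responses(x)
  }
  x <- as.matrix(x)
  p <- ncol(x)

  z <- npn_transform(x)
  redundancy <- find_redundant_pairs(x, threshold = config$redundancy_threshold,
                                     alpha = config$redundancy_alpha)
  model <- {
    S <- item_correlations(z)
    ebic_glasso(S, gamma = config$gamma, labels = colnames(x))
  }
  communities <- walktrap_communities(model)
  centrality <- centrality_table(model, z, communities = communities)

  utils::write.csv(as.data.frame(model$weights),
                   file.path(config$out_dir, "weights.csv"))
  utils::write.csv(edge_list(model),
                   file.path(config$out_dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(centrality,
                   file.path(config$out_dir, "centrality.csv"), row.names = FALSE)

  stability <- NULL
  if (isTRUE(config$run_stability)) {
    boot <- bootstrap_edges(x, nboot = config$nboot_edges,
                            seed = stage_seed(config$seed, 2L),
                            gamma = config$gamma)
    cs_ei <- case_dropping_cs(x, "ei", nboot = config$nboot_cs,
                              seed = stage_seed(config$seed, 3L),
                              gamma = config$gamma)
    cs_bei <- case_dropping_cs(x, "bei", nboot = config$nboot_cs,
                               seed = stage_seed(config$seed, 4L),
                               gamma = config$gamma)
    stability <- list(bootstrap = boot, cs_ei = cs_ei, cs_bei = cs_bei)
    jsonlite::write_json(list(
      edges = boot$edges,
      cs = list(ei = cs_ei$cs_coefficient, bei = cs_bei$cs_coefficient),
      nboot = list(edges = boot$nboot, cs = config$nboot_cs)
    ), file.path(config$out_dir, "stability.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }

  nct <- NULL
  if (isTRUE(config$run_nct)) {
    if (is.null(config$group)) stop("NCT stage requires a grouping vector")
    nct <- compare_by_group(x, config$group, n_perm = config$n_perm,
                            seed = stage_seed(config$seed, 5L),
                            gamma = config$gamma)
    jsonlite::write_json(list(
      m_statistic = nct$m_statistic, s_statistic = nct$s_statistic,
      global_strength = as.list(nct$global_strength),
      p_value_m = nct$p_value_m, p_value_s = nct$p_value_s,
      n_permutations = nct$n_permutations
    ), file.path(config$out_dir, "nct.json"), digits = NA, auto_unbox = TRUE)
  }

  nonzero <- sum(model$weights[upper.tri(model$weights)] != 0)
  potential <- p * (p - 1) / 2
  manifest <- list(
    package_version = as.character(utils::packageVersion("symptomnet")),
    seed = config$seed,
    parameters = list(gamma = config$gamma,
                      redundancy_threshold = config$redundancy_threshold,
                      redundancy_alpha = config$redundancy_alpha,
                      nboot_edges = config$nboot_edges,
                      nboot_cs = config$nboot_cs, n_perm = config$n_perm),
    n_respondents = nrow(x),
    nodes = p,
    potential_edges = potential,
    nonzero_edges = nonzero,
    edge_density = round(nonzero / potential, 4),
    n_communities = communities$n_communities,
    lambda_selected = model$lambda_selected,
    redundant_pairs_flagged = sum(redundancy$redundant)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(responses = x, truth = truth, transformed = z,
                 redundancy = redundancy, model = model,
                 communities = communities, centrality = centrality,
                 stability = stability, nct = nct, manifest = manifest))
}
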