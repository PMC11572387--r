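## One-call orchestration of the full workflow: parsimony (EW + IW),
## non-clock Bayesian inference, clock-prior derivation, tip-dated clock
## runs, rogue detection, common pruning, consensus/MCC summaries,
## stratigraphic congruence and ancestral-state reconstruction.

#' Default run configuration
#'
#' @param matrix_path,ages_path input file paths (NEXUS matrix, CSV ages);
#'   alternatively supply parsed objects to \code{\link{run_full}}.
#' @param outgroup outgroup taxa (ingroup = the rest, constrained
#'   monophyletic in clock runs).
#' @param extra_prune taxa always pruned from final summaries (e.g. extant
#'   taxa whose position is not interpretable).
#' @param k implied-weights concavity.
#' @param n_starts addition-sequence replicates per parsimony search.
#' @param bootstrap bootstrap replicates (0 = skip).
#' @param rho extant sampling probability.
#' @param clocks clock models to run.
#' @param strategies FBD sampling strategies to run.
#' @param generations,sample_every MCMC size per clock run.
#' @param nonclock_generations MCMC size of the non-clock stage (branch
#'   lengths via strict-clock parameterization; used only to derive the
#'   clock-rate prior's tree-length scale).
#' @param permutations stratigraphic permutation count.
#' @param n_maps stochastic maps per character.
#' @param asr_characters characters to map (default: all).
#' @param seed master seed.
#' @return a named list of settings for \code{\link{run_full}}.
#' @export
run_config <- function(matrix_path = NULL, ages_path = NULL,
                       outgroup = NULL, extra_prune = character(0),
                       k = 12, n_starts = 10, bootstrap = 0,
                       rho = 2 / 18,
                       clocks = c("igr", "tk02"),
                       strategies = c("fossiltip", "random"),
                       generations = 20000, sample_every = 50,
                       nonclock_generations = 5000,
                       permutations = 500, n_maps = 200,
                       asr_characters = NULL, seed = 1) {
  as.list(environment())
}

#' Run the full analysis pipeline
#'
#' Executes, in order: MP-EW and MP-IW searches (+ optional bootstrap), a
#' non-clock Bayesian stage whose posterior tree lengths set the clock-rate
#' prior, the requested clock-model x sampling-strategy tip-dating runs,
#' stepping-stone-free model comparison via their sampled likelihoods is
#' left to \code{\link{stepping_stone_tip_dating}}, rogue detection on the
#' pooled clock posteriors, common pruning of all tree sets (rogues + preset
#' extra taxa), consensus and MCC summaries, stratigraphic congruence of the
#' pruned parsimony consensus trees, and ancestral-state reconstruction
#' (parsimony mapping on the pruned IW consensus; stochastic mapping on the
#' pruned IGR MCC tree).
#'
#' @param config from \code{\link{run_config}}.
#' @param matrix optional parsed \code{char_matrix} (else read from
#'   \code{config$matrix_path}).
#' @param ages optional parsed \code{tip_ages}.
#' @param out_dir if non-NULL, artifacts are written there (NEXUS trees,
#'   CSV traces, JSON summary).
#' @return list of stage results with a machine-readable \code{summary}.
#' @export
run_full <- function(config, matrix = NULL, ages = NULL, out_dir = NULL) {
  set.seed(config$seed)
  if (is.null(matrix)) matrix <- parse_nexus(config$matrix_path)
  if (is.null(ages)) ages <- parse_tip_ages(config$ages_path, matrix)
  ingroup <- setdiff(matrix$taxa, config$outgroup)
  stages <- list()

  ## -- maximum parsimony ----------------------------------------------------
  stages$mp_ew <- parsimony_search(matrix, "ew", n_starts = config$n_starts,
                                   seed = config$seed)
  stages$mp_iw <- parsimony_search(matrix, "iw", k = config$k,
                                   n_starts = config$n_starts,
                                   seed = config$seed + 1)
  if (config$bootstrap > 0) {
    stages$bootstrap_ew <- bootstrap_support(matrix, B = config$bootstrap,
                                             criterion = "ew",
                                             seed = config$seed + 2)
  }

  ## -- non-clock stage: tree-length scale for the clock prior ---------------
  root_prior <- offset_exp_prior(max(ages$max_ma) + 0.01,
                                 max(ages$max_ma) + 0.01 + 8.2)
  nonclock <- run_tip_dating(
    matrix, ages, clock = "strict", strategy = "fossiltip",
    rho = config$rho, clock_prior = list(mean_log = log(0.1), sd_log = 1),
    root_prior = root_prior, ingroup = ingroup,
    generations = config$nonclock_generations,
    sample_every = config$sample_every, seed = config$seed + 3)
  stages$nonclock <- nonclock
  stages$clock_prior <- derive_clock_prior(nonclock$params$tree_length,
                                           root_prior_median = root_prior$median)

  ## -- tip-dated clock runs -------------------------------------------------
  stages$clock <- list()
  i <- 0
  for (cl in config$clocks) for (strat in config$strategies) {
    i <- i + 1
    key <- paste(cl, strat, sep = "_")
    stages$clock[[key]] <- run_tip_dating(
      matrix, ages, clock = cl, strategy = strat, rho = config$rho,
      clock_prior = stages$clock_prior[c("mean_log", "sd_log")],
      root_prior = root_prior, ingroup = ingroup,
      generations = config$generations,
      sample_every = config$sample_every, seed = config$seed + 10 + i)
  }

  ## -- rogue detection on pooled clock posteriors ---------------------------
  pooled <- do.call(c, lapply(unname(stages$clock), function(x)
    unclass(x$trees)))
  class(pooled) <- "multiPhylo"
  rogues <- detect_rogues(pooled)
  stages$rogues <- rogues
  drop <- union(rogues$taxon, config$extra_prune)
  drop <- intersect(drop, matrix$taxa)
  keep_n <- matrix$n_taxa - length(drop)
  if (keep_n < 4) drop <- character(0)
  stages$pruned_taxa <- drop

  ## -- pruned summaries -----------------------------------------------------
  restricted <- if (length(drop))
    subset_matrix(matrix, setdiff(matrix$taxa, drop)) else matrix
  prune_or_keep <- function(trs) if (length(drop))
    prune_sample(trs, drop) else as_multiphylo(trs)
  ew_pruned <- prune_or_keep(stages$mp_ew$trees)
  iw_pruned <- prune_or_keep(stages$mp_iw$trees)
  stages$consensus_ew <- majority_consensus(ew_pruned)
  stages$consensus_iw <- majority_consensus(iw_pruned)
  stages$consensus_ew_score <- tree_length(stages$consensus_ew, restricted)
  stages$consensus_iw_score <- tree_length(stages$consensus_iw, restricted)
  stages$mcc <- lapply(stages$clock, function(x)
    mcc_tree(prune_or_keep(x$trees)))

  ## -- stratigraphic congruence ---------------------------------------------
  ages_r <- ages[ages$taxon %in% restricted$taxa, , drop = FALSE]
  stages$strat <- list(
    ew = strat_indices(ape::multi2di(stages$consensus_ew), ages_r,
                       permutations = config$permutations,
                       seed = config$seed + 30),
    iw = strat_indices(ape::multi2di(stages$consensus_iw), ages_r,
                       permutations = config$permutations,
                       seed = config$seed + 31))

  ## -- ancestral states ------------------------------------------------------
  chars <- config$asr_characters
  if (is.null(chars)) chars <- seq_len(matrix$n_char)
  stages$asr_parsimony <- parsimony_map(stages$consensus_iw, restricted,
                                        characters = chars)
  igr_key <- grep("^igr", names(stages$mcc), value = TRUE)[1]
  if (!is.na(igr_key)) {
    mcc_tr <- stages$mcc[[igr_key]]$tree
    simmap_chars <- chars[seq_len(min(length(chars), 25L))]
    stages$asr_simmap <- lapply(simmap_chars, function(j)
      stochastic_map(mcc_tr, restricted, j, n_maps = config$n_maps,
                     seed = config$seed + 40 + j))
    names(stages$asr_simmap) <- simmap_chars
  }

  stages$summary <- pipeline_summary(stages, config)
  if (!is.null(out_dir)) write_pipeline_outputs(stages, config, out_dir)
  stages
}

pipeline_summary <- function(stages, config) {
  cl_sum <- lapply(names(stages$clock), function(k) {
    x <- stages$clock[[k]]
    list(model = k,
         root_age_median = stats::median(x$params$root_age),
         root_age_hpd = hpd_interval(x$params$root_age),
         clock_rate_median = stats::median(x$params$clock_rate),
         low_ess = x$low_ess)
  })
  list(
    seed = config$seed,
    mp_ew = list(steps = stages$mp_ew$score$total,
                 ci = stages$mp_ew$score$ci, ri = stages$mp_ew$score$ri,
                 n_trees = length(stages$mp_ew$trees)),
    mp_iw = list(steps = stages$mp_iw$score$total,
                 ci = stages$mp_iw$score$ci, ri = stages$mp_iw$score$ri,
                 fit = implied_fit(stages$mp_iw$score, config$k),
                 n_trees = length(stages$mp_iw$trees)),
    clock_prior = stages$clock_prior[c("rate", "mean_log", "sd_log")],
    clock_models = cl_sum,
    rogues = stages$rogues$taxon,
    pruned = stages$pruned_taxa,
    consensus_ew_steps = stages$consensus_ew_score$total,
    consensus_iw_steps = stages$consensus_iw_score$total,
    strat = lapply(stages$strat, function(s)
      list(rci = s$rci, ger = s$ger, msm = s$msm,
           p = as.list(s$p_values))))
}

write_pipeline_outputs <- function(stages, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.nexus(stages$mp_ew$trees,
                   file = file.path(out_dir, "mp_ew_trees.nex"))
  ape::write.nexus(stages$mp_iw$trees,
                   file = file.path(out_dir, "mp_iw_trees.nex"))
  ape::write.nexus(stages$consensus_ew,
                   file = file.path(out_dir, "consensus_ew.nex"))
  ape::write.nexus(stages$consensus_iw,
                   file = file.path(out_dir, "consensus_iw.nex"))
  for (k in names(stages$clock)) {
    ape::write.nexus(stages$clock[[k]]$trees,
                     file = file.path(out_dir, paste0("posterior_", k, ".nex")))
    utils::write.csv(stages$clock[[k]]$params,
                     file.path(out_dir, paste0("trace_", k, ".csv")),
                     row.names = FALSE)
    ape::write.nexus(stages$mcc[[k]]$tree,
                     file = file.path(out_dir, paste0("mcc_", k, ".nex")))
  }
  jsonlite::write_json(stages$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
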