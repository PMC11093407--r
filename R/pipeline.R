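pipeline_defaults <- function() {
  list(
    seed = 1L,
    tasks = c("magnitude", "probability"),
    n_sequences = list(magnitude = 100L, probability = 150L),
    n_agents = 96L,
    n_sessions = list(magnitude = 10L, probability = 15L),
    report_noise_sd = 0.05,
    window = c(-2L, 8L),
    n_permutations = 10000L,
    n_boot = 10000L,
    n_bins = 6L,
    spearman_check = TRUE
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("stage config: reading YAML configs requires the yaml package",
             call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  out <- utils::modifyList(defaults, config)
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full generate-simulate-analyze pipeline
#'
#' Chains every stage of the toolkit per task: sequence generation with the
#' task's generative parameters, the normative observer on every sequence, a
#' noiseless normative cohort (used for the learning-rate dynamics, the
#' two-determinant regression and the determinant-correlation check) and a
#' report-noise cohort (used for estimate accuracy and the bias/variance
#' decomposition), then writes all intermediate tables as CSV and a summary
#' as JSON. Everything is deterministic under the master seed; two runs with
#' the same config and seed produce byte-identical outputs.
#'
#' @param config A named list, or the path of a YAML/JSON file, overriding
#'   the defaults: `seed`, `tasks`, `n_sequences`, `n_agents`, `n_sessions`,
#'   `report_noise_sd`, `window`, `n_permutations`, `n_boot`, `n_bins`,
#'   `spearman_check`.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; also written to
#'   `file.path(out_dir, "summary.json")`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("adaptrate_run")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 4L * length(cfg$tasks))
  summary <- list(seed = cfg$seed, tasks = as.list(cfg$tasks))
  for (ti in seq_along(cfg$tasks)) {
    task <- cfg$tasks[[ti]]
    s <- seeds[(ti - 1L) * 4L + 1:4]
    gen_cfg <- if (task == "magnitude") magnitude_config() else probability_config()
    seqs <- stage("generate", generate_sequence_set(
      gen_cfg, cfg$n_sequences[[task]], seed = s[1]))
    write_sequences(seqs, file.path(out_dir, paste0("sequences_", task, ".csv")))

    norm <- stage("normative", lapply(seqs, normative_fit))
    utils::write.csv(traces_table(norm),
                     file.path(out_dir, paste0("traces_", task, ".csv")),
                     row.names = FALSE)

    n_sessions <- cfg$n_sessions[[task]]
    cohort_norm <- stage("simulate", simulate_cohort(
      seqs, cfg$n_agents, agent_config("normative"), n_sessions, seed = s[2]))
    cohort_noise <- stage("simulate", simulate_cohort(
      seqs, cfg$n_agents, agent_config("report_noise",
                                       noise_sd = cfg$report_noise_sd),
      n_sessions, seed = s[3]))
    write_sessions(sessions_table(cohort_noise, seqs),
                   file.path(out_dir, paste0("sessions_", task, ".csv")))

    seq_map <- stats::setNames(seqs, vapply(seqs, `[[`, "", "sequence_id"))
    series <- stage("dynamics", lapply(cohort_norm, function(tr) {
      compute_learning_rates(tr, seq_map[[tr$sequence_id]])
    }))
    dyn <- stage("dynamics", align_to_changepoints(series, cfg$window))
    clus <- stage("dynamics", cluster_permutation_test(
      dyn, n_permutations = cfg$n_permutations, seed = s[4]))
    utils::write.csv(
      data.frame(offset = dyn$offsets, mean = dyn$mean_curve,
                 sem = dyn$sem_curve, baseline = dyn$baseline),
      file.path(out_dir, paste0("dynamics_", task, ".csv")),
      row.names = FALSE)
    utils::write.csv(clus$clusters,
                     file.path(out_dir, paste0("clusters_", task, ".csv")),
                     row.names = FALSE)

    weights <- stage("determinants",
                     determinant_weights_by_subject(series, norm))
    tests <- stage("determinants", group_level_tests(weights))
    utils::write.csv(weights,
                     file.path(out_dir, paste0("weights_", task, ".csv")),
                     row.names = FALSE)

    acc <- stage("accuracy", estimate_accuracy(cohort_noise, norm, cfg$n_bins))
    dec <- stage("decompose", bootstrap_se(
      decompose_mse(cohort_noise, norm), n_boot = cfg$n_boot, seed = s[4]))
    utils::write.csv(dec$per_cell,
                     file.path(out_dir, paste0("decomposition_", task, ".csv")),
                     row.names = FALSE)

    task_summary <- list(
      n_sequences = length(seqs),
      n_agents = cfg$n_agents,
      mean_w_omega = tests$w_omega$mean,
      mean_w_u = tests$w_u$mean,
      paired_t = tests$paired$t,
      paired_p = tests$paired$p,
      peak_offset = dyn$offsets[which.max(dyn$mean_curve)],
      baseline = dyn$baseline,
      significant_clusters = nrow(clus$clusters[clus$clusters$significant, ]),
      accuracy_r_mean = acc$r_mean,
      bias_pct = dec$proportions[["sbe_pct"]],
      variance_pct = dec$proportions[["var_pct"]],
      bias_pct_se = dec$se[["sbe_pct"]],
      variance_pct_se = dec$se[["var_pct"]]
    )
    if (isTRUE(cfg$spearman_check)) {
      task_summary$spearman_omega_pe <-
        stage("spearman", measure_determinant_correlation(norm, seqs))
    }
    summary[[task]] <- task_summary
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
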