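#' Pipeline run configuration
#'
#' Assembles the options of a full end-to-end run: cohort source, K scan,
#' surrogate and energy arms, seeds and output directory. The cohort is
#' either a [synthetic_config()] (generated on the fly) or a directory
#' written by [write_cohort()].
#'
#' @param cohort a [synthetic_config()] or a directory path.
#' @param out_dir output directory.
#' @param k fixed number of states; if `NULL`, `k_range` is scanned and
#'   [select_k()] decides.
#' @param k_range contiguous k values scanned when `k` is `NULL`.
#' @param n_restarts k-medoids restarts per k.
#' @param n_surrogates surrogate cohorts for the null arm; 0 disables it.
#' @param run_energy logical; run the control-energy arm (skipped with a
#'   notice when no connectomes are available).
#' @param normalize transition-probability normalization, see
#'   [transition_probabilities()].
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, out_dir, k = 4L, k_range = 2:8,
                            n_restarts = 10L, n_surrogates = 0L,
                            run_energy = TRUE, normalize = "joint",
                            seed = 1L) {
  structure(list(cohort = cohort, out_dir = out_dir, k = k, k_range = k_range,
                 n_restarts = as.integer(n_restarts),
                 n_surrogates = as.integer(n_surrogates),
                 run_energy = isTRUE(run_energy), normalize = normalize,
                 seed = as.integer(seed)), class = "pipeline_config")
}

load_cohort_dir <- function(dir, tr_seconds = NULL) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  parc_df <- utils::read.csv(file.path(dir, "parcellation.csv"),
                             stringsAsFactors = FALSE)
  parc <- parcellation_table(parc_df$roi_label, parc_df$network)
  gt_path <- file.path(dir, "ground_truth.json")
  tr <- tr_seconds
  if (is.null(tr) && file.exists(gt_path)) {
    tr <- jsonlite::read_json(gt_path)$tr_seconds
  }
  if (is.null(tr)) stop("tr_seconds not given and no ground_truth.json in ", dir)
  ts <- lapply(clin$subject, function(id) {
    regional_time_series(id,
                         read_matrix(file.path(dir, paste0(id, "_bold.tsv")),
                                     kind = "bold"),
                         tr, roi_labels = parc$roi_label)
  })
  conns <- list()
  for (id in clin$subject) {
    p <- file.path(dir, paste0(id, "_connectome.tsv"))
    if (file.exists(p)) {
      conns[[id]] <- connectome(id, read_matrix(p, kind = "connectome"),
                                roi_labels = parc$roi_label)
    }
  }
  list(time_series = ts, connectomes = conns, clinical = clin,
       parcellation = parc, ground_truth = NULL)
}

#' Run the full co-activation pattern pipeline
#'
#' Executes, in dependency order: cohort generation or loading,
#' normalization and concatenation, k-medoids clustering (with the K scan
#' and [select_k()] when no fixed `k` is given), per-subject temporal
#' dynamics, the phase-randomized null comparison (optional), connectome
#' control energies (optional, skipped with a notice when connectomes are
#' missing), and HC-versus-MDD group tests. Every stage writes its outputs
#' under `config$out_dir` and the run is summarized in a JSON manifest with
#' the config snapshot, stage seeds, and MD5 digests of every output file.
#' Re-running with an identical config reproduces identical digests.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly, with attribute `results` holding the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(cohort = config$seed, cluster = config$seed + 1L,
                null = config$seed + 2L, permutation = config$seed + 3L)
  # --- stage: cohort -------------------------------------------------------
  cohort <- if (inherits(config$cohort, "synthetic_config")) {
    generate_cohort(config$cohort)
  } else {
    load_cohort_dir(config$cohort)
  }
  ts_norm <- lapply(cohort$time_series, normalize_subject)
  dataset <- concatenate_cohort(ts_norm)
  # --- stage: clustering ---------------------------------------------------
  report <- NULL
  if (is.null(config$k)) {
    report <- k_selection_report(dataset, k_range = config$k_range,
                                 n_restarts = config$n_restarts,
                                 seed = seeds$cluster)
    k <- select_k(report)
    solution <- attr(report, "solutions")[[paste0("k", k)]]
    utils::write.csv(as.data.frame(report), file.path(out, "k_selection.csv"),
                     row.names = FALSE)
  } else {
    k <- as.integer(config$k)
    solution <- kmedoids(dataset, k, n_restarts = config$n_restarts,
                         seed = seeds$cluster)
  }
  utils::write.table(
    data.frame(frame = seq_along(solution$labels),
               subject = dataset$frame_subject_index,
               state = solution$labels),
    file.path(out, "frame_labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  write_matrix(solution$mean_centroids, file.path(out, "centroids.tsv"))
  radar <- do.call(rbind, lapply(seq_len(k), function(s) {
    m <- map_state_to_networks(solution$mean_centroids[s, ],
                               cohort$parcellation)
    cbind(state = s, m)
  }))
  utils::write.csv(radar, file.path(out, "state_network_profiles.csv"),
                   row.names = FALSE)
  # --- stage: dynamics -----------------------------------------------------
  sequences <- split_state_sequences(solution, dataset)
  dyn <- cohort_dynamics(sequences, normalize = config$normalize)
  utils::write.csv(dyn, file.path(out, "dynamics.csv"), row.names = FALSE)
  # --- stage: null comparison ---------------------------------------------
  null_cmp <- NULL
  if (config$n_surrogates >= 2L) {
    null_cmp <- compare_cluster_quality(ts_norm, config$n_surrogates, k,
                                        seed = seeds$null,
                                        n_restarts = config$n_restarts)
    utils::write.csv(
      data.frame(quantity = c("delta_silhouette", "p_silhouette",
                              "real_silhouette"),
                 value = c(null_cmp$delta_silhouette, null_cmp$p_silhouette,
                           null_cmp$real_silhouette)),
      file.path(out, "null_comparison.csv"), row.names = FALSE)
  }
  # --- stage: control energies --------------------------------------------
  energies <- NULL
  landscape <- NULL
  if (config$run_energy && length(cohort$connectomes) > 0L) {
    energies <- lapply(cohort$connectomes, function(cn) {
      transition_energy_matrix(cn, solution$mean_centroids)
    })
    etab <- do.call(rbind, lapply(names(energies), function(id) {
      e <- energies[[id]]$total
      data.frame(subject = id,
                 from_state = rep(seq_len(k), k),
                 to_state = rep(seq_len(k), each = k),
                 total_energy = as.numeric(e))
    }))
    utils::write.csv(etab, file.path(out, "transition_energies.csv"),
                     row.names = FALSE)
    landscape <- do.call(rbind, lapply(names(energies), function(id) {
      cbind(subject = id, as.data.frame(exit_enter_energies(energies[[id]])))
    }))
    utils::write.csv(landscape, file.path(out, "energy_landscape.csv"),
                     row.names = FALSE)
  } else if (config$run_energy) {
    message("run_pipeline: no connectomes available; energy stage skipped")
  }
  # --- stage: group inference ---------------------------------------------
  tests <- compare_groups(dyn, cohort$clinical)
  utils::write.csv(tests, file.path(out, "group_tests.csv"), row.names = FALSE)
  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out), "manifest.json"))
  digests <- as.list(tools::md5sum(file.path(out, files)))
  names(digests) <- files
  manifest <- list(
    tool = "capdyn",
    version = as.character(utils::packageVersion("capdyn")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stage_seeds = seeds,
    k = k,
    config = config[setdiff(names(config), "cohort")],
    cohort_source = if (inherits(config$cohort, "synthetic_config"))
      "synthetic" else config$cohort,
    output_digests = digests)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(cohort = cohort, dataset = dataset, solution = solution,
              report = report, sequences = sequences, dynamics = dyn,
              null_comparison = null_cmp, energies = energies,
              landscape = landscape, group_tests = tests)
  attr(manifest, "results") <- res
  invisible(manifest)
}
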