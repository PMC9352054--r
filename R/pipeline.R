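#' Run the full analysis pipeline
#'
#' Orchestrates the stages -- input (manifest or simulation), posture
#' features, eigenposture basis, motif mining, HMM state segmentation,
#' behavioral-space mapping, and usage statistics -- from a single
#' declarative configuration, writing per-stage CSV/JSON outputs and a
#' provenance record into the run directory. Reruns with an identical
#' configuration and inputs are deterministic: every random stage receives
#' a sub-seed derived from the global seed.
#'
#' @param config configuration list, or the path to a YAML file holding
#'   one. Keys: `seed`, `output_dir`, `input` (either
#'   `list(manifest = <path>)` or `list(simulate = list(...))` with
#'   arguments for [simulate_dataset()]), `stages` (character subset of
#'   `c("features", "eigen", "motifs", "hmm", "map", "stats")`), and
#'   optional per-stage parameter lists `motifs`, `hmm`, `map`, `filter`
#'   (see the pipeline vignette for the key schema).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% stop_domain("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("features", "eigen", "motifs", "hmm", "map",
                                 "stats")
  results <- list()

  ## ---- input --------------------------------------------------------
  ds <- if (!is.null(config$input$manifest)) {
    read_manifest(config$input$manifest)
  } else if (!is.null(config$input$simulate)) {
    sim_args <- config$input$simulate
    sim_args$seed <- sim_args$seed %||% (seed + 17L)
    if (!is.null(sim_args$base_config) && is.list(sim_args$base_config) &&
        !inherits(sim_args$base_config, "swim_sim_config"))
      sim_args$base_config <- do.call(swim_sim_config, sim_args$base_config)
    sim_args$n_per_condition <- unlist(sim_args$n_per_condition)
    do.call(simulate_dataset, sim_args)
  } else stop_domain("config$input must provide a manifest or simulate block")
  min_valid <- config$filter$min_valid_fraction %||% 0.8
  ds_fit <- filter_recordings(ds, min_valid)
  results$dataset <- ds

  need <- function(stage, dep) {
    if (!dep %in% stages)
      stop_domain("stage '", stage, "' needs upstream stage '", dep,
                  "' which is toggled off")
  }

  ## ---- features -----------------------------------------------------
  if ("features" %in% stages) {
    parts <- lapply(ds$recordings, recording_partition)
    curvs <- lapply(ds$recordings, skeleton_curvature)
    results$partitions <- parts
    results$curvatures <- curvs
  }

  ## ---- eigenposture --------------------------------------------------
  if ("eigen" %in% stages) {
    need("eigen", "features")
    train_ids <- vapply(ds_fit$recordings, function(r) r$animal_id, character(1))
    ids <- vapply(ds$recordings, function(r) r$animal_id, character(1))
    train_curv <- results$curvatures[ids %in% train_ids]
    basis <- eigencionas(train_curv, k = 6)
    write_eigencionas(basis, file.path(out_dir, "eigencionas.csv"))
    results$basis <- basis
    results$panels <- lapply(seq_along(ds$recordings), function(i)
      feature_panel(ds$recordings[[i]], basis = basis,
                    partition = results$partitions[[i]],
                    curv = results$curvatures[[i]]))
    names(results$panels) <- ids
    panel_out <- do.call(rbind, lapply(ids, function(id)
      cbind(recording = id, results$panels[[id]])))
    write.csv(panel_out, file.path(out_dir, "feature_panel.csv"),
              row.names = FALSE)
  }

  ## ---- motifs --------------------------------------------------------
  if ("motifs" %in% stages) {
    need("motifs", "eigen")
    mp <- config$motifs %||% list()
    m <- mp$window %||% 30L
    segc <- lapply(seq_along(ds$recordings), function(i)
      segment_curvature(results$curvatures[[i]], results$partitions[[i]]))
    names(segc) <- names(results$panels)
    conds <- setNames(dataset_conditions(ds), names(segc))
    motifs <- motif_catalog(segc, m = m, threshold = mp$threshold %||% 8,
                            conditions = conds)
    results$motifs <- motifs
    if (length(motifs$data) >= (mp$k %||% 15L)) {
      model <- cluster_motifs(motifs, k = mp$k %||% 15L, seed = seed + 23L)
      usage <- motif_usage(motifs, model, ds$control_map)
      write.csv(cbind(motifs$info, cluster = model$labels),
                file.path(out_dir, "motif_catalog.csv"), row.names = FALSE)
      write.csv(usage$usage, file.path(out_dir, "motif_usage_pct.csv"))
      write.csv(usage$fold_change, file.path(out_dir, "motif_fold_change.csv"))
      results$motif_model <- model
      results$motif_usage <- usage
    }
  }

  ## ---- hmm -----------------------------------------------------------
  if ("hmm" %in% stages) {
    need("hmm", "eigen")
    hp <- config$hmm %||% list()
    feat_cols <- c(paste0("EC", 1:6), "quirkiness")
    fit_ids <- vapply(ds_fit$recordings, function(r) r$animal_id, character(1))
    seqs <- unlist(lapply(fit_ids, function(id)
      split_valid_segments(as.matrix(results$panels[[id]][feat_cols]))$segments),
      recursive = FALSE)
    seqs <- seqs[vapply(seqs, nrow, integer(1)) >= (hp$n_states %||% 10L)]
    model <- fit_ghmm(seqs, n_states = hp$n_states %||% 10L,
                      covariance_type = hp$covariance_type %||% "full",
                      seed = seed + 31L,
                      max_iter = hp$max_iter %||% 200)
    decoded <- lapply(results$panels, function(p)
      decode_recording(model, as.matrix(p[feat_cols])))
    usage <- state_usage(rep(dataset_conditions(ds),
                             vapply(decoded, length, integer(1))),
                         unlist(decoded), model$n_states, ds$control_map)
    trans <- empirical_transitions(decoded, model$n_states)
    jsonlite::write_json(list(init = model$init, trans = model$trans,
                              means = model$means,
                              covariance_type = model$covariance_type,
                              loglik = tail(model$loglik_trace, 1),
                              seed = model$seed),
                         file.path(out_dir, "ghmm_model.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    write.csv(usage$usage, file.path(out_dir, "state_usage_pct.csv"))
    write.csv(trans$trans, file.path(out_dir, "state_transitions.csv"))
    results$hmm <- model
    results$decoded <- decoded
    results$state_usage <- usage
    results$transitions <- trans
  }

  ## ---- behavior map ---------------------------------------------------
  if ("map" %in% stages) {
    need("map", "eigen")
    mp <- config$map %||% list()
    ec_cols <- paste0("EC", 1:6)
    wl <- list(); sp <- list()
    for (id in names(results$panels)) {
      p <- results$panels[[id]]
      segs <- split_valid_segments(as.matrix(p[ec_cols]), min_length = 64L)
      for (i in seq_along(segs$segments)) {
        wl[[length(wl) + 1L]] <- wavelet_features(segs$segments[[i]],
                                                  fps = ds$recordings[[id]]$fps)
        sp[[length(sp) + 1L]] <-
          as.matrix(p[segs$rows[[i]], paste0("s", SEGMENT_CODES[-1])])
      }
    }
    W <- do.call(rbind, wl); S <- do.call(rbind, sp)
    n_sample <- min(mp$n_sample %||% 20000L, nrow(W))
    draw <- speed_weighted_sample(S, n = n_sample, seed = seed + 41L)
    emb <- fit_behavior_embedding(W[draw, , drop = FALSE], seed = seed + 43L,
                                  iters = mp$iters %||% c(250, 500))
    map <- cluster_map(emb, eps = mp$eps %||% NULL,
                       min_samples = mp$min_samples %||% 20)
    write.csv(data.frame(frame = draw, map$composite, cluster = map$labels),
              file.path(out_dir, "behavior_map.csv"), row.names = FALSE)
    results$behavior_map <- map
  }

  ## ---- stats ----------------------------------------------------------
  if ("stats" %in% stages) {
    need("stats", "hmm")
    conds <- dataset_conditions(ds)
    usage_mat <- per_video_usage(results$decoded, results$hmm$n_states)
    tests <- list()
    for (cond in setdiff(unique(conds), unname(ds$control_map))) {
      ctrl <- control_of(ds, cond)
      if (ctrl == cond) next
      for (k in seq_len(results$hmm$n_states)) {
        a <- usage_mat[conds == cond, k]; b <- usage_mat[conds == ctrl, k]
        if (length(a) >= 2 && length(b) >= 2)
          tests[[length(tests) + 1L]] <- as.data.frame(
            usage_comparison(a, b, feature = sprintf("%s state %d", cond, k)))
      }
    }
    if (length(tests)) {
      stats_df <- do.call(rbind, tests)
      write.csv(stats_df, file.path(out_dir, "usage_tests.csv"),
                row.names = FALSE)
      results$usage_tests <- stats_df
    }
  }

  ## ---- provenance -----------------------------------------------------
  prov <- list(package_version = as.character(utils::packageVersion("cionaswim")),
               seed = seed, stages = stages,
               config = config[setdiff(names(config), "output_dir")],
               timestamp_free = TRUE)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(results)
}
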