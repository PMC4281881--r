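#' Pipeline configuration
#'
#' Bundles every stage parameter of the demonstration pipeline with a master
#' seed (all stage randomness is derived from it via named substreams) and a
#' schema version. Unknown parameter names are rejected, and a config
#' round-trips losslessly through its JSON serialization.
#'
#' @param seed Master seed.
#' @param n_trials Number of synthetic trials.
#' @param bouts_per_trial Bouts per trial.
#' @param classes Behavior classes sampled for the trial bouts.
#' @param frame_rate Frames per second.
#' @param rest_ms Rest duration between bouts (ms).
#' @param render Render and track video (TRUE) or use ground-truth traces
#'   directly (FALSE; faster).
#' @param n_train_prey,n_train_spont Training-set class sizes.
#' @param feature_subset Features used by the classifier.
#' @param threshold,min_gap,min_duration,smooth_window Bout segmentation
#'   parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_trials = 3, bouts_per_trial = 3,
                            classes = c("prey_forward", "j_turn",
                                        "spontaneous"),
                            frame_rate = 300, rest_ms = 200, render = TRUE,
                            n_train_prey = 60, n_train_spont = 40,
                            feature_subset = feature_names()[1:5],
                            threshold = 3.5, min_gap = 15, min_duration = 10,
                            smooth_window = 5) {
  cfg <- list(schema_version = "preybout/pipeline/1", seed = seed,
              n_trials = n_trials, bouts_per_trial = bouts_per_trial,
              classes = classes, frame_rate = frame_rate, rest_ms = rest_ms,
              render = render, n_train_prey = n_train_prey,
              n_train_spont = n_train_spont,
              feature_subset = feature_subset, threshold = threshold,
              min_gap = min_gap, min_duration = min_duration,
              smooth_window = smooth_window)
  structure(cfg, class = "pipeline_config")
}

#' Restore a pipeline config from a (parsed) serialized form
#'
#' @param x Named list, e.g. from `jsonlite::read_json(..., simplifyVector =
#'   TRUE)` or a YAML parse. Unknown keys are rejected (strict schema).
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  x$schema_version <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

#' Run the demonstration pipeline
#'
#' Executes the full workflow on synthetic data: generate trials, optionally
#' render and track them, segment bouts, extract features, train the
#' classifier on a synthetic labeled set, classify the detected bouts, and
#' score each trial. Every intermediate artifact is written to `out_dir`
#' together with a manifest (config, seed, file checksums) and a plain log;
#' identical configs produce byte-identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- "synth"
  manifest_files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest_files <<- c(manifest_files, path)
    path
  }
  result <- tryCatch({
    # --- synth: trials with known bout composition -----------------------
    classes <- rep_len(config$classes, config$bouts_per_trial)
    trials <- lapply(seq_len(config$n_trials), function(i) {
      params <- lapply(seq_along(classes), function(j) {
        sample_bout_params(classes[j], 1,
                           seed = derive_seed(config$seed,
                                              1000 * i + j))[[1]]
      })
      generate_trial(params, rest_durations = config$rest_ms,
                     frame_rate = config$frame_rate,
                     seed = derive_seed(config$seed, i))
    })
    for (i in seq_along(trials)) {
      emit(sprintf("trial_%02d_truth.csv", i), function(p) {
        write_bout_csv(trials[[i]]$bout_truth, p)
      })
    }
    note("synth: %d trials x %d bouts", length(trials), length(classes))

    # --- track (or pass ground truth through) ----------------------------
    stage <- "track"
    traces <- lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]$trace
      if (!config$render) return(tr)
      video <- render_video(tr, seed = derive_seed(config$seed, 500 + i))
      track_video(video, base_point = tr$base,
                  frame_rate = config$frame_rate)
    })
    for (i in seq_along(traces)) {
      emit(sprintf("trial_%02d_trace.json", i), function(p) {
        write_trace_json(traces[[i]], p)
      })
    }
    note("track: %s", if (config$render) "rendered and tracked" else
      "ground-truth traces")

    # --- segment + features ----------------------------------------------
    stage <- "segment"
    series <- lapply(traces, compute_kinematics)
    bout_tables <- lapply(seq_along(series), function(i) {
      b <- segment_bouts(series[[i]], smooth_window = config$smooth_window,
                         threshold = config$threshold,
                         min_gap = config$min_gap,
                         min_duration = config$min_duration)
      if (nrow(b)) b$trial_id <- i
      b
    })
    stage <- "features"
    feats <- do.call(rbind, lapply(seq_along(series), function(i) {
      b <- bout_tables[[i]]
      if (!nrow(b)) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
        extract_features(series[[i]], b[k, ])
      }))
    }))
    note("segment: %d bouts detected",
         sum(vapply(bout_tables, nrow, integer(1))))

    # --- train + classify + score ----------------------------------------
    stage <- "train"
    training <- synthesize_labeled_bouts(config$n_train_prey,
                                         config$n_train_spont,
                                         frame_rate = config$frame_rate,
                                         seed = derive_seed(config$seed, 7))
    emit("training_features.csv", function(p) {
      write_features_csv(training, p)
    })
    clf <- train_bout_classifier(training,
                                 feature_subset = config$feature_subset)
    emit("classifier.rds", function(p) save_bout_classifier(clf, p))
    stage <- "classify"
    scores <- data.frame(trial_id = seq_along(trials),
                         score = NA_real_)
    all_bouts <- NULL
    for (i in seq_along(trials)) {
      b <- bout_tables[[i]]
      if (nrow(b)) {
        fi <- do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
          extract_features(series[[i]], b[k, ])
        }))
        b$label <- as.character(classify_bouts(clf, as.data.frame(fi)))
      } else {
        b$label <- character(0)
      }
      scores$score[i] <- prey_capture_score(b, length(series[[i]]$tail_angle))
      all_bouts <- rbind(all_bouts, b)
    }
    emit("bouts.csv", function(p) write_bout_csv(
      all_bouts %||% data.frame(start_frame = integer(0),
                                end_frame = integer(0)), p))
    emit("scores.csv", function(p) write.csv(scores, p, row.names = FALSE))
    note("score: mean prey-capture score %.1f%%", mean(scores$score))
    scores
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    schema_version = config$schema_version,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(manifest_files,
                                       basename(manifest_files)),
                       function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, scores = result))
}
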