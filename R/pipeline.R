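#' Run configuration for the end-to-end pipeline
#'
#' A fully serializable description of one analysis run: cohort
#' specification, extraction parameters, selector, classifier grids,
#' repeats, permutations and the root seed. A run is reproducible from its
#' configuration alone.
#'
#' @param cohort a [cohort_spec()] or a list of its arguments.
#' @param block experimental block analysed.
#' @param modality `"kinematic"`, `"eye"` or `"combined"`.
#' @param selector_method,k,selector_args feature selection settings.
#' @param config a [classifier_config()].
#' @param n_repeats repeated development/testing runs.
#' @param n_perm label permutations for the significance test (0 disables).
#' @param cutoff_hz trajectory filter cutoff.
#' @param seed root seed; every stage derives its own substream from it.
#' @param from_trials simulate raw trials and extract features (slower),
#'   rather than sampling feature matrices directly.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), block = "general",
                       modality = "combined",
                       selector_method = "wrapped", k = 10,
                       selector_args = list(),
                       config = classifier_config(),
                       n_repeats = 5, n_perm = 0, cutoff_hz = 10,
                       seed = 1, from_trials = FALSE) {
  if (!inherits(cohort, "cohort_spec")) cohort <- do.call(cohort_spec, cohort)
  stopifnot(block %in% BLOCKS,
            modality %in% c("kinematic", "eye", "combined"))
  structure(
    list(cohort = cohort, block = block, modality = modality,
         selector_method = selector_method, k = k,
         selector_args = selector_args, config = config,
         n_repeats = n_repeats, n_perm = n_perm, cutoff_hz = cutoff_hz,
         seed = as.integer(seed), from_trials = from_trials),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML document
#'
#' @param path YAML file; top-level keys mirror the [run_config()]
#'   arguments, with `cohort` and `classifier` as nested maps.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- doc[setdiff(names(doc), c("cohort", "classifier"))]
  if (!is.null(doc$cohort)) {
    ch <- doc$cohort
    if (!is.null(ch$planted_features)) {
      ch$planted_features <- do.call(rbind, lapply(ch$planted_features,
                                                   as.data.frame))
    }
    args$cohort <- do.call(cohort_spec, ch)
  }
  if (!is.null(doc$classifier)) {
    args$config <- do.call(classifier_config, doc$classifier)
  }
  do.call(run_config, args)
}

#' Execute the full pipeline
#'
#' Orchestrates simulate -> extract -> preprocess -> select/evaluate ->
#' report. Per-stage artifacts (trial TSVs when simulating from trials,
#' feature CSVs, selection and results JSON, a plain-text report and, for
#' wrapped runs, a stability-trajectory figure) are written to `out_dir`.
#' Every output embeds the configuration hash and seed; a rerun with the
#' same configuration is bit-identical.
#'
#' @param rc a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages (written to stderr).
#' @return (invisibly) a list with the development/testing results, the
#'   final selected features, and file paths.
#' @export
run_pipeline <- function(rc, out_dir, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(rc)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[stabselect %s] ", format(Sys.time(), "%H:%M:%S")),
                        sprintf(fmt, ...))
  }

  say("stage simulate: %s path", if (rc$from_trials) "trial-level" else "matrix")
  if (rc$from_trials) {
    sim <- generate_trials(rc$cohort, seed = child_seed(rc$seed, 1))
    write_trials_tsv(sim$movement, file.path(out_dir, "trials.tsv"))
    write_trials_tsv(sim$gaze, file.path(out_dir, "gaze.tsv"))
    say("stage extract: block %s", rc$block)
    fm_parts <- list()
    roster <- sim$participants
    if (rc$modality %in% c("kinematic", "combined")) {
      fm_parts$kin <- extract_kinematic_features(sim$movement, rc$block,
                                                 cutoff_hz = rc$cutoff_hz)
    }
    if (rc$modality %in% c("eye", "combined")) {
      gz <- screen_missing_gaze(sim$gaze)
      fm_parts$eye <- aggregate_eye_features(
        gz, rc$block, participants = roster[, c("participant", "group")])
    }
    full <- if (length(fm_parts) > 1) do.call(combine_features, fm_parts)
            else fm_parts[[1]]
    devrows <- roster$set[match(full$sample_ids, roster$participant)] == "dev"
    say("stage preprocess: group-mean imputation")
    dev <- impute_group_outliers_and_missing(full[which(devrows), ])
    test <- impute_group_outliers_and_missing(
      full[which(!devrows), ], group_means = attr(dev, "group_means"))
  } else {
    mats <- generate_cohort_matrices(rc$cohort, blocks = rc$block,
                                     seed = child_seed(rc$seed, 1))
    keep <- if (rc$modality == "combined") rep(TRUE, ncol(mats$dev$values))
            else mats$dev$feature_meta$modality == rc$modality
    dev <- mats$dev[, which(keep)]
    test <- mats$test[, which(keep)]
  }
  write_feature_csv(dev, file.path(out_dir, "features_dev.csv"))
  write_feature_csv(test, file.path(out_dir, "features_test.csv"))

  say("stage select: %s (k=%d)", rc$selector_method, rc$k)
  selector <- do.call(make_selector, c(list(rc$selector_method, k = rc$k),
                                       rc$selector_args))
  sel_info <- list(method = rc$selector_method, k = rc$k, seed = rc$seed,
                   config_hash = cfg_hash)
  if (rc$selector_method == "wrapped") {
    prm <- fit_zscore(dev)
    zdev <- apply_zscore(prm, dev$values)
    wr <- do.call(wrapped_t_select,
                  c(list(zdev, dev$labels, k = rc$k,
                         seed = child_seed(rc$seed, 5)), rc$selector_args))
    sel_info$features <- wr$features
    sel_info$iterations <- wr$state$iterations
    sel_info$final_ki <- wr$state$ki[wr$state$iterations]
    plot_wrapped_trajectory(wr$state,
                            file.path(out_dir, "wrapped_trajectory.pdf"))
  } else {
    prm <- fit_zscore(dev)
    zdev <- apply_zscore(prm, dev$values)
    sel_info$features <- selector(zdev, dev$labels,
                                  seed = child_seed(rc$seed, 5))
  }
  jsonlite::write_json(sel_info, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage evaluate: %d repeats", rc$n_repeats)
  res <- repeat_runs(dev, test, selector, rc$config,
                     n_repeats = rc$n_repeats, seed = child_seed(rc$seed, 6))
  perm <- NULL
  if (rc$n_perm > 0) {
    say("stage permtest: %d permutations", rc$n_perm)
    perm <- permutation_significance(
      dev, test, selector, rc$config, n_perm = rc$n_perm,
      seed = child_seed(rc$seed, 7),
      observed = mean(res$runs$test_acc))
  }

  results <- list(
    config_hash = cfg_hash, seed = rc$seed,
    selector = rc$selector_method, modality = rc$modality, block = rc$block,
    development = list(acc = mean(res$runs$dev_acc),
                       ki = mean(res$runs$ki)),
    testing = list(acc = mean(res$runs$test_acc),
                   sensitivity = mean(res$runs$test_sens),
                   specificity = mean(res$runs$test_spec)),
    p = if (!is.null(perm)) perm$p else NA,
    runs = res$runs
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_summary_table(results, file.path(out_dir, "summary.csv"))
  write_report(results, sel_info, file.path(out_dir, "report.txt"))
  say("done: %s", out_dir)
  invisible(list(results = results, selection = sel_info,
                 evaluation = res, permutation = perm, out_dir = out_dir))
}

config_hash <- function(rc) {
  # stable content hash without external digest dependencies
  s <- paste(deparse(rc[setdiff(names(rc), "config_hash")]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_summary_table <- function(results, path) {
  df <- data.frame(
    selector = results$selector, modality = results$modality,
    block = results$block,
    dev_acc = results$development$acc, ki = results$development$ki,
    test_acc = results$testing$acc, sensitivity = results$testing$sensitivity,
    specificity = results$testing$specificity, p = results$p
  )
  write.csv(df, path, row.names = FALSE)
}

write_report <- function(results, sel_info, path) {
  lines <- c(
    sprintf("stabselect run %s (seed %d)", results$config_hash, results$seed),
    sprintf("selector: %s | modality: %s | block: %s",
            results$selector, results$modality, results$block),
    sprintf("development accuracy: %.1f%% (KI %.2f)",
            100 * results$development$acc, results$development$ki),
    sprintf("testing accuracy: %.1f%% (sens %.1f%%, spec %.1f%%)",
            100 * results$testing$acc, 100 * results$testing$sensitivity,
            100 * results$testing$specificity),
    if (!is.na(results$p)) sprintf("permutation p: %.4f", results$p)
    else "permutation p: not computed",
    sprintf("selected features: %s",
            paste(sel_info$features, collapse = ", "))
  )
  writeLines(lines, path)
  invisible(path)
}

plot_wrapped_trajectory <- function(state, path) {
  grDevices::pdf(path, width = 7, height = 4.5)
  on.exit(grDevices::dev.off())
  it <- seq_len(state$iterations)
  graphics::par(mar = c(4, 4, 1, 4))
  graphics::plot(it, state$ki, type = "l", col = "steelblue",
                 xlab = "iteration", ylab = "Kuncheva index", ylim = c(-0.2, 1))
  graphics::par(new = TRUE)
  graphics::plot(it, state$mean_acc, type = "l", col = "firebrick",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0.3, 1))
  graphics::axis(4)
  graphics::mtext("mean fold accuracy", side = 4, line = 2.5)
  graphics::legend("bottomright", c("KI", "accuracy"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(path)
}
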