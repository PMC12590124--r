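# End-to-end orchestration: per-subject feature extraction (evoked component
# peaks + band-limited TFR features in both response modes), min-max
# normalization across participants, per-feature group statistics, and
# optional classification.

#' Extract the full feature set for one subject
#'
#' Computes evoked component peaks (latency and amplitude per component
#' window) from the trial average, and the four TFR features (peak
#' frequency, peak latency, peak amplitude, average relative power) per
#' requested band for the requested response modes. Evoked beta/NBG features
#' come from the 1-100 Hz map, evoked BBG from the 100-250 Hz map; induced
#' features use the per-band ranges (1-30, 30-100, 100-250 Hz).
#'
#' @param recording An [epoched_recording()].
#' @param modes Response modes to compute (default both).
#' @param bands Bands to extract (default beta, NBG, BBG).
#' @param t_lo,t_hi Analysis window in ms (default 10-500).
#' @param components Detect evoked component peaks too (default TRUE).
#' @return One-row data.frame: `subject_id`, `group`, `modality`, then one
#'   column per feature, named `<mode>_<band>_<feature>` or
#'   `comp_<component>_<latency|amplitude>`.
#' @export
subject_features <- function(recording, modes = c("evoked", "induced"),
                             bands = c("beta", "NBG", "BBG"),
                             t_lo = 10, t_hi = 500, components = TRUE) {
  stopifnot(inherits(recording, "epoched_recording"))
  row <- data.frame(subject_id = recording$subject_id, group = recording$group,
                    modality = recording$modality)
  if (components) {
    det <- detect_components(average_evoked(recording),
                             component_windows(recording$modality))
    for (i in seq_len(nrow(det))) {
      row[[paste0("comp_", det$component[i], "_latency")]] <- det$latency_ms[i]
      row[[paste0("comp_", det$component[i], "_amplitude")]] <- det$amplitude[i]
    }
  }
  need_low <- "beta" %in% bands
  need_mid <- "NBG" %in% bands
  need_high <- "BBG" %in% bands
  maps <- list()
  if ("evoked" %in% modes) {
    if (need_low || need_mid) maps$evoked_lowmid <- evoked_tfr(recording, "full")
    if (need_high) maps$evoked_high <- evoked_tfr(recording, "high")
  }
  if ("induced" %in% modes) {
    if (need_low) maps$induced_low <- induced_tfr(recording, "low")
    if (need_mid) maps$induced_mid <- induced_tfr(recording, "mid")
    if (need_high) maps$induced_high <- induced_tfr(recording, "high")
  }
  pick <- function(mode, band) {
    key <- if (mode == "evoked") {
      if (band == "BBG") "evoked_high" else "evoked_lowmid"
    } else paste0("induced_", switch(band, beta = "low", NBG = "mid", BBG = "high"))
    maps[[key]]
  }
  for (mode in modes) {
    for (band in bands) {
      ft <- extract_band_features(pick(mode, band),
                                  band_window(band, t_lo = t_lo, t_hi = t_hi))
      for (nm in c("peak_frequency", "peak_latency", "peak_amplitude", "avg_power"))
        row[[paste(mode, band, nm, sep = "_")]] <- ft[[nm]]
    }
  }
  row
}

#' Feature table for a whole cohort
#'
#' @param recordings List of [epoched_recording()] objects (or
#'   [generate_cohort()] output).
#' @param ... Passed to [subject_features()].
#' @return data.frame with one row per subject.
#' @export
cohort_features <- function(recordings, ...) {
  if (!is.null(recordings$recordings)) recordings <- recordings$recordings
  do.call(rbind, lapply(recordings, subject_features, ...))
}

#' Min-max normalize feature columns across participants
#'
#' Applies [minmax_normalize()] to each numeric feature column; columns with
#' fewer than two distinct finite values are left untouched with a warning.
#'
#' @param features Feature table from [cohort_features()].
#' @param cols Columns to normalize (default: all numeric feature columns).
#' @return The table with normalized columns.
#' @export
normalize_features <- function(features, cols = NULL) {
  if (is.null(cols))
    cols <- names(features)[vapply(features, is.numeric, logical(1))]
  for (cl in cols) {
    x <- features[[cl]]
    ok <- is.finite(x)
    if (sum(ok) < 2 || length(unique(x[ok])) < 2) {
      warning(sprintf("feature '%s' is degenerate; left unnormalized", cl))
      next
    }
    features[[cl]][ok] <- minmax_normalize(x[ok])
  }
  features
}

#' Per-feature group comparison with FDR correction
#'
#' Wilcoxon rank-sum test of every feature column between the two groups,
#' Benjamini-Hochberg corrected across the tested features.
#'
#' @param features Feature table with a `group` column.
#' @param q FDR level (default 0.05).
#' @return data.frame: `feature`, group means and SDs, `statistic`, `p`,
#'   `p_adj`, `significant`.
#' @export
feature_group_stats <- function(features, q = 0.05) {
  cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                  c("fs"))
  ctl <- features$group == "control"
  rows <- lapply(cols, function(cl) {
    a <- features[[cl]][ctl]
    b <- features[[cl]][!ctl]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    rs <- ranksum(a, b)
    data.frame(feature = cl, mean_control = mean(a), sd_control = stats::sd(a),
               mean_patient = mean(b), sd_patient = stats::sd(b),
               statistic = rs$statistic, p = rs$p)
  })
  out <- do.call(rbind, rows)
  adj <- fdr_bh(out$p, q = q)
  out$p_adj <- adj$p_adjusted
  out$significant <- adj$rejected
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' Feature extraction for every subject, min-max normalization across
#' participants, per-feature rank-sum group statistics with FDR, and
#' (optionally) ANOVA feature selection followed by RBF-SVM classification.
#'
#' @param recordings List of [epoched_recording()] objects or
#'   [generate_cohort()] output.
#' @param modes,bands,t_lo,t_hi Passed to [subject_features()].
#' @param classify Run the classification stage (default TRUE; needs enough
#'   subjects per group for stratified resampling).
#' @param n_splits Train/test iterations for the classifier (default 100).
#' @param seed Seed for the classification stage.
#' @return List of class `pipeline_result`: `features`, `normalized`,
#'   `stats`, `selection`, `report` (NULL when classification is skipped).
#' @export
run_pipeline <- function(recordings, modes = c("evoked", "induced"),
                         bands = c("beta", "NBG", "BBG"), t_lo = 10,
                         t_hi = 500, classify = TRUE, n_splits = 100,
                         seed = 1) {
  features <- cohort_features(recordings, modes = modes, bands = bands,
                              t_lo = t_lo, t_hi = t_hi)
  normalized <- suppressWarnings(normalize_features(features))
  stats_tab <- feature_group_stats(normalized)
  selection <- NULL
  report <- NULL
  if (classify) {
    num_cols <- names(normalized)[vapply(normalized, is.numeric, logical(1))]
    complete <- num_cols[vapply(num_cols, function(cl)
      all(is.finite(normalized[[cl]])), logical(1))]
    selection <- select_features_anova(normalized[, complete, drop = FALSE],
                                       normalized$group)
    chosen <- selection$feature[selection$selected]
    if (length(chosen) >= 1) {
      report <- train_eval_svm(normalized[, chosen, drop = FALSE],
                               normalized$group, n_splits = n_splits,
                               seed = seed)
    }
  }
  structure(list(features = features, normalized = normalized,
                 stats = stats_tab, selection = selection, report = report),
            class = "pipeline_result")
}
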