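## On-disk containers. The epoch container stores the trials x sensors x
## time array together with a JSON sidecar carrying the logical schema
## (times, sampling rate, layout, trial table, normalization state);
## results serialize as delimited tables with a JSON config echo.

#' Write / read an epoch container
#'
#' The array is stored via R serialization (`<file>`), the metadata as a
#' JSON sidecar (`<file>.meta.json`) with fields `times`, `sfreq`,
#' `sensor_type`, `units`, `normalization_state` and `trials`.
#'
#' @param epochs an [EpochsData-class].
#' @param file path.
#' @return `writeEpochs()` returns `file` invisibly; `readEpochs()` the
#'   reconstructed [EpochsData-class].
#' @export
writeEpochs <- function(epochs, file) {
  stopifnot(is(epochs, "EpochsData"))
  saveRDS(epochs@data, file)
  meta <- list(times = epochs@times, sfreq = epochs@sfreq,
               sensor_type = epochs@layout@sensorType,
               units = as.list(epochs@layout@units),
               normalization_state = epochs@normalizationState,
               trials = epochs@trials)
  jsonlite::write_json(meta, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(file) {
  data <- readRDS(file)
  meta <- jsonlite::read_json(paste0(file, ".meta.json"),
                              simplifyVector = TRUE)
  layout <- new("SensorLayout", sensorType = meta$sensor_type,
                units = unlist(meta$units))
  trials <- as.data.frame(meta$trials, stringsAsFactors = FALSE)
  new("EpochsData", data = data, times = meta$times, sfreq = meta$sfreq,
      layout = layout, trials = trials,
      normalizationState = meta$normalization_state)
}

#' Write a decoding result as a delimited table
#'
#' TSV of `(time_ms, accuracy)` with a JSON sidecar echoing the condition
#' pair, trial counts and configuration.
#'
#' @param result a [DecodingResult-class].
#' @param file path of the TSV.
#' @return `file`, invisibly.
#' @export
writeDecodingResult <- function(result, file) {
  stopifnot(is(result, "DecodingResult"))
  write.table(data.frame(time_ms = result@times,
                         accuracy = result@accuracy),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(condition_pair = result@conditionPair,
         n_trials_used = result@nTrialsUsed, config = result@config),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Write a cluster-test result
#'
#' JSON with the cluster table, configuration and null-distribution
#' summary, plus a TSV of the per-time-point statistic map, pointwise p and
#' significance mask.
#'
#' @param result a [ClusterTestResult-class].
#' @param file path of the JSON; the mask table goes to `<file>.map.tsv`.
#' @return `file`, invisibly.
#' @export
writeClusterTestResult <- function(result, file) {
  stopifnot(is(result, "ClusterTestResult"))
  jsonlite::write_json(
    list(clusters = result@clusters, config = result@config,
         null_max_mass_quantiles =
           as.list(quantile(result@nullMaxMass, c(0.5, 0.95, 0.99)))),
    file, auto_unbox = TRUE, digits = NA)
  write.table(data.frame(time_ms = result@times,
                         statistic = result@statisticMap,
                         pointwise_p = result@pointwiseP,
                         significant = result@significantMask),
              paste0(file, ".map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Write a study report directory
#'
#' One directory per analysis family with machine-readable tables
#' (accuracy matrices as TSV, cluster tests via
#' [writeClusterTestResult()]) plus a single JSON manifest with the
#' configuration and summary statistics.
#'
#' @param report a `study_report` from [runFullStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- names(report$config$groupProfiles)
  writeMat <- function(m, path) {
    df <- as.data.frame(t(m))
    names(df) <- paste0("subj", seq_len(ncol(df)))
    df <- cbind(time_ms = report$times, df)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (grp in groups) {
    gdir <- file.path(dir, grp)
    dir.create(gdir, showWarnings = FALSE)
    for (ct in names(report$accuracy[[grp]])) {
      writeMat(report$accuracy[[grp]][[ct]],
               file.path(gdir, paste0("accuracy_", ct, ".tsv")))
      writeClusterTestResult(report$groupTests[[grp]][[ct]],
                             file.path(gdir, paste0("test_", ct, ".json")))
    }
  }
  summarize <- function(res) {
    list(n_clusters = nrow(res@clusters),
         min_corrected_p = if (nrow(res@clusters))
           min(res@clusters$corrected_p) else NULL,
         significant = any(res@clusters$corrected_p <
                             res@config$clusterAlpha))
  }
  manifest <- list(
    config = unclass(report$config)[
      setdiff(names(unclass(report$config)),
              c("design", "decode", "cluster"))],
    design = report$design@spec,
    decode = unclass(report$config$decode),
    cluster = unclass(report$config$cluster),
    usable_counts = lapply(report$usableCounts,
                           function(m) as.data.frame(unclass(m))),
    between_tests = lapply(report$betweenTests, summarize),
    subset_tests = lapply(report$subsetTests,
                          function(g) lapply(g, summarize)),
    repetition_tests = lapply(report$repetitionTests,
                              function(g) g$summary))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
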