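# Readers/writers for feature tables, dataset bundles and reports.

#' Read a per-trial feature table
#'
#' CSV/TSV with a header; required columns `label` (integer class) and
#' `subject` (integer subject id); every other column is a numeric feature.
#' The `eseed` dialect checks the feature names against the 13-name
#' catalogue of [esee_feature_names()] and warns on any mismatch; `seed`
#' and `free` accept any numeric feature set.
#'
#' @param path file path.
#' @param dialect one of `"free"`, `"seed"`, `"eseed"`.
#' @param sep field separator; guessed from the extension by default.
#' @return object of class `feature_table`: list with `features` (numeric
#'   data frame), `labels`, `subject_ids`, `dialect`.
#' @export
read_feature_table <- function(path, dialect = c("free", "seed", "eseed"),
                               sep = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("label", "subject")) {
    if (!col %in% names(df))
      stop(sprintf("missing column: %s", col), call. = FALSE)
  }
  feats <- df[, setdiff(names(df), c("label", "subject")), drop = FALSE]
  if (anyDuplicated(names(feats)))
    stop("feature names must be unique", call. = FALSE)
  for (f in names(feats)) {
    v <- feats[[f]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric feature cell in column '%s' at row %d", f,
                   if (length(bad)) bad[1L] else 1L), call. = FALSE)
    }
  }
  if (dialect == "eseed") {
    delta_missing <- setdiff(esee_feature_names(), names(feats))
    delta_extra <- setdiff(names(feats), esee_feature_names())
    if (length(delta_missing) || length(delta_extra))
      warning(sprintf("eseed dialect name mismatch; missing: [%s]; unexpected: [%s]",
                      paste(delta_missing, collapse = ", "),
                      paste(delta_extra, collapse = ", ")), call. = FALSE)
  }
  structure(list(features = feats, labels = as.integer(df$label),
                 subject_ids = as.integer(df$subject), dialect = dialect),
            class = "feature_table")
}

#' Default view assignment for the eSEE-d dialect
#'
#' Pupil-diameter features form the pupil view; all fixation/saccade
#' features form the gaze view.
#'
#' @return named character vector mapping feature name to "gaze"/"pupil".
#' @export
default_esee_view_map <- function() {
  nm <- esee_feature_names()
  stats::setNames(ifelse(grepl("^pupil_", nm), "pupil", "gaze"), nm)
}

#' Split a feature table into a dual-view dataset
#'
#' @param table a `feature_table`.
#' @param view_map named character vector assigning every feature to
#'   `"gaze"` or `"pupil"`; default uses the eSEE-d pupil/gaze split when
#'   the names match, else errors.
#' @return a `dual_modality_dataset`.
#' @export
split_views <- function(table, view_map = NULL) {
  feats <- names(table$features)
  if (is.null(view_map)) {
    vm <- default_esee_view_map()
    if (!all(feats %in% names(vm)))
      stop("no view_map supplied and feature names do not match the eseed catalogue",
           call. = FALSE)
    view_map <- vm[feats]
  }
  unassigned <- setdiff(feats, names(view_map))
  if (length(unassigned))
    stop(sprintf("unassigned feature(s): %s",
                 paste(unassigned, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(view_map), c("gaze", "pupil"))
  if (length(bad)) stop("view_map values must be 'gaze' or 'pupil'",
                        call. = FALSE)
  gz <- feats[view_map[feats] == "gaze"]
  pp <- feats[view_map[feats] == "pupil"]
  if (!length(pp)) stop("pupil view assignment is empty", call. = FALSE)
  if (!length(gz)) stop("gaze view assignment is empty", call. = FALSE)
  structure(list(gaze_view = as.matrix(table$features[, gz, drop = FALSE]),
                 pupil_view = as.matrix(table$features[, pp, drop = FALSE]),
                 labels = table$labels, subject_ids = table$subject_ids,
                 class_names = as.character(sort(unique(table$labels))),
                 spec = NULL),
            class = "dual_modality_dataset")
}

#' Impute missing feature values by training-split medians
#'
#' @param X numeric matrix with possible NAs.
#' @param medians optional per-column medians (from a training split); NULL
#'   computes them from `X`.
#' @return list with imputed `X` and the `medians` used.
#' @export
impute_median <- function(X, medians = NULL) {
  X <- as.matrix(X)
  if (is.null(medians))
    medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }
  list(X = X, medians = medians)
}

#' Write a dual-view dataset bundle
#'
#' A directory of plain-text arrays (`gaze_view.csv`, `pupil_view.csv`,
#' `labels.csv` with labels and subject ids) plus a JSON sidecar echoing the
#' generating spec. A combined `features.csv` with view-prefixed column
#' names is also written for spreadsheet use.
#'
#' @param dataset a `dual_modality_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset$gaze_view),
                   file.path(dir, "gaze_view.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$pupil_view),
                   file.path(dir, "pupil_view.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = dataset$labels,
                              subject = dataset$subject_ids),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  comb <- cbind(as.data.frame(dataset$gaze_view),
                as.data.frame(dataset$pupil_view),
                data.frame(label = dataset$labels,
                           subject = dataset$subject_ids))
  utils::write.csv(comb, file.path(dir, "features.csv"), row.names = FALSE)
  sidecar <- list(class_names = dataset$class_names,
                  n = nrow(dataset$gaze_view),
                  view_dims = c(ncol(dataset$gaze_view),
                                ncol(dataset$pupil_view)))
  if (!is.null(dataset$spec)) sidecar$spec <- unclass(dataset$spec)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dual-view dataset bundle written by [write_dataset()]
#' @param dir bundle directory.
#' @return a `dual_modality_dataset`.
#' @export
read_dataset <- function(dir) {
  gz <- as.matrix(utils::read.csv(file.path(dir, "gaze_view.csv")))
  pp <- as.matrix(utils::read.csv(file.path(dir, "pupil_view.csv")))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  sidecar <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                 simplifyVector = TRUE)
  spec <- NULL
  if (!is.null(sidecar$spec)) {
    spec <- sidecar$spec
    class(spec) <- "synthetic_spec"
  }
  structure(list(gaze_view = gz, pupil_view = pp,
                 labels = as.integer(lab$label),
                 subject_ids = as.integer(lab$subject),
                 class_names = sidecar$class_names, spec = spec),
            class = "dual_modality_dataset")
}

#' Read a raw gaze recording from CSV
#'
#' Expects columns `t_ms, x, y, pupil_l, pupil_r, valid`.
#'
#' @param path CSV path.
#' @param sample_rate optional sampling rate (Hz); inferred from the
#'   timestamps when omitted.
#' @return a [gaze_recording()].
#' @export
read_gaze_csv <- function(path, sample_rate = NULL) {
  df <- utils::read.csv(path)
  need <- c("t_ms", "x", "y", "pupil_l", "pupil_r", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing column: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  gaze_recording(df$t_ms, df$x, df$y, df$pupil_l, df$pupil_r,
                 as.logical(df$valid), sample_rate)
}

#' Save / load a trained model checkpoint
#'
#' A checkpoint directory holds the weights (RDS of plain arrays) and a JSON
#' echo of the architecture configuration.
#'
#' @param model a trained `ictd_model`.
#' @param dir checkpoint directory.
#' @return `dir` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(x) {
    if (is.environment(x)) return(x$value)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  saveRDS(strip(model$params), file.path(dir, "weights.rds"))
  jsonlite::write_json(list(cfg = unclass(model$cfg), d_in1 = model$d_in1,
                            d_in2 = model$d_in2, n_classes = model$n_classes,
                            seed = model$seed,
                            n_parameters = n_parameters(model)),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- meta$cfg
  cfg$pool_kernels <- as.integer(cfg$pool_kernels)
  class(cfg) <- "model_config"
  model <- ictd_model(meta$d_in1, meta$d_in2, meta$n_classes, cfg,
                      seed = meta$seed)
  w <- readRDS(file.path(dir, "weights.rds"))
  rewrap <- function(params, values) {
    for (i in seq_along(values)) {
      if (is.environment(params[[i]])) params[[i]]$value <- values[[i]]
      else rewrap(params[[i]], values[[i]])
    }
  }
  rewrap(model$params, w)
  model
}
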