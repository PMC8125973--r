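#' Read an OpenFace-style AU intensity CSV
#'
#' Parses the per-frame AU regression outputs (`AU01_r` ... `AU45_r`) of an
#' OpenFace CSV. Whitespace after commas (which OpenFace emits) is
#' tolerated; extra columns such as pose or gaze are ignored; a missing AU
#' column or an empty file is an error, never silently coerced.
#'
#' @param path CSV file path.
#' @return list with `series` (17 x T matrix, rows in canonical
#'   [au_names()] order) and `timestamp` (length-T numeric, seconds; NA if
#'   the file has no timestamp column).
#' @export
read_au_csv <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  df <- read.csv(path, check.names = TRUE, strip.white = TRUE)
  if (nrow(df) == 0) stop_arg("empty AU CSV: %s", path)
  names(df) <- trimws(names(df))
  missing <- setdiff(au_columns(), names(df))
  if (length(missing))
    stop_arg("AU CSV %s is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  series <- t(as.matrix(df[, au_columns()]))
  if (anyNA(series) || !is.numeric(series))
    stop_arg("non-numeric or missing AU intensities in %s", path)
  rownames(series) <- au_names()
  ts <- if ("timestamp" %in% names(df)) as.numeric(df$timestamp) else
    rep(NA_real_, ncol(series))
  list(series = series, timestamp = ts)
}

#' @rdname read_au_csv
#' @param series 17 x T AU intensity matrix.
#' @param fps frames per second used to write the timestamp column.
#' @export
write_au_csv <- function(series, path, fps = 25) {
  if (nrow(series) != length(au_names())) stop_arg("series must have 17 rows")
  df <- data.frame(frame = seq_len(ncol(series)),
                   timestamp = (seq_len(ncol(series)) - 1) / fps)
  df[au_columns()] <- t(series)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_classes <- function(codes, where) {
  bad <- setdiff(unique(codes), class_codes())
  if (length(bad))
    stop_arg("%s contains invalid class code(s): %s", where,
             paste(bad, collapse = ", "))
}

#' Read / write a sample manifest
#'
#' A manifest row names one 7-s sample: `sample_id`, `subject_id`, `class`
#' (one of the 7 codes), plus paths `au_csv` and `frames_dir` (may be
#' empty). Sample ids must be unique.
#'
#' @param path CSV path.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  df <- read.csv(path, strip.white = TRUE, colClasses = "character")
  need <- c("sample_id", "subject_id", "class")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_arg("manifest missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_arg("manifest has duplicated sample_id(s): %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]),
                   collapse = ", "))
  check_classes(df$class, "manifest")
  df$subject_id <- as.integer(df$subject_id)
  if (is.null(df$au_csv)) df$au_csv <- NA_character_
  if (is.null(df$frames_dir)) df$frames_dir <- NA_character_
  df
}

#' @rdname read_manifest
#' @param manifest data.frame with at least sample_id, subject_id, class.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[, c("sample_id", "subject_id", "class", "au_csv",
                         "frames_dir")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label file (ground truth or human observer)
#'
#' Rows are `(sample_id, class)`. Every sample id must occur in the
#' manifest; unknown ids are listed in the error. A `ground_truth` file must
#' cover the whole manifest; an `observer` file may cover any non-empty
#' subset (observers label only a random 10% of samples).
#'
#' @param path CSV path with columns `sample_id, class`.
#' @param manifest the manifest the labels refer to.
#' @param source `"ground_truth"` or `"observer"`.
#' @return data.frame of class `label_file` with attribute `source`.
#' @export
read_labels <- function(path, manifest, source = c("ground_truth",
                                                   "observer")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  df <- read.csv(path, strip.white = TRUE, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(df)))
    stop_arg("label file needs columns sample_id, class")
  if (nrow(df) == 0) stop_arg("empty label file: %s", path)
  check_classes(df$class, "label file")
  unknown <- setdiff(df$sample_id, manifest$sample_id)
  if (length(unknown))
    stop_arg("label file contains sample_id(s) not in the manifest: %s",
             paste(head(unknown, 10), collapse = ", "))
  if (source == "ground_truth" &&
      !setequal(df$sample_id, manifest$sample_id))
    stop_arg("ground_truth labels must cover every manifest sample")
  structure(df, source = source, class = c("label_file", "data.frame"))
}

#' @rdname read_labels
#' @param labels data.frame with sample_id and class columns.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels[, c("sample_id", "class")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read / write a results table
#'
#' Round-trip exact on valid data: `read_results(write_results(x))` equals
#' `x` (numeric columns kept at full precision).
#'
#' @param table data.frame of results.
#' @param path CSV path.
#' @export
write_results <- function(table, path) {
  write.csv(format(table, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  read.csv(path, strip.white = TRUE)
}

#' Read / write a fold plan as JSON
#'
#' Serialised as `fold index -> vector of subject ids`.
#'
#' @param plan a `fold_plan` from [make_folds()].
#' @param path JSON path.
#' @export
write_fold_plan <- function(plan, path) {
  by_fold <- split(as.integer(names(plan$assignment)), plan$assignment)
  names(by_fold) <- paste0("fold", names(by_fold))
  jsonlite::write_json(by_fold, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  by_fold <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- integer(0)
  for (i in seq_along(by_fold)) {
    subs <- as.integer(by_fold[[i]])
    assignment[as.character(subs)] <- as.integer(sub("fold", "",
                                                     names(by_fold)[i]))
  }
  structure(list(k = length(by_fold), assignment = assignment),
            class = "fold_plan")
}

#' Write a feature matrix with named columns
#' @param features matrix from [dataset_features()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(sample_id = rownames(features), features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE, strip.white = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Persist a synthetic dataset to disk
#'
#' Writes per-sample AU CSVs in the OpenFace dialect, optional frame PNGs
#' (only the key frames needed by the spatio-temporal encoding, or all
#' frames), and the manifest CSV, mirroring what an OpenFace run over real
#' videos would leave behind.
#'
#' @param dataset a `pain_dataset`.
#' @param dir output directory (created).
#' @param frames `"none"`, `"key"` (frames at seconds 1, 3, 4) or `"all"`.
#' @param render_size side of rendered frames in pixels.
#' @return the manifest (invisibly), with file paths filled in.
#' @export
write_dataset <- function(dataset, dir, frames = c("none", "key", "all"),
                          render_size = 96) {
  frames <- match.arg(frames)
  dir.create(file.path(dir, "au"), recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset$manifest
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    au_path <- file.path(dir, "au", paste0(s$sample_id, ".csv"))
    write_au_csv(s$series, au_path, fps = s$fps)
    manifest$au_csv[i] <- au_path
    if (frames != "none") {
      fdir <- file.path(dir, "frames", s$sample_id)
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      idx <- if (frames == "all") seq_len(ncol(s$series)) else
        frame_indices(ncol(s$series), s$fps)
      for (j in idx)
        png::writePNG(render_frame(s, j, size = render_size),
                      file.path(fdir, sprintf("frame_%04d.png", j)))
      manifest$frames_dir[i] <- fdir
    }
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_labels(data.frame(sample_id = manifest$sample_id,
                          class = manifest$class),
               file.path(dir, "labels.csv"))
  invisible(manifest)
}

#' Load a dataset from a manifest on disk
#'
#' @param manifest_path path to a manifest CSV written by [write_dataset()].
#' @param fps frame rate fallback when AU CSVs carry no timestamps.
#' @return a `pain_dataset`.
#' @export
read_dataset <- function(manifest_path, fps = 25) {
  manifest <- read_manifest(manifest_path)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    au <- read_au_csv(manifest$au_csv[i])
    f <- if (!anyNA(au$timestamp) && ncol(au$series) > 1)
      1 / stats::median(diff(au$timestamp)) else fps
    structure(list(sample_id = manifest$sample_id[i],
                   subject_id = manifest$subject_id[i],
                   label = manifest$class[i], fps = f,
                   series = au$series, bump_amp = NA_real_, stim = NULL,
                   frames_dir = if (is.na(manifest$frames_dir[i]) ||
                                    !nzchar(manifest$frames_dir[i])) NULL
                                else manifest$frames_dir[i]),
              class = "au_sample")
  })
  structure(list(samples = samples, manifest = manifest,
                 subjects = NULL, config = NULL),
            class = "pain_dataset")
}
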