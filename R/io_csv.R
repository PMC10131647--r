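#' Read one trial from the package CSV dialect
#'
#' The dialect is wide-format: one row per frame, a `time` column in seconds
#' and three columns `<label>_x`, `<label>_y`, `<label>_z` per marker, in
#' metres, lab frame (x along the walkway, z vertical). Occluded frames are
#' empty cells / `NA`. A schema can remap arbitrary column names onto this
#' convention and declare the nominal sampling rate.
#'
#' @param path CSV file path.
#' @param subject_id,group,condition trial metadata (see [trial_record()]).
#' @param schema optional schema: a named list (or path to a YAML file) with
#'   any of
#'   \describe{
#'     \item{fs}{declared sampling rate in Hz; the rate inferred from the time
#'       column must agree within 0.1\%.}
#'     \item{time_col}{name of the time column (default `"time"`).}
#'     \item{columns}{named list mapping an input column name to
#'       `list(label=, axis=)` with axis one of x/y/z, for files that do not
#'       follow the `<label>_<axis>` naming.}
#'     \item{axis_map}{named character vector mapping input axes onto the lab
#'       frame, e.g. `c(x = "y", y = "x", z = "z")` if the walkway ran along
#'       the input y axis. Default identity.}
#'     \item{scale}{multiplier to metres (e.g. `0.001` for mm). Default 1.}
#'   }
#' @param meta free-form metadata list.
#' @param require_labels passed to [trial_record()].
#' @param uniform_tol maximal relative deviation of any time step from the
#'   median step before the file is rejected as non-uniformly sampled.
#' @return a [trial_record()].
#' @export
read_csv_trial <- function(path, subject_id = "s01", group = "young",
                           condition = "ST", schema = NULL, meta = list(),
                           require_labels = TRUE, uniform_tol = 0.01) {
  schema <- load_schema(schema)
  df <- utils::read.csv(path, check.names = FALSE)
  time_col <- schema$time_col %||% "time"
  if (!time_col %in% names(df))
    stop("CSV has no time column '", time_col, "'")
  tt <- df[[time_col]]
  dt <- diff(tt)
  dt_med <- stats::median(dt)
  if (dt_med <= 0) stop("time column is not increasing")
  if (any(abs(dt - dt_med) > uniform_tol * dt_med))
    stop(sprintf(
      "non-uniform sampling: time steps deviate from the median (%.6g s) by more than %g%%",
      dt_med, 100 * uniform_tol))
  fs <- 1 / dt_med
  if (!is.null(schema$fs)) {
    if (abs(fs - schema$fs) > 1e-3 * schema$fs)
      stop(sprintf("inferred rate %.4f Hz disagrees with declared fs = %g Hz",
                   fs, schema$fs))
    fs <- schema$fs
  }
  colmap <- csv_column_map(setdiff(names(df), time_col), schema)
  scale <- schema$scale %||% 1
  axis_map <- schema$axis_map %||% c(x = "x", y = "y", z = "z")
  markers <- lapply(split(colmap, colmap$label), function(cm) {
    pos <- matrix(NA_real_, nrow(df), 3, dimnames = list(NULL, c("x", "y", "z")))
    for (i in seq_len(nrow(cm)))
      pos[, axis_map[[cm$axis[i]]]] <- df[[cm$column[i]]] * scale
    marker_trajectory(cm$label[1], pos, fs = fs, t0 = tt[1])
  })
  trial_record(subject_id, group, condition, markers, meta = meta,
               require_labels = require_labels)
}

# resolve input columns to (column, label, axis)
csv_column_map <- function(cols, schema) {
  if (!is.null(schema$columns)) {
    cm <- data.frame(
      column = names(schema$columns),
      label = vapply(schema$columns, function(e) e$label, character(1)),
      axis = vapply(schema$columns, function(e) e$axis, character(1)),
      stringsAsFactors = FALSE)
  } else {
    m <- regmatches(cols, regexec("^(.*)_([xyz])$", cols))
    keep <- lengths(m) == 3L
    cm <- data.frame(
      column = cols[keep],
      label = vapply(m[keep], `[`, character(1), 2L),
      axis = vapply(m[keep], `[`, character(1), 3L),
      stringsAsFactors = FALSE)
  }
  if (!nrow(cm)) stop("no marker coordinate columns found in CSV")
  bad <- !cm$axis %in% c("x", "y", "z")
  if (any(bad)) stop("invalid axis in schema: ", paste(cm$axis[bad], collapse = ", "))
  cm
}

load_schema <- function(schema) {
  if (is.null(schema)) return(list())
  if (is.character(schema) && length(schema) == 1L)
    schema <- yaml::read_yaml(schema)
  stopifnot(is.list(schema))
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one trial to the package CSV dialect
#'
#' Inverse of [read_csv_trial()]; positions are written in metres with full
#' double precision so that a write/read round trip is exact to the printed
#' precision. Occluded frames become empty cells.
#'
#' @param trial a [trial_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_trial <- function(trial, path) {
  m1 <- trial$markers[[1]]
  out <- list(time = time_vector(m1))
  for (m in trial$markers)
    for (ax in c("x", "y", "z"))
      out[[paste0(m$label, "_", ax)]] <- m$positions[, ax]
  df <- as.data.frame(out, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    s <- sprintf("%.17g", v); s[is.na(v)] <- ""; s
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort metrics table to CSV
#'
#' Long format, one row per subject x condition x measure, with columns
#' `subject_id, group, condition, gait_speed_mps, n_turns_used, measure,
#' value`. Values are written with full double precision so the file
#' round-trips exactly through [read_metrics()].
#'
#' @param table a [cohort_table] (or plain data.frame in the same layout).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  if (is.null(table) || !nrow(table)) stop("metrics table is empty")
  cols <- c("subject_id", "group", "condition", "gait_speed_mps",
            "n_turns_used", "measure", "value")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("metrics table lacks columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(table)[cols]
  for (cc in c("gait_speed_mps", "value")) {
    s <- sprintf("%.17g", df[[cc]]); s[is.na(df[[cc]])] <- ""; df[[cc]] <- s
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort metrics table written by [write_metrics()]
#' @param path CSV file path.
#' @return a [cohort_table].
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}
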