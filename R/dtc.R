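#' Dual-task cost
#'
#' Relative change of a measure between single task (ST) and a dual-task
#' condition, in percent. The default orientation is
#' `100 * (st - dt) / st`, so that a dual-task-related decrease of a
#' higher-is-better measure (e.g. peak angular velocity) yields a positive
#' cost; `orientation = "raw_change"` returns the raw relative change
#' `100 * (dt - st) / st` instead, which reads more naturally for
#' lower-is-better measures such as turn duration or step count. The two
#' conventions differ only by sign.
#'
#' @param st_value measure value under single task (non-zero).
#' @param dt_value measure value under the dual-task condition.
#' @param orientation `"cost"` (default) or `"raw_change"`.
#' @return dual-task cost in percent.
#' @export
compute_dtc <- function(st_value, dt_value,
                        orientation = c("cost", "raw_change")) {
  orientation <- match.arg(orientation)
  if (any(st_value == 0))
    stop("dual-task cost is undefined for st_value = 0")
  out <- 100 * (st_value - dt_value) / st_value
  if (orientation == "raw_change") -out else out
}

#' Dual-task cost table for a cohort
#'
#' Computes per-subject DTC between ST and each dual-task condition for the
#' requested measures.
#'
#' @param table a [cohort_table()] (long format).
#' @param measures measures to include; defaults to the measures the
#'   paradigm evaluates under dual task: turn duration, steps while turning
#'   and the three segmental peak angular velocities.
#' @param orientation passed to [compute_dtc()].
#' @return data.frame with columns `subject_id, group, measure,
#'   dt_condition, st_value, dt_value, dtc_pct`. Subjects lacking an ST
#'   value (or with ST = 0) are skipped with a warning.
#' @export
dtc_table <- function(table,
                      measures = c("duration_s", "n_steps",
                                   "peak_omega_head", "peak_omega_sternum",
                                   "peak_omega_pelvis"),
                      orientation = "cost") {
  stopifnot(is.data.frame(table))
  out <- list()
  skipped <- 0L
  for (m in intersect(measures, unique(table$measure))) {
    dm <- table[table$measure == m, ]
    for (sid in unique(dm$subject_id)) {
      ds <- dm[dm$subject_id == sid, ]
      st <- ds$value[ds$condition == "ST"]
      if (length(st) != 1L || is.na(st) || st == 0) { skipped <- skipped + 1L; next }
      for (dc in c("SDT", "CDT")) {
        dt <- ds$value[ds$condition == dc]
        if (length(dt) != 1L || is.na(dt)) next
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, group = ds$group[1], measure = m,
          dt_condition = dc, st_value = st, dt_value = dt,
          dtc_pct = compute_dtc(st, dt, orientation))
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " subject/measure combinations skipped (missing or zero ST value)")
  if (!length(out))
    return(data.frame(subject_id = character(0), group = character(0),
                      measure = character(0), dt_condition = character(0),
                      st_value = numeric(0), dt_value = numeric(0),
                      dtc_pct = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
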