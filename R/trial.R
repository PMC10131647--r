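#' @keywords internal
.groups <- c("young", "older", "pd", "stroke", "ms", "lbp")
#' @keywords internal
.conditions <- c("ST", "SDT", "CDT")

#' Marker labels the pipeline requires
#'
#' Three-marker clusters on head, sternum and pelvis plus heel and toe
#' markers on both feet. The cluster labels follow the convention
#' `<segment>_<1..3>`; feet are `heel_l`, `heel_r`, `toe_l`, `toe_r`.
#'
#' @return named list with elements `head`, `sternum`, `pelvis`, `feet`.
#' @export
required_marker_labels <- function() {
  list(head    = paste0("head_", 1:3),
       sternum = paste0("sternum_", 1:3),
       pelvis  = paste0("pelvis_", 1:3),
       feet    = c("heel_l", "heel_r", "toe_l", "toe_r"))
}

#' Trial record
#'
#' One recorded walking-and-turning trial: a set of marker trajectories
#' sharing one sampling rate and length, plus subject/group/condition
#' metadata. `group` is one of young, older, pd, stroke, ms, lbp; `condition`
#' is ST (single task), SDT (simple dual task: reaction-time test on a
#' smartphone) or CDT (complex dual task: numerical Stroop).
#'
#' @param subject_id subject identifier string.
#' @param group group label (see above); case-insensitive.
#' @param condition task condition, `"ST"`, `"SDT"` or `"CDT"`.
#' @param markers named list of [marker_trajectory] objects keyed by label.
#' @param meta free-form named list of clinical metadata (kept opaque).
#' @param require_labels if `TRUE` (default) fail unless every label in
#'   [required_marker_labels()] is present.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(subject_id, group, condition, markers,
                         meta = list(), require_labels = TRUE) {
  group <- tolower(group)
  condition <- toupper(condition)
  group <- match.arg(group, .groups)
  condition <- match.arg(condition, .conditions)
  stopifnot(is.list(markers), length(markers) > 0L)
  labs <- vapply(markers, function(m) m$label, character(1))
  names(markers) <- labs
  fs <- vapply(markers, function(m) m$fs, numeric(1))
  nf <- vapply(markers, n_frames, integer(1))
  if (length(unique(fs)) != 1L)
    stop("all markers in a trial must share one sampling rate")
  if (length(unique(nf)) != 1L)
    stop("all markers in a trial must share one length")
  if (require_labels) {
    need <- unlist(required_marker_labels(), use.names = FALSE)
    missing <- setdiff(need, labs)
    if (length(missing))
      stop("trial is missing required markers: ",
           paste(missing, collapse = ", "))
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         condition = condition, markers = markers, meta = meta),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  m1 <- x$markers[[1]]
  cat(sprintf(
    "<trial_record> subject %s (%s, %s): %d markers, %d frames @ %g Hz\n",
    x$subject_id, x$group, x$condition, length(x$markers),
    n_frames(m1), m1$fs))
  invisible(x)
}

#' Sampling rate of a trial
#' @param trial a `trial_record`.
#' @return sampling rate in Hz.
#' @export
trial_fs <- function(trial) trial$markers[[1]]$fs

#' Extract the marker cluster of one body segment
#' @param trial a `trial_record`.
#' @param segment `"head"`, `"sternum"` or `"pelvis"`.
#' @return list of `marker_trajectory` (the segment's >= 3 markers).
#' @export
segment_markers <- function(trial, segment) {
  segment <- match.arg(segment, c("head", "sternum", "pelvis"))
  labs <- required_marker_labels()[[segment]]
  trial$markers[labs]
}
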