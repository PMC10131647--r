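# Minimal C3D (3D motion capture container) support, Intel byte order.
# Covers what the pipeline needs: labelled 3D points at a fixed rate,
# float or scaled-integer storage, mm/m units, residual-based occlusion
# flags. Analog channels and DEC/MIPS byte orders are not supported.

C3D_PROC_INTEL <- 84L

#' Read a C3D motion-capture file
#'
#' Parses the header, the parameter section (POINT group) and the 3D point
#' data of an Intel-format C3D file. Positions are normalised to metres
#' using `POINT:UNITS` (mm is the C3D convention); samples whose residual is
#' negative (occlusions) become `NA` and stay flagged through the pipeline.
#'
#' @param path C3D file path.
#' @param subject_id,group,condition,meta trial metadata, see [trial_record()].
#' @param label_map optional named character vector renaming stored point
#'   labels onto the package convention, e.g.
#'   `c(HEAD1 = "head_1", LTOE = "toe_l")`.
#' @param require_labels if `TRUE` (default) fail, naming the absent markers,
#'   unless every label in [required_marker_labels()] is present.
#' @return a [trial_record()].
#' @export
read_c3d <- function(path, subject_id = "s01", group = "young",
                     condition = "ST", meta = list(), label_map = NULL,
                     require_labels = TRUE) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 512L) stop("corrupt C3D: file shorter than one block")
  i16 <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + 2L * n)], "integer", size = 2L, n = n,
            endian = "little")
  f32 <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + 4L * n)], "double", size = 4L, n = n,
            endian = "little")
  i8 <- function(off, n = 1L)
    readBin(raw[(off + 1L):(off + n)], "integer", size = 1L, n = n)
  u8 <- function(off, n = 1L) as.integer(raw[(off + 1L):(off + n)])

  if (u8(1L) != 0x50L) stop("corrupt C3D: bad header magic byte")
  param_block <- u8(0L)
  n_points <- i16(2L)
  first_frame <- i16(6L)
  last_frame <- i16(8L)
  hdr_scale <- f32(12L)
  data_block <- i16(16L)
  hdr_rate <- f32(20L)

  poff <- (param_block - 1L) * 512L
  if (length(raw) < poff + 4L) stop("corrupt C3D: missing parameter section")
  proc <- u8(poff + 3L)
  if (proc != C3D_PROC_INTEL)
    stop("unsupported C3D processor type ", proc, " (only Intel/",
         C3D_PROC_INTEL, " is supported)")

  params <- parse_c3d_params(raw, poff + 4L, i8, u8, i16, f32)
  point <- params[["POINT"]] %||% list()
  n_points <- point[["USED"]] %||% n_points
  fs <- point[["RATE"]] %||% hdr_rate
  scale <- point[["SCALE"]] %||% hdr_scale
  n_frames <- point[["FRAMES"]] %||% (last_frame - first_frame + 1L)
  n_frames <- as.integer(n_frames[1])
  data_block <- (point[["DATA_START"]] %||% data_block)[1]
  units <- trimws(point[["UNITS"]] %||% "mm")
  unit_scale <- switch(tolower(units), mm = 1e-3, cm = 1e-2, m = 1,
                       stop("unknown POINT:UNITS '", units, "'"))
  labels <- trimws(point[["LABELS"]] %||% character(0))
  if (length(labels) < n_points)
    labels <- c(labels, sprintf("point_%02d", seq_len(n_points - length(labels))))
  labels <- labels[seq_len(n_points)]

  doff <- (data_block - 1L) * 512L
  nval <- n_frames * n_points * 4L
  if (scale[1] < 0) {                    # float storage
    if (length(raw) < doff + 4L * nval) stop("corrupt C3D: truncated data")
    v <- f32(doff, nval)
    resid <- v[seq(4L, nval, by = 4L)]
  } else {                               # scaled-integer storage
    if (length(raw) < doff + 2L * nval) stop("corrupt C3D: truncated data")
    v <- as.numeric(i16(doff, nval))
    resid <- v[seq(4L, nval, by = 4L)]
    xyz_idx <- which(seq_len(nval) %% 4L != 0L)
    v[xyz_idx] <- v[xyz_idx] * scale[1]
  }
  arr <- array(v, dim = c(4L, n_points, n_frames))
  occluded <- matrix(resid < 0, nrow = n_points)   # n_points x n_frames

  markers <- vector("list", n_points)
  for (p in seq_len(n_points)) {
    pos <- t(arr[1:3, p, , drop = TRUE]) * unit_scale
    pos[occluded[p, ], ] <- NA_real_
    lab <- labels[p]
    if (!is.null(label_map) && lab %in% names(label_map))
      lab <- unname(label_map[[lab]])
    markers[[p]] <- marker_trajectory(lab, pos, fs = fs,
                                      t0 = (first_frame - 1L) / fs)
  }
  names(markers) <- vapply(markers, function(m) m$label, character(1))
  trial_record(subject_id, group, condition, markers, meta = meta,
               require_labels = require_labels)
}

# walk the parameter records; returns params[[GROUP]][[NAME]] -> value
parse_c3d_params <- function(raw, pos, i8, u8, i16, f32) {
  groups <- list()   # id -> name
  recs <- list()     # list of (gid, name, value)
  repeat {
    if (pos + 2L > length(raw)) break
    nchar_name <- i8(pos)
    gid <- i8(pos + 1L)
    if (nchar_name == 0L || gid == 0L) break
    nn <- abs(nchar_name)
    name <- toupper(rawToChar(raw[(pos + 3L):(pos + 2L + nn)]))
    off_pos <- pos + 2L + nn
    offset <- i16(off_pos)
    body <- off_pos + 2L
    if (gid < 0L) {                      # group record
      groups[[as.character(-gid)]] <- name
    } else {                             # parameter record
      type <- i8(body)
      ndim <- u8(body + 1L)
      dims <- if (ndim > 0L) u8(body + 2L, ndim) else integer(0)
      n <- prod(c(1L, dims))
      dpos <- body + 2L + ndim
      value <- switch(as.character(type),
        `-1` = {
          ch <- rawToChar(raw[(dpos + 1L):(dpos + n)])
          if (ndim >= 2L) {
            w <- dims[1]
            substring(ch, seq(1L, n, by = w), seq(w, n, by = w))
          } else ch
        },
        `1` = i8(dpos, n),
        `2` = i16(dpos, n),
        `4` = f32(dpos, n),
        stop("corrupt C3D: unknown parameter type ", type))
      recs[[length(recs) + 1L]] <- list(gid = gid, name = name, value = value)
    }
    if (offset == 0L) break
    pos <- off_pos + offset
  }
  params <- list()
  for (r in recs) {
    gname <- groups[[as.character(r$gid)]] %||% as.character(r$gid)
    params[[gname]][[r$name]] <- r$value
  }
  params
}

#' Write a trial to a C3D file
#'
#' Writes an Intel-format C3D with float point storage and a POINT parameter
#' group (USED, FRAMES, RATE, SCALE, DATA_START, UNITS, LABELS). Occluded
#' (`NA`) samples are stored with residual -1 per the C3D convention, so a
#' read/write round trip preserves occlusion flags.
#'
#' @param trial a [trial_record()].
#' @param path output path.
#' @param units `"mm"` (C3D convention, default) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path, units = c("mm", "m")) {
  units <- match.arg(units)
  unit_scale <- if (units == "mm") 1000 else 1
  markers <- trial$markers
  n_points <- length(markers)
  n_frames <- n_frames(markers[[1]])
  fs <- trial_fs(trial)
  labels <- names(markers)
  lw <- max(4L, max(nchar(labels)))
  pad <- function(s, w) formatC(s, width = -w)

  ch <- function(x) charToRaw(x)
  w8 <- function(...) writeBin(as.integer(c(...)), con, size = 1L)
  w16 <- function(...) writeBin(as.integer(c(...)), con, size = 2L,
                                endian = "little")
  wf <- function(...) writeBin(as.numeric(c(...)), con, size = 4L,
                               endian = "little")

  # parameter section byte stream ------------------------------------------
  rec_group <- function(name, id) {
    nm <- ch(name)
    c(as.raw(length(nm)), as.raw(bitwAnd(256L - id, 255L)), nm,
      writeBin(3L, raw(), size = 2L, endian = "little"),  # to next record
      as.raw(0L))                                    # desc len 0
  }
  rec_param <- function(name, id, type, dims, data_raw, last = FALSE) {
    nm <- ch(name)
    body <- c(writeBin(as.integer(type), raw(), size = 1L),
              as.raw(length(dims)), as.raw(dims), data_raw, as.raw(0L))
    off <- if (last) 0L else length(body) + 2L
    c(as.raw(length(nm)), as.raw(id), nm,
      writeBin(as.integer(off), raw(), size = 2L, endian = "little"), body)
  }
  r16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  rf <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
  lab_raw <- ch(paste(vapply(labels, pad, character(1), w = lw), collapse = ""))

  prm <- c(
    rec_group("POINT", 1L),
    rec_param("USED", 1L, 2L, integer(0), r16(n_points)),
    rec_param("FRAMES", 1L, 2L, integer(0), r16(n_frames)),
    rec_param("RATE", 1L, 4L, integer(0), rf(fs)),
    rec_param("SCALE", 1L, 4L, integer(0), rf(-1)),
    rec_param("UNITS", 1L, -1L, nchar(units), ch(units)),
    rec_param("LABELS", 1L, -1L, c(lw, n_points), lab_raw))
  n_param_blocks <- ceiling((length(prm) + 4L) / 512)
  data_start <- 2L + n_param_blocks
  # DATA_START must be known before serialisation; append it last
  prm <- c(prm, rec_param("DATA_START", 1L, 2L, integer(0), r16(data_start),
                          last = TRUE))
  n_param_blocks2 <- ceiling((length(prm) + 4L) / 512)
  if (n_param_blocks2 > n_param_blocks) {            # crossed a block boundary
    data_start <- 2L + n_param_blocks2
    prm[length(prm) - 2L + 0:1] <- r16(data_start)   # patch the int16 payload
  }

  con <- file(path, "wb")
  on.exit(close(con))
  # header block ------------------------------------------------------------
  w8(2L, 0x50L)                    # parameter section at block 2, magic
  w16(n_points, 0L, 1L, n_frames, 10L)
  wf(-1)                           # POINT scale (negative: float data)
  w16(data_start, 0L)
  wf(fs)
  writeBin(raw(512L - 24L), con)
  # parameter section ---------------------------------------------------------
  w8(1L, 0x50L, ceiling((length(prm) + 4L) / 512), C3D_PROC_INTEL)
  writeBin(prm, con)
  npad <- (512L - (length(prm) + 4L) %% 512L) %% 512L
  writeBin(raw(npad), con)
  # data section --------------------------------------------------------------
  arr <- array(0, dim = c(4L, n_points, n_frames))
  for (p in seq_len(n_points)) {
    pos <- markers[[p]]$positions * unit_scale
    occ <- !stats::complete.cases(pos)
    pos[occ, ] <- 0
    arr[1:3, p, ] <- t(pos)
    arr[4L, p, ] <- ifelse(occ, -1, 0)
  }
  wf(as.numeric(arr))
  invisible(path)
}
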