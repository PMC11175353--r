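#' @name formats
#' @title File formats
#'
#' @description
#' Two interchange formats are supported. YOLO labels: per-frame text files,
#' one object per line, `class cx cy w h` with centre/size normalised to
#' `[0, 1]` and written at 6-decimal fixed point; frame numbering in file
#' names is 0-based. MOTChallenge records: comma-delimited
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,-1,-1,-1` with 1-based
#' frames, `id = -1` for raw detections, box fields at 2 decimals and
#' confidence at 6. Readers reject malformed input with the file and line
#' named rather than skipping silently.
NULL

#' Read one YOLO label file
#'
#' @param path Label file (5 whitespace-separated fields per line).
#' @param img_w,img_h Frame size in pixels used to denormalise.
#' @return `data.frame(class_id, x1, y1, x2, y2)`; empty for an empty file.
#' @export
read_yolo_labels <- function(path, img_w, img_h) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("%s:%d: expected 5 fields, got %d", path, i,
                   length(parts)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop(sprintf("%s:%d: non-numeric field", path, i), call. = FALSE)
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stop(sprintf("%s:%d: normalised values outside [0, 1]", path, i),
           call. = FALSE)
    if (vals[4] <= 0 || vals[5] <= 0)
      stop(sprintf("%s:%d: nonpositive box size", path, i), call. = FALSE)
    cx <- vals[2] * img_w; cy <- vals[3] * img_h
    w <- vals[4] * img_w; h <- vals[5] * img_h
    out[nrow(out) + 1L, ] <- list(as.integer(vals[1]), cx - w / 2,
                                  cy - h / 2, cx + w / 2, cy + h / 2)
  }
  out
}

#' Write one YOLO label file
#'
#' @param boxes `data.frame(class_id, x1, y1, x2, y2)` in pixels.
#' @param img_w,img_h Frame size used to normalise.
#' @param path Output file.
#' @return `path`, invisibly. An empty data frame writes an empty file.
#' @export
write_yolo_labels <- function(boxes, img_w, img_h, path) {
  lines <- character(0)
  if (nrow(boxes)) {
    cx <- (boxes$x1 + boxes$x2) / 2 / img_w
    cy <- (boxes$y1 + boxes$y2) / 2 / img_h
    w <- (boxes$x2 - boxes$x1) / img_w
    h <- (boxes$y2 - boxes$y1) / img_h
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MOTChallenge file (ground truth, detections or tracks)
#'
#' @param path Comma-delimited file with at least 7 fields per line.
#' @return `data.frame(frame, id, x1, y1, x2, y2, conf)`; `id` is -1 for
#'   detection files.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  out <- data.frame(frame = integer(n), id = integer(n), x1 = numeric(n),
                    y1 = numeric(n), x2 = numeric(n), y2 = numeric(n),
                    conf = numeric(n))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 7L)
      stop(sprintf("%s:%d: expected at least 7 comma-separated fields",
                   path, i), call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts[1:7]))
    if (anyNA(vals))
      stop(sprintf("%s:%d: non-numeric field", path, i), call. = FALSE)
    if (vals[1] < 1)
      stop(sprintf("%s:%d: frames are 1-based", path, i), call. = FALSE)
    if (vals[5] <= 0 || vals[6] <= 0)
      stop(sprintf("%s:%d: nonpositive box size", path, i), call. = FALSE)
    out$frame[i] <- as.integer(vals[1]); out$id[i] <- as.integer(vals[2])
    out$x1[i] <- vals[3]; out$y1[i] <- vals[4]
    out$x2[i] <- vals[3] + vals[5]; out$y2[i] <- vals[4] + vals[6]
    out$conf[i] <- vals[7]
  }
  out
}

#' Write a MOTChallenge file
#'
#' @param df `data.frame(frame, id, x1, y1, x2, y2)` with optional `conf`
#'   (default 1). Use `id = -1` for raw detections.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mot <- function(df, path) {
  conf <- if ("conf" %in% names(df)) df$conf else rep(1, nrow(df))
  lines <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.6f,-1,-1,-1",
                   as.integer(df$frame), as.integer(df$id),
                   df$x1, df$y1, df$x2 - df$x1, df$y2 - df$y1, conf)
  writeLines(lines, path)
  invisible(path)
}

#' Read detections (MOT format) with an optional embeddings table
#'
#' The embeddings table is delimited text with header
#' `frame,det_index,e1,...,eD`; `det_index` is the 1-based index of the
#' detection within its frame, in file order.
#'
#' @param det_path MOT-format detection file.
#' @param embeddings_path Optional embeddings CSV.
#' @return A `"detection_set"` consumable by [tracker_run()].
#' @export
read_detections <- function(det_path, embeddings_path = NULL) {
  df <- read_mot(det_path)
  df$class_id <- 0L
  df$gt_id <- NA_integer_
  df <- df[order(df$frame), , drop = FALSE]
  emb <- NULL
  if (!is.null(embeddings_path)) {
    tab <- utils::read.csv(embeddings_path)
    if (ncol(tab) < 3L)
      stop("embeddings table needs frame, det_index and value columns",
           call. = FALSE)
    # align rows with the detections in (frame, within-frame index) order
    key_det <- paste(df$frame, stats::ave(df$frame, df$frame,
                                          FUN = seq_along))
    key_emb <- paste(tab[[1]], tab[[2]])
    idx <- match(key_det, key_emb)
    if (anyNA(idx))
      stop("embeddings table does not cover every detection", call. = FALSE)
    emb <- as.matrix(tab[idx, -(1:2), drop = FALSE])
    emb <- emb / sqrt(rowSums(emb^2))
  }
  structure(list(detections = df, embeddings = emb,
                 n_frames = max(df$frame, 0L)),
            class = "detection_set")
}

#' Export a simulation to disk
#'
#' Writes per-frame YOLO label files (`labels/frame_%06d.txt`, 0-based
#' frame numbers), MOT-format `gt.txt` and `det.txt`, and `embeddings.csv`;
#' optionally renders PNG frames (requires the `png` package).
#'
#' @param gt A `"ground_truth_set"`.
#' @param dets A `"detection_set"` (optional).
#' @param dir Output directory (created if needed).
#' @param render Render grayscale PNG frames under `frames/`?
#' @return `dir`, invisibly.
#' @export
export_simulation <- function(gt, dets = NULL, dir, render = FALSE) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  labdir <- file.path(dir, "labels")
  dir.create(labdir, showWarnings = FALSE)
  cfg <- gt$cfg
  for (f in seq_len(cfg$n_frames)) {
    rows <- gt$traj[gt$traj$frame == f, , drop = FALSE]
    write_yolo_labels(rows, cfg$width, cfg$height,
                      file.path(labdir, sprintf("frame_%06d.txt", f - 1L)))
  }
  write_mot(gt$traj, file.path(dir, "gt.txt"))
  if (!is.null(dets)) {
    d <- dets$detections
    d$id <- -1L
    write_mot(d, file.path(dir, "det.txt"))
    if (!is.null(dets$embeddings)) {
      det_index <- stats::ave(d$frame, d$frame, FUN = seq_along)
      tab <- data.frame(frame = d$frame, det_index = det_index)
      emb <- as.data.frame(dets$embeddings)
      names(emb) <- paste0("e", seq_len(ncol(emb)))
      utils::write.csv(cbind(tab, emb),
                       file.path(dir, "embeddings.csv"), row.names = FALSE)
    }
  }
  if (render) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("rendering PNG frames requires the 'png' package", call. = FALSE)
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    imgs <- render_frames(gt)
    for (f in seq_along(imgs))
      png::writePNG(imgs[[f]],
                    file.path(fdir, sprintf("frame_%06d.png", f - 1L)))
  }
  invisible(dir)
}

#' Convert a trajectory data frame between pixel corners and MOT fields
#'
#' Round-trips through [write_mot()]/[read_mot()] preserve boxes to the
#' format's 2-decimal precision.
#'
#' @param report An `"evaluation_report"`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$per_alpha <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
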