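#' Read an image sequence from disk
#'
#' Accepts a multi-page TIFF or a directory of lexicographically ordered
#' PNG/TIFF frames. RGB frames are converted to gray by Rec. 709 luminance.
#' Intensities are returned on the `[0, 255]` scale. If a JSON sidecar
#' `<path-sans-ext>.json` exists, `frame_interval`, `scale` and `exam_id`
#' are taken from it unless given explicitly.
#'
#' @param path File or directory.
#' @param frame_interval,scale,exam_id Overrides for the sidecar values;
#'   `frame_interval` defaults to `30/139` ms.
#' @return An [image_sequence()].
#' @export
read_sequence <- function(path, frame_interval = NULL, scale = NULL,
                          exam_id = NULL) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3)
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    a * 255
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2)
      stop("need at least two frames in ", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE))
        to_gray(png::readPNG(f))
      else to_gray(tiff::readTIFF(f))
    })
    sidecar <- file.path(path, "sidecar.json")
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2) stop("need at least two frames in ", path)
    frames <- lapply(pages, to_gray)
    sidecar <- sub("\\.[^.]+$", ".json", path)
  }
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  image_sequence(
    frames,
    frame_interval = frame_interval %||% meta$frame_interval %||% (30 / 139),
    scale = scale %||% meta$scale,
    exam_id = exam_id %||% meta$exam_id %||%
      sub("\\.[^.]+$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image sequence as a multi-page 16-bit TIFF
#'
#' Sequences rendered by [render_sequence()] are quantized to the 16-bit
#' gray grid, so write followed by [read_sequence()] reproduces the pixel
#' content exactly. A JSON sidecar with frame interval, scale, exam id and
#' the configuration hash is written next to the file.
#'
#' @param sequence An [image_sequence()].
#' @param path Output `.tif` path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @param config Optional `sim_config` recorded in the sidecar.
#' @export
write_sequence <- function(sequence, path, sidecar = TRUE, config = NULL) {
  tiff::writeTIFF(lapply(sequence$frames, function(f) f / 255), path,
                  bits.per.sample = 16, compression = "none")
  if (sidecar) {
    meta <- list(exam_id = sequence$exam_id,
                 frame_interval = sequence$frame_interval,
                 scale = sequence$scale,
                 n_frames = length(sequence$frames),
                 config_hash = if (is.null(config)) NULL
                 else config_hash(config))
    if (!is.null(config)) meta$config <- unclass(config)
    jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Short configuration hash
#'
#' Stable content hash recorded in every artifact a stage writes, so that
#' downstream stages can reject inputs produced under a different
#' configuration.
#' @param x Any serializable object.
#' @return Character scalar.
#' @export
config_hash <- function(x) rlang::hash(x)

#' Save / load a field history archive
#'
#' Field histories (displacement, strain, rate objects) are stored as
#' compressed R serializations carrying a content hash; `load_field()` can
#' verify the hash against an expected value and rejects mismatches.
#'
#' @param field Any field object (`dic_field`, `strain_field`, ...).
#' @param path Output `.rds` path.
#' @export
save_field <- function(field, path) {
  obj <- list(field = field, hash = config_hash(field))
  saveRDS(obj, path)
  invisible(obj$hash)
}

#' @rdname save_field
#' @param expect_hash If non-`NULL`, error unless the archive hash matches.
#' @export
load_field <- function(path, expect_hash = NULL) {
  obj <- readRDS(path)
  if (config_hash(obj$field) != obj$hash)
    stop("field archive is corrupted: ", path)
  if (!is.null(expect_hash) && obj$hash != expect_hash)
    stop("field archive hash mismatch: ", path)
  obj$field
}

#' Write / read evolution curves as CSV
#'
#' One row per frame; columns `frame` plus the eight curves. The exam id
#' travels in a `# exam_id:` comment line.
#'
#' @param curves An [extract_evolution_curves()] frame.
#' @param path CSV path.
#' @export
write_curves <- function(curves, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exam_id: %s", attr(curves, "exam_id") %||% ""), con)
  write.csv(curves, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  first <- readLines(path, n = 1)
  id <- if (startsWith(first, "# exam_id:"))
    trimws(sub("# exam_id:", "", first)) else ""
  out <- read.csv(path, comment.char = "#")
  attr(out, "exam_id") <- id
  class(out) <- c("evolution_curves", "data.frame")
  out
}

#' Write a rendered cohort to disk
#'
#' One multi-page TIFF + JSON sidecar per exam and a `manifest.csv` with
#' columns `exam_id`, `label`, `path`.
#'
#' @param cohort A rendered (`fast = FALSE`) cohort.
#' @param dir Output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(k) {
    e <- cohort[[k]]
    if (is.null(e$sequence))
      stop("write_cohort needs a rendered cohort (fast = FALSE)")
    fn <- sprintf("exam-%03d.tif", k)
    write_sequence(e$sequence, file.path(dir, fn), config = e$config)
    data.frame(exam_id = e$sequence$exam_id, label = e$label, path = fn)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_manifest <- function(dir) {
  read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
}

#' Write an evaluation report as JSON
#'
#' Serializes a [evaluate_bundle()] report (confusion matrices, metrics,
#' AUC; ROC points are written separately as CSV when `roc_csv` is given).
#'
#' @param report A `bundle_report`.
#' @param path JSON path.
#' @param roc_csv Optional path for the concatenated ROC points.
#' @param extra Named list merged into the JSON root (e.g. config hash).
#' @export
write_report <- function(report, path, roc_csv = NULL, extra = list()) {
  body <- list(dataset = report$dataset,
               models = lapply(report$reports, function(r) {
                 list(model = r$model,
                      confusion = r$cm[c("tp", "fp", "tn", "fn")],
                      accuracy = r$accuracy, precision = r$precision,
                      recall = r$recall, f1 = r$f1,
                      sensitivity = r$sensitivity,
                      specificity = r$specificity, auc = r$auc)
               }))
  jsonlite::write_json(c(extra, body), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(roc_csv)) {
    pts <- do.call(rbind, lapply(report$reports, function(r) {
      if (is.null(r$roc)) return(NULL)
      cbind(model = r$model, r$roc$points)
    }))
    write.csv(pts, roc_csv, row.names = FALSE)
  }
  invisible(path)
}
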