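#' Read and write YOLO-format label files
#'
#' The YOLO text format stores one box per line as
#' `class cx cy w h [confidence]`, whitespace-separated, with center and
#' size normalized to the image dimensions. These helpers convert to and
#' from the package's corner-format box tibbles; the image size must be
#' supplied explicitly for the (de)normalization.
#'
#' @param path File path (one file per image).
#' @param image_width,image_height Image size in pixels.
#' @return `read_yolo()` returns a tibble `class_id, x1, y1, x2, y2` plus
#'   `confidence` when the file carries a sixth column; an empty file
#'   yields zero rows.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_yolo(boxes(10, 10, 30, 50), f, 320, 320)
#' read_yolo(f, 320, 320)
#' @export
read_yolo <- function(path, image_width, image_height) {
  stopifnot(image_width > 0, image_height > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(class_id = integer(), x1 = numeric(),
                          y1 = numeric(), x2 = numeric(), y2 = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1 || !ncols %in% c(5, 6)) {
    stop("YOLO label lines must have 5 or 6 whitespace-separated fields",
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE)
  cx <- m[, 2] * image_width; cy <- m[, 3] * image_height
  w <- m[, 4] * image_width; h <- m[, 5] * image_height
  out <- tibble::tibble(class_id = as.integer(m[, 1]),
                        x1 = cx - w / 2, y1 = cy - h / 2,
                        x2 = cx + w / 2, y2 = cy + h / 2)
  if (ncols == 6) out$confidence <- m[, 6]
  out
}

#' @rdname read_yolo
#' @param b Box tibble (`x1, y1, x2, y2`; optional `class_id` and
#'   `confidence` columns are carried through).
#' @export
write_yolo <- function(b, path, image_width, image_height) {
  validate_boxes(b, allow_degenerate = TRUE)
  stopifnot(image_width > 0, image_height > 0)
  class_id <- if ("class_id" %in% names(b)) b$class_id else rep(0L, nrow(b))
  cx <- (b$x1 + b$x2) / 2 / image_width
  cy <- (b$y1 + b$y2) / 2 / image_height
  w <- (b$x2 - b$x1) / image_width
  h <- (b$y2 - b$y1) / image_height
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  lines <- paste(class_id, fmt(cx), fmt(cy), fmt(w), fmt(h))
  if ("confidence" %in% names(b)) {
    lines <- paste(lines, fmt(b$confidence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write plain-CSV box tables
#'
#' Corner-format CSV with header `x1,y1,x2,y2` (extra columns such as
#' `confidence` or `image_id` pass through).
#'
#' @param path File path.
#' @return A validated box tibble.
#' @export
read_boxes_csv <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE)
  validate_boxes(b, allow_degenerate = TRUE)
  b
}

#' @rdname read_boxes_csv
#' @param b Box tibble.
#' @export
write_boxes_csv <- function(b, path) {
  validate_boxes(b, allow_degenerate = TRUE)
  readr::write_csv(b, path)
  invisible(path)
}

#' Evaluate directories of YOLO-format predictions against ground truth
#'
#' Pairs files by name between a ground-truth directory and a prediction
#' directory (predictions carry a confidence column), denormalizes with the
#' given image size, and runs [evaluate_detections()] over the pooled
#' detections with per-file image identities.
#'
#' @param gt_dir,pred_dir Directories of `.txt` YOLO label files with
#'   matching names.
#' @param image_width,image_height Image size in pixels.
#' @param thresholds IoU thresholds (see [evaluate_detections()]).
#' @return A `detection_eval` object.
#' @export
evaluate_yolo_dirs <- function(gt_dir, pred_dir, image_width, image_height,
                               thresholds = seq(0.5, 0.9, by = 0.05)) {
  gt_files <- sort(list.files(gt_dir, pattern = "\\.txt$"))
  if (length(gt_files) == 0) stop("no .txt files in gt_dir", call. = FALSE)
  gts <- list(); dets <- list()
  for (i in seq_along(gt_files)) {
    f <- gt_files[i]
    g <- read_yolo(file.path(gt_dir, f), image_width, image_height)
    g$image_id <- i
    gts[[i]] <- g
    pf <- file.path(pred_dir, f)
    if (file.exists(pf)) {
      d <- read_yolo(pf, image_width, image_height)
      if (nrow(d) > 0 && !"confidence" %in% names(d)) {
        stop(sprintf("prediction file %s has no confidence column", f),
             call. = FALSE)
      }
      d$image_id <- i
      dets[[i]] <- d
    }
  }
  evaluate_detections(dplyr::bind_rows(dets), dplyr::bind_rows(gts),
                      thresholds = thresholds)
}
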