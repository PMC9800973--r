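# Image and label I/O, geometry helpers, and the single-image detection
# pipeline. Images are numeric HWC arrays (height x width x 3) in [0,1];
# labels follow the YOLO text convention: one "class cx cy w h" line per
# object with 0-based class and coordinates normalized to the image.

#' Read an RGB image (PNG)
#' @param path file path
#' @return numeric HWC array in \[0,1\] with 3 channels
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image (PNG)
#' @param img numeric HWC array in \[0,1\]
#' @param path file path
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read YOLO-format labels
#' @param path label text file; a missing or empty file yields zero rows
#' @return data.frame with columns class, cx, cy, w, h (normalized)
#' @export
read_labels <- function(path) {
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  d <- utils::read.table(path, col.names = c("class", "cx", "cy", "w", "h"))
  d$class <- as.integer(d$class)
  d
}

#' Write YOLO-format labels
#' @param labels data.frame with columns class, cx, cy, w, h
#' @param path output file
#' @export
write_labels <- function(labels, path) {
  if (!nrow(labels)) {
    cat("", file = path)
    return(invisible(path))
  }
  lines <- sprintf("%d %.17g %.17g %.17g %.17g", labels$class, labels$cx,
                   labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalized labels to pixel boxes
#' @param labels data.frame (class, cx, cy, w, h)
#' @param width,height image dimensions in pixels
#' @return data.frame (class, x1, y1, x2, y2)
#' @export
labels_to_boxes <- function(labels, width, height) {
  data.frame(class = labels$class,
             x1 = (labels$cx - labels$w / 2) * width,
             y1 = (labels$cy - labels$h / 2) * height,
             x2 = (labels$cx + labels$w / 2) * width,
             y2 = (labels$cy + labels$h / 2) * height)
}

#' Convert pixel boxes to normalized labels
#' @param boxes data.frame (class, x1, y1, x2, y2)
#' @param width,height image dimensions in pixels
#' @return data.frame (class, cx, cy, w, h)
#' @export
boxes_to_labels <- function(boxes, width, height) {
  data.frame(class = boxes$class,
             cx = (boxes$x1 + boxes$x2) / 2 / width,
             cy = (boxes$y1 + boxes$y2) / 2 / height,
             w = (boxes$x2 - boxes$x1) / width,
             h = (boxes$y2 - boxes$y1) / height)
}

#' Read one split of a dataset directory
#'
#' Layout: `images/<split>/*.png` paired with `labels/<split>/*.txt`.
#' @param dir dataset root
#' @param split split name
#' @return list of samples, each `list(id, image, labels)`
#' @export
read_dataset_split <- function(dir, split) {
  img_dir <- file.path(dir, "images", split)
  lab_dir <- file.path(dir, "labels", split)
  if (!dir.exists(img_dir)) stop("no such split directory: ", img_dir)
  files <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no images found under ", img_dir)
  lapply(files, function(f) {
    id <- sub("\\.png$", "", basename(f))
    lab <- file.path(lab_dir, paste0(id, ".txt"))
    list(id = id, image = read_image(f), labels = read_labels(lab))
  })
}

#' Bilinear image resize
#' @param img numeric HWC array
#' @param height,width target size
#' @return resized HWC array
#' @export
resize_image <- function(img, height, width) {
  d <- dim(img)
  sy <- d[1] / height; sx <- d[2] / width
  yc <- pmin(pmax((seq_len(height) - 0.5) * sy - 0.5, 0), d[1] - 1)
  xc <- pmin(pmax((seq_len(width) - 0.5) * sx - 0.5, 0), d[2] - 1)
  y0 <- floor(yc); x0 <- floor(xc)
  wy <- yc - y0; wx <- xc - x0
  y0 <- as.integer(y0) + 1L; x0 <- as.integer(x0) + 1L
  y1 <- pmin(y0 + 1L, d[1]); x1 <- pmin(x0 + 1L, d[2])
  tmp <- img[y0, , , drop = FALSE] * (1 - wy) + img[y1, , , drop = FALSE] * wy
  wxm <- rep(wx, each = height)
  tmp[, x0, , drop = FALSE] * (1 - wxm) + tmp[, x1, , drop = FALSE] * wxm
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving resize followed by symmetric gray padding
#' (value 114/255).
#'
#' @param img numeric HWC array
#' @param size target square side
#' @param fill padding intensity
#' @return list: `image` (size x size x 3), `scale`, `pad_x`, `pad_y` (the
#'   mapping original -> letterboxed is `p * scale + pad`)
#' @export
letterbox <- function(img, size, fill = 114 / 255) {
  d <- dim(img)
  scale <- min(size / d[1], size / d[2])
  nh <- round(d[1] * scale); nw <- round(d[2] * scale)
  resized <- if (nh == d[1] && nw == d[2]) img else resize_image(img, nh, nw)
  out <- array(fill, c(size, size, 3L))
  py <- (size - nh) %/% 2L; px <- (size - nw) %/% 2L
  out[py + seq_len(nh), px + seq_len(nw), ] <- resized
  list(image = out, scale = scale, pad_x = px, pad_y = py)
}

#' Detect objects in a single image
#'
#' Letterboxes the image to the model input size, runs the forward pass,
#' decodes the three scales and suppresses duplicates with Gaussian
#' Soft-NMS (the default) or classical NMS. Box coordinates are mapped back
#' to the original image frame.
#'
#' @param model a [pest_model]
#' @param img numeric HWC array in \[0,1\]
#' @param conf_thr decode confidence threshold
#' @param method `"soft"` (Gaussian Soft-NMS) or `"hard"` (classical NMS)
#' @param alpha Soft-NMS Gaussian width
#' @param iou_thr hard-NMS suppression threshold
#' @param final_thr Soft-NMS final score cutoff
#' @param max_det keep at most this many detections
#' @return detection data.frame (class, score, x1, y1, x2, y2)
#' @export
detect_image <- function(model, img, conf_thr = 0.001,
                         method = c("soft", "hard"), alpha = 0.5,
                         iou_thr = 0.45, final_thr = 0.001, max_det = 300L) {
  method <- match.arg(method)
  size <- model$cfg$input_size
  lb <- letterbox(img, size)
  raw <- model_forward(model, lb$image, training = FALSE)
  dets <- decode_predictions(raw, model$cfg$anchors, conf_thr, size)
  if (nrow(dets)) {
    dets <- if (method == "soft") soft_nms(dets, alpha, final_thr)
            else nms(dets, iou_thr)
    if (nrow(dets) > max_det) dets <- dets[seq_len(max_det), , drop = FALSE]
    dets$x1 <- (dets$x1 - lb$pad_x) / lb$scale
    dets$x2 <- (dets$x2 - lb$pad_x) / lb$scale
    dets$y1 <- (dets$y1 - lb$pad_y) / lb$scale
    dets$y2 <- (dets$y2 - lb$pad_y) / lb$scale
    d <- dim(img)
    dets$x1 <- pmin(pmax(dets$x1, 0), d[2]); dets$x2 <- pmin(pmax(dets$x2, 0), d[2])
    dets$y1 <- pmin(pmax(dets$y1, 0), d[1]); dets$y2 <- pmin(pmax(dets$y2, 0), d[1])
  }
  dets
}
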