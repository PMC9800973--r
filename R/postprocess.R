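# Box geometry and suppression of redundant detections. Boxes are
# axis-aligned (x1, y1, x2, y2), origin top-left, half-open. Soft-NMS
# follows the Gaussian rescoring rule: each neighbour of the current
# highest-scoring box of the same class is rescored
#   S_i <- S_i * exp(-IoU(Bbox_max, bbox_i) / alpha^2)
# with alpha = 0.5 by default, instead of being removed outright.

check_box <- function(b, arg = "box") {
  if (length(b) < 4L || any(!is.finite(b[1:4])))
    stop(arg, " must be four finite numbers (x1, y1, x2, y2)")
  invisible(b)
}

box_area <- function(b) pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 vectors (x1, y1, x2, y2)
#' @return IoU in \[0,1\]; 0 for disjoint or degenerate (zero-area) boxes
#'   (degenerate input logs a warning)
#' @export
box_iou <- function(a, b) {
  check_box(a, "a"); check_box(b, "b")
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  if (aa <= 0 || ab <= 0) {
    warning("degenerate (zero-area) box; IoU defined as 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (aa + ab - inter)
}

#' Generalized IoU of two boxes
#'
#' IoU minus the fraction of the smallest enclosing box not covered by the
#' union; ranges over \[-1, 1\] and stays informative for disjoint boxes.
#'
#' @inheritParams box_iou
#' @return GIoU in \[-1, 1\]
#' @export
box_giou <- function(a, b) {
  check_box(a, "a"); check_box(b, "b")
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- aa + ab - inter
  iou <- if (union > 0) inter / union else 0
  ew <- max(a[3], b[3]) - min(a[1], b[1])
  eh <- max(a[4], b[4]) - min(a[2], b[2])
  enc <- ew * eh
  if (enc <= 0) return(iou)
  iou - (enc - union) / enc
}

# vectorized IoU of one box against a matrix of boxes
iou_one_many <- function(a, B) {
  iw <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  ih <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- iw * ih
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  u <- aa + ab - inter
  ifelse(u > 0, inter / u, 0)
}

check_detections <- function(dets) {
  need <- c("class", "score", "x1", "y1", "x2", "y2")
  if (!is.data.frame(dets) || !all(need %in% names(dets)))
    stop("detections must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(dets) && (any(dets$score < 0) || any(dets$score > 1)))
    stop("detection scores must lie in [0, 1]")
  invisible(dets)
}

#' Classical greedy non-maximum suppression (per class)
#'
#' Repeatedly keeps the highest-scoring box of a class and removes all
#' remaining boxes of that class whose IoU with it exceeds `iou_thr`.
#'
#' @param dets detection data.frame (class, score, x1, y1, x2, y2)
#' @param iou_thr suppression threshold in (0, 1)
#' @return the kept detections, sorted by score descending
#' @export
nms <- function(dets, iou_thr = 0.45) {
  check_detections(dets)
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must lie in (0, 1)")
  if (!nrow(dets)) return(dets)
  out <- vector("list", 0L)
  for (cl in unique(dets$class)) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    B <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, nrow(d))
    sel <- integer(0)
    while (any(alive)) {
      i <- which(alive)[1L]
      sel <- c(sel, i)
      alive[i] <- FALSE
      rest <- which(alive)
      if (length(rest)) {
        ious <- iou_one_many(B[i, ], B[rest, , drop = FALSE])
        alive[rest[ious > iou_thr]] <- FALSE
      }
    }
    out[[length(out) + 1L]] <- d[sel, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res[order(-res$score), , drop = FALSE]
}

#' Gaussian Soft-NMS rescoring (per class)
#'
#' Greedy pass over each class: the unprocessed box with the highest
#' current score is fixed, and every remaining box of the class is rescored
#' by the Gaussian penalty `exp(-IoU / alpha^2)`. Boxes whose final score
#' falls below `final_thr` are dropped; no score ever increases.
#'
#' @param dets detection data.frame (class, score, x1, y1, x2, y2)
#' @param alpha Gaussian width hyperparameter (> 0); 0.5 by default
#' @param final_thr minimum final score kept
#' @return rescored detections sorted by final score descending
#' @export
soft_nms <- function(dets, alpha = 0.5, final_thr = 0.001) {
  check_detections(dets)
  if (alpha <= 0) stop("alpha must be > 0")
  if (!nrow(dets)) return(dets)
  out <- vector("list", 0L)
  for (cl in unique(dets$class)) {
    d <- dets[dets$class == cl, , drop = FALSE]
    B <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    s <- d$score
    done <- rep(FALSE, nrow(d))
    while (!all(done)) {
      i <- which(!done)[which.max(s[!done])]
      done[i] <- TRUE
      rest <- which(!done)
      if (length(rest)) {
        ious <- iou_one_many(B[i, ], B[rest, , drop = FALSE])
        s[rest] <- s[rest] * exp(-ious / alpha^2)
      }
    }
    d$score <- s
    out[[length(out) + 1L]] <- d[s >= final_thr, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res[order(-res$score), , drop = FALSE]
}

#' Write detections as delimited text
#'
#' Tab-separated columns: image, class, score, x1, y1, x2, y2.
#' @param dets detection data.frame; an `image` column is added as "0" when
#'   absent
#' @param path output file
#' @export
write_detections <- function(dets, path) {
  d <- dets
  if (is.null(d$image)) d$image <- "0"
  d <- d[, c("image", "class", "score", "x1", "y1", "x2", "y2")]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read detections written by [write_detections()]
#' @param path input file
#' @return detection data.frame with an `image` column
#' @export
read_detections <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "numeric",
                                        "numeric", "numeric", "numeric", "numeric"))
  check_detections(d)
  d
}
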