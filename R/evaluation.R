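# Detection evaluation: greedy score-ordered matching, average precision as
# the area under the monotone precision envelope, mAP@0.5 and
# mAP@[0.5:0.95] over the ten IoU thresholds 0.50, 0.55, ..., 0.95, and the
# noise-robustness harness (salt-&-pepper and Gaussian corruption sweeps).

#' Match detections to ground truth at one IoU threshold
#'
#' Detections are processed in score order; each is a true positive iff its
#' best IoU with a still-unmatched ground-truth box of the same class (and
#' image, when an `image` column is present) reaches `iou_thr`. Every
#' ground truth matches at most once; unmatched ground truths are misses.
#'
#' @param dets detection data.frame (class, score, x1..y2, optional image)
#' @param gts ground-truth data.frame (class, x1..y2, optional image)
#' @param iou_thr matching threshold
#' @return list: `tp` logical per detection (in score order), `order` the
#'   row permutation used, `fn` count of unmatched ground truths
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  if (is.null(dets$image)) dets$image <- "0"
  if (is.null(gts$image)) gts$image <- "0"
  ord <- order(-dets$score)
  d <- dets[ord, , drop = FALSE]
  matched <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(d))
  if (nrow(d)) {
    G <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nrow(d))) {
      cand <- which(!matched & gts$class == d$class[i] & gts$image == d$image[i])
      if (!length(cand)) next
      ious <- iou_one_many(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                           G[cand, , drop = FALSE])
      j <- which.max(ious)
      if (ious[j] >= iou_thr) {
        tp[i] <- TRUE
        matched[cand[j]] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, fn = sum(!matched))
}

#' Precision-recall curve from score-ordered match flags
#'
#' @param tp logical vector of per-detection true-positive flags, already
#'   in descending score order
#' @param n_gt number of ground-truth instances of the class
#' @return data.frame with cumulative recall and precision per step
#' @export
pr_curve <- function(tp, n_gt) {
  if (n_gt <= 0) stop("pr_curve needs at least one ground truth")
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  data.frame(recall = ctp / n_gt, precision = ctp / pmax(ctp + cfp, 1))
}

#' Average precision (area under the monotone precision envelope)
#'
#' All-point interpolation of the integral of precision over recall: the
#' precision at each recall level is replaced by the maximum precision at
#' any equal-or-higher recall, and the envelope is integrated exactly.
#' A 101-point interpolation is available for cross-checking.
#'
#' @param curve data.frame from [pr_curve()]
#' @param interpolation `"all"` (exact envelope area) or `"101"`
#' @return AP in \[0,1\]
#' @export
average_precision <- function(curve, interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  if (!nrow(curve)) return(0)
  r <- c(0, curve$recall)
  p <- c(0, curve$precision)
  # monotone non-increasing envelope from the right
  env <- rev(cummax(rev(p)))
  if (interpolation == "101") {
    grid <- seq(0, 1, length.out = 101L)
    vals <- vapply(grid, function(g) {
      ok <- which(r >= g)
      if (length(ok)) max(p[min(ok):length(p)]) else 0
    }, numeric(1))
    return(mean(vals))
  }
  sum(diff(r) * env[-1])
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP at each IoU threshold in {0.50, ..., 0.95}, the
#' per-class AP50:95 average, and the class means mAP@0.5 and
#' mAP@\[0.5:0.95\]. Classes absent from the ground truth are excluded from
#' the means (and listed in `skipped_classes`).
#'
#' @param dets detection data.frame (class, score, x1..y2, optional image)
#' @param gts ground-truth data.frame (class, x1..y2, optional image)
#' @param num_classes total number of classes (class ids 0-based)
#' @param interpolation passed to [average_precision()]
#' @return list of class `eval_report`: `ap` (class x threshold matrix),
#'   `ap5095` per class, `map50`, `map5095`, `skipped_classes`
#' @export
evaluate_detections <- function(dets, gts, num_classes,
                                interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(NA_real_, num_classes, length(thrs),
               dimnames = list(paste0("class", 0:(num_classes - 1)),
                               sprintf("ap%.0f", thrs * 100)))
  present <- sort(unique(gts$class))
  for (cl in present) {
    g_cl <- gts[gts$class == cl, , drop = FALSE]
    d_cl <- dets[dets$class == cl, , drop = FALSE]
    for (t in seq_along(thrs)) {
      if (!nrow(d_cl)) { ap[cl + 1L, t] <- 0; next }
      m <- match_detections(d_cl, g_cl, thrs[t])
      ap[cl + 1L, t] <- average_precision(pr_curve(m$tp, nrow(g_cl)),
                                          interpolation)
    }
  }
  ap5095 <- rowMeans(ap)
  skipped <- setdiff(0:(num_classes - 1), present)
  if (length(skipped))
    message("classes absent from ground truth excluded from means: ",
            paste(skipped, collapse = ", "))
  structure(list(
    ap = ap, ap5095 = ap5095,
    map50 = mean(ap[present + 1L, 1L]),
    map5095 = mean(ap5095[present + 1L]),
    num_classes = num_classes, skipped_classes = skipped
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mAP@0.5      = %.4f\n", x$map50))
  cat(sprintf("mAP@[.5:.95] = %.4f\n", x$map5095))
  cat(sprintf("classes evaluated: %d of %d\n",
              x$num_classes - length(x$skipped_classes), x$num_classes))
  invisible(x)
}

#' Export an evaluation report as CSV / JSON
#' @param report an `eval_report`
#' @param csv_path,json_path output files (either may be NULL)
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- data.frame(class = rownames(report$ap), report$ap,
                      ap5095 = report$ap5095, check.names = FALSE)
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(map50 = report$map50, map5095 = report$map5095,
                              ap = as.data.frame(report$ap)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

# ---- noise corruption ------------------------------------------------------

#' Salt-and-pepper corruption
#'
#' Sets exactly `round(level * H * W)` pixels, chosen without replacement,
#' to pure white or pure black with equal probability.
#'
#' @param img numeric HWC array in \[0,1\]
#' @param level fraction of pixels to corrupt, in \[0,1\]
#' @param seed optional integer seed for a reproducible mask
#' @return corrupted image
#' @export
add_salt_pepper <- function(img, level, seed = NULL) {
  stopifnot(level >= 0, level <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(img)
  n <- round(level * d[1] * d[2])
  if (n == 0) return(img)
  idx <- sample.int(d[1] * d[2], n)
  val <- sample(c(0, 1), n, replace = TRUE)
  out <- img
  for (ch in seq_len(d[3])) out[idx + (ch - 1L) * d[1] * d[2]] <- val
  out
}

#' Additive Gaussian corruption
#'
#' Adds i.i.d. normal noise (on the \[0,1\] intensity scale) and clips.
#'
#' @param img numeric HWC array in \[0,1\]
#' @param mean,std noise mean and standard deviation (std >= 0)
#' @param seed optional integer seed
#' @return corrupted image in \[0,1\]
#' @export
add_gaussian_noise <- function(img, mean = 0.1, std = 0.05, seed = NULL) {
  if (std < 0) stop("std must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  noise <- array(stats::rnorm(length(img), mean, std), dim(img))
  pmin(pmax(img + noise, 0), 1)
}

#' Noise-robustness sweep
#'
#' Runs detection and evaluation on a labelled image set at each corruption
#' level and tabulates mAP versus noise level. Level 0 reproduces the plain
#' evaluation exactly.
#'
#' @param model a trained [pest_model]
#' @param dataset_dir dataset directory (see [generate_dataset()] layout)
#' @param split split name, e.g. "val"
#' @param noise `"saltpepper"` or `"gaussian"`
#' @param levels noise levels, used exactly as given (one output row each);
#'   the default prepends 0 to the salt-&-pepper grid 0.005..0.05 in steps
#'   of 0.005 so the uncorrupted baseline is the first row
#' @param conf_thr,iou_thr detection decode threshold and Soft-NMS alpha
#'   are taken from [detect_image()] defaults
#' @param seed base seed for the noise masks
#' @param csv_path optional CSV output mirroring the sweep table
#' @return data.frame with columns level, map50, map5095
#' @export
robustness_sweep <- function(model, dataset_dir, split = "val",
                             noise = c("saltpepper", "gaussian"),
                             levels = c(0, seq(0.005, 0.05, by = 0.005)),
                             conf_thr = 0.001, seed = 1L, csv_path = NULL) {
  noise <- match.arg(noise)
  samples <- read_dataset_split(dataset_dir, split)
  nc <- model$cfg$num_classes
  rows <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    dets <- vector("list", length(samples))
    gts <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      img <- samples[[si]]$image
      if (lev > 0) {
        s <- seed + 1000L * li + si
        img <- if (noise == "saltpepper") add_salt_pepper(img, lev, seed = s)
               else add_gaussian_noise(img, mean = 0.1 * lev / max(levels),
                                       std = 0.05 * lev / max(levels), seed = s)
      }
      d <- detect_image(model, img, conf_thr = conf_thr)
      if (nrow(d)) d$image <- samples[[si]]$id
      dets[[si]] <- d
      g <- labels_to_boxes(samples[[si]]$labels, dim(img)[2], dim(img)[1])
      if (nrow(g)) g$image <- samples[[si]]$id
      gts[[si]] <- g
    }
    dd <- do.call(rbind, dets)
    gg <- do.call(rbind, gts)
    rep <- suppressMessages(evaluate_detections(
      if (is.null(dd)) empty_detections() else dd, gg, nc))
    rows[[li]] <- data.frame(level = lev, map50 = rep$map50,
                             map5095 = rep$map5095)
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}
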