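# Seeded generator of synthetic light-trap scenes: many small dark insects
# on a bright trap surface, with unlabeled clutter blobs and bright
# reflection spots, so the whole detection stack can be exercised without
# any external imagery. Insects are rendered procedurally as shaded
# ellipses with class-specific aspect ratio, darkness and optional leg
# strokes; labels are the exact bounding boxes of the rendered masks.

#' Specification of a synthetic light-trap scene
#'
#' @param image_size square image side in pixels
#' @param n_insects number of labelled insects to place
#' @param size_range linear relative-scale interval (box side as a fraction
#'   of the image side); the bulk of real trap catches sits well below 0.1
#' @param outlier_prob probability that an insect is drawn as a large-scale
#'   outlier (up to `outlier_scale`), mimicking the heavy upper tail of
#'   trap-catch size distributions
#' @param outlier_scale upper linear scale of outliers
#' @param n_classes number of insect classes (<= 24)
#' @param class_props class sampling proportions (length `n_classes`,
#'   summing to 1); defaults to a long-tailed geometric profile
#' @param density probability that an insect is deliberately placed
#'   overlapping an already-placed one (dense-catch pathology)
#' @param n_clutter number of unlabeled dark clutter blobs (debris)
#' @param n_reflections number of unlabeled bright reflection discs
#' @param background mean background tone in \[0,1\] (bright trap surface)
#' @param texture_sd standard deviation of the background texture noise
#' @param seed integer seed making the scene fully reproducible
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(image_size = 640L, n_insects = 20L,
                       size_range = c(0.005, 0.05), outlier_prob = 0.05,
                       outlier_scale = 0.3, n_classes = 8L,
                       class_props = NULL, density = 0.3,
                       n_clutter = 3L, n_reflections = 2L,
                       background = 0.82, texture_sd = 0.03, seed = 1L) {
  if (n_insects < 0L) stop("n_insects must be >= 0")
  if (n_classes < 1L || n_classes > 24L) stop("n_classes must be in 1..24")
  if (any(size_range <= 0) || any(size_range >= 1))
    stop("size_range must lie within (0, 1)")
  if (is.null(class_props)) {
    class_props <- 0.6^(seq_len(n_classes) - 1L)
    class_props <- class_props / sum(class_props)
  }
  if (length(class_props) != n_classes || abs(sum(class_props) - 1) > 1e-8)
    stop("class_props must have length n_classes and sum to 1")
  structure(list(
    image_size = as.integer(image_size), n_insects = as.integer(n_insects),
    size_range = size_range, outlier_prob = outlier_prob,
    outlier_scale = outlier_scale, n_classes = as.integer(n_classes),
    class_props = class_props, density = density,
    n_clutter = as.integer(n_clutter), n_reflections = as.integer(n_reflections),
    background = background, texture_sd = texture_sd, seed = as.integer(seed)
  ), class = "scene_spec")
}

# per-class shape/shade signature (deterministic function of class id)
class_signature <- function(class_id) {
  list(aspect = 1.3 + 0.18 * (class_id %% 5L),
       shade = 0.08 + 0.04 * (class_id %% 6L),
       legs = (class_id %% 2L) == 1L)
}

# stamp one elliptical insect (or clutter blob) onto the canvas; returns
# the canvas and the tight bounding box of the painted mask
stamp_ellipse <- function(canvas, cx, cy, len, aspect, angle, shade,
                          legs = FALSE, soften = 0.25) {
  S <- dim(canvas)[1]
  a <- len / 2; b <- a / aspect
  rad <- ceiling(a + (if (legs) a * 0.45 else 0)) + 2L
  xs <- max(1L, floor(cx - rad)):min(S, ceiling(cx + rad))
  ys <- max(1L, floor(cy - rad)):min(S, ceiling(cy + rad))
  if (!length(xs) || !length(ys)) return(list(canvas = canvas, box = NULL))
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  gy <- matrix(ys, length(ys), length(xs)) - cy
  u <- gx * cos(angle) + gy * sin(angle)
  v <- -gx * sin(angle) + gy * cos(angle)
  r2 <- (u / a)^2 + (v / b)^2
  mask <- r2 <= 1
  if (legs) {
    # six thin radial strokes approximated by narrow wedges
    th <- atan2(v, u)
    rr <- sqrt((u / (a * 1.45))^2 + (v / (b * 3))^2)
    wedge <- (abs(sin(3 * th)) > 0.92) & rr <= 1
    mask <- mask | wedge
  }
  if (!any(mask)) return(list(canvas = canvas, box = NULL))
  # soft-edged darkening toward the body center, darker head end
  depth <- pmax(0, 1 - r2)
  tone <- shade + soften * (1 - depth) * 0.3 + 0.05 * (u / max(a, 1) > 0.5)
  patch <- canvas[ys, xs, 1]
  for (ch in 1:3) {
    pc <- canvas[ys, xs, ch]
    pc[mask] <- pmin(pc[mask], tone[mask] * c(1, 0.95, 0.9)[ch])
    canvas[ys, xs, ch] <- pc
  }
  cols <- which(apply(mask, 2, any)); rows <- which(apply(mask, 1, any))
  list(canvas = canvas,
       box = c(x1 = xs[min(cols)] - 1, y1 = ys[min(rows)] - 1,
               x2 = xs[max(cols)], y2 = ys[max(rows)]))
}

#' Render one synthetic light-trap scene
#'
#' Places `n_insects` procedurally rendered insects on a bright textured
#' background, adds unlabeled clutter blobs and bright reflection discs,
#' and returns the image together with exact YOLO-style labels for the
#' insects only. If the requested count cannot be placed within bounds the
#' shortfall is reported in `stats`.
#'
#' @param spec a [scene_spec()]
#' @return list: `image` (HWC array in \[0,1\]), `labels` (data.frame
#'   class, cx, cy, w, h), `stats` (placed, shortfall, mean_rel_scale,
#'   overlap_fraction)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  S <- spec$image_size
  canvas <- array(spec$background, c(S, S, 3L))
  canvas <- canvas + array(stats::rnorm(S * S, 0, spec$texture_sd), c(S, S, 3L))
  # gentle illumination falloff toward the rim of the trap plate
  dx <- (seq_len(S) - S / 2) / S
  fall <- 1 - 0.25 * (outer(dx^2, dx^2, "+"))
  canvas <- canvas * array(rep(fall, 3L), c(S, S, 3L))
  canvas[, , 2] <- canvas[, , 2] * 0.98
  canvas[, , 3] <- canvas[, , 3] * 0.93
  canvas <- pmin(pmax(canvas, 0), 1)

  boxes <- list()
  classes <- integer(0)
  placed_centers <- NULL
  placed <- 0L
  for (i in seq_len(spec$n_insects)) {
    cl <- sample.int(spec$n_classes, 1L, prob = spec$class_props) - 1L
    sig <- class_signature(cl)
    rel <- if (stats::runif(1) < spec$outlier_prob)
      stats::runif(1, spec$size_range[2], spec$outlier_scale)
    else stats::runif(1, spec$size_range[1], spec$size_range[2])
    len <- max(3, rel * S)
    ok <- FALSE
    for (try in 1:25) {
      if (!is.null(placed_centers) && stats::runif(1) < spec$density) {
        j <- sample.int(nrow(placed_centers), 1L)
        cx <- placed_centers[j, 1] + stats::rnorm(1, 0, len * 0.4)
        cy <- placed_centers[j, 2] + stats::rnorm(1, 0, len * 0.4)
      } else {
        cx <- stats::runif(1, len, S - len)
        cy <- stats::runif(1, len, S - len)
      }
      if (cx > len / 2 + 1 && cx < S - len / 2 - 1 &&
          cy > len / 2 + 1 && cy < S - len / 2 - 1) { ok <- TRUE; break }
    }
    if (!ok) next
    st <- stamp_ellipse(canvas, cx, cy, len, sig$aspect,
                        stats::runif(1, 0, pi), sig$shade, sig$legs)
    if (is.null(st$box)) next
    canvas <- st$canvas
    boxes[[length(boxes) + 1L]] <- st$box
    classes <- c(classes, cl)
    placed_centers <- rbind(placed_centers, c(cx, cy))
    placed <- placed + 1L
  }
  # unlabeled clutter: soft gray blobs (debris, moth scales)
  for (i in seq_len(spec$n_clutter)) {
    st <- stamp_ellipse(canvas, stats::runif(1, 10, S - 10),
                        stats::runif(1, 10, S - 10),
                        stats::runif(1, 0.01, 0.06) * S,
                        stats::runif(1, 1, 1.6), stats::runif(1, 0, pi),
                        stats::runif(1, 0.45, 0.6))
    canvas <- st$canvas
  }
  # unlabeled bright reflection discs (light inflection points)
  for (i in seq_len(spec$n_reflections)) {
    cx <- stats::runif(1, 10, S - 10); cy <- stats::runif(1, 10, S - 10)
    r <- stats::runif(1, 0.01, 0.04) * S
    xs <- max(1L, floor(cx - r)):min(S, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(S, ceiling(cy + r))
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
    gy <- matrix(ys, length(ys), length(xs)) - cy
    m <- (gx^2 + gy^2) <= r^2
    for (ch in 1:3) {
      pc <- canvas[ys, xs, ch]
      pc[m] <- pmax(pc[m], 0.98)
      canvas[ys, xs, ch] <- pc
    }
  }

  if (placed) {
    B <- do.call(rbind, boxes)
    labels <- boxes_to_labels(
      data.frame(class = classes, x1 = B[, 1], y1 = B[, 2],
                 x2 = B[, 3], y2 = B[, 4]), S, S)
    # pairwise overlap fraction among labelled boxes
    ov <- 0L
    if (placed > 1L) {
      pb <- labels_to_boxes(labels, S, S)
      M <- as.matrix(pb[, c("x1", "y1", "x2", "y2")])
      for (i in seq_len(placed - 1L)) {
        ious <- iou_one_many(M[i, ], M[(i + 1):placed, , drop = FALSE])
        ov <- ov + sum(ious > 0)
      }
    }
    stats <- list(placed = placed, shortfall = spec$n_insects - placed,
                  mean_rel_scale = mean(pmax(labels$w, labels$h)),
                  overlap_pairs = ov,
                  overlap_fraction = if (placed > 1L)
                    ov / (placed * (placed - 1L) / 2) else 0)
  } else {
    labels <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                         w = numeric(0), h = numeric(0))
    stats <- list(placed = 0L, shortfall = spec$n_insects,
                  mean_rel_scale = NA_real_, overlap_pairs = 0L,
                  overlap_fraction = 0)
  }
  if (stats$shortfall > 0)
    message("placed ", placed, " of ", spec$n_insects, " insects (shortfall ",
            stats$shortfall, ")")
  list(image = canvas, labels = labels, stats = stats)
}

#' Generate a dataset directory of synthetic scenes
#'
#' Writes the training layout `images/<split>/scene_XXXX.png` +
#' `labels/<split>/scene_XXXX.txt` plus a JSON manifest with class names,
#' per-image seeds and the split assignment. Fully deterministic given
#' `seed`: image i is rendered from `spec` with seed `seed + i`.
#'
#' @param dir output directory (created if needed)
#' @param n_images number of scenes
#' @param spec a [scene_spec()] template (its `seed` field is overridden
#'   per image)
#' @param splits named fractions summing to 1, e.g. `c(train=.8, val=.2)`
#' @param seed base seed
#' @return invisibly, the manifest list
#' @export
generate_dataset <- function(dir, n_images, spec = scene_spec(),
                             splits = c(train = 0.8, val = 0.2), seed = 1L) {
  if (n_images < 1L) stop("n_images must be >= 1")
  if (abs(sum(splits) - 1) > 1e-8) stop("split fractions must sum to 1")
  counts <- diff(round(c(0, cumsum(splits)) * n_images))
  assignment <- rep(names(splits), counts)
  manifest <- list(classes = paste0("insect_", seq_len(spec$n_classes) - 1L),
                   n_images = n_images, base_seed = seed, images = list())
  for (sp in unique(assignment)) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n_images)) {
    sp <- assignment[i]
    s <- spec
    s$seed <- as.integer(seed + i)
    scene <- generate_scene(s)
    id <- sprintf("scene_%04d", i)
    write_image(scene$image, file.path(dir, "images", sp, paste0(id, ".png")))
    write_labels(scene$labels, file.path(dir, "labels", sp, paste0(id, ".txt")))
    manifest$images[[id]] <- list(split = sp, seed = s$seed,
                                  n_labels = nrow(scene$labels))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
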