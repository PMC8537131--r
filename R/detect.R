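#' Detector configuration
#'
#' Bundles every tunable of the detection pipeline. `beta1` is the
#' opposition-sum tolerance (flow units): the sums `u + u'` and `v + v'`
#' must be near zero for truly opposite flow, but grayscale constancy is
#' only approximate, so exact zero is never observed. `beta2` (squared-flow
#' units) is the anti-null floor: it rejects pixels where both flows are
#' merely near zero, whose sums would otherwise pass the `beta1` test.
#' Defaults (0.35, 3) are the best-scoring cell of the threshold sweep grid.
#'
#' @param beta1 Opposition-sum tolerance, in (0, 10). Default 0.35.
#' @param beta2 Anti-null product floor, > 0. Default 3.
#' @param alpha2,n_iters Forwarded to [hs_solve()].
#' @param connectivity Pixel adjacency for component labeling: 4 or 8.
#' @param min_area Minimum component size in pixels (>= 1); 2 suppresses
#'   single-pixel flicker, 1 disables the filter.
#' @param pixel_stride Compute flow on every `pixel_stride`-th row/column
#'   and upsample the mask by nearest neighbor. Default 1.
#' @param frame_stride Keep every `frame_stride`-th frame. Default 1.
#' @param flow_scale Flow-scale normalizer `s` for the `beta2` inequality
#'   (`-u u' > beta2 * s^2`); default 1 gives the raw inequality.
#' @param combine How the two threshold inequalities combine:
#'   `"axis_and_then_or"` (default) requires sum-small AND product-large on
#'   the same axis, then ORs across axes; `"joint_or"` is the literal
#'   reading (OR across axes within each inequality, then AND).
#' @param neighborhood_average,cube_mean Solver variants, see [hs_solve()]
#'   and [compute_gradients()].
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(beta1 = 0.35, beta2 = 3, alpha2 = 100,
                            n_iters = 100, connectivity = 8L, min_area = 2L,
                            pixel_stride = 1L, frame_stride = 1L,
                            flow_scale = 1,
                            combine = c("axis_and_then_or", "joint_or"),
                            neighborhood_average = "none",
                            cube_mean = FALSE) {
  combine <- match.arg(combine)
  if (!is.numeric(beta1) || beta1 <= 0 || beta1 >= 10) {
    stop("`beta1` must lie in (0, 10)", call. = FALSE)
  }
  if (!is.numeric(beta2) || beta2 <= 0) {
    stop("`beta2` must be > 0", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  min_area <- as.integer(min_area)
  pixel_stride <- as.integer(pixel_stride)
  frame_stride <- as.integer(frame_stride)
  if (min_area < 1L || pixel_stride < 1L || frame_stride < 1L) {
    stop("`min_area`, `pixel_stride` and `frame_stride` must be >= 1",
         call. = FALSE)
  }
  if (!is.numeric(flow_scale) || flow_scale <= 0) {
    stop("`flow_scale` must be > 0", call. = FALSE)
  }
  structure(list(beta1 = beta1, beta2 = beta2, alpha2 = alpha2,
                 n_iters = n_iters, connectivity = as.integer(connectivity),
                 min_area = min_area, pixel_stride = pixel_stride,
                 frame_stride = frame_stride, flow_scale = flow_scale,
                 combine = combine,
                 neighborhood_average = neighborhood_average,
                 cube_mean = cube_mean),
            class = "detector_config")
}

#' Dual-threshold opposition mask
#'
#' Marks the pixels whose two consecutive flows are genuinely opposite. In
#' the default combination a pixel is marked when at least one axis shows
#' both near-opposite sum and a substantial negative product:
#' `(|u + u'| < beta1 AND -u u' > beta2 s^2) OR (same for v)`. The absolute
#' value on the sum enforces its role as a tolerance around zero; the
#' product floor rejects the no-plankton case where both flows happen to be
#' small. `"joint_or"` applies each inequality as an OR over axes first.
#'
#' @param pair A [flow_pair()].
#' @inheritParams detector_config
#' @return A logical matrix shaped like the frames.
#' @export
opposition_mask <- function(pair, beta1 = 0.35, beta2 = 3, flow_scale = 1,
                            combine = c("axis_and_then_or", "joint_or")) {
  combine <- match.arg(combine)
  if (beta1 <= 0 || beta2 <= 0) {
    stop("thresholds `beta1` and `beta2` must be positive", call. = FALSE)
  }
  u <- pair$first$u; v <- pair$first$v
  u2 <- pair$second$u; v2 <- pair$second$v
  if (!identical(dim(u), dim(u2))) {
    stop("the two flow fields of a pair must share one shape", call. = FALSE)
  }
  s2 <- flow_scale^2
  sum_u <- abs(u + u2) < beta1
  sum_v <- abs(v + v2) < beta1
  prod_u <- -(u * u2) > beta2 * s2
  prod_v <- -(v * v2) > beta2 * s2
  if (combine == "axis_and_then_or") {
    (sum_u & prod_u) | (sum_v & prod_v)
  } else {
    (sum_u | sum_v) & (prod_u | prod_v)
  }
}

#' Label connected components and count plankton
#'
#' Standard connected-component labeling of a binary mask at 4- or
#' 8-adjacency (union-find). Components smaller than `min_area` pixels are
#' discarded, survivors are relabeled 1..k in first-pixel scan order, and
#' each component's centroid is the arithmetic mean of its member pixel
#' coordinates (x = column, y = row, 1-based). The component count is the
#' number of detected plankton in the frame.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @param min_area Minimum pixels per component.
#' @param frame_index Time index recorded in the result.
#' @return A list of class `detection_result`: `frame_index`, `mask` (the
#'   input mask with sub-`min_area` components removed), `n_components`,
#'   and `components`, a data.frame with columns `label`, `centroid_x`,
#'   `centroid_y`, `n_pixels`.
#' @export
label_components <- function(mask, connectivity = 8L, min_area = 2L,
                             frame_index = 0L) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical matrix", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  h <- nrow(mask); w <- ncol(mask)
  cells <- which(mask)
  if (length(cells) == 0L) {
    return(empty_detection(mask, frame_index))
  }
  row <- ((cells - 1L) %% h) + 1L
  col <- ((cells - 1L) %/% h) + 1L
  id_of <- matrix(0L, h, w)
  id_of[cells] <- seq_along(cells)

  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(0L, -1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))
  }
  for (k in seq_along(cells)) {
    for (o in offs) {
      nr <- row[k] + o[1]; nc <- col[k] + o[2]
      if (nr >= 1L && nr <= h && nc >= 1L && nc <= w) {
        nb <- id_of[nr, nc]
        if (nb > 0L) {
          ra <- find(k); rb <- find(nb)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  root <- vapply(seq_along(cells), find, integer(1))
  # relabel in first-occurrence (column-major scan) order
  lab <- match(root, unique(root))
  sizes <- tabulate(lab)
  keep <- sizes[lab] >= min_area
  if (!any(keep)) {
    return(empty_detection(mask & FALSE, frame_index))
  }
  lab2 <- match(lab[keep], unique(lab[keep]))
  comp <- data.frame(
    label = sort(unique(lab2)),
    centroid_x = as.numeric(tapply(col[keep], lab2, mean)),
    centroid_y = as.numeric(tapply(row[keep], lab2, mean)),
    n_pixels = as.integer(tapply(lab2, lab2, length))
  )
  out_mask <- matrix(FALSE, h, w)
  out_mask[cells[keep]] <- TRUE
  structure(list(frame_index = as.integer(frame_index), mask = out_mask,
                 n_components = nrow(comp), components = comp),
            class = "detection_result")
}

empty_detection <- function(mask, frame_index) {
  structure(list(frame_index = as.integer(frame_index),
                 mask = mask & FALSE, n_components = 0L,
                 components = data.frame(label = integer(0),
                                         centroid_x = numeric(0),
                                         centroid_y = numeric(0),
                                         n_pixels = integer(0))),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result> frame", x$frame_index, "-", x$n_components,
      "plankton\n")
  if (x$n_components > 0) print(x$components)
  invisible(x)
}

#' Run the detector over a frame sequence
#'
#' For every interior frame `t` of the (possibly frame-strided) sequence,
#' builds the triple `(t-1, t, t+1)`, computes the two consecutive flow
#' fields, applies the dual-threshold opposition mask, and labels connected
#' components. `pixel_stride p` computes flow on the grid of every p-th row
#' and column and upsamples the mask by nearest neighbor before labeling.
#' The returned list carries a `manifest` attribute recording every config
#' value used.
#'
#' @param frames A list of frames (see [read_frames()]), or anything
#'   [read_frames()] accepts.
#' @param cfg A [detector_config()].
#' @return List of [label_components()] results, ordered by frame index.
#' @export
detect_sequence <- function(frames, cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  frames <- read_frames(frames, frame_stride = cfg$frame_stride)
  n <- length(frames)
  if (n < 3L) stop("need at least 3 frames after striding", call. = FALSE)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  p <- cfg$pixel_stride
  rs <- seq(1L, h, by = p); cs <- seq(1L, w, by = p)
  results <- vector("list", n - 2L)
  for (t in 2:(n - 1L)) {
    res <- tryCatch({
      sub <- lapply(frames[(t - 1L):(t + 1L)], function(f) {
        m <- frame_pixels(f)[rs, cs, drop = FALSE]
        m
      })
      triple <- frame_triple(gray_frame(sub[[1]], 0L), gray_frame(sub[[2]], 1L),
                             gray_frame(sub[[3]], 2L))
      pair <- flow_pair(triple, alpha2 = cfg$alpha2, n_iters = cfg$n_iters,
                        neighborhood_average = cfg$neighborhood_average,
                        cube_mean = cfg$cube_mean)
      mask <- opposition_mask(pair, beta1 = cfg$beta1, beta2 = cfg$beta2,
                              flow_scale = cfg$flow_scale,
                              combine = cfg$combine)
      if (p > 1L) {
        mask <- mask[ceiling(seq_len(h) / p), ceiling(seq_len(w) / p),
                     drop = FALSE]
      }
      label_components(mask, connectivity = cfg$connectivity,
                       min_area = cfg$min_area,
                       frame_index = frame_index(frames[[t]]))
    }, error = function(e) {
      stop("detection failed at frame ", frame_index(frames[[t]]), ": ",
           conditionMessage(e), call. = FALSE)
    })
    results[[t - 1L]] <- res
  }
  attr(results, "manifest") <- c(unclass(cfg),
                                 list(n_frames = n, height = h, width = w))
  results
}
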