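#' Match detections to ground-truth blobs
#'
#' Greedy one-to-one matching by ascending centroid distance: candidate
#' (detection, truth) pairs within the match radius are sorted by distance
#' (ties broken by lower detection label, then lower truth id) and accepted
#' while both members are unused. Matched pairs are true positives,
#' unmatched detections false positives, unmatched truth blobs false
#' negatives. Object detection has no meaningful true-negative count; `tn`
#' is kept at 0 for confusion-matrix completeness.
#'
#' @param pred A [label_components()] result.
#' @param truth_frame Ground truth for the same frame: either a
#'   `scene_truth` (the matching frame is selected by `pred$frame_index`)
#'   or a data.frame with columns `x`, `y` and optionally `radius`.
#' @param match_radius Acceptance radius in pixels; `NULL` (default) uses
#'   each truth blob's own radius + 2.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
match_detections <- function(pred, truth_frame, match_radius = NULL) {
  stopifnot(inherits(pred, "detection_result"))
  tr <- truth_blobs_for_frame(truth_frame, pred$frame_index)
  det <- pred$components
  nd <- nrow(det); nt <- nrow(tr)
  if (nd == 0L || nt == 0L) {
    return(confusion_counts(tp = 0L, fp = nd, fn = nt))
  }
  radius <- if (is.null(match_radius)) {
    if (is.null(tr$radius)) stop("truth has no radius; give `match_radius`",
                                 call. = FALSE)
    tr$radius + 2
  } else {
    rep(match_radius, nt)
  }
  dx <- outer(det$centroid_x, tr$x, "-")
  dy <- outer(det$centroid_y, tr$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  ok <- which(dist <= rep(radius, each = nd), arr.ind = TRUE)
  if (nrow(ok) == 0L) return(confusion_counts(0L, nd, nt))
  ord <- order(dist[ok], ok[, 1L], ok[, 2L])
  ok <- ok[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt); tp <- 0L
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1L]; j <- ok[k, 2L]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
    }
  }
  confusion_counts(tp, nd - tp, nt - tp)
}

truth_blobs_for_frame <- function(truth, frame_index) {
  if (inherits(truth, "scene_truth")) {
    truth$blobs[truth$blobs$frame_index == frame_index, , drop = FALSE]
  } else if (is.data.frame(truth)) {
    truth
  } else {
    stop("`truth_frame` must be a scene_truth or a data.frame", call. = FALSE)
  }
}

confusion_counts <- function(tp, fp, fn, tn = 0L) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 P R / (P + R)`. An undefined metric (zero denominator) is
#' reported as `NA`, never silently as 0 — except the stated F1 convention
#' that `F1 = 0` when `P + R = 0`.
#'
#' @param counts A `confusion_counts` from [match_detections()], or a list
#'   with fields `tp`, `fp`, `fn`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' f1_from_rates(0.901, 0.955)  # 0.9272...
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' @rdname precision_recall_f1
#' @param precision,recall Already-averaged precision and recall rates.
#' @export
f1_from_rates <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Mean and population standard deviation of a count series
#'
#' Summarizes per-frame plankton counts the way abundance tables report
#' them: arithmetic mean and the population standard deviation (divide by
#' `n`, not `n - 1`), plus both rounded to one decimal for table-style
#' display.
#'
#' @param counts Nonempty numeric vector of per-frame counts.
#' @return List: `mean`, `std` (population), `mean_display`, `std_display`.
#' @examples
#' summarize_counts(c(16, 14, 12, 12, 12, 11, 12, 10, 11, 10))  # 12.0, 1.7
#' @export
summarize_counts <- function(counts) {
  if (length(counts) == 0L) stop("`counts` must be nonempty", call. = FALSE)
  m <- mean(counts)
  s <- sqrt(mean((counts - m)^2))
  list(mean = m, std = s,
       mean_display = round(m, 1), std_display = round(s, 1))
}

#' Cosine similarity between a frame and its masked detection
#'
#' Flattens the original grayscale frame and the masked frame (original
#' intensity where the detection mask is true, 0 elsewhere) into vectors
#' and returns their cosine similarity `<a,b>/(|a||b|)`; 0 by convention if
#' either vector is all zero. `vectorization = "binary"` compares the
#' original against the 0/1 mask itself instead. Larger scores mean the
#' detection preserves more of the image's structure.
#'
#' @param frame The original grayscale frame (matrix).
#' @param detection A [label_components()] result (or a logical mask).
#' @param vectorization `"masked_gray"` (default) or `"binary"`.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_score <- function(frame, detection,
                         vectorization = c("masked_gray", "binary")) {
  vectorization <- match.arg(vectorization)
  mask <- if (inherits(detection, "detection_result")) detection$mask
          else detection
  if (!identical(dim(frame), dim(mask))) {
    stop("frame and mask must share the same shape", call. = FALSE)
  }
  a <- as.numeric(frame)
  b <- if (vectorization == "masked_gray") a * as.numeric(mask)
       else as.numeric(mask)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Sweep the dual thresholds and score each cell by cosine similarity
#'
#' Runs the detector at every `(beta1, beta2)` combination of the grids and
#' scores each cell by the mean [cosine_score()] between each interior
#' frame and its masked detection. The flow fields depend only on the
#' solver parameters, so they are computed once per frame and re-thresholded
#' per cell. The default grids are beta1 = 0.05 to 0.35 by 0.05 and
#' beta2 = 3 to 9 by 1 (a 7x7 table); the best cell is the argmax (first
#' cell in grid order on ties).
#'
#' @param frames Frame sequence (see [detect_sequence()]).
#' @param cfg_base A [detector_config()]; its thresholds are overridden
#'   cell by cell, everything else (solver, labeling, strides) is kept.
#' @param beta1_grid,beta2_grid Threshold grids.
#' @param vectorization Forwarded to [cosine_score()].
#' @return A list of class `sweep_table`: `beta1`, `beta2`, `scores`
#'   (matrix, rows = beta2, cols = beta1), `best` (list `beta1`, `beta2`,
#'   `score`).
#' @export
threshold_sweep <- function(frames, cfg_base = detector_config(),
                            beta1_grid = seq(0.05, 0.35, by = 0.05),
                            beta2_grid = 3:9,
                            vectorization = "masked_gray") {
  frames <- read_frames(frames, frame_stride = cfg_base$frame_stride)
  n <- length(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  p <- cfg_base$pixel_stride
  rs <- seq(1L, h, by = p); cs <- seq(1L, w, by = p)
  pairs <- lapply(2:(n - 1L), function(t) {
    sub <- lapply(frames[(t - 1L):(t + 1L)],
                  function(f) frame_pixels(f)[rs, cs, drop = FALSE])
    flow_pair(frame_triple(gray_frame(sub[[1]], 0L), gray_frame(sub[[2]], 1L),
                           gray_frame(sub[[3]], 2L)),
              alpha2 = cfg_base$alpha2, n_iters = cfg_base$n_iters,
              neighborhood_average = cfg_base$neighborhood_average,
              cube_mean = cfg_base$cube_mean)
  })
  scores <- matrix(NA_real_, length(beta2_grid), length(beta1_grid),
                   dimnames = list(beta2 = beta2_grid, beta1 = beta1_grid))
  for (j in seq_along(beta1_grid)) {
    for (i in seq_along(beta2_grid)) {
      cell <- vapply(seq_along(pairs), function(k) {
        mask <- opposition_mask(pairs[[k]], beta1 = beta1_grid[j],
                                beta2 = beta2_grid[i],
                                flow_scale = cfg_base$flow_scale,
                                combine = cfg_base$combine)
        if (p > 1L) {
          mask <- mask[ceiling(seq_len(h) / p), ceiling(seq_len(w) / p),
                       drop = FALSE]
        }
        det <- label_components(mask, cfg_base$connectivity, cfg_base$min_area,
                                frame_index = frame_index(frames[[k + 1L]]))
        cosine_score(frame_pixels(frames[[k + 1L]]), det,
                     vectorization = vectorization)
      }, numeric(1))
      scores[i, j] <- mean(cell)
    }
  }
  best <- arrayInd(which.max(scores), dim(scores))
  structure(list(beta1 = beta1_grid, beta2 = beta2_grid, scores = scores,
                 best = list(beta1 = beta1_grid[best[2]],
                             beta2 = beta2_grid[best[1]],
                             score = scores[best])),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat("<sweep_table> cosine similarity, rows beta2 x cols beta1\n")
  print(round(x$scores, 4))
  cat(sprintf("best: beta1 = %g, beta2 = %g (score %.4f)\n",
              x$best$beta1, x$best$beta2, x$best$score))
  invisible(x)
}

#' Per-frame detection metrics against scene truth
#'
#' Convenience wrapper: matches every detection result against the scene
#' truth and tabulates counts and metrics per frame, with an averages row
#' appended.
#'
#' @param results List of [label_components()] results.
#' @param truth A `scene_truth`.
#' @param match_radius See [match_detections()].
#' @return data.frame: `frame_index`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`; the last row (`frame_index = NA`) holds column means.
#' @export
evaluate_sequence <- function(results, truth, match_radius = NULL) {
  rows <- lapply(results, function(r) {
    cc <- match_detections(r, truth, match_radius = match_radius)
    m <- precision_recall_f1(cc)
    data.frame(frame_index = r$frame_index, tp = cc$tp, fp = cc$fp,
               fn = cc$fn, precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(frame_index = NA_integer_,
                    tp = mean(out$tp), fp = mean(out$fp), fn = mean(out$fn),
                    precision = mean(out$precision, na.rm = TRUE),
                    recall = mean(out$recall, na.rm = TRUE),
                    f1 = mean(out$f1, na.rm = TRUE))
  rbind(out, avg)
}
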