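make_det <- function(xy, frame = 0L) {
  structure(list(frame_index = frame, mask = NULL,
                 n_components = nrow(xy),
                 components = data.frame(label = seq_len(nrow(xy)),
                                         centroid_x = xy[, 1],
                                         centroid_y = xy[, 2],
                                         n_pixels = rep(5L, nrow(xy)))),
            class = "detection_result")
}

test_that("centroid matching conserves objects and handles the worked case", {
  # perfect detection
  truth <- data.frame(x = c(5, 20), y = c(5, 20), radius = 2)
  cc <- match_detections(make_det(cbind(c(5, 20), c(5, 20))), truth)
  expect_equal(unlist(cc[c("tp", "fp", "fn")]), c(tp = 2L, fp = 0L, fn = 0L))

  # 16 detections vs 14 truths, 13 close: TP 13, FP 3, FN 1
  set.seed(8)
  tx <- seq(10, 140, by = 10); ty <- rep(c(10, 30), 7)      # 14 truths
  det <- cbind(c(tx[1:13] + 1, 300, 320, 340),
               c(ty[1:13], 300, 320, 340))                  # 13 near + 3 far
  cc <- match_detections(make_det(det),
                         data.frame(x = tx, y = ty, radius = 3))
  expect_equal(unlist(cc[c("tp", "fp", "fn")]), c(tp = 13L, fp = 3L, fn = 1L))
  m <- precision_recall_f1(cc)
  expect_equal(round(m[["precision"]], 2), 0.81)  # 13/16 = 0.8125
  expect_equal(round(m[["recall"]], 2), 0.93)     # 13/14 = 0.9286
  # conservation: TP + FP = detections, TP + FN = truths
  expect_equal(cc$tp + cc$fp, 16L)
  expect_equal(cc$tp + cc$fn, 14L)

  # two equidistant detections for one truth: one TP (lower label), one FP
  cc2 <- match_detections(make_det(cbind(c(9, 11), c(10, 10))),
                          data.frame(x = 10, y = 10, radius = 3))
  expect_equal(unlist(cc2[c("tp", "fp", "fn")]), c(tp = 1L, fp = 1L, fn = 0L))

  # empty cases
  cc3 <- match_detections(make_det(matrix(numeric(0), 0, 2)),
                          data.frame(x = 1, y = 1, radius = 1))
  expect_equal(cc3$fn, 1L)
})

test_that("greedy matching picks globally nearest pairs first", {
  # det 1 is near truth B, det 2 is nearer truth B but closest to A;
  # brute force over the greedy order: pair (2,A) d=1, then (1,B) d=2
  det <- make_det(cbind(c(10, 5), c(12, 5)))
  truth <- data.frame(x = c(5, 10), y = c(4, 10), radius = 5)
  cc <- match_detections(det, truth)
  expect_equal(cc$tp, 2L)
})

test_that("precision/recall/F1 follow their definitions and conventions", {
  expect_equal(precision_recall_f1(list(tp = 5, fp = 0, fn = 0)),
               c(precision = 1, recall = 1, f1 = 1))
  # undefined metrics are NA, never silent zero
  und <- precision_recall_f1(list(tp = 0, fp = 0, fn = 3))
  expect_true(is.na(und[["precision"]]))
  expect_equal(und[["recall"]], 0)
  expect_true(is.na(und[["f1"]]))
  # F1 = 0 convention when P + R = 0
  z <- precision_recall_f1(list(tp = 0, fp = 2, fn = 3))
  expect_equal(z[["f1"]], 0)

  # averaged-rate worked examples round to the printed three decimals
  expect_equal(round(f1_from_rates(0.901, 0.955), 3), 0.927)
  expect_equal(round(f1_from_rates(0.895, 0.943), 3), 0.918)

  # harmonic mean lies between P and R
  set.seed(14)
  for (i in 1:30) {
    tp <- sample(1:30, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    m <- precision_recall_f1(list(tp = tp, fp = fp, fn = fn))
    expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
  }
})

test_that("count summaries use the population standard deviation", {
  s <- summarize_counts(c(16, 14, 12, 12, 12, 11, 12, 10, 11, 10))
  expect_equal(s$mean_display, 12.0)
  expect_equal(s$std_display, 1.7)  # sample std would round to 1.8
  expect_equal(s$std, sqrt(3))

  s2 <- summarize_counts(c(15, 21, 22, 21, 22, 21, 21, 22, 19, 16))
  expect_equal(s2$mean_display, 20.0)
  expect_equal(s2$std_display, 2.4)

  s1 <- summarize_counts(5)
  expect_equal(s1$mean, 5)
  expect_equal(s1$std, 0)
  expect_error(summarize_counts(numeric(0)), "nonempty")
})

test_that("cosine score matches a direct dot-product computation", {
  set.seed(55)
  f <- random_frame(12, 12)
  full <- matrix(TRUE, 12, 12)
  expect_equal(cosine_score(f, full), 1)
  expect_equal(cosine_score(f, matrix(FALSE, 12, 12)), 0)
  for (i in 1:10) {
    mask <- matrix(runif(144) < 0.4, 12, 12)
    a <- as.numeric(f); b <- a * mask
    direct <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    expect_equal(cosine_score(f, mask), direct, tolerance = 1e-12)
    bin <- as.numeric(mask)
    direct_bin <- sum(a * bin) / (sqrt(sum(a^2)) * sqrt(sum(bin^2)))
    expect_equal(cosine_score(f, mask, vectorization = "binary"), direct_bin,
                 tolerance = 1e-12)
  }
  expect_error(cosine_score(f, matrix(TRUE, 3, 3)), "shape")
})

test_that("threshold sweep scores every grid cell and finds a sane optimum", {
  sc <- generate_scene(scene_config(n_frames = 8, height = 64, width = 64,
                                    blobs = list(count = 4L), seed = 9))
  cfg <- detector_config(n_iters = 60)
  # degenerate single-cell grid equals a direct detect + score run
  tab1 <- threshold_sweep(sc$frames, cfg, beta1_grid = 0.35, beta2_grid = 3)
  expect_equal(dim(tab1$scores), c(1L, 1L))
  dets <- detect_sequence(sc$frames, cfg)
  direct <- mean(mapply(function(d, k) {
    cosine_score(frame_pixels(sc$frames[[k]]), d)
  }, dets, seq(2, 7)))
  expect_equal(tab1$scores[1, 1], direct, tolerance = 1e-12)

  # small grid: the argmax cell's detection F1 is at least the grid median F1
  b1g <- c(0.15, 0.35); b2g <- c(3, 6)
  tab <- threshold_sweep(sc$frames, cfg, beta1_grid = b1g, beta2_grid = b2g)
  expect_equal(dim(tab$scores), c(2L, 2L))
  expect_true(all(tab$scores >= -1 & tab$scores <= 1))
  f1_of <- function(b1, b2) {
    d <- detect_sequence(sc$frames,
                         detector_config(beta1 = b1, beta2 = b2, n_iters = 60))
    ev <- evaluate_sequence(d, sc$truth)
    ev$f1[nrow(ev)]
  }
  f1s <- outer(b2g, b1g, Vectorize(f1_of))
  best_f1 <- f1_of(tab$best$beta1, tab$best$beta2)
  expect_gte(best_f1, stats::median(f1s))
})

test_that("sequence evaluation tabulates per-frame metrics plus averages", {
  sc <- generate_scene(scene_config(n_frames = 6, height = 64, width = 64,
                                    blobs = list(count = 3L), seed = 15))
  dets <- detect_sequence(sc$frames, detector_config())
  ev <- evaluate_sequence(dets, sc$truth)
  expect_equal(nrow(ev), 5)  # 4 interior frames + averages row
  expect_true(is.na(ev$frame_index[5]))
  expect_equal(ev$precision[5], mean(ev$precision[1:4], na.rm = TRUE))
  expect_true(all(ev$tp + ev$fn == 3))  # truths conserved per frame
})
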