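fake_pair <- function(u, v, u2, v2) {
  structure(list(
    first = structure(list(u = u, v = v), class = "flow_field"),
    second = structure(list(u = u2, v = v2), class = "flow_field")),
    class = "flow_pair")
}

test_that("opposition mask applies the dual thresholds per axis", {
  z <- matrix(0, 2, 2)
  expect_false(any(opposition_mask(fake_pair(z, z, z, z), 0.35, 3)))

  u <- z; u[1, 1] <- 2
  u2 <- z; u2[1, 1] <- -2
  m <- opposition_mask(fake_pair(u, z, u2, z), beta1 = 0.35, beta2 = 3)
  expect_true(m[1, 1])         # |u+u'| = 0 < 0.35 and -u u' = 4 > 3
  expect_equal(sum(m), 1L)

  # same-sign flows of equal size: sum fails the beta1 tolerance
  m2 <- opposition_mask(fake_pair(u, z, u, z), beta1 = 0.35, beta2 = 3)
  expect_false(any(m2))
  # opposite but tiny flows: product fails the beta2 floor
  u3 <- z; u3[1, 1] <- 0.1
  m3 <- opposition_mask(fake_pair(u3, z, -u3, z), beta1 = 0.35, beta2 = 3)
  expect_false(any(m3))

  expect_error(opposition_mask(fake_pair(u, z, u2, z), beta1 = -1, beta2 = 3),
               "positive")
})

test_that("mask is monotone in the thresholds", {
  set.seed(21)
  for (i in 1:10) {
    u <- matrix(rnorm(64, 0, 2), 8, 8); v <- matrix(rnorm(64, 0, 2), 8, 8)
    u2 <- -u + matrix(rnorm(64, 0, 0.3), 8, 8)
    v2 <- -v + matrix(rnorm(64, 0, 0.3), 8, 8)
    pair <- fake_pair(u, v, u2, v2)
    m_small <- opposition_mask(pair, beta1 = 0.2, beta2 = 3)
    m_b1 <- opposition_mask(pair, beta1 = 0.6, beta2 = 3)
    m_b2 <- opposition_mask(pair, beta1 = 0.2, beta2 = 6)
    expect_true(all(m_b1[m_small]))   # growing beta1 never unmarks
    expect_true(all(m_small[m_b2]))   # growing beta2 never marks anew
  }
})

test_that("component labeling matches a flood-fill oracle at both adjacencies", {
  # two diagonal-touching pixels: one component at 8, two at 4
  m <- matrix(FALSE, 4, 4); m[2, 2] <- m[3, 3] <- TRUE
  expect_equal(label_components(m, 8, min_area = 1)$n_components, 1L)
  expect_equal(label_components(m, 4, min_area = 1)$n_components, 2L)

  # two 3x3 squares separated by a background row
  m2 <- matrix(FALSE, 9, 5)
  m2[1:3, 2:4] <- TRUE; m2[5:7, 2:4] <- TRUE
  for (conn in c(4L, 8L)) {
    d <- label_components(m2, conn, min_area = 1)
    expect_equal(d$n_components, 2L)
    expect_equal(sort(d$components$n_pixels), c(9L, 9L))
    expect_equal(sort(d$components$centroid_y), c(2, 6))
    expect_equal(d$components$centroid_x, c(3, 3))
  }

  expect_equal(label_components(matrix(FALSE, 3, 3), 8)$n_components, 0L)

  set.seed(31)
  for (i in 1:20) {
    m <- matrix(runif(15 * 12) < 0.25, 15, 12)
    for (conn in c(4L, 8L)) {
      for (ma in c(1L, 2L, 3L)) {
        d <- label_components(m, conn, min_area = ma)
        sizes <- oracle_component_sizes(m, conn, ma)
        expect_equal(sort(d$components$n_pixels), sizes)
        expect_equal(d$n_components, length(sizes))
        expect_equal(sum(d$mask), sum(sizes))
      }
    }
  }
})

test_that("labeling agrees with EBImage at 4-connectivity", {
  skip_if_not_installed("EBImage")
  set.seed(77)
  for (i in 1:5) {
    m <- matrix(runif(20 * 20) < 0.3, 20, 20)
    ours <- label_components(m, connectivity = 4L, min_area = 1L)
    eb <- EBImage::bwlabel(m * 1)
    expect_equal(ours$n_components, max(eb))
    expect_equal(sort(ours$components$n_pixels),
                 sort(as.integer(tabulate(eb[eb > 0]))))
  }
})

test_that("component count is invariant to border padding of the mask", {
  set.seed(41)
  m <- matrix(runif(100) < 0.3, 10, 10)
  padded <- matrix(FALSE, 14, 14); padded[3:12, 3:12] <- m
  for (conn in c(4L, 8L)) {
    expect_equal(label_components(m, conn, 1)$n_components,
                 label_components(padded, conn, 1)$n_components)
  }
})

test_that("detector marks the blob's mid-frame position and nothing else", {
  # continuing motion over a constant noise-free background: the opposition
  # premise holds locally at the mid-frame position, and only there
  for (s in c(2, 13, 27)) {
    scene <- generate_scene(scene_config(n_frames = 3, height = 64,
                                         width = 64,
                                         blobs = list(count = 1L),
                                         noise_sigma = 0, seed = s))
    pair <- flow_pair(frame_triple(scene$frames[[1]], scene$frames[[2]],
                                   scene$frames[[3]]))
    mask <- opposition_mask(pair)
    support <- scene$truth$masks[[2]]
    # marked pixels stay within a 1-px dilation of the mid-frame support
    expect_true(all(mask[!dilate1(support)] == FALSE))
    # and form one component inside it
    det <- label_components(mask, 8L, 2L)
    expect_equal(det$n_components, 1L)
    blob <- scene$truth$blobs[scene$truth$blobs$frame_index == 1L, ]
    d <- sqrt((det$components$centroid_x - blob$x)^2 +
              (det$components$centroid_y - blob$y)^2)
    expect_lt(d, blob$radius + 2)
  }
})

test_that("out-and-back triples mark both genuine opposition sites", {
  g <- generate_triple("fast_blob", seed = 13)
  mask <- opposition_mask(flow_pair(g$triple))
  det <- label_components(mask, 8L, 2L)
  # the mid-frame position and the vacated-then-reoccupied site
  expect_equal(det$n_components, 2L)
  both <- dilate1(g$truth$masks[[1]]) | dilate1(g$truth$masks[[2]])
  expect_true(all(mask[!both] == FALSE))
})

test_that("slow movers violating the non-overlap premise are not detected", {
  g <- generate_triple("slow_blob", seed = 3)
  mask <- opposition_mask(flow_pair(g$triple))
  det <- label_components(mask, 8L, 2L)
  expect_equal(det$n_components, 0L)
})

test_that("detect_sequence orchestrates triples, strides and labeling", {
  # static 10-frame scene: every frame reports zero components
  f <- matrix(50, 24, 24); f[8:12, 6:10] <- 120
  frames <- lapply(0:9, function(i) gray_frame(f, i))
  res <- detect_sequence(frames, detector_config())
  expect_length(res, 8)
  expect_true(all(vapply(res, `[[`, integer(1), "n_components") == 0L))
  expect_equal(vapply(res, `[[`, integer(1), "frame_index"), 1:8)

  # frame_stride subsamples before building triples
  res2 <- detect_sequence(frames, detector_config(frame_stride = 3))
  expect_length(res2, 2)  # 4 kept frames -> 2 interior

  # manifest records the configuration actually used
  man <- attr(res, "manifest")
  expect_equal(man$beta1, 0.35)
  expect_equal(man$n_frames, 10)

  expect_error(detect_sequence(frames[1:2], detector_config()), "at least 3")
})

test_that("pixel stride reproduces stride-1 counts to within one blob", {
  sc <- generate_scene(scene_config(n_frames = 12, seed = 19))
  c1 <- vapply(detect_sequence(sc$frames, detector_config()),
               `[[`, integer(1), "n_components")
  c2 <- vapply(detect_sequence(sc$frames, detector_config(pixel_stride = 2)),
               `[[`, integer(1), "n_components")
  expect_gte(mean(abs(c1 - c2) <= 1), 0.8)
})
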