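#' Synthetic underwater scene configuration
#'
#' Describes a seeded synthetic video that emulates the data regime the
#' detector targets: a locally time-invariant (or slowly drifting)
#' background, small bright hard-edged blobs whose per-frame displacement
#' exceeds their own diameter (so consecutive positions never overlap), an
#' optional diffuse low-contrast sediment-cloud distractor, and additive
#' Gaussian sensor noise. The defaults are the package's reference scene:
#' 20 frames of 128x128, constant background at gray level 60, 8 blobs of
#' radius 2--4 px with intensity offsets 60--120 moving 9--14 px/frame,
#' noise sigma 1, seed 7.
#'
#' @param n_frames Number of frames, >= 3.
#' @param height,width Frame size in pixels.
#' @param background List: `mode` one of `"constant"`, `"texture"`,
#'   `"drift"`; `level` mean gray level; `contrast` texture amplitude;
#'   `velocity` drift in px/frame `c(dx, dy)`.
#' @param blobs List: `count`; `radius_range` (px, integers); `offset_range`
#'   additive intensity offset; `displacement_range` per-frame displacement
#'   magnitude (px); `mode` `"fast"` (default; enforces displacement
#'   >= 2*radius+1, the non-overlap premise) or `"slow"`; `soft_edge`
#'   logical, render blobs with a smooth 1-px falloff instead of hard disks.
#' @param sediment List: `enabled`; `extent` Gaussian sd in px; `contrast`
#'   peak amplitude; `velocity` px/frame `c(dx, dy)`.
#' @param noise_sigma Additive Gaussian noise level (gray levels).
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_frames = 20L, height = 128L, width = 128L,
                         background = list(), blobs = list(),
                         sediment = list(), noise_sigma = 1, seed = 7L) {
  bg <- utils::modifyList(list(mode = "constant", level = 60, contrast = 20,
                               velocity = c(0.3, 0.2)), background)
  bl <- utils::modifyList(list(count = 8L, radius_range = c(2L, 4L),
                               offset_range = c(60, 120),
                               displacement_range = c(9, 14),
                               mode = "fast", soft_edge = FALSE), blobs)
  sd_ <- utils::modifyList(list(enabled = FALSE, extent = 25, contrast = 8,
                                velocity = c(1, 0.5)), sediment)
  if (n_frames < 3L) stop("`n_frames` must be >= 3", call. = FALSE)
  if (!bg$mode %in% c("constant", "texture", "drift")) {
    stop("`background$mode` must be constant, texture or drift", call. = FALSE)
  }
  if (!bl$mode %in% c("fast", "slow")) {
    stop("`blobs$mode` must be fast or slow", call. = FALSE)
  }
  if (bl$count < 0L) stop("`blobs$count` must be >= 0", call. = FALSE)
  top <- bg$level + bg$contrast * (bg$mode != "constant") + max(bl$offset_range)
  if (top > 255 || bg$level - bg$contrast < 0) {
    stop("`blobs$offset_range`/`background$level` would leave the 0-255 range",
         call. = FALSE)
  }
  rmax <- max(bl$radius_range)
  if (bl$count > 0L && min(height, width) < 2L * (rmax + 3L)) {
    stop("`height`/`width` too small for `blobs$radius_range`", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width), background = bg, blobs = bl,
                 sediment = sd_, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# pixels of the discrete disk (dx^2 + dy^2 <= r^2) around integer center
disk_cells <- function(cx, cy, r, h, w, soft = FALSE) {
  dx <- rep(-r:r, times = 2L * r + 1L)
  dy <- rep(-r:r, each = 2L * r + 1L)
  d2 <- dx^2 + dy^2
  keep <- d2 <= r^2
  x <- cx + dx[keep]; y <- cy + dy[keep]
  inb <- x >= 1L & x <= w & y >= 1L & y <= h
  wgt <- if (soft) pmin(1, pmax(0.25, 1 - (sqrt(d2[keep]) - (r - 1)) / 2))
         else rep(1, sum(keep))
  list(idx = (x[inb] - 1L) * h + y[inb], weight = wgt[inb])
}

gauss_bump <- function(h, w, cx, cy, sd, amp) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sd^2))
}

smooth_texture <- function(h, w, level, contrast) {
  m <- matrix(stats::runif(h * w, -1, 1), h, w)
  for (i in 1:4) m <- mean3x3(m, include_center = TRUE)
  level + contrast * m / max(abs(m))
}

circ_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  r <- ((seq_len(h) - 1L - dy) %% h) + 1L
  c <- ((seq_len(w) - 1L - dx) %% w) + 1L
  m[r, c]
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# draw one element from a vector (safe for length-1 vectors, unlike sample())
draw1 <- function(v) v[sample.int(length(v), 1L)]

# one blob's integer trajectory; fast mode keeps consecutive disks disjoint
blob_track <- function(n_frames, h, w, radius, disp_range, fast) {
  margin <- radius + 2L
  pos <- c(x = draw1(margin:(w - margin)),
           y = draw1(margin:(h - margin)))
  floor_d <- if (fast) max(disp_range[1], 2 * radius + 1) else disp_range[1]
  hi_d <- max(disp_range[2], floor_d)
  track <- matrix(NA_integer_, n_frames, 2L, dimnames = list(NULL, c("x", "y")))
  track[1L, ] <- pos
  for (t in 2:n_frames) {
    ok <- FALSE
    for (try in 1:200) {
      d <- stats::runif(1, floor_d, hi_d)
      th <- stats::runif(1, 0, 2 * pi)
      step <- round(d * c(cos(th), sin(th)))
      cand <- pos + step
      if (fast && sum(step^2) < (2 * radius + 1)^2) next
      if (cand[1] >= margin && cand[1] <= w - margin &&
          cand[2] >= margin && cand[2] <= h - margin) {
        ok <- TRUE; break
      }
    }
    if (!ok) {  # deterministic fallback: hop toward the frame center
      ctr <- c(w, h) / 2
      dirn <- ctr - pos; dirn <- dirn / sqrt(sum(dirn^2))
      step <- round((floor_d + 1) * dirn)
      cand <- pos + step
    }
    pos <- cand
    track[t, ] <- pos
  }
  track
}

#' Generate a seeded synthetic scene with ground truth
#'
#' Renders the background for each frame per its mode (constant; static
#' smoothed texture; texture drifting at a sub-blob velocity with toroidal
#' wrap), adds the optional sediment cloud (a drifting Gaussian intensity
#' bump), stamps each blob as a constant additive intensity offset on a
#' hard-edged discrete disk, and adds Gaussian noise last (clamped to
#' 0--255). Ground truth records, per frame, exactly the pixels any blob
#' modified, plus each blob's center, radius and pixel count. All
#' randomness flows from `cfg$seed` through R's Mersenne-Twister generator;
#' each blob's trajectory uses a sub-seed drawn once from the main stream,
#' so scenes are bit-reproducible across platforms.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `synthetic_scene`: `frames` (list of
#'   [gray_frame()]), `truth` (class `scene_truth`: `masks`, logical
#'   matrices; `blobs`, a data.frame `frame_index`, `blob`, `x`, `y`,
#'   `radius`, `n_pixels`; `counts`, integer per frame), and `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  h <- cfg$height; w <- cfg$width; nf <- cfg$n_frames
  bl <- cfg$blobs; bg <- cfg$background
  with_seed(cfg$seed, {
    sub_seeds <- if (bl$count > 0L) sample.int(.Machine$integer.max - 1L,
                                               bl$count) else integer(0)
    rvals <- bl$radius_range[1]:bl$radius_range[2]
    radii <- if (bl$count > 0L)
      rvals[sample.int(length(rvals), bl$count, replace = TRUE)]
      else integer(0)
    offsets <- stats::runif(bl$count, bl$offset_range[1], bl$offset_range[2])
    tracks <- lapply(seq_len(bl$count), function(b) {
      with_seed(sub_seeds[b],
                blob_track(nf, h, w, radii[b], bl$displacement_range,
                           fast = bl$mode == "fast"))
    })
    texture <- if (bg$mode %in% c("texture", "drift")) {
      smooth_texture(h, w, bg$level, bg$contrast)
    }
    sed0 <- if (cfg$sediment$enabled) {
      c(x = stats::runif(1, w * 0.3, w * 0.7),
        y = stats::runif(1, h * 0.3, h * 0.7))
    }
    frames <- vector("list", nf)
    masks <- vector("list", nf)
    blob_rows <- list()
    counts <- integer(nf)
    for (t in seq_len(nf)) {
      base <- switch(bg$mode,
        constant = matrix(bg$level, h, w),
        texture = texture,
        drift = circ_shift(texture, round((t - 1) * bg$velocity[1]),
                           round((t - 1) * bg$velocity[2])))
      if (cfg$sediment$enabled) {
        base <- base + gauss_bump(h, w,
                                  sed0["x"] + (t - 1) * cfg$sediment$velocity[1],
                                  sed0["y"] + (t - 1) * cfg$sediment$velocity[2],
                                  cfg$sediment$extent, cfg$sediment$contrast)
      }
      mask <- matrix(FALSE, h, w)
      for (b in seq_len(bl$count)) {
        cells <- disk_cells(tracks[[b]][t, "x"], tracks[[b]][t, "y"], radii[b],
                            h, w, soft = bl$soft_edge)
        base[cells$idx] <- base[cells$idx] + offsets[b] * cells$weight
        mask[cells$idx] <- TRUE
        blob_rows[[length(blob_rows) + 1L]] <- data.frame(
          frame_index = t - 1L, blob = b,
          x = tracks[[b]][t, "x"], y = tracks[[b]][t, "y"],
          radius = radii[b], n_pixels = length(cells$idx))
      }
      counts[t] <- bl$count
      if (cfg$noise_sigma > 0) {
        base <- base + matrix(stats::rnorm(h * w, 0, cfg$noise_sigma), h, w)
        base <- pmin(pmax(base, 0), 255)
      }
      frames[[t]] <- gray_frame(base, index = t - 1L)
      masks[[t]] <- mask
    }
    truth <- structure(list(
      masks = masks,
      blobs = if (length(blob_rows)) do.call(rbind, blob_rows)
              else data.frame(frame_index = integer(0), blob = integer(0),
                              x = integer(0), y = integer(0),
                              radius = integer(0), n_pixels = integer(0)),
      counts = counts), class = "scene_truth")
    structure(list(frames = frames, truth = truth, config = cfg),
              class = "synthetic_scene")
  })
}

#' Generate a three-frame fixture for the opposition property
#'
#' Small seeded frame triples that satisfy — or deliberately violate — the
#' premises of the flow-opposition property:
#' \describe{
#'   \item{`fast_blob`}{Constant background, zero noise, one hard-edged blob
#'     whose mid-frame position is farther than its own diameter from its
#'     position in the flanking frames, which is the *same* in frames t-1
#'     and t+1 (out-and-back motion). The flanking frames are then
#'     identical, so the time-invariance premise holds at every pixel and
#'     the two flow fields are exact negatives everywhere. Note the
#'     detector then marks two sites: the mid-frame position, and the
#'     vacated-and-reoccupied flanking position, which is an equally
#'     genuine opposition event under this motion.}
#'   \item{`slow_blob`}{The blob moves 1 px per frame, overlapping its
#'     previous position: the non-overlap premise is violated.}
#'   \item{`static`}{A textured but frozen scene; both flow fields are
#'     identically zero.}
#'   \item{`sediment_only`}{Only the diffuse low-contrast drifting cloud;
#'     its flows are co-directed, never opposite.}
#' }
#'
#' @param kind One of `"fast_blob"`, `"slow_blob"`, `"static"`,
#'   `"sediment_only"`.
#' @param seed Integer seed.
#' @param height,width Frame size (default 48x48).
#' @return A list: `triple` (a [frame_triple()]) and `truth` (a
#'   `scene_truth` for the three frames).
#' @export
generate_triple <- function(kind = c("fast_blob", "slow_blob", "static",
                                     "sediment_only"),
                            seed = 1L, height = 48L, width = 48L) {
  kind <- match.arg(kind)
  h <- as.integer(height); w <- as.integer(width)
  with_seed(seed, {
    level <- 60
    empty_truth <- function() {
      structure(list(masks = replicate(3, matrix(FALSE, h, w),
                                       simplify = FALSE),
                     blobs = data.frame(frame_index = integer(0),
                                        blob = integer(0), x = integer(0),
                                        y = integer(0), radius = integer(0),
                                        n_pixels = integer(0)),
                     counts = c(0L, 0L, 0L)), class = "scene_truth")
    }
    if (kind == "static") {
      f <- smooth_texture(h, w, level, 20)
      frames <- lapply(0:2, function(i) gray_frame(f, index = i))
      return(list(triple = frame_triple(frames[[1]], frames[[2]], frames[[3]]),
                  truth = empty_truth()))
    }
    if (kind == "sediment_only") {
      cx <- stats::runif(1, w * 0.35, w * 0.65)
      cy <- stats::runif(1, h * 0.35, h * 0.65)
      frames <- lapply(0:2, function(i) {
        gray_frame(matrix(level, h, w) +
                     gauss_bump(h, w, cx + 2 * i, cy + 1 * i, h / 4, 8),
                   index = i)
      })
      return(list(triple = frame_triple(frames[[1]], frames[[2]], frames[[3]]),
                  truth = empty_truth()))
    }
    r <- draw1(2:3)
    offset <- stats::runif(1, 60, 120)
    if (kind == "fast_blob") {
      p2 <- c(x = draw1((w %/% 3):(2 * w %/% 3)),
              y = draw1((h %/% 3):(2 * h %/% 3)))
      repeat {
        d <- stats::runif(1, 2 * r + 2, 2 * r + 6)
        th <- stats::runif(1, 0, 2 * pi)
        step <- round(d * c(cos(th), sin(th)))
        p1 <- p2 - step
        if (sum(step^2) >= (2 * r + 1)^2 &&
            all(p1 >= r + 2) && p1[1] <= w - r - 1 && p1[2] <= h - r - 1) break
      }
      centers <- list(p1, p2, p1)   # out and back: frames t-1 and t+1 agree
    } else {                        # slow_blob: 1 px/frame, overlapping
      p1 <- c(x = w %/% 2, y = h %/% 2)
      centers <- list(p1, p1 + c(1L, 0L), p1 + c(2L, 0L))
    }
    frames <- vector("list", 3L)
    masks <- vector("list", 3L)
    rows <- list()
    for (i in 1:3) {
      base <- matrix(level, h, w)
      cells <- disk_cells(centers[[i]][1], centers[[i]][2], r, h, w)
      base[cells$idx] <- base[cells$idx] + offset
      m <- matrix(FALSE, h, w); m[cells$idx] <- TRUE
      frames[[i]] <- gray_frame(base, index = i - 1L)
      masks[[i]] <- m
      rows[[i]] <- data.frame(frame_index = i - 1L, blob = 1L,
                              x = centers[[i]][1], y = centers[[i]][2],
                              radius = r, n_pixels = length(cells$idx))
    }
    truth <- structure(list(masks = masks, blobs = do.call(rbind, rows),
                            counts = c(1L, 1L, 1L)), class = "scene_truth")
    list(triple = frame_triple(frames[[1]], frames[[2]], frames[[3]]),
         truth = truth)
  })
}
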