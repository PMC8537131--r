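#' Write per-frame detections as CSV
#'
#' One row per component: `frame_index`, `n_plankton`, `label`,
#' `centroid_x`, `centroid_y`, `n_pixels`. Frames with no detections emit a
#' single row with `NA` component fields so every evaluated frame appears.
#'
#' @param results List of [label_components()] results.
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_detections_csv <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (r$n_components == 0L) {
      data.frame(frame_index = r$frame_index, n_plankton = 0L,
                 label = NA_integer_, centroid_x = NA_real_,
                 centroid_y = NA_real_, n_pixels = NA_integer_)
    } else {
      cbind(data.frame(frame_index = r$frame_index,
                       n_plankton = r$n_components), r$components)
    }
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read a detections CSV back into detection summaries
#'
#' Inverse of [write_detections_csv()] as far as evaluation needs: per
#' frame, the component table (no masks).
#'
#' @param path CSV path.
#' @return List of `detection_result`s (with empty masks).
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$frame_index), function(d) {
    comp <- d[!is.na(d$label),
              c("label", "centroid_x", "centroid_y", "n_pixels")]
    rownames(comp) <- NULL
    structure(list(frame_index = d$frame_index[1], mask = NULL,
                   n_components = nrow(comp), components = comp),
              class = "detection_result")
  })
}

#' Write a quantification series as CSV
#' @param series A [aggregate_series()] result.
#' @param path Output CSV path.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(series)
}

#' Write a binary mask (or frame) as PNG
#'
#' Masks are written as 0/255; gray frames are clamped to 0--255 and scaled
#' to the PNG [0, 1] range (8-bit quantization applies).
#'
#' @param x Logical mask or numeric frame matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(x, path) {
  m <- if (is.logical(x)) x * 1 else pmin(pmax(x, 0), 255) / 255
  png::writePNG(m, path)
  invisible(path)
}

#' Write scene ground truth as PNG masks plus a JSON index
#'
#' @param truth A `scene_truth`.
#' @param dir Output directory; masks go to `dir/truth_mask_%04d.png`, the
#'   blob index (frame, blob id, center, radius, pixel count) to
#'   `dir/truth.json`.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(truth$masks)) {
    write_mask_png(truth$masks[[i]],
                   file.path(dir, sprintf("truth_mask_%04d.png", i - 1L)))
  }
  jsonlite::write_json(truth$blobs, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Read a ground-truth JSON index
#' @param path Path to `truth.json`.
#' @return A `scene_truth` (blob table and counts only; no masks).
#' @export
read_truth_json <- function(path) {
  blobs <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  counts <- if (nrow(blobs)) {
    as.integer(table(factor(blobs$frame_index,
                            levels = 0:max(blobs$frame_index))))
  } else integer(0)
  structure(list(masks = NULL, blobs = blobs, counts = counts),
            class = "scene_truth")
}

#' Write a reproducibility manifest
#'
#' Records the command, the fully resolved configuration, input identity
#' (paths and MD5 digests for files), the seed, the package version and a
#' timestamp as JSON. Re-running the same command with the same inputs and
#' seed reproduces deterministic outputs bit-identically.
#'
#' @param path Output JSON path.
#' @param command Command name.
#' @param config Named list of resolved configuration values.
#' @param inputs Character vector of input paths (digested when they
#'   exist).
#' @param seed Seed used, or `NA`.
#' @export
write_manifest <- function(path, command, config, inputs = character(0),
                           seed = NA) {
  files <- inputs[file.exists(inputs) & !dir.exists(inputs)]
  manifest <- list(
    command = command,
    config = config,
    inputs = lapply(inputs, function(p) {
      list(path = p,
           md5 = if (p %in% files) unname(tools::md5sum(p)) else NA)
    }),
    seed = seed,
    version = as.character(utils::packageVersion("planktonflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
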