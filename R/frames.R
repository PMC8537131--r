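#' Construct a grayscale frame
#'
#' A `gray_frame` is a plain numeric matrix of intensities (nominally on the
#' 0--255 grayscale) carrying a 0-based time index. Rows are the vertical
#' image coordinate `y` (increasing downward), columns the horizontal
#' coordinate `x` (increasing rightward); pixel positions reported elsewhere
#' in the package are 1-based matrix indices in this convention. Intensities
#' are held as reals: the optical-flow relaxation is real-valued, so frames
#' are never re-quantized after grayscale conversion.
#'
#' @param pixels Numeric matrix of intensities, at least 2x2, all finite.
#' @param index Integer time index `t >= 0`.
#' @return A numeric matrix of class `gray_frame` with attribute `index`.
#' @examples
#' f <- gray_frame(matrix(0, 4, 4), index = 0)
#' frame_index(f)
#' @export
gray_frame <- function(pixels, index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("a gray_frame needs height >= 2 and width >= 2", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L) {
    stop("`index` must be a single integer >= 0", call. = FALSE)
  }
  structure(pixels, index = index, class = c("gray_frame", class(pixels)))
}

#' @rdname gray_frame
#' @param frame A `gray_frame` (or plain matrix, giving index 0).
#' @export
frame_index <- function(frame) {
  idx <- attr(frame, "index")
  if (is.null(idx)) 0L else as.integer(idx)
}

# strip class/attrs down to a plain numeric matrix
frame_pixels <- function(frame) {
  matrix(as.numeric(frame), nrow = nrow(frame), ncol = ncol(frame))
}

#' Group three consecutive frames
#'
#' The detector's unit of work: frames at times t-1, t, t+1. All three must
#' share one shape, and their indices must be consecutive (after any
#' frame-stride subsampling has been applied and indices renumbered).
#'
#' @param prev,mid,nxt `gray_frame`s with consecutive indices.
#' @return A list of class `frame_triple` with elements `prev`, `mid`, `nxt`.
#' @export
frame_triple <- function(prev, mid, nxt) {
  dims <- rbind(dim(prev), dim(mid), dim(nxt))
  if (nrow(unique(dims)) != 1L) {
    stop("all three frames of a triple must share the same height and width",
         call. = FALSE)
  }
  idx <- c(frame_index(prev), frame_index(mid), frame_index(nxt))
  if (!all(diff(idx) == 1L)) {
    stop("frame indices must be consecutive (t-1, t, t+1); got ",
         paste(idx, collapse = ", "), call. = FALSE)
  }
  structure(list(prev = prev, mid = mid, nxt = nxt), class = "frame_triple")
}

#' Convert an RGB frame to grayscale
#'
#' Grayscale is the weighted sum of the three channels. The default weights
#' are the ITU-R BT.601 luma triple (0.299, 0.587, 0.114); they are
#' configurable but must sum to 1. Already-grayscale input (a 2D matrix)
#' passes through unchanged.
#'
#' @param rgb Either a `height x width x 3` numeric array or a 2D matrix
#'   (returned as-is).
#' @param weights Three nonnegative reals summing to 1 (tolerance 1e-9).
#' @param index Time index forwarded to [gray_frame()].
#' @return A [gray_frame()].
#' @examples
#' px <- array(0, dim = c(2, 2, 3)); px[1, 1, ] <- c(255, 0, 0)
#' to_grayscale(px)[1, 1]  # 76.245
#' @export
to_grayscale <- function(rgb, weights = c(0.299, 0.587, 0.114), index = 0L) {
  if (length(weights) != 3L || any(weights < 0)) {
    stop("`weights` must be 3 nonnegative reals", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("grayscale weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  }
  if (is.matrix(rgb)) {
    return(gray_frame(frame_pixels(rgb), index = index))
  }
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    stop("`rgb` must be a height x width x 3 array or a 2D matrix",
         call. = FALSE)
  }
  g <- rgb[, , 1] * weights[1] + rgb[, , 2] * weights[2] + rgb[, , 3] * weights[3]
  gray_frame(g, index = index)
}

#' Build the padded two-frame block consumed by the gradient kernels
#'
#' Stacks two same-shaped frames into a `(height+1) x (width+1) x 2` array,
#' extending each frame by one replicated last row and column. The 2x2x2
#' gradient kernels evaluated on this block are then defined at every
#' original pixel, with the `x+1` / `y+1` neighbor always in range; edge
#' replication makes border gradients depend only on real pixels rather than
#' fabricating contrast.
#'
#' @param a,b Same-shaped numeric matrices (or `gray_frame`s).
#' @return A numeric array of dim `c(nrow(a) + 1, ncol(a) + 1, 2)`.
#' @export
pad_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("frames must share the same shape to be padded as a pair",
         call. = FALSE)
  }
  h <- nrow(a); w <- ncol(a)
  block <- array(NA_real_, dim = c(h + 1L, w + 1L, 2L))
  block[1:h, 1:w, 1L] <- a
  block[1:h, 1:w, 2L] <- b
  block[h + 1L, , ] <- block[h, , ]      # replicate last row
  block[, w + 1L, ] <- block[, w, ]      # replicate last column
  block
}

#' Read an ordered image sequence as grayscale frames
#'
#' Reads a lexicographically sorted glob of PNG or TIFF frames (or an
#' explicit character vector of paths, kept in the given order), converts
#' color frames to grayscale, rescales the decoders' [0, 1] intensities to
#' the nominal 0--255 range, and applies an optional frame stride: stride
#' `s` keeps source frames `0, s, 2s, ...`. Returned frames are re-indexed
#' consecutively from 0 (the original source index is kept in attribute
#' `source_index`). A list of matrices passes through the same striding and
#' conversion, so in-memory scenes use the identical path.
#'
#' @param source A glob pattern (e.g. `"frames/*.png"`), a directory
#'   containing PNG/TIFF files, a character vector of file paths, or a list
#'   of matrices / `gray_frame`s.
#' @param frame_stride Positive integer; 1 keeps every frame.
#' @param weights Grayscale weights, see [to_grayscale()].
#' @return List of [gray_frame()]s in temporal order (at least 3).
#' @export
read_frames <- function(source, frame_stride = 1L,
                        weights = c(0.299, 0.587, 0.114)) {
  frame_stride <- as.integer(frame_stride)
  if (is.na(frame_stride) || frame_stride < 1L) {
    stop("`frame_stride` must be a positive integer", call. = FALSE)
  }
  if (is.list(source) && !is.data.frame(source)) {
    raw <- source
  } else if (is.character(source)) {
    paths <- resolve_frame_paths(source)
    raw <- lapply(paths, read_image_file)
  } else {
    stop("`source` must be a path/glob, a vector of paths, or a list of frames",
         call. = FALSE)
  }
  kept <- seq(1L, length(raw), by = frame_stride)
  frames <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    fr <- raw[[kept[i]]]
    g <- if (is.matrix(fr)) gray_frame(frame_pixels(fr), index = i - 1L)
         else to_grayscale(fr, weights = weights, index = i - 1L)
    attr(g, "source_index") <- kept[i] - 1L
    frames[[i]] <- g
  }
  if (length(frames) < 3L) {
    stop("need at least 3 frames after striding; got ", length(frames),
         call. = FALSE)
  }
  frames
}

resolve_frame_paths <- function(source) {
  if (length(source) == 1L) {
    if (dir.exists(source)) {
      paths <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
      paths <- sort(paths)
    } else if (grepl("[*?\\[]", source)) {
      paths <- sort(Sys.glob(source))
    } else {
      paths <- source
    }
  } else {
    paths <- source  # explicit ordering respected
  }
  missing <- paths[!file.exists(paths)]
  if (length(paths) == 0L || length(missing) > 0L) {
    stop("cannot read frames from '", paste(utils::head(missing, 1), collapse = ""),
         if (length(paths) == 0L) paste0(source, "': no files matched")
         else "': file does not exist",
         call. = FALSE)
  }
  paths
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF frames requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported frame format '", ext, "' for '", path,
         "' (PNG and TIFF image sequences are supported)", call. = FALSE)
  }
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE] * 255  # drop alpha if present
  } else if (length(d) == 3L) {
    img <- img[, , 1] * 255                  # gray(+alpha)
  } else {
    img <- img * 255
  }
  img
}
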