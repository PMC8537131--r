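#' Spatiotemporal gradients of a frame pair
#'
#' Evaluates the three 2x2x2 difference kernels on the padded two-frame
#' block: at every pixel `(x, y)` (x = column, y = row),
#' \deqn{\nabla t = \tfrac12[(b_{x,y}-a_{x,y}) + (b_{x+1,y}-a_{x+1,y})]}
#' \deqn{\nabla x = \tfrac12[(b_{x+1,y}-b_{x,y}) + (a_{x+1,y}-a_{x,y})]}
#' \deqn{\nabla y = \tfrac12[(b_{x,y+1}-b_{x,y}) + (a_{x,y+1}-a_{x,y})]}
#' with the `x+1` / `y+1` neighbors taken from the edge-replicated pad, so
#' the last row and column see zero artificial contrast. The temporal kernel
#' averages over the x-neighbor only (its printed two-term form); the full
#' four-term cube average over the 2x2 spatial footprint is available via
#' `cube_mean = TRUE`.
#'
#' @param a,b Same-shaped frames at times t and t+1 (`a` earlier).
#' @param cube_mean If `TRUE`, average each kernel over the full 2x2 spatial
#'   footprint of the cube instead of the two printed terms.
#' @return A list of class `gradient_field` with matrices `gx`, `gy`, `gt`
#'   shaped like the input frames.
#' @export
compute_gradients <- function(a, b, cube_mean = FALSE) {
  block <- pad_pair(a, b)
  h <- nrow(a); w <- ncol(a)
  A <- block[, , 1L]; B <- block[, , 2L]
  r <- 1:h; rr <- 2:(h + 1L)
  c0 <- 1:w; cc <- 2:(w + 1L)
  if (!cube_mean) {
    gt <- 0.5 * ((B[r, c0] - A[r, c0]) + (B[r, cc] - A[r, cc]))
    gx <- 0.5 * ((B[r, cc] - B[r, c0]) + (A[r, cc] - A[r, c0]))
    gy <- 0.5 * ((B[rr, c0] - B[r, c0]) + (A[rr, c0] - A[r, c0]))
  } else {
    gt <- 0.25 * ((B[r, c0] - A[r, c0]) + (B[r, cc] - A[r, cc]) +
                  (B[rr, c0] - A[rr, c0]) + (B[rr, cc] - A[rr, cc]))
    gx <- 0.25 * ((B[r, cc] - B[r, c0]) + (A[r, cc] - A[r, c0]) +
                  (B[rr, cc] - B[rr, c0]) + (A[rr, cc] - A[rr, c0]))
    gy <- 0.25 * ((B[rr, c0] - B[r, c0]) + (A[rr, c0] - A[r, c0]) +
                  (B[rr, cc] - B[r, cc]) + (A[rr, cc] - A[r, cc]))
  }
  structure(list(gx = gx, gy = gy, gt = gt), class = "gradient_field")
}

#' Solve for dense optical flow by pointwise gradient relaxation
#'
#' Starting from `u = v = 0`, repeats `n_iters` times, pointwise at every
#' pixel:
#' \deqn{\Delta = (\nabla x\,u + \nabla y\,v + \nabla t) /
#'               (\alpha^2 + \nabla x^2 + \nabla y^2)}
#' \deqn{u \leftarrow u - \nabla x\,\Delta,\qquad
#'       v \leftarrow v - \nabla y\,\Delta}
#' The smoothness weight `alpha2` (\eqn{\alpha^2 > 0}) keeps the denominator
#' positive and damps the step. By default the update uses each pixel's own
#' current `(u, v)` — the form under which the flow-opposition property is
#' exact; the classic Horn--Schunck variant that replaces `(u, v)` by a 3x3
#' neighborhood mean before the update is available via
#' `neighborhood_average`. The iteration is deterministic: identical inputs
#' give bit-identical outputs.
#'
#' @param grad A `gradient_field` from [compute_gradients()].
#' @param alpha2 Smoothness weight, `> 0`. Default 100.
#' @param n_iters Iteration count, `>= 1`. Default 100.
#' @param neighborhood_average One of `"none"` (pointwise, default),
#'   `"exclude_center"`, `"include_center"` (3x3 mean variants).
#' @return A list of class `flow_field` with matrices `u`, `v` (pixels/frame;
#'   u horizontal, v vertical/downward) and the solver parameters.
#' @export
hs_solve <- function(grad, alpha2 = 100, n_iters = 100,
                     neighborhood_average = c("none", "exclude_center",
                                              "include_center")) {
  neighborhood_average <- match.arg(neighborhood_average)
  if (!is.numeric(alpha2) || length(alpha2) != 1L || !is.finite(alpha2) ||
      alpha2 <= 0) {
    stop("`alpha2` must be a single positive number", call. = FALSE)
  }
  n_iters <- as.integer(n_iters)
  if (is.na(n_iters) || n_iters < 1L) {
    stop("`n_iters` must be an integer >= 1", call. = FALSE)
  }
  gx <- grad$gx; gy <- grad$gy; gt <- grad$gt
  if (!all(is.finite(gx), is.finite(gy), is.finite(gt))) {
    stop("gradients must be finite", call. = FALSE)
  }
  denom <- alpha2 + gx^2 + gy^2
  u <- v <- matrix(0, nrow(gx), ncol(gx))
  for (i in seq_len(n_iters)) {
    if (neighborhood_average != "none") {
      u <- mean3x3(u, include_center = neighborhood_average == "include_center")
      v <- mean3x3(v, include_center = neighborhood_average == "include_center")
    }
    delta <- (gx * u + gy * v + gt) / denom
    u <- u - gx * delta
    v <- v - gy * delta
  }
  structure(list(u = u, v = v, alpha2 = alpha2, n_iters = n_iters,
                 neighborhood_average = neighborhood_average),
            class = "flow_field")
}

# 3x3 neighborhood mean with edge replication; classic relaxation variant
mean3x3 <- function(m, include_center = FALSE) {
  h <- nrow(m); w <- ncol(m)
  up <- c(1L, 1:(h - 1L)); dn <- c(2:h, h)
  lf <- c(1L, 1:(w - 1L)); rt <- c(2:w, w)
  s <- m[up, lf] + m[up, ] + m[up, rt] +
       m[, lf]  +            m[, rt]  +
       m[dn, lf] + m[dn, ] + m[dn, rt]
  if (include_center) (s + m) / 9 else s / 8
}

#' Two consecutive flow fields from a frame triple
#'
#' Computes the flow for the pair (t-1, t) and the pair (t, t+1) with
#' identical solver parameters. For a fast-moving blob over a locally
#' time-invariant background the two fields are exact negatives at the
#' blob's mid-frame position — the opposition property the detector
#' thresholds on.
#'
#' @param triple A [frame_triple()].
#' @inheritParams hs_solve
#' @param cube_mean Forwarded to [compute_gradients()].
#' @return A list of class `flow_pair` with `flow_field`s `first`, `second`.
#' @export
flow_pair <- function(triple, alpha2 = 100, n_iters = 100,
                      neighborhood_average = "none", cube_mean = FALSE) {
  stopifnot(inherits(triple, "frame_triple"))
  g1 <- compute_gradients(triple$prev, triple$mid, cube_mean = cube_mean)
  g2 <- compute_gradients(triple$mid, triple$nxt, cube_mean = cube_mean)
  structure(list(
    first  = hs_solve(g1, alpha2, n_iters, neighborhood_average),
    second = hs_solve(g2, alpha2, n_iters, neighborhood_average)
  ), class = "flow_pair")
}

#' Export flow and gradient grids as TSV for inspection
#'
#' Writes each grid of a `flow_pair`, `flow_field`, or `gradient_field` as a
#' plain tab-separated matrix (one file per grid) for debugging.
#'
#' @param x A `flow_pair`, `flow_field`, or `gradient_field`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix, e.g. the frame index.
#' @return Invisibly, the written file paths.
#' @export
export_flow_fields <- function(x, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grids <- if (inherits(x, "flow_pair")) {
    list(u = x$first$u, v = x$first$v, u2 = x$second$u, v2 = x$second$v)
  } else if (inherits(x, "flow_field")) {
    list(u = x$u, v = x$v)
  } else if (inherits(x, "gradient_field")) {
    list(gx = x$gx, gy = x$gy, gt = x$gt)
  } else {
    stop("cannot export object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(grids)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    utils::write.table(grids[[nm]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
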