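# Independent brute-force oracles, kept deliberately naive so they cannot
# share bugs with the vectorized implementations they check.

# per-pixel double-loop evaluation of the three 2x2x2 gradient kernels
oracle_gradients <- function(a, b) {
  h <- nrow(a); w <- ncol(a)
  # replicate-pad by hand
  A <- rbind(cbind(a, a[, w]), c(a[h, ], a[h, w]))
  B <- rbind(cbind(b, b[, w]), c(b[h, ], b[h, w]))
  gx <- gy <- gt <- matrix(NA_real_, h, w)
  for (y in 1:h) {
    for (x in 1:w) {
      gt[y, x] <- 0.5 * ((B[y, x] - A[y, x]) + (B[y, x + 1] - A[y, x + 1]))
      gx[y, x] <- 0.5 * ((B[y, x + 1] - B[y, x]) + (A[y, x + 1] - A[y, x]))
      gy[y, x] <- 0.5 * ((B[y + 1, x] - B[y, x]) + (A[y + 1, x] - A[y, x]))
    }
  }
  list(gx = gx, gy = gy, gt = gt)
}

# scalar fixed-point iteration for a single pixel's relaxation
oracle_hs_pixel <- function(gx, gy, gt, alpha2, n) {
  u <- v <- 0
  for (i in seq_len(n)) {
    delta <- (gx * u + gy * v + gt) / (alpha2 + gx^2 + gy^2)
    u <- u - gx * delta
    v <- v - gy * delta
  }
  c(u = u, v = v)
}

# recursive flood fill over a logical mask
oracle_label <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  neigh <- if (connectivity == 4L) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  for (r0 in 1:h) for (c0 in 1:w) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r0, c0))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- nxt
        for (k in seq_len(nrow(neigh))) {
          rr <- p[1] + neigh[k, 1]; cc <- p[2] + neigh[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# component sizes after a min-area filter, as a sorted vector
oracle_component_sizes <- function(mask, connectivity, min_area) {
  lab <- oracle_label(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  sort(sizes[sizes >= min_area])
}

# dilate a mask by one pixel (8-neighborhood)
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(1:h + dr, 1), h)
    cs <- pmin(pmax(1:w + dc, 1), w)
    out <- out | mask[rs, cs]
  }
  out
}

random_frame <- function(h, w) {
  matrix(runif(h * w, 0, 255), h, w)
}
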