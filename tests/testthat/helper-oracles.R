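# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive algorithms (BFS flood fill, exhaustive
# distance scans, direct moment computation) so they share no code with the
# package internals.

# 8-connected components by BFS flood fill; returns a label matrix.
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Pixel sets of an oracle label matrix, ordered by (min row, min col).
oracle_pixel_sets <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  if (!length(sets)) return(list())
  nr <- nrow(lab)
  minr <- vapply(sets, function(px) min((px - 1L) %% nr + 1L), numeric(1))
  minc <- vapply(sets, function(px) min((px - 1L) %/% nr + 1L), numeric(1))
  sets[order(minr, minc)]
}

# All pixels within Euclidean distance `width` of a region, excluding the
# region itself: exhaustive scan over the full frame.
oracle_ring <- function(pixels, dim, width) {
  co <- cbind((pixels - 1L) %% dim[1] + 1L, (pixels - 1L) %/% dim[1] + 1L)
  out <- integer(0)
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
    idx <- (c - 1L) * dim[1] + r
    if (idx %in% pixels) next
    d2 <- min((co[, 1] - r)^2 + (co[, 2] - c)^2)
    if (d2 <= width^2) out <- c(out, idx)
  }
  sort(out)
}

# Major/minor axis ratio from the eigenvalues of the coordinate covariance.
oracle_axis_ratio <- function(pixels, dim) {
  r <- (pixels - 1L) %% dim[1] + 1L
  c <- (pixels - 1L) %/% dim[1] + 1L
  n <- length(pixels)
  mrr <- mean((r - mean(r))^2); mcc <- mean((c - mean(c))^2)
  mrc <- mean((r - mean(r)) * (c - mean(c)))
  tr <- mrr + mcc; det <- mrr * mcc - mrc^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  if (l2 < 1e-12) return(Inf)
  sqrt(l1 / l2)
}

# Textbook one-sample t statistic and two-sided p-value.
oracle_t_test <- function(x) {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  c(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Build a timelapse_stack from a list of matrices with minimal ceremony.
make_stack <- function(frames, interval = 5, px = 0.5, channel = "ecm") {
  timelapse_stack(frames, interval, px, channel)
}

# A frame with flat background plus named rectangular blocks of a value.
block_frame <- function(dim, bg = 0, blocks = list()) {
  f <- matrix(bg, dim[1], dim[2])
  for (b in blocks) f[b$rows, b$cols] <- b$value
  f
}
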