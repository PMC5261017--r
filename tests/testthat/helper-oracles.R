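# Independent oracles used across tests. These deliberately share no code
# with the implementation they check.

# Brute-force flood-fill (BFS) connected-component labeling; components are
# numbered in raster order of their first pixel, matching labelComponents().
floodFillLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  shifts <- if (connectivity == 4L) {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
          c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    head <- 1L
    while (head <= length(queue)) {
      i <- queue[head]; head <- head + 1L
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(shifts))) {
        r2 <- r + shifts[k, 1L]; c2 <- c + shifts[k, 2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive scan for strict local maxima of a vector (interior points).
bruteLocalMaxima <- function(y) {
  which(diff(sign(diff(y))) == -2L) + 1L
}

# Brute-force maximal constant-range spans (same greedy definition as the
# implementation, but recomputing max/min from scratch, O(n^2)).
bruteSpans <- function(g, tol) {
  n <- length(g)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (max(g[i:(j + 1L)]) - min(g[i:(j + 1L)])) <= tol) j <- j + 1L
    out[[length(out) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  do.call(rbind, out)
}

# Brute-force two-sample KS statistic over the pooled points.
bruteKS <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  max(abs(vapply(pool, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Match detected peak positions against truth within a tolerance; returns
# c(tp, fp, fn).
matchPeaks <- function(truth, detected, tol) {
  used <- rep(FALSE, length(truth))
  tp <- 0L; fp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) < tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L } else fp <- fp + 1L
  }
  c(tp = tp, fp = fp, fn = sum(!used))
}
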