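# Independent brute-force oracles. These deliberately use naive loops and
# flood fill so they share no code path with the package implementation.

# voxel confusion counts by explicit triple loop
naive_confusion <- function(pred, ref, dom) {
  tp <- fp <- fn <- tn <- 0L
  d <- dim(pred)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!dom[i, j, k]) next
    if (pred[i, j, k] && ref[i, j, k]) tp <- tp + 1L
    else if (pred[i, j, k] && !ref[i, j, k]) fp <- fp + 1L
    else if (!pred[i, j, k] && ref[i, j, k]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# 26-connected component labels by queue-based flood fill
naive_flood_components <- function(arr) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  labels <- array(0L, dim = d)
  nlab <- 0L
  for (start in which(arr)) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    labels[start] <- nlab
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      i <- v0 %% d[1] + 1L
      j <- (v0 %/% d[1]) %% d[2] + 1L
      k <- v0 %/% (d[1] * d[2]) + 1L
      nb <- cbind(i + offs[, 1], j + offs[, 2], k + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[arr[lin] & labels[lin] == 0L]
      labels[new] <- nlab
      queue <- c(queue, new)
    }
  }
  list(labels = labels, n = nlab)
}

# full reference delineation by naive loops: mean background, per-voxel
# threshold, flood-fill components, strict minimum-volume filter
naive_delineate <- function(img, dom, ratio, min_ml, voxvol_ml) {
  bg <- sum(img) / length(img)
  d <- dim(img)
  cand <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    if (dom[i, j, k] && img[i, j, k] >= ratio * bg) cand[i, j, k] <- TRUE
  lab <- naive_flood_components(cand)
  keep <- array(FALSE, dim = d)
  for (l in seq_len(lab$n)) {
    vox <- which(lab$labels == l)
    if (length(vox) * voxvol_ml > min_ml) keep[vox] <- TRUE
  }
  keep
}

# numeric time-average of a function over [a, b] for kinetic cross-checks
naive_frame_average <- function(f, a, b) {
  stats::integrate(f, a, b, rel.tol = 1e-10,
                   subdivisions = 500L)$value / (b - a)
}
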