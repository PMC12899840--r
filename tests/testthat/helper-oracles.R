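# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# queue-based BFS flood fill over the 8-neighbourhood; label values are
# arbitrary, only the induced partition matters
bfs_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nid <- 0L
  qr <- integer(sum(mask == 1L)); qc <- qr   # preallocated FIFO queue
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (mask[rr, cc] != 1L || lab[rr, cc] != 0L) next
    nid <- nid + 1L
    lab[rr, cc] <- nid
    qr[1L] <- rr; qc[1L] <- cc
    head <- 1L; tail <- 1L
    while (head <= tail) {
      r <- qr[head]; c <- qc[head]; head <- head + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            mask[r2, c2] == 1L && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nid
          tail <- tail + 1L
          qr[tail] <- r2; qc[tail] <- c2
        }
      }
    }
  }
  lab
}

# two labelings induce the same partition iff label values map one-to-one
# over the foreground
same_partition <- function(a, b) {
  fg <- a > 0L | b > 0L
  if (any((a > 0L) != (b > 0L))) return(FALSE)
  pairs <- unique(cbind(a[fg], b[fg]))
  nrow(pairs) == length(unique(pairs[, 1L])) &&
    nrow(pairs) == length(unique(pairs[, 2L]))
}

random_mask <- function(nr, nc, p = 0.3) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# closed-form Welch statistics
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# textbook Pearson formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# aligned pair from two same-size intensity matrices over a full-frame
# foreground (no resampling involved)
pair_from_values <- function(x, y) {
  nr <- 1L; nc <- length(x)
  a <- modality_crop(matrix(x, nr, nc), fg_mask = matrix(1L, nr, nc))
  b <- modality_crop(matrix(y, nr, nc), fg_mask = matrix(1L, nr, nc))
  prepare_pair(a, b)
}
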