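# Independent brute-force oracles used to cross-check the package's
# primitives. These deliberately share no code with the implementation:
# breadth-first searches and per-pixel loops instead of vectorized shifts.

neigh_off <- function(connectivity) {
  if (connectivity == 4) list(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  else list(dr = c(-1, 1, 0, 0, -1, -1, 1, 1), dc = c(0, 0, -1, 1, -1, 1, -1, 1))
}

# flood from every border background pixel; unreached background is a hole
oracle_fill_holes <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- neigh_off(connectivity)
  reach <- matrix(FALSE, nr, nc)
  queue <- which((row(mask) == 1 | row(mask) == nr |
                  col(mask) == 1 | col(mask) == nc) & !mask)
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (k in seq_along(off$dr)) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (!mask[rr, cc] && !reach[rr, cc]) {
        reach[rr, cc] <- TRUE
        queue <- c(queue, (cc - 1) * nr + rr)
      }
    }
  }
  mask | (!mask & !reach)
}

oracle_disk_offsets <- function(radius) {
  out <- NULL
  for (dr in -radius:radius) for (dc in -radius:radius)
    if (dr * dr + dc * dc <= radius * radius) out <- rbind(out, c(dr, dc))
  out
}

oracle_erode <- function(mask, offs) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
        keep <- FALSE; break
      }
    }
    out[r, c] <- keep
  }
  out
}

oracle_dilate <- function(mask, offs) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hit <- FALSE
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && mask[rr, cc]) {
        hit <- TRUE; break
      }
    }
    out[r, c] <- hit
  }
  out
}

# BFS component labelling for the oracle-side area filter
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- neigh_off(connectivity)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0) next
    nxt <- nxt + 1L
    queue <- i; lab[i] <- nxt
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      r <- (j - 1) %% nr + 1; c <- (j - 1) %/% nr + 1
      for (k in seq_along(off$dr)) {
        rr <- r + off$dr[k]; cc <- c + off$dc[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0) {
          lab[(cc - 1) * nr + rr] <- nxt
          queue <- c(queue, (cc - 1) * nr + rr)
        }
      }
    }
  }
  lab
}

oracle_open_and_filter <- function(mask, radius, min_area, max_area) {
  offs <- oracle_disk_offsets(radius)
  opened <- oracle_dilate(oracle_erode(mask, offs), offs)
  lab <- oracle_components(opened, 8)
  if (max(lab) == 0) return(opened)
  for (id in seq_len(max(lab))) {
    a <- sum(lab == id)
    if (a < min_area || a > max_area) opened[lab == id] <- FALSE
  }
  opened
}

# exhaustive 256-candidate scan computing between-class variance from the
# raw binned sample at each split
oracle_otsu <- function(values) {
  bins <- pmin(pmax(floor(values), 0), 255)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- bins[bins <= t]; hi <- bins[bins > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(bins); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# O(n^2) pair counting: (concordant + ties / 2) / (n_pos * n_neg)
oracle_auc <- function(scores, truths, positive = "CTC") {
  pos <- which(truths == positive); neg <- which(truths != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_f_score <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA
  r <- if (tp + fn > 0) tp / (tp + fn) else NA
  if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
}
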