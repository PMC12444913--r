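# Independent brute-force oracles. These deliberately share no code with the
# package implementations: direct loops, explicit formulas, exhaustive
# searches.

reflect_idx_oracle <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# dense 2-D convolution with a truncated Gaussian kernel, reflective borders
oracle_gaussian_blur <- function(x, sigma) {
  h <- ceiling(4 * sigma)
  k1 <- dnorm(-h:h, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- reflect_idx_oracle(i + di, nr)
      jj <- reflect_idx_oracle(j + dj, nc)
      acc <- acc + K[di + h + 1, dj + h + 1] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# exhaustive 256-bin between-class-variance scan
oracle_otsu <- function(x) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = 257)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), 256)
  centers <- (edges[-1] + edges[-257]) / 2
  best <- -Inf; best_k <- 1
  for (k in 1:255) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    m0 <- mean(centers[bin[lo]]); m1 <- mean(centers[bin[!lo]])
    sb <- (n0 / length(bin)) * (n1 / length(bin)) * (m0 - m1)^2
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  edges[best_k + 1]
}

# geometric triangle construction: distance of each bin to the peak-tail chord
oracle_triangle <- function(x) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = 257)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), 256)
  cnt <- tabulate(bin, 256)
  centers <- (edges[-1] + edges[-257]) / 2
  peak <- which.max(cnt)
  nz <- which(cnt > 0)
  tail_bin <- if ((nz[length(nz)] - peak) >= (peak - nz[1])) nz[length(nz)] else nz[1]
  if (tail_bin == peak) return(centers[peak])
  span <- if (tail_bin > peak) peak:tail_bin else tail_bin:peak
  p1 <- c(peak, cnt[peak]); p2 <- c(tail_bin, cnt[tail_bin])
  dist <- sapply(span, function(b) {
    num <- abs((p2[2] - p1[2]) * b - (p2[1] - p1[1]) * cnt[b] +
                 p2[1] * p1[2] - p2[2] * p1[1])
    num / sqrt(sum((p2 - p1)^2))
  })
  centers[span[which.max(dist)]]
}

# per-candidate BFS reachability oracle for prominence maxima
oracle_maxima <- function(x, prom) {
  nr <- nrow(x); nc <- ncol(x)
  is_cand <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (x[ii, jj] > x[i, j]) is_cand[i, j] <- FALSE
    }
  }
  cands <- which(is_cand)
  reach_of <- function(p0) {
    v <- x[p0]
    seen <- rep(FALSE, nr * nc); seen[p0] <- TRUE
    queue <- p0; qi <- 1
    while (qi <= length(queue)) {
      p <- queue[qi]; qi <- qi + 1
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        q <- ii + (jj - 1) * nr
        if (seen[q] || x[q] < v - prom) next
        seen[q] <- TRUE
        queue <- c(queue, q)
      }
    }
    which(seen)
  }
  accepted <- list()
  for (p in cands) {
    r <- reach_of(p)
    if (any(x[r] > x[p])) next
    accepted[[length(accepted) + 1]] <- list(p = p, reach = r, v = x[p])
  }
  # merge equal-valued accepted candidates lying in each other's reach
  n <- length(accepted)
  if (n == 0) return(list(count = 0, points = matrix(0, 0, 2)))
  grp <- seq_len(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a < b && accepted[[a]]$v == accepted[[b]]$v &&
        accepted[[b]]$p %in% accepted[[a]]$reach) {
      old <- grp[b]; grp[grp == old] <- grp[a]
    }
  }
  pts <- NULL; count <- 0
  for (g in unique(grp)) {
    members <- accepted[grp == g]
    reach <- unique(unlist(lapply(members, `[[`, "reach")))
    v <- members[[1]]$v
    plateau <- reach[x[reach] == v]
    pi <- (plateau - 1) %% nr + 1; pj <- (plateau - 1) %/% nr + 1
    if (any(pi == 1 | pi == nr | pj == 1 | pj == nc)) next
    count <- count + 1
    mr <- mean(pi); mc <- mean(pj)
    d <- (pi - mr)^2 + (pj - mc)^2
    ord <- order(d, pi, pj)
    pts <- rbind(pts, c(pi[ord[1]], pj[ord[1]]))
  }
  list(count = count, points = pts)
}

# grayscale opening with a ball structuring function, explicit loops
oracle_ball_opening <- function(x, r) {
  rr <- ceiling(r)
  off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  h <- sqrt(r^2 - off$dr^2 - off$dc^2)
  nr <- nrow(x); nc <- ncol(x)
  er <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (t in seq_len(nrow(off))) {
      ii <- i + off$dr[t]; jj <- j + off$dc[t]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      best <- min(best, x[ii, jj] - h[t])
    }
    er[i, j] <- best
  }
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- -Inf
    for (t in seq_len(nrow(off))) {
      ii <- i - off$dr[t]; jj <- j - off$dc[t]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      best <- max(best, er[ii, jj] + h[t])
    }
    out[i, j] <- best
  }
  out
}

# binary dilation via pixelwise distance check
oracle_disc_dilate <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  if (nrow(fg) == 0) return(out)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
    out[i, j] <- any(d2 <= r^2)
  }
  out
}

# O(n^2) nearest-neighbour distances
oracle_nnd <- function(p) {
  n <- nrow(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# hand step-down Holm
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    val <- (m - k + 1) * p[ord[k]]
    running <- max(running, val)
    adj[ord[k]] <- min(running, 1)
  }
  adj
}

# mid-ranks then explicit Pearson formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# explicit normal-equations OLS
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}

# brute-force circular cross-correlation shift search
oracle_register <- function(ref, mov, max_shift = 8) {
  r0 <- ref - mean(ref); m0 <- mov - mean(mov)
  nr <- nrow(ref); nc <- ncol(ref)
  best <- -Inf; best_s <- c(0, 0)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    sh <- m0[((seq_len(nr) - 1 + dy) %% nr) + 1, ((seq_len(nc) - 1 + dx) %% nc) + 1]
    cc <- sum(r0 * sh)
    if (cc > best) { best <- cc; best_s <- c(dy, dx) }
  }
  best_s
}

# small helpers for building planted fields in tests
planted_spot_field <- function(dim_px, px_um, centers_um, area_um2, amplitude,
                               psf_sigma_um, background = 8, ar = 1.3,
                               theta = 0.7) {
  canvas <- matrix(0, dim_px[1], dim_px[2])
  a <- sqrt(area_um2 * ar / pi); b <- sqrt(area_um2 / (ar * pi))
  for (k in seq_len(nrow(centers_um))) {
    idx <- synaptiq:::ellipse_indices(dim_px, px_um, centers_um[k, 1],
                                      centers_um[k, 2], a, b, theta)
    canvas[idx] <- canvas[idx] + amplitude
  }
  gaussian_blur(canvas, psf_sigma_um / px_um) + background
}
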