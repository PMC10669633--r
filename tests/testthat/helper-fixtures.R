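# Seeded fixtures and independent oracles shared across test files.

# seeded random gray image (integer matrix, values 0..255)
rand_gray <- function(h, w, seed, mean = 128, sd = 40) {
  set.seed(seed)
  matrix(as.integer(pmin(255, pmax(0, floor(rnorm(h * w, mean, sd) + 0.5)))),
         h, w)
}

# seeded random logical mask with at least one TRUE pixel
rand_mask <- function(h, w, seed, p = 0.4) {
  set.seed(seed)
  m <- matrix(runif(h * w) < p, h, w)
  if (!any(m)) m[1, 1] <- TRUE
  m
}

# seeded 4-connected blob without interior holes, grown by 4-adjacent
# accretion from a random seed pixel
blob_mask <- function(h, w, seed, steps = 40) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  r <- sample(2:(h - 1), 1); c <- sample(2:(w - 1), 1)
  m[r, c] <- TRUE
  steps4 <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), 4, 2, byrow = TRUE)
  for (i in seq_len(steps)) {
    idx <- which(m, arr.ind = TRUE)
    j <- idx[sample.int(nrow(idx), 1), ]
    d <- steps4[sample.int(4, 1), ]
    nr <- min(max(j[1] + d[1], 2L), h - 1L)
    nc <- min(max(j[2] + d[2], 2L), w - 1L)
    m[nr, nc] <- TRUE
  }
  fill_holes(m)
}

# flood-fill the background from the frame; unreached FALSE pixels are holes
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  comp <- choroidsps:::cpp_components(pad + 0L)
  outside <- comp == comp[1, 1] & !pad
  filled <- !outside[2:(h + 1), 2:(w + 1)]
  filled | mask
}

# pixels of `mask` with at least one 4-neighbour outside the mask
boundary4_oracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h))
    for (c in seq_len(w)) {
      if (!mask[r, c]) next
      nb <- c(
        if (r > 1) mask[r - 1, c] else FALSE,
        if (r < h) mask[r + 1, c] else FALSE,
        if (c > 1) mask[r, c - 1] else FALSE,
        if (c < w) mask[r, c + 1] else FALSE)
      out[r, c] <- any(!nb) || r == 1 || r == h || c == 1 || c == w
    }
  out
}

# total variation (sum of absolute 4-neighbour differences)
total_variation <- function(img) {
  sum(abs(diff(img))) + sum(abs(t(diff(t(img)))))
}

# Shannon entropy (bits) of the 256-bin gray-level histogram
hist_entropy <- function(img) {
  p <- tabulate(as.integer(img) + 1L, 256L)
  p <- p[p > 0] / length(img)
  -sum(p * log2(p))
}

# Unwindowed brute-force SLIC oracle: identical seeding and distance as
# the implementation, but every pixel is compared against every center
# each round, run to convergence. Independent R re-derivation used to
# check the windowed C++ path on small instances.
slic_bruteforce <- function(img, K, m, max_iter = 100) {
  H <- nrow(img); W <- ncol(img); N <- H * W
  S <- sqrt(N / K)
  ny <- max(1L, floor(sqrt(K * H / W)))
  nx <- max(1L, K %/% ny)
  centers <- NULL
  grad <- function(r, c) {
    rp <- function(i, n) { if (i < 0) -i - 1 else if (i >= n) 2 * n - i - 1 else i }
    gx <- img[r + 1, rp(c + 1, W) + 1] - img[r + 1, rp(c - 1, W) + 1]
    gy <- img[rp(r + 1, H) + 1, c + 1] - img[rp(r - 1, H) + 1, c + 1]
    abs(gx) + abs(gy)
  }
  for (i in 0:(ny - 1)) for (j in 0:(nx - 1)) {
    sr <- min(floor((i + 0.5) * H / ny), H - 1)
    sc <- min(floor((j + 0.5) * W / nx), W - 1)
    best <- grad(sr, sc); br <- sr; bc <- sc
    for (da in -1:1) for (db in -1:1) {
      a <- sr + da; b <- sc + db
      if (a < 0 || a >= H || b < 0 || b >= W) next
      g <- grad(a, b)
      if (g < best) { best <- g; br <- a; bc <- b }
    }
    centers <- rbind(centers, c(br, bc, img[br + 1, bc + 1]))
  }
  nc <- nrow(centers)
  rows0 <- as.vector(row(img)) - 1  # 0-based like the implementation
  cols0 <- as.vector(col(img)) - 1
  ints <- as.vector(img) + 0.0
  lab <- rep(0L, N)
  for (it in seq_len(max_iter)) {
    D <- matrix(Inf, N, nc)
    for (k in seq_len(nc)) {
      dI <- ints - centers[k, 3]
      dxy2 <- (rows0 - centers[k, 1])^2 + (cols0 - centers[k, 2])^2
      D[, k] <- sqrt(dI^2 + dxy2 / S^2 * m^2)
    }
    new_lab <- max.col(-D, ties.method = "first")
    for (k in seq_len(nc)) {
      sel <- new_lab == k
      if (any(sel))  # sum()/n: same long-double accumulation as the C++ core
        centers[k, ] <- c(sum(rows0[sel]), sum(cols0[sel]),
                          sum(ints[sel])) / sum(sel)
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # renumber surviving labels 1..K in center order, as the implementation does
  used <- sort(unique(lab))
  matrix(match(lab, used), H, W)
}

# write a gray matrix to a temp PNG and return the path
tmp_png <- function(img) {
  p <- tempfile(fileext = ".png")
  save_gray(img, p)
  p
}
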