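# Independent oracles used by the unit tests. Deliberately naive
# implementations: they must stay independent of the code paths they check.

# Brute-force single-linkage grouping by transitive closure (union-find).
oracle_single_linkage <- function(coords, h) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= h) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Direct spatial-domain difference-of-Gaussians convolution (no FFT).
oracle_dog <- function(img, sigma_small, sigma_large) {
  kern <- function(sigma) {
    r <- ceiling(4 * sigma)
    k <- outer(-r:r, -r:r, function(y, x) exp(-(y^2 + x^2) / (2 * sigma^2)))
    k / sum(k)
  }
  conv <- function(img, k) {
    r <- (nrow(k) - 1L) / 2L
    h <- nrow(img); w <- ncol(img)
    out <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- 0; wt <- 0
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          acc <- acc + img[ii, jj] * k[di + r + 1L, dj + r + 1L]
          wt <- wt + k[di + r + 1L, dj + r + 1L]
        }
      }
      out[i, j] <- acc / wt
    }
    out
  }
  out <- conv(img, kern(sigma_small)) - conv(img, kern(sigma_large))
  out[out < 0] <- 0
  out
}

# Analytic roundness of an axis-aligned ellipse with semi-axes a, b
# (Ramanujan perimeter approximation).
oracle_ellipse_roundness <- function(a, b) {
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * (pi * a * b) / per^2
}

# Match detected centroids to truth centroids (greedy nearest neighbour);
# returns counts for recall/precision at a pixel tolerance.
oracle_match_centroids <- function(truth, detected, tol_px = 5) {
  if (nrow(truth) == 0L || nrow(detected) == 0L)
    return(list(tp = 0L, fn = nrow(truth), fp = nrow(detected)))
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$cy - truth$cy[i])^2 + (detected$cx - truth$cx[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol_px^2) { tp <- tp + 1L; used[j] <- TRUE }
  }
  list(tp = tp, fn = nrow(truth) - tp, fp = sum(!used))
}
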