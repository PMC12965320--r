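# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic derived seed for well/field indices, kept inside 32-bit range.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed)
  for (i in ix) s <- (s * 69069 + i * 12345 + 1) %% 2147483647
  as.integer(s)
}

# floor(f * n) plus a Bernoulli draw on the fractional remainder: the planted
# count is exact whenever f * n is an integer and otherwise off by at most one.
quota_count <- function(n, frac) {
  if (n == 0L || frac <= 0) return(0L)
  if (frac >= 1) return(as.integer(n))
  ex <- frac * n
  as.integer(floor(ex) + stats::rbinom(1L, 1L, ex - floor(ex)))
}

# Perimeter of a labelled mask estimated from exposed 4-neighbour edges.
# The taxicab edge count of a smooth convex boundary overestimates the
# Euclidean length by 4/pi on average, hence the pi/4 correction; a rasterised
# disk then gets roundness 4*pi*A/P^2 ~ 1.
label_perimeter <- function(labels) {
  nl <- max(labels)
  if (nl == 0L) return(numeric(0))
  h <- nrow(labels); w <- ncol(labels)
  edges <- numeric(nl)
  pad <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad(labels, sh[1L], sh[2L])
    diff_px <- labels > 0L & labels != nb
    if (any(diff_px)) {
      tab <- tabulate(labels[diff_px], nbins = nl)
      edges <- edges + tab
    }
  }
  edges * pi / 4
}

# Area/centroid/mean-intensity summaries for an integer label matrix.
label_stats <- function(labels, images = list()) {
  nl <- max(labels)
  if (nl == 0L) {
    out <- data.frame(label = integer(0), area_px = integer(0),
                      cy = numeric(0), cx = numeric(0))
    for (nm in names(images)) out[[paste0("mean_", nm)]] <- numeric(0)
    return(out)
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  area <- tabulate(lab, nbins = nl)
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  cy <- as.numeric(rowsum(as.numeric(rows), lab, reorder = TRUE))
  cx <- as.numeric(rowsum(as.numeric(cols), lab, reorder = TRUE))
  present <- sort(unique(lab))
  out <- data.frame(label = present, area_px = area[present],
                    cy = cy / area[present], cx = cx / area[present])
  for (nm in names(images)) {
    s <- as.numeric(rowsum(as.numeric(images[[nm]][idx]), lab, reorder = TRUE))
    out[[paste0("mean_", nm)]] <- s / area[present]
  }
  out
}

roundness_of <- function(area_px, perimeter_px) {
  r <- 4 * pi * area_px / pmax(perimeter_px, .Machine$double.eps)^2
  pmin(r, 1)
}

# Robust per-channel field background: median of pixels outside all somata.
field_background <- function(image, soma_labels = NULL) {
  if (is.null(soma_labels)) return(stats::median(image))
  out <- image[soma_labels == 0L]
  if (length(out) == 0L) return(stats::median(image))
  stats::median(out)
}

as_ebimage <- function(m) EBImage::Image(m)

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
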