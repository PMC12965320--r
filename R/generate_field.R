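#' Generate one synthetic multi-channel field with planted ground truth
#'
#' Renders a wide-field high-content scene from a [scene_config()]: a DAPI
#' channel with one disk-like nucleus per neuron, a MAP2 channel with soma
#' blobs and thin random-walk neurites, a GVB-marker channel whose bright
#' Gaussian punctae occur only in the somata of planted GVB+ neurons
#' (always outside the nucleus), and one measurement channel per entry of
#' `channel_effects` whose per-population mean intensities follow the
#' configured multipliers. Pixel values are integer camera counts with
#' Poisson shot noise and Gaussian read noise.
#'
#' @param config a [scene_config()].
#' @param render render the pixel channels (default). `render = FALSE`
#'   skips rasterisation and returns only the planted truth (`stack` is
#'   `NULL`), which is much faster for planting-level studies at large
#'   `n_neurons`.
#' @return A list with elements `stack` (a `channel_stack`: named list of
#'   H x W integer matrices, channel roles and the pixel size) and `truth`
#'   (a `scene_truth`: per-neuron table, planted punctae coordinates,
#'   nucleus/soma label masks and the seed).
#' @examples
#' fs <- generate_field(scene_config(n_neurons = 20, seed = 7))
#' table(fs$truth$neurons$population)
#' @export
generate_field <- function(config, render = TRUE) {
  if (!inherits(config, "scene_config"))
    stop("`config` must be a scene_config", call. = FALSE)
  with_seed(config$seed, render_field(config, render))
}

render_field <- function(config, render = TRUE) {
  H <- config$field_shape[1L]; W <- config$field_shape[2L]
  px <- config$pixel_size
  n <- config$n_neurons
  amp <- config$intensity
  has_gfp <- !is.na(config$frac_gfp_pos)

  channel_names <- c("dapi", "map2", "gvb", names(config$channel_effects),
                     if (has_gfp) "gfp", if (config$syp1) "syp1")
  roles <- c(dapi = "nucleus", map2 = "soma", gvb = "marker",
             stats::setNames(rep("measurement",
                                 length(config$channel_effects)),
                             names(config$channel_effects)),
             if (has_gfp) c(gfp = "gfp"),
             if (config$syp1) c(syp1 = "syp1"))
  canvases <- stats::setNames(
    lapply(channel_names, function(ch) matrix(config$noise$background, H, W)),
    channel_names)
  nucleus_labels <- matrix(0L, H, W)
  soma_labels <- matrix(0L, H, W)

  neurons <- data.frame(
    id = integer(0), cy = numeric(0), cx = numeric(0),
    nucleus_r_um = numeric(0), soma_r_um = numeric(0),
    tau_status = logical(0), gvb_status = logical(0),
    gfp_status = logical(0), population = character(0),
    n_punctae = integer(0), neurite_length_um = numeric(0),
    n_syp1 = integer(0))
  punctae <- data.frame(neuron = integer(0), cy = numeric(0), cx = numeric(0))

  if (n > 0L) {
    sep_px <- config$min_separation / px
    r_s_max <- config$min_separation / 2 - px
    margin <- r_s_max / px + 2
    ctr <- place_centres(n, H, W, sep_px, margin, config$min_separation)

    r_s <- pmin(pmax(stats::rnorm(n, config$soma_radius[1L],
                                  config$soma_radius[2L]),
                     config$soma_radius[1L] - 2 * config$soma_radius[2L]),
                r_s_max)
    r_n <- pmin(pmax(stats::rnorm(n, config$nucleus_radius[1L],
                                  config$nucleus_radius[2L]),
                     config$nucleus_radius[1L] - 2 * config$nucleus_radius[2L]),
                r_s - 2.5)

    # Quota planting: exact planted fractions up to one neuron per stratum.
    tau_status <- rep(FALSE, n)
    tau_status[sample.int(n, quota_count(n, config$frac_tau_pos))] <- TRUE
    gfp_status <- rep(FALSE, n)
    if (has_gfp)
      gfp_status[sample.int(n, quota_count(n, config$frac_gfp_pos))] <- TRUE
    gvb_status <- rep(FALSE, n)
    for (g in unique(gfp_status)) {
      stratum <- which(tau_status & gfp_status == g)
      k <- quota_count(length(stratum), config$frac_gvb_pos_given_tau)
      if (k > 0L) gvb_status[sample(stratum, k)] <- TRUE
    }
    population <- ifelse(!tau_status, "tau_neg",
                         ifelse(gvb_status, "gvb_pos", "gvb_neg"))

    sig <- sqrt(log(1 + config$cell_cv^2))
    cell_mult <- function() exp(stats::rnorm(n, -sig^2 / 2, sig))
    m_dapi <- cell_mult(); m_map2 <- cell_mult()
    m_marker <- cell_mult(); m_gfp <- cell_mult()
    m_meas <- lapply(config$channel_effects, function(ef)
      unname(ef[population]) * cell_mult())

    edge_soma <- 0.5; edge_nuc <- 0.35  # soft-edge widths, um
    n_punct <- integer(n); neurite_len <- numeric(n); n_syp1 <- integer(n)
    punct_list <- vector("list", n)
    sigma_px <- config$spot_sigma / px

    for (i in seq_len(n)) {
      cy <- ctr[i, 1L]; cx <- ctr[i, 2L]
      R <- ceiling(r_s[i] / px) + 4L
      rows <- max(1L, floor(cy - R)):min(H, ceiling(cy + R))
      cols <- max(1L, floor(cx - R)):min(W, ceiling(cx + R))
      d_um <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+")) * px
      ws <- 1 / (1 + exp((d_um - r_s[i]) / edge_soma))
      wn <- 1 / (1 + exp((d_um - r_n[i]) / edge_nuc))

      nucleus_labels[rows, cols][d_um <= r_n[i]] <- i
      soma_labels[rows, cols][d_um <= r_s[i]] <- i

      if (render) {
        canvases$dapi[rows, cols] <-
          canvases$dapi[rows, cols] + amp$dapi * m_dapi[i] * wn
        canvases$map2[rows, cols] <-
          canvases$map2[rows, cols] + amp$map2 * m_map2[i] * ws
        canvases$gvb[rows, cols] <-
          canvases$gvb[rows, cols] + amp$marker * m_marker[i] * ws
        for (ch in names(config$channel_effects))
          canvases[[ch]][rows, cols] <-
            canvases[[ch]][rows, cols] +
              amp$measurement * m_meas[[ch]][i] * ws
        if (has_gfp) {
          g_amp <- amp$gfp * if (gfp_status[i]) amp$gfp_pos_contrast else 1
          canvases$gfp[rows, cols] <-
            canvases$gfp[rows, cols] + g_amp * m_gfp[i] * ws
        }
      }

      # Neurites: thin random-walk strokes, cosmetic except for SYP1 planting.
      nt <- draw_neurites(cy, cx, r_s[i] / px, H, W)
      if (nrow(nt$coords)) {
        neurite_len[i] <- nt$n_steps * px
        if (render)
          canvases$map2[nt$coords] <- canvases$map2[nt$coords] + amp$neurite
        if (config$syp1 && nrow(nt$spots)) {
          n_syp1[i] <- nrow(nt$spots)
          if (render)
            for (s in seq_len(nrow(nt$spots)))
              canvases$syp1 <- add_spot(canvases$syp1, nt$spots[s, 1L],
                                        nt$spots[s, 2L], 500, sigma_px)
        }
      }

      if (gvb_status[i]) {
        k <- sample(seq(config$punctae_per_gvb_neuron[1L],
                        config$punctae_per_gvb_neuron[2L]), 1L)
        pp <- place_punctae(k, cy, cx, (r_n[i] + 1) / px,
                            (r_s[i] - 1) / px, config$puncta_min_sep / px)
        n_punct[i] <- nrow(pp)
        if (nrow(pp)) {
          punct_list[[i]] <- data.frame(neuron = i, cy = pp[, 1L],
                                        cx = pp[, 2L])
          amp_p <- amp$puncta_contrast * amp$marker * m_marker[i]
          if (render)
            for (s in seq_len(nrow(pp)))
              canvases$gvb <- add_spot(canvases$gvb, pp[s, 1L], pp[s, 2L],
                                       amp_p, sigma_px)
        }
      }
    }
    punctae <- do.call(rbind, c(list(punctae), punct_list))
    neurons <- data.frame(
      id = seq_len(n), cy = ctr[, 1L], cx = ctr[, 2L],
      nucleus_r_um = r_n, soma_r_um = r_s, tau_status = tau_status,
      gvb_status = gvb_status, gfp_status = gfp_status,
      population = population, n_punctae = n_punct,
      neurite_length_um = neurite_len, n_syp1 = n_syp1)
  }

  stack <- NULL
  if (render) {
    images <- lapply(canvases, function(cv) {
      x <- cv
      if (isTRUE(config$noise$poisson))
        x <- matrix(stats::rpois(length(x), pmax(x, 0)), nrow(x), ncol(x))
      if (config$noise$read_sd > 0)
        x <- x + stats::rnorm(length(x), 0, config$noise$read_sd)
      matrix(pmin(pmax(round(x), 0), 65535), nrow(x), ncol(x))
    })
    stack <- structure(list(images = images, roles = roles,
                            pixel_size = px),
                       class = "channel_stack")
  }
  truth <- structure(list(neurons = neurons, punctae = punctae,
                          nucleus_labels = nucleus_labels,
                          soma_labels = soma_labels,
                          seed = config$seed, config = config),
                     class = "scene_truth")
  list(stack = stack, truth = truth)
}

# Dart-throwing placement with a hard minimum separation.
place_centres <- function(n, H, W, sep_px, margin, sep_um) {
  ctr <- matrix(NA_real_, n, 2L)
  lo_r <- 1 + margin; hi_r <- H - margin
  lo_c <- 1 + margin; hi_c <- W - margin
  if (hi_r <= lo_r || hi_c <= lo_c)
    stop("field too small for the configured soma radius", call. = FALSE)
  max_attempts <- 400L * n
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0(
        "could not place %d neurons at min_separation = %g um in this ",
        "field; reduce `n_neurons` or `min_separation`"), n, sep_um),
        call. = FALSE)
    y <- stats::runif(1, lo_r, hi_r); x <- stats::runif(1, lo_c, hi_c)
    if (placed == 0L ||
        min((ctr[seq_len(placed), 1L] - y)^2 +
            (ctr[seq_len(placed), 2L] - x)^2) >= sep_px^2) {
      placed <- placed + 1L
      ctr[placed, ] <- c(y, x)
    }
  }
  ctr
}

# Random punctae positions in the cytosolic annulus, minimum spacing enforced.
place_punctae <- function(k, cy, cx, r_in, r_out, min_sep) {
  if (r_out <= r_in) r_out <- r_in + 0.5
  pts <- matrix(NA_real_, 0L, 2L)
  for (attempt in seq_len(400L)) {
    if (nrow(pts) >= k) break
    r <- sqrt(stats::runif(1, r_in^2, r_out^2))
    a <- stats::runif(1, 0, 2 * pi)
    y <- cy + r * sin(a); x <- cx + r * cos(a)
    if (nrow(pts) == 0L ||
        min((pts[, 1L] - y)^2 + (pts[, 2L] - x)^2) >= min_sep^2)
      pts <- rbind(pts, c(y, x))
  }
  pts
}

# 2-3 jittered straight-ish strokes leaving the soma; returns stroke pixels
# and candidate presynapse spot positions along the paths.
draw_neurites <- function(cy, cx, r_s_px, H, W) {
  n_str <- sample(2:3, 1L)
  coords <- vector("list", n_str); spots <- vector("list", n_str)
  n_steps <- 0L
  for (s in seq_len(n_str)) {
    a0 <- stats::runif(1, 0, 2 * pi)
    len <- sample(30:60, 1L)
    a <- a0 + cumsum(stats::rnorm(len, 0, 0.15))
    y <- cy + (r_s_px + 1) * sin(a0) + cumsum(sin(a))
    x <- cx + (r_s_px + 1) * cos(a0) + cumsum(cos(a))
    inside <- y >= 2 & y <= H - 1 & x >= 2 & x <= W - 1
    cut <- which(!inside)[1L]
    if (!is.na(cut)) { y <- y[seq_len(cut - 1L)]; x <- x[seq_len(cut - 1L)] }
    if (!length(y)) next
    coords[[s]] <- cbind(round(y), round(x))
    n_steps <- n_steps + length(y)
    at <- cumsum(sample(8:14, 6L, replace = TRUE))
    at <- at[at <= length(y)]
    if (length(at)) spots[[s]] <- cbind(y[at], x[at])
  }
  list(coords = do.call(rbind, c(list(matrix(0L, 0L, 2L)), coords)),
       spots = do.call(rbind, c(list(matrix(0, 0L, 2L)), spots)),
       n_steps = n_steps)
}

# Add a 2D Gaussian spot of amplitude `amp` at fractional position (cy, cx).
add_spot <- function(canvas, cy, cx, amp, sigma_px) {
  H <- nrow(canvas); W <- ncol(canvas)
  R <- ceiling(4 * sigma_px)
  rows <- max(1L, floor(cy - R)):min(H, ceiling(cy + R))
  cols <- max(1L, floor(cx - R)):min(W, ceiling(cx + R))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  canvas[rows, cols] <- canvas[rows, cols] + amp * exp(-d2 / (2 * sigma_px^2))
  canvas
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack: %d channels, %dx%d px, %.2f um/px\n",
              length(x$images), nrow(x$images[[1L]]), ncol(x$images[[1L]]),
              x$pixel_size))
  cat(paste(sprintf("  %s (%s)", names(x$images), x$roles[names(x$images)]),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d neurons (%d tau+, %d GVB+), %d punctae, seed %d\n",
              nrow(x$neurons), sum(x$neurons$tau_status),
              sum(x$neurons$gvb_status), nrow(x$punctae), x$seed))
  invisible(x)
}
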