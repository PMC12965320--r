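#' Per-marker band-pass profiles for GVB punctum enhancement
#'
#' The proprietary "curvature" background filter of the original HCS
#' software is realised as a difference-of-Gaussians band-pass: a small
#' sigma near the punctum scale minus a large sigma near the soma scale.
#' Each supported marker carries its own profile; unknown markers require
#' explicit parameters.
#'
#' @return Named list of profiles, each `list(sigma_small, sigma_large)`
#'   in microns.
#' @export
marker_profiles <- function() {
  list(pperk     = list(sigma_small = 0.85, sigma_large = 3.5),
       ck1d      = list(sigma_small = 0.85, sigma_large = 3.5),
       golgina4  = list(sigma_small = 1.0,  sigma_large = 4.0),
       gfp_ck1d  = list(sigma_small = 0.85, sigma_large = 3.5))
}

#' Suppress diffuse background in a GVB-marker channel
#'
#' Difference-of-Gaussians band-pass, clipped at zero: diffuse background
#' and the smooth somatic marker signal are removed while blob-scale
#' structure (punctae) is retained. A constant image maps to all zeros.
#'
#' @param marker marker channel matrix.
#' @param marker_name name of a profile in [marker_profiles()]; ignored if
#'   both sigmas are given.
#' @param sigma_small,sigma_large band-pass sigmas in microns.
#' @param pixel_size microns per pixel.
#' @return Non-negative filtered matrix of the same shape.
#' @export
background_filter <- function(marker, marker_name = NULL,
                              sigma_small = NULL, sigma_large = NULL,
                              pixel_size = 0.65) {
  if (is.null(sigma_small) || is.null(sigma_large)) {
    prof <- marker_profiles()[[tolower(marker_name %||% "")]]
    if (is.null(prof))
      stop(sprintf(paste0("no band-pass profile for marker '%s'; pass ",
                          "`sigma_small`/`sigma_large` explicitly"),
                   marker_name %||% "<missing>"), call. = FALSE)
    sigma_small <- sigma_small %||% prof$sigma_small
    sigma_large <- sigma_large %||% prof$sigma_large
  }
  if (sigma_small >= sigma_large)
    stop("`sigma_small` must be smaller than `sigma_large`", call. = FALSE)
  if (stats::sd(marker) == 0)
    return(matrix(0, nrow(marker), ncol(marker)))
  lo <- EBImage::gblur(marker, sigma = sigma_small / pixel_size)
  hi <- EBImage::gblur(marker, sigma = sigma_large / pixel_size)
  out <- lo - hi
  out[out < 0] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect GVB punctae as thresholded local maxima
#'
#' Local maxima of the background-filtered marker image above an intensity
#' threshold become punctum records. The threshold defaults to
#' `mean + k * sd` of the filtered signal inside somata. Each punctum is
#' assigned to the soma containing it (`parent_soma = 0` outside every
#' soma; such punctae never enter neuron classification). Plateau ties are
#' broken by raster order, making detection deterministic.
#'
#' @param filtered output of [background_filter()].
#' @param somata a `soma_set`.
#' @param k threshold multiplier on the in-soma sd (default 4).
#' @param threshold absolute threshold overriding the `k`-rule.
#' @return Data frame of punctae (`cy`, `cx`, `peak_intensity`, `area_um2`,
#'   `parent_soma`) with the threshold attached as attribute `"threshold"`.
#' @export
detect_puncta <- function(filtered, somata, k = 4, threshold = NULL) {
  if (!inherits(somata, "soma_set"))
    stop("`somata` must be a soma_set", call. = FALSE)
  px <- somata$pixel_size
  in_soma <- somata$labels > 0L
  if (is.null(threshold)) {
    vals <- filtered[in_soma]
    threshold <- if (length(vals)) mean(vals) + k * stats::sd(vals) else Inf
  }
  mx <- local_maxima(filtered)
  sel <- which(mx & filtered >= threshold)
  if (!length(sel)) {
    out <- data.frame(cy = numeric(0), cx = numeric(0),
                      peak_intensity = numeric(0), area_um2 = numeric(0),
                      parent_soma = integer(0))
    attr(out, "threshold") <- threshold
    return(out)
  }
  rows <- (sel - 1L) %% nrow(filtered) + 1L
  cols <- (sel - 1L) %/% nrow(filtered) + 1L
  peak <- filtered[sel]
  area <- vapply(seq_along(sel), function(i)
    punctum_area(filtered, rows[i], cols[i], peak[i]), numeric(1))
  out <- data.frame(cy = rows, cx = cols, peak_intensity = peak,
                    area_um2 = area * px^2,
                    parent_soma = somata$labels[sel])
  out <- out[order(out$cy, out$cx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

# Raster-order deterministic 8-neighbour local maxima: a pixel wins if it is
# strictly greater than every neighbour earlier in column-major order and at
# least as great as every later neighbour (first pixel of a plateau wins).
local_maxima <- function(v) {
  h <- nrow(v); w <- ncol(v)
  shift <- function(dr, dc) {
    o <- matrix(-Inf, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
    o[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
    o
  }
  out <- matrix(TRUE, h, w)
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- shift(dr, dc)
    earlier <- dc < 0L || (dc == 0L && dr < 0L)
    out <- out & if (earlier) v > nb else v >= nb
  }
  out
}

# Pixels above half the peak inside a 9x9 window around the maximum.
punctum_area <- function(v, r, c, peak) {
  rows <- max(1L, r - 4L):min(nrow(v), r + 4L)
  cols <- max(1L, c - 4L):min(ncol(v), c + 4L)
  sum(v[rows, cols] >= peak / 2)
}

#' Group punctae into candidate GVB clusters by proximity
#'
#' Single-linkage grouping at `max_link_distance` microns; links never
#' cross soma boundaries (punctae in different somata are never merged,
#' regardless of distance). Cluster ids are assigned in raster order of
#' each cluster's first punctum, so clustering is deterministic.
#'
#' @param punctae output of [detect_puncta()].
#' @param max_link_distance single-linkage cut distance in microns
#'   (default 2); must be positive.
#' @param pixel_size microns per pixel.
#' @return A list: `punctae` with a `cluster` column and `clusters` (one
#'   row per unscored cluster: `cluster`, `parent_soma`, `n_punctae`).
#' @export
cluster_puncta <- function(punctae, max_link_distance = 2, pixel_size = 0.65) {
  if (max_link_distance <= 0)
    stop("`max_link_distance` must be positive", call. = FALSE)
  punctae$cluster <- rep(NA_integer_, nrow(punctae))
  if (nrow(punctae)) {
    grp_of <- integer(nrow(punctae))
    next_grp <- 0L
    for (s in unique(punctae$parent_soma)) {
      ix <- which(punctae$parent_soma == s)
      if (length(ix) == 1L) {
        next_grp <- next_grp + 1L
        grp_of[ix] <- next_grp
      } else {
        d <- stats::dist(cbind(punctae$cy[ix], punctae$cx[ix]) * pixel_size)
        ct <- stats::cutree(stats::hclust(d, method = "single"),
                            h = max_link_distance)
        grp_of[ix] <- next_grp + ct
        next_grp <- next_grp + max(ct)
      }
    }
    # renumber clusters by the raster position of their first punctum
    first <- tapply(seq_len(nrow(punctae)), grp_of, min)
    ord <- order(punctae$cy[first], punctae$cx[first])
    remap <- integer(length(ord)); remap[as.integer(names(first))[ord]] <-
      seq_along(ord)
    punctae$cluster <- remap[grp_of]
  }
  clusters <- if (nrow(punctae)) {
    data.frame(cluster = sort(unique(punctae$cluster)),
               parent_soma = tapply(punctae$parent_soma, punctae$cluster,
                                    function(z) z[1L]),
               n_punctae = as.integer(table(punctae$cluster)))
  } else data.frame(cluster = integer(0), parent_soma = integer(0),
                    n_punctae = integer(0))
  rownames(clusters) <- NULL
  list(punctae = punctae, clusters = clusters)
}

#' Score candidate clusters against the five GVB acceptance gates
#'
#' A cluster is an accepted GVB when all five gates pass: (1) size - the
#' cluster mask area lies in `area_range`; (2) roundness; (3) GVB-marker
#' intensity - mean raw marker over the cluster at least `marker_ratio`
#' times the marker mean of the parent soma's cytosol excluding clusters;
#' (4) MAP2 intensity in the cluster above the field MAP2 gate (clusters
#' off the MAP2 mask are rejected); (5) nuclear exclusion - the fraction of
#' cluster pixels inside a nucleus below `max_nucleus_overlap`. Gates are
#' evaluated independently; a rejection records the first failing gate.
#'
#' The cluster mask is the connected component of
#' `filtered >= punctum threshold` containing the member punctae,
#' restricted to the parent soma and to the cluster's half-maximum
#' support (pixels at half the peak filtered intensity or more), which
#' keeps the mask punctum-scaled even when the global threshold sits
#' close to the noise floor.
#'
#' @param clustered output of [cluster_puncta()].
#' @param somata a `soma_set`.
#' @param marker,map2 raw channel matrices.
#' @param filtered the background-filtered marker image.
#' @param threshold the punctum threshold (defaults to the attribute left
#'   by [detect_puncta()] on `clustered$punctae`).
#' @param area_range accepted cluster area window in um^2.
#' @param min_roundness roundness gate.
#' @param marker_ratio marker-over-cytosol gate.
#' @param map2_gate `"auto"` (field median + 2 MAD) or numeric cutoff.
#' @param max_nucleus_overlap maximum nuclear overlap fraction.
#' @return `clustered` with its `clusters` table scored: gate values,
#'   `accepted`, `failing_gate`, and a `pixels` list column of cluster
#'   mask indices.
#' @export
accept_clusters <- function(clustered, somata, marker, map2, filtered,
                            threshold = NULL,
                            area_range = c(0.5, 20), min_roundness = 0.5,
                            marker_ratio = 2, map2_gate = "auto",
                            max_nucleus_overlap = 0.5) {
  punctae <- clustered$punctae
  cl <- clustered$clusters
  px <- somata$pixel_size
  threshold <- threshold %||% attr(punctae, "threshold")
  if (is.null(threshold))
    stop("no punctum threshold available", call. = FALSE)
  m2gate <- if (identical(map2_gate, "auto"))
    stats::median(map2) + 2 * stats::mad(map2) else map2_gate

  n_cl <- nrow(cl)
  cl$area_um2 <- cl$roundness <- cl$mean_marker <- cl$mean_map2 <-
    cl$cytosol_marker <- cl$nucleus_overlap_frac <- rep(NA_real_, n_cl)
  cl$accepted <- rep(FALSE, n_cl)
  cl$failing_gate <- rep(NA_character_, n_cl)
  cl$pixels <- replicate(n_cl, integer(0), simplify = FALSE)
  if (n_cl == 0L) { clustered$clusters <- cl; return(clustered) }

  comp <- EBImage::bwlabel(filtered >= threshold)
  comp <- matrix(as.integer(EBImage::imageData(comp)),
                 nrow(filtered), ncol(filtered))
  h <- nrow(filtered); w <- ncol(filtered)
  comp_px <- split(which(comp > 0L), comp[comp > 0L])

  # all cluster pixels first, so cytosol means can exclude every cluster
  for (i in seq_len(n_cl)) {
    members <- which(punctae$cluster == cl$cluster[i])
    lin <- (punctae$cx[members] - 1L) * h + punctae$cy[members]
    comps <- unique(comp[lin]); comps <- comps[comps > 0L]
    mask_px <- unlist(comp_px[as.character(comps)], use.names = FALSE)
    if (cl$parent_soma[i] > 0L)
      mask_px <- mask_px[somata$labels[mask_px] == cl$parent_soma[i]]
    if (!length(mask_px)) mask_px <- lin
    # half-maximum support: the component above the global threshold can
    # sprawl when the threshold sits near the noise floor (fields with few
    # punctae), so the mask keeps only pixels at >= half the cluster's
    # peak filtered intensity
    peak <- max(filtered[mask_px])
    mask_px <- mask_px[filtered[mask_px] >= 0.5 * peak]
    cl$pixels[[i]] <- mask_px
  }
  # distinct clusters can share a connected component (e.g. two punctae
  # just beyond the linkage distance); contested pixels go to the cluster
  # with the nearest member punctum so each mask stays punctum-shaped
  all_px <- unlist(cl$pixels)
  dup <- unique(all_px[duplicated(all_px)])
  if (length(dup)) {
    claims <- lapply(cl$pixels, function(z) z[z %in% dup])
    for (p in dup) {
      claimants <- which(vapply(claims, function(z) p %in% z, logical(1)))
      if (length(claimants) < 2L) next
      pr <- (p - 1L) %% h + 1L; pc <- (p - 1L) %/% h + 1L
      d2 <- vapply(claimants, function(ci) {
        mem <- which(punctae$cluster == cl$cluster[ci])
        min((punctae$cy[mem] - pr)^2 + (punctae$cx[mem] - pc)^2)
      }, numeric(1))
      for (ci in claimants[-which.min(d2)])
        cl$pixels[[ci]] <- setdiff(cl$pixels[[ci]], p)
    }
  }
  all_cluster_px <- unlist(cl$pixels)

  # cytosol marker mean per soma, excluding every cluster's pixels
  cyt_labels <- somata$labels
  cyt_labels[somata$nucleus_labels > 0L] <- 0L
  cyt_labels[all_cluster_px] <- 0L
  cyt_st <- label_stats(cyt_labels, list(marker = marker))
  cyt_mean <- stats::setNames(cyt_st$mean_marker, cyt_st$label)

  for (i in seq_len(n_cl)) {
    mask_px <- cl$pixels[[i]]
    area_px <- length(mask_px)
    # perimeter on a cropped bounding box
    rows <- (mask_px - 1L) %% h + 1L; cols <- (mask_px - 1L) %/% h + 1L
    r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
    msk <- matrix(0L, max(rows) - r0 + 2L, max(cols) - c0 + 2L)
    msk[cbind(rows - r0, cols - c0)] <- 1L
    cl$area_um2[i] <- area_px * px^2
    cl$roundness[i] <- roundness_of(area_px, label_perimeter(msk))
    cl$mean_marker[i] <- mean(marker[mask_px])
    cl$mean_map2[i] <- mean(map2[mask_px])
    cl$nucleus_overlap_frac[i] <-
      mean(somata$nucleus_labels[mask_px] > 0L)
    cl$cytosol_marker[i] <-
      unname(cyt_mean[as.character(cl$parent_soma[i])])

    gates <- c(
      size = cl$area_um2[i] >= area_range[1L] &&
        cl$area_um2[i] <= area_range[2L],
      roundness = cl$roundness[i] >= min_roundness,
      marker_intensity = !is.na(cl$cytosol_marker[i]) &&
        cl$mean_marker[i] >= marker_ratio * cl$cytosol_marker[i],
      map2_intensity = cl$mean_map2[i] > m2gate,
      nuclear_exclusion = cl$nucleus_overlap_frac[i] < max_nucleus_overlap)
    cl$accepted[i] <- all(gates)
    if (!cl$accepted[i]) cl$failing_gate[i] <- names(gates)[!gates][1L]
  }
  clustered$clusters <- cl
  clustered
}

#' Classify the GVB status of each neuron
#'
#' A neuron is GVB+ when the accepted clusters in its soma together hold at
#' least `min_puncta` punctae (default 2, the confocal rule), GVB- with no
#' punctae at all, and indeterminate in between. Indeterminate neurons are
#' excluded from both classes by default; `indeterminate_to_negative`
#' folds them into GVB- to mirror the high-content "GVB+ somas / all
#' somas" counting mode.
#'
#' @param somata a `soma_set`.
#' @param scored output of [accept_clusters()].
#' @param min_puncta punctae needed for GVB+ (default 2).
#' @param indeterminate_to_negative logical.
#' @return Data frame with `label`, `n_punctae` (accepted punctae in the
#'   soma) and `gvb_status` (factor `GVB+` / `GVB-` / `indeterminate`).
#' @export
classify_neuron <- function(somata, scored, min_puncta = 2L,
                            indeterminate_to_negative = FALSE) {
  cl <- scored$clusters
  labs <- somata$table$label
  counts <- stats::setNames(integer(length(labs)), labs)
  acc <- cl[cl$accepted & cl$parent_soma > 0L, , drop = FALSE]
  if (nrow(acc)) {
    agg <- tapply(acc$n_punctae, acc$parent_soma, sum)
    counts[names(agg)[names(agg) %in% names(counts)]] <-
      agg[names(agg) %in% names(counts)]
  }
  status <- ifelse(counts >= min_puncta, "GVB+",
                   ifelse(counts == 0L, "GVB-", "indeterminate"))
  if (indeterminate_to_negative) status[status == "indeterminate"] <- "GVB-"
  data.frame(label = labs, n_punctae = as.integer(counts),
             gvb_status = factor(status,
                                 levels = c("GVB-", "indeterminate", "GVB+")))
}

#' Per-neuron GVB morphometrics
#'
#' For a GVB+ neuron: total accepted GVB area, the individual cluster
#' sizes, and the GVB/cytosol ratio of marker intensity (mean marker over
#' accepted-cluster pixels divided by the mean over cytosol pixels
#' excluding clusters).
#'
#' @param soma_label the neuron's soma label.
#' @param scored output of [accept_clusters()].
#' @param somata a `soma_set`.
#' @param marker raw marker channel.
#' @return List with `gvb_area_per_neuron` (um^2), `single_gvb_sizes`
#'   (um^2) and `gvb_to_cytosol_ratio`.
#' @export
gvb_metrics <- function(soma_label, scored, somata, marker) {
  acc <- scored$clusters[scored$clusters$accepted &
                           scored$clusters$parent_soma == soma_label, ,
                         drop = FALSE]
  n_punctae <- sum(acc$n_punctae)
  if (n_punctae < 2L)
    stop("GVB metrics are defined only for GVB+ neurons", call. = FALSE)
  cl_px <- unlist(acc$pixels)
  cyt_px <- which(somata$labels == soma_label &
                  somata$nucleus_labels == 0L)
  cyt_px <- setdiff(cyt_px, unlist(scored$clusters$pixels))
  list(gvb_area_per_neuron = sum(acc$area_um2),
       single_gvb_sizes = acc$area_um2,
       gvb_to_cytosol_ratio = mean(marker[cl_px]) /
         mean(marker[cyt_px]))
}
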