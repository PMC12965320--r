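#' Somatic mean intensity per neuron
#'
#' Arithmetic mean of a channel over each soma (cytosol plus nucleus).
#' `exclude` removes pixels (e.g. accepted GVB cluster pixels, for the
#' "marker intensity in the soma without the GVBs" variant) before
#' averaging.
#'
#' @param somata a `soma_set`.
#' @param channel channel matrix.
#' @param exclude integer vector of linear pixel indices to exclude.
#' @return Named numeric vector, one mean per soma label.
#' @export
somatic_intensity <- function(somata, channel, exclude = NULL) {
  if (is.null(channel)) stop("channel is absent", call. = FALSE)
  labs <- somata$labels
  if (!is.null(exclude) && length(exclude)) labs[exclude] <- 0L
  st <- label_stats(labs, list(v = channel))
  out <- stats::setNames(rep(NA_real_, nrow(somata$table)),
                         somata$table$label)
  out[as.character(st$label)] <- st$mean_v
  out
}

#' Background-corrected nuclear intensity per neuron
#'
#' Mean nuclear intensity minus the mean intensity of the same neuron's
#' cytosol (soma without the nucleus); the result may legitimately be
#' negative for cytosolic markers and is not clipped. With
#' `correct = FALSE` the raw nuclear mean is returned (the ARC / c-FOS
#' convention, which skips the correction). `exclude` removes pixels (GVB
#' clusters) from the cytosol term. Neurons with an empty cytosol get `NA`.
#'
#' @param somata a `soma_set`.
#' @param channel channel matrix.
#' @param correct subtract the cytosolic mean (default TRUE).
#' @param exclude linear pixel indices excluded from the cytosol.
#' @return Named numeric vector per soma label.
#' @export
nuclear_corrected_intensity <- function(somata, channel, correct = TRUE,
                                        exclude = NULL) {
  if (is.null(channel)) stop("channel is absent", call. = FALSE)
  nuc <- label_stats(somata$nucleus_labels, list(v = channel))
  out <- stats::setNames(rep(NA_real_, nrow(somata$table)),
                         somata$table$label)
  out[as.character(nuc$label)] <- nuc$mean_v
  if (!correct) return(out)
  cyt_labs <- somata$labels
  cyt_labs[somata$nucleus_labels > 0L] <- 0L
  if (!is.null(exclude) && length(exclude)) cyt_labs[exclude] <- 0L
  cyt <- label_stats(cyt_labs, list(v = channel))
  cyt_mean <- stats::setNames(rep(NA_real_, nrow(somata$table)),
                              somata$table$label)
  cyt_mean[as.character(cyt$label)] <- cyt$mean_v
  out - cyt_mean
}

#' Gate GFP-positive neurons against a negative-control population
#'
#' The GFP threshold is the `q` quantile (default 0.99) of somatic mean
#' GFP intensity in the untransduced negative-control population; a neuron
#' is GFP+ when its somatic mean GFP exceeds it.
#'
#' @param gfp_means somatic mean GFP of the neurons to gate.
#' @param control_means somatic mean GFP of negative-control neurons.
#' @param q control quantile defining the threshold.
#' @return Logical vector with the threshold as attribute `"threshold"`.
#' @export
gfp_gate <- function(gfp_means, control_means, q = 0.99) {
  if (is.null(control_means) || length(control_means) == 0L)
    stop("empty negative-control population for GFP gating", call. = FALSE)
  thr <- stats::quantile(control_means, q, names = FALSE)
  structure(gfp_means > thr, threshold = thr)
}

#' Tau load of a field: summed tau intensity per MAP2 area
#'
#' Sum of the tau-channel intensity over the MAP2 mask, normalised to the
#' total mask area in um^2 (an intensive quantity: doubling the mask at
#' equal intensity leaves it unchanged).
#'
#' @param tau tau channel matrix.
#' @param map2_mask logical matrix (the MAP2-positive mask).
#' @param pixel_size microns per pixel.
#' @return Intensity per um^2.
#' @export
tau_load <- function(tau, map2_mask, pixel_size = 0.65) {
  n_px <- sum(map2_mask)
  if (n_px == 0L) stop("empty MAP2 mask", call. = FALSE)
  sum(tau[map2_mask]) / (n_px * pixel_size^2)
}

#' Presynapse density along dendrites
#'
#' SYP1-like punctae are counted as thresholded local intensity maxima
#' inside an enlarged MAP2 mask and divided by the externally supplied
#' total dendrite length (neurite tracing itself is out of scope).
#'
#' @param syp1 presynapse channel matrix.
#' @param map2_mask logical MAP2 mask.
#' @param dendrite_length_um total dendrite length in microns (> 0).
#' @param dilate_um mask enlargement radius in microns.
#' @param pixel_size microns per pixel.
#' @param k threshold multiplier (`median + k * mad` inside the enlarged
#'   mask).
#' @return Punctae per micron of dendrite.
#' @export
presynapse_density <- function(syp1, map2_mask, dendrite_length_um,
                               dilate_um = 2, pixel_size = 0.65, k = 6) {
  if (dendrite_length_um <= 0)
    stop("`dendrite_length_um` must be positive", call. = FALSE)
  brush_size <- 2L * max(1L, round(dilate_um / pixel_size)) + 1L
  big <- EBImage::dilate(map2_mask * 1,
                         EBImage::makeBrush(brush_size, shape = "disc")) > 0
  vals <- syp1[big]
  thr <- stats::median(vals) + k * stats::mad(vals)
  mx <- local_maxima(syp1) & big & syp1 > thr
  sum(mx) / dendrite_length_um
}
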