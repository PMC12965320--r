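#' Configuration for a synthetic high-content field
#'
#' Defines every parameter of the synthetic multi-channel fluorescence scene
#' generator: geometry of the field, the neuron populations to plant
#' (tau-negative, tau-positive/GVB-negative, tau-positive/GVB-positive),
#' per-channel intensity effects and the acquisition noise model. The
#' generator emulates wide-field high-content images of primary neuron
#' cultures: disk-like DAPI nuclei, blob-like MAP2 somata with thin neurites,
#' and bright GVB-marker punctae restricted to the somata of planted GVB+
#' neurons.
#'
#' Population fractions are planted by quota (floor of `fraction * n` plus a
#' Bernoulli draw on the remainder, stratified by tau and GFP status), so the
#' planted fraction of a field is exact up to at most one neuron.
#'
#' @param field_shape integer height and width in pixels.
#' @param pixel_size microns per pixel (default 0.65, a typical 20x HCS
#'   sCMOS sampling); every micron-specified rule downstream converts
#'   through this value.
#' @param n_neurons number of neurons to place.
#' @param frac_tau_pos fraction of neurons carrying pathological tau.
#' @param frac_gvb_pos_given_tau fraction of tau+ neurons planted GVB+.
#'   GVBs are only ever planted in tau+ neurons.
#' @param frac_gfp_pos fraction of neurons transduced with a GFP construct
#'   (`NA` omits the GFP channel). GFP transduction is planted independently
#'   of tau status; GVB quota are drawn within each GFP x tau stratum.
#' @param punctae_per_gvb_neuron integer range `c(min, max)` of GVB punctae
#'   planted per GVB+ neuron (default at least 2, matching the confocal
#'   GVB+ definition; set the minimum to 1 only for edge-case exploration).
#' @param nucleus_radius,soma_radius mean and sd in microns.
#' @param min_separation minimum distance between neuron centres in microns;
#'   guarantees disjoint somata.
#' @param channel_effects named list of per-population mean-intensity
#'   multipliers, each a numeric vector `c(tau_neg=, gvb_neg=, gvb_pos=)`.
#'   Every named channel becomes a measurement channel of the stack. The
#'   default plants a `tau` channel at 5x intensity in tau+ neurons.
#' @param intensity base amplitudes (camera counts above background) for the
#'   structural channels: `dapi` nucleus, `map2` soma, `neurite` strokes,
#'   `marker` diffuse somatic GVB-marker level, `puncta_contrast` punctum
#'   amplitude as a multiple of the somatic marker level, `measurement`
#'   amplitude of measurement channels, `gfp` amplitude of the GFP channel
#'   and `gfp_pos_contrast` the GFP+ fold over baseline.
#' @param noise list with `background` (counts), `read_sd` (Gaussian read
#'   noise sd) and `poisson` (logical, shot noise).
#' @param cell_cv lognormal coefficient of variation of per-neuron intensity
#'   multipliers (biological cell-to-cell variability).
#' @param spot_sigma Gaussian sigma of a rendered punctum in microns. The
#'   imaging system's PSF is not modelled explicitly; spot size is a free,
#'   documented parameter.
#' @param puncta_min_sep minimum distance between planted punctae (microns).
#' @param syp1 logical; add a SYP1-like presynapse channel with punctae
#'   planted along neurite paths.
#' @param seed integer; fixes the full scene byte-for-byte.
#' @return An object of class `scene_config` (a validated list).
#' @seealso [generate_field()], [generate_plate()]
#' @export
scene_config <- function(field_shape = c(560L, 560L),
                         pixel_size = 0.65,
                         n_neurons = 100L,
                         frac_tau_pos = 0.7,
                         frac_gvb_pos_given_tau = 0.10,
                         frac_gfp_pos = NA_real_,
                         punctae_per_gvb_neuron = c(2L, 6L),
                         nucleus_radius = c(mean = 4, sd = 0.4),
                         soma_radius = c(mean = 8, sd = 0.8),
                         min_separation = 20,
                         channel_effects = list(
                           tau = c(tau_neg = 1, gvb_neg = 5, gvb_pos = 5)),
                         intensity = list(),
                         noise = list(),
                         cell_cv = 0.10,
                         spot_sigma = 0.85,
                         puncta_min_sep = 3,
                         syp1 = FALSE,
                         seed = 1L) {
  intensity <- utils::modifyList(list(
    dapi = 600, map2 = 400, neurite = 120, marker = 150,
    puncta_contrast = 6, measurement = 400, gfp = 300,
    gfp_pos_contrast = 10), intensity)
  noise <- utils::modifyList(list(
    background = 100, read_sd = 3, poisson = TRUE), noise)

  stopifnot_scalar(pixel_size, "pixel_size", lower = 1e-3)
  stopifnot_scalar(n_neurons, "n_neurons", lower = 0)
  stopifnot_scalar(frac_tau_pos, "frac_tau_pos", 0, 1)
  stopifnot_scalar(frac_gvb_pos_given_tau, "frac_gvb_pos_given_tau", 0, 1)
  if (!is.na(frac_gfp_pos))
    stopifnot_scalar(frac_gfp_pos, "frac_gfp_pos", 0, 1)
  if (length(field_shape) != 2L || any(field_shape < 8))
    stop("`field_shape` must be two pixel dimensions >= 8", call. = FALSE)
  if (length(punctae_per_gvb_neuron) != 2L ||
      punctae_per_gvb_neuron[1L] < 1L ||
      punctae_per_gvb_neuron[2L] < punctae_per_gvb_neuron[1L])
    stop("`punctae_per_gvb_neuron` must be an increasing integer pair >= 1",
         call. = FALSE)
  if (nucleus_radius[1L] >= soma_radius[1L])
    stop("mean `nucleus_radius` must be smaller than mean `soma_radius`",
         call. = FALSE)
  if (!is.list(channel_effects) ||
      (length(channel_effects) && is.null(names(channel_effects))))
    stop("`channel_effects` must be a named list", call. = FALSE)
  for (nm in names(channel_effects)) {
    ef <- channel_effects[[nm]]
    if (!all(c("tau_neg", "gvb_neg", "gvb_pos") %in% names(ef)))
      stop(sprintf(
        "channel effect '%s' needs tau_neg, gvb_neg and gvb_pos entries", nm),
        call. = FALSE)
    if (any(ef < 0)) stop("channel effects must be non-negative", call. = FALSE)
  }
  structure(list(
    field_shape = as.integer(field_shape), pixel_size = pixel_size,
    n_neurons = as.integer(n_neurons), frac_tau_pos = frac_tau_pos,
    frac_gvb_pos_given_tau = frac_gvb_pos_given_tau,
    frac_gfp_pos = frac_gfp_pos,
    punctae_per_gvb_neuron = as.integer(punctae_per_gvb_neuron),
    nucleus_radius = unname(nucleus_radius),
    soma_radius = unname(soma_radius),
    min_separation = min_separation,
    channel_effects = channel_effects, intensity = intensity, noise = noise,
    cell_cv = cell_cv, spot_sigma = spot_sigma,
    puncta_min_sep = puncta_min_sep, syp1 = isTRUE(syp1),
    seed = as.integer(seed)), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "scene_config: %dx%d px (%.2f um/px), %d neurons, tau+ %.2f, GVB+|tau+ %.2f, seed %d\n",
    x$field_shape[1L], x$field_shape[2L], x$pixel_size, x$n_neurons,
    x$frac_tau_pos, x$frac_gvb_pos_given_tau, x$seed))
  cat("measurement channels:",
      paste(names(x$channel_effects), collapse = ", "), "\n")
  invisible(x)
}
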