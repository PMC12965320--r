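#' Generate a synthetic plate of fields
#'
#' Produces one or more fields per well according to a plate layout. Each
#' well's fields are generated from the configuration named by its
#' `config` column, with a seed derived deterministically from that
#' configuration's seed and the well/field index, so the whole plate is
#' reproducible from the layout alone.
#'
#' @param configs_by_well named list of [scene_config()] objects, keyed by
#'   the layout's `config` column.
#' @param layout data frame with columns `well`, `condition`, `replicate`,
#'   `config` and optionally `n_fields` (default 1).
#' @return A list with one element per field: `well`, `condition`,
#'   `replicate`, `field`, `stack`, `truth`.
#' @export
generate_plate <- function(configs_by_well, layout) {
  req <- c("well", "condition", "replicate", "config")
  if (!all(req %in% names(layout)))
    stop("`layout` needs columns well, condition, replicate, config",
         call. = FALSE)
  if (anyDuplicated(layout$well))
    stop("duplicate well ids in `layout`", call. = FALSE)
  missing_cfg <- setdiff(unique(layout$config), names(configs_by_well))
  if (length(missing_cfg))
    stop(sprintf("layout references config keys absent from `configs_by_well`: %s",
                 paste(missing_cfg, collapse = ", ")), call. = FALSE)
  if (is.null(layout$n_fields)) layout$n_fields <- 1L

  out <- list()
  for (w in seq_len(nrow(layout))) {
    cfg <- configs_by_well[[layout$config[w]]]
    for (f in seq_len(layout$n_fields[w])) {
      cfg_f <- cfg
      cfg_f$seed <- derive_seed(cfg$seed, w, f)
      fld <- generate_field(cfg_f)
      out[[length(out) + 1L]] <- list(
        well = layout$well[w], condition = layout$condition[w],
        replicate = layout$replicate[w], field = f,
        stack = fld$stack, truth = fld$truth)
    }
  }
  out
}

#' Write and re-read a field as a multi-page TIFF
#'
#' `write_field()` stores each channel as one 16-bit page plus a plain-text
#' sidecar (`<file>.channels.txt`) holding channel names, roles and the
#' pixel size; `read_field()` restores a numerically identical
#' `channel_stack`.
#'
#' @param stack a `channel_stack` with integer pixel values in [0, 65535].
#' @param file path of the TIFF to write/read.
#' @return `write_field()` the file path, invisibly; `read_field()` a
#'   `channel_stack`.
#' @export
write_field <- function(stack, file) {
  if (!inherits(stack, "channel_stack"))
    stop("`stack` must be a channel_stack", call. = FALSE)
  pages <- lapply(stack$images, function(m) m / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  sidecar <- data.frame(channel = names(stack$images),
                        role = unname(stack$roles[names(stack$images)]),
                        pixel_size = stack$pixel_size)
  utils::write.csv(sidecar, paste0(file, ".channels.txt"), row.names = FALSE)
  invisible(file)
}

#' @rdname write_field
#' @export
read_field <- function(file) {
  sidecar <- utils::read.csv(paste0(file, ".channels.txt"),
                             stringsAsFactors = FALSE)
  pages <- tiff::readTIFF(file, all = TRUE)
  if (length(pages) != nrow(sidecar))
    stop("channel sidecar does not match TIFF page count", call. = FALSE)
  images <- lapply(pages, function(p) {
    m <- round(p * 65535)
    matrix(m, nrow(m), ncol(m))
  })
  names(images) <- sidecar$channel
  structure(list(images = images,
                 roles = stats::setNames(sidecar$role, sidecar$channel),
                 pixel_size = sidecar$pixel_size[1L]),
            class = "channel_stack")
}

#' Write the planted ground truth of a field as a CSV
#'
#' One row per neuron; punctae coordinates go to a companion file
#' `<file>.punctae.csv`.
#' @param truth a `scene_truth`.
#' @param file path of the CSV to write.
#' @export
write_truth <- function(truth, file) {
  utils::write.csv(truth$neurons, file, row.names = FALSE)
  utils::write.csv(truth$punctae, paste0(file, ".punctae.csv"),
                   row.names = FALSE)
  invisible(file)
}
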