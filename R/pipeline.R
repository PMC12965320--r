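#' Run the full single-field analysis cascade
#'
#' Segments nuclei and somata, runs the GVB punctum detection /
#' clustering / acceptance cascade, classifies each neuron's raw GVB
#' status and measures somatic and nuclear intensities for every
#' measurement channel. Tau and GFP status are not assigned here because
#' their thresholds are calibrated across a plate (see [analyze_plate()]);
#' the somatic means needed for those gates are returned.
#'
#' @param stack a `channel_stack` with at least `nucleus`, `soma` and
#'   `marker` roles.
#' @param marker_name band-pass profile for the GVB marker channel
#'   (default `"pperk"`).
#' @param params named list overriding cascade defaults: `min_puncta`,
#'   `max_link`, `k_puncta`, `area_range`, `min_roundness`,
#'   `marker_ratio`, `max_nucleus_overlap`, `nucleus_area_range`,
#'   `nucleus_min_roundness`, `indeterminate_to_negative`.
#' @return List with `neurons` (one row per segmented object), `clusters`
#'   (scored cluster table), `somata`, `nuclei` and `background` (per
#'   channel field background, the median intensity outside all somata).
#' @export
analyze_field <- function(stack, marker_name = "pperk", params = list()) {
  if (!inherits(stack, "channel_stack"))
    stop("`stack` must be a channel_stack", call. = FALSE)
  p <- utils::modifyList(list(
    min_puncta = 2L, max_link = 2, k_puncta = 4,
    area_range = c(0.5, 20), min_roundness = 0.5, marker_ratio = 2,
    max_nucleus_overlap = 0.5, nucleus_area_range = c(25, 300),
    nucleus_min_roundness = 0.7, indeterminate_to_negative = FALSE),
    params)
  px <- stack$pixel_size
  img <- stack$images
  ch_role <- function(role) {
    nm <- names(stack$roles)[stack$roles == role]
    if (length(nm)) img[[nm[1L]]] else NULL
  }
  dapi <- ch_role("nucleus"); map2 <- ch_role("soma")
  marker <- ch_role("marker")
  if (is.null(dapi) || is.null(map2) || is.null(marker))
    stop("stack must contain nucleus, soma and marker channels",
         call. = FALSE)

  nuclei <- detect_nuclei(dapi, map2, pixel_size = px,
                          area_range = p$nucleus_area_range,
                          min_roundness = p$nucleus_min_roundness)
  somata <- build_somata(nuclei, map2)

  filtered <- background_filter(marker, marker_name, pixel_size = px)
  punctae <- detect_puncta(filtered, somata, k = p$k_puncta)
  clustered <- cluster_puncta(punctae, max_link_distance = p$max_link,
                              pixel_size = px)
  scored <- accept_clusters(clustered, somata, marker, map2, filtered,
                            area_range = p$area_range,
                            min_roundness = p$min_roundness,
                            marker_ratio = p$marker_ratio,
                            max_nucleus_overlap = p$max_nucleus_overlap)
  status <- classify_neuron(somata, scored, min_puncta = p$min_puncta,
                            indeterminate_to_negative =
                              p$indeterminate_to_negative)

  neurons <- merge(nuclei$table, somata$table, by = "label", all.x = TRUE)
  neurons <- merge(neurons, status, by = "label", all.x = TRUE)
  names(neurons)[names(neurons) == "area_um2.x"] <- "nucleus_area_um2"
  names(neurons)[names(neurons) == "area_um2.y"] <- "soma_area_um2"
  names(neurons)[names(neurons) == "gvb_status"] <- "gvb_status_raw"
  acc_cl <- scored$clusters[scored$clusters$accepted, , drop = FALSE]
  ncl <- table(factor(acc_cl$parent_soma, levels = neurons$label))
  neurons$n_gvb_clusters <- as.integer(ncl[as.character(neurons$label)])

  cluster_px <- unlist(scored$clusters$pixels[scored$clusters$accepted])
  measure <- names(img)[stack$roles[names(img)] %in%
                          c("measurement", "gfp", "marker")]
  background <- numeric(0)
  for (ch in measure) {
    v <- somatic_intensity(somata, img[[ch]])
    neurons[[paste0("somatic_", ch)]] <- v[as.character(neurons$label)]
    background[ch] <- field_background(img[[ch]], somata$labels)
    neurons[[paste0("somatic_", ch, "_corr")]] <-
      neurons[[paste0("somatic_", ch)]] - background[ch]
    nc <- nuclear_corrected_intensity(
      somata, img[[ch]],
      exclude = if (stack$roles[ch] == "marker") cluster_px else NULL)
    neurons[[paste0("nuccorr_", ch)]] <- nc[as.character(neurons$label)]
  }
  mk_name <- names(stack$roles)[stack$roles == "marker"][1L]
  v_excl <- somatic_intensity(somata, marker, exclude = cluster_px)
  neurons[[paste0("somatic_", mk_name, "_excl")]] <-
    v_excl[as.character(neurons$label)]

  # per-neuron GVB morphometrics for GVB+ neurons
  neurons$gvb_area_um2 <- NA_real_
  neurons$gvb_cytosol_ratio <- NA_real_
  for (l in neurons$label[!is.na(neurons$gvb_status_raw) &
                          neurons$gvb_status_raw == "GVB+"]) {
    m <- gvb_metrics(l, scored, somata, marker)
    neurons$gvb_area_um2[neurons$label == l] <- m$gvb_area_per_neuron
    neurons$gvb_cytosol_ratio[neurons$label == l] <- m$gvb_to_cytosol_ratio
  }

  list(neurons = neurons, clusters = scored$clusters, punctae =
         scored$punctae, somata = somata, nuclei = nuclei,
       background = background)
}

#' Analyse a plate of fields and assemble the per-neuron table
#'
#' Runs [analyze_field()] on every field, calibrates the tau threshold on
#' the untransduced control wells (somatic mean tau, `mean + k * sd`),
#' classifies tau status, applies the false-positive rule (tau- neurons
#' are forced GVB-, the raw call is kept in `gvb_status_raw`) and, when a
#' GFP channel is present, gates GFP+ neurons against the same control
#' wells.
#'
#' @param fields list of fields as produced by [generate_plate()], or any
#'   list whose elements carry `well`, `condition`, `replicate`, `field`
#'   and `stack`.
#' @param marker_name GVB marker profile name.
#' @param tau_control_condition condition label of the untransduced
#'   calibration wells (default `"untransduced"`); pass `tau_threshold`
#'   to skip calibration.
#' @param tau_threshold absolute somatic tau threshold (optional).
#' @param tau_k sd multiplier of the tau calibration.
#' @param gfp_q control quantile of the GFP gate.
#' @param params cascade parameter overrides, see [analyze_field()].
#' @return List with `neurons` (all fields, neuronal objects only, with
#'   `tau_status`, `gvb_status`, `population`), `all_objects` (including
#'   non-neuronal ones), `clusters`, `tau_threshold` and `gfp_threshold`.
#' @export
analyze_plate <- function(fields, marker_name = "pperk",
                          tau_control_condition = "untransduced",
                          tau_threshold = NULL, tau_k = 3, gfp_q = 0.99,
                          params = list()) {
  res <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    out <- analyze_field(f$stack, marker_name = marker_name, params = params)
    out$neurons <- cbind(well = f$well, condition = f$condition,
                         replicate = f$replicate, field = f$field,
                         out$neurons)
    res[[i]] <- out
  }
  objects <- do.call(rbind, lapply(res, `[[`, "neurons"))
  clusters <- do.call(rbind, lapply(seq_along(res), function(i) {
    cl <- res[[i]]$clusters
    if (!nrow(cl)) return(NULL)
    cl$pixels <- NULL
    cbind(well = fields[[i]]$well, condition = fields[[i]]$condition,
          field = fields[[i]]$field, cl)
  }))

  tau_col <- grep("^somatic_tau$", names(objects), value = TRUE)
  if (length(tau_col)) {
    ctrl <- objects$condition == tau_control_condition & objects$is_neuronal
    ctrl_means <- objects$somatic_tau[ctrl]
    if (is.null(tau_threshold) && !any(ctrl))
      stop(sprintf(paste0("no wells with condition '%s' to calibrate the ",
                          "tau threshold and no `tau_threshold` given"),
                   tau_control_condition), call. = FALSE)
    ts <- classify_tau_status(objects$somatic_tau,
                              control_means = if (any(ctrl)) ctrl_means,
                              threshold = tau_threshold, k = tau_k)
    objects$tau_status <- as.logical(ts)
    tau_threshold <- attr(ts, "threshold")
  } else {
    objects$tau_status <- NA
    tau_threshold <- NA_real_
  }

  gfp_threshold <- NA_real_
  if ("somatic_gfp" %in% names(objects)) {
    ctrl <- objects$condition == tau_control_condition & objects$is_neuronal
    gg <- gfp_gate(objects$somatic_gfp, objects$somatic_gfp[ctrl], q = gfp_q)
    objects$gfp_positive <- as.logical(gg)
    gfp_threshold <- attr(gg, "threshold")
  }

  # false-positive rule: tau- neurons cannot be GVB+
  objects$gvb_status <- objects$gvb_status_raw
  objects$gvb_status[!is.na(objects$tau_status) & !objects$tau_status] <-
    "GVB-"
  objects$population <- ifelse(
    !objects$tau_status, "tau_neg",
    ifelse(objects$gvb_status == "GVB+", "gvb_pos",
           ifelse(objects$gvb_status == "GVB-", "gvb_neg",
                  "indeterminate")))

  list(neurons = objects[objects$is_neuronal, , drop = FALSE],
       all_objects = objects, clusters = clusters,
       tau_threshold = tau_threshold, gfp_threshold = gfp_threshold)
}
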