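# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A mid-size field with a high planted GVB+ fraction, analysed once.
std_field <- function() {
  if (is.null(.fixtures$std)) {
    cfg <- scene_config(n_neurons = 60, field_shape = c(460L, 460L),
                        frac_tau_pos = 0.7, frac_gvb_pos_given_tau = 0.4,
                        seed = 42)
    fs <- generate_field(cfg)
    .fixtures$std <- c(fs, list(analysis = analyze_field(fs$stack),
                                config = cfg))
  }
  .fixtures$std
}

# A small plate: untransduced calibration wells plus transduced wells.
std_plate <- function() {
  if (is.null(.fixtures$plate)) {
    base <- scene_config(n_neurons = 50, field_shape = c(430L, 430L),
                         frac_tau_pos = 0.8, frac_gvb_pos_given_tau = 0.3,
                         seed = 5)
    ctrl <- base; ctrl$frac_tau_pos <- 0; ctrl$frac_gvb_pos_given_tau <- 0
    layout <- data.frame(
      well = c("A1", "A2", "B1", "B2", "B3"),
      condition = c("untransduced", "untransduced", "tau", "tau", "tau"),
      replicate = c("N1", "N1", "N1", "N2", "N2"),
      config = c("ctrl", "ctrl", "tau", "tau", "tau"))
    fields <- generate_plate(list(ctrl = ctrl, tau = base), layout)
    .fixtures$plate <- list(fields = fields, layout = layout,
                            analysis = analyze_plate(fields))
  }
  .fixtures$plate
}

# Planting-level truth only (no rasterisation).
with_seed_truth <- function(cfg) {
  generate_field(cfg, render = FALSE)$truth$neurons
}

# Deterministic nested replicate table generator for the statistics tests.
sim_nested <- function(n_groups = 2, n_bio = 3, n_tech = 3,
                       group_effects = rep(0, n_groups),
                       sd_bio = 1, sd_tech = 1, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    do.call(rbind, lapply(seq_len(n_bio), function(b) {
      mu <- group_effects[g] + rnorm(1, 0, sd_bio)
      data.frame(condition = paste0("g", g),
                 replicate = paste0("g", g, "_b", b),
                 value = mu + rnorm(n_tech, 0, sd_tech))
    }))
  }))
  rownames(out) <- NULL
  out
}
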