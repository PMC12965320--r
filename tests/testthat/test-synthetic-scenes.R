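test_that("empty and degenerate configurations render pure background", {
  fs <- generate_field(scene_config(n_neurons = 0, field_shape = c(64L, 64L),
                                    seed = 1))
  expect_equal(nrow(fs$truth$neurons), 0L)
  expect_equal(max(fs$truth$nucleus_labels), 0L)
  bg <- fs$stack$images$dapi
  expect_lt(abs(mean(bg) - 100), 3)  # background counts plus noise only

  # no GVB+ neurons planted => not a single punctum in the marker channel
  fs0 <- generate_field(scene_config(n_neurons = 25,
                                     field_shape = c(300L, 300L),
                                     frac_gvb_pos_given_tau = 0, seed = 2))
  expect_equal(nrow(fs0$truth$punctae), 0L)
  expect_false(any(fs0$truth$neurons$gvb_status))
})

test_that("the seed fixes the full scene bit for bit", {
  cfg <- scene_config(n_neurons = 30, field_shape = c(300L, 300L), seed = 7)
  a <- generate_field(cfg); b <- generate_field(cfg)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth$neurons, b$truth$neurons)
  expect_identical(a$truth$punctae, b$truth$punctae)
})

test_that("planted statuses respect the generator invariants", {
  fs <- std_field()
  tr <- fs$truth$neurons
  # GVB only in tau+ neurons
  expect_true(all(tr$tau_status[tr$gvb_status]))
  # punctae of a GVB+ neuron lie inside its soma and outside its nucleus
  pp <- fs$truth$punctae
  lin <- cbind(round(pp$cy), round(pp$cx))
  expect_true(all(fs$truth$soma_labels[lin] == pp$neuron))
  expect_true(all(fs$truth$nucleus_labels[lin] == 0L))
  # every GVB+ neuron got at least 2 punctae (default confocal-rule floor)
  expect_true(all(tr$n_punctae[tr$gvb_status] >= 2L))
  expect_true(all(tr$n_punctae[!tr$gvb_status] == 0L))
})

test_that("planted fractions are conserved at scale", {
  # quota planting: aggregate over many fields, compare to the target
  # within 3 binomial SDs (the planting scheme is tighter than binomial)
  frac_tau <- 0.7; frac_gvb <- 0.34
  n_tot <- 0L; n_tau <- 0L; n_gvb <- 0L
  for (s in 1:25) {
    cfg <- scene_config(n_neurons = 400, field_shape = c(1120L, 1120L),
                        frac_tau_pos = frac_tau,
                        frac_gvb_pos_given_tau = frac_gvb, seed = s)
    tr <- with_seed_truth(cfg)
    n_tot <- n_tot + nrow(tr)
    n_tau <- n_tau + sum(tr$tau_status)
    n_gvb <- n_gvb + sum(tr$gvb_status)
  }
  expect_equal(n_tot, 10000L)
  p <- frac_tau * frac_gvb
  expect_lt(abs(n_gvb / n_tot - p), 3 * sqrt(p * (1 - p) / n_tot))
  expect_lt(abs(n_tau / n_tot - frac_tau),
            3 * sqrt(frac_tau * (1 - frac_tau) / n_tot))
})

test_that("measurement-channel effects do not perturb structural channels", {
  base <- scene_config(n_neurons = 20, field_shape = c(300L, 300L),
                       channel_effects = list(
                         tau = c(tau_neg = 1, gvb_neg = 5, gvb_pos = 5),
                         puromycin = c(tau_neg = 1, gvb_neg = 1,
                                       gvb_pos = 1)),
                       seed = 3)
  alt <- base
  alt$channel_effects$puromycin <- c(tau_neg = 1, gvb_neg = 0.5,
                                     gvb_pos = 2)
  a <- generate_field(base); b <- generate_field(alt)
  expect_identical(a$stack$images$dapi, b$stack$images$dapi)
  expect_identical(a$stack$images$map2, b$stack$images$map2)
  expect_identical(a$truth$neurons$tau_status, b$truth$neurons$tau_status)
  expect_false(identical(a$stack$images$puromycin,
                         b$stack$images$puromycin))
})

test_that("overcrowded configurations fail with an explicit error", {
  cfg <- scene_config(n_neurons = 400, field_shape = c(120L, 120L), seed = 1)
  expect_error(generate_field(cfg), "min_separation")
})

test_that("a field written to TIFF reads back numerically identical", {
  fs <- generate_field(scene_config(n_neurons = 10,
                                    field_shape = c(200L, 200L), seed = 9))
  path <- file.path(tempdir(), "field.tiff")
  write_field(fs$stack, path)
  back <- read_field(path)
  expect_identical(names(back$images), names(fs$stack$images))
  expect_equal(back$images, fs$stack$images)
  expect_equal(back$pixel_size, fs$stack$pixel_size)
  unlink(c(path, paste0(path, ".channels.txt")))
})

test_that("generate_plate validates its layout and keys truths by well", {
  cfg <- scene_config(n_neurons = 5, field_shape = c(160L, 160L), seed = 1)
  layout1 <- data.frame(well = "A1", condition = "ctrl", replicate = "N1",
                        config = "c")
  p1 <- generate_plate(list(c = cfg), layout1)
  expect_length(p1, 1L)
  expect_equal(p1[[1L]]$well, "A1")

  bad <- rbind(layout1, layout1)
  expect_error(generate_plate(list(c = cfg), bad), "duplicate")
  layout2 <- data.frame(well = "A1", condition = "ctrl", replicate = "N1",
                        config = "missing")
  expect_error(generate_plate(list(c = cfg), layout2), "absent")
})

test_that("planted control/treated ratio is exact at the planting stage", {
  # 3 control + 3 treated wells, planted ratio 1/3 with quota-exact counts
  ctrl <- scene_config(n_neurons = 60, field_shape = c(460L, 460L),
                       frac_tau_pos = 5 / 6,
                       frac_gvb_pos_given_tau = 0.3, seed = 4)
  trt <- ctrl; trt$frac_gvb_pos_given_tau <- 0.1
  layout <- data.frame(well = paste0("A", 1:6),
                       condition = rep(c("control", "treated"), each = 3),
                       replicate = "N1",
                       config = rep(c("c", "t"), each = 3))
  plate <- generate_plate(list(c = ctrl, t = trt), layout)
  counts <- sapply(plate, function(f)
    c(gvb = sum(f$truth$neurons$gvb_status),
      tau = sum(f$truth$neurons$tau_status)))
  # 60 neurons * 5/6 = 50 tau+ exactly; 0.3 * 50 = 15 and 0.1 * 50 = 5
  expect_true(all(counts["tau", ] == 50))
  expect_true(all(counts["gvb", 1:3] == 15))
  expect_true(all(counts["gvb", 4:6] == 5))
})

test_that("time-course sampling matches the formation-block decay model", {
  kt <- kinetic_truth(times = c(0, 10, 20), fractions = c(0, 10, 20),
                      t0 = 10, half_life = 5.4, obs_times = c(10, 12, 18),
                      noise_sd = 0)
  tc <- generate_timecourse(kt, n_replicates = 1, seed = 1)
  trt <- tc[tc$arm == "treated", ]
  ctl <- tc[tc$arm == "control", ]
  # continuity at treatment start: treated value equals control value at t0
  expect_equal(trt$fraction[trt$time == 10],
               ctl$fraction[ctl$time == 10])
  # half-life definition: one half-life after t0 the fraction has halved
  kt2 <- kinetic_truth(times = c(0, 10, 20), fractions = c(0, 10, 20),
                       t0 = 10, half_life = 5.4,
                       obs_times = 10 + 5.4, noise_sd = 0)
  tc2 <- generate_timecourse(kt2, n_replicates = 1, seed = 1)
  expect_equal(tc2$fraction[tc2$arm == "treated"], 10 / 2)
  # closed-form retention factors at offsets 2 and 8 days, t1/2 = 5.4 d
  expect_equal(trt$fraction[trt$time == 12] / 10, 2^(-2 / 5.4))
  expect_equal(trt$fraction[trt$time == 18] / 10, 2^(-8 / 5.4))
  expect_error(kinetic_truth(half_life = -1), "positive")
})
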