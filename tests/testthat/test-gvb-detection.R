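test_that("the band-pass filter suppresses flat and ramp backgrounds", {
  const <- matrix(500, 60, 60)
  expect_true(all(background_filter(const, "pperk") == 0))

  # a single Gaussian spot on flat background: maximum at the centroid
  img <- matrix(100, 61, 61)
  d2 <- outer((1:61 - 31)^2, (1:61 - 31)^2, "+")
  img <- img + 900 * exp(-d2 / (2 * 2^2))
  f <- background_filter(img, "pperk")
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(31, 31))

  # spot + linear ramp: the ramp response stays well below the spot
  # response; checked against a direct spatial-domain band-pass oracle
  ramp <- img + outer(rep(1, 61), seq(0, 600, length.out = 61))
  fr <- background_filter(ramp, "pperk")
  spot_resp <- fr[31, 31]
  ramp_only <- fr[8, 45]  # far from the spot
  expect_gt(spot_resp, 5 * ramp_only)
  orc <- oracle_dog(ramp[16:46, 16:46], 0.85 / 0.65, 3.5 / 0.65)
  expect_gt(cor(as.vector(fr[16:46, 16:46]), as.vector(orc)), 0.98)
  expect_lt(abs(spot_resp - orc[16, 16]) / orc[16, 16], 0.1)

  expect_error(background_filter(const, "nonesuch"), "profile")
})

test_that("punctum detection finds planted spots and respects somata", {
  fs <- std_field()
  an <- fs$analysis
  # every planted punctum of a detected neuron is recovered within 2 px
  pp <- fs$truth$punctae
  det <- an$punctae
  hits <- vapply(seq_len(nrow(pp)), function(i)
    any((det$cy - pp$cy[i])^2 + (det$cx - pp$cx[i])^2 <= 4), logical(1))
  expect_gte(mean(hits), 0.95)

  # a zero-GVB field yields an empty punctum list
  f0 <- generate_field(scene_config(n_neurons = 20,
                                    field_shape = c(300L, 300L),
                                    frac_gvb_pos_given_tau = 0, seed = 3))
  a0 <- analyze_field(f0$stack)
  expect_equal(nrow(a0$punctae), 0L)
  expect_true(all(a0$neurons$gvb_status_raw == "GVB-"))
})

test_that("punctae outside every soma never classify a neuron", {
  # plant one bright spot in empty background, far from the only neuron
  fs <- generate_field(scene_config(n_neurons = 1,
                                    field_shape = c(220L, 220L),
                                    frac_tau_pos = 1,
                                    frac_gvb_pos_given_tau = 0, seed = 8))
  img <- fs$stack$images$gvb
  d2 <- outer((1:220 - 40)^2, (1:220 - 40)^2, "+")
  img <- img + 1200 * exp(-d2 / (2 * 1.7^2))
  fs$stack$images$gvb <- img
  an <- analyze_field(fs$stack)
  out <- an$punctae[an$punctae$parent_soma == 0L, ]
  expect_gte(nrow(out), 1L)
  expect_true(all(an$neurons$gvb_status_raw != "GVB+"))
})

test_that("proximity clustering is single linkage and soma-bounded", {
  mk <- function(cy, cx, soma) data.frame(cy = cy, cx = cx,
                                          peak_intensity = 1,
                                          area_um2 = 1, parent_soma = soma)
  px <- 0.65
  # two punctae 1.3 um apart in one soma: one cluster of 2
  p2 <- mk(c(10, 12), c(10, 10), c(1L, 1L))
  cl2 <- cluster_puncta(p2, max_link_distance = 2, pixel_size = px)
  expect_equal(nrow(cl2$clusters), 1L)
  expect_equal(cl2$clusters$n_punctae, 2L)
  # same geometry in different somata: never merged
  p3 <- mk(c(10, 12), c(10, 10), c(1L, 2L))
  cl3 <- cluster_puncta(p3, max_link_distance = 2, pixel_size = px)
  expect_equal(nrow(cl3$clusters), 2L)
  expect_error(cluster_puncta(p2, max_link_distance = 0), "positive")
})

test_that("single-linkage grouping matches a brute-force union-find oracle", {
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(2:10, 1)
    coords <- cbind(runif(n, 1, 60), runif(n, 1, 60))
    p <- data.frame(cy = coords[, 1], cx = coords[, 2],
                    peak_intensity = 1, area_um2 = 1, parent_soma = 1L)
    got <- cluster_puncta(p, max_link_distance = 8, pixel_size = 1)
    want <- oracle_single_linkage(coords, 8)
    # same partition (compare co-membership matrices)
    expect_identical(outer(got$punctae$cluster, got$punctae$cluster, "=="),
                     outer(want, want, "=="))
  }
  # an explicit chain: consecutive links merge transitively
  chain <- data.frame(cy = seq(5, 5 + 9 * 2.5, by = 2.5), cx = 5,
                      peak_intensity = 1, area_um2 = 1, parent_soma = 1L)
  got <- cluster_puncta(chain, max_link_distance = 3, pixel_size = 1)
  expect_equal(nrow(got$clusters), 1L)
  expect_equal(got$clusters$n_punctae, 10L)
})

test_that("acceptance gates reject nuclear and off-MAP2 clusters", {
  fs <- generate_field(scene_config(n_neurons = 4,
                                    field_shape = c(260L, 260L),
                                    frac_tau_pos = 1,
                                    frac_gvb_pos_given_tau = 0, seed = 12))
  img <- fs$stack$images$gvb
  tr <- fs$truth$neurons
  spot <- function(img, cy, cx) {
    d2 <- outer((seq_len(nrow(img)) - cy)^2, (seq_len(ncol(img)) - cx)^2, "+")
    img + 1400 * exp(-d2 / (2 * 1.7^2))
  }
  # one spot dead-centre in neuron 1's nucleus, one far outside all somata
  img <- spot(img, tr$cy[1], tr$cx[1])
  bg_y <- 20; bg_x <- 20
  img <- spot(img, bg_y, bg_x)
  fs$stack$images$gvb <- img
  an <- analyze_field(fs$stack)
  cl <- an$clusters
  in_nuc <- cl[cl$nucleus_overlap_frac > 0.5, ]
  expect_gte(nrow(in_nuc), 1L)
  expect_true(all(!in_nuc$accepted))
  expect_true(all(in_nuc$failing_gate == "nuclear_exclusion"))
  off <- cl[cl$parent_soma == 0L, ]
  expect_gte(nrow(off), 1L)
  expect_true(all(!off$accepted))
  expect_true(all(off$failing_gate %in%
                    c("map2_intensity", "marker_intensity")))
})

test_that("bona fide planted GVB clusters are accepted with sane metrics", {
  fs <- std_field()
  an <- fs$analysis
  cl <- an$clusters
  expect_gt(mean(cl$accepted[cl$parent_soma > 0L]), 0.9)
  acc <- cl[cl$accepted, ]
  expect_true(all(acc$area_um2 >= 0.5 & acc$area_um2 <= 20))
  expect_true(all(acc$mean_marker >= 2 * acc$cytosol_marker))
  expect_true(all(acc$nucleus_overlap_frac < 0.5))

  # per-neuron metrics: area sum equals the sum of single sizes; the
  # GVB/cytosol marker ratio is well above 1 for bright planted punctae
  gvb_lab <- an$neurons$label[an$neurons$gvb_status_raw == "GVB+"][1]
  m <- gvb_metrics(gvb_lab, list(clusters = an$clusters), an$somata,
                   fs$stack$images$gvb)
  expect_equal(m$gvb_area_per_neuron, sum(m$single_gvb_sizes))
  expect_gt(m$gvb_to_cytosol_ratio, 1.5)
  gvbneg_lab <- an$neurons$label[an$neurons$gvb_status_raw == "GVB-"][1]
  expect_error(gvb_metrics(gvbneg_lab, list(clusters = an$clusters),
                           an$somata, fs$stack$images$gvb), "GVB\\+")
})

test_that("the confocal counting rule drives neuron classification", {
  fs <- std_field()
  an <- fs$analysis
  st <- classify_neuron(an$somata, list(clusters = an$clusters))
  expect_true(all(st$gvb_status[st$n_punctae == 0L] == "GVB-"))
  expect_true(all(st$gvb_status[st$n_punctae == 1L] == "indeterminate"))
  expect_true(all(st$gvb_status[st$n_punctae >= 2L] == "GVB+"))
  st1 <- classify_neuron(an$somata, list(clusters = an$clusters),
                         indeterminate_to_negative = TRUE)
  expect_false(any(st1$gvb_status == "indeterminate"))
})

test_that("raising the punctum threshold never adds GVB+ neurons", {
  fs <- std_field()
  an <- fs$analysis
  counts <- vapply(c(3, 4, 6, 9, 15), function(k) {
    a <- analyze_field(fs$stack, params = list(k_puncta = k))
    sum(a$neurons$gvb_status_raw == "GVB+")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the cascade is deterministic and gates only ever remove", {
  fs <- generate_field(scene_config(n_neurons = 30,
                                    field_shape = c(340L, 340L),
                                    frac_gvb_pos_given_tau = 0.5, seed = 21))
  a1 <- analyze_field(fs$stack)
  a2 <- analyze_field(fs$stack)
  expect_identical(a1$clusters$cluster, a2$clusters$cluster)
  expect_identical(a1$neurons$gvb_status_raw, a2$neurons$gvb_status_raw)

  # disabling a gate can only add accepted clusters, never remove any
  base <- a1$clusters$accepted
  for (relax in list(list(area_range = c(0, Inf)),
                     list(min_roundness = 0),
                     list(marker_ratio = 0),
                     list(max_nucleus_overlap = 1.01))) {
    ar <- analyze_field(fs$stack, params = relax)
    expect_true(all(ar$clusters$accepted[base]))
  }
})
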