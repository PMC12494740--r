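test_that("default signatures concentrate class contrast in the window", {
  cfg <- sim_config("test", n_classes = 11, include_background = TRUE)
  sigs <- make_default_signatures(cfg)
  expect_length(sigs, 11)
  wl <- wavelengths(cfg$axis)
  win <- cfg$informative_window
  inside <- wl >= win[1] & wl <= win[2]

  # all peak centers strictly inside the window, distinct center sets
  centers <- lapply(sigs[1:10], function(s) s$peaks$center_nm)
  for (cs in centers) {
    expect_length(cs, 2)
    expect_true(all(cs > win[1] & cs < win[2]))
  }
  expect_equal(length(unique(vapply(centers, function(cs)
    paste(round(cs, 3), collapse = "/"), character(1)))), 10)

  # background class has no peaks
  expect_equal(nrow(sigs[[11]]$peaks), 0)

  # pairwise contrast outside the window <= 10% of in-window contrast
  curves <- vapply(sigs, eval_signature, numeric(length(wl)), wl = wl)
  pairs <- utils::combn(10, 2)
  for (p in seq_len(ncol(pairs))) {
    d <- abs(curves[, pairs[1, p]] - curves[, pairs[2, p]])
    expect_lte(max(d[!inside]), 0.1 * max(d[inside]))
  }
})

test_that("signatures are deterministic given the seed", {
  cfg <- sim_config("test", seed = 5)
  s1 <- make_default_signatures(cfg)
  s2 <- make_default_signatures(cfg)
  expect_identical(s1, s2)
  cfg2 <- cfg; cfg2$seed <- 6L
  s3 <- make_default_signatures(cfg2)
  expect_false(identical(s1, s3))
})

test_that("two-class signatures share the spectrum outside the window", {
  cfg <- sim_config("test", n_classes = 2, include_background = FALSE)
  sigs <- make_default_signatures(cfg)
  wl <- wavelengths(cfg$axis)
  inside <- wl >= cfg$informative_window[1] & wl <= cfg$informative_window[2]
  d <- abs(eval_signature(sigs[[1]], wl) - eval_signature(sigs[[2]], wl))
  expect_lte(max(d[!inside]), 0.1 * max(d[inside]))
})

test_that("too-narrow informative windows are rejected", {
  expect_error(sim_config("test", informative_window = c(390, 360)),
               "increasing")
  expect_error(sim_config("test", informative_window = c(100, 200)),
               "inside the axis")
})

test_that("noise scale ramps up linearly at the spectral edges", {
  ax <- wavelength_axis(0, 1, 101)
  nm <- noise_model(base_sigma = 0.1, edge_factor = 3, edge_width_nm = 10)
  sc <- noise_scale(nm, ax)
  expect_equal(sc[1], 0.3)            # extreme channel: factor x base
  expect_equal(sc[101], 0.3)
  expect_equal(sc[6], 0.1 * (1 + 2 * 0.5))  # half way up the ramp
  expect_equal(sc[51], 0.1)           # interior: base
  expect_true(all(diff(sc[1:11]) < 0))
})

test_that("noiseless, texture-free cubes reproduce the signature exactly", {
  cfg <- tiny_sim(texture_amp = 0, noise = noise_model(0, 1, 0))
  sigs <- make_default_signatures(cfg)
  set.seed(1)
  cube <- simulate_cube(sigs[[1]], cfg)
  sg <- eval_signature(sigs[[1]], cfg$axis)
  for (i in c(1, 4)) for (j in c(2, 8))
    expect_equal(cube$values[i, j, ], sg)
  expect_equal(max(band_std_scores(cube)$scores), 0)
})

test_that("with texture and no noise, sigma is std(A) times the signature", {
  cfg <- tiny_sim(texture_amp = 0.3, noise = noise_model(0, 1, 0),
                  spatial = c(16, 16))
  sigs <- make_default_signatures(cfg)
  set.seed(2)
  cube <- simulate_cube(sigs[[2]], cfg)
  sg <- eval_signature(sigs[[2]], cfg$axis)
  A <- cube$values[, , 1] / sg[1]
  pop_sd <- sqrt(mean((A - mean(A))^2))
  expect_equal(band_std_scores(cube)$scores, pop_sd * sg,
               tolerance = 1e-9)
})

test_that("empirical edge noise matches the configured inflation", {
  cfg <- sim_config("test", n_classes = 2, cubes_per_class = 1,
                    spatial = c(40, 40), texture_amp = 0,
                    noise = noise_model(0.05, 4, 40), seed = 9,
                    informative_window = c(360, 390))
  sigs <- make_default_signatures(cfg)
  sg <- eval_signature(sigs[[1]], cfg$axis)
  set.seed(9)
  cube <- simulate_cube(sigs[[1]], cfg)
  resid <- sweep(matrix(cube$values, 1600, 200), 2, sg)
  sdhat <- apply(resid, 2, sd)
  sc <- noise_scale(cfg$noise, cfg$axis)
  # interior channels: base sigma; extreme channels: ~edge_factor x base
  interior <- 90:110
  expect_equal(mean(sdhat[interior]), 0.05, tolerance = 0.1)
  expect_equal(sdhat[200] / mean(sdhat[interior]), 4, tolerance = 0.15)
  expect_equal(sdhat[200], sc[200], tolerance = 0.1)
})

test_that("simulated datasets are deterministic, labeled and finite", {
  cfg <- tiny_sim(seed = 12)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_equal(n_cubes(ds1), 12)
  expect_equal(as.vector(table(ds1$labels)), rep(4, 3))
  expect_identical(ds1$cubes[[7]]$values, ds2$cubes[[7]]$values)
  expect_true(all(vapply(ds1$cubes, function(cb)
    all(is.finite(cb$values)) && all(cb$values >= 0), logical(1))))

  cfg2 <- tiny_sim(n_classes = 2, cubes_per_class = 1)
  expect_equal(n_cubes(simulate_dataset(cfg2)), 2)
})

test_that("paper-profile config matches the study design constants", {
  cfg <- sim_config("paper")
  expect_equal(cfg$n_classes, 11L)
  expect_equal(cfg$cubes_per_class, 100L)
  expect_equal(cfg$spatial, c(64L, 64L))
  expect_equal(cfg$axis$n_channels, 1004L)
  expect_equal(cfg$axis$step_nm, 0.728)
  expect_true(cfg$include_background)
  expect_equal(cfg$informative_window, c(470, 570))
})

test_that("planted window maps wavelengths to covering channels", {
  cfg <- sim_config("paper")
  pw <- planted_window(cfg)
  expect_identical(c(pw$s, pw$e), c(199L, 337L))

  full <- sim_config("test", informative_window = c(325, 325 + 199 * 0.728))
  pf <- planted_window(full)
  expect_identical(pf$s, 0L)
  expect_identical(pf$e, 199L)

  thin <- sim_config("test", informative_window = c(400, 400.728))
  pt <- planted_window(thin)
  expect_equal(window_width(pt), 2L)  # floor/ceiling cover the interval
})

test_that("higher peak amplitude never hurts downstream accuracy", {
  amps <- c(0.05, 0.3, 1.0)
  tc <- train_config(lr_init = 1e-3, max_epochs = 6, patience = 6,
                     seed = 1, val_fraction_of_train = 0.25)
  accs <- matrix(NA_real_, 3, length(amps))
  for (si in 1:3) for (ai in seq_along(amps)) {
    cfg <- tiny_sim(n_classes = 3, cubes_per_class = 6, spatial = c(8, 8),
                    seed = 40 + si, peak_amplitude = amps[ai])
    ds <- simulate_dataset(cfg)
    tc_run <- tc; tc_run$seed <- 40L + si
    sp <- split_dataset(ds, tc_run)
    win <- select_for_dataset(sp$train, selection_config("std", 20))
    norm <- fit_normalizer(sp$train, win)
    model <- build_model(cnn_spec(window_width(win), 3, c(8, 8), c(4, 8)),
                         seed = 40 + si)
    fit <- train_model(model, prepare_cnn_data(sp$train, win, norm),
                       prepare_cnn_data(sp$val, win, norm), tc_run)
    accs[si, ai] <- evaluate_model(
      fit, prepare_cnn_data(sp$test, win, norm))$accuracy
  }
  mean_acc <- colMeans(accs)
  expect_true(all(diff(mean_acc) >= -1e-9))
})
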