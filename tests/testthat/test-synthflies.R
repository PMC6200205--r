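test_that("populations are balanced, reproducible, and dimorphism is a knob", {
  pop <- make_population(20L, seed = 1L)
  sexes <- vapply(pop, function(f) f$sex, "")
  expect_equal(sum(sexes == "M"), 10L)
  expect_equal(sum(sexes == "F"), 10L)
  lat <- t(vapply(pop, function(f) f$latent, numeric(11)))
  expect_equal(nrow(unique(lat)), 20L)  # distinct individuals
  pop2 <- make_population(20L, seed = 1L)
  expect_identical(lapply(pop, `[[`, "latent"), lapply(pop2, `[[`, "latent"))
  # females larger than males on average (body length dimorphism)
  sm <- attr(pop, "sex_means")
  expect_gt(sm$F["body_len"], sm$M["body_len"])
  # knob at 0: the generating distributions coincide
  sm0 <- attr(make_population(2L, seed = 2L, dimorphism = 0), "sex_means")
  expect_identical(sm0$M, sm0$F)
  expect_error(make_population(1L), "at least 2")
  expect_error(make_population(5L), "even")
})

test_that("rendering is deterministic under a seed and distinct across identities", {
  pop <- make_population(4L, seed = 3L)
  a <- render_chip(pop[[1]], "dorsal", seed = 5L)
  expect_identical(a, render_chip(pop[[1]], "dorsal", seed = 5L))
  b <- render_chip(pop[[2]], "dorsal", seed = 5L)
  expect_gt(mean(abs(a - b)), 0)
  expect_equal(dim(a), c(181L, 181L))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(render_chip(pop[[1]], "sideways"), "viewpoint")
})

test_that("with day drift off, days differ only by frame noise", {
  pop <- make_population(2L, seed = 4L)
  args <- list(pop[[1]], "dorsal", day_drift_sd = 0, noise_sd = 0,
               pose_rot_sd = 0, pose_shift_sd = 0, seed = 7L)
  d1 <- do.call(render_chip, c(args, day = 1L))
  d3 <- do.call(render_chip, c(args, day = 3L))
  expect_identical(d1, d3)
  # with drift on, the same fly changes between days
  argsd <- list(pop[[1]], "dorsal", day_drift_sd = 0.05, noise_sd = 0,
                pose_rot_sd = 0, pose_shift_sd = 0, seed = 7L)
  e1 <- do.call(render_chip, c(argsd, day = 1L))
  e3 <- do.call(render_chip, c(argsd, day = 3L))
  expect_gt(mean(abs(e1 - e3)), 0)
})

test_that("rendered flies are centred with the body axis vertical", {
  pop <- make_population(6L, seed = 5L)
  for (i in c(1L, 4L)) {
    for (vp in c("dorsal", "ventral", "lateral")) {
      chip <- render_chip(pop[[i]], vp, noise_sd = 0,
                          pose_rot_sd = 0, pose_shift_sd = 0, seed = 1L)
      mask <- chip > 0.2
      ij <- which(mask, arr.ind = TRUE)
      ctr <- colMeans(ij)
      expect_lt(abs(ctr[1] - 91), 15)  # rows (anterior/posterior asymmetry)
      expect_lt(abs(ctr[2] - 91), 12)  # columns (lateral wing/legs one-sided)
      # principal axis of the body pixels is close to vertical
      cv <- stats::cov(ij)
      ev <- eigen(cv)$vectors[, 1]
      angle <- atan2(abs(ev[2]), abs(ev[1])) * 180 / pi
      expect_lt(angle, 10)
    }
  }
})

test_that("session specs encode the acquisition design", {
  spec <- session_spec()
  expect_identical(spec$frames_per_day, 14400L)
  expect_identical(spec$n_flies, 20L)
  expect_identical(spec$n_days, 3L)
  expect_identical(session_spec(minutes = 1)$frames_per_day, 960L)
  # total frames of a default session
  expect_equal(spec$n_flies * spec$n_days * spec$frames_per_day, 864000)
  # frames_per_day override keeps the frames == minutes*60*fps invariant
  s2 <- session_spec(frames_per_day = 200L)
  expect_equal(s2$minutes * 60 * s2$fps, 200)
  expect_error(session_spec(viewpoint_mix = c(dorsal = 0.5, ventral = 0.5,
                                              lateral = 0.5)),
               "sum to 1")
})

test_that("make_dataset produces labelled stacks, reproducibly, with streamed HDF5 output", {
  spec <- session_spec(n_flies = 4L, n_days = 2L, frames_per_day = 6L,
                       chip_size = 61L)
  ds <- make_dataset(spec, seed = 9L)
  expect_s3_class(ds, "chip_stack")
  expect_equal(n_chips(ds), 4L * 2L * 6L)
  expect_equal(dim(ds$images)[1:2], c(61L, 61L))
  expect_equal(sort(unique(ds$meta$identity)), 1:4)
  expect_equal(unname(table(ds$meta$identity)), rep(12L, 4L),
               ignore_attr = TRUE)
  expect_true(all(ds$meta$viewpoint %in% c("dorsal", "ventral", "lateral")))
  expect_length(attr(ds, "fly_sizes"), 4L)
  ds2 <- make_dataset(spec, seed = 9L)
  expect_identical(ds$images, ds2$images)
  # streamed HDF5 output round-trips the in-memory result
  h5 <- withr::local_tempfile(fileext = ".h5")
  make_dataset(spec, seed = 9L, out = h5)
  expect_error(make_dataset(spec, seed = 9L, out = h5), "exists")
  back <- read_chips(h5)
  expect_equal(back$images, ds$images, tolerance = 1e-15)
  expect_equal(back$meta, ds$meta)
  expect_equal(attr(back, "fly_sizes"), attr(ds, "fly_sizes"),
               tolerance = 1e-15)
})

test_that("a transform applied at generation changes only the stored chips", {
  spec <- session_spec(n_flies = 2L, n_days = 1L, frames_per_day = 4L,
                       chip_size = 61L)
  raw <- make_dataset(spec, seed = 11L)
  small <- make_dataset(spec, seed = 11L,
                        transform = function(ch) bottleneck_29(ch))
  expect_equal(dim(small$images)[1:2], c(29L, 29L))
  expect_equal(small$meta, raw$meta)
  expect_equal(small$images[, , 3], bottleneck_29(raw$images[, , 3]),
               tolerance = 1e-12)
})

test_that("identity is recoverable across days by a plain nearest-centroid classifier", {
  ds <- headline_stacks()$plain
  f1 <- centroid_f1(ds)
  expect_gt(f1, 0.3)  # 3x the 0.1 chance line for 10 balanced classes
})

test_that("stronger day-to-day drift degrades across-day recoverability monotonically", {
  drifts <- c(0.01, 0.12, 0.3)
  f1s <- sapply(seq_len(5), function(s)
    sapply(drifts, function(dr) centroid_f1(drift_dataset(dr, seed = 100 + s))))
  avg <- rowMeans(f1s)
  expect_true(all(diff(avg) < 0))
})
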