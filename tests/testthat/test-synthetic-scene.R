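test_that("identical seeds give bit-identical scenes and ground truth", {
  a <- generate_scene(small_scene(seed = 7))
  b <- generate_scene(small_scene(seed = 7))
  expect_identical(a$series$channels, b$series$channels)
  expect_identical(a$truth$puncta, b$truth$puncta)
  expect_identical(a$truth$jitter, b$truth$jitter)
  expect_identical(a$truth$speckles, b$truth$speckles)
})

test_that("zero densities and zero noise give an empty black scene", {
  cfg <- scene_config(footprint_um = c(4, 4), n_sections = 5,
                      density_presynapse_um3 = 0, density_postsynapse_um3 = 0,
                      speckle_count = 0, background_noise_sd = 0,
                      background_level = 0, jitter_px = 0, seed = 3)
  sc <- generate_scene(cfg)
  expect_equal(nrow(sc$truth$puncta), 0)
  expect_equal(nrow(sc$truth$speckles), 0)
  for (ch in sc$series$channels) {
    expect_true(all(vapply(ch, function(m) all(m == 0), logical(1))))
  }
})

test_that("planted counts follow density times physical volume", {
  cfg <- scene_config(footprint_um = c(10, 10), n_sections = 30,
                      density_presynapse_um3 = 0.3,
                      density_postsynapse_um3 = 1.0,
                      min_separation_um = 0.35, seed = 11)
  expect_equal(scene_volume_um3(cfg), 10 * 10 * 30 * 0.07)
  sc <- generate_scene(cfg)
  expect_equal(sum(sc$truth$puncta$channel == "postsynapse"),
               round(1.0 * 10 * 10 * 30 * 0.07))  # 210
  expect_equal(sum(sc$truth$puncta$channel == "presynapse"),
               round(0.3 * 210))
})

test_that("planted tau flags match the configured fraction within binomial CI", {
  n_tot <- 0; n_tau <- 0
  for (seed in 1:5) {
    cfg <- scene_config(density_postsynapse_um3 = 0.5,
                        frac_post_tau_positive = 0.10, seed = seed)
    sc <- generate_scene(cfg)
    post <- sc$truth$puncta[sc$truth$puncta$channel == "postsynapse", ]
    n_tot <- n_tot + nrow(post)
    n_tau <- n_tau + sum(post$tau_positive)
  }
  expect_gte(n_tot, 500)
  ci <- qbinom(c(0.025, 0.975), n_tot, 0.10) / n_tot
  expect_gte(n_tau / n_tot, ci[1])
  expect_lte(n_tau / n_tot, ci[2])
})

test_that("rendered foreground voxels lie inside the stated ellipsoid and span", {
  cfg <- small_scene(jitter_px = 0, speckle_count = 0,
                     background_noise_sd = 0, background_level = 0, seed = 5)
  sc <- generate_scene(cfg)
  stacks <- series_to_stacks(sc$series)
  arr <- stacks$postsynapse$data
  d <- dim(arr)
  post <- sc$truth$puncta[sc$truth$puncta$channel == "postsynapse", ]
  fg <- which(arr > 0)
  idx0 <- fg - 1L
  r <- idx0 %% d[1]; c <- (idx0 %/% d[1]) %% d[2]; s <- idx0 %/% (d[1] * d[2])
  xc <- (c + 0.5) * cfg$pixel_size_um
  yc <- (r + 0.5) * cfg$pixel_size_um
  zc <- (s + 0.5) * cfg$section_thickness_um
  inside_any <- rep(FALSE, length(fg))
  for (i in seq_len(nrow(post))) {
    e <- ((xc - post$x_um[i]) / post$radius_um[i])^2 +
      ((yc - post$y_um[i]) / post$radius_um[i])^2 +
      ((zc - post$z_um[i]) / post$z_radius_um[i])^2
    in_span <- (s + 1) >= post$first_section[i] &
      (s + 1) <= post$first_section[i] + post$span_sections[i] - 1
    inside_any <- inside_any | (e <= 1 + 1e-9 & in_span)
  }
  expect_true(all(inside_any))
  # every planted object section-span is honoured in the rendering
  for (i in seq_len(nrow(post))) {
    secs <- unique(s[inside_any & zc >= (post$first_section[i] - 1) *
                       cfg$section_thickness_um] + 1)
    expect_true(all(secs >= 1 & secs <= cfg$n_sections))
  }
})

test_that("speckles span exactly one section and true puncta span at least two", {
  sc <- generate_scene(small_scene(seed = 9))
  expect_true(all(sc$truth$puncta$span_sections >= 2))
  # render a sparse speckle-only scene (speckles far enough apart that no
  # two merge across sections) and confirm every object has span 1
  cfg <- scene_config(footprint_um = c(8, 8), n_sections = 6,
                      density_presynapse_um3 = 0, density_postsynapse_um3 = 0,
                      speckle_count = 1, background_noise_sd = 0,
                      background_level = 0, jitter_px = 0, seed = 2)
  spk <- generate_scene(cfg)
  stacks <- series_to_stacks(spk$series)
  for (role in names(stacks)) {
    arr <- stacks[[role]]$data > 0
    if (!any(arr)) next
    labs <- oracle_flood_fill(arr)
    for (l in seq_len(max(labs))) {
      secs <- unique(which(labs == l, arr.ind = TRUE)[, 3])
      expect_length(secs, 1)
    }
  }
})

test_that("noise-free foreground volume matches per-object analytic voxel counts", {
  cfg <- small_scene(jitter_px = 0, speckle_count = 0,
                     background_noise_sd = 0, background_level = 0, seed = 13)
  sc <- generate_scene(cfg)
  stacks <- series_to_stacks(sc$series)
  px <- cfg$pixel_size_um; dz <- cfg$section_thickness_um
  count_object <- function(o, d) {
    # analytic recount: voxel centres inside the truncated ellipsoid
    n <- 0L
    for (s in o$first_section:(o$first_section + o$span_sections - 1)) {
      zc <- (s - 0.5) * dz
      rem <- 1 - ((zc - o$z_um) / o$z_radius_um)^2
      if (rem <= 0) next
      cols <- seq_len(d[2]); rows <- seq_len(d[1])
      xs <- (cols - 0.5) * px; ys <- (rows - 0.5) * px
      m <- outer((ys - o$y_um)^2, (xs - o$x_um)^2, "+") <= rem * o$radius_um^2
      n <- n + sum(m)
    }
    n
  }
  pre <- sc$truth$puncta[sc$truth$puncta$channel == "presynapse", ]
  d <- dim(stacks$presynapse$data)
  analytic <- sum(vapply(seq_len(nrow(pre)), function(i)
    count_object(as.list(pre[i, ]), d), numeric(1)))
  rendered <- sum(stacks$presynapse$data > 0)
  # equality up to overlap between the rare touching objects
  expect_lte(abs(rendered - analytic), nrow(pre))
})

test_that("ground truth CSV round-trips losslessly", {
  sc <- generate_scene(small_scene(seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sc$truth, path)
  back <- read_ground_truth(path)
  n_obj <- nrow(sc$truth$puncta) + nrow(sc$truth$speckles)
  expect_equal(nrow(back), n_obj)
  orig <- sc$truth$puncta
  got <- back[!back$is_speckle, names(orig)]
  expect_equal(as.data.frame(got), as.data.frame(orig), tolerance = 1e-12)

  # empty truth -> header-only CSV
  cfg <- scene_config(footprint_um = c(3, 3), n_sections = 4,
                      density_presynapse_um3 = 0, density_postsynapse_um3 = 0,
                      speckle_count = 0, seed = 1)
  empty <- generate_scene(cfg)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(empty$truth, p2)
  expect_equal(nrow(read_ground_truth(p2)), 0)
  expect_equal(length(readLines(p2)), 1)
})

test_that("overcrowded scenes fail with the channel named", {
  cfg <- scene_config(footprint_um = c(2, 2), n_sections = 4,
                      density_presynapse_um3 = 200,
                      min_separation_um = 1.5, seed = 1)
  expect_error(generate_scene(cfg), "presynapse")
})

test_that("scene_config rejects invalid parameters", {
  expect_error(scene_config(frac_post_tau_positive = 1.2))
  expect_error(scene_config(punctum_span_sections = c(1, 4)))
  expect_error(scene_config(pixel_size_um = 0))
})
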