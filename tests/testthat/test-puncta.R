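test_that("in-plane diagonal voxels join one 26-connected component", {
  arr <- array(FALSE, dim = c(5, 5, 3))
  arr[2, 2, 2] <- TRUE
  arr[3, 3, 2] <- TRUE
  pc <- label_components(raw_mask(arr))
  expect_equal(nrow(pc), 1)
  # and a corner-diagonal across sections also joins
  arr2 <- array(FALSE, dim = c(5, 5, 3))
  arr2[2, 2, 1] <- TRUE
  arr2[3, 3, 2] <- TRUE
  expect_equal(nrow(label_components(raw_mask(arr2))), 1)
})

test_that("the same disc repeated on consecutive sections is one object", {
  arr <- array(FALSE, dim = c(10, 10, 8))
  disc <- outer((1:10 - 5)^2, (1:10 - 5)^2, "+") <= 4
  for (s in 4:6) arr[, , s] <- disc
  pc <- label_components(raw_mask(arr))
  expect_equal(nrow(pc), 1)
  expect_equal(pc$section_span, 3L)
  expect_equal(pc$n_voxels, 3L * sum(disc))
  expect_equal(pc$volume_um3, 3 * sum(disc) * 0.1 * 0.1 * 0.07)
})

test_that("component labelling matches brute-force flood fill on sparse masks", {
  set.seed(101)
  for (i in 1:20) {
    arr <- random_sparse_mask(c(12, 12, 6), p = 0.05)
    pc <- label_components(raw_mask(arr))
    orc <- oracle_flood_fill(arr)
    expect_equal(nrow(pc), max(orc))
    # identical partitions: every detected voxel set is one oracle label
    for (k in seq_len(nrow(pc))) {
      expect_length(unique(orc[pc$voxels[[k]]]), 1)
    }
    expect_equal(sum(pc$n_voxels), sum(arr))
  }
})

test_that("single-section filter keeps exactly the multi-section objects", {
  arr <- array(FALSE, dim = c(8, 8, 5))
  arr[2, 2, 2] <- TRUE                 # span 1: removed
  arr[5, 5, 2] <- TRUE; arr[5, 5, 3] <- TRUE  # span 2: kept
  pc <- label_components(raw_mask(arr))
  kept <- filter_single_section(pc)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$section_span, 2L)
  # idempotence
  expect_identical(tibble::as_tibble(filter_single_section(kept)),
                   tibble::as_tibble(kept))
})

test_that("filter removal set equals independent span recomputation", {
  set.seed(202)
  arr <- random_sparse_mask(c(15, 15, 8), p = 0.04)
  pc <- label_components(raw_mask(arr))
  kept <- filter_single_section(pc)
  spans <- vapply(pc$voxels, oracle_span, numeric(1), dims = c(15, 15, 8))
  expect_equal(sort(kept$id), sort(pc$id[spans >= 2]))
})

test_that("density is count over crop volume with exact conservation", {
  arr <- array(FALSE, dim = c(100, 100, 30))
  pc <- label_components(raw_mask(arr))
  expect_equal(puncta_density(pc), 0)
  expect_equal(attr(pc, "crop_volume_um3"), 210)   # 10 x 10 x 2.1 um
  # 47 objects in 210 um^3
  set.seed(7)
  rs <- sample(2:97, 47); cs <- sample(2:97, 47)
  for (i in 1:47) arr[rs[i], cs[i], (2 * (i %% 14)) + 2] <- TRUE
  pc <- label_components(raw_mask(arr))
  expect_equal(nrow(pc), 47)
  expect_equal(puncta_density(pc), 47 / 210, tolerance = 1e-12)
  expect_equal(puncta_density(pc) * attr(pc, "crop_volume_um3"), 47)
})

test_that("GFP positivity follows the overlap rule and its edge cases", {
  arr <- array(FALSE, dim = c(10, 10, 4))
  arr[2:3, 2:3, 2] <- TRUE; arr[2:3, 2:3, 3] <- TRUE
  pre <- label_components(raw_mask(arr, channel = "presynapse"))
  all_true <- raw_mask(array(TRUE, dim = c(10, 10, 4)), channel = "gfp")
  none <- raw_mask(array(FALSE, dim = c(10, 10, 4)), channel = "gfp")
  expect_equal(percent_gfp_positive(pre, all_true), 100)
  expect_equal(percent_gfp_positive(pre, none), 0)
  empty <- label_components(raw_mask(array(FALSE, dim = c(10, 10, 4)),
                                     channel = "presynapse"))
  expect_true(is.na(percent_gfp_positive(empty, all_true)))  # missing, not 0
})

test_that("planted GFP fractions are recovered through the full chain", {
  n_pos <- 0; n_tot <- 0
  for (seed in 1:3) {
    cfg <- scene_config(footprint_um = c(8, 8), n_sections = 20,
                        density_presynapse_um3 = 0.6,
                        density_postsynapse_um3 = 0,
                        frac_pre_gfp_positive = 0.3, seed = 300 + seed)
    sc <- generate_scene(cfg)
    al <- align_series(sc$series)
    pre <- filter_single_section(
      label_components(binarize_stack(al$stacks$presynapse, "combined")))
    rec <- classify_overlap(pre, binarize_stack(al$stacks$gfp, "combined"))
    n_pos <- n_pos + sum(rec$positive); n_tot <- n_tot + nrow(rec)
  }
  ci <- qbinom(c(0.025, 0.975), n_tot, 0.3) / n_tot
  expect_gte(n_pos / n_tot, ci[1])
  expect_lte(n_pos / n_tot, ci[2])
})

test_that("border exclusion drops exactly the face-touching objects", {
  arr <- array(FALSE, dim = c(8, 8, 5))
  arr[1, 4, 2] <- TRUE; arr[1, 4, 3] <- TRUE      # touches y face
  arr[4, 4, 2] <- TRUE; arr[4, 4, 3] <- TRUE      # interior
  pc <- label_components(raw_mask(arr))
  inner <- exclude_border_puncta(pc)
  expect_equal(nrow(pc), 2)
  expect_equal(nrow(inner), 1)
  expect_equal(inner$centroid_y_um, (4 - 0.5) * 0.1)
})

test_that("puncta tables export without the voxel payload", {
  sc <- generate_scene(small_scene(seed = 17))
  pc <- filter_single_section(label_components(
    binarize_stack(series_to_stacks(sc$series)$presynapse)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_puncta(pc, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(pc))
  expect_false("voxels" %in% names(back))
  expect_true(all(c("centroid_x_um", "volume_um3", "section_span") %in%
                    names(back)))
})

test_that("filtered counts match planted counts on clean scenes within 5 percent", {
  cfg <- scene_config(jitter_px = 0, speckle_count = 0,
                      background_noise_sd = 0, background_level = 0,
                      seed = 909)
  sc <- generate_scene(cfg)
  stacks <- series_to_stacks(sc$series)
  for (role in c("presynapse", "postsynapse")) {
    pc <- filter_single_section(label_components(binarize_stack(stacks[[role]])))
    planted <- sum(sc$truth$puncta$channel == role)
    expect_lte(abs(nrow(pc) - planted) / planted, 0.05)
  }
})

test_that("end-to-end detection F1 reaches 0.95 on the default noisy scene", {
  sc <- generate_scene(scene_config(seed = 910))
  res <- analyze_scene(sc$series)
  truth <- sc$truth$puncta[sc$truth$puncta$channel == "postsynapse", ]
  det <- res$puncta$postsynapse
  used <- logical(nrow(det))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((det$centroid_x_um - truth$x_um[i])^2 +
                (det$centroid_y_um - truth$y_um[i])^2 +
                (det$centroid_z_um - truth$z_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= 0.25) { tp <- tp + 1; used[j] <- TRUE }
  }
  precision <- tp / nrow(det)
  recall <- tp / nrow(truth)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.95)
})
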