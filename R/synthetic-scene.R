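#' Configuration for a synthetic array-tomography scene
#'
#' Defines one ground-truthed imaging volume emulating punctate synaptic
#' immunoreactivity: ellipsoidal puncta spanning a few consecutive 70 nm
#' sections, inter-section misalignment, Gaussian background, and
#' single-section speckle artifacts. Four channels are rendered:
#' `presynapse` (all presynaptic terminals), `gfp` (the GFP-labelled subset
#' of presynapses), `postsynapse` (postsynaptic densities), and `tau`
#' (human tau, rendered inside tau-positive objects of either side).
#'
#' @param footprint_um `(x, y)` field extent in micrometres; the default
#'   10 x 10 um field matches a typical cropped region of interest.
#' @param n_sections Number of serial sections.
#' @param section_thickness_um Section thickness (default 0.07, i.e. 70 nm).
#' @param pixel_size_um In-plane pixel size.
#' @param density_presynapse_um3,density_postsynapse_um3 Planted puncta per
#'   cubic micrometre for the two synaptic channels.
#' @param punctum_radius_um `(mean, sd)` of the in-plane punctum radius.
#' @param punctum_span_sections Integer range `(min, max)` of consecutive
#'   sections a planted synaptic punctum occupies; the minimum must be >= 2
#'   so the single-section noise filter never removes a true synapse.
#' @param min_separation_um Minimum 3D centroid separation between puncta of
#'   the same channel, so touching-object merges stay rare.
#' @param frac_pre_gfp_positive Fraction of presynapses carrying GFP.
#' @param frac_pre_paired Fraction of GFP-positive presynapses given a
#'   planted postsynaptic partner.
#' @param frac_post_tau_positive Fraction of postsynapses containing tau.
#' @param frac_pre_tau_positive Fraction of GFP-positive presynapses
#'   containing tau (tau travels in the labelled axons).
#' @param pair_offset_um Mean pre-to-post centroid offset of planted pairs;
#'   the default 0.25 um keeps pairs inside the 0.5 um detection radius.
#' @param pair_offset_sd_um SD of the planted offset length.
#' @param amplitude_dim,amplitude_bright `(lo, hi)` intensity ranges for the
#'   dim and bright punctum classes; half the puncta are drawn from each, so
#'   segmentation must recover both high- and low-intensity synapses.
#' @param frac_bright Fraction of puncta drawn from the bright class.
#' @param jitter_px Maximum per-section translation magnitude (pixels);
#'   applied identically to all channels of a section. Section 1 is never
#'   jittered, so planted translations equal the cumulative transforms an
#'   aligner should recover.
#' @param speckle_count Single-section noise objects per section per channel.
#' @param background_level,background_noise_sd Mean and SD of the additive
#'   Gaussian background (intensity units).
#' @param seed Integer seed; one seed expands into independent substreams
#'   per generation stage, so identical seeds give bit-identical scenes.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(footprint_um = c(10, 10),
                         n_sections = 30,
                         section_thickness_um = 0.07,
                         pixel_size_um = 0.1,
                         density_presynapse_um3 = 0.6,
                         density_postsynapse_um3 = 0.5,
                         punctum_radius_um = c(0.2, 0.04),
                         punctum_span_sections = c(2, 5),
                         min_separation_um = 0.5,
                         frac_pre_gfp_positive = 0.3,
                         frac_pre_paired = 0.6,
                         frac_post_tau_positive = 0.10,
                         frac_pre_tau_positive = 0.8,
                         pair_offset_um = 0.25,
                         pair_offset_sd_um = 0.05,
                         amplitude_dim = c(25, 40),
                         amplitude_bright = c(150, 220),
                         frac_bright = 0.5,
                         jitter_px = 3,
                         speckle_count = 5,
                         background_level = 10,
                         background_noise_sd = 5,
                         seed = 1L) {
  cfg <- as.list(environment())
  # short stacks cap the span range at the section count
  punctum_span_sections[2] <- min(punctum_span_sections[2], n_sections)
  punctum_span_sections[1] <- min(punctum_span_sections[1],
                                  punctum_span_sections[2])
  cfg$punctum_span_sections <- punctum_span_sections
  fracs <- c(cfg$frac_pre_gfp_positive, cfg$frac_pre_paired,
             cfg$frac_post_tau_positive, cfg$frac_pre_tau_positive,
             cfg$frac_bright)
  stopifnot(
    length(footprint_um) == 2, all(footprint_um > 0),
    n_sections >= 1, section_thickness_um > 0, pixel_size_um > 0,
    density_presynapse_um3 >= 0, density_postsynapse_um3 >= 0,
    length(punctum_radius_um) == 2, punctum_radius_um[1] > 0,
    punctum_radius_um[2] >= 0,
    length(punctum_span_sections) == 2,
    punctum_span_sections[1] >= 2,
    punctum_span_sections[2] >= punctum_span_sections[1],
    punctum_span_sections[2] <= n_sections,
    min_separation_um >= 0,
    all(fracs >= 0), all(fracs <= 1),
    pair_offset_um >= 0, pair_offset_sd_um >= 0,
    jitter_px >= 0, speckle_count >= 0,
    background_level >= 0, background_noise_sd >= 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scene_config")
}

#' Physical volume of the configured scene in cubic micrometres
#' @param config A `scene_config`.
#' @return Scalar volume in um^3.
#' @export
scene_volume_um3 <- function(config) {
  config$footprint_um[1] * config$footprint_um[2] *
    config$n_sections * config$section_thickness_um
}

# Seed a deterministic substream; stage keys keep channels independent so
# adding one does not perturb another.
.with_substream <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 97 + stage * 7919) %% 2147483647)
  force(code)
}

# Rejection-sample n centres in the box with pairwise min separation.
.place_centres <- function(n, footprint_um, z_extent_um, min_sep, channel,
                           fixed = NULL) {
  pts <- if (is.null(fixed)) matrix(numeric(0), 0, 3) else fixed
  out <- matrix(NA_real_, n, 3)
  cap <- 300L * max(n, 1L)
  tries <- 0L
  placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > cap) {
      stop(sprintf(
        "could not place %d puncta in channel '%s' without crowding (retry cap hit)",
        n, channel), call. = FALSE)
    }
    cand <- c(stats::runif(1, 0, footprint_um[1]),
              stats::runif(1, 0, footprint_um[2]),
              stats::runif(1, 0, z_extent_um))
    if (nrow(pts) > 0) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
        (pts[, 3] - cand[3])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    out[placed, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

# Assign a section span entirely inside [1, nz] around a z position (um).
.assign_span <- function(z_um, span_range, nz, dz) {
  span <- sample(seq(span_range[1], span_range[2]), length(z_um),
                 replace = TRUE)
  centre_sec <- pmin(pmax(round(z_um / dz + 0.5), 1L), nz)
  first <- centre_sec - span %/% 2L
  first <- pmin(pmax(first, 1L), nz - span + 1L)
  list(span = span, first = first,
       z_centre = (first - 1) * dz + span * dz / 2)
}

.draw_amplitude <- function(n, cfg) {
  bright <- stats::runif(n) < cfg$frac_bright
  lo <- ifelse(bright, cfg$amplitude_bright[1], cfg$amplitude_dim[1])
  hi <- ifelse(bright, cfg$amplitude_bright[2], cfg$amplitude_dim[2])
  round(stats::runif(n, lo, hi))
}

# Render one ellipsoidal punctum into a (ny, nx, nz) array, in place.
# The z semi-axis is span*dz/2 about the span midpoint, so the object
# intersects exactly `span` sections.
.render_ellipsoid <- function(arr, x, y, z, r_um, z_r_um, first, span,
                              amplitude, px, dz) {
  d <- dim(arr)
  c_lo <- max(1L, floor((x - r_um) / px)); c_hi <- min(d[2], ceiling((x + r_um) / px) + 1L)
  r_lo <- max(1L, floor((y - r_um) / px)); r_hi <- min(d[1], ceiling((y + r_um) / px) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(arr)
  secs <- seq(first, min(first + span - 1L, d[3]))
  cols <- c_lo:c_hi; rows <- r_lo:r_hi
  xc <- (cols - 0.5) * px; yc <- (rows - 0.5) * px
  for (s in secs) {
    zc <- (s - 0.5) * dz
    rem <- 1 - ((zc - z) / z_r_um)^2
    if (rem <= 0) next
    # in-plane ellipse mask at this section
    m <- outer((yc - y)^2, (xc - x)^2, "+") <= rem * r_um^2
    if (any(m)) {
      block <- arr[rows, cols, s]
      block[m] <- pmax(block[m], amplitude)
      arr[rows, cols, s] <- block
    }
  }
  arr
}

#' Generate a ground-truthed synthetic scene
#'
#' Plants presynaptic and postsynaptic puncta (with GFP, tau and pairing
#' structure), renders them as constant-amplitude intensity ellipsoids
#' truncated to their section span, adds single-section speckles and
#' Gaussian background, and applies per-section jitter translations
#' identically to all channels. The same seed yields bit-identical output.
#'
#' @param config A [scene_config()].
#' @return A list with elements `truth` (ground-truth tables, see
#'   [write_ground_truth()]) and `series` (a raw, jittered
#'   [section_series()] with channels `presynapse`, `gfp`, `postsynapse`,
#'   `tau`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  px <- cfg$pixel_size_um; dz <- cfg$section_thickness_um
  nx <- round(cfg$footprint_um[1] / px); ny <- round(cfg$footprint_um[2] / px)
  nz <- cfg$n_sections
  vol <- scene_volume_um3(cfg)
  z_extent <- nz * dz

  n_pre <- round(cfg$density_presynapse_um3 * vol)
  n_post <- round(cfg$density_postsynapse_um3 * vol)

  # --- presynapses -------------------------------------------------------
  pre <- .with_substream(cfg$seed, 1, {
    centres <- .place_centres(n_pre, cfg$footprint_um, z_extent,
                              cfg$min_separation_um, "presynapse")
    sp <- .assign_span(centres[, 3], cfg$punctum_span_sections, nz, dz)
    tibble::tibble(
      id = if (n_pre > 0) paste0("pre_", seq_len(n_pre)) else character(0),
      channel = rep("presynapse", n_pre),
      x_um = centres[, 1], y_um = centres[, 2], z_um = sp$z_centre,
      radius_um = pmax(stats::rnorm(n_pre, cfg$punctum_radius_um[1],
                                    cfg$punctum_radius_um[2]), 1.2 * px),
      z_radius_um = sp$span * dz / 2,
      first_section = sp$first, span_sections = sp$span,
      amplitude = .draw_amplitude(n_pre, cfg),
      gfp_positive = stats::runif(n_pre) < cfg$frac_pre_gfp_positive,
      tau_positive = rep(FALSE, n_pre),
      pair_id = rep(NA_character_, n_pre))
  })
  pre$tau_positive <- .with_substream(cfg$seed, 2, {
    pre$gfp_positive & stats::runif(nrow(pre)) < cfg$frac_pre_tau_positive
  })

  # --- postsynapses: paired partners first, then independent placements --
  gfp_ids <- which(pre$gfp_positive)
  post <- .with_substream(cfg$seed, 3, {
    paired_pre <- gfp_ids[stats::runif(length(gfp_ids)) < cfg$frac_pre_paired]
    n_paired <- min(length(paired_pre), n_post)
    paired_pre <- paired_pre[seq_len(n_paired)]
    cx <- numeric(0); cy <- numeric(0); cz <- numeric(0)
    partner <- character(0)
    for (i in paired_pre) {
      for (attempt in seq_len(200)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        len <- max(stats::rnorm(1, cfg$pair_offset_um, cfg$pair_offset_sd_um),
                   0.05)
        cand <- c(pre$x_um[i], pre$y_um[i], pre$z_um[i]) + u * len
        inside <- cand[1] >= 0 && cand[1] <= cfg$footprint_um[1] &&
          cand[2] >= 0 && cand[2] <= cfg$footprint_um[2] &&
          cand[3] >= dz && cand[3] <= z_extent - dz
        if (!inside) next
        if (length(cx) > 0) {
          d2 <- (cx - cand[1])^2 + (cy - cand[2])^2 + (cz - cand[3])^2
          if (min(d2) < cfg$min_separation_um^2) next
        }
        cx <- c(cx, cand[1]); cy <- c(cy, cand[2]); cz <- c(cz, cand[3])
        partner <- c(partner, pre$id[i])
        break
      }
    }
    n_free <- max(n_post - length(cx), 0L)
    free <- .place_centres(n_free, cfg$footprint_um, z_extent,
                           cfg$min_separation_um, "postsynapse",
                           fixed = cbind(cx, cy, cz))
    centres <- rbind(cbind(cx, cy, cz), free)
    n_all <- nrow(centres)
    sp <- .assign_span(centres[, 3], cfg$punctum_span_sections, nz, dz)
    tibble::tibble(
      id = if (n_all > 0) paste0("post_", seq_len(n_all)) else character(0),
      channel = rep("postsynapse", n_all),
      x_um = centres[, 1], y_um = centres[, 2], z_um = sp$z_centre,
      radius_um = pmax(stats::rnorm(n_all, cfg$punctum_radius_um[1],
                                    cfg$punctum_radius_um[2]), 1.2 * px),
      z_radius_um = sp$span * dz / 2,
      first_section = sp$first, span_sections = sp$span,
      amplitude = .draw_amplitude(n_all, cfg),
      gfp_positive = rep(FALSE, n_all),
      tau_positive = stats::runif(n_all) < cfg$frac_post_tau_positive,
      pair_id = c(partner, rep(NA_character_, n_free)))
  })
  pre$pair_id[match(post$pair_id[!is.na(post$pair_id)], pre$id)] <-
    post$id[!is.na(post$pair_id)]

  puncta <- dplyr::bind_rows(pre, post)

  # --- jitter and speckles ----------------------------------------------
  jitter <- .with_substream(cfg$seed, 4, {
    j <- cfg$jitter_px
    tibble::tibble(
      section = seq_len(nz),
      dx_px = c(0L, if (nz > 1) sample(seq(-j, j), nz - 1, replace = TRUE) else integer(0)),
      dy_px = c(0L, if (nz > 1) sample(seq(-j, j), nz - 1, replace = TRUE) else integer(0)))
  })
  roles <- c("presynapse", "gfp", "postsynapse", "tau")
  speckles <- .with_substream(cfg$seed, 5, {
    n_spk <- cfg$speckle_count * nz * length(roles)
    if (n_spk == 0) {
      tibble::tibble(channel = character(0), section = integer(0),
                     x_um = numeric(0), y_um = numeric(0),
                     radius_um = numeric(0), amplitude = numeric(0))
    } else {
      tibble::tibble(
        channel = rep(roles, each = cfg$speckle_count * nz),
        section = rep(rep(seq_len(nz), each = cfg$speckle_count),
                      times = length(roles)),
        x_um = stats::runif(n_spk, 0, cfg$footprint_um[1]),
        y_um = stats::runif(n_spk, 0, cfg$footprint_um[2]),
        radius_um = stats::runif(n_spk, 0.08, 0.15),
        amplitude = .draw_amplitude(n_spk, cfg))
    }
  })

  # --- render ------------------------------------------------------------
  render_channel <- function(objs, spk) {
    arr <- array(0, dim = c(ny, nx, nz))
    if (nrow(objs) > 0) {
      for (i in seq_len(nrow(objs))) {
        arr <- .render_ellipsoid(arr, objs$x_um[i], objs$y_um[i], objs$z_um[i],
                                 objs$radius_um[i], objs$z_radius_um[i],
                                 objs$first_section[i], objs$span_sections[i],
                                 objs$amplitude[i], px, dz)
      }
    }
    if (nrow(spk) > 0) {
      for (i in seq_len(nrow(spk))) {
        arr <- .render_ellipsoid(arr, spk$x_um[i], spk$y_um[i],
                                 (spk$section[i] - 0.5) * dz,
                                 spk$radius_um[i], dz / 2 * 0.99,
                                 spk$section[i], 1L, spk$amplitude[i], px, dz)
      }
    }
    arr
  }
  vols <- list(
    presynapse  = render_channel(pre, speckles[speckles$channel == "presynapse", ]),
    gfp         = render_channel(pre[pre$gfp_positive, ],
                                 speckles[speckles$channel == "gfp", ]),
    postsynapse = render_channel(post, speckles[speckles$channel == "postsynapse", ]),
    tau         = render_channel(dplyr::filter(puncta, .data$tau_positive),
                                 speckles[speckles$channel == "tau", ]))

  channels <- lapply(seq_along(vols), function(k) {
    arr <- vols[[k]]
    out <- vector("list", nz)
    for (s in seq_len(nz)) {
      img <- arr[, , s]
      if (cfg$background_noise_sd > 0 || cfg$background_level > 0) {
        img <- .with_substream(cfg$seed, 10 + k * 1009 + s, {
          img + stats::rnorm(length(img), cfg$background_level,
                             cfg$background_noise_sd)
        })
      }
      out[[s]] <- matrix(pmin(pmax(round(img), 0), 65535), ny, nx)
    }
    out
  })
  names(channels) <- names(vols)
  # jitter: translate every channel of a section by the same vector
  if (any(jitter$dx_px != 0L | jitter$dy_px != 0L)) {
    for (role in names(channels)) {
      for (s in seq_len(nz)) {
        channels[[role]][[s]] <- translate_image(
          channels[[role]][[s]], jitter$dx_px[s], jitter$dy_px[s])
      }
    }
  }

  truth <- list(puncta = puncta, jitter = jitter, speckles = speckles,
                config = cfg)
  class(truth) <- "scene_truth"
  list(truth = truth,
       series = section_series(channels, px, dz))
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d presynapses (%d GFP+), %d postsynapses (%d tau+), %d pairs, %d speckles\n",
    sum(x$puncta$channel == "presynapse"),
    sum(x$puncta$gfp_positive),
    sum(x$puncta$channel == "postsynapse"),
    sum(x$puncta$tau_positive & x$puncta$channel == "postsynapse"),
    sum(!is.na(x$puncta$pair_id)) / 2,
    nrow(x$speckles)))
  invisible(x)
}

.truth_cols <- readr::cols(
  id = readr::col_character(), channel = readr::col_character(),
  x_um = readr::col_double(), y_um = readr::col_double(),
  z_um = readr::col_double(), radius_um = readr::col_double(),
  z_radius_um = readr::col_double(), first_section = readr::col_integer(),
  span_sections = readr::col_integer(), amplitude = readr::col_double(),
  gfp_positive = readr::col_logical(), tau_positive = readr::col_logical(),
  pair_id = readr::col_character(), is_speckle = readr::col_logical())

#' Write / read planted ground truth as CSV
#'
#' One row per planted object (synaptic puncta and speckles, flagged by
#' `is_speckle`); round-trips losslessly with [read_ground_truth()].
#'
#' @param truth The `truth` element returned by [generate_scene()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  spk <- truth$speckles
  spk_rows <- tibble::tibble(
    id = if (nrow(spk) > 0) paste0("speckle_", seq_len(nrow(spk))) else character(0),
    channel = spk$channel, x_um = spk$x_um, y_um = spk$y_um,
    z_um = (spk$section - 0.5) * truth$config$section_thickness_um,
    radius_um = spk$radius_um,
    z_radius_um = rep(truth$config$section_thickness_um / 2, nrow(spk)),
    first_section = spk$section,
    span_sections = rep(1L, nrow(spk)),
    amplitude = spk$amplitude,
    gfp_positive = rep(NA, nrow(spk)), tau_positive = rep(NA, nrow(spk)),
    pair_id = rep(NA_character_, nrow(spk)))
  tbl <- dplyr::bind_rows(
    dplyr::mutate(truth$puncta, is_speckle = FALSE),
    dplyr::mutate(spk_rows, is_speckle = TRUE))
  readr::write_csv(tbl, path, na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, col_types = .truth_cols, na = "")
}
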