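#' Label 3D puncta from a binary mask
#'
#' Forms maximal 26-connected (3D) foreground components — 8-connectivity
#' in plane plus all inter-section diagonals, the permissive convention
#' that keeps a punctum continuing across sections one object despite
#' residual one-pixel misalignment. Centroids are unweighted voxel means
#' converted to micrometres in parent coordinates (honouring the mask's
#' crop origin); volume is voxel count times the voxel volume;
#' `section_span` counts the distinct sections an object touches.
#' Components are numbered by their minimum voxel in `(z, y, x)`
#' lexicographic order, so labelling is deterministic.
#'
#' @param mask A `binary_mask` from [binarize_stack()] (or any list with a
#'   logical 3D `data` plus calibration fields).
#' @return A `puncta` tibble with columns `id`, `channel`,
#'   `centroid_x_um`, `centroid_y_um`, `centroid_z_um`, `volume_um3`,
#'   `n_voxels`, `section_span`, and a `voxels` list-column of linear voxel
#'   indices; attributes carry the grid dimensions, calibration, origin and
#'   total crop volume.
#' @export
label_components <- function(mask) {
  d <- dim(mask$data)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  px <- mask$pixel_size_um; dz <- mask$section_thickness_um
  fg <- which(mask$data)
  empty <- length(fg) == 0
  if (!empty) {
    idx0 <- fg - 1L
    r <- idx0 %% ny
    c <- (idx0 %/% ny) %% nx
    s <- idx0 %/% (ny * nx)
    pos <- integer(ny * nx * nz)
    pos[fg] <- seq_along(fg)
    # 13 forward neighbour offsets cover all 26 neighbours once
    offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
    offs <- offs[offs$ds > 0 | (offs$ds == 0 & offs$dc > 0) |
                   (offs$ds == 0 & offs$dc == 0 & offs$dr > 0), ]
    from <- integer(0); to <- integer(0)
    for (k in seq_len(nrow(offs))) {
      nr <- r + offs$dr[k]; nc <- c + offs$dc[k]; ns <- s + offs$ds[k]
      ok <- nr >= 0 & nr < ny & nc >= 0 & nc < nx & ns >= 0 & ns < nz
      if (!any(ok)) next
      nidx <- nr[ok] + nc[ok] * ny + ns[ok] * ny * nx + 1L
      p <- pos[nidx]
      hit <- p > 0L
      if (any(hit)) {
        from <- c(from, pos[fg[ok]][hit])
        to <- c(to, p[hit])
      }
    }
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (length(from) > 0) {
      g <- igraph::add_edges(g, rbind(from, to))
    }
    memb <- igraph::components(g)$membership
    # deterministic relabel: by minimum voxel in (z, y, x) order
    key <- s * (ny * nx) + r * nx + c          # z-major, then y, then x
    min_key <- tapply(key, memb, min)
    relabel <- match(memb, as.integer(names(sort(min_key))))
    n_comp <- max(relabel)
    vox <- split(fg, relabel)
    cx <- tapply((c + 0.5) * px, relabel, mean) + mask$origin_um[1]
    cy <- tapply((r + 0.5) * px, relabel, mean) + mask$origin_um[2]
    cz <- tapply((s + 0.5) * dz, relabel, mean)
    span <- tapply(s, relabel, function(z) length(unique(z)))
    nvox <- tapply(s, relabel, length)
    tbl <- tibble::tibble(
      id = seq_len(n_comp),
      channel = rep(mask$channel %||% "unknown", n_comp),
      centroid_x_um = as.numeric(cx),
      centroid_y_um = as.numeric(cy),
      centroid_z_um = as.numeric(cz),
      volume_um3 = as.numeric(nvox) * px * px * dz,
      n_voxels = as.integer(nvox),
      section_span = as.integer(span),
      voxels = unname(vox))
  } else {
    tbl <- tibble::tibble(
      id = integer(0), channel = character(0),
      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
      centroid_z_um = numeric(0), volume_um3 = numeric(0),
      n_voxels = integer(0), section_span = integer(0),
      voxels = list())
  }
  new_puncta(tbl, dims = d, pixel_size_um = px, section_thickness_um = dz,
             origin_um = mask$origin_um %||% c(0, 0),
             channel = mask$channel %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_puncta <- function(tbl, dims, pixel_size_um, section_thickness_um,
                       origin_um, channel) {
  structure(tbl,
            dims = dims,
            pixel_size_um = pixel_size_um,
            section_thickness_um = section_thickness_um,
            origin_um = origin_um,
            crop_volume_um3 = prod(dims) * pixel_size_um^2 *
              section_thickness_um,
            channel = channel,
            class = c("puncta", class(tbl)))
}

# subset rows of a puncta table preserving its measurement attributes
puncta_subset <- function(pc, keep) {
  new_puncta(tibble::as_tibble(pc)[keep, , drop = FALSE],
             dims = attr(pc, "dims"),
             pixel_size_um = attr(pc, "pixel_size_um"),
             section_thickness_um = attr(pc, "section_thickness_um"),
             origin_um = attr(pc, "origin_um"),
             channel = attr(pc, "channel"))
}

#' Remove single-section objects (background-noise filter)
#'
#' Objects present in only one serial section are imaging noise, not
#' synapses: real synaptic structures span multiple 70 nm sections. Keeps
#' exactly the puncta with `section_span >= 2`, leaves every other property
#' untouched, and is idempotent.
#'
#' @param pc A `puncta` tibble from [label_components()].
#' @return The filtered `puncta` tibble.
#' @export
filter_single_section <- function(pc) {
  puncta_subset(pc, pc$section_span >= 2L)
}

#' Drop puncta touching the crop border
#'
#' Optional exclusion of objects whose voxels touch any face of the crop;
#' border objects are retained by default throughout the pipeline.
#'
#' @param pc A `puncta` tibble.
#' @return The filtered `puncta` tibble.
#' @export
exclude_border_puncta <- function(pc) {
  d <- attr(pc, "dims")
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  touches <- vapply(pc$voxels, function(v) {
    idx0 <- v - 1L
    r <- idx0 %% ny
    c <- (idx0 %/% ny) %% nx
    s <- idx0 %/% (ny * nx)
    any(r == 0 | r == ny - 1 | c == 0 | c == nx - 1 | s == 0 | s == nz - 1)
  }, logical(1))
  puncta_subset(pc, !touches)
}

#' Puncta density in objects per cubic micrometre
#'
#' @param pc A `puncta` tibble whose attributes carry the crop volume.
#' @return Scalar density (um^-3).
#' @export
puncta_density <- function(pc) {
  vol <- attr(pc, "crop_volume_um3")
  if (is.null(vol) || vol <= 0) stop("crop volume unknown or zero", call. = FALSE)
  nrow(pc) / vol
}

#' Classify puncta by overlap with a reference channel's foreground
#'
#' For each target punctum, the overlap fraction is the share of its OWN
#' voxels that fall inside the reference foreground; the punctum is
#' positive when that fraction reaches `min_overlap` (inclusive), the
#' standard 50 percent volume-overlap colocalization rule.
#'
#' @param targets A `puncta` tibble (e.g. PSD95 postsynapses).
#' @param reference_mask A congruent `binary_mask` (e.g. the tau channel).
#' @param min_overlap Inclusive positivity threshold in `[0, 1]`.
#' @return Tibble `id`, `n_voxels`, `n_overlap`, `overlap_fraction`,
#'   `positive` — one row per target punctum.
#' @export
classify_overlap <- function(targets, reference_mask, min_overlap = 0.5) {
  if (!identical(as.integer(attr(targets, "dims")),
                 as.integer(dim(reference_mask$data)))) {
    stop("target puncta grid and reference mask are not congruent",
         call. = FALSE)
  }
  n_ov <- vapply(targets$voxels, function(v) sum(reference_mask$data[v]),
                 numeric(1))
  frac <- ifelse(targets$n_voxels > 0, n_ov / targets$n_voxels, 0)
  tibble::tibble(id = targets$id,
                 n_voxels = targets$n_voxels,
                 n_overlap = as.integer(n_ov),
                 overlap_fraction = frac,
                 positive = frac >= min_overlap)
}

#' Percentage of presynapses that are GFP-positive
#'
#' A presynaptic punctum counts as GFP-positive when at least `min_overlap`
#' of its voxels lie inside the GFP-channel foreground. With no presynapses
#' the percentage is undefined and reported as `NA` (missing), never 0.
#'
#' @param total_pre `puncta` tibble of all presynapses.
#' @param gfp_mask Congruent `binary_mask` of the GFP channel.
#' @param min_overlap Inclusive overlap threshold.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
percent_gfp_positive <- function(total_pre, gfp_mask, min_overlap = 0.5) {
  if (nrow(total_pre) == 0) return(NA_real_)
  rec <- classify_overlap(total_pre, gfp_mask, min_overlap)
  100 * sum(rec$positive) / nrow(rec)
}

#' Pooled percentage of positive objects across crops
#'
#' Pools by sums — total positives over total objects — never by averaging
#' per-crop percentages, matching the per-mouse aggregation rule for
#' colocalization statistics.
#'
#' @param records A tibble with a logical `positive` column (rows from one
#'   mouse, possibly multiple crops bound together).
#' @return Percentage, or `NA_real_` when there are no objects.
#' @export
percent_positive <- function(records) {
  if (nrow(records) == 0) return(NA_real_)
  100 * sum(records$positive) / nrow(records)
}

#' Export a puncta table as CSV
#' @param pc A `puncta` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_puncta <- function(pc, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(pc), -"voxels"), path)
  invisible(path)
}
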