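#' Configure a full analysis run
#'
#' Gathers every numeric convention of the analysis in one validated
#' object: the 50 percent volume-overlap colocalization rule, the 0.5 um
#' pairing radius, the combined thresholding method, 26-connectivity, and
#' the single-section noise filter, plus the cohort design for synthetic
#' runs (genotypes crossed with age groups; human tau is planted only in
#' the transgenic genotype, as in the mouse model, where control animals
#' carry the GFP reporter but no human tau).
#'
#' @param mode `"synthetic"` (generate scenes per mouse/crop) or `"tiff"`
#'   (read stacks from `channel_files`).
#' @param scene A [scene_config()] template used for transgenic synthetic
#'   mice; controls reuse it with tau fractions forced to zero.
#' @param genotypes,age_groups Cohort design factors.
#' @param n_mice_per_group,n_crops_per_mouse Cohort sizes.
#' @param min_overlap Inclusive colocalization overlap threshold.
#' @param max_pair_dist_um Inclusive synaptic-pair centroid radius.
#' @param threshold_method Passed to [binarize_stack()].
#' @param exclude_border Drop puncta touching the crop border.
#' @param align Run translation registration (disable only for pre-aligned
#'   input).
#' @param search_radius Registration search radius (px).
#' @param channel_files For `mode = "tiff"`: tibble with columns `mouse`,
#'   `genotype`, `age_group`, `crop`, `channel`, `path`.
#' @param pixel_size_um,section_thickness_um Calibration for TIFF input.
#' @param seed Master seed; all randomness in a run flows from it.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "tiff"),
                       scene = scene_config(),
                       genotypes = c("transgenic", "control"),
                       age_groups = c("3-6", "9", "18"),
                       n_mice_per_group = 4,
                       n_crops_per_mouse = 1,
                       min_overlap = 0.5,
                       max_pair_dist_um = 0.5,
                       threshold_method = "combined",
                       exclude_border = FALSE,
                       align = TRUE,
                       search_radius = 10,
                       channel_files = NULL,
                       pixel_size_um = 0.1,
                       section_thickness_um = 0.07,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(min_overlap >= 0, min_overlap <= 1, max_pair_dist_um >= 0,
            n_mice_per_group >= 1, n_crops_per_mouse >= 1)
  structure(
    list(mode = mode, scene = scene, genotypes = genotypes,
         age_groups = age_groups, n_mice_per_group = n_mice_per_group,
         n_crops_per_mouse = n_crops_per_mouse, min_overlap = min_overlap,
         max_pair_dist_um = max_pair_dist_um,
         threshold_method = threshold_method,
         exclude_border = exclude_border, align = align,
         search_radius = search_radius, channel_files = channel_files,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Analyse one multi-channel scene end to end
#'
#' Runs the per-crop measurement chain: translation registration on the
#' total-presynapse channel, per-section combined thresholding of every
#' channel, 3D 26-connected labelling, the single-section noise filter,
#' then the synaptic measurements — densities, GFP positivity of
#' presynapses, tau colocalization of postsynapses, and putative synaptic
#' pairs (GFP-positive presynapses within `max_pair_dist_um` of a
#' postsynapse, both sides classified against the tau mask).
#'
#' @param series A [section_series()] with channels `presynapse`, `gfp`,
#'   `postsynapse`, `tau`.
#' @param config A [run_config()].
#' @return List with `counts` (one-row tibble of the crop's counts and
#'   volume), `puncta` (named list of filtered collections), `records`
#'   (colocalization record tibbles), `pairs`, and `transforms`.
#' @export
analyze_scene <- function(series, config = run_config()) {
  needed <- c("presynapse", "gfp", "postsynapse", "tau")
  missing_ch <- setdiff(needed, names(series$channels))
  if (length(missing_ch) > 0) {
    stop("missing channels: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  if (config$align) {
    al <- align_series(series, reference_channel = "presynapse",
                       search_radius = config$search_radius)
    stacks <- al$stacks
    transforms <- al$transforms
  } else {
    stacks <- series_to_stacks(series)
    transforms <- tibble::tibble(section = seq_len(n_sections(series)),
                                 dx_px = 0L, dy_px = 0L)
  }
  masks <- lapply(stacks, binarize_stack, method = config$threshold_method)
  collect <- function(role) {
    pc <- filter_single_section(label_components(masks[[role]]))
    if (config$exclude_border) pc <- exclude_border_puncta(pc)
    pc
  }
  pre <- collect("presynapse")
  post <- collect("postsynapse")
  vol <- stack_volume_um3(stacks[["presynapse"]])

  gfp_rec <- classify_overlap(pre, masks[["gfp"]], config$min_overlap)
  gfp_pre <- puncta_subset(pre, gfp_rec$positive)
  post_tau_rec <- classify_overlap(post, masks[["tau"]], config$min_overlap)
  pre_tau_rec <- classify_overlap(pre, masks[["tau"]], config$min_overlap)
  pairs <- find_pairs(gfp_pre, post, config$max_pair_dist_um)
  pair_tau <- if (nrow(pairs) > 0) {
    pre_pos <- pre_tau_rec$positive[match(pairs$pre_id, pre_tau_rec$id)]
    post_pos <- post_tau_rec$positive[match(pairs$post_id, post_tau_rec$id)]
    pre_pos & post_pos
  } else logical(0)

  counts <- tibble::tibble(
    n_pre = nrow(pre),
    n_gfp_pre = sum(gfp_rec$positive),
    n_post = nrow(post),
    n_post_tau = sum(post_tau_rec$positive),
    n_pairs = nrow(pairs),
    n_pairs_tau = sum(pair_tau),
    volume_um3 = vol)
  list(counts = counts,
       puncta = list(presynapse = pre, postsynapse = post, gfp_pre = gfp_pre),
       records = list(gfp = gfp_rec, post_tau = post_tau_rec,
                      pre_tau = pre_tau_rec),
       pairs = dplyr::mutate(pairs, tau_positive = pair_tau),
       transforms = transforms)
}

# deterministic per-scene seed derived from the master seed
.scene_seed <- function(master, index) {
  as.integer((as.numeric(master) * 131 + index * 1000003) %% 2147483629)
}

#' Run the full pipeline over a cohort
#'
#' Synthetic mode generates one ground-truthed scene per mouse and crop
#' (tau planted only in transgenic animals) and runs [analyze_scene()] on
#' each; TIFF mode reads the configured stacks instead. Crop-level counts
#' are aggregated per mouse with [aggregate_mice()], then the group
#' comparisons are fitted: two-way ANOVA (genotype x age) for the density
#' statistics and Kruskal-Wallis across age groups within the transgenic
#' genotype for the tau colocalization percentages, mirroring the
#' reporting conventions of the source analyses. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, crop table, per-mouse
#'   summary, statistics and a text report are written there as CSV/text.
#' @return A `synaptomo_run` list: `crops`, `mice`, `stats`, `truth`
#'   (synthetic mode), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  design <- tidyr::expand_grid(
    genotype = config$genotypes,
    age_group = config$age_groups,
    mouse_index = seq_len(config$n_mice_per_group))
  design$mouse <- sprintf("%s_%s_m%d", design$genotype, design$age_group,
                          design$mouse_index)
  crop_rows <- list()
  truths <- list()
  scene_i <- 0L
  for (i in seq_len(nrow(design))) {
    for (crop in seq_len(config$n_crops_per_mouse)) {
      scene_i <- scene_i + 1L
      if (config$mode == "synthetic") {
        sc <- config$scene
        if (design$genotype[i] != config$genotypes[1]) {
          # control genotype: GFP reporter present, human tau absent
          sc$frac_post_tau_positive <- 0
          sc$frac_pre_tau_positive <- 0
        }
        sc$seed <- .scene_seed(config$seed, scene_i)
        scene <- generate_scene(sc)
        series <- scene$series
        truths[[length(truths) + 1L]] <- scene$truth
      } else {
        files <- config$channel_files
        sel <- files[files$mouse == design$mouse[i] & files$crop == crop, ]
        if (nrow(sel) == 0) {
          stop("no channel files configured for mouse ", design$mouse[i],
               " crop ", crop, call. = FALSE)
        }
        series <- read_series(stats::setNames(sel$path, sel$channel),
                              config$pixel_size_um,
                              config$section_thickness_um)
      }
      res <- tryCatch(
        analyze_scene(series, config),
        error = function(e) {
          stop(sprintf("analysis failed for mouse %s crop %d: %s",
                       design$mouse[i], crop, conditionMessage(e)),
               call. = FALSE)
        })
      crop_rows[[scene_i]] <- dplyr::bind_cols(
        tibble::tibble(mouse = design$mouse[i],
                       genotype = design$genotype[i],
                       age_group = design$age_group[i],
                       crop = crop),
        res$counts)
    }
  }
  crops <- dplyr::bind_rows(crop_rows)
  mice <- aggregate_mice(crops)
  tg <- mice[mice$genotype == config$genotypes[1], ]
  stats_list <- list(
    density_pre = two_way_anova(mice, "density_pre_um3"),
    density_gfp_pre = two_way_anova(mice, "density_gfp_pre_um3"),
    pct_gfp_pre = two_way_anova(mice, "pct_gfp_pre"),
    pct_post_tau = if (length(unique(tg$age_group)) >= 2)
      kruskal_wallis(tg, "pct_post_tau", "age_group") else NULL,
    pct_pairs_tau = if (length(unique(tg$age_group)) >= 2 &&
                        sum(!is.na(tg$pct_pairs_tau)) >= 2)
      kruskal_wallis(tg, "pct_pairs_tau", "age_group") else NULL)
  bundle <- structure(
    list(crops = crops, mice = mice, stats = stats_list,
         truth = if (config$mode == "synthetic") truths else NULL,
         config = config),
    class = "synaptomo_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(crops, file.path(out_dir, "crops.csv"))
    readr::write_csv(mice, file.path(out_dir, "mouse_summary.csv"))
    stats_tbl <- dplyr::bind_rows(lapply(
      Filter(Negate(is.null), stats_list), tidy), .id = "statistic")
    readr::write_csv(stats_tbl, file.path(out_dir, "group_stats.csv"))
    writeLines(make_report(bundle), file.path(out_dir, "report.txt"))
  }
  bundle
}

#' @export
print.synaptomo_run <- function(x, ...) {
  cat(sprintf("<synaptomo_run> %d crops, %d mice\n", nrow(x$crops),
              nrow(x$mice)))
  invisible(x)
}

.fmt <- function(x, digits = 4) formatC(x, digits = digits, format = "g")

#' Human-readable summary report of a pipeline run
#'
#' Density statistics are reported as group mean and SEM; colocalization
#' percentages as median and interquartile range, matching the reporting
#' conventions of each analysis. Group tests are included when fitted;
#' sections without data are omitted with a notice.
#'
#' @param bundle A `synaptomo_run` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "synaptomo_run"))
  if (nrow(bundle$mice) == 0) stop("empty result bundle", call. = FALSE)
  mice <- bundle$mice
  lines <- c("Array-tomography synapse quantification report",
             strrep("=", 47), "")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  mean_sem_block <- function(col, label) {
    tb <- mice |>
      dplyr::group_by(.data$genotype, .data$age_group) |>
      dplyr::summarise(mean = mean(.data[[col]], na.rm = TRUE),
                       sem = sem(.data[[col]][!is.na(.data[[col]])]),
                       n = sum(!is.na(.data[[col]])), .groups = "drop")
    c(sprintf("%s (mean +/- SEM per group):", label),
      sprintf("  %-12s %-6s %s +/- %s (n=%d)", tb$genotype, tb$age_group,
              .fmt(tb$mean), .fmt(tb$sem), tb$n), "")
  }
  med_iqr_block <- function(col, label) {
    sub <- mice[!is.na(mice[[col]]), ]
    if (nrow(sub) == 0) return(sprintf("%s: no data (section omitted)", label))
    tb <- sub |>
      dplyr::group_by(.data$genotype, .data$age_group) |>
      dplyr::summarise(median = stats::median(.data[[col]]),
                       q1 = stats::quantile(.data[[col]], 0.25),
                       q3 = stats::quantile(.data[[col]], 0.75),
                       n = dplyr::n(), .groups = "drop")
    c(sprintf("%s (median [IQR] per group):", label),
      sprintf("  %-12s %-6s %s [%s, %s] (n=%d)", tb$genotype, tb$age_group,
              .fmt(tb$median), .fmt(tb$q1), .fmt(tb$q3), tb$n), "")
  }
  lines <- c(lines,
             mean_sem_block("density_pre_um3", "Total presynapse density (um^-3)"),
             mean_sem_block("density_gfp_pre_um3", "GFP+ presynapse density (um^-3)"),
             mean_sem_block("pct_gfp_pre", "% GFP-positive presynapses"),
             med_iqr_block("pct_post_tau", "% postsynapses tau-positive"),
             med_iqr_block("pct_pairs_tau", "% synaptic pairs tau-positive"),
             "Group comparisons:")
  for (nm in names(bundle$stats)) {
    fit <- bundle$stats[[nm]]
    if (is.null(fit)) {
      lines <- c(lines, sprintf("  %s: not fitted (insufficient groups)", nm))
    } else if (inherits(fit, "synaptomo_anova")) {
      t <- fit$terms
      lines <- c(lines, sprintf(
        "  %s: two-way ANOVA %s F=%.3g p=%.3g; %s F=%.3g p=%.3g; interaction F=%.3g p=%.3g",
        nm, t$term[1], t$statistic[1], t$p.value[1],
        t$term[2], t$statistic[2], t$p.value[2],
        t$statistic[3], t$p.value[3]))
    } else {
      lines <- c(lines, sprintf(
        "  %s: Kruskal-Wallis H=%.4g df=%d p=%.3g", nm,
        fit$statistic, fit$df, fit$p.value))
    }
  }
  lines
}
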