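#' Study configuration
#'
#' Assembles every parameter of a simulated gated vs non-gated DWI study.
#' Per-subject anatomical variation comes from jittering the tract geometry;
#' per-subject seeds are derived from the master seed by a fixed counter
#' scheme (subject i uses `master_seed + 1000 i` for geometry and
#' `master_seed + 1000 i + 1/+2` for the non-gated/gated acquisitions), so
#' adding subjects never changes earlier subjects' data.
#'
#' @param n_subjects number of synthetic subjects (default 22).
#' @param master_seed integer master seed.
#' @param phantom overrides for [phantom_config()].
#' @param pulsatile overrides for [pulsatile_model()] arguments.
#' @param n_repetitions repetitions per gating mode (default 5).
#' @param noise_sigma Rician noise level (default SNR 30 on the brain b=0
#'   signal of 1000).
#' @param tracking a [track_params()] list.
#' @param qc_threshold_k artefact-flagging threshold, see [flag_artifacts()].
#' @param alpha significance level for paired tests.
#' @param jitter_curve_amp_sd,jitter_center_sd SDs (mm) of the per-subject
#'   tract-geometry jitter.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 22, master_seed = 1,
                         phantom = list(), pulsatile = list(),
                         n_repetitions = 5, noise_sigma = 1000 / 30,
                         tracking = track_params(), qc_threshold_k = 0.15,
                         alpha = 0.05,
                         jitter_curve_amp_sd = 1, jitter_center_sd = 2) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (abs(master_seed) + 1000 * n_subjects + 2 >= 2^31)
    stop("master_seed too large for the per-subject seed scheme")
  structure(list(n_subjects = as.integer(n_subjects),
                 master_seed = as.integer(master_seed),
                 phantom = utils::modifyList(phantom_config(), phantom),
                 pulsatile = pulsatile,
                 n_repetitions = as.integer(n_repetitions),
                 noise_sigma = noise_sigma, tracking = tracking,
                 qc_threshold_k = qc_threshold_k, alpha = alpha,
                 jitter_curve_amp_sd = jitter_curve_amp_sd,
                 jitter_center_sd = jitter_center_sd),
            class = "study_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

subject_seed <- function(config, subject) config$master_seed + 1000L * subject

# paired_compare that degrades to NAs when fewer than 2 complete pairs exist
# (single-subject runs, regions empty on a small grid)
safe_paired <- function(x, y, alpha) {
  if (sum(is.finite(x) & is.finite(y)) < 2L)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = NA_real_, n = 0L, significant = FALSE,
                degenerate = TRUE))
  paired_compare(x, y, alpha)
}

# Anatomical subdivision masks on the study grid: brainstem below 25 mm,
# posterior limb of the internal capsule 25-50 mm, subcortex above the corpus
# callosum level (>= 65 mm). The 50-65 mm band (corpus callosum level) is
# deliberately outside all three, as in the conventional subdivision.
subdivision_masks <- function(dims, voxel_size) {
  zc <- (seq_len(dims[3]) - 0.5) * voxel_size
  zmask <- function(lo, hi) {
    m <- array(FALSE, dim = dims)
    m[, , zc >= lo & zc < hi] <- TRUE
    m
  }
  list(BS = zmask(0, 25), PLIC = zmask(25, 50), SC = zmask(65, Inf))
}

jittered_phantom <- function(config, subject) {
  set.seed(subject_seed(config, subject))
  pc <- config$phantom
  ext <- pc$grid_shape * pc$voxel_size
  amp <- max(0, pc$tract_curve_amp +
               stats::rnorm(1, 0, config$jitter_curve_amp_sd))
  cx <- ext[1] / 2 + stats::rnorm(1, 0, config$jitter_center_sd)
  cy <- ext[2] / 2 + stats::rnorm(1, 0, config$jitter_center_sd)
  # keep the tube inside the grid
  margin <- pc$tract_radius + amp + 1
  cx <- min(max(cx, margin), ext[1] - margin)
  cy <- min(max(cy, pc$tract_radius + 1), ext[2] - pc$tract_radius - 1)
  pc$tract_curve_amp <- amp
  pc$tract_center_x <- cx
  pc$tract_center_y <- cy
  build_phantom(pc)
}

process_gating <- function(config, phantom, gating, seed, gt, extremes,
                           region_masks) {
  pm <- do.call(pulsatile_model, config$pulsatile)
  proto <- acquisition_protocol(gt, config$n_repetitions, gating,
                                config$noise_sigma, seed)
  study <- simulate_acquisition(phantom, pm, proto)
  h <- phantom$voxel_size
  brain <- phantom$masks$brain

  fits <- lapply(study$repetitions, dti_fit, table = gt, mask = brain,
                 voxel_size = h)
  eigs <- lapply(fits, dti_eigen)
  avg <- function(maps) Reduce(`+`, maps) / length(maps)
  fa_avg <- avg(lapply(eigs, fa_map))
  md_avg <- avg(lapply(eigs, md_map))
  ang_avg <- avg(lapply(eigs, function(e) v1_z_angle_map(e)))

  roi_qc <- phantom$pulsatile_zones$brainstem
  fl_min <- flag_artifacts(study, extremes$min_index, roi_qc,
                           config$qc_threshold_k)
  fl_max <- flag_artifacts(study, extremes$max_index, roi_qc,
                           config$qc_threshold_k)
  sd_min <- sd_map(lapply(study$repetitions, function(r)
    r[, , , extremes$min_index]))
  sd_max <- sd_map(lapply(study$repetitions, function(r)
    r[, , , extremes$max_index]))

  rois <- roi_set(list(phantom$rois$include_inferior,
                       phantom$rois$include_superior),
                  list(phantom$rois$exclude))
  seed_mask <- phantom$masks$tract | phantom$rois$include_inferior
  tracts <- vector("list", length(fits))
  for (r in seq_along(fits)) {
    sls <- seed_and_track(fits[[r]], seed_mask, config$tracking)
    sls <- apply_roi_filters(sls, rois)
    tracts[[r]] <- rasterize_tract(sls, gating = gating, repetition = r)
  }
  volumes <- vapply(tracts, function(t) t$volume_cm3, numeric(1))
  jd_whole <- jaccard_distance(tracts)
  jd_region <- vapply(names(region_masks), function(rg) {
    parts <- lapply(tracts, function(t)
      t$mask & region_masks[[rg]])
    if (!any(Reduce(`|`, parts))) return(NA_real_)
    jaccard_distance(parts)
  }, numeric(1))
  dice <- vapply(tracts, function(t)
    dice_coefficient(t$mask, phantom$masks$tract), numeric(1))

  prof <- slab_profile(list(FA = fa_avg, MD = md_avg, angle = ang_avg),
                       phantom$masks$tract, h)
  tract_vox <- phantom$masks$tract
  list(flags_min = sum(fl_min$flagged), flags_max = sum(fl_max$flagged),
       sd_min = sd_min, sd_max = sd_max,
       volumes = volumes, jd_whole = jd_whole, jd_region = jd_region,
       dice = dice, profile = prof,
       tract_mean_fa = mean(fa_avg[tract_vox], na.rm = TRUE),
       tract_mean_md = mean(md_avg[tract_vox], na.rm = TRUE),
       fa_err = mean(fa_avg[tract_vox], na.rm = TRUE) -
         mean(phantom$fa_truth[tract_vox]))
}

#' Run a complete simulated gated vs non-gated study
#'
#' For every synthetic subject: builds a jittered phantom, simulates
#' `n_repetitions` non-gated and cardiac-gated acquisitions, fits tensors per
#' repetition, computes repetition-SD maps and artefact flags for the
#' encoding directions closest to and farthest from the z-axis, reconstructs
#' the tract per repetition, and derives tract volumes, generalized Jaccard
#' distances (whole tract and BS/PLIC/SC subdivisions) and along-tract slab
#' profiles of subject-averaged FA/MD/eigenvector-angle maps. Group level:
#' artefact occurrence ratios, paired slab-wise tests, paired volume and JD
#' tests, and pulsatile-region vs background summaries of the SD difference
#' maps.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, tables (TSV + JSON),
#'   group SD-difference maps (NIfTI) and a manifest are written. An existing
#'   manifest with a different configuration hash aborts the run rather than
#'   mixing outputs.
#' @param verbose print per-subject progress.
#' @return Object of class `study_report`; see the elements documented above
#'   plus `manifest` (seeds, hash, versions).
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    mf <- file.path(out_dir, "manifest.json")
    if (file.exists(mf)) {
      old <- jsonlite::read_json(mf)
      if (!identical(old$config_hash, hash))
        stop("output directory holds a run with a different configuration; ",
             "refusing to mix outputs")
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  gt <- default_gradient_table()
  extremes <- select_extreme_volumes(gt)
  dims <- as.integer(config$phantom$grid_shape)
  h <- config$phantom$voxel_size
  region_masks <- subdivision_masks(dims, h)

  subj_rows <- list()
  profiles <- list()
  sd_group <- list(non_gated = list(min = 0, max = 0),
                   cardiac_gated = list(min = 0, max = 0))
  flags <- list(non_gated = c(min = 0L, max = 0L),
                cardiac_gated = c(min = 0L, max = 0L))
  pz_union <- NULL; bg_mask <- NULL; tract_any <- NULL

  for (s in seq_len(config$n_subjects)) {
    ph <- jittered_phantom(config, s)
    if (is.null(pz_union)) {
      pz_union <- ph$pulsatile_zones$brainstem | ph$pulsatile_zones$cerebellum
      bg_mask <- ph$masks$background
      tract_any <- ph$masks$tract
    } else {
      # group summaries use the intersection of backgrounds / union of zones
      pz_union <- pz_union | ph$pulsatile_zones$brainstem |
        ph$pulsatile_zones$cerebellum
      bg_mask <- bg_mask & ph$masks$background
      tract_any <- tract_any | ph$masks$tract
    }
    res <- list()
    for (gating in c("non_gated", "cardiac_gated")) {
      seed <- subject_seed(config, s) +
        if (gating == "non_gated") 1L else 2L
      res[[gating]] <- process_gating(config, ph, gating, seed, gt,
                                      extremes, region_masks)
      sd_group[[gating]]$min <- sd_group[[gating]]$min + res[[gating]]$sd_min
      sd_group[[gating]]$max <- sd_group[[gating]]$max + res[[gating]]$sd_max
      flags[[gating]]["min"] <- flags[[gating]]["min"] + res[[gating]]$flags_min
      flags[[gating]]["max"] <- flags[[gating]]["max"] + res[[gating]]$flags_max
      profiles[[paste(s, gating, sep = "_")]] <-
        cbind(subject = s, gating = gating, res[[gating]]$profile)
    }
    row <- data.frame(subject = s)
    for (gating in c("non_gated", "cardiac_gated")) {
      g <- if (gating == "non_gated") "ng" else "g"
      r <- res[[gating]]
      row[[paste0("volume_", g)]] <- mean(r$volumes)
      row[[paste0("jd_", g)]] <- r$jd_whole
      for (rg in names(region_masks))
        row[[paste0("jd_", rg, "_", g)]] <- r$jd_region[[rg]]
      row[[paste0("fa_", g)]] <- r$tract_mean_fa
      row[[paste0("md_", g)]] <- r$tract_mean_md
      row[[paste0("fa_err_", g)]] <- r$fa_err
      row[[paste0("dice_", g)]] <- mean(r$dice)
      row[[paste0("flags_min_", g)]] <- r$flags_min
      row[[paste0("flags_max_", g)]] <- r$flags_max
    }
    subj_rows[[s]] <- row
    if (verbose)
      message(sprintf("subject %d/%d done", s, config$n_subjects))
  }
  subjects <- do.call(rbind, subj_rows)
  profiles <- do.call(rbind, profiles)
  rownames(profiles) <- NULL
  n_total <- config$n_subjects * config$n_repetitions

  occurrence <- data.frame(
    gating = rep(c("non_gated", "cardiac_gated"), each = 2),
    volume = rep(c("min_angle", "max_angle"), 2),
    volume_index = rep(c(extremes$min_index, extremes$max_index), 2),
    n_flagged = c(flags$non_gated, flags$cardiac_gated),
    ratio_percent = c(
      occurrence_ratio(flags$non_gated["min"], config$n_subjects, config$n_repetitions),
      occurrence_ratio(flags$non_gated["max"], config$n_subjects, config$n_repetitions),
      occurrence_ratio(flags$cardiac_gated["min"], config$n_subjects, config$n_repetitions),
      occurrence_ratio(flags$cardiac_gated["max"], config$n_subjects, config$n_repetitions)))

  # group-mean SD maps and their non-gated minus gated difference
  for (gating in names(sd_group))
    for (v in c("min", "max"))
      sd_group[[gating]][[v]] <- sd_group[[gating]][[v]] / config$n_subjects
  sd_diff <- list(min = difference_sd_map(sd_group$non_gated$min,
                                          sd_group$cardiac_gated$min),
                  max = difference_sd_map(sd_group$non_gated$max,
                                          sd_group$cardiac_gated$max))
  sd_summary <- data.frame(
    volume = rep(c("min_angle", "max_angle"), each = 2),
    region = rep(c("pulsatile", "background"), 2),
    mean_sd_diff = c(mean(sd_diff$min[pz_union]), mean(sd_diff$min[bg_mask]),
                     mean(sd_diff$max[pz_union]), mean(sd_diff$max[bg_mask])),
    mean_sd_gated = c(mean(sd_group$cardiac_gated$min[pz_union]),
                      mean(sd_group$cardiac_gated$min[bg_mask]),
                      mean(sd_group$cardiac_gated$max[pz_union]),
                      mean(sd_group$cardiac_gated$max[bg_mask])))

  # slab-wise paired tests across subjects
  slab_tests <- NULL
  for (metric in c("FA", "MD", "angle")) {
    col <- paste0("mean_", metric)
    for (sl in sort(unique(profiles$slab_index))) {
      sub <- profiles[profiles$slab_index == sl, ]
      w <- stats::reshape(sub[, c("subject", "gating", col)],
                          direction = "wide", idvar = "subject",
                          timevar = "gating")
      x <- w[[paste0(col, ".non_gated")]]
      y <- w[[paste0(col, ".cardiac_gated")]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 2) {
        pc <- paired_compare(x[ok], y[ok], config$alpha)
        slab_tests <- rbind(slab_tests, data.frame(
          metric = metric, slab_index = sl,
          section = sub$section[1], n = pc$n, mean_diff = pc$mean_diff,
          t = pc$t, p = pc$p, significant = isTRUE(pc$significant)))
      }
    }
  }

  volume_test <- safe_paired(subjects$volume_ng, subjects$volume_g,
                             config$alpha)
  jd_rows <- list()
  for (rg in c("whole", names(region_masks))) {
    cn <- if (rg == "whole") c("jd_ng", "jd_g") else
      paste0("jd_", rg, c("_ng", "_g"))
    pc <- safe_paired(subjects[[cn[1]]], subjects[[cn[2]]], config$alpha)
    jd_rows[[rg]] <- data.frame(
      region = rg,
      jd_ng_mean = mean(subjects[[cn[1]]], na.rm = TRUE),
      jd_ng_sd = stats::sd(subjects[[cn[1]]], na.rm = TRUE),
      jd_g_mean = mean(subjects[[cn[2]]], na.rm = TRUE),
      jd_g_sd = stats::sd(subjects[[cn[2]]], na.rm = TRUE),
      p = pc$p)
  }
  jd_table <- do.call(rbind, jd_rows)
  rownames(jd_table) <- NULL

  report <- structure(list(
    config = config, subjects = subjects, profiles = profiles,
    occurrence = occurrence, sd_summary = sd_summary,
    sd_diff_maps = sd_diff, slab_tests = slab_tests,
    volume_test = volume_test, jd_table = jd_table,
    extremes = extremes,
    manifest = list(config_hash = hash,
                    master_seed = config$master_seed,
                    subject_seeds = vapply(seq_len(config$n_subjects),
                                           function(s) subject_seed(config, s),
                                           numeric(1)),
                    package_version = as.character(utils::packageVersion("pulsedti")),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "study_report")
  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d subjects x %d repetitions x 2 gating modes\n",
              x$config$n_subjects, x$config$n_repetitions))
  cat("\nArtefact occurrence ratios (%):\n")
  print(x$occurrence, row.names = FALSE)
  cat(sprintf("\nWhole-tract volume, paired non-gated vs gated: p = %.3f\n",
              x$volume_test$p))
  if (!is.null(x$slab_tests)) {
    sig <- x$slab_tests[x$slab_tests$significant & x$slab_tests$metric == "FA", ]
    cat(sprintf("Slabs with significant FA differences: %s\n",
                if (nrow(sig)) paste(sig$slab_index, collapse = ", ") else "none"))
  }
  invisible(x)
}

write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  wr(report$subjects, "subjects")
  wr(report$profiles, "slab_profiles")
  wr(report$occurrence, "occurrence")
  wr(report$sd_summary, "sd_summary")
  if (!is.null(report$slab_tests)) wr(report$slab_tests, "slab_tests")
  wr(report$jd_table, "jd_table")
  h <- report$config$phantom$voxel_size
  write_nifti_volume(report$sd_diff_maps$min,
                     file.path(out_dir, "sd_diff_min_angle.nii.gz"), h)
  write_nifti_volume(report$sd_diff_maps$max,
                     file.path(out_dir, "sd_diff_max_angle.nii.gz"), h)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render summary tables and figures from a completed study
#'
#' Writes a tract-volume / Jaccard-distance summary table (one row per
#' region and gating mode, with paired p-values) and a slab-profile figure
#' (group-mean FA, MD and eigenvector angle along the tract for both gating
#' modes). Re-rendering is idempotent.
#'
#' @param study a `study_report` from [run_study()], or a directory written
#'   by it (missing stage outputs are reported by name).
#' @param out_dir where to write `table2.tsv` and `slab_profiles.pdf`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(study, out_dir) {
  if (is.character(study)) {
    need <- c("subjects.json", "slab_profiles.json", "jd_table.json",
              "occurrence.json", "manifest.json")
    missing <- need[!file.exists(file.path(study, need))]
    if (length(missing))
      stop("incomplete study directory; missing: ",
           paste(missing, collapse = ", "))
    subjects <- as.data.frame(jsonlite::fromJSON(
      file.path(study, "subjects.json")))
    profiles <- as.data.frame(jsonlite::fromJSON(
      file.path(study, "slab_profiles.json")))
    jd_table <- as.data.frame(jsonlite::fromJSON(
      file.path(study, "jd_table.json")))
    alpha <- 0.05
  } else {
    stopifnot(inherits(study, "study_report"))
    subjects <- study$subjects
    profiles <- study$profiles
    jd_table <- study$jd_table
    alpha <- study$config$alpha
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fmt <- function(m, s) sprintf("%.2f +/- %.2f", m, s)
  rows <- list()
  for (rg in jd_table$region) {
    vn <- if (rg == "whole") c("volume_ng", "volume_g") else NULL
    jr <- jd_table[jd_table$region == rg, ]
    for (g in c("ng", "g")) {
      lab <- if (g == "ng") "non_gated" else "cardiac_gated"
      vol <- if (!is.null(vn)) {
        v <- subjects[[vn[[if (g == "ng") 1 else 2]]]]
        fmt(mean(v), stats::sd(v))
      } else ""
      vp <- if (!is.null(vn) && g == "ng")
        sprintf("%.3f", safe_paired(subjects$volume_ng,
                                    subjects$volume_g, alpha)$p) else ""
      jd <- fmt(jr[[paste0("jd_", g, "_mean")]], jr[[paste0("jd_", g, "_sd")]])
      jp <- if (g == "ng" && is.finite(jr$p)) sprintf("%.3f", jr$p) else ""
      rows[[paste(rg, g)]] <- data.frame(
        region = rg, gating = lab, tract_volume_cm3 = vol, volume_p = vp,
        jd = jd, jd_p = jp)
    }
  }
  table2 <- do.call(rbind, rows)
  rownames(table2) <- NULL
  tpath <- file.path(out_dir, "table2.tsv")
  utils::write.table(table2, tpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  ppath <- file.path(out_dir, "slab_profiles.pdf")
  grDevices::pdf(ppath, width = 9, height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  for (metric in c("FA", "MD", "angle")) {
    col <- paste0("mean_", metric)
    agg <- stats::aggregate(profiles[[col]],
                            by = list(slab = profiles$slab_index,
                                      gating = profiles$gating),
                            FUN = mean, na.rm = TRUE)
    ng <- agg[agg$gating == "non_gated", ]
    g <- agg[agg$gating == "cardiac_gated", ]
    ylim <- range(agg$x, na.rm = TRUE)
    graphics::plot(ng$slab, ng$x, type = "b", pch = 16, col = "firebrick",
                   xlab = "slab (5 mm)", ylab = metric, main = metric,
                   ylim = ylim)
    graphics::lines(g$slab, g$x, type = "b", pch = 17, col = "steelblue")
    if (metric == "FA")
      graphics::legend("bottomleft", c("non-gated", "gated"),
                       col = c("firebrick", "steelblue"), pch = c(16, 17),
                       bty = "n", cex = 0.8)
  }
  invisible(c(tpath, ppath))
}
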