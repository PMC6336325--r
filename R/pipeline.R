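#' Pipeline configuration
#'
#' Assembles the configuration driving [run_pipeline()], with every analysis
#' threshold surfaced: 6 mm smoothing, BPnd > 0.05 pooling for k2', the five
#' ePIB intervals, voxel p = 0.005 with cluster FWE alpha = 0.05, FDR q =
#' 0.05 and the GTM PSF width.
#'
#' @param out_dir output directory, or `NULL` to keep results in memory.
#' @param cohort_dir existing cohort directory (see [write_cohort()]); when
#'   `NULL` a synthetic cohort is simulated.
#' @param n_pos,n_neg simulated group sizes.
#' @param seed master seed for simulation and permutation.
#' @param grid,voxel_size_mm,n_cortical_regions phantom-atlas geometry.
#' @param noise_scale PIB TAC noise level (CoV at the peak).
#' @param smoothing_fwhm_mm Gaussian smoothing applied to all images.
#' @param smooth_before_tacs smooth before extracting the reference TAC.
#' @param bp_threshold BPnd cutoff for k2' pooling.
#' @param theta_grid k2a candidate grid for the kinetic fits.
#' @param intervals named list of ePIB [interval()]s.
#' @param p_voxel,alpha_cluster,n_perm voxelwise-test thresholds.
#' @param fdr_q FDR significance threshold for regional tests.
#' @param do_pvc,pvc_fwhm_mm GTM partial-volume correction switch and PSF.
#' @param do_voxelwise run the permutation cluster tests.
#' @param voxelwise_measures measures entering the voxelwise comparison.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = NULL, cohort_dir = NULL,
                            n_pos = 15, n_neg = 15, seed = 1,
                            grid = 32, voxel_size_mm = 4,
                            n_cortical_regions = 4, noise_scale = 0.05,
                            smoothing_fwhm_mm = 6,
                            smooth_before_tacs = TRUE,
                            bp_threshold = 0.05,
                            theta_grid = default_theta_grid(),
                            intervals = epib_intervals(),
                            p_voxel = 0.005, alpha_cluster = 0.05,
                            n_perm = 500, fdr_q = 0.05,
                            do_pvc = TRUE, pvc_fwhm_mm = 6,
                            do_voxelwise = TRUE,
                            voxelwise_measures = c("SUVR", "R1",
                                                   "ePIB-20-130s",
                                                   "ePIB-1-8min")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$intervals))
    y$intervals <- lapply(y$intervals, function(v) interval(v[1L], v[2L]))
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on a cohort
#'
#' End-to-end orchestration: cohort simulation (or loading), smoothing and
#' brain masking, two-pass SRTM/SRTM2 R1 mapping, ePIB images for every
#' configured interval, FDG SUVR maps, regional tables, per-region group
#' t-tests with FDR, pooled within-group regressions (each flow surrogate
#' against FDG SUVR, and every ePIB interval against R1), Bland-Altman
#' agreement, per-group mean and difference images, optional GTM-corrected
#' regional tables, and permutation-based voxelwise group comparisons. A
#' manifest of every file written accompanies the outputs.
#'
#' @param config a [pipeline_config()], a YAML file path, or a list of
#'   `pipeline_config` arguments.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the cohort, regional table, statistics
#'   tables, images, voxelwise results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  say <- function(fmt, ...) if (!quiet)
    message(sprintf("[petflow %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  t0 <- proc.time()[3L]
  manifest <- character(0)
  out <- config$out_dir
  emit <- function(path) { manifest <<- c(manifest, path); path }

  # ---- cohort ----
  if (!is.null(config$cohort_dir)) {
    say("reading cohort from %s", config$cohort_dir)
    cohort <- read_cohort(config$cohort_dir)
  } else {
    say("simulating cohort: %d PIB+ / %d PIB- at %d^3 voxels",
        config$n_pos, config$n_neg, config$grid)
    atlas <- make_phantom_atlas(rep(config$grid, 3L),
                                config$n_cortical_regions,
                                config$voxel_size_mm)
    cohort <- simulate_cohort(config$n_pos, config$n_neg, seed = config$seed,
                              atlas = atlas, noise_scale = config$noise_scale)
  }
  atlas <- cohort$atlas
  bmask <- brain_mask(atlas)
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  if (length(unique(groups)) != 2L)
    stop("cohort must contain exactly two groups")

  # ---- per-subject maps ----
  say("per-subject processing (%d subjects)", length(cohort$subjects))
  measures <- c("R1", "SUVR", paste0("ePIB-", names(config$intervals)))
  maps <- stats::setNames(vector("list", length(measures)), measures)
  k2p <- numeric(length(cohort$subjects))
  n_clip <- 0L
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    dyn <- s$dynamic_pib
    if (config$smooth_before_tacs)
      dyn <- smooth_gaussian(dyn, config$smoothing_fwhm_mm)
    dyn <- apply_brain_mask(dyn, bmask)
    km <- parametric_r1(dyn, atlas,
                        srtm2_config(theta_grid = config$theta_grid,
                                     bp_threshold = config$bp_threshold))
    k2p[i] <- km$k2_prime
    n_clip <- n_clip + km$n_clipped
    r1 <- km$R1_map
    r1$voxels[!is.finite(r1$voxels)] <- 0
    maps$R1[[i]] <- r1
    fdg <- apply_brain_mask(
      smooth_gaussian(s$static_fdg, config$smoothing_fwhm_mm), bmask)
    maps$SUVR[[i]] <- suvr_map(fdg, atlas)
    for (nm in names(config$intervals))
      maps[[paste0("ePIB-", nm)]][[i]] <-
        epib_map(dyn, config$intervals[[nm]], atlas)
  }
  if (n_clip > 0) say("warning summary: %d voxel fits clipped at R1 = 0",
                      n_clip)

  subj_ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  entries <- list()
  for (m in measures) for (i in seq_along(subj_ids))
    entries[[length(entries) + 1L]] <-
      list(subject = subj_ids[i], group = groups[i], measure = m,
           map = maps[[m]][[i]])
  say("regional table")
  table <- build_regional_table(entries, atlas)

  # ---- regional statistics ----
  say("regional group tests and agreement statistics")
  glev <- c("PIB+", "PIB-")
  ttests <- lapply(stats::setNames(measures, measures), function(m)
    group_ttests_fdr(table, m, groups = glev))

  wide <- function(m, g) {
    t <- table[table$measure == m & table$group == g, ]
    t <- t[order(t$subject, t$region), ]
    t$value
  }
  reg_rows <- list(); ba <- list()
  pairs <- rbind(
    data.frame(y = "R1", x = "SUVR"),
    data.frame(y = paste0("ePIB-", names(config$intervals)), x = "SUVR"),
    data.frame(y = paste0("ePIB-", names(config$intervals)), x = "R1"))
  for (g in glev) for (k in seq_len(nrow(pairs))) {
    fr <- fit_regression(wide(pairs$x[k], g), wide(pairs$y[k], g))
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      group = g, y = pairs$y[k], x = pairs$x[k], slope = fr$slope,
      intercept = fr$intercept, r_squared = fr$r_squared,
      pearson_r = fr$pearson_r, p_value = fr$p_value, n = fr$n)
  }
  regressions <- do.call(rbind, reg_rows)
  for (g in glev) {
    ba[[paste0("R1_vs_SUVR_", g)]] <- bland_altman(wide("SUVR", g),
                                                   wide("R1", g))
    ba[[paste0("ePIB-20-130s_vs_SUVR_", g)]] <-
      tryCatch(bland_altman(wide("SUVR", g), wide("ePIB-20-130s", g)),
               error = function(e) NULL)
  }

  # ---- group mean and difference images ----
  say("group mean and difference images")
  gmean <- function(lst) {
    acc <- Reduce(`+`, lapply(lst, function(m) m$voxels))
    static_image(acc / length(lst), lst[[1L]]$voxel_size_mm)
  }
  images <- list()
  for (m in measures) for (g in glev)
    images[[paste0("mean_", m, "_", g)]] <- gmean(maps[[m]][groups == g])
  for (m in setdiff(measures, "SUVR")) for (g in glev)
    images[[paste0("diff_", m, "-SUVR_", g)]] <-
      mean_difference_image(maps[[m]][groups == g], maps$SUVR[groups == g])

  # ---- partial-volume corrected tables ----
  pvc_table <- NULL; pvc_ttests <- NULL
  if (isTRUE(config$do_pvc)) {
    say("GTM partial-volume correction (fwhm %.1f mm)", config$pvc_fwhm_mm)
    g <- build_gtm(atlas, config$pvc_fwhm_mm)
    key <- interaction(table$subject, table$measure, drop = TRUE)
    parts <- lapply(split(table, key), function(t) {
      t <- t[match(g$regions, t$region), ]
      t$value <- gtm_correct(t$value, g)$corrected
      t
    })
    pvc_table <- do.call(rbind, parts)
    rownames(pvc_table) <- NULL
    pvc_ttests <- lapply(stats::setNames(measures, measures), function(m)
      group_ttests_fdr(pvc_table, m, groups = glev))
  }

  # ---- voxelwise permutation tests ----
  voxelwise <- NULL
  if (isTRUE(config$do_voxelwise)) {
    voxelwise <- list()
    for (m in intersect(config$voxelwise_measures, measures)) {
      say("voxelwise permutation test: %s", m)
      voxelwise[[m]] <- voxelwise_permutation_test(
        maps[[m]][groups == glev[1L]], maps[[m]][groups == glev[2L]],
        p_voxel = config$p_voxel, alpha_cluster = config$alpha_cluster,
        n_perm = config$n_perm, seed = config$seed, mask = bmask)
    }
  }

  # ---- outputs ----
  if (!is.null(out)) {
    say("writing outputs to %s", out)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    wtab <- function(df, name) {
      p <- file.path(out, name)
      utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
      emit(p)
    }
    wtab(table, "regional_table.tsv")
    wtab(regressions, "regressions.tsv")
    for (m in measures)
      wtab(ttests[[m]], sprintf("ttests_fdr_%s.tsv", m))
    ba_df <- do.call(rbind, lapply(names(ba), function(nm) {
      b <- ba[[nm]]
      if (is.null(b)) return(NULL)
      data.frame(comparison = nm, bias = b$bias, sd_diff = b$sd_diff,
                 loa_low = b$loa_low, loa_high = b$loa_high, n = b$n)
    }))
    wtab(ba_df, "bland_altman.tsv")
    wtab(data.frame(subject = subj_ids, group = groups, k2_prime = k2p),
         "k2prime.tsv")
    if (!is.null(pvc_table)) {
      wtab(pvc_table, "regional_table_pvc.tsv")
      for (m in measures)
        wtab(pvc_ttests[[m]], sprintf("ttests_fdr_pvc_%s.tsv", m))
    }
    for (nm in names(images)) {
      p <- file.path(out, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nii.gz"))
      write_nifti_array(images[[nm]]$voxels, images[[nm]]$voxel_size_mm, p)
      emit(p)
    }
    if (!is.null(voxelwise)) {
      for (m in names(voxelwise)) {
        vr <- voxelwise[[m]]
        p <- file.path(out, sprintf("tmap_%s.nii.gz", m))
        tm <- vr$t_map; tm[!is.finite(tm)] <- 0
        write_nifti_array(tm, atlas$voxel_size_mm, p); emit(p)
        wtab(vr$clusters, sprintf("clusters_%s.tsv", m))
        pj <- file.path(out, sprintf("voxelwise_%s.json", m))
        jsonlite::write_json(list(measure = m, t_threshold = vr$t_threshold,
                                  df = vr$df, n_perm = vr$n_perm_used,
                                  p_voxel = vr$p_voxel,
                                  alpha_cluster = vr$alpha_cluster),
                             pj, auto_unbox = TRUE, digits = NA)
        emit(pj)
      }
    }
    cfg_out <- config
    cfg_out$theta_grid <- range(config$theta_grid)
    cfg_out$intervals <- lapply(config$intervals, unlist)
    mf <- file.path(out, "manifest.json")
    jsonlite::write_json(list(
      package = "petflow",
      version = as.character(utils::packageVersion("petflow")),
      seed = config$seed,
      config = cfg_out[setdiff(names(cfg_out), "out_dir")],
      config_hash = sum(utf8ToInt(paste(utils::capture.output(
        utils::str(cfg_out)), collapse = ""))),
      files = basename(manifest),
      elapsed_s = unname(proc.time()[3L] - t0)),
      mf, auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, mf)
  }
  say("done in %.1f s", proc.time()[3L] - t0)
  invisible(list(cohort = cohort, table = table, regressions = regressions,
                 ttests = ttests, bland_altman = ba, images = images,
                 pvc_table = pvc_table, pvc_ttests = pvc_ttests,
                 voxelwise = voxelwise, k2_prime = k2p,
                 manifest = manifest, config = config))
}
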