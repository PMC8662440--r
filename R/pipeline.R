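#' Default pipeline configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()]. Any
#' element can be overridden by passing a replacement list with the same
#' names; unnamed defaults are kept.
#'
#' @param simulate simulation block: `preset` (plot label, see
#'   [plot_preset()]), `transform` (the rigid offset of the BLS frame),
#'   `taper` (optional override of the truth taper), `uls`/`bls` sampler
#'   arguments.
#' @param inputs alternative to `simulate`: paths to XYZ clouds and CSV
#'   control points / reference lists (`uls`, `bls`, `control_uls`,
#'   `control_bls`, `reference`).
#' @param stages logical stage toggles: `bls`, `register`, `taper`,
#'   `volume`.
#' @param preprocess,uls_seg,bls_seg,register,taper,volume per-stage
#'   parameter blocks; see the stage functions for the meaning of each
#'   entry.
#' @param out_dir optional directory for per-stage output files.
#' @param seed global seed; every stochastic stage derives its stream from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            stages = list(), preprocess = list(),
                            uls_seg = list(), bls_seg = list(),
                            register = list(), taper = list(),
                            volume = list(), out_dir = NULL, seed = 1) {
  merge_block <- function(defaults, user) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  cfg <- list(
    simulate = merge_block(list(
      preset = "b",
      transform = rigid2d(0.05, 5, -3),
      taper = NULL,
      uls = list(density = 84, ground_density = 9, noise_sigma = 0.03),
      bls = list(pts_per_stem_slice = 200, noise_sigma = 0.01,
                 height_cap = 9)), simulate),
    inputs = inputs,
    stages = merge_block(list(bls = TRUE, register = TRUE, taper = TRUE,
                              volume = TRUE), stages),
    # denoise_bls is off by default: the k-NN filter's global threshold
    # assumes roughly homogeneous density, and an under-canopy cloud mixes
    # very dense stem returns with sparse ground returns, which a global
    # threshold would strip wholesale
    preprocess = merge_block(list(denoise = TRUE, denoise_bls = FALSE,
                                  k = 8, n_sigma = 3,
                                  seed_cell = 5, max_angle = 8,
                                  max_dist = 0.5, cell = 1,
                                  idw_power = 2, idw_k = 12), preprocess),
    uls_seg = merge_block(list(t1 = 2, t2 = NULL, h_min = 2,
                               min_points = 30), uls_seg),
    bls_seg = merge_block(list(eps = 0.2, minpts = 15,
                               heights = seq(1.3, 8.3, by = 1)), bls_seg),
    register = merge_block(list(max_pair_dist = 2, max_iter = 50,
                                tol = 1e-6), register),
    taper = merge_block(list(models = c("M1", "M2", "M3", "M4", "M5")),
                        taper),
    volume = merge_block(list(plot_area = NULL, tolerance = 0.05,
                              dbh_step = 2, h_step = 1), volume),
    out_dir = out_dir,
    seed = seed
  )
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(report, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  message(msg)
  report$log <- c(report$log, msg)
  report
}

#' Run the full near-field LiDAR workflow
#'
#' Executes simulate/ingest -> preprocess -> ULS crown segmentation -> BLS
#' trunk detection -> co-registration -> stem profiles -> taper fitting and
#' selection -> volume table -> stand volume, and returns a structured
#' report. With simulated input the report additionally scores detection
#' against the ground truth, compares the recovered transform with the
#' applied one, and refits the generating taper model from the measured
#' stem diameters paired with the true (D, H) covariates (the
#' simulation-mode recovery diagnostic; see the methods vignette for why
#' the production fit, which uses measured covariates, is not the right
#' yardstick for coefficient recovery).
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list; principal elements: `uls_trees`,
#'   `bls_trunks`, `registration`, `samples`, `fits`, `selected_fit`,
#'   `volume_table`, `plot_summary`, and (simulation mode) `truth`,
#'   `uls_detection`, `bls_detection`, `transform_error_m`,
#'   `recovery_fit`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  rep <- list(log = character(), config = cfg)

  # ---- stage: simulate or ingest -----------------------------------------
  simulated <- is.null(cfg$inputs)
  if (simulated) {
    pre <- plot_preset(cfg$simulate$preset)
    taper <- cfg$simulate$taper
    if (is.null(taper)) taper <- list(model = "M4", coefficients = 1.417)
    truth <- generate_plot(pre$species, pre$row_spacing, pre$col_spacing,
                           thinning = pre$thinning, taper = taper,
                           seed = cfg$seed)
    tr_applied <- cfg$simulate$transform
    uls_scan <- do.call(sample_uls_cloud,
                        c(list(truth = truth, seed = cfg$seed + 1),
                          cfg$simulate$uls))
    bls_scan <- do.call(sample_bls_cloud,
                        c(list(truth = truth, transform = tr_applied,
                               seed = cfg$seed + 2), cfg$simulate$bls))
    ctrl <- simulate_control_points(truth, tr_applied,
                                    seed = cfg$seed + 3)
    uls_cloud <- uls_scan$cloud
    bls_cloud <- bls_scan$cloud
    rep$truth <- truth
    rep <- pipeline_log(rep, "simulate",
                        sprintf("preset %s: %d trees, ULS %d pts, BLS %d pts",
                                cfg$simulate$preset, nrow(truth$trees),
                                nrow(uls_cloud), nrow(bls_cloud)))
  } else {
    uls_cloud <- read_xyz(cfg$inputs$uls)
    bls_cloud <- if (!is.null(cfg$inputs$bls)) read_xyz(cfg$inputs$bls)
    ctrl <- NULL
    if (!is.null(cfg$inputs$control_uls))
      ctrl <- list(uls = utils::read.csv(cfg$inputs$control_uls),
                   bls = utils::read.csv(cfg$inputs$control_bls))
    rep <- pipeline_log(rep, "ingest",
                        sprintf("ULS %d pts", nrow(uls_cloud)))
  }

  # ---- stage: preprocess -------------------------------------------------
  pp <- cfg$preprocess
  prep <- function(cloud, tag) {
    do_denoise <- if (tag == "BLS") isTRUE(pp$denoise_bls)
                  else isTRUE(pp$denoise)
    if (do_denoise)
      cloud <- suppressWarnings(remove_outliers(cloud, pp$k, pp$n_sigma))
    cloud <- classify_ground(cloud, pp$seed_cell, pp$max_angle, pp$max_dist)
    dem <- build_dem(cloud, pp$cell, pp$idw_power, pp$idw_k)
    cloud <- normalize_heights(cloud, dem)
    rep <<- pipeline_log(rep, "preprocess",
                         sprintf("%s: %d pts, %d ground, DEM %dx%d",
                                 tag, nrow(cloud),
                                 sum(cloud$class == "ground"),
                                 nrow(dem$z), ncol(dem$z)))
    list(cloud = cloud, dem = dem)
  }
  uls <- prep(uls_cloud, "ULS")
  rep$uls_dem <- uls$dem

  # ---- stage: ULS segmentation -------------------------------------------
  us <- cfg$uls_seg
  t2 <- us$t2
  if (is.null(t2))
    t2 <- if (simulated) truth$row_spacing / 2 else 2.5
  seg <- segment_trees(uls$cloud, us$t1, t2, us$h_min, us$min_points)
  rep$uls_trees <- seg$trees
  rep <- pipeline_log(rep, "detect-uls",
                      sprintf("%d trees (t1=%.1f, t2=%.1f)",
                              nrow(seg$trees), us$t1, t2))
  if (simulated) {
    # detections count as correct inside the crown of an inventory tree
    refs <- data.frame(x = truth$trees$x, y = truth$trees$y,
                       crown_radius = truth$trees$crown_radius)
    mm <- match_detections(seg$trees, refs)
    rep$uls_detection <- detection_metrics(mm$Nt, mm$No, mm$Nc)
  }

  if (!isTRUE(cfg$stages$bls) || is.null(bls_cloud)) {
    rep <- pipeline_log(rep, "stop",
                        "BLS stage disabled: no DBH source, pipeline ends ",
                        "after ULS outputs")
    class(rep) <- "pipeline_report"
    return(rep)
  }

  # ---- stage: BLS trunk detection ----------------------------------------
  bls <- prep(bls_cloud, "BLS")
  rep$bls_dem <- bls$dem
  bs <- cfg$bls_seg
  sl <- slice_cloud(bls$cloud, 1.3, 0.1)
  tk <- detect_trunks(sl, bs$eps, bs$minpts)
  rep$bls_trunks <- tk$trunks
  rep <- pipeline_log(rep, "detect-bls",
                      sprintf("%d trunks (eps=%.2f, minpts=%d)",
                              nrow(tk$trunks), bs$eps, bs$minpts))
  if (simulated) {
    inv_true <- invert_rigid(bls_scan$applied_transform)
    tk_plot <- apply_rigid(inv_true, as.matrix(tk$trunks[, c("x", "y")]))
    refs <- data.frame(x = truth$trees$x, y = truth$trees$y,
                       crown_radius = truth$trees$crown_radius)
    mm <- match_detections(data.frame(x = tk_plot[, 1], y = tk_plot[, 2]),
                           refs)
    rep$bls_detection <- detection_metrics(mm$Nt, mm$No, mm$Nc)
  }

  # ---- stage: co-registration --------------------------------------------
  if (isTRUE(cfg$stages$register)) {
    init <- if (!is.null(ctrl))
      rigid_from_control_points(ctrl$bls, ctrl$uls) else rigid2d()
    reg <- refine_by_tree_matching(rep$uls_trees, tk$trunks, init,
                                   cfg$register$max_pair_dist,
                                   cfg$register$max_iter,
                                   cfg$register$tol)
    rep$registration <- reg
    rep <- pipeline_log(rep, "register",
                        sprintf("%d matches, mean error %.1f cm, %d iter",
                                nrow(reg$matches),
                                registration_error(reg$matches),
                                reg$iterations))
    if (simulated) {
      inv_true <- invert_rigid(bls_scan$applied_transform)
      b_xy <- as.matrix(tk$trunks[, c("x", "y")])
      rep$transform_error_m <- mean(sqrt(rowSums(
        (apply_rigid(reg$transform, b_xy) -
           apply_rigid(inv_true, b_xy))^2)))
    }
  } else {
    rep$registration <- NULL
  }

  # ---- stage: stem profiles + taper samples ------------------------------
  if (!isTRUE(cfg$stages$taper)) {
    class(rep) <- "pipeline_report"
    return(rep)
  }
  matches <- if (!is.null(rep$registration)) rep$registration$matches
             else data.frame(uls_id = tk$trunks$id, bls_id = tk$trunks$id)
  profs <- list()
  samples <- list()
  for (r in seq_len(nrow(matches))) {
    bls_id <- matches$bls_id[r]
    trunk <- tk$trunks[tk$trunks$id == bls_id, ]
    prof <- stem_profile(bls$cloud, trunk, bs$heights, bs$eps, bs$minpts)
    profs[[r]] <- prof
    if (nrow(prof) == 0) next
    uls_row <- rep$uls_trees[rep$uls_trees$id == matches$uls_id[r], ]
    if (nrow(uls_row) != 1) next
    samples[[r]] <- data.frame(tree_id = bls_id, D = trunk$D, H = uls_row$H,
                               h = prof$h, d = prof$d)
  }
  rep$profiles <- profs
  samples <- do.call(rbind, samples)
  if (is.null(samples) || nrow(samples) == 0)
    stop("profile stage produced no diameter-height samples")
  samples <- samples[samples$h < samples$H, , drop = FALSE]
  rep$samples <- samples
  rep <- pipeline_log(rep, "profile",
                      sprintf("%d diameter-height samples from %d trees",
                              nrow(samples), length(unique(samples$tree_id))))

  # ---- stage: taper fitting ----------------------------------------------
  fits <- list()
  for (mdl in cfg$taper$models) {
    f <- tryCatch(fit_taper(samples, model = mdl),
                  error = function(e) e)
    if (inherits(f, "taper_fit")) fits[[mdl]] <- f
    else rep <- pipeline_log(rep, "fit-taper",
                             sprintf("%s failed: %s", mdl,
                                     conditionMessage(f)))
  }
  if (length(fits) == 0) stop("taper stage failed: no model converged")
  rep$fits <- fits
  rep$selected_fit <- select_model(fits)
  rep <- pipeline_log(rep, "fit-taper",
                      sprintf("selected %s (RMSE %.2f cm)",
                              rep$selected_fit$model,
                              rep$selected_fit$stats$RMSE))

  if (simulated) {
    # recovery diagnostic: measured stem diameters + true covariates
    inv_true <- invert_rigid(bls_scan$applied_transform)
    tk_plot <- apply_rigid(inv_true, as.matrix(tk$trunks[, c("x", "y")]))
    rec <- list()
    for (r in seq_len(nrow(matches))) {
      prof <- profs[[r]]
      if (is.null(prof) || nrow(prof) == 0) next
      bi <- which(tk$trunks$id == matches$bls_id[r])
      d2t <- (tk_plot[bi, 1] - truth$trees$x)^2 +
        (tk_plot[bi, 2] - truth$trees$y)^2
      ti <- which.min(d2t)
      if (sqrt(d2t[ti]) > 1) next
      rec[[r]] <- data.frame(tree_id = truth$trees$id[ti],
                             D = truth$trees$D[ti], H = truth$trees$H[ti],
                             h = prof$h, d = prof$d)
    }
    rec <- do.call(rbind, rec)
    rec <- rec[rec$h < rec$H, , drop = FALSE]
    if (!is.null(rec) && nrow(rec) > 0) {
      rep$recovery_fit <- tryCatch(
        fit_taper(rec, model = truth$taper$model), error = function(e) e)
      rep$recovery_samples <- rec
    }
  }

  # ---- stage: volume -----------------------------------------------------
  if (isTRUE(cfg$stages$volume)) {
    vv <- cfg$volume
    tree_list <- unique(samples[, c("tree_id", "D", "H")])
    dd <- range(tree_list$D)
    hh <- range(tree_list$H)
    dbh_classes <- seq(floor(dd[1] / vv$dbh_step) * vv$dbh_step,
                       ceiling(dd[2] / vv$dbh_step) * vv$dbh_step,
                       by = vv$dbh_step)
    height_classes <- seq(floor(hh[1]), ceiling(hh[2]), by = vv$h_step)
    rep$volume_table <- build_volume_table(rep$selected_fit,
                                           dbh_classes, height_classes)
    area <- vv$plot_area
    if (is.null(area))
      area <- if (simulated) truth$plot_size^2 else 900
    rep$plot_summary <- stand_volume(tree_list, rep$selected_fit, area,
                                     vv$tolerance)
    rep <- pipeline_log(rep, "volume",
                        sprintf("M = %.2f m3, stand volume %.2f m3/ha",
                                rep$plot_summary$M,
                                rep$plot_summary$stand_volume))
  }

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(rep, cfg$out_dir)
  class(rep) <- "pipeline_report"
  rep
}

# plain-file outputs so every stage can be inspected and rerun in isolation
write_pipeline_outputs <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  if (!is.null(rep$uls_trees)) w(rep$uls_trees, "uls_trees.csv")
  if (!is.null(rep$bls_trunks)) w(rep$bls_trunks, "bls_trunks.csv")
  if (!is.null(rep$registration))
    w(rep$registration$matches, "matches.csv")
  if (!is.null(rep$samples)) w(rep$samples, "taper_samples.csv")
  if (!is.null(rep$volume_table))
    utils::write.csv(as.data.frame(unclass(rep$volume_table)),
                     file.path(out_dir, "volume_table.csv"))
  if (!is.null(rep$log))
    writeLines(rep$log, file.path(out_dir, "pipeline.log"))
  manifest <- list.files(out_dir)
  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
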