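# Orchestration of the six-step intra-extraoral registration workflow and
# the study's two experiments on synthetic data: "scannability" (scan vs.
# original geometry) and "in-face" (geometry aligned within the facial
# scan). Everything is seed-deterministic.

#' Workflow configuration
#'
#' Noise and smoothing default to paper scale (0.05 mm accuracy, radiused
#' edges); sample spacings are coarser than the 0.1 mm scanner resolution so
#' a full synthetic run fits a desktop CPU — the vignette discusses this
#' scaling.
#'
#' @param seed master seed; all per-stage seeds derive from it.
#' @param noise_sigma scanner noise s.d. [mm].
#' @param smoothing_iters edge-radiusing passes.
#' @param landmark_sigma s.d. of the operator's point-picking jitter [mm].
#' @param tray_spacing,face_spacing scan sampling spacings [mm].
#' @param model_perturb_deg,model_perturb_mm initial misplacement of the
#'   plaster-model frame the gumline ICP must recover.
#' @param out_dir optional directory for intermediate artifacts (STL/JSON).
#' @param verbose print step-tagged log lines.
#' @export
workflow_config <- function(seed = 1L, noise_sigma = 0.05, smoothing_iters = 3L,
                            landmark_sigma = 0.15, tray_spacing = 1.0,
                            face_spacing = 3.0, model_perturb_deg = 3,
                            model_perturb_mm = 3, out_dir = NULL,
                            verbose = FALSE) {
  stopifnot(noise_sigma >= 0, landmark_sigma >= 0, tray_spacing > 0)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 smoothing_iters = as.integer(smoothing_iters),
                 landmark_sigma = landmark_sigma, tray_spacing = tray_spacing,
                 face_spacing = face_spacing,
                 model_perturb_deg = model_perturb_deg,
                 model_perturb_mm = model_perturb_mm,
                 out_dir = out_dir, verbose = verbose),
            class = "workflow_config")
}

wf_log <- function(cfg, step, msg) {
  line <- sprintf("[%s] step=%d %s", format(Sys.time(), "%H:%M:%OS2"), step, msg)
  if (isTRUE(cfg$verbose)) cat(line, "\n")
  line
}

#' Synthetic six-step registration scene with ground truth
#'
#' Builds the full stated world of one virtual participant: a face
#' surrogate; a tray plate carrying BOTH fiducial assemblies (sphere and
#' cross — two separated markers pin all six degrees of freedom; a lone
#' sphere leaves rotation about its centre unobservable) and the maxillary
#' impression (the normal-inverted arch); ground-truth poses for tray,
#' maxilla model and mandible; noisy landmark picks.
#'
#' @param config a [workflow_config].
#' @return list of meshes, landmark sets, regions and ground-truth
#'   transforms (`truth$maxilla`, `truth$mandible`, `truth$tray_to_face`).
#' @export
make_workflow_scene <- function(config = workflow_config()) {
  seed <- config$seed
  face <- make_face_surrogate(seed = seed)
  arch <- make_arch_surrogate(n_teeth = 14L, seed = seed)

  plate <- box_mesh(c(-45, -6, -2), c(45, 6, 2))
  sp_spec <- fiducial_spec("sphere")
  cr_spec <- fiducial_spec("cross")
  sphere_asm <- mesh_translate(attach_to_base(make_sphere_marker(
    sp_spec$sphere_radius, refinement = 2), sp_spec), c(-30, 0, 12))
  cross_asm <- mesh_translate(attach_to_base(make_cross_marker(cr_spec), cr_spec),
                              c(30, 0, 12))
  arch_tray_offset <- c(0, 14, -16)
  arch_tray <- mesh_translate(arch, arch_tray_offset)    # positive anatomy, tray frame
  impression <- invert_normals(arch_tray)                # what the silicone records
  tray_extraoral <- mesh_concat(plate, sphere_asm, cross_asm, name = "tray_extraoral")
  tray_full <- mesh_concat(plate, sphere_asm, cross_asm, impression,
                           name = "tray_with_impression")

  # ground-truth tray pose in the face frame: in front of the lower face
  t_tray_face <- rigid_transform(rot_axis_angle(c(1, 0, 0), -8), c(0, -45, 72))

  # landmark picks on the fiducial surfaces (3 per marker, well spread)
  sc <- c(-30, 0, 12) + sp_spec$mount_offset
  r <- sp_spec$sphere_radius
  sphere_lm <- rbind(sc + c(r, 0, 0), sc + c(0, r, 0), sc + c(0, 0, r))
  cc <- c(30, 0, 12) + cr_spec$mount_offset
  L <- cr_spec$cross_arm_length / 2; d <- cr_spec$cross_arm_depth / 2
  cross_lm <- rbind(cc + c(L, 0, 0), cc + c(0, L, 0), cc + c(-L, 0, d))
  lm_tray <- rbind(sphere_lm, cross_lm)
  lm_face <- rt_apply(t_tray_face, lm_tray)
  jit <- function(p) p + matrix(stats::rnorm(length(p), 0, config$landmark_sigma),
                                nrow(p), 3)
  lms <- with_seed(seed + 101L, list(tray = jit(lm_tray), face = jit(lm_face)))

  # plaster-model frame: the arch perturbed by a small known rigid motion
  q <- with_seed(seed + 202L, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, -1, 1) * config$model_perturb_deg
    tr <- stats::runif(3, -1, 1) * config$model_perturb_mm
    rigid_transform(rot_axis_angle(ax, ang), tr)
  })
  maxilla_model <- rt_apply(q, arch_tray)
  maxilla_model$name <- "maxilla_model"
  truth_maxilla <- rt_compose(t_tray_face, rt_invert(q))

  # mandible: arch flipped cusp-down, posed by a fixed interocclusal relation
  mand <- rt_apply(rigid_transform(rot_axis_angle(c(1, 0, 0), 180)), arch_tray)
  mand$name <- "mandible_model"
  w <- rigid_transform(diag(3), c(0, 0, -24))  # mandible -> maxilla-model frame
  occl_mand_pts <- pick_spread_vertices(mand, 4L)
  occl_max_pts <- rt_apply(w, occl_mand_pts)
  occl <- with_seed(seed + 303L,
                    list(mand = jit(occl_mand_pts), max = jit(occl_max_pts)))
  truth_mandible <- rt_compose(truth_maxilla, w)

  impression_region <- region_box(arch_tray_offset + c(-30, -8, -12),
                                  arch_tray_offset + c(30, 48, 16))

  list(face = face, arch = arch, tray_extraoral = tray_extraoral,
       tray_full = tray_full, impression_region = impression_region,
       maxilla_model = maxilla_model, mandible_model = mand,
       landmarks_tray = landmark_set(lms$tray),
       landmarks_face = landmark_set(lms$face),
       occlusion_mand = landmark_set(occl$mand),
       occlusion_max = landmark_set(occl$max),
       truth = list(tray_to_face = t_tray_face, maxilla = truth_maxilla,
                    mandible = truth_mandible, model_perturb = q))
}

# axis-aligned box as a watertight 12-triangle mesh
box_mesh <- function(lo, hi, name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6),   # -x, +x
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),   # -y, +y
             c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7))   # -z, +z
  triangle_mesh(v, f, name = name)
}

#' Run the six-step workflow on a synthetic scene
#'
#' Steps: (1) facial scan with the tray in situ, (2) extraoral scan of the
#' tray with impression, (3) segmentation, (4) fiducial alignment,
#' (5) impression crop + normal inversion + gumline model fit, (6) occlusal
#' mandible placement. Returns the placed transforms, their error against
#' ground truth, per-alignment deviation reports and a step-tagged log.
#'
#' @param config a [workflow_config].
#' @return a `workflow_report` list.
#' @export
run_six_step_workflow <- function(config = workflow_config()) {
  stopifnot(inherits(config, "workflow_config"))
  scene <- make_workflow_scene(config)
  log <- character(0)

  sc_face <- scan_config(noise_sigma = config$noise_sigma,
                         sample_spacing = config$face_spacing,
                         smoothing_iters = config$smoothing_iters,
                         seed = config$seed + 11L)
  sc_trayface <- scan_config(noise_sigma = config$noise_sigma,
                             sample_spacing = config$tray_spacing,
                             smoothing_iters = config$smoothing_iters,
                             seed = config$seed + 12L)
  sc_tray <- scan_config(noise_sigma = config$noise_sigma,
                         sample_spacing = config$tray_spacing,
                         smoothing_iters = config$smoothing_iters,
                         seed = config$seed + 13L)

  # step 1: face scan (face context coarse, tray-in-face at tray resolution)
  face_scan <- mesh_concat(
    simulate_scan(scene$face, sc_face),
    simulate_scan(rt_apply(scene$truth$tray_to_face, scene$tray_extraoral),
                  sc_trayface),
    name = "face_scan")
  log <- c(log, wf_log(config, 1L, sprintf("face scan: %d vertices",
                                           nrow(face_scan$vertices))))
  # step 2: extraoral scan of tray + impression
  tray_scan <- simulate_scan(scene$tray_full, sc_tray)
  log <- c(log, wf_log(config, 2L, sprintf("tray scan: %d vertices",
                                           nrow(tray_scan$vertices))))
  # step 3: segmentation sanity (components of the tray scan)
  n_comp <- length(connected_components(tray_scan, connectivity = "vertex"))
  log <- c(log, wf_log(config, 3L, sprintf("tray scan segments into %d components", n_comp)))

  chain <- chain_to_face_frame(
    face_scan, tray_scan,
    scene$landmarks_tray, scene$landmarks_face,
    scene$impression_region,
    scene$maxilla_model, scene$mandible_model,
    scene$occlusion_mand, scene$occlusion_max)
  log <- c(log, wf_log(config, 4L, sprintf("fiducial alignment rms %.4f mm",
                                           chain$fiducial_result$final_rms)))
  log <- c(log, wf_log(config, 5L, sprintf("gumline fit rms %.4f mm",
                                           chain$maxilla_fit$final_rms)))
  log <- c(log, wf_log(config, 6L, "mandible posed by occlusal landmarks"))

  err_max <- rt_difference(scene$truth$maxilla, chain$maxilla,
                           points = scene$maxilla_model$vertices)
  err_mand <- rt_difference(scene$truth$mandible, chain$mandible,
                            points = scene$mandible_model$vertices)

  report <- list(config = config, scene = scene, face_scan = face_scan,
                 tray_scan = tray_scan, chain = chain,
                 maxilla_error = err_max, mandible_error = err_mand,
                 alignment_rms = c(fiducial = chain$fiducial_result$final_rms,
                                   gumline = chain$maxilla_fit$final_rms),
                 log = log)
  class(report) <- "workflow_report"
  if (!is.null(config$out_dir)) write_workflow_artifacts(report, config$out_dir)
  report
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>\n")
  cat(sprintf("  maxilla placement error: %.4f mm RMS (%.4f deg, %.4f mm)\n",
              x$maxilla_error$rms_mm, x$maxilla_error$angle_deg,
              x$maxilla_error$translation_mm))
  cat(sprintf("  mandible placement error: %.4f mm RMS\n", x$mandible_error$rms_mm))
  cat(sprintf("  alignment rms: fiducial %.4f, gumline %.4f mm\n",
              x$alignment_rms["fiducial"], x$alignment_rms["gumline"]))
  invisible(x)
}

write_workflow_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stl(report$face_scan, file.path(out_dir, "face_scan.stl"))
  write_stl(report$tray_scan, file.path(out_dir, "tray_scan.stl"))
  write_stl(report$chain$positive, file.path(out_dir, "positive_counterfeit.stl"))
  tf <- list(maxilla = rt_to_matrix(report$chain$maxilla),
             mandible = rt_to_matrix(report$chain$mandible),
             tray_to_face = rt_to_matrix(report$chain$tray_to_face))
  jsonlite::write_json(tf, file.path(out_dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  writeLines(report$log, file.path(out_dir, "workflow.log"))
  invisible(out_dir)
}

pick_spread_vertices <- function(mesh, k) {
  idx <- as.integer(seq(1L, nrow(mesh$vertices), length.out = k + 2L))[2:(k + 1L)]
  mesh$vertices[idx, , drop = FALSE]
}

#' Sphere-vs-cross geometry comparison on synthetic subjects
#'
#' For each synthetic subject, both default markers are virtually scanned
#' and scored by RMSE against the pristine geometry (`mode = "scannability"`,
#' the Table-1-style design), or two independent scans per marker are
#' registered to each other and scored scan-to-scan (`mode = "in_face"`, a
#' desk-scale surrogate of the Table-2 design). Returns the paired table,
#' summaries and both rank tests.
#'
#' @param n_subjects number of synthetic subjects, >= 2.
#' @param config a [scan_config] template (its seed is overridden per
#'   subject and marker).
#' @param seed base seed.
#' @param mode `"scannability"` or `"in_face"`.
#' @param align if TRUE, ICP-refine each scan onto its reference before the
#'   deviation (the simulator already emits scans in the reference frame, so
#'   this is off by default).
#' @return list with `table` (data.frame: participant, rmse_sphere,
#'   rmse_cross), `samples` ([paired_samples]), `summary_sphere`,
#'   `summary_cross`, `signed_rank`, `rank_sum`.
#' @export
run_geometry_comparison <- function(n_subjects = 10L,
                                    config = scan_config(noise_sigma = 0.05,
                                                         sample_spacing = 0.5,
                                                         smoothing_iters = 3L),
                                    seed = 1L, mode = c("scannability", "in_face"),
                                    align = FALSE) {
  mode <- match.arg(mode)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  sphere <- make_sphere_marker(fiducial_spec("sphere")$sphere_radius)
  cross <- make_cross_marker(fiducial_spec("cross"))
  score <- function(marker, s) {
    cfg <- config
    cfg$seed <- s
    scan <- simulate_scan(marker, cfg)
    if (mode == "in_face") {
      cfg2 <- config
      cfg2$seed <- s + 500000L
      ref <- simulate_scan(marker, cfg2)
      fit <- icp(scan, ref, reject_distance_mm = 2.0, max_iterations = 30L)
      return(surface_deviation(rt_apply(fit$transform, scan), ref,
                               sample_spacing = config$sample_spacing)$rmse)
    }
    if (align) {
      fit <- icp(scan, marker, reject_distance_mm = 2.0, max_iterations = 30L)
      scan <- rt_apply(fit$transform, scan)
    }
    surface_deviation(scan, marker, sample_spacing = config$sample_spacing)$rmse
  }
  rs <- numeric(n_subjects); rc <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    rs[i] <- score(sphere, seed * 1000L + 2L * i)
    rc[i] <- score(cross, seed * 1000L + 2L * i + 1L)
  }
  tab <- data.frame(participant = seq_len(n_subjects),
                    rmse_sphere = rs, rmse_cross = rc)
  samples <- paired_samples(rs, rc)
  list(table = tab, samples = samples,
       summary_sphere = summarize_values(rs),
       summary_cross = summarize_values(rc),
       signed_rank = tryCatch(wilcoxon_signed_rank(samples),
                              error = function(e) NULL),
       rank_sum = mann_whitney_exact(rs, rc),
       mode = mode)
}

#' Recompute the published summary tables from the packaged fixtures
#'
#' Recomputes every "Mean (range)" cell and the test statistics from the
#' fixture CSVs and flags each against the printed value. Two printed
#' numbers are known not to reproduce and are flagged as mismatches rather
#' than patched: the scannability cross mean (printed 0.36, arithmetic mean
#' of the printed cells is 0.354 -> 0.35) and the in-face p-value (printed
#' 0.70; no standard zero/tie convention of the signed-rank test yields it).
#'
#' @return data.frame with columns `table`, `quantity`, `computed`,
#'   `printed`, `match`.
#' @export
reproduce_paper_tables <- function() {
  t1 <- load_rmse_table("scannability")
  t2 <- load_rmse_table("in_face")
  p1 <- mann_whitney_exact(t1$rmse_sphere, t1$rmse_cross)$p_two_sided
  w2 <- wilcoxon_signed_rank(paired_samples(t2$rmse_sphere, t2$rmse_cross))
  rows <- list(
    c("scannability", "sphere mean (range)", mean_range_label(t1$rmse_sphere), "0.24 (0.23-0.28)"),
    c("scannability", "cross mean (range)", mean_range_label(t1$rmse_cross), "0.36 (0.33-0.40)"),
    c("scannability", "p (exact rank-sum)", sprintf("%.4f", p1), "< 0.008"),
    c("in_face", "sphere mean (range)", mean_range_label(t2$rmse_sphere), "0.32 (0.19-0.41)"),
    c("in_face", "cross mean (range)", mean_range_label(t2$rmse_cross), "0.36 (0.25-0.46)"),
    c("in_face", "p (signed-rank, zeros dropped)", sprintf("%.4f", w2$p_two_sided), "0.70"))
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- c("table", "quantity", "computed", "printed")
  out$match <- c(out$computed[1] == out$printed[1],
                 out$computed[2] == out$printed[2],
                 p1 < 0.008,
                 out$computed[4] == out$printed[4],
                 out$computed[5] == out$printed[5],
                 abs(w2$p_two_sided - 0.70) < 0.005)
  out
}

#' Repetition study: variance of the virtual alignment workflow
#'
#' Re-runs the alignment stages (from segmentation onward) on FIXED scans of
#' one scene, re-randomizing only the landmark picks — the paper's tenfold
#' repetition restarts from digitized models, so scan noise is frozen and
#' operator picking is the replicated step. Each repetition's posed maxilla
#' is compared to the first (base) repetition by placement RMS.
#'
#' @param n_repetitions replicate count (the study used 10).
#' @param config a [workflow_config].
#' @return list with `rmse` (length `n_repetitions`) and `stats`
#'   (`summary_stats` via [repetition_analysis()]).
#' @export
run_repetition_study <- function(n_repetitions = 10L,
                                 config = workflow_config()) {
  scene <- make_workflow_scene(config)
  sc_tray <- scan_config(noise_sigma = config$noise_sigma,
                         sample_spacing = config$tray_spacing,
                         smoothing_iters = config$smoothing_iters,
                         seed = config$seed + 13L)
  sc_trayface <- scan_config(noise_sigma = config$noise_sigma,
                             sample_spacing = config$tray_spacing,
                             smoothing_iters = config$smoothing_iters,
                             seed = config$seed + 12L)
  face_scan <- simulate_scan(rt_apply(scene$truth$tray_to_face, scene$tray_extraoral),
                             sc_trayface)
  tray_scan <- simulate_scan(scene$tray_full, sc_tray)
  lm_true_tray <- scene$landmarks_tray$points
  lm_true_face <- rt_apply(scene$truth$tray_to_face, lm_true_tray)
  one_rep <- function(k) {
    lms <- with_seed(config$seed + 7000L + k, {
      jt <- lm_true_tray + matrix(stats::rnorm(length(lm_true_tray), 0,
                                               config$landmark_sigma),
                                  nrow(lm_true_tray), 3)
      jf <- lm_true_face + matrix(stats::rnorm(length(lm_true_face), 0,
                                               config$landmark_sigma),
                                  nrow(lm_true_face), 3)
      list(t = jt, f = jf)
    })
    chain_to_face_frame(face_scan, tray_scan,
                        landmark_set(lms$t), landmark_set(lms$f),
                        scene$impression_region,
                        scene$maxilla_model, scene$mandible_model,
                        scene$occlusion_mand, scene$occlusion_max)$maxilla
  }
  base <- one_rep(0L)
  rmse <- vapply(seq_len(n_repetitions), function(k)
    rt_difference(base, one_rep(k), points = scene$maxilla_model$vertices)$rms_mm,
    numeric(1))
  list(rmse = rmse, stats = repetition_analysis(rmse))
}
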