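#' Named target ROIs of an atlas
#'
#' Returns one voxel set per distinct target name, pooling hemispheres
#' (the left/right labels of a bilateral region form one ROI).
#'
#' @param atlas a [label_atlas].
#' @param role roles to include (default `"target"`).
#' @return Named list of voxel-index vectors.
#' @export
target_rois <- function(atlas, role = "target") {
  tab <- atlas$table[atlas$table$role %in% role, ]
  nms <- unique(tab$name)
  stats::setNames(lapply(nms, function(nm)
    atlas_voxels(atlas, tab$label_id[tab$name == nm])), nms)
}

#' Default configuration for the phantom demonstration pipeline
#'
#' All tunables of [run_demo()] in one JSON-serializable list: phantom grid
#' shapes, tracer-collection size and noise, parcellation seed count and
#' ICA orders (4 to 9), fingerprint seed counts (10 mouse-analogue, 12
#' human-analogue), band-pass bands (0.01-0.25 Hz mouse, 0.01-0.1 Hz
#' human), QC thresholds (0.1 and 0.1) and RNG seeds.
#'
#' @param rng_seed master seed; the per-stage seeds are derived from it.
#' @return A nested list of class `pipeline_config`.
#' @export
demo_config <- function(rng_seed = 1L) {
  rng_seed <- as.integer(rng_seed)
  structure(list(
    grid = list(tracer_shape = c(40L, 60L, 30L),
                fmri_shape = c(24L, 30L, 16L),
                n_targets = 9L, bilateral = TRUE),
    tracer = list(n_experiments = 60L, noise_sd = 0.2,
                  frac_off_strip = 0.25, n_parcellation_seeds = 20L,
                  ica_orders = 4:9, n_fingerprint_seeds = 10L),
    fmri = list(
      mouse = list(n_subjects = 10L, n_timepoints = 250L, tr_s = 1,
                   band = c(0.01, 0.25), n_seeds = 10L, frac_bad = 0),
      human = list(n_subjects = 14L, n_timepoints = 250L, tr_s = 1,
                   band = c(0.01, 0.1), n_seeds = 12L, frac_bad = 0.2)),
    qc = list(thr_pos = 0.1, thr_neg = 0.1),
    seeds = list(atlas = rng_seed, tracer = rng_seed + 1L,
                 ica = rng_seed + 2L, mouse_fmri = rng_seed + 3L,
                 human_fmri = rng_seed + 4L),
    write_volumes = FALSE), class = c("pipeline_config", "list"))
}

#' Run the full phantom pipeline end to end
#'
#' simulate -> tracer similarity map -> ICA parcellation -> tracer
#' fingerprint -> rs-fMRI fingerprints for the mouse- and human-analogue
#' cohorts (with scan-level QC on the human side) -> repeated-measures
#' ANOVA per species -> cross-species fingerprint comparison. All tabular
#' outputs are written as TSV under `out_dir` together with a run log;
#' reruns with the same seeds are byte-identical. Any stage error aborts
#' with the stage name.
#'
#' @param config a [demo_config()] list (possibly edited).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the main in-memory results (`sweep`,
#'   `fp_tracer`, `fp_mouse`, `fp_human`, `anova`, `comparison`, `qc`).
#' @export
run_demo <- function(config = demo_config(), out_dir) {
  stopifnot(!missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }

  ## simulate: atlases and tracer collection
  atl_tr <- stage("simulate", build_phantom_atlas(
    config$grid$tracer_shape, config$grid$n_targets, config$grid$bilateral,
    rng_seed = config$seeds$atlas))
  atl_fm <- stage("simulate", build_phantom_atlas(
    config$grid$fmri_shape, config$grid$n_targets, config$grid$bilateral,
    rng_seed = config$seeds$atlas))
  stage("simulate", {
    write_label_atlas(atl_tr, file.path(out_dir, "atlas_tracer.nii.gz"),
                      file.path(out_dir, "atlas_tracer.tsv"))
    write_label_atlas(atl_fm, file.path(out_dir, "atlas_fmri.nii.gz"),
                      file.path(out_dir, "atlas_fmri.tsv"))
  })
  experiments <- stage("simulate", simulate_tracer_experiments(
    atl_tr, default_tracer_rules("mouse", config$tracer$noise_sd),
    config$tracer$n_experiments, rng_seed = config$seeds$tracer,
    frac_off_strip = config$tracer$frac_off_strip))
  stage("simulate", tsv(attr(experiments, "manifest"),
                        "tracer_manifest.tsv"))
  if (isTRUE(config$write_volumes))
    stage("simulate", write_tracer_experiments(
      experiments, file.path(out_dir, "tracer_volumes"),
      atl_tr$voxel_size_mm))

  ## tracer-map: projection similarity of the parcellation seeds
  sim <- stage("tracer-map", {
    n_seeds <- min(config$tracer$n_parcellation_seeds,
                   length(atlas_voxels(atl_tr,
                                       atlas_labels(atl_tr,
                                                    role = "seed_roi"))))
    sp <- place_seeds(atl_tr, n_seeds = n_seeds)
    strip_ids <- atlas_labels(atl_tr, role = "seed_roi")
    support <- which(atl_tr$labels > 0L &
                       !(atl_tr$labels %in% strip_ids))
    seed_d <- sample_density(experiments, sp)
    brain_d <- sample_density(experiments, brain_locations(atl_tr, support))
    s <- projection_similarity(seed_d, brain_d, seed_u = sp$u)
    tsv(data.frame(seed_index = seq_along(sp$u), u = sp$u,
                   voxel = unlist(sp$seeds)), "parcellation_seeds.tsv")
    s
  })

  ## parcellate: ICA order sweep
  sweep_res <- stage("parcellate", {
    sw <- order_sweep(sim, config$tracer$ica_orders,
                      rng_seed = config$seeds$ica)
    assign_tab <- do.call(rbind, lapply(names(sw$solutions), function(o)
      data.frame(order = as.integer(o),
                 seed_index = seq_along(sw$solutions[[o]]$seed_assignment),
                 u = sim$seed_u,
                 component = sw$solutions[[o]]$seed_assignment)))
    tsv(assign_tab, "seed_assignment.tsv")
    tsv(sw$matching, "component_matching.tsv")
    sw
  })

  ## tracer fingerprint: 10 seeds x 9 targets
  fp_tracer <- stage("tracer-fingerprint", {
    sp10 <- place_seeds(atl_tr, n_seeds = config$tracer$n_fingerprint_seeds)
    targets <- target_rois(atl_tr)
    seed_d <- sample_density(experiments, sp10)
    targ_d <- sample_density(experiments, targets)
    brain_d <- sample_density(experiments, brain_locations(atl_tr))
    sim_s <- projection_similarity(seed_d, brain_d, seed_u = sp10$u)
    sim_t <- projection_similarity(targ_d, brain_d)
    excl <- c(atlas_voxels(atl_tr, atlas_labels(atl_tr, role = "seed_roi")),
              unlist(targets))
    fp <- tracer_fingerprint(sim_s, sim_t, excl,
                             target_names = names(targets),
                             species = "mouse")
    write_fingerprint_table(fp, file.path(out_dir,
                                          "fingerprint_mouse_tracer.tsv"))
    fp
  })

  ## rs-fMRI fingerprints, both species-analogues
  run_fmri <- function(tag) {
    cfg <- config$fmri[[tag]]
    model <- default_bold_model(atl_fm, tag, frac_bad = cfg$frac_bad)
    sp <- place_seeds(atl_fm, n_seeds = cfg$n_seeds)
    targets <- target_rois(atl_fm)
    qc_args <- NULL
    if (tag == "human") {
      sens <- atlas_labels(atl_fm, name = "somatosensory")
      hemi <- atl_fm$table$hemisphere[match(sens, atl_fm$table$label_id)]
      qc_args <- list(sensory = atlas_voxels(atl_fm, sens[hemi == "L"]),
                      homotopic = atlas_voxels(atl_fm, sens[hemi == "R"]),
                      dmn = atlas_voxels(atl_fm,
                                         atlas_labels(atl_fm, role = "dmn")),
                      thr_pos = config$qc$thr_pos,
                      thr_neg = config$qc$thr_neg)
    }
    res <- cohort_fingerprint(atl_fm, model, sp, targets,
                              n_subjects = cfg$n_subjects,
                              n_timepoints = cfg$n_timepoints,
                              tr_s = cfg$tr_s, band = cfg$band,
                              qc = qc_args,
                              rng_seed = config$seeds[[paste0(tag, "_fmri")]],
                              species = tag)
    write_fingerprint_table(res$fingerprint,
                            file.path(out_dir,
                                      sprintf("fingerprint_%s_rsfmri.tsv",
                                              tag)))
    long <- do.call(rbind, lapply(seq_along(res$per_subject), function(s) {
      m <- res$per_subject[[s]]
      data.frame(subject = s, seed = rep(seq_len(nrow(m)), ncol(m)),
                 target = rep(colnames(m), each = nrow(m)),
                 r = as.vector(m))
    }))
    tsv(long, sprintf("subject_fc_%s.tsv", tag))
    if (!is.null(res$qc)) tsv(res$qc, "qc_human.tsv")
    res
  }
  res_mouse <- stage("fingerprint", run_fmri("mouse"))
  res_human <- stage("fingerprint", run_fmri("human"))

  ## repeated-measures ANOVA per species
  anova_res <- stage("anova", {
    fits <- lapply(list(mouse = res_mouse, human = res_human), function(r) {
      arr <- array(unlist(r$per_subject),
                   dim = c(dim(r$per_subject[[1L]]), length(r$per_subject)))
      two_way_rm_anova(aperm(arr, c(3L, 1L, 2L)))
    })
    tsv(do.call(rbind, lapply(names(fits), function(sp) {
      f <- fits[[sp]]
      data.frame(species = sp, n = f$n, F_interaction = f$F_interaction,
                 df1 = f$df1, df2 = f$df2, epsilon_gg = f$epsilon_gg,
                 epsilon_hf = f$epsilon_hf, p_unadjusted = f$p_unadjusted,
                 p_adjusted = f$p_adjusted)
    })), "rm_anova.tsv")
    fits
  })

  ## cross-species comparison
  comparison <- stage("compare", {
    pair <- align_fingerprints(res_mouse$fingerprint, res_human$fingerprint)
    sim_fp <- fingerprint_similarity(pair)
    tsv(data.frame(target = names(sim_fp$per_target),
                   pearson_r = sim_fp$per_target), "compare_per_target.tsv")
    tsv(data.frame(metric = names(sim_fp$overall),
                   score = unname(sim_fp$overall)), "compare_overall.tsv")
    sim_fp
  })

  ## run log
  stage("log", {
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("cingfp %s on R %s",
              as.character(utils::packageVersion("cingfp")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seeds: %s",
              paste(names(config$seeds), unlist(config$seeds), sep = "=",
                    collapse = " "))),
      file.path(out_dir, "run_log.txt"))
  })

  invisible(list(sweep = sweep_res, fp_tracer = fp_tracer,
                 fp_mouse = res_mouse$fingerprint,
                 fp_human = res_human$fingerprint, anova = anova_res,
                 comparison = comparison, qc = res_human$qc))
}
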