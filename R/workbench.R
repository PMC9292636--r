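# Canned experiments tying the pipeline together: for each synthetic
# subject, generate (and optionally corrupt) a phantom, preprocess the MR,
# build the three candidate sCTs, reconstruct four PET arms (reference CT
# AC + seg/atlas/DL AC), and evaluate SUV bias against the reference arm.
# Seeds derive hierarchically from the master seed so every stage is
# replayable in isolation.

SCENARIOS <- c("baseline", "truncation", "metal", "single_lung", "nodule")

default_scenario_params <- function() list(
  truncation = list(lateral_fraction = 0.15),
  metal = list(center = c(0, -22), void_radius = 17, implant_radius = 6),
  single_lung = list(side = "left"),
  nodule = list(radius_mm = 7, uptake_ratio = 4)
)

#' Experiment configuration
#'
#' Desk-scale defaults: 64 x 64 single-slice phantoms at 4 mm in-plane, 96
#' projection angles, noiseless projections (deterministic), 5 atlases, 12
#' training subjects. DL training subjects, atlas subjects and evaluation
#' subjects draw from disjoint seed streams, so no subject is ever part of
#' its own atlas or training set.
#'
#' @param scenario one of "baseline", "truncation", "metal", "single_lung",
#'   "nodule"
#' @param n_subjects evaluation subjects
#' @param n_atlases atlas subjects (LOOCV-style: always distinct from
#'   evaluation subjects)
#' @param n_train_subjects DL training subjects
#' @param train_slices_per_subject slices generated per training subject
#' @param phantom \code{phantom_config} for all cohorts
#' @param net \code{network_config}
#' @param train \code{training_config}
#' @param train_lung_scale_range lung size-scale range for the TRAINING
#'   cohort: broad lung-volume variability teaches the network to follow
#'   the image rather than a positional prior, as a clinically varied
#'   training set would
#' @param train_hu_jitter tissue-density jitter scale for the TRAINING
#'   cohort; larger than the evaluation default so the trained intensity
#'   map covers dense (consolidated) lungs
#' @param n_angles projection angles
#' @param total_counts counts per slice or "noiseless"
#' @param suv_floor validity floor for bias maps
#' @param scenario_params corruption parameters per scenario
#' @param master_seed master seed
#' @return object of class \code{experiment_config}
#' @export
experiment_config <- function(scenario = "baseline", n_subjects = 3L,
                              n_atlases = 5L, n_train_subjects = 12L,
                              train_slices_per_subject = 3L,
                              phantom = phantom_config(
                                grid_shape = c(64L, 64L, 1L),
                                voxel_spacing = c(4, 4, 4)),
                              net = network_config("desk"),
                              train = training_config("desk", epochs = 120L),
                              train_lung_scale_range = c(0.25, 1.15),
                              train_hu_jitter = 2,
                              n_angles = 96L,
                              total_counts = "noiseless",
                              suv_floor = 0.05,
                              scenario_params = default_scenario_params(),
                              master_seed = 1L) {
  if (!scenario %in% SCENARIOS)
    stop_sctpet("unknown scenario '%s'", scenario)
  structure(list(scenario = scenario, n_subjects = as.integer(n_subjects),
                 n_atlases = as.integer(n_atlases),
                 n_train_subjects = as.integer(n_train_subjects),
                 train_slices_per_subject = as.integer(train_slices_per_subject),
                 train_lung_scale_range = train_lung_scale_range,
                 train_hu_jitter = train_hu_jitter,
                 phantom = phantom, net = net, train = train,
                 n_angles = as.integer(n_angles), total_counts = total_counts,
                 suv_floor = suv_floor, scenario_params = scenario_params,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Apply a named corruption scenario to a phantom
#' @param phantom \code{torso_phantom}
#' @param scenario scenario name
#' @param params scenario parameter list (see
#'   \code{default_scenario_params})
#' @return corrupted phantom (baseline returns the phantom unchanged)
#' @export
apply_scenario <- function(phantom, scenario,
                           params = default_scenario_params()) {
  switch(scenario,
    baseline = phantom,
    truncation = do.call(inject_truncation,
                         c(list(phantom), params$truncation)),
    metal = do.call(inject_metal, c(list(phantom), params$metal)),
    single_lung = do.call(remove_lung, c(list(phantom), params$single_lung)),
    nodule = {
      p <- params$nodule
      # centre the nodule in the right lung
      do.call(add_lung_nodule, c(list(phantom), p))
    },
    stop_sctpet("unknown scenario '%s'", scenario))
}

# standard MR conditioning: rough mask -> bias correction -> histogram
# matching to the cohort reference -> unit-range normalization
preprocess_mr <- function(mr, reference = NULL) {
  thr <- otsu_threshold(as.vector(mr))
  rough <- as_vol3d(mr) > thr
  corrected <- correct_bias_field(mr, rough)
  attr(corrected, "bias_field") <- NULL
  if (!is.null(reference)) corrected <- match_histogram(corrected, reference)
  list(mr_norm = normalize_unit_range(corrected), corrected = corrected)
}

# phantom cohort for one seed stream
make_cohort <- function(cfg, stream, n) {
  lapply(seq_len(n), function(i) {
    generate_phantom(cfg$phantom, derive_seed(cfg$master_seed, stream, i))
  })
}

#' Train the DL arm on a cohort of uncorrupted phantoms
#'
#' The histogram-matching reference built here travels with the model
#' (attribute \code{"reference"}) so inference-time preprocessing matches
#' the intensity distribution the network was trained on.
#' @param cfg \code{experiment_config}
#' @param ref optional histogram-matching reference volume; built from the
#'   first training subject when NULL
#' @param verbose print progress
#' @return trained \code{sct_model} with the reference attached
#' @export
train_experiment_model <- function(cfg, ref = NULL, verbose = FALSE) {
  tcfg <- cfg
  # training phantoms carry their own slice count so the slice budget does
  # not depend on the evaluation grid, and broad lung-volume variability so
  # the network learns image content rather than a positional lung prior
  tcfg$phantom$grid_shape[3] <- cfg$train_slices_per_subject
  tcfg$phantom$lung_scale_range <- cfg$train_lung_scale_range %||%
    tcfg$phantom$lung_scale_range
  tcfg$phantom$subject_hu_jitter <- cfg$train_hu_jitter %||%
    tcfg$phantom$subject_hu_jitter
  cohort <- make_cohort(tcfg, "train", cfg$n_train_subjects)
  if (is.null(ref)) {
    # canonical intensity reference: a subject with evaluation-style
    # anatomy, so histogram matching does not inherit the training
    # cohort's widened lung-volume distribution
    ref_ph <- generate_phantom(cfg$phantom,
                               derive_seed(cfg$master_seed, "reference"))
    ref <- preprocess_mr(ref_ph$mr)$corrected
  }
  mr_list <- list(); ct_list <- list()
  for (ph in cohort) {
    pp <- preprocess_mr(ph$mr, ref)
    nz <- min(dim(ph$mr)[3], cfg$train_slices_per_subject)
    for (k in seq_len(nz)) {
      mr_list[[length(mr_list) + 1]] <- pp$mr_norm[, , k]
      ct_list[[length(ct_list) + 1]] <- ph$ct_hu[, , k]
    }
  }
  h <- nrow(mr_list[[1]]); w <- ncol(mr_list[[1]])
  mr_arr <- array(unlist(mr_list), dim = c(h, w, length(mr_list)))
  ct_arr <- array(unlist(ct_list), dim = c(h, w, length(ct_list)))
  model <- build_network(cfg$net, seed = derive_seed(cfg$master_seed, "init"))
  tr <- cfg$train
  tr$seed <- derive_seed(cfg$master_seed, "training")
  fit <- train_network(model, mr_arr, ct_arr, tr, verbose = verbose)
  out <- fit$model
  attr(out, "reference") <- ref
  out
}

#' Run one canned experiment
#'
#' Generates the cohorts, trains (or reuses) the DL model, and for every
#' evaluation subject builds the three candidate sCTs, reconstructs the
#' four PET arms and accumulates bias statistics. A failing subject is
#' recorded as a machine-readable error and the run continues.
#'
#' @param cfg \code{experiment_config}
#' @param model optional pre-trained \code{sct_model} (reused across
#'   scenarios); trained on the fly when NULL
#' @param atlases optional precomputed atlas cohort (list of phantoms)
#' @param out_dir optional artifact directory: every intermediate volume,
#'   config and log is written there as NIfTI/YAML/CSV
#' @param verbose print progress
#' @return list(report, per_subject, errors, model, affected): the
#'   \code{bias_report}, per-subject detail rows, error records, the model
#'   used, and per-subject affected-region stats (outlier scenarios)
#' @export
run_experiment <- function(cfg, model = NULL, atlases = NULL, out_dir = NULL,
                           verbose = FALSE) {
  sp <- cfg$phantom$voxel_spacing
  if (is.null(atlases)) atlases <- make_cohort(cfg, "atlas", cfg$n_atlases)
  # one intensity reference for the whole experiment: the model's training
  # reference when a trained model exists, else the first atlas subject
  ref <- if (!is.null(model)) attr(model, "reference") else NULL
  if (is.null(ref)) ref <- preprocess_mr(atlases[[1]]$mr)$corrected
  if (is.null(model)) {
    model <- train_experiment_model(cfg, ref = ref, verbose = verbose)
  }
  atlas_pp <- lapply(atlases, function(ph) preprocess_mr(ph$mr, ref)$mr_norm)
  atlas_cts <- lapply(atlases, function(ph) ph$ct_hu)

  geom <- geometry_for_grid(cfg$phantom$grid_shape, sp, cfg$n_angles)
  arms <- c("seg", "atlas", "dl")
  region_rows <- list(); rmse_rows <- list(); voi_rows <- list()
  affected_rows <- list(); errors <- list()

  for (si in seq_len(cfg$n_subjects)) {
    res <- tryCatch({
      ph <- generate_phantom(cfg$phantom, derive_seed(cfg$master_seed, "eval", si))
      ph <- apply_scenario(ph, cfg$scenario, cfg$scenario_params)
      pp <- preprocess_mr(ph$mr, ref)
      mr_norm <- pp$mr_norm

      seg <- build_seg_sct(mr_norm, spacing = sp)
      atl <- build_atlas_sct(mr_norm, atlas_pp, atlas_cts, spacing = sp)
      dl_sct <- predict_sct(model, mr_norm)

      mu_true <- hu_to_mu(ph$ct_hu, "reference_ct", sp)
      mu_arms <- list(
        seg = seg$mu_map,
        atlas = hu_to_mu(atl$sct_hu, "atlas", sp),
        dl = hu_to_mu(dl_sct, "dl", sp)
      )
      sino <- forward_project(ph$activity, mu_true, geom, cfg$total_counts,
                              seed = derive_seed(cfg$master_seed, "counts", si))
      recon_ref <- osem_reconstruct(sino, mu_true)
      body <- ph$organs$body
      suv_ref <- to_suv(recon_ref, body)
      tmask <- tissue_masks_from_ct(ph$ct_hu,
                                    ph$organs$right_lung | ph$organs$left_lung,
                                    body)
      affected <- if (length(ph$outliers_applied)) {
        ph$outliers_applied[[1]]$mask
      } else NULL

      sub_rows <- list(); sub_rmse <- list(); sub_voi <- list(); sub_aff <- list()
      for (arm in arms) {
        recon <- osem_reconstruct(sino, mu_arms[[arm]])
        suv <- to_suv(recon, body, reference = recon_ref)
        bm <- voxel_bias_map(suv, suv_ref, cfg$suv_floor)
        for (rg in c("lung", "soft", "bone", "body")) {
          st <- region_stats(bm$bias, bm$valid, tmask[[rg]])
          sub_rows[[length(sub_rows) + 1]] <-
            data.frame(subject = si, region = rg, arm = arm,
                       mean = st$mean, sd = st$sd, abs_mean = st$abs_mean,
                       abs_sd = st$abs_sd, n_voxels = st$n_voxels)
        }
        sub_rmse[[length(sub_rmse) + 1]] <-
          data.frame(subject = si, arm = arm,
                     rmse = rmse_volumes(suv, suv_ref, body))
        if (!is.null(affected)) {
          st <- region_stats(bm$bias, bm$valid, affected)
          sub_aff[[length(sub_aff) + 1]] <-
            data.frame(subject = si, arm = arm, mean = st$mean,
                       abs_mean = st$abs_mean, n_voxels = st$n_voxels)
          sub_rows[[length(sub_rows) + 1]] <-
            data.frame(subject = si, region = "affected", arm = arm,
                       mean = st$mean, sd = st$sd, abs_mean = st$abs_mean,
                       abs_sd = st$abs_sd, n_voxels = st$n_voxels)
        }
        lesions <- ph$organs[grepl("^lesion_", names(ph$organs))]
        if (length(lesions)) {
          vb <- voi_bias(bm$bias, bm$valid, lesions, sp, suv = suv)
          vb$arm <- arm; vb$subject <- si
          sub_voi[[length(sub_voi) + 1]] <- vb
        }
      }
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sprintf("subject_%02d", si))
        write_phantom(ph, sdir)
        write_volume(seg$sct_hu, file.path(sdir, "sct_seg.nii.gz"), sp)
        write_volume(atl$sct_hu, file.path(sdir, "sct_atlas.nii.gz"), sp)
        write_volume(dl_sct, file.path(sdir, "sct_dl.nii.gz"), sp)
        write_volume(suv_ref, file.path(sdir, "suv_reference.nii.gz"), sp)
      }
      list(rows = sub_rows, rmse = sub_rmse, voi = sub_voi, aff = sub_aff)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1]] <- list(subject = si,
                                           message = conditionMessage(res))
      if (verbose) message(sprintf("subject %d failed: %s", si,
                                   conditionMessage(res)))
      next
    }
    region_rows <- c(region_rows, res$rows)
    rmse_rows <- c(rmse_rows, res$rmse)
    voi_rows <- c(voi_rows, res$voi)
    affected_rows <- c(affected_rows, res$aff)
    if (verbose) message(sprintf("subject %d/%d done", si, cfg$n_subjects))
  }
  if (!length(region_rows))
    stop_sctpet("every subject failed; first error: %s",
                errors[[1]]$message %||% "unknown")
  region_table <- do.call(rbind, region_rows)
  rmse_table <- do.call(rbind, rmse_rows)
  voi_table <- if (length(voi_rows)) do.call(rbind, voi_rows) else NULL
  report <- build_report(region_table, rmse_table, voi_table,
                         test_metric = if (length(affected_rows)) "affected" else "body")
  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report"))
    yaml::write_yaml(list(scenario = cfg$scenario,
                          master_seed = cfg$master_seed,
                          n_subjects = cfg$n_subjects,
                          errors = errors),
                     file.path(out_dir, "run.yaml"))
  }
  list(report = report,
       per_subject = region_table,
       affected = if (length(affected_rows)) do.call(rbind, affected_rows) else NULL,
       errors = errors, model = model)
}

#' Run the four outlier scenarios with shared model and atlases
#'
#' Trains one DL model on uncorrupted phantoms, builds one atlas cohort,
#' and runs each requested scenario against them, collecting the
#' affected-region mean bias of the three candidate arms.
#'
#' @param scenarios scenario names (subset of the four outlier scenarios)
#' @param n_subjects evaluation subjects per scenario
#' @param master_seed master seed
#' @param cfg base \code{experiment_config} (scenario field ignored)
#' @param verbose print progress
#' @return list(bias = data.frame(scenario, arm, mean_bias, abs_mean_bias),
#'   runs = per-scenario run results, model)
#' @export
run_scenario_suite <- function(scenarios = c("truncation", "metal",
                                             "single_lung", "nodule"),
                               n_subjects = 5L, master_seed = 1L,
                               cfg = experiment_config(), verbose = FALSE) {
  cfg$master_seed <- as.integer(master_seed)
  cfg$n_subjects <- as.integer(n_subjects)
  model <- train_experiment_model(cfg, verbose = verbose)
  atlases <- make_cohort(cfg, "atlas", cfg$n_atlases)
  runs <- list(); rows <- list()
  for (sc in scenarios) {
    cfg$scenario <- sc
    run <- run_experiment(cfg, model = model, atlases = atlases,
                          verbose = verbose)
    runs[[sc]] <- run
    aff <- run$affected
    for (arm in unique(aff$arm)) {
      sub <- aff[aff$arm == arm, ]
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc, arm = arm,
        mean_bias = mean(sub$mean, na.rm = TRUE),
        abs_mean_bias = mean(abs(sub$mean), na.rm = TRUE),
        n_subjects = sum(!is.na(sub$mean)))
    }
    if (verbose) message(sprintf("scenario %s done", sc))
  }
  list(bias = do.call(rbind, rows), runs = runs, model = model)
}

#' Build a small deterministic fixture cohort
#' @param seed master seed
#' @param n_subjects cohort size
#' @param grid_shape,voxel_spacing phantom grid
#' @return list of \code{torso_phantom}
#' @export
make_fixtures <- function(seed = 1L, n_subjects = 8L,
                          grid_shape = c(64L, 64L, 1L),
                          voxel_spacing = c(4, 4, 4)) {
  cfg <- phantom_config(grid_shape = grid_shape, voxel_spacing = voxel_spacing)
  lapply(seq_len(n_subjects), function(i) {
    generate_phantom(cfg, derive_seed(seed, "fixture", i))
  })
}
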