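#' Configuration of the synthetic two-group cohort
#'
#' The generator plants, on a shared 3 mm grid, (i) a focal gray-matter
#' atrophy region whose depth scales with a latent per-patient severity,
#' (ii) a connectivity hub inside that region whose BOLD signal loading on a
#' shared low-frequency latent decays with severity (the target regions keep
#' full loading, so hub degree and seed-target FC both decline), (iii)
#' behavior scores linearly coupled to severity on the semantic tasks only,
#' and (iv) an anisotropic white-matter path from the hub to the first
#' target whose principal diffusivity (hence FA) decreases with severity.
#' Controls have severity 0.
#'
#' ROI boxes are given as 2x3 matrices `rbind(lower, upper)` of 1-based
#' voxel subscripts (inclusive). The hub, the two targets and the tract are
#' mutually disjoint; the hub and targets lie inside the atrophy region,
#' which models the atrophic network the downstream analyses are restricted
#' to.
#'
#' @param grid_shape integer 3-vector, default `c(20, 20, 14)`.
#' @param voxel_mm isotropic voxel size, default 3.
#' @param n_patients,n_controls group sizes (17 patients, 18 controls).
#' @param repeat_counts per-patient extra observation counts; default two
#'   patients observed twice and one three times, for 21 observations.
#' @param tr_s,n_volumes BOLD sampling (2 s, 200 frames).
#' @param dwi_directions,b_value diffusion scheme (40 directions, b=1000).
#' @param severity_range latent severity range for first observations.
#' @param severity_increment upward drift per repeat observation.
#' @param beta_fc hub-loading loss per unit severity (loading =
#'   `lambda0 * (1 - beta_fc * s)`).
#' @param beta_gmv atrophy depth per unit severity (GMV units).
#' @param beta_behavior named numeric: score loss per unit severity per task
#'   (zero for non-semantic tasks).
#' @param behavior_baseline,behavior_sd named numeric: task intercepts and
#'   noise sds.
#' @param beta_tract principal-diffusivity loss per unit severity (mm^2/s).
#' @param noise_sds list with `gmv`, `bold`, `dwi` channel noise sds.
#' @param lambda0 full hub/target loading on the shared latent.
#' @param bold_band frequency band of the shared latent signal (Hz).
#' @param dwi_noise `"gaussian"` (default) or `"rician"`.
#' @param rois optional ROI override list (atrophy, hub, target1, target2, tract).
#' @param rng_seed integer master seed.
#' @return object of class `nb_synth_config`.
#' @export
synthetic_config <- function(grid_shape = c(20L, 20L, 14L),
                             voxel_mm = 3,
                             n_patients = 17L,
                             n_controls = 18L,
                             repeat_counts = c(2L, 2L, 3L),
                             tr_s = 2,
                             n_volumes = 200L,
                             dwi_directions = 40L,
                             b_value = 1000,
                             severity_range = c(0.2, 0.8),
                             severity_increment = 0.1,
                             beta_fc = 1.0,
                             beta_gmv = 0.35,
                             beta_behavior = c(oral_picture_naming = 110,
                                               picture_matching = 18,
                                               word_matching = 20,
                                               calculation = 0,
                                               reyo_recall = 0),
                             behavior_baseline = c(oral_picture_naming = 125,
                                                   picture_matching = 66.5,
                                                   word_matching = 67,
                                                   calculation = 6.4,
                                                   reyo_recall = 17),
                             behavior_sd = c(oral_picture_naming = 8,
                                             picture_matching = 2.5,
                                             word_matching = 2.5,
                                             calculation = 0.8,
                                             reyo_recall = 6),
                             beta_tract = 4e-4,
                             noise_sds = list(gmv = 0.08, bold = 2, dwi = 2),
                             lambda0 = 1,
                             bold_band = c(0.01, 0.08),
                             dwi_noise = c("gaussian", "rician"),
                             rois = NULL,
                             rng_seed = 1L) {
  dwi_noise <- match.arg(dwi_noise)
  if (is.null(rois)) {
    rois <- list(
      atrophy = rbind(c(4L, 6L, 4L), c(17L, 13L, 9L)),
      hub     = rbind(c(5L, 8L, 6L), c(7L, 10L, 8L)),
      target1 = rbind(c(13L, 8L, 6L), c(15L, 10L, 8L)),
      target2 = rbind(c(9L, 11L, 4L), c(11L, 13L, 6L)),
      tract   = rbind(c(8L, 8L, 6L), c(12L, 10L, 8L))
    )
  }
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    affine = grid_affine(grid_shape, voxel_mm),
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    repeat_counts = as.integer(repeat_counts),
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    dwi_directions = as.integer(dwi_directions), b_value = b_value,
    severity_range = severity_range, severity_increment = severity_increment,
    beta_fc = beta_fc, beta_gmv = beta_gmv,
    beta_behavior = beta_behavior, behavior_baseline = behavior_baseline,
    behavior_sd = behavior_sd, beta_tract = beta_tract,
    noise_sds = noise_sds, lambda0 = lambda0, bold_band = bold_band,
    dwi_noise = dwi_noise, rois = rois,
    s0_dwi = 100, d_iso = 7e-4, tract_evals = c(1.7e-3, 3e-4, 3e-4),
    rng_seed = as.integer(rng_seed)), class = "nb_synth_config")
  validate_synth_config(cfg)
  cfg
}

roi_box_mask <- function(box, dim) {
  arr <- array(FALSE, dim)
  arr[box[1, 1]:box[2, 1], box[1, 2]:box[2, 2], box[1, 3]:box[2, 3]] <- TRUE
  arr
}

validate_synth_config <- function(cfg) {
  d <- cfg$grid_shape
  for (nm in names(cfg$rois)) {
    b <- cfg$rois[[nm]]
    if (any(b[1, ] < 1L) || any(b[2, ] > d) || any(b[1, ] > b[2, ]))
      stop("ROI '", nm, "' outside grid or inverted")
  }
  masks <- lapply(cfg$rois, roi_box_mask, dim = d)
  for (pair in list(c("hub", "target1"), c("hub", "target2"),
                    c("target1", "target2"), c("hub", "tract"),
                    c("target1", "tract"), c("target2", "tract"))) {
    if (any(masks[[pair[1]]] & masks[[pair[2]]]))
      stop("ROIs '", pair[1], "' and '", pair[2], "' overlap")
  }
  for (nm in c("hub", "target1", "target2")) {
    if (any(masks[[nm]] & !masks$atrophy))
      stop("ROI '", nm, "' must lie inside the atrophy region")
  }
  if (cfg$n_volumes <= 10L) stop("n_volumes must exceed the 10-frame discard")
  if (length(cfg$repeat_counts) > cfg$n_patients || any(cfg$repeat_counts < 1L))
    stop("inconsistent repeat counts")
  invisible(cfg)
}

# Deterministic near-uniform unit directions (spherical Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Diffusion gradient table
#' @param directions m x 3 matrix of unit vectors for the weighted volumes.
#' @param b_value b-value of the weighted volumes (s/mm^2).
#' @param n_b0 number of leading b=0 volumes.
#' @return object of class `nb_gradient_table` with `bvecs` ((n_b0+m) x 3)
#'   and `bvals`.
#' @export
gradient_table <- function(directions, b_value = 1000, n_b0 = 1L) {
  directions <- as.matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("gradient directions must be unit vectors")
  if (nrow(directions) < 6L) stop("need at least 6 weighted directions")
  if (qr(weighted_design(directions, 1))$rank < 6L)
    stop("gradient directions are collinear/degenerate for tensor fitting")
  structure(list(
    bvecs = rbind(matrix(0, n_b0, 3), directions),
    bvals = c(rep(0, n_b0), rep(b_value, nrow(directions)))),
    class = "nb_gradient_table")
}

weighted_design <- function(dirs, b) {
  g <- as.matrix(dirs)
  b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
            2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

# Observation table: patients (with repeats) then controls.
synth_observation_table <- function(cfg) {
  rep_extra <- cfg$repeat_counts
  pat <- data.frame(patient_id = sprintf("P%02d", seq_len(cfg$n_patients)),
                    n_obs = 1L, stringsAsFactors = FALSE)
  pat$n_obs[seq_along(rep_extra)] <- rep_extra
  rows <- do.call(rbind, lapply(seq_len(nrow(pat)), function(i) {
    data.frame(patient_id = pat$patient_id[i], obs_index = seq_len(pat$n_obs[i]),
               group = "patient", stringsAsFactors = FALSE)
  }))
  ctl <- data.frame(patient_id = sprintf("C%02d", seq_len(cfg$n_controls)),
                    obs_index = 1L, group = "control", stringsAsFactors = FALSE)
  obs <- rbind(rows, ctl)
  obs$observation_id <- ifelse(obs$group == "patient",
                               sprintf("%s_o%d", obs$patient_id, obs$obs_index),
                               obs$patient_id)
  obs
}

# Severities are a deterministic function of the master seed so that
# ground_truth(config) and generate_cohort(config) agree without sharing
# state.
synth_severities <- function(cfg) {
  obs <- synth_observation_table(cfg)
  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(cfg$rng_seed)
    expr
  }
  base <- withr_seed(stats::runif(cfg$n_patients, cfg$severity_range[1],
                                  cfg$severity_range[2]))
  names(base) <- sprintf("P%02d", seq_len(cfg$n_patients))
  s <- ifelse(obs$group == "patient",
              pmin(1, base[obs$patient_id] +
                     cfg$severity_increment * (obs$obs_index - 1L)),
              0)
  obs$severity <- as.numeric(s)
  obs
}

# Band-limited unit-variance latent signal via spectral shaping.
band_limited_latent <- function(n, tr_s, band) {
  x <- stats::rnorm(n)
  f <- fft_freqs(n, tr_s)
  keep <- f >= band[1] - 1e-12 & f <= band[2] + 1e-12
  X <- stats::fft(x)
  X[!keep] <- 0
  u <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(u))
}

fft_freqs <- function(n, tr_s) {
  k <- 0:(n - 1)
  k2 <- pmin(k, n - k)          # two-sided bins share the same |frequency|
  k2 / (n * tr_s)
}

#' Generate a synthetic cohort
#'
#' Returns all per-observation artifacts except the 4D BOLD arrays, which
#' are materialized on demand by [cohort_bold()] from per-observation
#' sub-seeds stored in the cohort (a fully materialized cohort at the
#' default 200 volumes would need gigabytes). Equal seeds give identical
#' cohorts, including the lazily generated BOLD.
#'
#' @param config a `nb_synth_config`.
#' @return object of class `nb_cohort` with elements `config`,
#'   `observations` (data.frame incl. latent severity), `gmv` (list of
#'   `nb_volume`), `behavior` (long data.frame), `motion` (list with
#'   per-frame series and 6-vector max summaries), `dwi` (list of 4D
#'   arrays), `gradients`, and `bold_seeds`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cfg <- config
  validate_synth_config(cfg)
  obs <- synth_severities(cfg)
  n_obs <- nrow(obs)
  d <- cfg$grid_shape
  masks <- lapply(cfg$rois, roi_box_mask, dim = d)

  set.seed(cfg$rng_seed)
  stats::runif(cfg$n_patients)   # skip the severity draws (already consumed)

  # fixed smooth anatomical baseline shared by all subjects
  baseline <- 1 + 0.1 * gaussian_smooth(array(stats::rnorm(prod(d)), d),
                                        fwhm_mm = 12, voxel_mm = cfg$voxel_mm)

  gmv <- vector("list", n_obs)
  motion_series <- vector("list", n_obs)
  motion_summary <- matrix(NA_real_, n_obs, 6,
                           dimnames = list(obs$observation_id,
                                           c("tx", "ty", "tz", "rx", "ry", "rz")))
  dwi <- vector("list", n_obs)
  behavior_rows <- vector("list", n_obs)

  gtab <- gradient_table(fibonacci_directions(cfg$dwi_directions),
                         b_value = cfg$b_value, n_b0 = 1L)
  tasks <- names(cfg$behavior_baseline)

  # planted diffusion-tensor field (severity-independent part)
  path_mask <- masks$hub | masks$tract | masks$target1

  for (i in seq_len(n_obs)) {
    s_i <- obs$severity[i]
    g <- baseline - cfg$beta_gmv * s_i * masks$atrophy +
      array(stats::rnorm(prod(d), sd = cfg$noise_sds$gmv), d)
    gmv[[i]] <- volume(g, cfg$affine, units = "gmv")

    mo <- apply(matrix(stats::rnorm(cfg$n_volumes * 6, sd = 0.02),
                       cfg$n_volumes, 6), 2, cumsum)
    colnames(mo) <- colnames(motion_summary)
    motion_series[[i]] <- mo
    motion_summary[i, ] <- apply(abs(mo), 2, max)

    dwi[[i]] <- synth_dwi_signal(cfg, masks, path_mask, s_i, gtab)

    raw <- cfg$behavior_baseline[tasks] - cfg$beta_behavior[tasks] * s_i +
      stats::rnorm(length(tasks), sd = cfg$behavior_sd[tasks])
    behavior_rows[[i]] <- data.frame(
      observation_id = obs$observation_id[i], patient_id = obs$patient_id[i],
      group = obs$group[i], obs_index = obs$obs_index[i],
      task_id = tasks, raw_score = as.numeric(raw),
      stringsAsFactors = FALSE)
  }
  bold_seeds <- sample.int(.Machine$integer.max - 1L, n_obs)

  structure(list(config = cfg, observations = obs,
                 gmv = stats::setNames(gmv, obs$observation_id),
                 behavior = do.call(rbind, behavior_rows),
                 motion = list(series = stats::setNames(motion_series,
                                                        obs$observation_id),
                               summary = motion_summary),
                 dwi = stats::setNames(dwi, obs$observation_id),
                 gradients = gtab,
                 bold_seeds = stats::setNames(bold_seeds, obs$observation_id)),
            class = "nb_cohort")
}

#' @export
print.nb_cohort <- function(x, ...) {
  cat(sprintf("<nb_cohort: %d patient observations, %d controls, grid %s>\n",
              sum(x$observations$group == "patient"),
              sum(x$observations$group == "control"),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

# Planted tensor field and DWI signal for one observation.
synth_dwi_signal <- function(cfg, masks, path_mask, s_i, gtab) {
  d <- cfg$grid_shape
  nvox <- prod(d)
  ev <- cfg$tract_evals
  l1 <- ev[1] - cfg$beta_tract * s_i
  # D g for the two tensor variants (principal axis = +x on the path)
  wdirs <- gtab$bvecs[gtab$bvals > 0, , drop = FALSE]
  b <- gtab$bvals[gtab$bvals > 0]
  q_iso <- b * cfg$d_iso * rowSums(wdirs^2)
  q_path <- b * (l1 * wdirs[, 1]^2 + ev[2] * wdirs[, 2]^2 + ev[3] * wdirs[, 3]^2)
  onpath <- as.numeric(path_mask)
  att <- outer(q_iso, 1 - onpath) + outer(q_path, onpath)  # (nweighted x nvox)
  sig <- cfg$s0_dwi * exp(-att)
  full <- rbind(matrix(cfg$s0_dwi, sum(gtab$bvals == 0), nvox), sig)
  noise <- matrix(stats::rnorm(length(full), sd = cfg$noise_sds$dwi),
                  nrow(full), nvox)
  if (cfg$dwi_noise == "rician") {
    noise2 <- matrix(stats::rnorm(length(full), sd = cfg$noise_sds$dwi),
                     nrow(full), nvox)
    full <- sqrt((full + noise)^2 + noise2^2)
  } else {
    full <- full + noise
  }
  array(t(full), c(d, nrow(full)))
}

#' Materialize the BOLD series of one observation
#'
#' Regenerates the 4D BOLD array deterministically from the observation's
#' stored sub-seed: every in-grid voxel carries white noise; hub voxels add
#' `lambda0 * (1 - beta_fc * severity)` times a shared band-limited latent
#' signal, and target voxels add the same latent at full loading.
#'
#' @param cohort a `nb_cohort`.
#' @param observation_id one of `cohort$observations$observation_id`.
#' @return a `nb_bold`.
#' @export
cohort_bold <- function(cohort, observation_id) {
  cfg <- cohort$config
  row <- match(observation_id, cohort$observations$observation_id)
  if (is.na(row)) stop("unknown observation: ", observation_id)
  s_i <- cohort$observations$severity[row]
  d <- cfg$grid_shape
  n <- cfg$n_volumes
  set.seed(cohort$bold_seeds[[observation_id]])
  u <- band_limited_latent(n, cfg$tr_s, cfg$bold_band)
  masks <- lapply(cohort$config$rois, roi_box_mask, dim = d)
  loading <- array(0, d)
  loading[masks$hub] <- cfg$lambda0 * (1 - cfg$beta_fc * s_i)
  loading[masks$target1 | masks$target2] <- cfg$lambda0
  arr <- array(stats::rnorm(prod(d) * n, sd = cfg$noise_sds$bold), c(d, n))
  sig <- outer(loading, u)       # (x,y,z,t)
  bold_series(arr + sig, tr_s = cfg$tr_s, affine = cfg$affine)
}

#' Ground truth of the planted effects
#'
#' @param config a `nb_synth_config`.
#' @return list with the ROI masks (`nb_volume` 0/1), the tract-path mask,
#'   the per-observation table including latent severities, and the
#'   expected sign of each planted association.
#' @export
ground_truth <- function(config = synthetic_config()) {
  cfg <- config
  validate_synth_config(cfg)
  d <- cfg$grid_shape
  masks <- lapply(cfg$rois, roi_box_mask, dim = d)
  vols <- lapply(masks, function(m) volume(m + 0, cfg$affine, units = "mask"))
  semantic_slope <- unname(cfg$beta_behavior["oral_picture_naming"])
  list(masks = vols,
       observations = synth_severities(cfg),
       expected_signs = list(
         # worse severity -> lower FC and lower semantic score, so the
         # FC-behavior and degree-behavior associations are positive when
         # both couplings are positive; FA-behavior likewise.
         fc_behavior = sign(cfg$beta_fc) * sign(semantic_slope),
         degree_behavior = sign(cfg$beta_fc) * sign(semantic_slope),
         fa_behavior = sign(cfg$beta_tract) * sign(semantic_slope),
         gmv_group = -sign(cfg$beta_gmv)))
}

#' Write a cohort to disk
#'
#' NIfTI-1 volumes (`<obs>_gmv.nii.gz`, `<obs>_dwi.nii.gz`), FSL-style
#' `dwi.bvec`/`dwi.bval`, the behavior table as TSV and the observation
#' table (with severities) as JSON. BOLD is written only for the requested
#' observations to keep disk use bounded.
#'
#' @param cohort a `nb_cohort`.
#' @param dir output directory (created if needed).
#' @param bold_for observation ids whose BOLD series should be written.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, bold_for = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$observations$observation_id) {
    write_nifti(cohort$gmv[[id]], file.path(dir, paste0(id, "_gmv.nii.gz")))
    write_nifti(cohort$dwi[[id]], file.path(dir, paste0(id, "_dwi.nii.gz")),
                affine = cohort$config$affine)
  }
  for (id in bold_for) {
    write_nifti(cohort_bold(cohort, id), file.path(dir, paste0(id, "_bold.nii.gz")))
  }
  write_bvec_bval(cohort$gradients, file.path(dir, "dwi"))
  write_behavior_tsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  jsonlite::write_json(cohort$observations, file.path(dir, "observations.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
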