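#' Pipeline parameter registry
#'
#' Collects every analysis setting of the network-behavior mapping
#' pipeline: the effective-connection threshold (r > 0.10), the 3 mm seed
#' radius, voxel-level p and cluster-corrected alpha per stage (0.05/0.05
#' for the atrophy and degree contrasts; 0.05 voxel-level with corrected
#' alpha 0.001 for the FC-behavior maps), smoothing kernels (8 mm for
#' gray-matter volume, 4 mm for BOLD), the 0.01-0.10 Hz band, the
#' four-covariate validation set, and the tracking parameters (100 seeds
#' per voxel, 45 degrees, FA 0.15, count-mask threshold 4 subjects).
#'
#' @param r_threshold effective-FC threshold for degree centrality.
#' @param seed_radius_mm seed sphere radius.
#' @param voxel_p_atrophy,alpha_atrophy GMV-contrast thresholds.
#' @param voxel_p_degree,alpha_degree degree-contrast thresholds.
#' @param voxel_p_fc,alpha_fc FC-behavior map thresholds.
#' @param fwhm_gmv_mm,fwhm_bold_mm smoothing kernels.
#' @param band band-pass in Hz.
#' @param discard_volumes leading BOLD frames dropped.
#' @param trans_limit_mm,rot_limit_deg motion-exclusion limits.
#' @param alphasim_iterations,connectivity Monte-Carlo settings.
#' @param seeds_per_voxel,angle_max_deg,fa_min,min_tract_subjects tracking.
#' @param semantic_tasks,nonsemantic_tasks task ids in the behavior table.
#' @param atrophy_mask_override optional mask (`nb_volume`/array) replacing
#'   the data-driven atrophic-network mask (used for null calibration,
#'   where no real atrophy exists to detect).
#' @param brain_mask optional analysis mask (default: whole grid).
#' @param rng_seed master seed for all Monte-Carlo stages.
#' @return object of class `nb_pipeline_config`.
#' @export
pipeline_config <- function(r_threshold = 0.10,
                            seed_radius_mm = 3,
                            voxel_p_atrophy = 0.05, alpha_atrophy = 0.05,
                            voxel_p_degree = 0.05, alpha_degree = 0.05,
                            voxel_p_fc = 0.05, alpha_fc = 0.001,
                            fwhm_gmv_mm = 8, fwhm_bold_mm = 4,
                            band = c(0.01, 0.10),
                            discard_volumes = 10L,
                            trans_limit_mm = 2.5, rot_limit_deg = 2.5,
                            alphasim_iterations = 1000L,
                            connectivity = 26L,
                            seeds_per_voxel = 100L,
                            angle_max_deg = 45, fa_min = 0.15,
                            min_tract_subjects = 4L,
                            semantic_tasks = c("oral_picture_naming",
                                               "picture_matching",
                                               "word_matching"),
                            nonsemantic_tasks = c("calculation", "reyo_recall"),
                            atrophy_mask_override = NULL,
                            brain_mask = NULL,
                            rng_seed = 1L) {
  for (p in c(voxel_p_atrophy, alpha_atrophy, voxel_p_degree, alpha_degree,
              voxel_p_fc, alpha_fc)) {
    if (!(p > 0 && p < 1)) stop("thresholds must lie in (0,1)")
  }
  if (fwhm_gmv_mm < 0 || fwhm_bold_mm < 0) stop("FWHMs must be non-negative")
  structure(as.list(environment()), class = "nb_pipeline_config")
}

clamp_fwhm <- function(fw, voxel_mm, log_fun = NULL) {
  f <- fw$fwhm_mm
  bad <- is.na(f) | f < voxel_mm
  if (any(bad)) {
    f[bad] <- rep(voxel_mm, length.out = 3)[bad]
    if (!is.null(log_fun))
      log_fun(sprintf("FWHM axis %s unresolvable/sub-voxel; clamped to voxel size",
                      paste(which(bad), collapse = ",")))
  }
  f
}

values_in_voxels <- function(vol, vox) {
  mean(vol$data[vox], na.rm = TRUE)
}

#' Run the full network-behavior mapping pipeline
#'
#' Executes, on a (synthetic or user-supplied) cohort: behavior correction
#' and semantic composites; the gray-matter-volume group contrast with
#' Monte-Carlo cluster correction (atrophic network); within-mask degree
#' centrality, its group contrast, seed extraction at the disconnection
#' peak and the degree-behavior correlation; seed FC z-maps and the
#' cluster-corrected FC-behavior correlation map; four-covariate partial
#' validation and first-observation subset; non-semantic specificity; and
#' deterministic tractography between the disconnected region and each FC
#' cluster with tract-integrity group tests and correlations.
#'
#' @param cohort a `nb_cohort` (see [generate_cohort()]).
#' @param config a `nb_pipeline_config`.
#' @param stages subset of
#'   `c("behavior", "atrophy", "degree", "seedfc", "validate",
#'   "specificity", "tract")`; later stages require their prerequisites.
#' @return object of class `nb_results`; see the elements stored per stage.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         stages = c("behavior", "atrophy", "degree", "seedfc",
                                    "validate", "specificity", "tract")) {
  res <- list(config = config, stages = stages, log = character())
  logf <- function(msg) res$log <<- c(res$log, msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  obs <- cohort$observations
  pat_ids <- obs$observation_id[obs$group == "patient"]
  ctl_ids <- obs$observation_id[obs$group == "control"]
  d <- cohort$config$grid_shape
  affine <- cohort$config$affine
  voxel_mm <- min(voxel_sizes(affine))
  brain <- if (is.null(config$brain_mask)) array(TRUE, d)
           else as_mask_array(config$brain_mask)

  ## ---- behavior -----------------------------------------------------------
  if ("behavior" %in% stages) {
    res$behavior <- stage("behavior", {
      beh <- cohort$behavior
      tasks <- unique(beh$task_id)
      controls <- lapply(stats::setNames(tasks, tasks), function(tk)
        control_sample(beh$raw_score[beh$group == "control" & beh$task_id == tk]))
      corrected <- matrix(NA_real_, length(pat_ids), length(tasks),
                          dimnames = list(pat_ids, tasks))
      for (id in pat_ids) for (tk in tasks) {
        raw <- beh$raw_score[beh$observation_id == id & beh$task_id == tk]
        corrected[id, tk] <- crawford_howell_t(raw, controls[[tk]],
                                               task_id = tk)$t_value
      }
      comp <- composite_semantic(corrected[, config$semantic_tasks, drop = FALSE])
      composite <- stats::setNames(comp$value, comp$observation_id)
      group_tests <- lapply(stats::setNames(tasks, tasks), function(tk) {
        p <- beh$raw_score[beh$group == "patient" & beh$task_id == tk]
        cc <- beh$raw_score[beh$group == "control" & beh$task_id == tk]
        list(welch = welch_t(mean(p), stats::sd(p), length(p),
                             mean(cc), stats::sd(cc), length(cc)),
             pooled = student_t_pooled(mean(p), stats::sd(p), length(p),
                                       mean(cc), stats::sd(cc), length(cc)))
      })
      list(controls = controls, corrected_t = corrected,
           composite = composite, group_tests = group_tests)
    })
  }

  ## ---- atrophic network ---------------------------------------------------
  if ("atrophy" %in% stages) {
    res$atrophy <- stage("atrophy", {
      gmv_s <- lapply(cohort$gmv, gaussian_smooth, fwhm_mm = config$fwhm_gmv_mm)
      out <- list(gmv_smoothed = gmv_s)
      if (!is.null(config$atrophy_mask_override)) {
        out$mask <- as_mask_array(config$atrophy_mask_override)
        out$source <- "override"
        logf("atrophy mask supplied externally")
      } else {
        gt <- group_t_map(gmv_s[pat_ids], gmv_s[ctl_ids], brain, "pooled")
        fw <- estimate_fwhm(gt$residuals, brain)
        fwhm <- clamp_fwhm(fw, voxel_mm, logf)
        ac <- alphasim_min_cluster(volume(brain + 0, affine), fwhm,
                                   config$voxel_p_atrophy, config$alpha_atrophy,
                                   config$alphasim_iterations,
                                   config$connectivity,
                                   seed = config$rng_seed + 101L)
        tcrit <- stats::qt(1 - config$voxel_p_atrophy / 2, gt$df)
        cl <- extract_clusters(gt$t, brain, tcrit, ac$min_cluster_voxels,
                               config$connectivity)
        mask <- array(FALSE, d)
        for (v in attr(cl, "voxels")) mask[v] <- TRUE
        if (!any(mask))
          stop("empty atrophy mask: no cluster survived the corrected GMV contrast")
        out <- c(out, list(t_map = gt$t, df = gt$df, fwhm_mm = fwhm,
                           alphasim = ac, clusters = cl, mask = mask,
                           source = "data"))
      }
      out
    })
  }

  ## ---- fMRI preprocessing + degree ---------------------------------------
  if ("degree" %in% stages) {
    res$degree <- stage("degree", {
      amask <- res$atrophy$mask
      avox <- which(amask)
      keep <- vapply(obs$observation_id, function(id)
        motion_exclude(cohort$motion$summary[id, ],
                       config$trans_limit_mm, config$rot_limit_deg), logical(1))
      if (any(!keep))
        logf(sprintf("motion exclusion: dropped %s",
                     paste(obs$observation_id[!keep], collapse = ", ")))
      kept_ids <- obs$observation_id[keep]
      series <- list(); mfalff <- list(); zdeg <- list()
      for (id in kept_ids) {
        bo <- cohort_bold(cohort, id)
        bo <- discard_initial_volumes(bo, config$discard_volumes)
        bo <- gaussian_smooth(bo, config$fwhm_bold_mm)
        if (id %in% pat_ids)   # covariate only used for patient observations
          mfalff[[id]] <- mfalff_map(bo, brain, config$band)
        # detrend / band-pass / nuisance regression are voxel-wise, so they
        # are run on the atrophy-mask voxels only (compact layout)
        cd <- c(length(avox), 1L, 1L)
        sub <- bold_series(array(bold_vox_by_time(bo)[avox, , drop = FALSE],
                                 c(cd, dim(bo$data)[4])), bo$tr_s)
        sub <- detrend_bandpass(sub, config$band[1], config$band[2])
        conf <- cohort$motion$series[[id]][-seq_len(config$discard_volumes), ,
                                           drop = FALSE]
        sub <- nuisance_regress(sub, conf)
        S <- t(bold_vox_by_time(sub))                        # time x V(mask)
        series[[id]] <- S
        fc <- fc_matrix(sub, array(TRUE, cd))
        dm <- degree_map(fc, config$r_threshold)
        zc <- z_standardize(dm$data, array(TRUE, cd))
        zarr <- array(NA_real_, d)
        zarr[avox] <- zc$data
        zdeg[[id]] <- volume(zarr, affine, units = "z-degree")
      }
      pk <- intersect(pat_ids, kept_ids); ck <- intersect(ctl_ids, kept_ids)
      gt <- group_t_map(zdeg[pk], zdeg[ck], amask, "pooled")
      fw <- estimate_fwhm(gt$residuals, amask)
      fwhm <- clamp_fwhm(fw, voxel_mm, logf)
      ac <- alphasim_min_cluster(volume(amask + 0, affine), fwhm,
                                 config$voxel_p_degree, config$alpha_degree,
                                 config$alphasim_iterations, config$connectivity,
                                 seed = config$rng_seed + 102L)
      tcrit <- stats::qt(1 - config$voxel_p_degree / 2, gt$df)
      cl <- extract_clusters(gt$t, amask, tcrit, ac$min_cluster_voxels,
                             config$connectivity)
      out <- list(kept = kept_ids, n_patients = length(pk),
                  n_controls = length(ck), series = series, mfalff = mfalff,
                  zdegree = zdeg, t_map = gt$t, df = gt$df, fwhm_mm = fwhm,
                  alphasim = ac, clusters = cl, atrophy_voxels = avox)
      if (nrow(cl) > 0) {
        cl_vox <- attr(cl, "voxels")
        seeds <- lapply(cl_vox, function(v) {
          cm <- array(FALSE, d); cm[v] <- TRUE
          seed_from_peak(gt$t, cm, config$seed_radius_mm)
        })
        out$seeds <- seeds
        comp <- res$behavior$composite[pk]
        out$degree_behavior <- lapply(seq_along(seeds), function(i) {
          sv <- seeds[[i]]$voxels
          vals <- vapply(pk, function(id) values_in_voxels(zdeg[[id]], sv),
                         numeric(1))
          pearson_r(vals, comp)
        })
      } else {
        logf("no degree-contrast cluster survived; seed stages skipped")
      }
      out
    })
  }

  ## ---- seed FC-behavior maps ---------------------------------------------
  if ("seedfc" %in% stages && !is.null(res$degree$seeds)) {
    res$seedfc <- stage("seedfc", {
      amask <- res$atrophy$mask
      avox <- res$degree$atrophy_voxels
      seed <- res$degree$seeds[[1]]
      pk <- intersect(pat_ids, res$degree$kept)
      comp <- res$behavior$composite[pk]
      seed_compact <- seed
      seed_compact$voxels <- match(seed$voxels, avox)
      cd <- c(length(avox), 1L, 1L)
      zmaps <- lapply(pk, function(id) {
        S <- res$degree$series[[id]]
        pseudo <- bold_series(array(t(S), c(cd, nrow(S))), cohort$config$tr_s)
        zc <- seed_fc_zmap(pseudo, seed_compact, array(TRUE, cd))
        zarr <- array(NA_real_, d)
        zarr[avox] <- zc$data
        volume(zarr, affine, units = "fisher_z")
      })
      names(zmaps) <- pk
      bc <- map_behavior_correlation(zmaps, comp, mask = amask)
      # residual maps (per-voxel mean removed) carry the spatial smoothness
      resid <- lapply(zmaps, function(v) v)
      mean_arr <- Reduce(`+`, lapply(zmaps, function(v) {
        a <- v$data; a[is.na(a)] <- 0; a
      })) / length(zmaps)
      resid <- lapply(zmaps, function(v) volume(v$data - mean_arr, affine))
      fw <- estimate_fwhm(resid, amask)
      fwhm <- clamp_fwhm(fw, voxel_mm, logf)
      ac <- alphasim_min_cluster(volume(amask + 0, affine), fwhm,
                                 config$voxel_p_fc, config$alpha_fc,
                                 config$alphasim_iterations, config$connectivity,
                                 seed = config$rng_seed + 103L)
      rcrit <- r_critical(config$voxel_p_fc, bc$df)
      cl <- extract_clusters(bc$r, amask, rcrit, ac$min_cluster_voxels,
                             config$connectivity)
      cluster_r <- if (nrow(cl) > 0) {
        vl <- attr(cl, "voxels")
        lapply(seq_along(vl), function(i) {
          vals <- vapply(pk, function(id) values_in_voxels(zmaps[[id]], vl[[i]]),
                         numeric(1))
          pearson_r(vals, comp)
        })
      } else list()
      list(seed = seed, zmaps = zmaps, r_map = bc$r, p_map = bc$p, df = bc$df,
           fwhm_mm = fwhm, alphasim = ac, clusters = cl,
           cluster_correlations = cluster_r)
    })
  }

  ## ---- covariate validation ----------------------------------------------
  if ("validate" %in% stages && !is.null(res$seedfc) &&
      nrow(res$seedfc$clusters) > 0) {
    res$validate <- stage("validate", {
      pk <- intersect(pat_ids, res$degree$kept)
      cov <- pipeline_covariates(cohort, res, pk, brain)
      vl <- attr(res$seedfc$clusters, "voxels")
      vals <- vapply(vl, function(v)
        vapply(pk, function(id) values_in_voxels(res$seedfc$zmaps[[id]], v),
               numeric(1)),
        numeric(length(pk)))
      colnames(vals) <- paste0("cluster", seq_along(vl))
      first_obs <- obs$obs_index[match(pk, obs$observation_id)] == 1L
      validate_with_covariates(vals, res$behavior$composite[pk], cov,
                               first_obs = first_obs)
    })
  }

  ## ---- non-semantic specificity ------------------------------------------
  if ("specificity" %in% stages && !is.null(res$seedfc) &&
      nrow(res$seedfc$clusters) > 0) {
    res$specificity <- stage("specificity", {
      pk <- intersect(pat_ids, res$degree$kept)
      vl <- attr(res$seedfc$clusters, "voxels")
      vals <- vapply(vl, function(v)
        vapply(pk, function(id) values_in_voxels(res$seedfc$zmaps[[id]], v),
               numeric(1)),
        numeric(length(pk)))
      colnames(vals) <- paste0("cluster", seq_along(vl))
      ns <- res$behavior$corrected_t[pk, config$nonsemantic_tasks, drop = FALSE]
      specificity_test(vals, res$behavior$composite[pk], ns)
    })
  }

  ## ---- structural basis ---------------------------------------------------
  if ("tract" %in% stages && !is.null(res$seedfc) &&
      nrow(res$seedfc$clusters) > 0) {
    res$tract <- stage("tract", {
      pk <- intersect(pat_ids, res$degree$kept)
      roiA_vox <- attr(res$degree$clusters, "voxels")[[1]]
      roiA <- array(FALSE, d); roiA[roiA_vox] <- TRUE
      tensors <- lapply(stats::setNames(obs$observation_id, obs$observation_id),
                        function(id)
        fit_tensor(cohort$dwi[[id]], cohort$gradients, affine = affine))
      ldh <- lapply(stats::setNames(obs$observation_id, obs$observation_id),
                    function(id)
        ldh_map(cohort$dwi[[id]], cohort$gradients, affine = affine))
      vl <- attr(res$seedfc$clusters, "voxels")
      per_cluster <- lapply(seq_along(vl), function(ci) {
        roiB <- array(FALSE, d); roiB[vl[[ci]]] <- TRUE
        masks <- lapply(seq_along(ctl_ids), function(j) {
          st <- fact_track(tensors[[ctl_ids[j]]], which(roiA),
                           config$seeds_per_voxel, config$angle_max_deg,
                           config$fa_min,
                           rng_seed = config$rng_seed + 200L + j)
          tract_mask_between(st, roiA, roiB)
        })
        gm <- group_count_mask(masks, config$min_tract_subjects)
        if (!any(gm$mask$data != 0)) {
          logf(sprintf("FC cluster %d: no group tract (count mask empty)", ci))
          return(list(tract = gm, connected = FALSE))
        }
        integ <- lapply(obs$observation_id, function(id)
          tract_integrity(gm, tensors[[id]]$fa, ldh[[id]]))
        names(integ) <- obs$observation_id
        fa_v <- vapply(integ, `[[`, numeric(1), "mean_fa")
        ldh_v <- vapply(integ, `[[`, numeric(1), "mean_ldh")
        gtest <- function(x) {
          list(welch = welch_t(mean(x[pat_ids]), stats::sd(x[pat_ids]),
                               length(pat_ids),
                               mean(x[ctl_ids]), stats::sd(x[ctl_ids]),
                               length(ctl_ids)),
               pooled = student_t_pooled(mean(x[pat_ids]), stats::sd(x[pat_ids]),
                                         length(pat_ids),
                                         mean(x[ctl_ids]), stats::sd(x[ctl_ids]),
                                         length(ctl_ids)))
        }
        comp <- res$behavior$composite[pk]
        cov <- pipeline_covariates(cohort, res, pk, brain)
        first_obs <- obs$obs_index[match(pk, obs$observation_id)] == 1L
        mk_tab <- function(x) {
          m <- matrix(x[pk], ncol = 1,
                      dimnames = list(pk, "tract"))
          validate_with_covariates(m, comp, cov, first_obs = first_obs)
        }
        ns <- res$behavior$corrected_t[pk, config$nonsemantic_tasks,
                                       drop = FALSE]
        list(tract = gm, connected = TRUE,
             mean_fa = fa_v, mean_ldh = ldh_v,
             fa_group = gtest(fa_v), ldh_group = gtest(ldh_v),
             fa_behavior = pearson_r(fa_v[pk], comp),
             ldh_behavior = pearson_r(ldh_v[pk], comp),
             fa_validation = mk_tab(fa_v),
             ldh_validation = mk_tab(ldh_v),
             fa_specificity = specificity_test(
               matrix(fa_v[pk], ncol = 1, dimnames = list(pk, "tract")),
               comp, ns),
             ldh_specificity = specificity_test(
               matrix(ldh_v[pk], ncol = 1, dimnames = list(pk, "tract")),
               comp, ns))
      })
      list(per_cluster = per_cluster)
    })
  }

  structure(res, class = "nb_results")
}

r_critical <- function(p, df) {
  tc <- stats::qt(1 - p / 2, df)
  sqrt(tc^2 / (tc^2 + df))
}

pipeline_covariates <- function(cohort, res, pat_ids, brain) {
  seed <- if (!is.null(res$seedfc)) res$seedfc$seed else res$degree$seeds[[1]]
  gmv_s <- res$atrophy$gmv_smoothed
  obs <- cohort$observations
  data.frame(
    total_gmv = vapply(pat_ids, function(id) sum(gmv_s[[id]]$data[brain]),
                       numeric(1)),
    seed_gmv = vapply(pat_ids, function(id)
      sum(gmv_s[[id]]$data[seed$voxels]), numeric(1)),
    seed_mfalff = vapply(pat_ids, function(id)
      sum(res$degree$mfalff[[id]]$data[seed$voxels]), numeric(1)),
    obs_index = obs$obs_index[match(pat_ids, obs$observation_id)],
    row.names = pat_ids)
}

#' Confound-controlled correlation table
#'
#' For each column of `cluster_values`: the raw correlation with the
#' scores, the partial correlation with each covariate removed
#' individually, the partial with all covariates removed jointly, and the
#' raw correlation on the first-observation subset.
#'
#' @param cluster_values numeric matrix, observations x clusters.
#' @param scores behavioral scores aligned with the rows.
#' @param covariates data.frame/matrix of covariates (full rank).
#' @param first_obs logical vector marking first observations (optional).
#' @return data.frame with columns `cluster`, `model`, `r`, `df`, `p`, `n`.
#' @export
validate_with_covariates <- function(cluster_values, scores, covariates,
                                     first_obs = NULL) {
  M <- as.matrix(cluster_values)
  C <- as.matrix(covariates)
  if (qr(cbind(1, C))$rank < ncol(C) + 1)
    stop("collinearity: covariate design is rank deficient")
  labs <- colnames(C)
  rows <- list()
  add <- function(cluster, model, cr, n) {
    # degenerate partials (e.g. a covariate equal to the scores) are
    # flagged as NA rather than aborting the whole table
    if (inherits(cr, "error")) cr <- list(r = NA_real_, df = NA_integer_,
                                          p = NA_real_)
    rows[[length(rows) + 1]] <<- data.frame(
      cluster = cluster, model = model, r = cr$r, df = cr$df, p = cr$p, n = n)
  }
  try_cor <- function(expr) tryCatch(expr, error = function(e) e)
  for (j in seq_len(ncol(M))) {
    cn <- colnames(M)[j]
    x <- M[, j]
    add(cn, "raw", try_cor(pearson_r(x, scores)), length(x))
    for (k in seq_len(ncol(C))) {
      add(cn, paste0("partial:", labs[k]),
          try_cor(partial_r(x, scores, C[, k, drop = FALSE],
                            covariate_labels = labs[k])), length(x))
    }
    add(cn, "partial:all",
        try_cor(partial_r(x, scores, C, covariate_labels = labs)), length(x))
    if (!is.null(first_obs) && sum(first_obs) >= 3) {
      add(cn, "first_observations",
          pearson_r(x[first_obs], scores[first_obs]), sum(first_obs))
    }
  }
  do.call(rbind, rows)
}

#' Non-semantic specificity table
#'
#' Correlates each cluster value with each non-semantic score, and the
#' semantic score partialling out all non-semantic scores jointly.
#'
#' @param cluster_values numeric matrix, observations x clusters.
#' @param semantic_scores semantic composite per observation.
#' @param nonsemantic_scores matrix observations x non-semantic tasks.
#' @return data.frame with `cluster`, `model`, `r`, `df`, `p`.
#' @export
specificity_test <- function(cluster_values, semantic_scores,
                             nonsemantic_scores) {
  M <- as.matrix(cluster_values)
  NS <- as.matrix(nonsemantic_scores)
  if (nrow(NS) != nrow(M) || length(semantic_scores) != nrow(M))
    stop("length mismatch between cluster values and scores")
  rows <- list()
  for (j in seq_len(ncol(M))) {
    cn <- colnames(M)[j]
    for (k in seq_len(ncol(NS))) {
      cr <- pearson_r(M[, j], NS[, k])
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cn, model = paste0("nonsemantic:", colnames(NS)[k]),
        r = cr$r, df = cr$df, p = cr$p)
    }
    cr <- tryCatch(partial_r(M[, j], semantic_scores, NS,
                             covariate_labels = colnames(NS)),
                   error = function(e) list(r = NA_real_, df = NA_integer_,
                                            p = NA_real_))
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cn, model = "semantic|nonsemantic", r = cr$r, df = cr$df,
      p = cr$p)
  }
  do.call(rbind, rows)
}

#' Does a results bundle report any significant behavior association?
#'
#' Checks, at the pipeline's own thresholds: the degree-behavior
#' correlation (p < 0.05), any surviving FC-behavior cluster, and the
#' tract FA/LDH-behavior correlations (p < 0.05).
#'
#' @param results a `nb_results`.
#' @return TRUE if any behavior association is reported significant.
#' @export
has_significant_association <- function(results) {
  if (!is.null(results$degree$degree_behavior)) {
    if (any(vapply(results$degree$degree_behavior,
                   function(cr) cr$p < 0.05, logical(1)))) return(TRUE)
  }
  if (!is.null(results$seedfc) && nrow(results$seedfc$clusters) > 0) return(TRUE)
  if (!is.null(results$tract)) {
    for (pc in results$tract$per_cluster) {
      if (isTRUE(pc$connected) &&
          (pc$fa_behavior$p < 0.05 || pc$ldh_behavior$p < 0.05)) return(TRUE)
    }
  }
  FALSE
}

#' Write-then-read consistency check
#'
#' Writes the object in its canonical on-disk format and reads it back:
#' NIfTI-1 for volumes and 4D series, TSV for behavior tables, bvec/bval
#' for gradient tables.
#'
#' @param x a `nb_volume`, `nb_bold`, behavior data.frame, or
#'   `nb_gradient_table`.
#' @param dir directory for the temporary file (default `tempdir()`).
#' @return the re-read object.
#' @export
io_roundtrip <- function(x, dir = tempdir()) {
  if (inherits(x, "nb_volume") || inherits(x, "nb_bold")) {
    p <- file.path(dir, "roundtrip.nii.gz")
    write_nifti(x, p)
    read_nifti(p)
  } else if (inherits(x, "nb_gradient_table")) {
    p <- file.path(dir, "roundtrip")
    write_bvec_bval(x, p)
    read_bvec_bval(p)
  } else if (is.data.frame(x)) {
    p <- file.path(dir, "roundtrip.tsv")
    write_behavior_tsv(x, p)
    read_behavior_tsv(p)
  } else stop("unsupported object for io_roundtrip")
}
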