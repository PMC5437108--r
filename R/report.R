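#' Write a results bundle to disk with a Markdown report
#'
#' Emits: `report.md` (settings header with the stage thresholds verbatim,
#' behavioral group tests, cluster tables, correlation tables), the cluster
#' tables as TSV, the seed as JSON, the statistic maps as NIfTI, and a JSON
#' manifest listing every artifact so each reported number traces to a
#' file.
#'
#' @param results a `nb_results`.
#' @param dir output directory (created if needed).
#' @return path of `report.md`, invisibly.
#' @export
results_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- results$config
  manifest <- list()
  put <- function(name, path) manifest[[name]] <<- basename(path)
  lines <- c("# Network-behavior mapping report", "",
             "## Settings", "",
             sprintf("- effective FC threshold: r > %g", cfg$r_threshold),
             sprintf("- seed radius: %g mm", cfg$seed_radius_mm),
             sprintf("- atrophy contrast: voxel p < %g, corrected alpha %g",
                     cfg$voxel_p_atrophy, cfg$alpha_atrophy),
             sprintf("- degree contrast: voxel p < %g, corrected alpha %g",
                     cfg$voxel_p_degree, cfg$alpha_degree),
             sprintf("- FC-behavior maps: voxel p < %g, corrected alpha %g",
                     cfg$voxel_p_fc, cfg$alpha_fc),
             sprintf("- smoothing: %g mm (GMV), %g mm (BOLD)",
                     cfg$fwhm_gmv_mm, cfg$fwhm_bold_mm),
             sprintf("- band-pass: %g-%g Hz", cfg$band[1], cfg$band[2]),
             sprintf("- tracking: %d seeds/voxel, angle %g deg, FA >= %g, count > %d-1 subjects",
                     cfg$seeds_per_voxel, cfg$angle_max_deg, cfg$fa_min,
                     cfg$min_tract_subjects),
             sprintf("- rng seed: %d", cfg$rng_seed), "")
  fmt_corr <- function(cr) sprintf("r = %.3f (df = %d, p = %.4g)", cr$r, cr$df, cr$p)
  if (!is.null(results$behavior)) {
    lines <- c(lines, "## Behavioral group tests", "",
               "| task | Welch t (df) | pooled t (df) |", "|---|---|---|")
    for (tk in names(results$behavior$group_tests)) {
      g <- results$behavior$group_tests[[tk]]
      lines <- c(lines, sprintf("| %s | %.2f (%.1f) | %.2f (%d) |", tk,
                                g$welch$t, g$welch$df, g$pooled$t, g$pooled$df))
    }
    lines <- c(lines, "")
  }
  dump_clusters <- function(cl, name) {
    p <- file.path(dir, paste0(name, "_clusters.tsv"))
    write_cluster_tsv(cl, p); put(paste0(name, "_clusters"), p)
    c(sprintf("## %s clusters (%d)", name, nrow(cl)), "",
      utils::capture.output(print(as.data.frame(cl))), "")
  }
  if (!is.null(results$atrophy$clusters)) {
    write_nifti(results$atrophy$t_map, file.path(dir, "atrophy_t.nii.gz"))
    put("atrophy_t_map", file.path(dir, "atrophy_t.nii.gz"))
    lines <- c(lines, dump_clusters(results$atrophy$clusters, "atrophy"),
               sprintf("AlphaSim min cluster: %d voxels",
                       results$atrophy$alphasim$min_cluster_voxels), "")
  }
  if (!is.null(results$degree)) {
    write_nifti(results$degree$t_map, file.path(dir, "degree_t.nii.gz"))
    put("degree_t_map", file.path(dir, "degree_t.nii.gz"))
    lines <- c(lines, dump_clusters(results$degree$clusters, "degree"))
    if (!is.null(results$degree$degree_behavior)) {
      for (i in seq_along(results$degree$degree_behavior)) {
        lines <- c(lines, sprintf("degree-behavior (cluster %d): %s", i,
                                  fmt_corr(results$degree$degree_behavior[[i]])))
      }
      sp <- file.path(dir, "seed.json")
      write_seed_json(results$degree$seeds[[1]], sp); put("seed", sp)
      lines <- c(lines, "")
    }
  }
  if (!is.null(results$seedfc)) {
    write_nifti(results$seedfc$r_map, file.path(dir, "fc_behavior_r.nii.gz"))
    put("fc_behavior_r_map", file.path(dir, "fc_behavior_r.nii.gz"))
    lines <- c(lines, dump_clusters(results$seedfc$clusters, "fc_behavior"))
    for (i in seq_along(results$seedfc$cluster_correlations)) {
      lines <- c(lines, sprintf("FC-behavior (cluster %d): %s", i,
                                fmt_corr(results$seedfc$cluster_correlations[[i]])))
    }
    lines <- c(lines, "")
  }
  dump_table <- function(tab, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    put(name, p)
    c(sprintf("## %s", name), "", utils::capture.output(print(tab)), "")
  }
  if (!is.null(results$validate))
    lines <- c(lines, dump_table(results$validate, "validation"))
  if (!is.null(results$specificity))
    lines <- c(lines, dump_table(results$specificity, "specificity"))
  if (!is.null(results$tract)) {
    for (i in seq_along(results$tract$per_cluster)) {
      pc <- results$tract$per_cluster[[i]]
      if (!isTRUE(pc$connected)) {
        lines <- c(lines, sprintf("## Tract to FC cluster %d: not connected", i), "")
        next
      }
      lines <- c(lines,
                 sprintf("## Tract to FC cluster %d", i), "",
                 sprintf("- voxels: %d", sum(pc$tract$mask$data != 0)),
                 sprintf("- FA group Welch t = %.2f; LDH group Welch t = %.2f",
                         pc$fa_group$welch$t, pc$ldh_group$welch$t),
                 sprintf("- FA-behavior: %s", fmt_corr(pc$fa_behavior)),
                 sprintf("- LDH-behavior: %s", fmt_corr(pc$ldh_behavior)), "")
    }
  }
  if (length(results$log))
    lines <- c(lines, "## Log", "", paste0("- ", results$log), "")
  rp <- file.path(dir, "report.md")
  writeLines(lines, rp)
  put("report", rp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(rp)
}

#' Command-line entry point
#'
#' Subcommands: `synth --out DIR [--seed N]` writes a synthetic cohort;
#' `run --out DIR [--seed N] [--config cfg.json]` generates a cohort, runs
#' the pipeline and writes the report; `report DIR` prints an existing
#' report.
#'
#' @param args character vector (default: the R session's command line).
#' @return exit status, invisibly.
#' @export
netbeh_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cmd <- if (length(args)) args[1] else "help"
  status <- 0L
  tryCatch({
    if (cmd == "synth") {
      seed <- as.integer(getopt("--seed", "1"))
      out <- getopt("--out", stop("synth requires --out"))
      cohort <- generate_cohort(synthetic_config(rng_seed = seed))
      write_cohort(cohort, out)
      cat("cohort written to ", out, "\n")
    } else if (cmd == "run") {
      seed <- as.integer(getopt("--seed", "1"))
      out <- getopt("--out", stop("run requires --out"))
      cfgf <- getopt("--config")
      cfg_args <- if (!is.null(cfgf)) jsonlite::read_json(cfgf, simplifyVector = TRUE)
                  else list()
      cfg_args$rng_seed <- seed
      config <- do.call(pipeline_config, cfg_args)
      cohort <- generate_cohort(synthetic_config(rng_seed = seed))
      results <- run_pipeline(cohort, config)
      results_report(results, out)
      cat("report written to ", file.path(out, "report.md"), "\n")
    } else if (cmd == "report") {
      if (length(args) < 2) stop("report requires a directory")
      cat(readLines(file.path(args[2], "report.md")), sep = "\n")
    } else {
      cat("usage: netbeh <synth|run|report> [--out DIR] [--seed N] [--config cfg.json]\n")
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}
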