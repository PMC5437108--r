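#' Control sample summary for single-case standardization
#'
#' @param values numeric vector of control scores.
#' @return object of class `nb_control_sample` with `values`, `n`, `mean`,
#'   `sd` (sample, n-1 denominator).
#' @export
control_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("insufficient controls: need n >= 2")
  s <- stats::sd(values)
  structure(list(values = values, n = length(values),
                 mean = mean(values), sd = s),
            class = "nb_control_sample")
}

#' Crawford-Howell single-case t
#'
#' Compares one patient score against a small control sample:
#' `t = (x - mean) / (sd * sqrt((n + 1) / n))` with `df = n - 1`. The
#' classification follows the clinical rule: impaired below the cutoff,
#' spared above it (the dichotomy the diagnostic criteria use).
#'
#' @param patient_score single raw score.
#' @param controls a `nb_control_sample` (or numeric vector of control scores).
#' @param cutoff classification cutoff on the t scale (default -1.96).
#' @param task_id optional label.
#' @return object of class `nb_corrected_score` with `t_value`, `df`, `p`
#'   (two-sided), `classification` in `impaired` / `spared` /
#'   `indeterminate` (exactly at the cutoff), and `cutoff`.
#' @export
crawford_howell_t <- function(patient_score, controls, cutoff = -1.96,
                              task_id = NA_character_) {
  if (!inherits(controls, "nb_control_sample")) controls <- control_sample(controls)
  if (controls$sd <= 0) stop("standardization undefined: control sd is zero")
  t_val <- (patient_score - controls$mean) /
    (controls$sd * sqrt((controls$n + 1) / controls$n))
  df <- controls$n - 1
  cls <- if (t_val < cutoff) "impaired" else if (t_val > cutoff) "spared" else "indeterminate"
  structure(list(task_id = task_id, t_value = t_val, df = df,
                 p = 2 * stats::pt(-abs(t_val), df),
                 classification = cls, cutoff = cutoff),
            class = "nb_corrected_score")
}

#' Semantic composite scores
#'
#' Per task, z-transforms the corrected t scores across patients (sample
#' sd), then averages the per-task z scores within each patient
#' (observation). Composites are centered: they sum to zero across the
#' standardization set.
#'
#' @param corrected_t_by_task numeric matrix, patients x tasks.
#' @return data.frame with `observation_id` and `value`.
#' @export
composite_semantic <- function(corrected_t_by_task) {
  m <- as.matrix(corrected_t_by_task)
  if (nrow(m) < 2L) stop("need at least 2 patients")
  sds <- apply(m, 2, stats::sd)
  if (any(sds <= 0)) {
    stop("degenerate task: constant corrected-t column ",
         paste(which(sds <= 0), collapse = ", "))
  }
  z <- scale(m)                      # sample sd
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  data.frame(observation_id = ids, value = rowMeans(z),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch's unequal-variance two-sample t from summary statistics
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("undefined test: both group sds are zero")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pooled-variance (Student) two-sample t from summary statistics
#'
#' @inheritParams welch_t
#' @return list with `t`, `df = n1 + n2 - 2` and two-sided `p`.
#' @export
student_t_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 + n2 >= 3)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("undefined test: pooled variance is zero")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

correlation_result <- function(r, df, covariate_labels = character(0)) {
  t <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(r = r, df = df, p = p, covariate_labels = covariate_labels),
            class = "nb_correlation")
}

#' @export
print.nb_correlation <- function(x, ...) {
  lab <- if (length(x$covariate_labels))
    paste0(" | ", paste(x$covariate_labels, collapse = ", ")) else ""
  cat(sprintf("r = %.3f (df = %d, p = %.4g)%s\n", x$r, x$df, x$p, lab))
  invisible(x)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return `nb_correlation` with `r`, `df = n - 2`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  correlation_result(stats::cor(x, y), n - 2L)
}

#' Partial Pearson correlation by residualization
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares, then correlates the residuals; `df = n - 2 - q`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x q) or NULL/empty for plain Pearson.
#' @param covariate_labels optional labels recorded in the result.
#' @return `nb_correlation`.
#' @export
partial_r <- function(x, y, covariates = NULL, covariate_labels = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0 || length(covariates) == 0)
    return(pearson_r(x, y))
  C <- as.matrix(covariates)
  q <- ncol(C)
  if (is.null(covariate_labels)) {
    covariate_labels <- colnames(C)
    if (is.null(covariate_labels)) covariate_labels <- paste0("cov", seq_len(q))
  }
  if (n <= 2 + q) stop("too few observations for ", q, " covariates")
  X <- cbind(1, C)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("collinearity: covariate design is rank deficient")
  rx <- stats::residuals(stats::lm.fit(X, x))
  ry <- stats::residuals(stats::lm.fit(X, y))
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) || stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    stop("undefined correlation: residuals are constant after covariate removal")
  correlation_result(stats::cor(rx, ry), as.integer(n - 2L - q), covariate_labels)
}

#' Fisher r-to-z transform
#'
#' @param r correlation in (-1, 1).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("saturated correlation: |r| >= 1 has no finite z")
  atanh(r)
}

#' Pearson chi-square on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of counts with positive margins.
#' @return list with `chi2`, `df = 1`, `p`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("undefined chi-square: empty margin")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - e)^2 / e)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Rule-based semantic-dementia diagnostic classification
#'
#' Core features: impaired confrontation naming (both naming tasks),
#' impaired single-word comprehension (all three comprehension tasks), and
#' anterior-temporal gray-matter volume strictly below the control mean
#' minus two control standard deviations. The profile must additionally
#' satisfy at least 3 of 4 other features (surface dyslexia and impaired
#' object knowledge = impaired; repetition and speech production = spared).
#'
#' @param corrected named list of `nb_corrected_score` objects; required
#'   names: `oral_picture_naming`, `oral_sound_naming`, `picture_matching`,
#'   `word_matching`, `word_picture_verification`, `surface_dyslexia`,
#'   `object_knowledge`, `repetition`, `speech_production`.
#' @param atl_gmv anterior-temporal gray-matter volume of the patient.
#' @param control_atl `nb_control_sample` of control anterior-temporal GMV.
#' @return list with per-feature logicals and `meets_criteria`.
#' @export
classify_sd_diagnosis <- function(corrected, atl_gmv, control_atl) {
  core_naming <- c("oral_picture_naming", "oral_sound_naming")
  core_compr <- c("picture_matching", "word_matching", "word_picture_verification")
  other <- c(surface_dyslexia = "impaired", object_knowledge = "impaired",
             repetition = "spared", speech_production = "spared")
  needed <- c(core_naming, core_compr, names(other))
  missing <- setdiff(needed, names(corrected))
  if (length(missing))
    stop("incomplete profile: missing task(s) ", paste(missing, collapse = ", "))
  cls <- vapply(corrected, function(s) s$classification, character(1))
  if (!inherits(control_atl, "nb_control_sample"))
    control_atl <- control_sample(control_atl)
  naming_impaired <- all(cls[core_naming] == "impaired")
  comprehension_impaired <- all(cls[core_compr] == "impaired")
  atrophy <- atl_gmv < control_atl$mean - 2 * control_atl$sd    # strict
  other_ok <- cls[names(other)] == other
  n_other <- sum(other_ok)
  list(naming_impaired = naming_impaired,
       comprehension_impaired = comprehension_impaired,
       anterior_temporal_atrophy = atrophy,
       other_features = other_ok,
       n_other_features = n_other,
       meets_criteria = naming_impaired && comprehension_impaired &&
         atrophy && n_other >= 3)
}
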