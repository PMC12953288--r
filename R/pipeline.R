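#' Pipeline run configuration
#'
#' Assembles and validates the configuration for an end-to-end run:
#' simulate -> (optionally segment) -> grade -> analyze. Every random stage
#' derives its own seed deterministically from the global seed, so one
#' integer reproduces the whole run.
#'
#' @param seed Global integer seed.
#' @param output_dir Directory for artifacts and the run report.
#' @param mode "tabular" (cohort generated directly; fast statistics path) or
#'   "imaging" (a subset of patients additionally gets synthetic images that
#'   are actually segmented, validating the DIA arm against ground truth).
#' @param cohort Named list of \code{\link{cohort_spec}} overrides.
#' @param image Named list of \code{\link{image_spec}} overrides.
#' @param n_imaging_patients Patients receiving images in imaging mode.
#' @param morphometry List: pixel_size_um, intensity_threshold,
#'   circularity_min, watershed.
#' @param analysis List: alpha, candidate predictor names, optional
#'   interaction terms.
#' @param stages Named logical list enabling simulate/grade/analyze.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L,
                       output_dir = tempfile("steatomorph_run_"),
                       mode = c("tabular", "imaging"),
                       cohort = list(),
                       image = list(),
                       n_imaging_patients = 3L,
                       morphometry = list(pixel_size_um = 0.25,
                                          intensity_threshold = 0.75,
                                          circularity_min = 0.6,
                                          watershed = FALSE),
                       analysis = list(
                         alpha = 0.05,
                         candidates = c("age", "pdff_distance",
                                        "biopsy_length_mm", "portal_tracts",
                                        "microvesicular", "inflammation_ge2",
                                        "fibrosis_f2_4", "tiny_pct",
                                        "small_pct", "large_pct", "total_pct"),
                         interactions = NULL
                       ),
                       stages = list(simulate = TRUE, grade = TRUE,
                                     analyze = TRUE)) {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), output_dir = output_dir, mode = mode,
              cohort = cohort, image = image,
              n_imaging_patients = as.integer(n_imaging_patients),
              morphometry = morphometry, analysis = analysis, stages = stages)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$seed)) stop("seed must be an integer")
  a <- cfg$analysis$alpha
  if (is.null(a) || a <= 0 || a >= 1) stop("analysis$alpha must lie in (0, 1)")
  if (!cfg$mode %in% c("tabular", "imaging")) stop("unknown mode")
  for (s in c("simulate", "grade", "analyze")) {
    if (is.null(cfg$stages[[s]])) stop("stages$", s, " missing")
  }
  invisible(cfg)
}

# fixed per-stage offsets keep stage seeds deterministic and < 2^31
stage_seed <- function(seed, stage) {
  offs <- c(cohort = 101L, image = 211L, outcome = 307L)
  (as.integer(seed) * 1000L + offs[[stage]]) %% .Machine$integer.max
}

#' Serialize / parse a run configuration
#'
#' YAML round-trip of the configuration: \code{read_run_config} returns a
#' \code{run_config} equal to the one written.
#'
#' @param config A \code{\link{run_config}}.
#' @param path YAML file path.
#' @return \code{read_run_config} returns a \code{run_config};
#'   \code{write_run_config} returns \code{path} invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cohort <- as_spec_list(raw$cohort)
  raw$image <- as_spec_list(raw$image)
  do.call(run_config, raw)
}

# yaml returns nested lists; restore plain numeric vectors where specs expect
as_spec_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(el) {
    if (is.list(el) && length(el) && all(vapply(el, is.numeric, logical(1))) &&
        all(lengths(el) == 1) && is.null(names(el))) {
      unlist(el)
    } else el
  })
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writes versioned CSV artifacts under
#' \code{output_dir} (cohort, graded cohort, cross-tabulation, Table-2-style
#' model, stratified comparison, correlations) plus a human-readable
#' \code{report.txt} listing per-stage parameters, seeds and headline
#' numbers. Identical configurations produce identical files.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the cohort, the analysis objects and the
#'   report lines.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  rpt <- c("steatomorph pipeline report",
           sprintf("global seed: %d | mode: %s", config$seed, config$mode))
  result <- list(config = config)

  cohort <- NULL
  if (isTRUE(config$stages$simulate)) {
    cs_args <- config$cohort
    cs_args$seed <- stage_seed(config$seed, "cohort")
    cspec <- do.call(cohort_spec, cs_args)
    cohort <- generate_cohort(cspec)
    write_cohort(cohort, out("cohort.csv"))
    rpt <- c(rpt, sprintf(
      "simulate: n = %d patients (seed %d); total LD %.2f +/- %.2f %%",
      nrow(cohort), cspec$seed, mean(cohort$total_pct), stats::sd(cohort$total_pct)))

    if (config$mode == "imaging") {
      val <- imaging_validation(cohort, config)
      utils::write.csv(val, out("imaging_validation.csv"), row.names = FALSE)
      result$imaging_validation <- val
      rpt <- c(rpt, sprintf(
        "imaging: %d patients segmented; mean |recovered - true| total LD = %.3f %%",
        nrow(val), mean(abs(val$recovered_total_pct - val$true_total_pct))))
    }
  } else {
    cohort <- read_cohort(out("cohort.csv"))
  }

  if (isTRUE(config$stages$grade)) {
    cohort <- grade_cohort(cohort)
    write_cohort(cohort, out("cohort_graded.csv"))
    rpt <- c(rpt, sprintf("grade: PDFF grades assigned at thresholds %s",
                          paste(PDFF_GRADE_THRESHOLDS, collapse = "/")))
  }

  if (isTRUE(config$stages$analyze)) {
    an <- analyze_cohort(cohort, config$analysis)
    utils::write.csv(as.data.frame(an$discordance$crosstab),
                     out("crosstab.csv"), row.names = FALSE)
    utils::write.csv(an$model_table, out("model.csv"), row.names = FALSE)
    utils::write.csv(an$stratified, out("stratified.csv"), row.names = FALSE)
    utils::write.csv(an$correlations, out("correlations.csv"), row.names = FALSE)
    result$analysis <- an
    rpt <- c(rpt,
      sprintf("analyze: discordance %.1f%% (95%% CI %.1f-%.1f%%), n = %d",
              100 * an$discordance$rate, 100 * an$discordance$rate_ci[1],
              100 * an$discordance$rate_ci[2], an$discordance$n),
      sprintf("analyze: Pearson r(pdff_pct, total_pct) = %.3f",
              an$correlations$coefficient[
                an$correlations$x == "pdff_pct" &
                an$correlations$y == "total_pct"]),
      sprintf("analyze: multivariable predictors entered: %s",
              paste(an$model$predictors_entered, collapse = ", ")),
      sprintf("analyze: excluded for collinearity: %s",
              paste(an$model$predictors_excluded_collinear, collapse = ", ")))
  }

  result$cohort <- cohort
  writeLines(rpt, out("report.txt"))
  result$report <- rpt
  invisible(result)
}

analyze_cohort <- function(cohort, analysis) {
  disc <- discordance_summary(cohort)
  candidates <- intersect(analysis$candidates, names(cohort))
  model <- multivariable_logit(cohort, candidates,
                               alpha = analysis$alpha,
                               interactions = analysis$interactions)
  uni <- model$univariable
  uni$stage <- "univariable"
  multi <- model$table
  multi$candidate <- multi$predictor
  multi$stage <- "multivariable"
  model_table <- rbind(uni[, c("candidate", "predictor", "odds_ratio",
                               "ci_low", "ci_high", "p_value", "stage")],
                       multi[, c("candidate", "predictor", "odds_ratio",
                                 "ci_low", "ci_high", "p_value", "stage")])
  strat <- stratified_comparison(cohort)
  cors <- rbind(
    data.frame(x = "pdff_pct", y = "total_pct", method = "pearson",
               stringsAsFactors = FALSE),
    data.frame(x = "hist_grade", y = c("tiny_pct", "small_pct", "large_pct",
                                       "total_pct", "pdff_pct"),
               method = "spearman", stringsAsFactors = FALSE)
  )
  cors$coefficient <- NA_real_
  cors$p_value <- NA_real_
  for (i in seq_len(nrow(cors))) {
    cr <- correlate(cohort, cors$x[i], cors$y[i], cors$method[i])
    cors$coefficient[i] <- cr$coefficient
    cors$p_value[i] <- cr$p_value
  }
  wil <- wilcoxon_paired_by_grade(cohort)
  qf_ts <- quad_fit(cohort$total_pct, cohort$tiny_pct + cohort$small_pct)
  qf_l <- quad_fit(cohort$total_pct, cohort$large_pct)
  list(discordance = disc, model = model, model_table = model_table,
       stratified = strat, correlations = cors, wilcoxon = wil,
       quad_tiny_small = qf_ts, quad_large = qf_l)
}

# imaging-mode validation: render and segment images for a few patients whose
# droplet counts approximate the patient's composition, then compare
# recovered vs true total proportionate area
imaging_validation <- function(cohort, config) {
  n <- min(config$n_imaging_patients, nrow(cohort))
  m <- config$morphometry
  rows <- lapply(seq_len(n), function(i) {
    p <- cohort[i, ]
    ispec_args <- config$image
    ispec_args$seed <- (stage_seed(config$seed, "image") + i) %%
      .Machine$integer.max
    ispec_args$pixel_size_um <- m$pixel_size_um
    base <- do.call(image_spec, ispec_args)
    tissue_px <- base$tissue_fraction * base$width_px * base$height_px
    tissue_um2 <- tissue_px * base$pixel_size_um^2
    # droplet counts matched to the patient's per-class target areas
    mean_area <- vapply(base$area_dist_params, function(b) {
      exp(mean(log(b)))
    }, numeric(1))
    counts <- pmin(60, round(p[, c("tiny_pct", "small_pct", "large_pct")] / 100 *
                               tissue_um2 / mean_area))
    ispec_args$n_tiny <- max(0L, as.integer(counts[[1]]))
    ispec_args$n_small <- max(0L, as.integer(counts[[2]]))
    ispec_args$n_large <- max(0L, as.integer(counts[[3]]))
    spec <- do.call(image_spec, ispec_args)
    im <- generate_image(spec)
    mask <- segment_tissue(im$image)
    drops <- segment_droplets(im$image, mask, spec$pixel_size_um,
                              intensity_threshold = m$intensity_threshold,
                              circularity_min = m$circularity_min,
                              watershed = isTRUE(m$watershed))
    prof <- compute_profile(drops, sum(mask) * spec$pixel_size_um^2)
    truth <- compute_profile(
      data.frame(area_um2 = im$droplets$area_um2,
                 size_class = im$droplets$size_class),
      sum(im$tissue_mask) * spec$pixel_size_um^2)
    data.frame(patient_id = p$patient_id,
               true_total_pct = truth$total_pct,
               recovered_total_pct = prof$total_pct,
               n_true = nrow(im$droplets), n_detected = nrow(drops),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
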