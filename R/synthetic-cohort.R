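#' Specification for a synthetic patient cohort
#'
#' Defines the joint distribution of lipid-droplet morphometry, MRI-PDFF and
#' clinical covariates emulating the statistical structure of a chronic
#' liver disease cohort with paired biopsy and MRI: total LD proportionate
#' area 8.7 +/- 7.2% ranging 0.5--35.8%, a size composition that shifts from
#' tiny/small towards large droplets as total fat rises, and a PDFF that
#' tracks total LD area with Pearson r close to 0.89.
#'
#' @param n_patients Number of patients.
#' @param total_area_mean,total_area_sd Target mean and SD (%) of total LD
#'   proportionate area before range truncation.
#' @param total_area_range Truncation range (%) for total LD area.
#' @param composition_params List with \code{large_share_max} (asymptotic
#'   large-LD share of total area), \code{half_saturation_pct} (total area at
#'   which the large share reaches half its asymptote), \code{jitter_sd}
#'   (SD of logit-scale noise around the large-share curve, giving the
#'   scatter seen in real composition data) and \code{tiny_frac_shape1},
#'   \code{tiny_frac_shape2} (Beta parameters of the tiny fraction of the
#'   non-large remainder; mean 0.9 reflects tiny >> small areas).
#' @param pdff_noise_sd SD (%) of the Gaussian measurement noise linking PDFF
#'   to total LD area. The default 3.69 solves
#'   r = sd_T / sqrt(sd_T^2 + sigma^2) for r = 0.89 at sd_T = 7.2.
#' @param hepatocyte_frac_per_large_pct Slope k mapping large-LD proportionate
#'   area (%) to the perceived fraction (%) of hepatocytes bearing large
#'   droplets. A calibration knob, not a biological claim.
#' @param pathologist_bias Multiplicative overestimation (>= 1) of the
#'   perceived large-droplet hepatocyte fraction; pathologist estimates
#'   systematically exceed the measured proportion.
#' @param microvesicular_rate_params Numeric \code{c(intercept, slope)} of the
#'   logistic link giving the probability of a microvesicular-steatosis flag
#'   as a function of tiny-LD area (%).
#' @param covariate_params List of simple documented covariate distributions:
#'   \code{age_mean}, \code{age_sd}, \code{age_range}, \code{p_female},
#'   \code{fibrosis_link} (logistic intercept/slope on total area),
#'   \code{p_inflammation}, \code{biopsy_length_mean}, \code{biopsy_length_sd},
#'   \code{portal_tracts_lambda}.
#' @param seed Integer seed; identical spec + seed reproduce the table.
#' @return An object of class \code{cohort_spec}.
#' @seealso \code{\link{generate_cohort}}
#' @export
cohort_spec <- function(n_patients = 355,
                        total_area_mean = 8.7,
                        total_area_sd = 7.2,
                        total_area_range = c(0.5, 35.8),
                        composition_params = list(
                          large_share_max = 0.65,
                          half_saturation_pct = 12,
                          jitter_sd = 0.3,
                          tiny_frac_shape1 = 45,
                          tiny_frac_shape2 = 5
                        ),
                        pdff_noise_sd = 3.69,
                        hepatocyte_frac_per_large_pct = 8,
                        pathologist_bias = 1.15,
                        microvesicular_rate_params = c(intercept = -2.6, slope = 0.4),
                        covariate_params = list(
                          age_mean = 55, age_sd = 10, age_range = c(18, 90),
                          p_female = 0.59,
                          fibrosis_link = c(intercept = -1.2, slope = 0.04),
                          p_inflammation = 0.3,
                          biopsy_length_mean = 18, biopsy_length_sd = 4,
                          portal_tracts_lambda = 11
                        ),
                        seed = 1L) {
  spec <- list(
    n_patients = n_patients,
    total_area_mean = total_area_mean,
    total_area_sd = total_area_sd,
    total_area_range = total_area_range,
    composition_params = composition_params,
    pdff_noise_sd = pdff_noise_sd,
    hepatocyte_frac_per_large_pct = hepatocyte_frac_per_large_pct,
    pathologist_bias = pathologist_bias,
    microvesicular_rate_params = microvesicular_rate_params,
    covariate_params = covariate_params,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(n_patients) || n_patients < 1) stop("n_patients must be >= 1")
    if (total_area_sd <= 0) stop("total_area_sd must be positive")
    if (length(total_area_range) != 2 || diff(total_area_range) <= 0 ||
        total_area_range[1] <= 0) {
      stop("total_area_range must be an increasing positive pair")
    }
    if (total_area_mean < total_area_range[1] ||
        total_area_mean > total_area_range[2]) {
      stop("total_area_mean must lie within total_area_range")
    }
    if (pdff_noise_sd <= 0) stop("pdff_noise_sd must be positive")
    if (pathologist_bias < 1) stop("pathologist_bias must be >= 1")
    cp <- composition_params
    if (cp$large_share_max <= 0 || cp$large_share_max > 1) {
      stop("large_share_max must lie in (0, 1]")
    }
    if (cp$half_saturation_pct <= 0) stop("half_saturation_pct must be positive")
    if (cp$jitter_sd < 0) stop("jitter_sd must be >= 0")
    if (cp$tiny_frac_shape1 <= 0 || cp$tiny_frac_shape2 <= 0) {
      stop("tiny fraction Beta parameters must be positive")
    }
  })
  invisible(spec)
}

#' Expected large-droplet share of total LD area
#'
#' The deterministic composition curve: the large-LD share of total
#' proportionate area is an increasing, saturating function of total area T,
#' \code{L_max * T^2 / (T^2 + h^2)}. Small/tiny droplets dominate at low fat
#' content and large droplets take over as fat accumulates.
#'
#' @param total_pct Total LD proportionate area (%), non-negative.
#' @param composition_params As in \code{\link{cohort_spec}}.
#' @return Expected large share in \[0, 1).
#' @export
large_share_curve <- function(total_pct,
                              composition_params = cohort_spec()$composition_params) {
  stopifnot(all(total_pct >= 0))
  Lmax <- composition_params$large_share_max
  h <- composition_params$half_saturation_pct
  Lmax * total_pct^2 / (total_pct^2 + h^2)
}

# right-skewed total-area draw: gamma reparametrized to mean/sd, truncated
# by rejection to the observed range
rtrunc_gamma <- function(n, mean, sd, range) {
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    x <- stats::rgamma(max(2L * n, 100L), shape = shape, scale = scale)
    out <- c(out, x[x >= range[1] & x <= range[2]])
    tries <- tries + 1
    if (tries > 1000) stop("truncation range rejects nearly all mass")
  }
  out[seq_len(n)]
}

#' Generate a synthetic patient cohort
#'
#' Draws one row per patient:
#' \enumerate{
#'   \item total LD area T from a gamma distribution reparametrized to the
#'     target mean/SD, truncated to the target range;
#'   \item an additive split of T into tiny/small/large areas: the large share
#'     follows \code{\link{large_share_curve}} with logit-scale jitter, and a
#'     Beta-distributed tiny fraction splits the remainder (tiny + small +
#'     large = T exactly);
#'   \item PDFF = T + Gaussian noise, truncated below at 0;
#'   \item a histology grade from the perceived large-droplet hepatocyte
#'     fraction \code{min(100, k * large_pct * pathologist_bias)} via
#'     \code{\link{grade_histology}};
#'   \item a microvesicular flag from a logistic link on tiny-LD area;
#'   \item age, sex, fibrosis, inflammation and biopsy-quality covariates from
#'     simple documented distributions.
#' }
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A data.frame with columns patient_id, age, sex, tiny_pct,
#'   small_pct, large_pct, total_pct, pdff_pct, hist_grade, microvesicular,
#'   fibrosis_f2_4, inflammation_ge2, biopsy_length_mm, portal_tracts.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' mean(coh$total_pct)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  cp <- spec$composition_params
  cv <- spec$covariate_params

  total <- rtrunc_gamma(n, spec$total_area_mean, spec$total_area_sd,
                        spec$total_area_range)

  mu <- stats::qlogis(pmin(pmax(large_share_curve(total, cp), 1e-6), 1 - 1e-6))
  share <- stats::plogis(mu + stats::rnorm(n, 0, cp$jitter_sd))
  large <- share * total
  rem <- total - large
  tf <- stats::rbeta(n, cp$tiny_frac_shape1, cp$tiny_frac_shape2)
  tiny <- tf * rem
  small <- rem - tiny          # exact additivity: tiny + small + large == total

  pdff <- pmax(0, total + stats::rnorm(n, 0, spec$pdff_noise_sd))

  perceived <- pmin(100, spec$hepatocyte_frac_per_large_pct *
                           large * spec$pathologist_bias)
  hist_grade <- grade_histology(perceived)

  mv <- spec$microvesicular_rate_params
  microvesicular <- stats::rbinom(n, 1,
    stats::plogis(mv[["intercept"]] + mv[["slope"]] * tiny)) == 1

  age <- round(pmin(cv$age_range[2], pmax(cv$age_range[1],
               stats::rnorm(n, cv$age_mean, cv$age_sd))))
  sex <- ifelse(stats::rbinom(n, 1, cv$p_female) == 1, "female", "male")
  fl <- cv$fibrosis_link
  fibrosis <- stats::rbinom(n, 1,
    stats::plogis(fl[["intercept"]] + fl[["slope"]] * total)) == 1
  inflammation <- stats::rbinom(n, 1, cv$p_inflammation) == 1
  biopsy_len <- pmax(5, stats::rnorm(n, cv$biopsy_length_mean,
                                     cv$biopsy_length_sd))
  portal <- stats::rpois(n, cv$portal_tracts_lambda) + 1L

  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age,
    sex = sex,
    tiny_pct = tiny,
    small_pct = small,
    large_pct = large,
    total_pct = total,
    pdff_pct = pdff,
    hist_grade = hist_grade,
    microvesicular = microvesicular,
    fibrosis_f2_4 = fibrosis,
    inflammation_ge2 = inflammation,
    biopsy_length_mm = biopsy_len,
    portal_tracts = portal,
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort table as CSV
#'
#' Plain one-header-row CSV with the fixed documented column set.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return \code{read_cohort} returns the cohort data.frame;
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "tiny_pct", "small_pct", "large_pct",
                "total_pct", "pdff_pct", "hist_grade")
  missing <- setdiff(required, names(coh))
  if (length(missing)) {
    stop("cohort file lacks required columns: ", paste(missing, collapse = ", "))
  }
  coh
}
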