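# shared fixtures: centroid matching and planted-effect outcome simulation

# greedy nearest-centroid matching between ground-truth and detected droplets
match_droplets <- function(truth, detected, max_dist_px = 3) {
  if (nrow(truth) == 0 || nrow(detected) == 0) {
    return(list(matched = 0L, n_truth = nrow(truth), n_detected = nrow(detected),
                truth_idx = integer(), det_idx = integer()))
  }
  dmat <- sqrt(outer(truth$center_x, detected$centroid_x, "-")^2 +
               outer(truth$center_y, detected$centroid_y, "-")^2)
  truth_idx <- integer(); det_idx <- integer()
  repeat {
    if (min(dmat) > max_dist_px) break
    k <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    truth_idx <- c(truth_idx, k[1]); det_idx <- c(det_idx, k[2])
    dmat[k[1], ] <- Inf; dmat[, k[2]] <- Inf
    if (all(is.infinite(dmat))) break
  }
  list(matched = length(truth_idx), n_truth = nrow(truth),
       n_detected = nrow(detected), truth_idx = truth_idx, det_idx = det_idx)
}

# draw a discordance outcome from a known logistic model on the LD predictors;
# coefficients emulate the qualitative structure of real concordance cohorts:
# all three droplet classes marginally associated with discordance, with
# positive conditional effects for tiny/small and a negative one for large
planted_outcome <- function(cohort, seed,
                            beta = c(tiny = 0.40, small = 1.2, large = -0.15),
                            intercept = -2.0) {
  set.seed(seed)
  lp <- intercept + beta[["tiny"]] * cohort$tiny_pct +
    beta[["small"]] * cohort$small_pct + beta[["large"]] * cohort$large_pct
  cohort$discordant <- stats::rbinom(nrow(cohort), 1, stats::plogis(lp)) == 1
  cohort
}
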