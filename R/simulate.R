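#' Parameters for the synthetic-cohort generator
#'
#' Defaults emulate the study conditions the pipeline was designed for: about
#' 300 cases and 150 controls followed over 6 annual visits on ~120 clinical
#' features spanning the motor, cognitive and sleep domains; three latent
#' subtypes with slow/moderate/fast progression velocities mixed at
#' 0.45/0.39/0.16; under 5% completely-at-random missingness; a fraction of
#' features oriented lower-is-worse; serum neurofilament light (Nfl)
#' trajectories with a steeper slope in the fast subtype; and a genetic risk
#' score (GRS) weakly, negatively associated with fast-subtype membership.
#'
#' @param n_cases,n_controls Subject counts.
#' @param n_features_per_domain Named counts for motor/cognitive/sleep
#'   features.
#' @param n_visits Number of annual visits including baseline.
#' @param subtype_mixing Mixing proportions (slow, moderate, fast); must sum
#'   to 1.
#' @param subtype_velocity 3x3 matrix of mean progression slopes
#'   (normalized score per year), rows = domains, columns = slow/moderate/fast.
#'   Slopes must be non-decreasing slow -> fast in every domain.
#' @param baseline_shift Per-subtype mean baseline severity offset; faster
#'   progressors present with greater baseline impairment, which is what makes
#'   long-horizon subtype membership predictable from baseline data.
#' @param control_velocity Slow-aging drift slope applied to controls.
#' @param within_subtype_sd List with `intercept` and `slope`: SDs of the
#'   per-subject, per-domain deviations from the subtype means.
#' @param noise_sd Per-observation Gaussian measurement noise SD.
#' @param flip_fraction Fraction of clinical features generated with
#'   lower-is-worse orientation.
#' @param missing_rate MCAR missingness rate on clinical cells (< 0.05).
#' @param outlier_rate,outlier_magnitude Rate and additive magnitude of
#'   spurious extreme values.
#' @param nfl_baseline_mean,nfl_baseline_sd Baseline serum-Nfl distribution.
#' @param nfl_slopes Per-subtype annual Nfl slopes (fast > slow).
#' @param nfl_noise_sd Nfl measurement noise SD.
#' @param grs_effect Log-odds of fast-subtype membership per SD of GRS
#'   (negative by default: higher risk burden, lower odds of fast
#'   progression).
#' @param instrument_seed Seed for the feature definitions (scale offsets,
#'   sensitivities, orientation flips). Kept separate from the cohort seed so
#'   two cohorts drawn with the same parameters share their measurement
#'   instruments, as independent studies using the same clinical scales do —
#'   a prerequisite for model transfer between cohorts.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_cases = 300,
                             n_controls = 150,
                             n_features_per_domain = c(motor = 60, cognitive = 30, sleep = 30),
                             n_visits = 6,
                             subtype_mixing = c(slow = 0.45, moderate = 0.39, fast = 0.16),
                             subtype_velocity = rbind(
                               motor     = c(0.05, 0.10, 0.18),
                               cognitive = c(0.03, 0.06, 0.11),
                               sleep     = c(0.04, 0.08, 0.14)),
                             baseline_shift = c(slow = 0, moderate = 0.18, fast = 0.36),
                             control_velocity = 0.01,
                             within_subtype_sd = list(intercept = 0.05, slope = 0.02),
                             noise_sd = 0.10,
                             flip_fraction = 0.25,
                             missing_rate = 0.03,
                             outlier_rate = 0.005,
                             outlier_magnitude = 2,
                             nfl_baseline_mean = 12,
                             nfl_baseline_sd = 3,
                             nfl_slopes = c(slow = 0.5, moderate = 1.2, fast = 2.5),
                             nfl_noise_sd = 1,
                             grs_effect = -0.574,
                             instrument_seed = 760) {
  if (abs(sum(subtype_mixing) - 1) > 1e-8)
    stop("parameter error: subtype_mixing must sum to 1")
  colnames(subtype_velocity) <- c("slow", "moderate", "fast")
  if (any(apply(subtype_velocity, 1, function(v) any(diff(v) < 0))))
    stop("parameter error: subtype slopes must satisfy fast >= moderate >= slow in every domain")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("parameter error: missing_rate must be in [0, 1)")
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("parameter error: flip_fraction must be in [0, 1]")
  structure(as.list(environment()), class = "generator_params")
}

#' Generate a synthetic longitudinal cohort with known subtypes
#'
#' Each case is assigned a latent subtype; every clinical feature trajectory is
#' baseline level + subtype velocity x years + Gaussian noise, truncated at 0
#' (the factorization requires non-negative data). Controls drift at the
#' slow-aging slope. A stated fraction of features is generated lower-is-worse
#' (reflected), missingness is applied completely at random, and per-subject
#' serum-Nfl trajectories and a scalar GRS are attached (`serum_nfl` as a
#' biomarker feature, `grs` as a subject column).
#'
#' @param params A [generator_params()] object.
#' @param seed Integer RNG seed.
#' @return A list with `cohort` (a [longitudinal_cohort()]) and `labels`
#'   (`data.frame` of subject_id and true subtype, cases only).
#' @export
generate_cohort <- function(params = generator_params(), seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  subtypes <- c("slow", "moderate", "fast")
  domains <- c("motor", "cognitive", "sleep")

  # instrument definitions: deterministic given params, shared across cohorts
  set.seed(p$instrument_seed)
  feats <- data.frame(
    name = unlist(lapply(domains, function(d)
      sprintf("%s_%02d", d, seq_len(p$n_features_per_domain[[d]])))),
    domain = rep(domains, p$n_features_per_domain[domains]),
    stringsAsFactors = FALSE)
  nf <- nrow(feats)
  n_flip <- round(p$flip_fraction * nf)
  flipped <- rep(FALSE, nf)
  flipped[sample.int(nf, n_flip)] <- TRUE
  base_level <- stats::runif(nf, 0.8, 1.6)   # feature-specific offset
  sensitivity <- stats::runif(nf, 0.7, 1.3)  # feature-specific progression gain

  # subject-level draws under the cohort seed
  set.seed(seed)
  n <- p$n_cases + p$n_controls
  ids <- sprintf("S%04d", seq_len(n))
  group <- c(rep("case", p$n_cases), rep("control", p$n_controls))
  subtype <- rep(NA_character_, n)
  subtype[group == "case"] <- sample(subtypes, p$n_cases, replace = TRUE,
                                     prob = p$subtype_mixing)

  visits <- data.frame(label = c("BL", sprintf("V%02d", 2 + 2 * seq_len(p$n_visits - 1))),
                       month = 12 * (seq_len(p$n_visits) - 1),
                       stringsAsFactors = FALSE)
  years <- visits$month / 12

  # per-subject, per-domain severity intercept and slope
  sev <- matrix(0, n, 3, dimnames = list(ids, domains))
  slp <- matrix(p$control_velocity, n, 3, dimnames = list(ids, domains))
  for (d in domains) {
    is_case <- group == "case"
    sev[is_case, d] <- p$baseline_shift[subtype[is_case]] +
      stats::rnorm(sum(is_case), 0, p$within_subtype_sd$intercept)
    slp[is_case, d] <- p$subtype_velocity[d, subtype[is_case]] +
      stats::rnorm(sum(is_case), 0, p$within_subtype_sd$slope)
  }

  # clinical panel: value = base + sensitivity * (severity + slope * years) + noise
  grid <- expand.grid(fi = seq_len(nf), vi = seq_len(p$n_visits),
                      si = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  dom_i <- match(feats$domain[grid$fi], domains)
  signal <- sev[cbind(grid$si, dom_i)] + slp[cbind(grid$si, dom_i)] * years[grid$vi]
  value <- base_level[grid$fi] + sensitivity[grid$fi] * signal
  if (p$noise_sd > 0)
    value <- value + stats::rnorm(length(value), 0, p$noise_sd)
  if (p$outlier_rate > 0) {
    k <- stats::runif(length(value)) < p$outlier_rate
    value[k] <- value[k] + sample(c(-1, 1), sum(k), replace = TRUE) * p$outlier_magnitude
  }
  # reflect lower-is-worse features: higher value now means better health
  refl <- flipped[grid$fi]
  value[refl] <- (base_level[grid$fi] + 3)[refl] - value[refl]
  value <- pmax(value, 0)
  if (p$missing_rate > 0)
    value[stats::runif(length(value)) < p$missing_rate] <- NA_real_

  data <- data.frame(subject_id = ids[grid$si],
                     visit = visits$label[grid$vi],
                     feature = feats$name[grid$fi],
                     value = value, stringsAsFactors = FALSE)

  # serum Nfl trajectories: steeper in faster subtypes
  nfl_base <- stats::rnorm(n, p$nfl_baseline_mean, p$nfl_baseline_sd)
  nfl_slope <- ifelse(group == "case", p$nfl_slopes[subtype],
                      p$nfl_slopes[["slow"]] / 2)
  nfl_grid <- expand.grid(vi = seq_len(p$n_visits), si = seq_len(n),
                          KEEP.OUT.ATTRS = FALSE)
  nfl_val <- nfl_base[nfl_grid$si] + nfl_slope[nfl_grid$si] * years[nfl_grid$vi]
  if (p$nfl_noise_sd > 0)
    nfl_val <- nfl_val + stats::rnorm(length(nfl_val), 0, p$nfl_noise_sd)
  data <- rbind(data,
                data.frame(subject_id = ids[nfl_grid$si],
                           visit = visits$label[nfl_grid$vi],
                           feature = "serum_nfl",
                           value = pmax(nfl_val, 0),
                           stringsAsFactors = FALSE))

  # GRS: equal-variance Gaussians whose mean shift in the fast subtype implies
  # a fast-vs-rest logistic log-OR equal to grs_effect
  grs <- stats::rnorm(n, 0, 1)
  grs[group == "case" & subtype == "fast"] <-
    grs[group == "case" & subtype == "fast"] + p$grs_effect

  subjects <- data.frame(subject_id = ids, group = group,
                         sex = sample(c("F", "M"), n, replace = TRUE),
                         age = round(stats::rnorm(n, 61, 9), 1),
                         height = round(stats::rnorm(n, 170, 10), 1),
                         weight = round(stats::rnorm(n, 78, 14), 1),
                         grs = grs, stringsAsFactors = FALSE)

  features <- rbind(
    feature_meta(feats$name, feats$domain, higher_is_worse = !flipped),
    feature_meta("serum_nfl", "biomarker", higher_is_worse = TRUE))

  cohort <- longitudinal_cohort(data, subjects, features, visits)
  labels <- data.frame(subject_id = ids[group == "case"],
                       subtype = subtype[group == "case"],
                       stringsAsFactors = FALSE)
  list(cohort = cohort, labels = labels)
}

#' Draw labelled points from a Gaussian mixture in progression space
#'
#' Emulates the published progression-space geometry directly: points are
#' drawn from a spherical Gaussian mixture at stated component means (2-D or
#' 3-D) with stated mixing proportions.
#'
#' @param means List of numeric component mean vectors (equal length, 2 or 3).
#' @param sds Component dispersion(s): scalar or one per component.
#' @param mixing Mixing proportions summing to 1.
#' @param n Number of points (0 allowed).
#' @param seed Integer RNG seed.
#' @return List with `points` (n x d matrix) and `labels` (component index).
#' @export
generate_space_points <- function(means, sds, mixing, n, seed = 1) {
  k <- length(means)
  if (length(mixing) != k)
    stop("parameter error: length(means) must equal length(mixing)")
  if (abs(sum(mixing) - 1) > 1e-8)
    stop("parameter error: mixing must sum to 1")
  sds <- rep_len(sds, k)
  if (any(sds <= 0)) stop("parameter error: dispersions must be positive")
  d <- length(means[[1]])
  stopifnot(all(vapply(means, length, 1L) == d))
  set.seed(seed)
  if (n == 0)
    return(list(points = matrix(numeric(0), 0, d), labels = integer(0)))
  lab <- sample.int(k, n, replace = TRUE, prob = mixing)
  pts <- t(vapply(lab, function(j) means[[j]] + stats::rnorm(d, 0, sds[j]),
                  numeric(d)))
  list(points = pts, labels = lab)
}
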