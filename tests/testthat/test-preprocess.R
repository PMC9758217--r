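# two-feature cohort where feature 1 is oriented higher-is-worse and
# feature 2 is its mirror image (lower-is-worse)
direction_cohort <- function(n_per_group = 50, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(2 * n_per_group))
  group <- rep(c("case", "control"), each = n_per_group)
  f1 <- ifelse(group == "case", 10, 2) + stats::rnorm(length(ids), 0, 1)
  f2 <- 20 - f1
  data <- rbind(
    data.frame(subject_id = ids, visit = "BL", feature = "motor_01", value = f1),
    data.frame(subject_id = ids, visit = "BL", feature = "motor_02", value = f2))
  longitudinal_cohort(
    data,
    data.frame(subject_id = ids, group = group, stringsAsFactors = FALSE),
    feature_meta(c("motor_01", "motor_02"), "motor"),
    data.frame(label = "BL", month = 0))
}

test_that("directionality test flips exactly the lower-is-worse features", {
  co <- direction_cohort()
  # independent oracle: one-sided Welch test computed directly per feature
  oracle_p <- vapply(c("motor_01", "motor_02"), function(f) {
    d <- co$data[co$data$feature == f, ]
    is_case <- co$subjects$group[match(d$subject_id, co$subjects$subject_id)] == "case"
    stats::t.test(d$value[!is_case], d$value[is_case],
                  alternative = "greater")$p.value
  }, numeric(1))
  al <- align_directionality(co, alpha = 0.05)
  expect_equal(al$report$p, unname(oracle_p), tolerance = 1e-12)
  expect_equal(al$report$flipped, unname(oracle_p < 0.05))
  expect_false(al$report$flipped[al$report$feature == "motor_01"])
  expect_true(al$report$flipped[al$report$feature == "motor_02"])
  # after reflection the flipped feature reads higher-in-cases
  d2 <- al$cohort$data[al$cohort$data$feature == "motor_02", ]
  is_case <- co$subjects$group[match(d2$subject_id, co$subjects$subject_id)] == "case"
  expect_gt(mean(d2$value[is_case]), mean(d2$value[!is_case]))
  # flipped = TRUE iff p < alpha, and alpha = 0 flips nothing
  expect_true(all(al$report$flipped == (al$report$p < 0.05)))
  al0 <- align_directionality(co, alpha = 0)
  expect_false(any(al0$report$flipped))
})

test_that("constant features are flagged, never flipped", {
  co <- direction_cohort()
  co$data$value[co$data$feature == "motor_02"] <- 7
  al <- align_directionality(co)
  row <- al$report[al$report$feature == "motor_02", ]
  expect_true(row$constant)
  expect_false(row$flipped)
})

test_that("alignment recovers the generator's flipped set under strong separation", {
  p <- generator_params(n_cases = 80, n_controls = 80,
                        n_features_per_domain = c(motor = 10, cognitive = 10, sleep = 10),
                        flip_fraction = 0.3, noise_sd = 0.05,
                        baseline_shift = c(slow = 0.3, moderate = 0.5, fast = 0.7),
                        missing_rate = 0, outlier_rate = 0)
  sim <- generate_cohort(p, seed = 9)
  al <- align_directionality(sim$cohort)
  truth <- !sim$cohort$features$higher_is_worse[
    match(al$report$feature, sim$cohort$features$name)]
  expect_equal(al$report$flipped, truth)
})

test_that("percentile clipping matches a brute-force percentile oracle", {
  ids <- sprintf("P%03d", 1:100)
  co <- longitudinal_cohort(
    data.frame(subject_id = ids, visit = "BL", feature = "motor_01",
               value = as.numeric(1:100)),
    data.frame(subject_id = ids, group = rep(c("case", "control"), 50)),
    feature_meta("motor_01", "motor"),
    data.frame(label = "BL", month = 0))
  # brute-force linear-interpolation percentile on the sorted 100-point vector
  brute_pct <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  expect_equal(brute_pct(1:100, 0.02), 2.98)
  cl <- clip_percentiles(co)
  expect_equal(min(cl$data$value), brute_pct(1:100, 0.02))
  expect_equal(max(cl$data$value), brute_pct(1:100, 0.98))
  interior <- co$data$value > 2.98 & co$data$value < 98.02
  expect_equal(cl$data$value[interior], co$data$value[interior])
  # idempotent when re-applied with the recorded bounds
  cl2 <- clip_percentiles(cl, bounds = attr(cl, "clip_bounds"))
  expect_equal(cl2$data$value, cl$data$value)
  # constant feature unchanged
  co$data$value <- 5
  expect_equal(clip_percentiles(co)$data$value, rep(5, 100))
})

test_that("longitudinal interpolation fills gaps on the month axis", {
  co <- toy_cohort(ns = 1, nv = 3, nf = 1)
  co$data$value <- c(1, NA, 3)
  out <- interpolate_missing(co)
  expect_equal(out$data$value, c(1, 2, 3))
  co$data$value <- c(NA, 5, NA)
  expect_equal(interpolate_missing(co)$data$value, c(5, 5, 5))
  co$data$value <- rep(NA_real_, 3)
  expect_error(interpolate_missing(co), "fully missing")
})

test_that("interpolation exactly recovers MCAR-masked noise-free linear data", {
  p <- small_params(noise_sd = 0, missing_rate = 0, outlier_rate = 0,
                    flip_fraction = 0,
                    within_subtype_sd = list(intercept = 0, slope = 0))
  sim <- generate_cohort(p, seed = 13)
  co <- sim$cohort
  clin <- which(co$data$feature != "serum_nfl")
  set.seed(99)
  # mask interior visits only (edge fill is nearest-value, not linear)
  maskable <- clin[!co$data$visit[clin] %in% c("BL", "V12")]
  mask <- sample(maskable, round(0.05 * length(maskable)))
  truth <- co$data$value[mask]
  co$data$value[mask] <- NA
  out <- interpolate_missing(co)
  expect_equal(out$data$value[mask], truth, tolerance = 1e-10)
})

test_that("vectorize stacks (feature, visit) rows and inverts cleanly", {
  co <- toy_cohort(ns = 4, nv = 3, nf = 2)
  vm <- vectorize(co)
  expect_equal(dim(vm$X), c(6, 4))
  expect_equal(vm$X["motor_01.V04", "P02"],
               co$data$value[co$data$subject_id == "P02" &
                               co$data$visit == "V04" &
                               co$data$feature == "motor_01"])
  back <- devectorize(vm)
  key <- function(d) paste(d$subject_id, d$visit, d$feature)
  expect_equal(back$value[match(key(co$data), key(back))], co$data$value)
  # single feature, single visit
  co1 <- toy_cohort(ns = 5, nv = 1, nf = 1)
  vm1 <- vectorize(co1)
  expect_equal(dim(vm1$X), c(1, 5))
  expect_equal(as.numeric(vm1$X), co1$data$value)
  # subject permutation permutes columns identically
  cop <- co
  perm <- c(3, 1, 4, 2)
  cop$subjects <- cop$subjects[perm, ]
  vmp <- vectorize(cop)
  expect_equal(vmp$X, vm$X[, perm])
  # missing cells violate the precondition
  co$data$value[5] <- NA
  expect_error(vectorize(co), "missing")
})

test_that("min-max normalization maps rows to [0, 1] and transfers bounds", {
  co <- toy_cohort(ns = 3, nv = 1, nf = 1)
  vm <- vectorize(co)
  vm$X[1, ] <- c(2, 4, 6)
  nm <- minmax_normalize(vm)
  expect_equal(as.numeric(nm$X), c(0, 0.5, 1))
  expect_equal(nm$bounds$min, 2)
  expect_equal(nm$bounds$max, 6)
  # constant row maps to 0 with degenerate bounds recorded
  vm$X[1, ] <- 7
  nc <- minmax_normalize(vm)
  expect_equal(as.numeric(nc$X), c(0, 0, 0))
  expect_equal(nc$bounds$min, 7)
  expect_equal(nc$bounds$max, 7)
  # transfer: training bounds applied to new data; out-of-range clipped
  vm$X[1, ] <- c(6, 8, 0)
  tr <- minmax_normalize(vm, bounds = nm$bounds)
  expect_equal(as.numeric(tr$X), c(1, 1, 0))
})

test_that("preprocessing output is non-negative, complete, and order-stable", {
  sim <- generate_cohort(small_params(), seed = 17)
  pc <- preprocess_cohort(sim$cohort)
  expect_true(all(pc$vm$X >= 0 & pc$vm$X <= 1))
  expect_false(anyNA(pc$vm$X))
  expect_equal(nrow(pc$vm$X),
               sum(sim$cohort$features$domain %in% c("motor", "cognitive", "sleep")) *
                 nrow(sim$cohort$visits))
  # shuffling subject order changes nothing but column order
  shuf <- sim$cohort
  set.seed(1)
  perm <- sample(nrow(shuf$subjects))
  shuf$subjects <- shuf$subjects[perm, ]
  pc2 <- preprocess_cohort(shuf)
  expect_equal(pc2$vm$X, pc$vm$X[, perm])
})
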