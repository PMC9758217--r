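# Shared fixtures: all built in code at test time.

# minimal hand-built cohort: ns subjects x nv visits x nf features, values
# filled from a deterministic formula so expectations are easy to state
toy_cohort <- function(ns = 3, nv = 2, nf = 2, groups = NULL) {
  ids <- sprintf("P%02d", seq_len(ns))
  vis <- c("BL", "V04", "V06", "V08", "V10", "V12")[seq_len(nv)]
  feats <- sprintf("motor_%02d", seq_len(nf))
  grid <- expand.grid(subject_id = ids, visit = vis, feature = feats,
                      stringsAsFactors = FALSE)
  grid$value <- match(grid$subject_id, ids) +
    10 * match(grid$visit, vis) + 100 * match(grid$feature, feats)
  if (is.null(groups)) groups <- rep(c("case", "control"), length.out = ns)
  longitudinal_cohort(
    grid,
    data.frame(subject_id = ids, group = groups, stringsAsFactors = FALSE),
    feature_meta(feats, "motor"),
    data.frame(label = vis, month = 12 * (seq_len(nv) - 1)))
}

# wide CSV on disk matching the default schema
toy_cohort_csv <- function(path, blank_one_cell = FALSE, drop_group = FALSE) {
  df <- expand.grid(subject_id = c("P01", "P02", "P03"),
                    visit = c("BL", "V04"), stringsAsFactors = FALSE)
  df$group <- ifelse(df$subject_id == "P03", "control", "case")
  df$motor_01 <- seq_len(nrow(df))
  df$motor_02 <- 10 + seq_len(nrow(df))
  if (blank_one_cell) df$motor_01[2] <- NA
  if (drop_group) df$group <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

toy_schema <- function() {
  cohort_schema(feature_columns = c("motor_01", "motor_02"),
                visit_levels = c(BL = 0, V04 = 12))
}

toy_meta <- function() feature_meta(c("motor_01", "motor_02"), "motor")

# sparse planted non-negative factors: sparsity pins the factorization down
# (dense strictly positive factors are not identifiable), so recovery up to
# permutation and scale is a valid oracle
planted_factors <- function(m = 120, n = 80, p = 3, seed = 5,
                            density = c(0.5, 0.6)) {
  set.seed(seed)
  U0 <- matrix(stats::runif(m * p) * (stats::runif(m * p) < density[1]), m, p)
  V0 <- matrix(stats::runif(p * n) * (stats::runif(p * n) < density[2]), p, n)
  list(U0 = U0, V0 = V0, X = U0 %*% V0)
}

# align projected indicators with planted rows (NMF is defined up to
# component permutation and positive scaling); returns max relative error
aligned_indicator_error <- function(V_proj, V_true) {
  max(vapply(seq_len(nrow(V_true)), function(k) {
    j <- which.max(abs(stats::cor(t(V_proj), V_true[k, ])))
    s <- sum(V_proj[j, ] * V_true[k, ]) / sum(V_proj[j, ]^2)
    sqrt(sum((s * V_proj[j, ] - V_true[k, ])^2)) / sqrt(sum(V_true[k, ]^2))
  }, numeric(1)))
}

# small, fast generator settings for tests that only need structure,
# not the full study-scale cohort
small_params <- function(n_cases = 60, n_controls = 30,
                         n_features_per_domain = c(motor = 6, cognitive = 4,
                                                   sleep = 4), ...) {
  generator_params(n_cases = n_cases, n_controls = n_controls,
                   n_features_per_domain = n_features_per_domain, ...)
}

# deterministic three-cluster points for subtype tests
three_cluster_points <- function(n = 294, sds = 0.08, seed = 1) {
  generate_space_points(list(c(0.43, 0.40), c(0.64, 0.57), c(0.89, 0.71)),
                        sds = sds, mixing = c(0.45, 0.39, 0.16),
                        n = n, seed = seed)
}

true_labels_for <- function(sim, subject_ids) {
  sim$labels$subtype[match(subject_ids, sim$labels$subject_id)]
}
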