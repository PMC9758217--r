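# reduced-scale cohort + labels for classifier tests
pred_fixture <- function(seed = 2, n_cases = 100, ...) {
  sim <- generate_cohort(small_params(
    n_cases = n_cases, n_controls = 40,
    n_features_per_domain = c(motor = 8, cognitive = 5, sleep = 5), ...),
    seed = seed)
  tab <- suppressMessages(filter_and_impute(
    build_feature_table(sim$cohort, visits = "BL")))
  y <- factor(true_labels_for(sim, rownames(tab)),
              levels = c("slow", "moderate", "fast"))
  list(sim = sim, tab = tab, y = y)
}

test_that("feature table columns follow the requested visits and sets", {
  sim <- generate_cohort(small_params(), seed = 2)
  n_clin <- sum(sim$cohort$features$domain %in% c("motor", "cognitive", "sleep"))
  bl <- build_feature_table(sim$cohort, visits = "BL")
  expect_equal(ncol(bl), n_clin)
  expect_equal(nrow(bl), 60)
  two <- build_feature_table(sim$cohort, visits = c("BL", "V04"))
  expect_equal(ncol(two), 2 * n_clin)
  gen <- build_feature_table(sim$cohort, feature_sets = "genetics")
  expect_equal(names(gen), "grs")
  expect_equal(attr(gen, "provenance")$kind, "genetic")
  expect_error(build_feature_table(sim$cohort, feature_sets = "imaging"),
               "unknown feature-set")
  # leakage guard: no label or progression-space column ever enters the table
  full <- build_feature_table(sim$cohort, visits = "BL",
                              feature_sets = c("clinical", "biomarker",
                                               "demographics", "genetics"))
  prov <- attr(full, "provenance")
  expect_setequal(prov$column, names(full))
  expect_false(any(c("subtype", "motor", "cognitive", "sleep") %in% names(full)))
  expect_true(all(prov$visit %in% c("BL", NA)))
})

test_that("missingness filtering and imputation follow the stated rules", {
  tab <- data.frame(a = c(1, 2, NA, 3, 4),
                    b = c(NA, NA, 1, 2, 3),
                    g1 = c(NA, 1, 2, 3, 4),
                    cat = factor(c("x", "x", "y", NA, "x")))
  attr(tab, "provenance") <- data.frame(
    column = c("a", "b", "g1", "cat"),
    kind = c("clinical", "clinical", "genetic", "demographic"),
    visit = NA)
  out <- suppressMessages(filter_and_impute(tab, max_missing_fraction = 0.35))
  # subject 1 (missing its only genetic column) removed first
  expect_equal(nrow(out), 4)
  # b was 40% missing overall but the drop happens after that removal
  expect_true("b" %in% names(out))
  expect_false(anyNA(out))
  expect_equal(out$a[2], mean(c(2, 3, 4)))  # numeric mean imputation
  expect_equal(as.character(out$cat[3]), "x")  # modal category
  # a column above the threshold is dropped
  tab2 <- data.frame(keep = 1:5, drop = c(NA, NA, 1, 2, 3))
  attr(tab2, "provenance") <- data.frame(column = c("keep", "drop"),
                                         kind = "clinical", visit = NA)
  expect_message(out2 <- filter_and_impute(tab2, max_missing_fraction = 0.35),
                 "drop")
  expect_false("drop" %in% names(out2))
})

test_that("the stacked ensemble separates a separable toy problem perfectly", {
  set.seed(1)
  n <- 150
  y <- factor(rep(c("slow", "moderate", "fast"), each = n / 3),
              levels = c("slow", "moderate", "fast"))
  tab <- data.frame(x1 = as.integer(y) + stats::runif(n, -0.2, 0.2),
                    x2 = stats::rnorm(n))
  m <- train_stacked_classifier(tab, y, seed = 1)
  p <- predict(m, tab)
  expect_equal(unname(rowSums(p)), rep(1, n), tolerance = 1e-8)
  aucs <- progspace:::one_vs_rest_auc(y, p)
  expect_equal(unname(aucs), rep(1, 3))
  # deterministic under a fixed seed
  m2 <- train_stacked_classifier(tab, y, seed = 1)
  expect_equal(predict(m2, tab), p)
  # classes smaller than the fold count are refused
  expect_error(train_stacked_classifier(tab[c(1:4, 51:100, 101:150), ],
                                        y[c(1:4, 51:100, 101:150)], seed = 1),
               "fewer members")
})

test_that("outer CV folds partition the subjects exactly once", {
  fx <- pred_fixture()
  rep <- suppressMessages(nested_cv_evaluate(fx$tab, fx$y, seed = 3,
                                             ntree = 100))
  expect_s3_class(rep, "prediction_report")
  expect_setequal(unique(rep$fold_assignment), 1:5)
  expect_equal(length(rep$fold_assignment), nrow(fx$tab))
  expect_false(anyNA(rep$predictions[, levels(fx$y)]))
  # macro AUC is the unweighted mean of the per-class AUCs
  expect_equal(rep$macro_auc, mean(rep$per_class$mean))
  expect_true(all(rep$per_class$mean >= 0 & rep$per_class$mean <= 1))
})

test_that("label-permuted data scores at chance level", {
  fx <- pred_fixture()
  set.seed(11)
  aucs <- vapply(1:3, function(i) {
    suppressMessages(nested_cv_evaluate(fx$tab, sample(fx$y), seed = 20 + i,
                                        ntree = 100))$macro_auc
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) < 0.12))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("inner tuning stays inside the outer-training split", {
  fx <- pred_fixture(n_cases = 80)
  grid <- data.frame(max_depth = c(2, 4), eta = c(0.3, 0.2), nrounds = 40)
  rep <- nested_cv_evaluate(fx$tab, fx$y, seed = 5, hyper_grid = grid,
                            ntree = 60)
  expect_length(rep$chosen_hyper, 5)
  for (h in rep$chosen_hyper)
    expect_true(h$max_depth %in% grid$max_depth)
  # fold predictions exist for every subject exactly once
  expect_setequal(rep$predictions$subject_id, rownames(fx$tab))
})

test_that("feature importance finds a planted signal and normalizes to 1", {
  set.seed(7)
  n <- 120
  y <- factor(rep(c("slow", "moderate", "fast"), each = n / 3),
              levels = c("slow", "moderate", "fast"))
  tab <- data.frame(signal = as.integer(y) + stats::runif(n, -0.3, 0.3),
                    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
                    noise3 = stats::rnorm(n))
  m <- train_stacked_classifier(tab, y, seed = 2)
  fi <- feature_importance(m, tab, y, k_grid = c(1, 4), seed = 2)
  expect_equal(fi$ranking$feature[1], "signal")
  expect_equal(max(fi$ranking$score), 1)
  expect_true(all(fi$ranking$score >= 0))
  # with every feature retained the curve matches the full-model CV AUC
  full <- suppressMessages(nested_cv_evaluate(tab, y, seed = 2,
                                              ntree = 200))$macro_auc
  expect_lt(abs(fi$top_k_curve$macro_auc[2] - full), 0.03)
})

test_that("incremental horizons reuse the baseline evaluation consistently", {
  fx <- pred_fixture(n_cases = 80)
  labels <- fx$sim$labels
  expect_error(incremental_evaluation(fx$sim$cohort, labels,
                                      horizons = list(c("BL", "V99"))),
               "beyond last visit")
  inc <- suppressMessages(
    incremental_evaluation(fx$sim$cohort, labels, horizons = list("BL"),
                           seed = 9, ntree = 100))
  expect_equal(nrow(inc), 1)
  direct <- suppressMessages(nested_cv_evaluate(
    filter_and_impute(build_feature_table(fx$sim$cohort, visits = "BL")),
    factor(true_labels_for(fx$sim,
                           rownames(filter_and_impute(
                             build_feature_table(fx$sim$cohort, visits = "BL")))),
           levels = c("slow", "moderate", "fast")),
    seed = 9, ntree = 100))
  expect_equal(inc$macro_auc[1], direct$macro_auc)
})

test_that("extreme subtypes are at least as predictable as the moderate one", {
  hits <- vapply(1:5, function(s) {
    fx <- pred_fixture(seed = 40 + s,
                       baseline_shift = c(slow = 0, moderate = 0.1, fast = 0.2),
                       noise_sd = 0.15)
    rep <- suppressMessages(nested_cv_evaluate(fx$tab, fx$y, seed = s,
                                               ntree = 100))
    pc <- stats::setNames(rep$per_class$mean, rep$per_class$class)
    mean(c(pc["slow"], pc["fast"]) >= pc["moderate"] - 0.02)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})
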