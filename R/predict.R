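#' Assemble the predictor table for early subtype prediction
#'
#' Builds one row per case with clinical features expanded per included visit
#' and baseline-only biomarker / vital / demographic / genetic predictors
#' joined from the subject table. Column provenance (kind and visit) is
#' recorded so leakage guards can assert that nothing outside the declared
#' horizon enters the model. Subtype labels are never part of the table.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param visits Visit labels to include for visit-varying clinical features
#'   (the prediction horizon), e.g. `"BL"` or `c("BL", "V04")`.
#' @param feature_sets Named selection among `"clinical"`, `"biomarker"`,
#'   `"vitals"`, `"demographics"`, `"genetics"`.
#' @return A `data.frame` (rownames = case subject ids) with attribute
#'   `"provenance"`: a `data.frame` of column, kind, visit.
#' @export
build_feature_table <- function(cohort, visits = "BL",
                                feature_sets = c("clinical")) {
  known_sets <- c("clinical", "biomarker", "vitals", "demographics", "genetics")
  bad <- setdiff(feature_sets, known_sets)
  if (length(bad))
    stop("unknown feature-set name(s): ", paste(bad, collapse = ", "))
  missing_vis <- setdiff(visits, cohort$visits$label)
  if (length(missing_vis))
    stop("requested visit(s) not in cohort: ", paste(missing_vis, collapse = ", "))
  cases <- cohort$subjects$subject_id[cohort$subjects$group == "case"]
  d <- cohort$data
  tab <- data.frame(row.names = cases)
  prov <- data.frame(column = character(), kind = character(),
                     visit = character(), stringsAsFactors = FALSE)

  add_panel_cols <- function(tab, prov, feats, vis, kind) {
    for (f in feats) for (v in vis) {
      sub <- d[d$feature == f & d$visit == v, c("subject_id", "value")]
      col <- paste(f, v, sep = ".")
      tab[[col]] <- sub$value[match(cases, sub$subject_id)]
      prov <- rbind(prov, data.frame(column = col, kind = kind, visit = v,
                                     stringsAsFactors = FALSE))
    }
    list(tab = tab, prov = prov)
  }

  if ("clinical" %in% feature_sets) {
    feats <- clinical_features(cohort, c("motor", "cognitive", "sleep"))
    r <- add_panel_cols(tab, prov, feats, visits, "clinical")
    tab <- r$tab; prov <- r$prov
  }
  if ("biomarker" %in% feature_sets) {
    feats <- cohort$features$name[cohort$features$domain == "biomarker"]
    r <- add_panel_cols(tab, prov, feats, "BL", "biomarker")
    tab <- r$tab; prov <- r$prov
  }
  if ("vitals" %in% feature_sets) {
    feats <- cohort$features$name[cohort$features$domain == "vital"]
    r <- add_panel_cols(tab, prov, feats, "BL", "vital")
    tab <- r$tab; prov <- r$prov
  }
  if ("demographics" %in% feature_sets) {
    for (col in intersect(c("sex", "age", "height", "weight"),
                          names(cohort$subjects))) {
      v <- cohort$subjects[[col]][match(cases, cohort$subjects$subject_id)]
      tab[[col]] <- if (is.character(v)) factor(v) else v
      prov <- rbind(prov, data.frame(column = col, kind = "demographic",
                                     visit = NA, stringsAsFactors = FALSE))
    }
  }
  if ("genetics" %in% feature_sets) {
    gcols <- c(intersect("grs", names(cohort$subjects)),
               grep("^var_", names(cohort$subjects), value = TRUE))
    if (!length(gcols)) stop("no genetic columns in the subject table")
    for (col in gcols) {
      tab[[col]] <- cohort$subjects[[col]][match(cases, cohort$subjects$subject_id)]
      prov <- rbind(prov, data.frame(column = col, kind = "genetic",
                                     visit = NA, stringsAsFactors = FALSE))
    }
  }
  attr(tab, "provenance") <- prov
  tab
}

#' Drop high-missingness predictors and impute the rest
#'
#' Columns with a missing fraction above the threshold are dropped; remaining
#' numeric gaps are imputed with the column mean and categorical gaps with the
#' modal category. Subjects missing every genetic column are removed before
#' imputation.
#'
#' @param tab Feature table from [build_feature_table()].
#' @param max_missing_fraction Column drop threshold (default 0.35).
#' @return The imputed table (provenance attribute updated); dropped columns
#'   are reported via `message()`.
#' @export
filter_and_impute <- function(tab, max_missing_fraction = 0.35) {
  prov <- attr(tab, "provenance")
  gcols <- prov$column[prov$kind == "genetic"]
  if (length(gcols)) {
    all_missing <- rowSums(!is.na(tab[, gcols, drop = FALSE])) == 0
    if (any(all_missing)) {
      message("removing ", sum(all_missing), " subject(s) missing all genetic data")
      tab <- tab[!all_missing, , drop = FALSE]
    }
  }
  miss <- vapply(tab, function(x) mean(is.na(x)), numeric(1))
  drop <- names(miss)[miss > max_missing_fraction]
  if (length(drop)) {
    message("dropping high-missingness column(s): ", paste(drop, collapse = ", "))
    tab <- tab[, setdiff(names(tab), drop), drop = FALSE]
    prov <- prov[prov$column %in% names(tab), , drop = FALSE]
  }
  for (col in names(tab)) {
    x <- tab[[col]]
    if (!anyNA(x)) next
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    } else {
      tb <- table(x)
      x[is.na(x)] <- names(tb)[which.max(tb)]
    }
    tab[[col]] <- x
  }
  attr(tab, "provenance") <- prov
  tab
}

# numeric design matrix with stored factor levels; template makes new data
# expand to identical columns
to_design <- function(tab, template = NULL) {
  if (is.null(template)) {
    xlev <- lapply(Filter(is.factor, tab), levels)
    template <- list(xlev = xlev, cols = NULL,
                     feature_of = NULL)
  }
  for (f in names(template$xlev))
    tab[[f]] <- factor(tab[[f]], levels = template$xlev[[f]])
  mm <- stats::model.matrix(~ . - 1, data = tab)
  if (is.null(template$cols)) {
    template$cols <- colnames(mm)
    # map each design column back to its source feature (factor dummies share
    # the feature-name prefix)
    template$feature_of <- vapply(colnames(mm), function(cn) {
      hits <- names(tab)[startsWith(cn, names(tab))]
      hits[which.max(nchar(hits))]
    }, character(1))
  } else {
    miss <- setdiff(template$cols, colnames(mm))
    if (length(miss)) {
      pad <- matrix(0, nrow(mm), length(miss), dimnames = list(NULL, miss))
      mm <- cbind(mm, pad)
    }
    mm <- mm[, template$cols, drop = FALSE]
  }
  list(mat = mm[, template$cols, drop = FALSE], template = template)
}

# stratified k-fold assignment; every class spread as evenly as possible
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# per-class one-vs-rest AUC; direction fixed so chance performance is 0.5
one_vs_rest_auc <- function(y, probs) {
  vapply(colnames(probs), function(cl) {
    resp <- factor(y == cl, levels = c(FALSE, TRUE))
    as.numeric(pROC::auc(resp, probs[, cl], quiet = TRUE,
                         direction = "<", levels = c(FALSE, TRUE)))
  }, numeric(1))
}

default_hyper <- function() list(max_depth = 4, eta = 0.2, nrounds = 80)

fit_base_learners <- function(X, y, hyper, ntree, seed) {
  nc <- nlevels(y)
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = ntree)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1)
  common <- list(objective = "multi:softprob", num_class = nc, nthread = 1,
                 verbosity = 0)
  set.seed(seed)
  gbA <- xgboost::xgb.train(c(common, list(max_depth = hyper$max_depth,
                                           eta = hyper$eta,
                                           subsample = 0.8,
                                           colsample_bytree = 0.8)),
                            dtrain, nrounds = hyper$nrounds)
  set.seed(seed)
  gbB <- xgboost::xgb.train(c(common, list(max_depth = max(2L, hyper$max_depth - 2L),
                                           eta = min(1, hyper$eta * 1.5))),
                            dtrain, nrounds = hyper$nrounds)
  list(rf = rf, gbA = gbA, gbB = gbB, levels = levels(y))
}

predict_base_learners <- function(bases, X) {
  nc <- length(bases$levels)
  p_rf <- predict(bases$rf, X, type = "prob")[, bases$levels, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(X)
  p_a <- matrix(predict(bases$gbA, dm), ncol = nc, byrow = TRUE)
  p_b <- matrix(predict(bases$gbB, dm), ncol = nc, byrow = TRUE)
  colnames(p_a) <- colnames(p_b) <- bases$levels
  out <- cbind(p_rf, p_a, p_b)
  colnames(out) <- c(paste0("rf.", bases$levels),
                     paste0("gbA.", bases$levels),
                     paste0("gbB.", bases$levels))
  out
}

#' Train the stacked tree-ensemble subtype classifier
#'
#' Three base learners — a bagged-tree ensemble (random forest) and two
#' gradient-boosted tree ensembles with different depth/learning-rate/
#' subsampling configurations — are combined by a multinomial-logistic
#' meta-learner trained on out-of-fold base-class probabilities, so the meta
#' model never sees predictions a base learner made on its own training rows.
#'
#' @param tab Imputed feature table ([filter_and_impute()]).
#' @param labels Factor of subtype labels aligned with `tab` rows.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param hyper List with `max_depth`, `eta`, `nrounds` for the boosted
#'   learners.
#' @param ntree Random-forest tree count.
#' @param stack_folds Folds used to build out-of-fold meta features.
#' @return An object of class `stacked_classifier`.
#' @export
train_stacked_classifier <- function(tab, labels, seed = 1,
                                     hyper = default_hyper(),
                                     ntree = 200, stack_folds = 5) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 3) stop("need at least 3 classes")
  if (any(table(y) < stack_folds))
    stop("a class has fewer members than the number of folds")
  ds <- to_design(tab, NULL)
  X <- ds$mat
  fold <- stratified_folds(y, stack_folds, seed)
  oof <- matrix(NA_real_, nrow(X), 3 * nlevels(y))
  for (f in seq_len(stack_folds)) {
    tr <- fold != f
    bases_f <- fit_base_learners(X[tr, , drop = FALSE], y[tr], hyper, ntree,
                                 seed + f)
    oof[!tr, ] <- predict_base_learners(bases_f, X[!tr, , drop = FALSE])
  }
  bases <- fit_base_learners(X, y, hyper, ntree, seed)
  colnames(oof) <- colnames(predict_base_learners(bases, X[1, , drop = FALSE]))
  meta_df <- data.frame(oof, check.names = TRUE)
  meta <- nnet::multinom(y ~ ., data = cbind(y = y, meta_df), trace = FALSE,
                         MaxNWts = 5000)
  structure(list(bases = bases, meta = meta, template = ds$template,
                 levels = levels(y), hyper = hyper, ntree = ntree,
                 seed = seed),
            class = "stacked_classifier")
}

#' Predict subtype membership probabilities
#'
#' @param object A `stacked_classifier`.
#' @param newdata Feature table with the training columns.
#' @param ... Unused.
#' @return Matrix (subjects x classes) of membership probabilities.
#' @export
predict.stacked_classifier <- function(object, newdata, ...) {
  X <- to_design(newdata, object$template)$mat
  base_p <- predict_base_learners(object$bases, X)
  meta_df <- data.frame(base_p, check.names = TRUE)
  p <- predict(object$meta, newdata = meta_df, type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p[, object$levels, drop = FALSE]
}

#' Evaluate subtype prediction under (nested) cross-validation
#'
#' Stratified 5x5 nested cross-validation: each outer fold is held out exactly
#' once; when a hyperparameter grid is supplied, candidates are compared only
#' on inner folds of the outer-training split and the winner is refitted on
#' the full outer-training data. Per-class one-vs-rest AUCs are averaged
#' across the outer folds; the macro AUC is their unweighted mean. With a
#' `NULL`/empty grid the default hyperparameters are used (logged) and the
#' procedure reduces to plain stratified k-fold CV.
#'
#' @param tab Imputed feature table.
#' @param labels Subtype labels aligned with `tab` rows.
#' @param outer,inner Outer and inner fold counts.
#' @param seed Integer seed.
#' @param hyper_grid `data.frame` with columns `max_depth`, `eta`, `nrounds`
#'   (one row per candidate), or `NULL` for defaults.
#' @param ntree Random-forest tree count.
#' @return Object of class `prediction_report`: `per_class` (mean/sd across
#'   folds), `macro_auc`, `fold_macro`, `predictions` (fold-level held-out
#'   probabilities), `chosen_hyper`, `fold_assignment`.
#' @export
nested_cv_evaluate <- function(tab, labels, outer = 5, inner = 5, seed = 1,
                               hyper_grid = NULL, ntree = 200) {
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(tab) == length(y))
  if (is.null(hyper_grid) || !nrow(hyper_grid)) {
    message("empty hyperparameter grid: using defaults")
    hyper_grid <- as.data.frame(default_hyper())
  }
  fold <- stratified_folds(y, outer, seed)
  n <- nrow(tab)
  pred <- matrix(NA_real_, n, nlevels(y), dimnames = list(rownames(tab), levels(y)))
  chosen <- vector("list", outer)
  per_fold_auc <- matrix(NA_real_, outer, nlevels(y),
                         dimnames = list(NULL, levels(y)))
  for (f in seq_len(outer)) {
    tr <- which(fold != f); te <- which(fold == f)
    hyper <- as.list(hyper_grid[1, , drop = FALSE])
    if (nrow(hyper_grid) > 1) {
      inner_fold <- stratified_folds(y[tr], inner, seed + 100 + f)
      score <- vapply(seq_len(nrow(hyper_grid)), function(g) {
        hg <- as.list(hyper_grid[g, , drop = FALSE])
        aucs <- vapply(seq_len(inner), function(i) {
          itr <- tr[inner_fold != i]; ite <- tr[inner_fold == i]
          m <- train_stacked_classifier(tab[itr, , drop = FALSE], y[itr],
                                        seed = seed + 1000 * f + i,
                                        hyper = hg, ntree = ntree)
          p <- predict(m, tab[ite, , drop = FALSE])
          mean(one_vs_rest_auc(y[ite], p))
        }, numeric(1))
        mean(aucs)
      }, numeric(1))
      hyper <- as.list(hyper_grid[which.max(score), , drop = FALSE])
    }
    chosen[[f]] <- hyper
    m <- train_stacked_classifier(tab[tr, , drop = FALSE], y[tr],
                                  seed = seed + f, hyper = hyper,
                                  ntree = ntree)
    p <- predict(m, tab[te, , drop = FALSE])
    pred[te, ] <- p
    per_fold_auc[f, ] <- one_vs_rest_auc(y[te], p)
  }
  per_class <- data.frame(class = levels(y),
                          mean = colMeans(per_fold_auc),
                          sd = apply(per_fold_auc, 2, stats::sd))
  structure(list(per_class = per_class,
                 macro_auc = mean(per_class$mean),
                 fold_macro = rowMeans(per_fold_auc),
                 per_fold_auc = per_fold_auc,
                 predictions = data.frame(subject_id = rownames(tab),
                                          fold = fold, truth = y, pred,
                                          check.names = FALSE),
                 chosen_hyper = chosen,
                 fold_assignment = fold),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("prediction_report: macro AUC", round(x$macro_auc, 3), "\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-9s AUC %.3f +/- %.3f\n", pc$class[i], pc$mean[i], pc$sd[i]))
  invisible(x)
}

#' Macro AUC as later visits are added to the predictors
#'
#' Runs one cross-validated evaluation per horizon, each horizon adding the
#' clinical features of later visits to the baseline table.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param labels `data.frame` with `subject_id` and `subtype` (e.g. the
#'   subtyping-assignment table, or generator truth).
#' @param horizons List of visit-label vectors, ordered, e.g.
#'   `list("BL", c("BL", "V04"))`.
#' @param feature_sets Passed to [build_feature_table()].
#' @param ... Passed to [nested_cv_evaluate()].
#' @return `data.frame` with one row per horizon (`horizon`, `macro_auc`) and
#'   the full reports as attribute `"reports"`.
#' @export
incremental_evaluation <- function(cohort, labels, horizons = list("BL"),
                                   feature_sets = "clinical", ...) {
  bad <- setdiff(unique(unlist(horizons)), cohort$visits$label)
  if (length(bad))
    stop("horizon beyond last visit: ", paste(bad, collapse = ", "))
  reports <- lapply(horizons, function(h) {
    tab <- filter_and_impute(build_feature_table(cohort, visits = h,
                                                 feature_sets = feature_sets))
    y <- as.character(labels$subtype[match(rownames(tab), labels$subject_id)])
    lev <- intersect(c("slow", "moderate", "fast"), unique(y))
    if (length(lev) < length(unique(y))) lev <- sort(unique(y))
    nested_cv_evaluate(tab, factor(y, levels = lev), ...)
  })
  out <- data.frame(horizon = vapply(horizons, paste, "", collapse = "+"),
                    macro_auc = vapply(reports, function(r) r$macro_auc, 1))
  attr(out, "reports") <- reports
  out
}

#' Gain-based feature importance and top-k performance curve
#'
#' Per-feature scores are gain-based for the boosted learners and
#' impurity-based for the forest, each normalized to max 1, averaged across
#' the three base learners and renormalized so the top feature scores 1.
#' Optionally retrains on the top-k features for each k in a grid, reporting
#' the cross-validated macro AUC.
#'
#' @param model A trained `stacked_classifier`.
#' @param tab,labels Feature table and labels (needed for `k_grid`).
#' @param k_grid Optional integer vector of top-k sizes for the curve.
#' @param seed Integer seed for the curve CV.
#' @return List with `ranking` (`data.frame` feature, score, descending) and
#'   `top_k_curve` (`data.frame` k, macro_auc) when requested.
#' @export
feature_importance <- function(model, tab = NULL, labels = NULL,
                               k_grid = NULL, seed = 1) {
  stopifnot(inherits(model, "stacked_classifier"))
  feat_of <- model$template$feature_of
  score_by_feature <- function(raw) {
    s <- tapply(raw, feat_of[names(raw)], sum)
    out <- structure(rep(0, length(unique(feat_of))),
                     names = unique(feat_of))
    out[names(s)] <- s
    if (max(out) > 0) out <- out / max(out)
    out
  }
  rf_imp <- model$bases$rf$importance[, "MeanDecreaseGini"]
  imp_rf <- score_by_feature(rf_imp)
  xgb_imp <- function(bst) {
    it <- xgboost::xgb.importance(model = bst)
    structure(it$Gain, names = it$Feature)
  }
  imp_a <- score_by_feature(xgb_imp(model$bases$gbA))
  imp_b <- score_by_feature(xgb_imp(model$bases$gbB))
  feats <- unique(feat_of)
  avg <- (imp_rf[feats] + imp_a[feats] + imp_b[feats]) / 3
  avg <- avg / max(avg)
  ranking <- data.frame(feature = feats, score = as.numeric(avg))
  ranking <- ranking[order(-ranking$score), , drop = FALSE]
  rownames(ranking) <- NULL
  out <- list(ranking = ranking)
  if (!is.null(k_grid)) {
    stopifnot(!is.null(tab), !is.null(labels))
    k_grid <- pmin(k_grid, nrow(ranking))
    out$top_k_curve <- data.frame(k = k_grid, macro_auc = vapply(k_grid, function(k) {
      keep <- ranking$feature[seq_len(k)]
      sub <- tab[, keep, drop = FALSE]
      attr(sub, "provenance") <- attr(tab, "provenance")
      suppressMessages(nested_cv_evaluate(sub, labels, seed = seed,
                                          ntree = model$ntree))$macro_auc
    }, numeric(1)))
  }
  out
}
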