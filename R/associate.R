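#' Subtype-by-time association with serum neurofilament light
#'
#' Linear mixed-effects model of longitudinal serum-Nfl measurements:
#' `nfl ~ subtype * time + sex + height + weight + age + (1 | subject)`,
#' with the slow subtype as reference and time in years since baseline.
#' A significantly positive `fast:time` interaction indicates a steeper Nfl
#' slope in fast progressors than in slow progressors. Random intercepts only:
#' the question concerns fixed-effect slope differences, and random slopes are
#' poorly identified at 4-6 visits.
#'
#' @param cohort A [longitudinal_cohort()] whose panel contains the Nfl
#'   feature and whose subject table has sex/height/weight/age.
#' @param assignments `data.frame` with `subject_id` and `subtype`, e.g. the
#'   table of a `subtype_assignment` or generator truth labels.
#' @param nfl_feature Name of the Nfl feature in the panel.
#' @return Object of class `association_result` with the fixed-effect table
#'   (term, estimate, se, p), the model descriptor and `n` subjects used.
#' @export
nfl_mixed_model <- function(cohort, assignments, nfl_feature = "serum_nfl") {
  d <- cohort$data[cohort$data$feature == nfl_feature, , drop = FALSE]
  if (!nrow(d)) stop("feature not found in panel: ", nfl_feature)
  d$time <- visit_months(cohort, d$visit) / 12
  d <- d[!is.na(d$value), , drop = FALSE]
  obs_per_subj <- table(d$subject_id)
  if (max(obs_per_subj) < 2)
    stop("slope not identifiable: no subject has >= 2 observed visits")
  d$subtype <- assignments$subtype[match(d$subject_id, assignments$subject_id)]
  d <- d[!is.na(d$subtype), , drop = FALSE]
  d$subtype <- stats::relevel(factor(as.character(d$subtype),
                                     levels = c("slow", "moderate", "fast")),
                              ref = "slow")
  sj <- cohort$subjects
  m <- match(d$subject_id, sj$subject_id)
  d$sex <- factor(sj$sex[m]); d$height <- sj$height[m]
  d$weight <- sj$weight[m]; d$age <- sj$age[m]
  fit <- lmerTest::lmer(value ~ subtype * time + sex + height + weight + age +
                          (1 | subject_id), data = d, REML = TRUE)
  co <- summary(fit)$coefficients
  association_result(
    terms = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                       se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
                       row.names = NULL),
    model = "lmm: nfl ~ subtype * time + sex + height + weight + age + (1|subject)",
    n = length(unique(d$subject_id)), fit = fit)
}

#' Linear association of the genetic risk score with a continuous outcome
#'
#' Ordinary least squares of a continuous progression indicator (or predicted
#' cluster-membership probability) on the GRS, standardized to mean 0 / SD 1
#' over the supplied subjects so the coefficient is per 1 SD of GRS.
#' Collinear covariates are dropped with a warning.
#'
#' @param grs Numeric GRS vector.
#' @param outcome Numeric outcome vector.
#' @param covariates Optional `data.frame` of adjustment covariates (e.g. age
#'   at onset, sex, genetic principal components).
#' @return An `association_result` with the GRS beta (per SD), SE, p-value and
#'   the model's adjusted R-squared in `extra$adj_r_squared`.
#' @export
grs_linear <- function(grs, outcome, covariates = NULL) {
  dat <- data.frame(outcome = outcome, grs = as.numeric(scale(grs)))
  dat <- add_covariates(dat, covariates)
  fit <- stats::lm(outcome ~ ., data = dat)
  fit <- drop_aliased(fit, dat)
  co <- summary(fit)$coefficients
  association_result(
    terms = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                       se = co[, "Std. Error"], p = co[, "Pr(>|t|)"],
                       row.names = NULL),
    model = "ols: outcome ~ grs (per SD) + covariates",
    n = nrow(dat), fit = fit,
    extra = list(adj_r_squared = summary(fit)$adj.r.squared))
}

#' Logistic association of the genetic risk score with subtype membership
#'
#' Logistic regression of binary membership in one subtype (vs the rest) on
#' the standardized GRS; reports the log-odds beta, SE, p-value and the odds
#' ratio `exp(beta)` per 1 SD of GRS. If the fit shows (quasi-)complete
#' separation the result is flagged and a weak-ridge penalized fit supplies
#' the estimate (SE/p reported as `NA`).
#'
#' @param grs Numeric GRS vector.
#' @param membership Logical/0-1 vector: member of the subtype of interest.
#' @param covariates Optional `data.frame` of adjustment covariates.
#' @return An `association_result`; `extra$odds_ratio` holds `exp(beta)` and
#'   `extra$separation` the separation flag.
#' @export
grs_logistic <- function(grs, membership, covariates = NULL) {
  y <- as.integer(membership)
  if (length(unique(y)) < 2) stop("both membership classes must be present")
  dat <- data.frame(y = y, grs = as.numeric(scale(grs)))
  dat <- add_covariates(dat, covariates)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  fit <- drop_aliased(fit, dat)
  if (separation) {
    warning("separation detected; reporting weak-ridge penalized estimate")
    X <- stats::model.matrix(y ~ ., data = dat)[, -1, drop = FALSE]
    Xp <- if (ncol(X) == 1) cbind(X, .pad = 0) else X
    rf <- glmnet::glmnet(Xp, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    est <- as.numeric(stats::coef(rf))[-1][seq_len(ncol(X))]
    terms <- data.frame(term = colnames(X), estimate = est,
                        se = NA_real_, p = NA_real_)
  } else {
    co <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], p = co[, "Pr(>|z|)"],
                        row.names = NULL)
  }
  beta <- terms$estimate[terms$term == "grs"]
  association_result(
    terms = terms,
    model = "logistic: membership ~ grs (per SD) + covariates",
    n = nrow(dat), fit = fit,
    extra = list(odds_ratio = exp(beta), separation = separation))
}

add_covariates <- function(dat, covariates) {
  if (is.null(covariates)) return(dat)
  stopifnot(nrow(covariates) == nrow(dat))
  cbind(dat, covariates)
}

# refit without aliased (collinear) covariates, with a warning
drop_aliased <- function(fit, dat) {
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (!length(aliased)) return(fit)
  warning("collinear covariate(s) dropped: ", paste(aliased, collapse = ", "))
  keep <- setdiff(names(dat), aliased)
  stats::update(fit, data = dat[, keep, drop = FALSE])
}

association_result <- function(terms, model, n, fit = NULL, extra = list()) {
  stopifnot(all(terms$se > 0 | is.na(terms$se)),
            all((terms$p >= 0 & terms$p <= 1) | is.na(terms$p)))
  structure(list(terms = terms, model = model, n = n, fit = fit,
                 extra = extra),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result [", x$model, "] n =", x$n, "\n")
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, 4)
  tt$se <- signif(tt$se, 3)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  if (length(x$extra))
    for (nm in names(x$extra))
      if (is.numeric(x$extra[[nm]]))
        cat(" ", nm, "=", signif(x$extra[[nm]], 4), "\n")
  invisible(x)
}

#' Extract one term from an association result
#' @param result An `association_result`.
#' @param term Term name (e.g. `"subtypefast:time"` or `"grs"`).
#' @return Named list with estimate, se, p.
#' @export
association_term <- function(result, term) {
  i <- match(term, result$terms$term)
  if (is.na(i)) stop("term not found: ", term)
  as.list(result$terms[i, c("estimate", "se", "p")])
}
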