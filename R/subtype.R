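#' Fit a full-covariance Gaussian mixture in progression space
#'
#' EM fit of a `k`-component mixture with unrestricted (full) covariance
#' matrices. The deterministic model-based agglomerative initialization is
#' supplemented by `n_init` kmeans-seeded EM restarts and the solution with
#' the best log-likelihood is kept, so fits are deterministic given `seed`.
#' Near-singular component covariances are regularized with a small diagonal
#' floor and flagged.
#'
#' @param points n x d matrix of progression coordinates (d = 2 or 3).
#' @param k Number of components.
#' @param seed Integer seed for the restart initializations.
#' @param n_init Number of kmeans-seeded EM restarts (besides the
#'   agglomerative initialization).
#' @param cov_floor Diagonal floor added to a singular component covariance.
#' @return Object of class `gmm_fit`: `weights`, `means` (k x d),
#'   `covariances` (d x d x k), `loglik`, `n`, `d`, `df`, `bic`,
#'   `regularized` flag.
#' @export
fit_gmm <- function(points, k, seed = 1, n_init = 10, cov_floor = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n <= k * d) stop("too few points: need n > k*d")
  set.seed(seed)
  res <- Mclust(points, G = k, modelNames = "VVV", verbose = FALSE)
  if (is.null(res))
    res <- Mclust(points, G = k, modelNames = "VVV", verbose = FALSE,
                  prior = priorControl())
  best_ll <- -Inf; pars <- NULL
  if (!is.null(res) && is.finite(res$loglik)) {
    best_ll <- res$loglik; pars <- res$parameters
  }
  if (k > 1 && n_init > 0) {
    set.seed(seed)
    for (s in seq_len(n_init)) {
      km <- tryCatch(stats::kmeans(points, k, nstart = 3),
                     error = function(e) NULL)
      if (is.null(km)) next
      m <- tryCatch(meVVV(data = points, z = unmap(km$cluster)),
                    error = function(e) NULL)
      if (!is.null(m) && !is.na(m$loglik) && m$loglik > best_ll) {
        best_ll <- m$loglik; pars <- m$parameters
      }
    }
  }
  if (is.null(pars)) stop("GMM fit failed for k = ", k)
  means <- t(pars$mean)
  if (k == 1) means <- matrix(pars$mean, 1, d)
  covs <- pars$variance$sigma
  if (length(dim(covs)) == 2) covs <- array(covs, c(d, d, 1))
  regularized <- FALSE
  for (j in seq_len(k)) {
    ev <- eigen(covs[, , j], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < cov_floor) {
      covs[, , j] <- covs[, , j] + diag(cov_floor, d)
      regularized <- TRUE
    }
  }
  if (regularized) warning("degenerate component covariance regularized")
  q <- (k - 1) + k * d + k * d * (d + 1) / 2
  weights <- as.numeric(pars$pro)
  loglik <- gmm_loglik(points, weights, means, covs)
  structure(list(weights = weights, means = means, covariances = covs,
                 loglik = loglik, n = n, d = d, df = q,
                 bic = -2 * loglik + q * log(n),
                 regularized = regularized),
            class = "gmm_fit")
}

# log N(x; mu, Sigma) for all rows of x
dmvnorm_log <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

gmm_logdens <- function(points, weights, means, covs) {
  k <- length(weights)
  ld <- vapply(seq_len(k), function(j)
    log(weights[j]) + dmvnorm_log(points, means[j, ], covs[, , j]),
    numeric(nrow(points)))
  matrix(ld, nrow = nrow(points))
}

gmm_loglik <- function(points, weights, means, covs) {
  ld <- gmm_logdens(points, weights, means, covs)
  mx <- apply(ld, 1, max)
  sum(mx + log(rowSums(exp(ld - mx))))
}

#' Select the number of progression subtypes by BIC
#'
#' Fits full-covariance mixtures over a range of component counts and selects
#' the count minimizing `BIC = -2 loglik + q log(n)`, with `q` the
#' free-parameter count of the mixture. Candidates that fail to fit are
#' excluded with a warning.
#'
#' @param points n x d progression coordinates.
#' @param k_range Candidate component counts (default 1..6).
#' @param seed Integer seed.
#' @return Object of class `subtype_model`: selected `k`, mixture parameters,
#'   `bic_table` (k, bic), `label_order` (component indices sorted slow ->
#'   fast by the mean of the per-dimension component means) and `labels`
#'   (`"slow"`, `"moderate"`, `"fast"` when `k` = 3).
#' @export
select_k_bic <- function(points, k_range = 1:6, seed = 1) {
  if (!length(k_range)) stop("k_range must be non-empty")
  fits <- list(); bics <- numeric(0); ks <- integer(0)
  for (k in k_range) {
    f <- tryCatch(fit_gmm(points, k, seed = seed),
                  error = function(e) {
                    warning("k = ", k, " excluded: ", conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) {
      fits[[as.character(k)]] <- f
      bics <- c(bics, f$bic); ks <- c(ks, k)
    }
  }
  if (!length(ks)) stop("no candidate k could be fitted")
  best <- ks[which.min(bics)]
  subtype_model(fits[[as.character(best)]],
                bic_table = data.frame(k = ks, bic = bics))
}

#' Construct a subtype model from a fitted mixture
#'
#' Orders components slow -> fast by the mean of their per-dimension means
#' (overall progression), and names them `slow`/`moderate`/`fast` when there
#' are three.
#'
#' @param fit A `gmm_fit`.
#' @param bic_table Optional BIC table from [select_k_bic()].
#' @return An object of class `subtype_model`.
#' @export
subtype_model <- function(fit, bic_table = NULL) {
  stopifnot(inherits(fit, "gmm_fit"))
  k <- length(fit$weights)
  ord <- order(rowMeans(fit$means))
  labels <- if (k == 3) c("slow", "moderate", "fast") else
    paste0("subtype", seq_len(k))
  structure(list(k = k, weights = fit$weights, means = fit$means,
                 covariances = fit$covariances, loglik = fit$loglik,
                 n = fit$n, d = fit$d, bic = fit$bic,
                 bic_table = bic_table, label_order = ord, labels = labels),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype_model:", x$k, "Gaussian components in", x$d, "dimensions",
      "(n =", x$n, ")\n")
  m <- x$means[x$label_order, , drop = FALSE]
  rownames(m) <- x$labels
  print(round(m, 3))
  if (!is.null(x$bic_table)) {
    cat("BIC-selected k =", x$k, "over candidates",
        paste(x$bic_table$k, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign subjects to progression subtypes
#'
#' Computes posterior responsibilities under the fitted mixture and relabels
#' components through the slow -> fast ordering, so `"fast"` is always the
#' component with the highest mean progression.
#'
#' @param model A `subtype_model`.
#' @param points n x d coordinates (same space the model was fitted in).
#' @param subject_ids Optional subject identifiers.
#' @return Object of class `subtype_assignment`: `data.frame` `table` with
#'   subject_id, hard `subtype` label and one posterior column per ordered
#'   label, plus the raw `posterior` matrix.
#' @export
assign_subtypes <- function(model, points, subject_ids = NULL) {
  stopifnot(inherits(model, "subtype_model"))
  points <- as.matrix(points)
  if (ncol(points) != model$d) stop("points dimensionality mismatch")
  ld <- gmm_logdens(points, model$weights, model$means, model$covariances)
  mx <- apply(ld, 1, max)
  post <- exp(ld - mx)
  post <- post / rowSums(post)
  post_ord <- post[, model$label_order, drop = FALSE]
  colnames(post_ord) <- model$labels
  hard <- model$labels[max.col(post_ord, ties.method = "first")]
  if (is.null(subject_ids))
    subject_ids <- rownames(points) %||% as.character(seq_len(nrow(points)))
  tab <- data.frame(subject_id = subject_ids,
                    subtype = factor(hard, levels = model$labels),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(post_ord))
  structure(list(table = tab, posterior = post_ord), class = "subtype_assignment")
}

#' Transfer a frozen subtype model to an independent cohort
#'
#' Projects the replication cohort onto the training progression space (frozen
#' loadings, contributions and bounds) and assigns subtypes with the frozen
#' mixture. No parameter is refitted.
#'
#' @param model A fitted `subtype_model` (frozen).
#' @param space The training `progression_space_model`.
#' @param vm_new The replication cohort's `vectorized_matrix`, preprocessed
#'   with the training decisions ([apply_preprocess()]).
#' @return A `subtype_assignment` for the new cohort.
#' @export
transfer_subtypes <- function(model, space, vm_new) {
  stopifnot(inherits(model, "subtype_model"),
            inherits(space, "progression_space_model"))
  proj <- project_cohort(space, vm_new)
  pts <- progression_coordinates(space, dims = model$d,
                                 normalized = proj$normalized)
  assign_subtypes(model, pts, subject_ids = vm_new$subjects)
}

#' End-to-end subtype discovery on a raw cohort
#'
#' Convenience wrapper: preprocess, fit the progression space on the full
#' cohort (cases and controls), then select and fit the mixture on the case
#' population only, in the default 2-D (motor, cognitive/sleep) view.
#'
#' @param cohort A raw [longitudinal_cohort()].
#' @param p NMF rank.
#' @param dims Clustering space dimensionality (2 or 3).
#' @param k_range Candidate subtype counts.
#' @param seed Integer seed.
#' @return List with `prep` (`preprocessed_cohort`), `space`
#'   (`progression_space_model`), `model` (`subtype_model`), `assignment`
#'   (cases only) and `points` (case coordinates).
#' @export
subtype_pipeline <- function(cohort, p = 3, dims = 2, k_range = 1:6, seed = 1) {
  prep <- preprocess_cohort(cohort)
  space <- fit_progression_space(prep, p = p, seed = seed)
  pts <- progression_coordinates(space, dims = dims)
  cases <- cohort$subjects$subject_id[cohort$subjects$group == "case"]
  pts_cases <- pts[space$subjects %in% cases, , drop = FALSE]
  rownames(pts_cases) <- space$subjects[space$subjects %in% cases]
  model <- select_k_bic(pts_cases, k_range = k_range, seed = seed)
  assignment <- assign_subtypes(model, pts_cases)
  list(prep = prep, space = space, model = model,
       assignment = assignment, points = pts_cases)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
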