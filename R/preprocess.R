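#' Align feature directionality so that higher always means worse
#'
#' For each clinical feature a two-sample one-tailed t-test compares controls
#' against cases. A feature is judged oriented lower-is-worse (and reflected)
#' when the test shows the control mean significantly exceeding the case mean;
#' after alignment the highest values uniformly represent the worst outcome.
#' Reflection is `x' = max(x) - x` per feature over the pooled cohort, which
#' preserves non-negativity.
#'
#' @param cohort A [longitudinal_cohort()] with both cases and controls.
#' @param alpha One-sided significance level for the flip decision.
#' @param domains Feature domains subject to alignment.
#' @return List with `cohort` (aligned) and `report`: per feature the
#'   t-statistic (case minus control), one-sided p-value for control > case,
#'   `flipped`, `constant` flag, and the reflection constant used.
#' @export
align_directionality <- function(cohort, alpha = 0.05,
                                 domains = c("motor", "cognitive", "sleep")) {
  feats <- clinical_features(cohort, domains)
  if (!all(c("case", "control") %in% cohort$subjects$group))
    stop("directionality test needs both cases and controls")
  case_ids <- cohort$subjects$subject_id[cohort$subjects$group == "case"]
  d <- cohort$data
  rows <- lapply(feats, function(f) {
    v <- d$value[d$feature == f]
    is_case <- d$subject_id[d$feature == f] %in% case_ids
    x_case <- v[is_case & !is.na(v)]
    x_ctrl <- v[!is_case & !is.na(v)]
    if (stats::sd(x_case) == 0 && stats::sd(x_ctrl) == 0) {
      return(data.frame(feature = f, t = NA_real_, p = NA_real_,
                        flipped = FALSE, constant = TRUE,
                        reflect_at = NA_real_))
    }
    tt <- stats::t.test(x_ctrl, x_case, alternative = "greater")
    flip <- tt$p.value < alpha
    data.frame(feature = f, t = -unname(tt$statistic), p = tt$p.value,
               flipped = flip, constant = FALSE,
               reflect_at = if (flip) max(v, na.rm = TRUE) else NA_real_)
  })
  report <- do.call(rbind, rows)
  cohort <- apply_directions(cohort, report)
  list(cohort = cohort, report = report)
}

#' Apply recorded direction decisions to a cohort
#'
#' Used to preprocess a replication cohort with the training cohort's flip
#' decisions and reflection constants (no re-testing).
#'
#' @param cohort A [longitudinal_cohort()].
#' @param report A direction report from [align_directionality()].
#' @return The reflected cohort.
#' @export
apply_directions <- function(cohort, report) {
  for (i in which(report$flipped)) {
    f <- report$feature[i]
    sel <- cohort$data$feature == f
    cohort$data$value[sel] <- report$reflect_at[i] - cohort$data$value[sel]
  }
  cohort
}

#' Clip features at outer percentiles
#'
#' Limits each feature to the range given by its lower and upper percentiles
#' (defaults 2nd and 98th), computed per feature over all non-missing values
#' pooled across visits and subjects. Percentiles use the linear-interpolation
#' definition (R type 7). Idempotent.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param lo,hi Percentile bounds in \[0, 100\].
#' @param domains Feature domains to clip.
#' @param bounds Optional bounds `data.frame` (feature, lo, hi) from a
#'   previous call, for transferring training clip bounds to a new cohort.
#' @return Clipped cohort with the bounds table attached as attribute
#'   `"clip_bounds"`.
#' @export
clip_percentiles <- function(cohort, lo = 2, hi = 98,
                             domains = c("motor", "cognitive", "sleep"),
                             bounds = NULL) {
  feats <- clinical_features(cohort, domains)
  if (is.null(bounds)) {
    bounds <- do.call(rbind, lapply(feats, function(f) {
      v <- cohort$data$value[cohort$data$feature == f]
      v <- v[!is.na(v)]
      if (!length(v)) stop("all-missing feature cannot be clipped: ", f)
      q <- stats::quantile(v, c(lo, hi) / 100, type = 7, names = FALSE)
      data.frame(feature = f, lo = q[1], hi = q[2])
    }))
  }
  for (i in seq_len(nrow(bounds))) {
    sel <- cohort$data$feature == bounds$feature[i]
    cohort$data$value[sel] <- pmin(pmax(cohort$data$value[sel], bounds$lo[i]),
                                   bounds$hi[i])
  }
  attr(cohort, "clip_bounds") <- bounds
  cohort
}

#' Fill missing visits by longitudinal linear interpolation
#'
#' Interior gaps in each (subject, feature) trajectory are filled by linear
#' interpolation on the month axis; leading/trailing gaps take the nearest
#' observed value (interpolation is undefined outside the observed span).
#' Output has zero missing cells.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param domains Feature domains to interpolate (default: all features).
#' @return Fully observed cohort.
#' @export
interpolate_missing <- function(cohort, domains = NULL) {
  d <- cohort$data
  feats <- if (is.null(domains)) cohort$features$name else
    cohort$features$name[cohort$features$domain %in% domains]
  sel <- d$feature %in% feats
  months <- visit_months(cohort, d$visit)
  key <- paste(d$subject_id, d$feature, sep = "\r")
  ord <- order(key, months)
  idx <- which(sel)[order(key[sel], months[sel])]
  grp <- key[idx]
  pieces <- split(seq_along(idx), factor(grp, levels = unique(grp)))
  fully_missing <- vapply(pieces, function(ii) all(is.na(d$value[idx[ii]])), TRUE)
  if (any(fully_missing))
    stop("fully missing (subject, feature) trajectories: ",
         paste(utils::head(names(pieces)[fully_missing], 5), collapse = ", "))
  filled <- unlist(lapply(pieces, function(ii) {
    v <- d$value[idx[ii]]
    if (!anyNA(v)) return(v)
    if (sum(!is.na(v)) == 1) return(rep(v[!is.na(v)], length(v)))
    zoo::na.approx(v, x = months[idx[ii]], rule = 2, na.rm = FALSE)
  }), use.names = FALSE)
  d$value[idx] <- filled
  cohort$data <- d
  cohort
}

#' Stack a cohort panel into the factorization matrix
#'
#' Transforms all observations of each clinical feature into a column vector
#' across visits, then appends features: `X[(feature, visit), subject]`. The
#' row and column index maps make the operation invertible
#' (see [devectorize()]).
#'
#' @param cohort Fully observed [longitudinal_cohort()].
#' @param domains Feature domains entering the matrix.
#' @return An object of class `vectorized_matrix`: `X` (un-normalized),
#'   `row_index` (feature, visit per row), `subjects`, `feature_domains`,
#'   `normalized = FALSE`.
#' @export
vectorize <- function(cohort, domains = c("motor", "cognitive", "sleep")) {
  feats <- clinical_features(cohort, domains)
  subs <- cohort$subjects$subject_id
  vis <- cohort$visits$label
  d <- cohort$data[cohort$data$feature %in% feats, , drop = FALSE]
  if (anyNA(d$value))
    stop("vectorize precondition violated: missing cells present (interpolate first)")
  row_index <- data.frame(feature = rep(feats, each = length(vis)),
                          visit = rep(vis, length(feats)),
                          stringsAsFactors = FALSE)
  ri <- match(paste(d$feature, d$visit, sep = "\r"),
              paste(row_index$feature, row_index$visit, sep = "\r"))
  ci <- match(d$subject_id, subs)
  X <- matrix(NA_real_, nrow(row_index), length(subs),
              dimnames = list(paste(row_index$feature, row_index$visit, sep = "."), subs))
  X[cbind(ri, ci)] <- d$value
  if (anyNA(X)) stop("vectorize: panel is not complete over features x visits x subjects")
  fd <- cohort$features$domain[match(row_index$feature, cohort$features$name)]
  structure(list(X = X, row_index = row_index, subjects = subs,
                 feature_domains = fd, bounds = NULL, normalized = FALSE),
            class = "vectorized_matrix")
}

#' Reconstruct the long panel from a vectorized matrix
#'
#' @param vm A `vectorized_matrix`.
#' @return `data.frame` with subject_id, visit, feature, value.
#' @export
devectorize <- function(vm) {
  data.frame(subject_id = rep(vm$subjects, each = nrow(vm$X)),
             visit = rep(vm$row_index$visit, length(vm$subjects)),
             feature = rep(vm$row_index$feature, length(vm$subjects)),
             value = as.vector(vm$X), stringsAsFactors = FALSE)
}

#' @export
print.vectorized_matrix <- function(x, ...) {
  cat("vectorized_matrix: ", nrow(x$X), " (feature, visit) rows x ",
      ncol(x$X), " subjects; normalized: ", x$normalized, "\n", sep = "")
  invisible(x)
}

#' Min-max normalize each matrix row to \[0, 1\]
#'
#' Each row is mapped by `(x - min) / (max - min)`; constant rows map to 0.
#' The per-row bounds are recorded so that a replication cohort can be
#' normalized with the training bounds (out-of-range values are clipped to
#' \[0, 1\]).
#'
#' @param vm A `vectorized_matrix` from [vectorize()].
#' @param bounds Optional per-row bounds `data.frame` (row name, min, max)
#'   from a previous call.
#' @return The normalized `vectorized_matrix` with `bounds` set.
#' @export
minmax_normalize <- function(vm, bounds = NULL) {
  stopifnot(inherits(vm, "vectorized_matrix"))
  if (is.null(bounds)) {
    bounds <- data.frame(row = rownames(vm$X),
                         min = apply(vm$X, 1, min),
                         max = apply(vm$X, 1, max),
                         stringsAsFactors = FALSE)
  } else {
    m <- match(rownames(vm$X), bounds$row)
    if (anyNA(m)) stop("normalization bounds missing for rows: ",
                       paste(utils::head(rownames(vm$X)[is.na(m)], 5), collapse = ", "))
    bounds <- bounds[m, , drop = FALSE]
  }
  rng <- bounds$max - bounds$min
  Xn <- (vm$X - bounds$min) / ifelse(rng > 0, rng, 1)
  Xn[rng == 0, ] <- 0
  vm$X <- pmin(pmax(Xn, 0), 1)
  vm$bounds <- bounds
  vm$normalized <- TRUE
  vm
}

#' Full preprocessing pipeline: align, clip, interpolate, vectorize, normalize
#'
#' Runs the five preprocessing stages in order and captures every data-driven
#' decision (flip decisions and reflection constants, clip bounds, row
#' normalization bounds) so a replication cohort can be transformed with the
#' training decisions via [apply_preprocess()].
#'
#' @param cohort A raw [longitudinal_cohort()].
#' @param alpha Significance level for the direction test.
#' @param clip Length-2 percentile clip bounds.
#' @param domains Feature domains entering the factorization matrix.
#' @return List of class `preprocessed_cohort`: `vm` (normalized matrix),
#'   `cohort` (aligned/clipped/interpolated panel) and `params`
#'   (class `preprocess_params`) holding the frozen decisions.
#' @export
preprocess_cohort <- function(cohort, alpha = 0.05, clip = c(2, 98),
                              domains = c("motor", "cognitive", "sleep")) {
  al <- align_directionality(cohort, alpha = alpha, domains = domains)
  cl <- clip_percentiles(al$cohort, lo = clip[1], hi = clip[2], domains = domains)
  it <- interpolate_missing(cl, domains = domains)
  vm <- minmax_normalize(vectorize(it, domains = domains))
  params <- structure(list(direction_report = al$report,
                           clip_bounds = attr(cl, "clip_bounds"),
                           row_bounds = vm$bounds,
                           domains = domains),
                      class = "preprocess_params")
  structure(list(vm = vm, cohort = it, params = params),
            class = "preprocessed_cohort")
}

#' Preprocess a replication cohort with frozen training decisions
#'
#' @param cohort A raw [longitudinal_cohort()] (may have fewer visits than the
#'   training cohort).
#' @param params `preprocess_params` from [preprocess_cohort()].
#' @return A normalized `vectorized_matrix` on the training scale.
#' @export
apply_preprocess <- function(cohort, params) {
  stopifnot(inherits(params, "preprocess_params"))
  co <- apply_directions(cohort, params$direction_report)
  co <- clip_percentiles(co, domains = params$domains, bounds = params$clip_bounds)
  co <- interpolate_missing(co, domains = params$domains)
  minmax_normalize(vectorize(co, domains = params$domains),
                   bounds = params$row_bounds)
}
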