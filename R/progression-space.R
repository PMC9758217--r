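#' Domain-contribution matrix from NMF loadings
#'
#' For each symptom domain `s` and latent dimension `d`, the contribution
#' `C[s, d]` is the sum of the loading weights `U[r, d]` over the
#' (feature, visit) rows `r` whose feature belongs to domain `s`, with each
#' domain row then normalized to sum 1. Row normalization makes the adjusted
#' indicators invariant (up to a per-dimension scale absorbed by the final
#' min-max) to the NMF scale indeterminacy.
#'
#' @param U Loadings matrix, rows = (feature, visit) pairs.
#' @param feature_domains Domain of each row of `U`.
#' @param domain_order Domain names defining the output row order.
#' @return Contribution matrix `C` (domains x latent dimensions), rows sum
#'   to 1.
#' @export
domain_contributions <- function(U, feature_domains,
                                 domain_order = c("motor", "cognitive", "sleep")) {
  if (length(feature_domains) != nrow(U))
    stop("every row of U needs a domain assignment")
  if (anyNA(feature_domains) || !all(feature_domains %in% domain_order))
    stop("rows with no (or unknown) domain assignment present")
  C <- t(vapply(domain_order,
                function(s) colSums(U[feature_domains == s, , drop = FALSE]),
                numeric(ncol(U))))
  rs <- rowSums(C)
  if (any(rs == 0)) stop("domain with all-zero loadings: ",
                         paste(domain_order[rs == 0], collapse = ", "))
  C <- C / rs
  dimnames(C) <- list(domain_order, colnames(U))
  C
}

#' Latent-space adjustment of progression indicators
#'
#' Remaps the raw per-subject NMF indicators into domain-named axes by the
#' weighted sum `i_new[s] = sum_d C[s, d] * i_old[d]`, i.e. `i_new = C V`.
#'
#' @param V Raw indicator matrix (latent dimensions x subjects), non-negative.
#' @param C Domain-contribution matrix with rows summing to 1.
#' @return Adjusted indicator matrix (domains x subjects), non-negative.
#' @export
adjust_indicators <- function(V, C) {
  if (ncol(C) != nrow(V)) stop("dimension mismatch between C and V")
  if (any(V < 0)) stop("indicators must be non-negative")
  if (any(abs(rowSums(C) - 1) > 1e-8)) stop("rows of C must sum to 1")
  C %*% V
}

#' Min-max normalize adjusted indicators into the unit progression space
#'
#' @param adjusted Adjusted indicator matrix (domains x subjects).
#' @param bounds Optional per-dimension (min, max) matrix from a training fit,
#'   for replication-cohort transfer; new values are clipped to \[0, 1\].
#' @return List with `normalized` (same shape, entries in \[0, 1\]), `bounds`,
#'   and `constant` (flag per dimension).
#' @export
normalize_space <- function(adjusted, bounds = NULL) {
  stopifnot(all(is.finite(adjusted)))
  if (is.null(bounds)) {
    bounds <- cbind(min = apply(adjusted, 1, min),
                    max = apply(adjusted, 1, max))
    rownames(bounds) <- rownames(adjusted)
  }
  rng <- bounds[, "max"] - bounds[, "min"]
  constant <- rng == 0
  if (any(constant))
    warning("constant progression dimension(s) mapped to 0: ",
            paste(rownames(bounds)[constant], collapse = ", "))
  normalized <- (adjusted - bounds[, "min"]) / ifelse(rng > 0, rng, 1)
  normalized[constant, ] <- 0
  list(normalized = pmin(pmax(normalized, 0), 1), bounds = bounds,
       constant = constant)
}

#' Fit the full progression-space model
#'
#' Runs rank-`p` NMF on the preprocessed matrix, computes the domain
#' contributions from the learned loadings, applies the latent-space
#' adjustment and normalizes each domain axis to \[0, 1\]. Each adjusted
#' dimension is named by its symptom domain by construction of the
#' contribution matrix.
#'
#' @param x A `preprocessed_cohort` from [preprocess_cohort()] or a normalized
#'   `vectorized_matrix`.
#' @param p NMF rank (default 3).
#' @param seed,max_iter,tol Passed to [fit_nmf()].
#' @param domain_order Domain axis order.
#' @return An object of class `progression_space_model` with fields `U`, `V`,
#'   `p`, `C`, `adjusted`, `normalized`, `space_bounds`, `domain_order`,
#'   `explained_fraction`, `row_index`, `subjects`, `rel_error`.
#' @export
fit_progression_space <- function(x, p = 3, seed = 1, max_iter = 2000,
                                  tol = 1e-7,
                                  domain_order = c("motor", "cognitive", "sleep")) {
  vm <- if (inherits(x, "preprocessed_cohort")) x$vm else x
  stopifnot(inherits(vm, "vectorized_matrix"))
  if (!vm$normalized) stop("matrix must be min-max normalized before fitting")
  fit <- fit_nmf(vm$X, p = p, seed = seed, max_iter = max_iter, tol = tol)
  C <- domain_contributions(fit$U, vm$feature_domains, domain_order)
  adjusted <- adjust_indicators(fit$V, C)
  ns <- normalize_space(adjusted)
  model <- structure(list(U = fit$U, V = fit$V, p = p, C = C,
                          adjusted = adjusted, normalized = ns$normalized,
                          space_bounds = ns$bounds,
                          domain_order = domain_order,
                          explained_fraction = NULL,
                          row_index = vm$row_index,
                          feature_domains = vm$feature_domains,
                          subjects = vm$subjects,
                          rel_error = fit$rel_error),
                     class = "progression_space_model")
  model$explained_fraction <- explained_variance(model)
  model
}

#' @export
print.progression_space_model <- function(x, ...) {
  cat("progression_space_model: rank", x$p, "NMF on",
      nrow(x$U), "(feature, visit) rows x", length(x$subjects), "subjects\n")
  cat("  relative reconstruction error:", signif(x$rel_error, 4), "\n")
  ef <- round(100 * x$explained_fraction, 2)
  cat("  explained variance:",
      paste(sprintf("%s %.2f%%", names(ef), ef), collapse = ", "), "\n")
  invisible(x)
}

#' Per-dimension explained-variance fractions
#'
#' The fraction for each domain axis is the across-subject variance of its
#' adjusted indicator divided by the total variance over the three axes.
#'
#' @param model A `progression_space_model`.
#' @return Named numeric vector summing to 1.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "progression_space_model"))
  if (ncol(model$adjusted) < 2)
    stop("explained variance needs at least 2 subjects")
  v <- apply(model$adjusted, 1, stats::var)
  v / sum(v)
}

#' Project a new cohort onto a fitted progression space
#'
#' Solves a non-negative least-squares problem per new subject with the
#' training loadings `U` frozen, then applies the training contribution matrix
#' and the training space bounds. Replication cohorts with fewer visits are
#' projected using only the shared (feature, visit) rows of `U`.
#'
#' @param model A fitted `progression_space_model`.
#' @param vm_new A `vectorized_matrix` for the new cohort, normalized with the
#'   TRAINING row bounds (see [apply_preprocess()]).
#' @return List with `V` (raw projected indicators), `adjusted` and
#'   `normalized` (domains x new subjects).
#' @export
project_cohort <- function(model, vm_new) {
  stopifnot(inherits(model, "progression_space_model"),
            inherits(vm_new, "vectorized_matrix"))
  train_keys <- paste(model$row_index$feature, model$row_index$visit, sep = "\r")
  new_keys <- paste(vm_new$row_index$feature, vm_new$row_index$visit, sep = "\r")
  m <- match(new_keys, train_keys)
  if (anyNA(m))
    stop("feature set mismatch; rows absent from the training space: ",
         paste(utils::head(rownames(vm_new$X)[is.na(m)], 5), collapse = ", "))
  U <- model$U[m, , drop = FALSE]
  V_new <- nnls_project(U, vm_new$X)
  adjusted <- adjust_indicators(V_new, model$C)
  ns <- normalize_space(adjusted, bounds = model$space_bounds)
  list(V = V_new, adjusted = adjusted, normalized = ns$normalized)
}

#' Progression-space coordinates for clustering and plotting
#'
#' Returns per-subject coordinates in the normalized space. The default 2-D
#' view is (motor, cognitive/sleep): the cognitive and sleep axes are combined
#' by a contribution-weighted average, weights proportional to each domain's
#' explained-variance fraction.
#'
#' @param model A `progression_space_model`, or the `normalized` matrix from
#'   [project_cohort()] (then supply `weights` from the training model).
#' @param dims 2 or 3.
#' @param normalized Optional external normalized matrix (domains x subjects),
#'   e.g. for a projected replication cohort.
#' @return Matrix (subjects x dims) with columns `motor`, `cogsleep` (2-D) or
#'   `motor`, `cognitive`, `sleep` (3-D).
#' @export
progression_coordinates <- function(model, dims = 2, normalized = NULL) {
  stopifnot(inherits(model, "progression_space_model"), dims %in% c(2, 3))
  nm <- if (is.null(normalized)) model$normalized else normalized
  if (dims == 3) {
    out <- t(nm[model$domain_order, , drop = FALSE])
    colnames(out) <- model$domain_order
    return(out)
  }
  w <- model$explained_fraction[c("cognitive", "sleep")]
  w <- w / sum(w)
  cbind(motor = nm["motor", ],
        cogsleep = w[["cognitive"]] * nm["cognitive", ] +
          w[["sleep"]] * nm["sleep", ])
}
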