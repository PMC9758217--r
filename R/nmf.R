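#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `X` (m x n) into non-negative `U` (m x p)
#' and `V` (p x n) minimizing the Frobenius reconstruction error
#' `||X - UV||_F`. Initialization is the deterministic non-negative double
#' SVD (NNDSVD) with zero entries filled by the matrix mean and a tiny seeded
#' perturbation; optimization is hierarchical alternating least squares
#' (HALS), updating one latent component at a time with a closed-form
#' non-negative projection. Deterministic given the seed.
#'
#' @param X Non-negative numeric matrix with no missing entries (typically a
#'   normalized `vectorized_matrix$X`).
#' @param p Factorization rank (default 3).
#' @param seed Integer seed for the initialization perturbation.
#' @param max_iter Maximum multiplicative-update iterations.
#' @param tol Stop when the relative reconstruction error improves by less
#'   than `tol` between checks.
#' @return List with `U`, `V`, `rel_error` (final relative Frobenius error)
#'   and `iterations`.
#' @export
fit_nmf <- function(X, p = 3, seed = 1, max_iter = 1000, tol = 1e-9) {
  if (inherits(X, "vectorized_matrix")) X <- X$X
  stopifnot(is.matrix(X), all(is.finite(X)))
  if (any(X < 0)) stop("NMF requires a non-negative matrix")
  m <- nrow(X); n <- ncol(X)
  if (p < 1 || p > min(m, n))
    stop("parameter error: rank p must be in 1..min(dim(X))")

  init <- nndsvd_init(X, p, seed)
  U <- init$U; V <- init$V
  eps <- .Machine$double.eps
  xnorm <- sqrt(sum(X^2))
  prev <- Inf; it <- 0
  while (it < max_iter) {
    it <- it + 1
    VVt <- tcrossprod(V); XVt <- X %*% t(V)
    for (j in seq_len(p))
      U[, j] <- pmax(0, U[, j] + (XVt[, j] - U %*% VVt[, j]) / max(VVt[j, j], eps))
    UtU <- crossprod(U); UtX <- crossprod(U, X)
    for (j in seq_len(p))
      V[j, ] <- pmax(0, V[j, ] + (UtX[j, ] - UtU[j, ] %*% V) / max(UtU[j, j], eps))
    if (it %% 10 == 0) {
      rel <- sqrt(sum((X - U %*% V)^2)) / max(xnorm, eps)
      if (prev - rel < tol) break
      prev <- rel
    }
  }
  rel <- sqrt(sum((X - U %*% V)^2)) / max(xnorm, eps)
  dimnames(U) <- list(rownames(X), paste0("dim", seq_len(p)))
  dimnames(V) <- list(paste0("dim", seq_len(p)), colnames(X))
  list(U = U, V = V, rel_error = rel, iterations = it)
}

# Non-negative double SVD initialization (Boutsidis & Gallopoulos scheme),
# zeros filled with mean(X)/100 plus a small seeded jitter to avoid
# multiplicative-update lock-in.
nndsvd_init <- function(X, p, seed) {
  sv <- svd(X, nu = p, nv = p)
  U <- matrix(0, nrow(X), p)
  V <- matrix(0, p, ncol(X))
  U[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  V[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (p > 1) for (j in 2:p) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
    n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      s <- sqrt(sv$d[j] * n_up * n_vp)
      U[, j] <- if (n_up > 0) s * up / n_up else 0
      V[j, ] <- if (n_vp > 0) s * vp / n_vp else 0
    } else {
      s <- sqrt(sv$d[j] * n_un * n_vn)
      U[, j] <- if (n_un > 0) s * un / n_un else 0
      V[j, ] <- if (n_vn > 0) s * vn / n_vn else 0
    }
  }
  floor_val <- mean(X) / 100
  set.seed(seed)
  U[U <= 0] <- floor_val * (1 + stats::runif(sum(U <= 0)))
  V[V <= 0] <- floor_val * (1 + stats::runif(sum(V <= 0)))
  list(U = U, V = V)
}

# non-negative least squares projection of columns of Xnew onto a frozen U:
# argmin_{v >= 0} || x - U v ||_2 per column
nnls_project <- function(U, Xnew) {
  V <- apply(Xnew, 2, function(x) pracma::lsqnonneg(U, x)$x)
  V <- matrix(V, nrow = ncol(U), dimnames = list(colnames(U), colnames(Xnew)))
  V
}
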