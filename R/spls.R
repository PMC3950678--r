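## NIPALS PLS2 on centered (optionally scaled) matrices.
## Returns W (p x K, unit-norm direction vectors) and beta (p x q) on the
## centered/scaled working scale.
pls_nipals <- function(X, Y, K) {
  p <- ncol(X); q <- ncol(Y)
  K <- min(K, p, nrow(X) - 1L)
  E <- X; F_ <- Y
  W <- matrix(0, p, 0); P_ <- matrix(0, p, 0); Q_ <- matrix(0, q, 0)
  for (k in seq_len(K)) {
    M <- crossprod(E, F_)
    if (max(abs(M)) < 1e-300) break
    w <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-300) break
    pvec <- crossprod(E, t_) / tt
    qvec <- crossprod(F_, t_) / tt
    E <- E - tcrossprod(t_, pvec)
    F_ <- F_ - tcrossprod(t_, qvec)
    W <- cbind(W, w); P_ <- cbind(P_, pvec); Q_ <- cbind(Q_, qvec)
  }
  if (!ncol(W)) return(list(W = matrix(0, p, 1L), beta = matrix(0, p, q)))
  beta <- W %*% solve(crossprod(P_, W), t(Q_))
  list(W = W, beta = beta)
}

#' Sparse partial least squares regression (SPLS)
#'
#' Fits the SPLS model `Y = X W R + F` for a multivariate response, selecting
#' predictors by an L1 soft-threshold on the direction-vector surrogate. At
#' each of `K` components the surrogate direction is the first left singular
#' vector `z` of `t(X) %*% Y_res`; its entries are thresholded as
#' `c_j = sign(z_j) (|z_j| - eta * max|z|)+`, the active set is the union of
#' nonzero surrogate supports over components, and an ordinary PLS fit on the
#' active predictors supplies coefficients (and the deflation of `Y`). Rows of
#' `beta` outside the active set are exactly zero. `X` and `Y` are centered
#' internally (and `X` optionally scaled); `beta` is returned on the original
#' scale.
#'
#' `eta` in `[0, 1)` controls sparsity (0 = ordinary PLS); `kappa` (default
#' 0.5, the standard compromise for multivariate responses) is accepted for
#' completeness — the singular-vector surrogate used here corresponds to that
#' default.
#'
#' @param X n x p predictor matrix (e.g. SNP dosages, additively coded).
#' @param Y n x q response matrix (module expression, samples in rows).
#' @param eta sparsity parameter in `[0, 1)`.
#' @param K number of latent components (>= 1).
#' @param kappa objective weight in (0, 0.5]; fixed at its 0.5 default.
#' @param scale_x standardize predictor columns before fitting.
#' @return An object of class `SplsFit`: list with `selected` (integer indices
#'   of predictors with nonzero coefficients), `beta` (p x q, original scale),
#'   `W` (direction vectors of the final refit, unit-norm columns), `eta`,
#'   `K`, `kappa`, and the centering/scaling constants.
#' @export
spls_fit <- function(X, Y, eta, K = 1L, kappa = 0.5, scale_x = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
  if (K < 1L) stop("K must be >= 1")
  n <- nrow(X)
  if (n < 3L || nrow(Y) != n) stop("need n >= 3 aligned rows in X and Y")
  p <- ncol(X); q <- ncol(Y)
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc)
  xs <- rep(1, p)
  if (scale_x) {
    xs <- apply(Xc, 2L, sd)
    if (any(xs == 0)) stop("constant predictor column(s); drop monomorphic SNPs first")
    Xc <- sweep(Xc, 2L, xs, "/")
  }
  Yc <- sweep(Y, 2L, yc)

  A <- integer(0)
  Y1 <- Yc
  for (k in seq_len(K)) {
    M <- crossprod(Xc, Y1)
    if (max(abs(M)) < 1e-12) break
    z <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
    thr <- eta * max(abs(z))
    cvec <- sign(z) * pmax(abs(z) - thr, 0)
    A <- sort(union(A, which(cvec != 0)))
    fit_k <- pls_nipals(Xc[, A, drop = FALSE], Yc, min(k, length(A)))
    Y1 <- Yc - Xc[, A, drop = FALSE] %*% fit_k$beta
  }
  beta <- matrix(0, p, q, dimnames = list(colnames(X), colnames(Y)))
  W_full <- matrix(0, p, 1L)
  if (length(A)) {
    fit <- pls_nipals(Xc[, A, drop = FALSE], Yc, min(K, length(A)))
    beta_scaled <- fit$beta / xs[A]          # undo predictor scaling
    beta[A, ] <- beta_scaled
    W_full <- matrix(0, p, ncol(fit$W))
    W_full[A, ] <- fit$W
  }
  structure(list(selected = A, beta = beta, W = W_full, eta = eta, K = K,
                 kappa = kappa, x_center = xc, x_scale = xs, y_center = yc),
            class = "SplsFit")
}

#' Predict from an SPLS fit
#' @param object an `SplsFit`.
#' @param newdata n x p matrix on the original predictor scale.
#' @param ... unused.
#' @return n x q matrix of fitted responses.
#' @export
predict.SplsFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$x_center) %*% object$beta +
    matrix(object$y_center, nrow(newdata), length(object$y_center), byrow = TRUE)
}

#' Tune SPLS sparsity and components by cross-validation
#'
#' Minimizes the k-fold cross-validated mean squared prediction error summed
#' over responses, over a grid of `eta` and `K`. Ties are broken toward larger
#' `eta` and then smaller `K` (the sparser model).
#'
#' @inheritParams spls_fit
#' @param eta_grid candidate sparsity values (default 0.1 ... 0.9).
#' @param K_grid candidate component counts (default 1 ... 5).
#' @param folds number of folds (default 5); must not exceed n.
#' @param seed integer seed for the fold assignment.
#' @return list with `eta`, `K`, and the full `cv` results data.frame.
#' @export
tune_spls <- function(X, Y, eta_grid = seq(0.1, 0.9, by = 0.1), K_grid = 1:5,
                      folds = 5L, seed = 1L, scale_x = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds > n) stop("folds exceeds the number of samples")
  if (folds < 2L) stop("need at least 2 folds")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  grid <- expand.grid(eta = eta_grid, K = K_grid)
  cv_err <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (sum(tr) < 3L) return(Inf)
      fit <- tryCatch(
        spls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                 eta = grid$eta[g], K = grid$K[g], scale_x = scale_x),
        error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      errs <- errs + sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
    errs / n
  }, numeric(1L))
  grid$cv_mse <- cv_err
  ord <- order(grid$cv_mse, -grid$eta, grid$K)
  best <- grid[ord[1L], ]
  list(eta = best$eta, K = best$K, cv = grid)
}
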