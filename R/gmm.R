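# seeded k-means++ center selection
kmeanspp_centers <- function(X, G) {
  n <- nrow(X)
  centers <- matrix(NA_real_, G, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq_len(G - 1L) + 1L) {
    pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[k, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

# VEV M-step for the covariances: given per-component scatter matrices W_k
# and sizes n_k, estimate Sigma_k = lambda_k * D_k %*% diag(A) %*% t(D_k)
# with shared det-1 diagonal shape A. D_k are the eigenvectors of W_k; the
# paired (lambda_k, A) are obtained by alternating closed-form updates.
vev_covariances <- function(W, n_k, d, floor_eps, A_start = NULL) {
  G <- length(W)
  eig <- lapply(W, function(w) eigen(w, symmetric = TRUE))
  omega <- lapply(eig, function(e) pmax(e$values, floor_eps))
  D <- lapply(eig, function(e) e$vectors)
  A <- if (is.null(A_start)) rep(1, d) else A_start
  for (it in seq_len(50L)) {
    lambda <- vapply(seq_len(G), function(k)
      sum(omega[[k]] / A) / (n_k[k] * d), numeric(1))
    lambda <- pmax(lambda, floor_eps)
    A_raw <- Reduce(`+`, lapply(seq_len(G), function(k) omega[[k]] / lambda[k]))
    A_raw <- pmax(A_raw, floor_eps)
    A_new <- A_raw / exp(mean(log(A_raw)))   # det(diag(A)) = 1
    if (max(abs(A_new - A)) < 1e-10) { A <- A_new; break }
    A <- A_new
  }
  lambda <- vapply(seq_len(G), function(k)
    sum(omega[[k]] / A) / (n_k[k] * d), numeric(1))
  lambda <- pmax(lambda, floor_eps)
  list(lambda = lambda, A = A, D = D)
}

# component log-densities, n x G
gmm_logdens <- function(X, mean, lambda, A, D) {
  n <- nrow(X); d <- ncol(X); G <- ncol(mean)
  out <- matrix(NA_real_, n, G)
  for (k in seq_len(G)) {
    Xc <- sweep(X, 2L, mean[, k])
    rot <- Xc %*% D[[k]]
    mahal <- rowSums(sweep(rot^2, 2L, lambda[k] * A, `/`))
    logdet <- d * log(lambda[k]) + sum(log(A))
    out[, k] <- -0.5 * (d * log(2 * pi) + logdet + mahal)
  }
  out
}

#' Fit a VEV-constrained Gaussian mixture by EM
#'
#' Fits a `G`-component multivariate Gaussian mixture whose covariances share
#' the ellipsoidal VEV parameterization `Sigma_k = lambda_k D_k A t(D_k)`:
#' variable volume (`lambda_k`), equal shape (a shared diagonal `A` with
#' determinant 1) and variable orientation (orthogonal `D_k`). This is the
#' covariance family used to cluster temporal 24-nt siRNA profiles of TEs.
#'
#' Initialization is k-means++ with `n_init` seeded restarts, keeping the fit
#' with the best final log-likelihood. Component eigenvalues are floored at
#' `1e-8` times the mean column variance for stability; components that lose
#' (nearly) all responsibility are re-initialized from a random observation.
#'
#' @param X numeric matrix, rows = observations (TEs), columns = samples.
#' @param G number of mixture components (>= 1).
#' @param seed integer seed controlling initialization.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param n_init number of k-means++ restarts.
#' @return an object of class `gmm_vev`: component weights `pi`, means
#'   (`d x G`), `lambda`, shared shape `A`, orientations `D`, responsibility
#'   matrix `z`, hard `classification`, `loglik`, the per-iteration
#'   `loglik_trace`, free-parameter count `df` and `bic` (the mclust sign
#'   convention, `2*loglik - df*log(n)`; larger is better).
#' @export
fit_gmm_vev <- function(X, G, seed = 1L, max_iter = 200L, tol = 1e-6,
                        n_init = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (G < 1L) stop("G must be >= 1")
  if (n <= G) stop("need more observations than components")
  if (d < 1L) stop("X must have at least one column")
  floor_eps <- 1e-8 * mean(apply(X, 2L, stats::var)) + 1e-300
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- tryCatch(
      gmm_vev_em(X, G, floor_eps, max_iter, tol),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("all EM initializations failed for G = ", G)
  df <- gmm_vev_df(G, d)
  best$df <- df
  best$bic <- 2 * best$loglik - df * log(n)
  best$G <- G
  class(best) <- "gmm_vev"
  best
}

# free parameters of the VEV model:
# mixing proportions + means + volumes + shared shape + orientations
gmm_vev_df <- function(G, d) {
  (G - 1) + G * d + G + (d - 1) + G * d * (d - 1) / 2
}

gmm_vev_em <- function(X, G, floor_eps, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  centers <- kmeanspp_centers(X, G)
  d2 <- vapply(seq_len(G), function(k)
    rowSums(sweep(X, 2L, centers[k, ])^2), numeric(n))
  assign0 <- max.col(-matrix(d2, nrow = n))
  z <- matrix(1e-10, n, G)
  z[cbind(seq_len(n), assign0)] <- 1
  z <- z / rowSums(z)

  A <- NULL
  loglik_trace <- numeric(0)
  loglik <- -Inf
  n_reinit <- 0L
  reinit_iters <- integer(0)
  for (iter in seq_len(max_iter)) {
    # M-step
    n_k <- colSums(z)
    dead <- which(n_k < max(2, d / 2))
    if (length(dead)) reinit_iters <- c(reinit_iters, iter)
    for (k in dead) {
      # re-seed a starved component from a random observation
      z[, k] <- 1e-8
      z[sample.int(n, 1L), k] <- 1
      n_reinit <- n_reinit + 1L
    }
    if (length(dead)) { z <- z / rowSums(z); n_k <- colSums(z) }
    pi_k <- n_k / n
    mu <- vapply(seq_len(G), function(k)
      colSums(X * z[, k]) / n_k[k], numeric(d))
    mu <- matrix(mu, nrow = d)
    W <- lapply(seq_len(G), function(k) {
      Xc <- sweep(X, 2L, mu[, k])
      crossprod(Xc * sqrt(z[, k]))
    })
    cov <- vev_covariances(W, n_k, d, floor_eps, A_start = A)
    A <- cov$A

    # E-step
    ld <- gmm_logdens(X, mu, cov$lambda, A, cov$D)
    lw <- sweep(ld, 2L, log(pi_k), `+`)
    m <- apply(lw, 1L, max)
    lse <- m + log(rowSums(exp(lw - m)))
    new_loglik <- sum(lse)
    z <- exp(lw - lse)
    loglik_trace <- c(loglik_trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  list(pi = pi_k, mean = mu, lambda = cov$lambda, A = A, D = cov$D,
       z = z, classification = max.col(z), loglik = loglik,
       loglik_trace = loglik_trace, n_reinit = n_reinit,
       reinit_iters = reinit_iters)
}

#' @export
print.gmm_vev <- function(x, ...) {
  cat("VEV Gaussian mixture: G =", x$G, " loglik =", format(x$loglik),
      " BIC =", format(x$bic), "\n")
  invisible(x)
}

#' Select the mixture size by BIC over a component grid
#'
#' Fits [fit_gmm_vev()] for every `G` in the grid (default 2 to 20 in
#' increments of two) and returns the model at the smallest `G` achieving the
#' maximum BIC (larger-is-better convention), together with the full BIC
#' table.
#'
#' @param X numeric matrix (observations x samples).
#' @param G_grid integer vector of component counts.
#' @param seed integer seed.
#' @param ... passed to [fit_gmm_vev()].
#' @return the selected `gmm_vev` model with a `bic_table` attribute
#'   (data.frame: G, loglik, df, bic, error).
#' @export
select_model_bic <- function(X, G_grid = seq(2L, 20L, by = 2L), seed = 1L,
                             ...) {
  G_grid <- sort(unique(as.integer(G_grid)))
  fits <- vector("list", length(G_grid))
  errs <- rep(NA_character_, length(G_grid))
  for (i in seq_along(G_grid)) {
    fits[[i]] <- tryCatch(
      fit_gmm_vev(X, G_grid[i], seed = seed + G_grid[i], ...),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  bic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                numeric(1))
  tab <- data.frame(G = G_grid,
                    loglik = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
                    df = vapply(fits, function(f)
                      if (is.null(f)) NA_real_ else f$df, numeric(1)),
                    bic = bic, error = errs, stringsAsFactors = FALSE)
  if (all(is.na(bic)))
    stop("all GMM fits failed:\n",
         paste(sprintf("  G=%d: %s", G_grid, errs), collapse = "\n"))
  best <- fits[[which.max(bic)]]   # first max = smallest G on a tie
  attr(best, "bic_table") <- tab
  best
}
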