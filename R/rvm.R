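# Relevance vector machine for probabilistic binary classification, written
# from scratch in the sparse Bayesian (automatic relevance determination)
# formulation: a Laplace-approximation logistic fit alternating with
# evidence-based re-estimation of the per-weight precisions alpha, pruning
# basis functions whose alpha diverges.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# solve(H, g) with escalating diagonal jitter relative to the largest
# diagonal entry (the Hessian mixes wildly different feature scales)
.solve_safe <- function(H, g) {
  scale <- max(diag(H), 1e-300)
  jit <- 0
  repeat {
    Hj <- H
    if (jit > 0) diag(Hj) <- diag(Hj) + jit * scale
    out <- tryCatch(solve(Hj, g), error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
    jit <- if (jit == 0) 1e-10 else jit * 100
    if (jit > 1e-2) stop("Hessian irreparably singular")
  }
}

.inv_safe <- function(H) {
  scale <- max(diag(H), 1e-300)
  jit <- 0
  repeat {
    Hj <- H
    if (jit > 0) diag(Hj) <- diag(Hj) + jit * scale
    out <- tryCatch(chol2inv(chol(Hj)), error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
    jit <- if (jit == 0) 1e-10 else jit * 100
    if (jit > 1e-2) stop("Hessian irreparably singular")
  }
}

.kernel_hi <- function(X, B) {
  # histogram intersection: K[i, j] = sum_d min(X[i, d], B[j, d])
  if (any(X < 0) || any(B < 0))
    stop("histogram intersection kernel requires nonnegative histogram features")
  K <- matrix(0, nrow(X), nrow(B))
  tX <- t(X)
  for (j in seq_len(nrow(B))) K[, j] <- colSums(pmin(tX, B[j, ]))
  K
}

.rvm_design <- function(X, kernel, basis) {
  switch(kernel,
         linear = cbind(1, X),
         histogram_intersection = cbind(1, .kernel_hi(X, basis)),
         stop("unknown kernel: ", kernel))
}

#' Fit a relevance vector machine classifier
#'
#' Sparse Bayesian logistic classification: each basis-function weight gets
#' an independent Gaussian prior with precision `alpha_m`; the posterior mode
#' is found by iteratively reweighted least squares (a Laplace
#' approximation), and the `alpha_m` are re-estimated sequentially — one
#' basis function per outer iteration, round-robin — by maximizing the
#' marginal likelihood analytically in that `alpha_m` (the s/q sparsity
#' statistics of Tipping & Faul), which sets
#' `alpha_m = s_m^2 / (q_m^2 - s_m)` when `q_m^2 > s_m` and prunes the
#' basis function otherwise; basis functions whose precision exceeds
#' `prune_alpha` are likewise pruned. The
#' bias term carries a flat prior (its precision is fixed at zero and it is
#' never pruned), so the decision boundary is not shrunk toward the origin.
#' The surviving basis functions are the relevance vectors. The fit is
#' deterministic: initialization is fixed, no random numbers are drawn.
#'
#' With `kernel = "linear"` the basis is the raw feature columns (plus bias)
#' and the model is a sparse probabilistic linear classifier; with
#' `kernel = "histogram_intersection"` the basis is the histogram
#' intersection similarity to each training point (features must be
#' nonnegative histograms — after a PCA projection they no longer are, and
#' the kernel refuses them).
#'
#' @param x numeric matrix of training features (rows = examples).
#' @param y labels: logical, 0/1 numeric, or a 2-level factor (second level
#'   = positive class).
#' @param kernel `"linear"` or `"histogram_intersection"`.
#' @param max_iter maximum outer alpha re-estimation iterations.
#' @param tol convergence tolerance on `max |delta log alpha|`.
#' @param alpha_init initial weight-precision.
#' @param prune_alpha precision above which a basis function is pruned.
#' @return an object of class `rvm` with components `weights` (named, bias
#'   first), `alpha`, `relevance_vectors` (matrix of retained training
#'   points, `NULL` for linear kernel), `rv_index`, `kernel`, `converged`,
#'   `iterations`, `n_basis_initial`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 1), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c(0, 1), each = 20)
#' fit <- rvm(x, y, kernel = "linear")
#' predict(fit, x)[c(1, 40)]
#' @export
rvm <- function(x, y, kernel = c("linear", "histogram_intersection"),
                max_iter = 2000, tol = 1e-4, alpha_init = 1e-2,
                prune_alpha = 1e9) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1, logical or 2-level factor)")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (any(!is.finite(x))) stop("features must be finite")
  if (table(y)[1] < 2 || table(y)[2] < 2)
    stop("need at least 2 examples per class")

  basis <- if (kernel == "histogram_intersection") x else NULL
  Phi_full <- .rvm_design(x, kernel, basis)
  M <- ncol(Phi_full)
  # the bias carries a flat prior: alpha fixed at 0, never re-estimated and
  # never pruned, so the decision boundary is not shrunk toward the origin
  alpha <- rep(alpha_init, M)
  alpha[1] <- 0
  w <- numeric(M)
  active <- rep(TRUE, M)
  converged <- FALSE
  it <- 0
  cursor <- 0L   # round-robin position among non-bias basis functions
  stable <- 0L   # consecutive sub-tolerance coordinate updates

  for (it in seq_len(max_iter)) {
    idx <- which(active)
    Phi <- Phi_full[, idx, drop = FALSE]
    A <- alpha[idx]
    wa <- w[idx]
    # inner IRLS / Newton for the posterior mode
    for (inner in seq_len(50)) {
      z <- drop(Phi %*% wa)
      p <- .sigmoid(z)
      g <- drop(crossprod(Phi, y - p)) - A * wa
      B <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(Phi * B, Phi)
      diag(H) <- diag(H) + A
      step <- .solve_safe(H, g)
      obj0 <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))) -
        0.5 * sum(A * wa * wa)
      lam <- 1
      repeat {
        wn <- wa + lam * step
        pn <- .sigmoid(drop(Phi %*% wn))
        objn <- sum(y * log(pmax(pn, 1e-300)) + (1 - y) * log(pmax(1 - pn, 1e-300))) -
          0.5 * sum(A * wn * wn)
        if (objn >= obj0 - 1e-12 || lam < 1e-6) break
        lam <- lam / 2
      }
      moved <- max(abs(wn - wa))
      wa <- wn
      if (moved < 1e-8) break
    }
    # posterior covariance at the mode
    p <- .sigmoid(drop(Phi %*% wa))
    B <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Phi * B, Phi)
    diag(H) <- diag(H) + A
    Sg <- .inv_safe(H)
    # sequential analytic evidence update (Tipping & Faul s/q sparsity
    # statistics): the marginal likelihood, maximized over a single
    # alpha_m with all others fixed, peaks at s_m^2 / (q_m^2 - s_m) when
    # q_m^2 > s_m and at infinity (prune) otherwise. Exactly one basis
    # function is updated per outer iteration, round-robin — the
    # statistics are conditional on the rest of the model, so a
    # simultaneous update is invalid (and deletes everything on
    # correlated kernel bases). The leave-one-out quantities come from a
    # rank-1 downdate of the posterior covariance, which stays accurate
    # even for small alpha, where the usual alpha*S/(alpha - S)
    # transformation cancels catastrophically.
    a_new <- A
    nb <- seq_along(A)[-1]
    delta <- 0
    if (length(nb)) {
      cursor <- cursor %% length(nb) + 1L
      m <- nb[cursor]
      Bt <- B * drop(Phi %*% wa) + (y - p)       # B * linearized targets
      U <- crossprod(Phi * B, Phi)               # likelihood Hessian part
      b <- drop(crossprod(Phi, Bt))
      u <- U[, m]; umm <- U[m, m]; smm <- Sg[m, m]
      Su <- drop(Sg %*% u)
      Sb <- drop(Sg %*% b)
      su_m <- Su[m]
      cross <- su_m - umm * smm
      s <- umm - (sum(u * Su) - 2 * umm * su_m + umm^2 * smm -
                    cross^2 / smm)
      crossb <- Sb[m] - b[m] * smm
      q <- b[m] - (sum(u * Sb) - umm * Sb[m] - b[m] * su_m +
                     umm * b[m] * smm - cross * crossb / smm)
      if (q * q > s && s > 1e-300) {
        a_new[m] <- s * s / (q * q - s)
        delta <- abs(log(pmax(a_new[m], 1e-300)) - log(pmax(A[m], 1e-300)))
      } else if (length(A) > 2L) {
        a_new[m] <- Inf
        delta <- Inf  # model changed: keep iterating
      }
      # converged once a full round-robin pass changes nothing
      stable <- if (delta < tol) stable + 1L else 0L
    }
    w[] <- 0; w[idx] <- wa
    alpha[idx] <- a_new
    # prune diverged basis functions; keep the bias term always
    active <- alpha < prune_alpha
    active[1] <- TRUE
    w[!active] <- 0
    # pruning shifts the remaining positions left one slot: step the
    # cursor back so the round-robin order skips nothing
    if (!is.finite(delta)) cursor <- cursor - 1L
    if (length(nb) == 0 || stable >= length(nb)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("rvm did not converge within max_iter; returning the current model")

  idx <- which(active)
  rv_index <- idx[idx > 1] - 1L  # training-point indices for kernel basis
  structure(list(
    kernel = kernel,
    weights = setNames(w[idx], c("(bias)", paste0("b", idx[-1] - 1))[seq_along(idx)]),
    basis_index = idx,
    alpha = alpha[idx],
    relevance_vectors = if (kernel == "histogram_intersection")
      x[rv_index, , drop = FALSE] else NULL,
    rv_index = rv_index,
    n_basis_initial = M,
    n_features = ncol(x),
    converged = converged,
    iterations = it,
    call = match.call()
  ), class = "rvm")
}

#' @export
print.rvm <- function(x, ...) {
  cat(sprintf("Relevance vector machine (%s kernel)\n", x$kernel))
  cat(sprintf("  %d of %d basis functions retained (%d relevance vectors)%s\n",
              length(x$weights), x$n_basis_initial, length(x$rv_index),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
summary.rvm <- function(object, ...) {
  print(object)
  cat(sprintf("  iterations: %d\n", object$iterations))
  cat("  weights:\n")
  print(object$weights)
  invisible(object)
}

#' @export
coef.rvm <- function(object, ...) object$weights

#' Posterior class probabilities from an RVM
#'
#' @param object an [rvm()] fit.
#' @param newdata feature matrix (or vector for a single example).
#' @param type `"response"` for probabilities (strictly inside (0,1)),
#'   `"link"` for the latent score.
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict.rvm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$n_features, ncol(X)))
  z <- if (object$kernel == "linear") {
    wfull <- numeric(object$n_features + 1)
    wfull[object$basis_index] <- object$weights
    drop(cbind(1, X) %*% wfull)
  } else {
    K <- if (length(object$rv_index))
      .kernel_hi(X, object$relevance_vectors) else matrix(0, nrow(X), 0)
    drop(cbind(1, K) %*% object$weights)
  }
  if (type == "link") return(z)
  pmin(1 - 1e-12, pmax(1e-12, .sigmoid(z)))
}
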