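# Firth-penalized logistic regression: maximize the Jeffreys-prior
# penalized log-likelihood l(beta) + 0.5 * log det I(beta) by Newton
# iterations on the modified score
#   U*_j = sum_i (y_i - pi_i + h_i (1/2 - pi_i)) x_ij ,
# h_i the diagonal of the weighted hat matrix. Estimates stay finite under
# complete separation, which is the whole point for tiny cohorts.

firth_penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  w <- pi * (1 - pi)
  info <- crossprod(X, X * w)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

#' Fit a Firth-penalized logistic regression
#'
#' @param x numeric matrix, samples x features (no intercept column unless
#'   `add_intercept = FALSE`).
#' @param y binary response (0/1), at least one sample per class.
#' @param add_intercept prepend an intercept column (default TRUE).
#' @param max_iter Newton iteration cap (default 100).
#' @param tol convergence tolerance on the modified score (default 1e-8).
#' @return a `firth_model`: list with `coefficients` (intercept first),
#'   `converged`, `n_iter`, `hat_diagonals`.
#' @export
firth_fit <- function(x, y, add_intercept = TRUE, max_iter = 100,
                      tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("response needs both classes")
  if (!all(y %in% c(0, 1))) stopf("response must be binary 0/1")
  X <- if (add_intercept) cbind(`(Intercept)` = 1, x) else x
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(dep, collapse = ", "))
  }
  p <- ncol(X); n <- nrow(X)
  beta <- rep(0, p)
  ll_old <- firth_penalized_loglik(X, y, beta)
  converged <- FALSE
  iter <- 0
  h <- rep(0, n)
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    w <- pmax(pi * (1 - pi), 1e-12)
    info <- crossprod(X, X * w)
    # hat diagonals of W^1/2 X (X'WX)^-1 X' W^1/2
    XW <- X * sqrt(w)
    h <- rowSums((XW %*% solve(info)) * XW)
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- solve(info, score)
    # step-halving on the penalized likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- firth_penalized_loglik(X, y, cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    beta <- beta + lam * step
    ll_old <- firth_penalized_loglik(X, y, beta)
    if (iter >= max_iter) break
  }
  structure(list(coefficients = setNames(beta, colnames(X)),
                 converged = converged, n_iter = iter,
                 hat_diagonals = h),
            class = "firth_model")
}

#' Predict probabilities from a Firth model
#' @param object a `firth_model`.
#' @param newdata samples x features matrix (same features as the fit,
#'   without intercept).
#' @param ... unused.
#' @return predicted probabilities.
#' @export
predict.firth_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  plogis(drop(X %*% object$coefficients))
}
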