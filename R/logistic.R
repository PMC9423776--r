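## Ridge-penalized logistic regression by damped Newton (IRLS) iterations.
##
## Minimizes the normalized negative log likelihood
##   NNLL(beta) = (1/n) sum_i [ -y_i eta_i + log(1 + exp(eta_i)) ],
##   eta = beta0 + X beta,
## plus lambda * ||beta||^2 (intercept excluded unless penalizeIntercept).
## The penalty is added to the per-sample-normalized NNLL, so lambda = 1
## means exactly that convention. X may be a dense matrix or a sparse
## Matrix (spike-history designs are ~1% dense, which makes the Newton
## cross-products cheap).

nnllValue <- function(eta, y) {
  mean(-y * eta + log1pexp(eta))
}

## sigmoid and log(1 + exp(eta)) from one exp(-|eta|) pass
logisticParts <- function(eta) {
  z <- exp(-abs(eta))
  mu <- 1 / (1 + z)
  neg <- eta < 0
  mu[neg] <- 1 - mu[neg]
  list(mu = mu, l1pe = pmax(eta, 0) + log1p(z))
}

## X' diag(w) X and X' w without materializing diag(w)
weightedCross <- function(X, w) {
  if (inherits(X, "dgCMatrix")) {
    Xw <- X
    Xw@x <- X@x * w[X@i + 1L]
    list(
      Hxx = as.matrix(Matrix::crossprod(X, Xw)),
      hx0 = as.numeric(Matrix::colSums(Xw))
    )
  } else if (inherits(X, "Matrix")) {
    Xw <- Matrix::Diagonal(x = w) %*% X
    list(
      Hxx = as.matrix(Matrix::crossprod(X, Xw)),
      hx0 = as.numeric(Matrix::colSums(Xw))
    )
  } else {
    Xw <- X * w
    list(Hxx = crossprod(X, Xw), hx0 = colSums(Xw))
  }
}

ridgeLogistic <- function(X, y, lambda = 0, penalizeIntercept = FALSE,
                          tol = 1e-8, maxit = 200L) {
  n <- length(y)
  if (n == 0L) stop("empty design")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match target length")
  if (lambda == 0 && (all(y == 0) || all(y == 1))) {
    stop("targets are all ", y[1],
         "; the unpenalized logistic MLE is degenerate")
  }
  sparse <- inherits(X, "Matrix")
  ## rescale columns to unit scale for unpenalized fits (Newton conditioning
  ## when regressor scales differ wildly); no centering, so sparsity and the
  ## model itself are unchanged -- coefficients are mapped back at the end.
  ## Penalized fits are NOT rescaled: lambda applies to the raw coefficients.
  colScale <- rep(1, p)
  if (lambda == 0 && p > 0L) {
    cs <- if (sparse) {
      sqrt(Matrix::colSums(X^2) / n)
    } else {
      sqrt(colSums(X^2) / n)
    }
    colScale <- ifelse(cs > 0, cs, 1)
    X <- if (sparse) {
      X %*% Matrix::Diagonal(x = 1 / colScale)
    } else {
      sweep(X, 2L, colScale, "/")
    }
  }
  penMask <- c(if (penalizeIntercept) 1 else 0, rep(1, p))
  beta <- numeric(p + 1L)
  etaOf <- function(b) {
    if (p > 0L) as.numeric(X %*% b[-1L]) + b[1L] else rep(b[1L], n)
  }
  eta <- etaOf(beta)
  parts <- logisticParts(eta)
  obj <- mean(-y * eta + parts$l1pe) + lambda * sum(penMask * beta^2)
  gnorm <- Inf
  for (it in seq_len(maxit)) {
    mu <- parts$mu
    resid <- mu - y
    grad <- c(
      mean(resid),
      if (p > 0L) as.numeric(Matrix::crossprod(X, resid)) / n
    ) + 2 * lambda * penMask * beta
    gnorm <- max(abs(grad))
    if (gnorm < tol) break
    w <- mu * (1 - mu)
    if (p > 0L) {
      wc <- weightedCross(X, w)
      H <- rbind(
        c(mean(w), wc$hx0 / n),
        cbind(wc$hx0 / n, wc$Hxx / n)
      )
    } else {
      H <- matrix(mean(w), 1L, 1L)
    }
    diag(H) <- diag(H) + 2 * lambda * penMask + 1e-12
    step <- tryCatch(
      solve(H, -grad),
      error = function(e) -grad  # gradient fallback on singular Hessian
    )
    ## damped Newton: halve until the objective does not increase
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      etaC <- etaOf(cand)
      partsC <- logisticParts(etaC)
      objC <- mean(-y * etaC + partsC$l1pe) +
        lambda * sum(penMask * cand^2)
      if (is.finite(objC) && objC <= obj + 1e-14) {
        beta <- cand
        eta <- etaC
        parts <- partsC
        obj <- objC
        ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  ## complete separation: every outcome perfectly classified means the
  ## unpenalized MLE does not exist -- refuse rather than return a runaway fit
  if (lambda == 0) {
    mu <- parts$mu
    if (all(mu[y == 1] > 1 - 1e-4) && all(mu[y == 0] < 1e-4)) {
      stop("complete separation: the unpenalized logistic MLE is unbounded; ",
           "consider an L2 penalty")
    }
  }
  beta[-1L] <- beta[-1L] / colScale
  list(
    coefficients = unname(beta), nnll = nnllValue(eta, y),
    converged = gnorm < tol, gradientNorm = gnorm, iterations = it
  )
}
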