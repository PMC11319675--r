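## Phylogenetic linear regression under a Pagel's-lambda covariance model.
##
## y = X beta + e, e ~ N(0, sigma^2 * V_lambda) where V_lambda is the
## Brownian covariance of the tree with off-diagonals multiplied by lambda.
## (beta, sigma^2, lambda) are estimated by maximum likelihood: for fixed
## lambda the GLS solution is closed-form, and lambda is profiled over
## [0, 1] on a 0.01 grid followed by bounded refinement. Coefficient
## p-values come from Wald t-statistics (df = n - p) and from a parametric
## bootstrap of B refits from the fitted model.

#' Phylogenetic linear regression with a lambda covariance model
#'
#' @param formula model formula (response on the observed count/continuous
#'   scale; estimates are reported on that same scale).
#' @param data data.frame, one row per tip; matched to the tree by rownames
#'   or a `genome_id` column.
#' @param tree a `phylo` object with branch lengths.
#' @param B parametric bootstrap replicates (default 100; 0 skips).
#' @param seed integer seed for the bootstrap.
#' @param lambda optional fixed lambda in `[0, 1]`; when `NULL` (default)
#'   lambda is estimated by profile ML.
#' @return an object of class `phylolm_lambda`.
#' @export
phylolm_lambda <- function(formula, data, tree, B = 100L, seed = 1L,
                           lambda = NULL) {
  validate_tree(tree, require_lengths = TRUE)
  data <- align_to_tips(data, tree)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (n <= ncol(X)) stopf("need more tips than coefficients (n = %d, p = %d)", n, ncol(X))
  if (qr(X)$rank < ncol(X)) stopf("singular design matrix")
  V <- ape::vcv.phylo(tree)[rownames(data), rownames(data)]

  fit_at <- function(lam) gls_lambda_fit(y, X, V, lam)

  if (is.null(lambda)) {
    grid <- seq(0, 1, by = 0.01)
    ll <- vapply(grid, function(l) fit_at(l)$loglik, 0)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(l) fit_at(l)$loglik,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    lambda_hat <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  } else {
    if (lambda < 0 || lambda > 1) stopf("lambda must lie in [0, 1]")
    lambda_hat <- lambda
  }
  fit <- fit_at(lambda_hat)
  if (!is.finite(fit$loglik)) stopf("non-finite likelihood at lambda = %g", lambda_hat)

  p_dim <- ncol(X)
  sigma2_unbiased <- fit$rss / (n - p_dim)
  vc <- sigma2_unbiased * fit$XtViX_inv
  se <- sqrt(diag(vc))
  tstat <- fit$beta / se
  p_wald <- 2 * stats::pt(-abs(tstat), df = n - p_dim)

  boot <- NULL; p_boot <- rep(NA_real_, p_dim)
  if (B > 0L) {
    Vl <- lambda_transform(V, lambda_hat)
    ch <- chol(fit$sigma2 * Vl)
    mu <- drop(X %*% fit$beta)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    boot <- matrix(NA_real_, nrow = B, ncol = p_dim,
                   dimnames = list(NULL, colnames(X)))
    boot_lambda <- rep(NA_real_, B)
    ## lambda re-profiled on a 0.05 grid in refits; the Cholesky factor of
    ## each grid V_lambda is fixed across replicates, so cache them
    coarse <- seq(0, 1, by = 0.05)
    cache <- lapply(coarse, function(l) {
      chl <- tryCatch(chol(lambda_transform(V, l)), error = function(e) NULL)
      if (is.null(chl)) return(NULL)
      Xw <- backsolve(chl, X, transpose = TRUE)
      list(ch = chl, Xw = Xw, qr_x = qr(Xw), logdet = sum(log(diag(chl))))
    })
    ok_grid <- !vapply(cache, is.null, logical(1L))
    for (b in seq_len(B)) {
      ystar <- mu + drop(crossprod(ch, stats::rnorm(n)))
      best <- NULL; best_ll <- -Inf; best_l <- NA_real_
      for (gi in which(ok_grid)) {
        cc <- cache[[gi]]
        yw <- backsolve(cc$ch, ystar, transpose = TRUE)
        bb <- qr.coef(cc$qr_x, yw)
        rss <- sum((yw - cc$Xw %*% bb)^2)
        llb <- -n / 2 * log(2 * pi * rss / n) - cc$logdet - n / 2
        if (llb > best_ll) { best_ll <- llb; best <- drop(bb); best_l <- coarse[gi] }
      }
      boot[b, ] <- best
      boot_lambda[b] <- best_l
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    p_boot <- vapply(seq_len(p_dim), function(r) {
      bs <- boot[!is.na(boot[, r]), r]
      (1 + sum(abs(bs - fit$beta[r]) >= abs(fit$beta[r]))) / (length(bs) + 1)
    }, 0)
  }

  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    lambda = lambda_hat,
    sigma2 = fit$sigma2,
    loglik = fit$loglik,
    p_wald = stats::setNames(p_wald, colnames(X)),
    p_boot = stats::setNames(p_boot, colnames(X)),
    bootstrap_replicates = boot,
    B = as.integer(B),
    vcov = vc,
    fitted = drop(X %*% fit$beta),
    y = y, X = X,
    n = n,
    df_residual = n - p_dim,
    converged = TRUE,
    formula = formula,
    call = match.call()
  ), class = "phylolm_lambda")
}

## Closed-form GLS at fixed lambda; ML sigma^2 (rss/n).
gls_lambda_fit <- function(y, X, V, lam) {
  Vl <- lambda_transform(V, lam)
  ch <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(ch))
    return(list(beta = rep(NA_real_, ncol(X)), sigma2 = NA_real_,
                loglik = -Inf, rss = NA_real_, XtViX_inv = NULL))
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  n <- length(y)
  sigma2 <- rss / n
  loglik <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(ch))) - n / 2
  XtViX_inv <- chol2inv(qr.R(qr_x))
  list(beta = drop(beta), sigma2 = sigma2, loglik = loglik, rss = rss,
       XtViX_inv = XtViX_inv)
}

#' @export
print.phylolm_lambda <- function(x, ...) {
  cat("Phylogenetic linear regression (lambda covariance model)\n")
  cat(sprintf("  n = %d tips, lambda = %.4f, sigma2 = %.4g\n",
              x$n, x$lambda, x$sigma2))
  print(round(rbind(estimate = x$coefficients, se = x$se,
                    p_wald = x$p_wald, p_boot = x$p_boot), 4))
  invisible(x)
}

#' @export
summary.phylolm_lambda <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    t = object$coefficients / object$se,
    p_wald = object$p_wald,
    p_boot = object$p_boot
  )
  out <- list(coefficients = tab, lambda = object$lambda,
              sigma2 = object$sigma2, loglik = object$loglik, n = object$n,
              B = object$B, call = object$call)
  class(out) <- "summary.phylolm_lambda"
  out
}

#' @export
print.summary.phylolm_lambda <- function(x, ...) {
  cat("Phylogenetic linear regression (lambda covariance model)\n")
  cat("Call: "); print(x$call)
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("lambda = %.4f; sigma2 = %.4g; logLik = %.4f; n = %d; B = %d\n",
              x$lambda, x$sigma2, x$loglik, x$n, x$B))
  invisible(x)
}

#' @export
coef.phylolm_lambda <- function(object, ...) object$coefficients

#' @export
vcov.phylolm_lambda <- function(object, ...) object$vcov

#' @export
residuals.phylolm_lambda <- function(object, ...) object$y - object$fitted

#' @export
fitted.phylolm_lambda <- function(object, ...) object$fitted

#' Simulate responses from a fitted lambda-covariance model
#'
#' @param object a `phylolm_lambda` fit.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param tree the tree used in fitting.
#' @param ... unused.
#' @return matrix `n x nsim`.
#' @export
simulate.phylolm_lambda <- function(object, nsim = 1, seed = NULL, tree, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- ape::vcv.phylo(tree)
  ids <- rownames(object$X)
  V <- V[ids, ids]
  ch <- chol(object$sigma2 * lambda_transform(V, object$lambda))
  out <- replicate(nsim, object$fitted + drop(crossprod(ch, stats::rnorm(object$n))))
  matrix(out, nrow = object$n)
}
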