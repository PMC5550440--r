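#' Fit the polygenic null model
#'
#' Maximum-likelihood fit of `y = X b + g + e`, `g ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`, by profiling the likelihood over the variance
#' ratio `delta = sigma_g^2 / sigma_e^2` on the eigenbasis of `K` (a 1-D
#' optimization; `b` and `sigma_e^2` are profiled out analytically). The
#' returned object carries everything score tests need: the rotation `U`,
#' eigenvalues, per-sample inverse-variance weights and the rotated
#' phenotype/covariates.
#'
#' @param y numeric phenotype vector (no missing values), length >= 30 for a
#'   stable fit.
#' @param K kinship matrix (positive semi-definite; bent if not).
#' @param X covariate matrix (an intercept is added if absent); optional.
#' @param eig optionally, a precomputed `eigen(K, symmetric = TRUE)`.
#' @param tol tolerance of the 1-D optimization over `log(delta)`.
#' @return list of class `polygenic_fit`: `delta`, `h2`, `sigma_g2`,
#'   `sigma_e2`, `loglik`, `U`, `lambda`, `w` (weights `1/(delta*lambda+1)`),
#'   `ytilde`, `Xtilde`, `n`.
#' @export
polygenic_fit <- function(y, K = NULL, X = NULL, eig = NULL, tol = 1e-8) {
  n <- length(y)
  if (anyNA(y)) stopf("phenotype must be complete")
  if (is.null(eig)) {
    if (is.null(K)) stopf("either `K` or its eigendecomposition is required")
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < -1e-8) {
      warnf("kinship not PSD (min eigenvalue %.2e); bending", min(eig$values))
    }
    eig$values <- pmax(eig$values, 1e-6)
  }
  if (is.null(X)) X <- matrix(1, n, 1)
  if (!any(apply(X, 2L, function(col) stats::sd(col) == 0))) X <- cbind(1, X)
  U <- eig$vectors
  lambda <- eig$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  yt_v <- drop(yt)
  x1 <- if (ncol(Xt) == 1L) drop(Xt) else NULL
  nll <- function(log_delta) {
    v <- exp(log_delta) * lambda + 1
    w <- 1 / v
    if (!is.null(x1)) {  # intercept-only fast path
      rss <- sum(yt_v^2 * w) - sum(x1 * yt_v * w)^2 / sum(x1^2 * w)
    } else {
      A <- crossprod(Xt, Xt * w)
      b <- solve(A, crossprod(Xt, yt * w))
      r <- yt - Xt %*% b
      rss <- sum(r^2 * w)
    }
    0.5 * (n * log(rss / n) + sum(log(v)))
  }
  opt <- stats::optimize(nll, c(-12, 12), tol = tol)
  # non-identifiable / flat likelihoods (e.g. identity kinship) resolve to the
  # parsimonious end: sigma_g2 ~ 0
  if (nll(-12) <= opt$objective + 1e-7) opt <- list(minimum = -12, objective = nll(-12))
  # the lower boundary just means sigma_g2 ~ 0, a regular point; only an
  # exploding variance ratio deserves a warning
  if (opt$minimum > 11.5) {
    warnf("variance-ratio estimate at the search boundary (log delta = %.1f)", opt$minimum)
  }
  delta <- exp(opt$minimum)
  v <- delta * lambda + 1
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  b <- solve(A, crossprod(Xt, yt * w))
  r <- yt - Xt %*% b
  sigma_e2 <- sum(r^2 * w) / n
  structure(list(
    delta = delta, h2 = delta * mean(lambda) / (delta * mean(lambda) + 1),
    sigma_g2 = delta * sigma_e2, sigma_e2 = sigma_e2,
    loglik = -opt$objective - 0.5 * n * (1 + log(2 * pi)),
    U = U, lambda = lambda, w = w, ytilde = drop(yt), Xtilde = Xt, n = n
  ), class = "polygenic_fit")
}

# Vectorized kinship-corrected score test over a rotated marker matrix.
# Gt = U'G (n x M), Gt2 = Gt^2 elementwise. Optionally a replacement rotated
# phenotype (for permutations) and extra rotated covariates.
score_scan <- function(fit, Gt, Gt2 = NULL, ytilde = NULL, Xtilde = NULL) {
  w <- fit$w
  yt <- ytilde %||% fit$ytilde
  Xt <- Xtilde %||% fit$Xtilde
  if (is.null(Gt2)) Gt2 <- Gt * Gt
  A <- crossprod(Xt, Xt * w)
  Ainv <- solve(A)
  b <- Ainv %*% crossprod(Xt, yt * w)
  r <- yt - drop(Xt %*% b)
  rw <- r * w
  sigma2 <- sum(r * rw) / fit$n
  if (sigma2 < 1e-12 * max(sum(yt^2 * w) / fit$n, 1e-300)) {
    # covariates absorb the phenotype (numerically zero residual): nothing
    # left to test
    M <- ncol(Gt)
    return(list(stat = rep(0, M), p = rep(1, M), flagged = rep(TRUE, M)))
  }
  num <- drop(crossprod(Gt, rw))
  B <- crossprod(Xt * w, Gt)              # p x M
  gWg <- drop(crossprod(Gt2, w))
  den <- gWg - colSums(B * (Ainv %*% B))
  stat <- num^2 / (sigma2 * pmax(den, 0))
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  flagged <- !is.finite(stat) | den < 1e-10
  p[flagged] <- 1
  stat[flagged] <- 0
  list(stat = stat, p = p, flagged = flagged)
}

#' Kinship-corrected score test for one marker
#'
#' One-degree-of-freedom chi-square score test of a coded marker added to the
#' polygenic null model, on the whitened residuals of [polygenic_fit()]. A
#' marker monomorphic (or collinear with the covariates) is flagged and
#' returns p = 1.
#'
#' @param fit a [polygenic_fit()].
#' @param g numeric vector of coded genotype values (sample order of the fit).
#' @param X_extra optional additional covariates (unrotated).
#' @return list with `stat`, `p`, `flagged`.
#' @export
score_test <- function(fit, g, X_extra = NULL) {
  Gt <- crossprod(fit$U, matrix(as.numeric(g), ncol = 1))
  Xt <- fit$Xtilde
  if (!is.null(X_extra)) Xt <- cbind(Xt, crossprod(fit$U, as.matrix(X_extra)))
  res <- score_scan(fit, Gt, Xtilde = Xt)
  lapply(res, `[`, 1L)
}

#' Recode genotype calls under an inheritance model
#'
#' Codings on (hom-major, het, hom-minor): additive `(0, 1, 2)`; dominance
#' `(0, 0, 2)` (heterozygote grouped with the major homozygote); recessive
#' `(0, 2, 2)` (heterozygote grouped with the minor homozygote);
#' overdominance `(0, 1, 0)` (heterozygote against both homozygotes).
#'
#' @param calls integer matrix or vector of 0/1/2 calls.
#' @param model one of `"additive"`, `"dominance"`, `"recessive"`,
#'   `"overdominance"`.
#' @return numeric recoded object of the same shape.
#' @export
recode_model <- function(calls, model = c("additive", "dominance", "recessive",
                                          "overdominance")) {
  model <- match.arg(model)
  codes <- switch(model,
    additive      = c(0, 1, 2),
    dominance     = c(0, 0, 2),
    recessive     = c(0, 2, 2),
    overdominance = c(0, 1, 0)
  )
  out <- codes[calls + 1L]
  if (is.matrix(calls)) dim(out) <- dim(calls); dimnames(out) <- dimnames(calls)
  out
}
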