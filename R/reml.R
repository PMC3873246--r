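# Average-information REML for variance-component models
#   y = X b + sum_c g_c + e,  g_c ~ N(0, sigma2_c A_c),  e ~ N(0, sigma2_e I)
#
# The restricted log-likelihood is maximized by AI quasi-Newton steps with a
# single EM-REML step as fallback whenever the AI step leaves the feasible
# region; the inverse of the final AI matrix provides the asymptotic
# covariance of the variance-component estimates, and the delta method
# converts it to standard errors on the heritability ratios.
#
# Single-GRM fits take a spectral path (eigendecomposition of the GRM
# restricted to the orthocomplement of the fixed effects), which makes each
# iteration O(n); the dense path handles any number of components. Both
# paths compute the identical restricted likelihood (the dense path includes
# the log|X'X| term so the two agree to machine precision).

#' Fit variance components by AI-REML
#'
#' Estimates \eqn{\sigma^2_c} for each genetic relatedness matrix plus a
#' residual component, with fixed effects projected out of the likelihood
#' (REML). Convergence requires both an absolute log-likelihood change below
#' \code{tol_loglik} and a maximum relative parameter change below
#' \code{tol_param}. Components whose iterates go negative are clamped to
#' \code{1e-6 * var(y)} and flagged as pinned.
#'
#' @param y numeric phenotype vector.
#' @param grms a single \code{grm}/matrix or a (optionally named) list of
#'   them, all aligned to \code{y}.
#' @param X fixed-effect design matrix (default: intercept only). Must have
#'   full column rank. Candidate SNPs must not be included here.
#' @param max_iter maximum iterations (default 100).
#' @param tol_loglik,tol_param convergence tolerances (defaults 1e-4, 1e-6).
#' @param start optional starting values for all variance components
#'   (genetic components then residual); default splits \code{var(y)}
#'   equally.
#' @param verbose print per-iteration progress.
#' @return an object of class \code{"greml"} with elements \code{sigma2},
#'   \code{se_sigma2}, \code{h2} (per component and \code{total}),
#'   \code{se_h2}, \code{ai_inverse}, \code{loglik}, \code{n_iter},
#'   \code{converged}, \code{pinned}, \code{beta}, \code{n}.
#' @export
greml <- function(y, grms, X = NULL, max_iter = 100L, tol_loglik = 1e-4,
                  tol_param = 1e-6, start = NULL, verbose = FALSE) {
  cl <- match.call()
  y <- as.numeric(y)
  n <- length(y)
  if (inherits(grms, "grm") || is.matrix(grms)) grms <- list(grms)
  As <- lapply(grms, function(g) if (inherits(g, "grm")) g$A else as.matrix(g))
  k <- length(As)
  if (k < 1L) stop("at least one GRM is required")
  for (A in As) if (!all(dim(A) == n)) stop("GRM dimensions must match length(y)")
  cnames <- names(grms)
  if (is.null(cnames) || any(!nzchar(cnames)))
    cnames <- if (k == 1L) "genetic" else paste0("genetic", seq_len(k))
  # non-identifiability guards
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (max(abs(As[[i]] - As[[j]])) < 1e-10)
        stop("GRM components ", i, " and ", j, " are identical: model not identifiable")
  }
  for (i in seq_len(k))
    if (max(abs(As[[i]] - diag(n))) < 1e-10)
      stop("GRM component ", i, " equals the identity: not separable from the residual")
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "affine"))
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  p <- ncol(X)
  vy <- stats::var(y)
  if (vy <= 0) stop("phenotype has zero variance")
  lower <- 1e-6 * vy
  if (is.null(start)) start <- rep(vy / (k + 1L), k + 1L)
  theta <- pmax(as.numeric(start), lower)

  fit <- if (k == 1L) {
    .reml_spectral(y, X, qx, As[[1L]], theta, max_iter, tol_loglik, tol_param,
                   lower, verbose)
  } else {
    .reml_dense(y, X, qx, As, theta, max_iter, tol_loglik, tol_param,
                lower, verbose)
  }

  theta <- fit$theta
  names(theta) <- c(cnames, "residual")
  ai_inv <- fit$ai_inverse
  dimnames(ai_inv) <- list(names(theta), names(theta))
  se_sigma2 <- sqrt(pmax(diag(ai_inv), 0))
  S <- sum(theta)
  h2 <- theta[seq_len(k)] / S
  h2_total <- sum(theta[seq_len(k)]) / S
  # delta method on the full covariance of the variance components
  se_h2 <- vapply(seq_len(k), function(cc) {
    g <- rep(-theta[cc] / S^2, k + 1L)
    g[cc] <- g[cc] + 1 / S
    sqrt(max(0, drop(t(g) %*% ai_inv %*% g)))
  }, numeric(1L))
  Gsum <- sum(theta[seq_len(k)])
  gtot <- c(rep((S - Gsum) / S^2, k), -Gsum / S^2)
  se_h2_total <- sqrt(max(0, drop(t(gtot) %*% ai_inv %*% gtot)))
  h2 <- c(h2, total = h2_total)
  se_h2 <- c(stats::setNames(se_h2, cnames), total = se_h2_total)

  structure(list(call = cl, sigma2 = theta, se_sigma2 = se_sigma2,
                 h2 = h2, se_h2 = se_h2, ai_inverse = ai_inv,
                 loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged, pinned = fit$pinned,
                 beta = fit$beta, n = n, p = p, var_y = vy,
                 y = y, X = X, path = fit$path),
            class = "greml")
}

# ---- spectral path: one GRM + residual -------------------------------------

.reml_spectral <- function(y, X, qx, A, theta, max_iter, tol_loglik, tol_param,
                           lower, verbose) {
  n <- length(y); p <- ncol(X)
  if (p == 1L && stats::sd(X[, 1L]) == 0 && max(abs(A %*% rep(1, n))) < 1e-8 * n) {
    # column-centered GRM: the constant vector is an exact null eigenvector,
    # so eigen(A) directly yields the restricted basis
    ed <- eigen(A, symmetric = TRUE)
    iunit <- which.max(abs(crossprod(ed$vectors, rep(1 / sqrt(n), n))))
    keep <- setdiff(seq_len(n), iunit)
    d <- ed$values[keep]
    yt <- drop(crossprod(ed$vectors[, keep, drop = FALSE], y))
  } else {
    Q2 <- qr.Q(qx, complete = TRUE)[, (p + 1L):n, drop = FALSE]
    At <- crossprod(Q2, A %*% Q2)
    ed <- eigen(At, symmetric = TRUE)
    d <- ed$values
    yt <- drop(crossprod(ed$vectors, crossprod(Q2, y)))
  }
  d[d < 0 & d > -1e-10] <- 0
  nr <- length(d)
  yt2 <- yt^2

  ll_fun <- function(th) {
    v <- th[1L] * d + th[2L]
    if (any(v <= 0)) return(-Inf)
    -0.5 * (sum(log(v)) + sum(yt2 / v) + nr * log(2 * pi))
  }
  ll <- ll_fun(theta)
  pinned <- c(FALSE, FALSE)
  converged <- FALSE
  iter <- 0L
  em_count <- 0L
  ai <- NULL
  repeat {
    iter <- iter + 1L
    v <- theta[1L] * d + theta[2L]
    w <- yt2 / v^2
    dl <- -0.5 * c(sum(d / v) - sum(d * w), sum(1 / v) - sum(w))
    ai <- 0.5 * matrix(c(sum(d^2 * yt2 / v^3), sum(d * yt2 / v^3),
                         sum(d * yt2 / v^3), sum(yt2 / v^3)), 2L, 2L)
    step_em <- iter == 1L
    prop <- ai_prop <- NULL
    if (!step_em) {
      ai_prop <- tryCatch(theta + solve(ai, dl), error = function(e) NULL)
      if (is.null(ai_prop) || any(!is.finite(ai_prop)) || any(ai_prop < 0)) {
        step_em <- TRUE
      } else prop <- ai_prop
    }
    if (step_em) {
      em_count <- em_count + 1L
      if (em_count >= 3L && !is.null(ai_prop) && all(is.finite(ai_prop))) {
        # persistent boundary attraction: pin the offending component and
        # take a reduced AI step on the free one
        pin <- which(ai_prop < 0)
        prop <- theta
        prop[pin] <- lower
        free <- setdiff(1:2, pin)
        if (length(free)) {
          step_f <- tryCatch(solve(ai[free, free, drop = FALSE], dl[free]),
                             error = function(e) 0)
          prop[free] <- theta[free] + step_f
        }
        prop <- pmax(prop, lower)
      } else {
        prop <- theta + theta^2 * c(sum(d * w) - sum(d / v), sum(w) - sum(1 / v)) / nr
      }
    } else em_count <- 0L
    pinned <- prop <= lower
    prop <- pmax(prop, lower)
    ll_new <- ll_fun(prop)
    rel <- max(abs(prop - theta) / pmax(abs(theta), lower))
    dll <- ll_new - ll
    theta <- prop; ll <- ll_new
    if (verbose)
      message(sprintf("iter %d: loglik %.6f, sigma2 = %s", iter, ll,
                      paste(signif(theta, 5L), collapse = ", ")))
    # convergence is only declared off an AI step (EM progress is slow and
    # can satisfy the deltas far from the optimum) unless a bound is active
    if (iter >= 2L && (!step_em || any(pinned)) &&
        abs(dll) < tol_loglik && rel < tol_param) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  beta <- .gls_beta(y, X, theta[1L], A, theta[2L])
  list(theta = theta, ai_inverse = .safe_inv(ai), loglik = ll, n_iter = iter,
       converged = converged, pinned = pinned, beta = beta, path = "spectral")
}

# ---- dense path: any number of components ----------------------------------

.reml_dense <- function(y, X, qx, As, theta, max_iter, tol_loglik, tol_param,
                        lower, verbose) {
  n <- length(y); p <- ncol(X)
  k <- length(As)
  nc <- k + 1L
  ldXX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  chol_jitter <- function(V) {
    for (j in 0:3) {
      jit <- if (j == 0) 0 else 10^(j - 9) * mean(diag(V))
      ch <- tryCatch(chol(V + diag(jit, n)), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
    }
    stop("V is not positive definite even after jitter")
  }

  eval_state <- function(th) {
    V <- diag(th[nc], n)
    for (i in seq_len(k)) V <- V + th[i] * As[[i]]
    ch <- chol_jitter(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) -
                    ldXX + sum(y * Py) + (n - p) * log(2 * pi))
    list(P = P, Py = Py, loglik = ll)
  }

  st <- eval_state(theta)
  pinned <- rep(FALSE, nc)
  converged <- FALSE
  iter <- 0L
  em_count <- 0L
  ai <- NULL
  repeat {
    iter <- iter + 1L
    P <- st$P; Py <- st$Py
    APy <- matrix(0, n, nc)
    trPA <- numeric(nc)
    for (i in seq_len(k)) {
      APy[, i] <- As[[i]] %*% Py
      trPA[i] <- sum(P * As[[i]])
    }
    APy[, nc] <- Py
    trPA[nc] <- sum(diag(P))
    yPAPy <- drop(crossprod(Py, APy))        # y'P A_i P y
    dl <- -0.5 * (trPA - yPAPy)
    PAPy <- P %*% APy
    ai <- 0.5 * crossprod(APy, PAPy)
    step_em <- iter == 1L
    prop <- ai_prop <- NULL
    if (!step_em) {
      ai_prop <- tryCatch(theta + solve(ai, dl), error = function(e) NULL)
      if (is.null(ai_prop) || any(!is.finite(ai_prop)) || any(ai_prop < 0)) {
        step_em <- TRUE
      } else prop <- ai_prop
    }
    if (step_em) {
      em_count <- em_count + 1L
      if (em_count >= 3L && !is.null(ai_prop) && all(is.finite(ai_prop))) {
        pin <- which(ai_prop < 0)
        prop <- theta
        prop[pin] <- lower
        free <- setdiff(seq_len(nc), pin)
        if (length(free)) {
          step_f <- tryCatch(solve(ai[free, free, drop = FALSE], dl[free]),
                             error = function(e) rep(0, length(free)))
          prop[free] <- theta[free] + step_f
        }
        prop <- pmax(prop, lower)
      } else {
        prop <- theta + theta^2 * (yPAPy - trPA) / n
      }
    } else em_count <- 0L
    pinned <- prop <= lower
    prop <- pmax(prop, lower)
    st_new <- eval_state(prop)
    rel <- max(abs(prop - theta) / pmax(abs(theta), lower))
    dll <- st_new$loglik - st$loglik
    theta <- prop; st <- st_new
    if (verbose)
      message(sprintf("iter %d: loglik %.6f, sigma2 = %s", iter, st$loglik,
                      paste(signif(theta, 5L), collapse = ", ")))
    # convergence is only declared off an AI step (EM progress is slow and
    # can satisfy the deltas far from the optimum) unless a bound is active
    if (iter >= 2L && (!step_em || any(pinned)) &&
        abs(dll) < tol_loglik && rel < tol_param) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  Vfin <- diag(theta[nc], n)
  for (i in seq_len(k)) Vfin <- Vfin + theta[i] * As[[i]]
  Vi <- chol2inv(chol_jitter(Vfin))
  XtViX <- crossprod(X, Vi %*% X)
  beta <- drop(solve(XtViX, crossprod(X, Vi %*% y)))
  names(beta) <- colnames(X)
  list(theta = theta, ai_inverse = .safe_inv(ai), loglik = st$loglik,
       n_iter = iter, converged = converged, pinned = pinned, beta = beta,
       path = "dense")
}

.gls_beta <- function(y, X, sg, A, se) {
  V <- sg * A + diag(se, length(y))
  Vi <- chol2inv(chol(V + diag(1e-10 * mean(diag(V)), length(y))))
  b <- drop(solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y)))
  names(b) <- colnames(X)
  b
}

.safe_inv <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(solve(M + diag(1e-8 * mean(abs(diag(M))), nrow(M))),
                    error = function(e) matrix(NA_real_, nrow(M), ncol(M)))
  }
  (out + t(out)) / 2
}

# ---- methods ---------------------------------------------------------------

#' @export
print.greml <- function(x, ...) {
  k <- length(x$sigma2) - 1L
  cat("AI-REML variance-component fit (", x$n, " samples, ", k,
      " genetic component", if (k > 1L) "s", ")\n", sep = "")
  tab <- data.frame(sigma2 = x$sigma2, SE = x$se_sigma2)
  print(round(tab, 6L))
  cat(sprintf("h2 (total): %.4f (SE %.4f)\n", x$h2[["total"]], x$se_h2[["total"]]))
  cat(sprintf("logLik %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (any(x$pinned)) cat("note: component(s) pinned at lower bound:",
                         paste(names(x$sigma2)[x$pinned], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  k <- length(object$sigma2) - 1L
  comp <- names(object$sigma2)[seq_len(k)]
  z <- object$h2[comp] / object$se_h2[comp]
  out <- list(fit = object,
              table = data.frame(component = c(comp, "total"),
                                 h2 = unname(object$h2[c(comp, "total")]),
                                 se = unname(object$se_h2[c(comp, "total")]),
                                 z = c(unname(z), object$h2[["total"]] / object$se_h2[["total"]]),
                                 p_one_sided = stats::pnorm(c(unname(z),
                                   object$h2[["total"]] / object$se_h2[["total"]]),
                                   lower.tail = FALSE)))
  class(out) <- "summary.greml"
  out
}

#' @export
print.summary.greml <- function(x, ...) {
  print(x$fit)
  cat("\nHeritability components:\n")
  print(x$table, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$sigma2

#' @export
vcov.greml <- function(object, ...) object$ai_inverse

#' @export
logLik.greml <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2), nobs = object$n,
            class = "logLik")
}

#' @export
fitted.greml <- function(object, ...) drop(object$X %*% object$beta)

#' @export
residuals.greml <- function(object, ...) object$y - fitted(object)

# ---- liability scale and increase test -------------------------------------

#' Observed-to-liability-scale transformation
#'
#' For an ascertained case-control trait with population prevalence \eqn{K}
#' and in-sample case fraction \eqn{P}, the observed-scale heritability maps
#' to the liability scale as
#' \deqn{h^2_{liab} = h^2_{obs} \; K^2 (1-K)^2 / (z^2 P (1-P))}
#' with \eqn{z = \phi(\Phi^{-1}(1-K))}, the standard-normal density at the
#' threshold truncating the upper \eqn{K} fraction. The map is linear, so
#' standard errors scale by the same factor and all ratios, z-scores and
#' p-values on transformed estimates are unchanged.
#'
#' @param h2_obs observed-scale heritability estimate.
#' @param se_obs its standard error.
#' @param K population prevalence, in (0, 1).
#' @param P in-sample case fraction, in (0, 1).
#' @return list with \code{h2_liab}, \code{se_liab}, and the multiplicative
#'   \code{factor}.
#' @export
liability_transform <- function(h2_obs, se_obs, K, P) {
  if (!is.finite(K) || K <= 0 || K >= 1) stop("prevalence K must be in (0, 1)")
  if (!is.finite(P) || P <= 0 || P >= 1) stop("case fraction P must be in (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  fac <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  list(h2_liab = h2_obs * fac, se_liab = se_obs * fac, factor = fac)
}

#' Z-test for an increase of an estimate over its expectation
#'
#' One-sided upper-tail normal test of an estimated heritability against a
#' fixed expectation, using the analytical standard error; noise on the
#' expectation is deliberately not modelled (the estimate and its
#' expectation derive from the same SNPs and samples and are partially
#' nested).
#'
#' @param h2_est estimate.
#' @param se_est its analytical standard error.
#' @param expected the expectation tested against.
#' @return list with \code{gain} (= h2_est/expected), \code{z}, \code{p}
#'   (one-sided upper tail).
#' @export
ztest_increase <- function(h2_est, se_est, expected) {
  if (se_est < 0) stop("standard error must be non-negative")
  z <- if (se_est == 0) {
    if (h2_est == expected) 0 else sign(h2_est - expected) * Inf
  } else (h2_est - expected) / se_est
  list(gain = if (expected != 0) h2_est / expected else NA_real_,
       z = z, p = stats::pnorm(z, lower.tail = FALSE))
}
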