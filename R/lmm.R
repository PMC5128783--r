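#' Fit the study's linear mixed-effects model
#'
#' REML fit of a Gaussian linear mixed model with random intercepts for
#' an arbitrary set of grouping factors — by default the study's
#' structure: farm, cow nested within farm, and the cow x period
#' interaction (which absorbs individual drift over the experiment, such
#' as progressing gestation).  Fitting is performed by \pkg{lme4}; the
#' returned object additionally carries the dense design/covariance
#' pieces needed for Satterthwaite degrees of freedom and residual
#' diagnostics, which this package computes itself.
#'
#' @param fixed two-sided formula for the fixed part, e.g.
#'   `value ~ period` or `value ~ position * period`.
#' @param data data.frame containing the response, fixed covariates and
#'   grouping variables.
#' @param random character vector of grouping expressions, each fitted
#'   as a random intercept, e.g. `c("farm", "farm:cow",
#'   "farm:cow:period")`.
#' @return object of class `herd_lmm`.
#' @seealso [satterthwaite_contrast()], [remove_outliers_refit()]
#' @export
herd_lmm <- function(fixed, data,
                     random = c("farm", "farm:cow", "farm:cow:period")) {
  stopifnot(inherits(fixed, "formula"), length(random) >= 1)
  data <- as.data.frame(data)
  rs <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  full <- stats::as.formula(paste(deparse(fixed), "+", rs))
  fit <- lme4::lmer(full, data = data, REML = TRUE)
  X <- stats::model.matrix(fixed, data = data)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)
  y <- stats::model.response(stats::model.frame(fixed, data = data))
  n <- length(y)

  ## random-intercept indicator matrices, in `random` order
  Zs <- lapply(random, function(r) {
    g <- interaction(lapply(strsplit(r, ":", fixed = TRUE)[[1]],
                            function(v) data[[v]]), drop = TRUE)
    stats::model.matrix(~ 0 + g)
  })
  names(Zs) <- random

  vc <- as.data.frame(lme4::VarCorr(fit))
  sig2 <- vc$vcov[match("Residual", vc$grp)]
  ## lme4 names grouping terms by the interaction variable name
  vnames <- setdiff(vc$grp, "Residual")
  varcomp <- stats::setNames(numeric(length(random)), random)
  for (r in random) {
    key <- gsub(" ", "", r)
    hit <- which(gsub("[ `]", "", vnames) == key)
    if (length(hit) != 1) {    # fall back to matching by grouping size
      hit <- which(vapply(vnames, function(v) {
        lev <- lme4::getME(fit, "flist")[[v]]
        nlevels(lev) == ncol(Zs[[r]])
      }, TRUE))[1]
    }
    varcomp[r] <- vc$vcov[match(vnames[hit], vc$grp)]
  }

  beta <- lme4::fixef(fit)
  Vb <- as.matrix(stats::vcov(fit))
  fitted_m <- drop(X %*% beta)
  Vhat <- build_V(c(varcomp, residual = sig2), Zs, n)
  res <- y - fitted_m
  std <- res / sqrt(diag(Vhat))

  structure(list(
    call = match.call(), fixed = fixed, random = random, data = data,
    y = y, X = X, Zs = Zs, beta = beta, vcov_beta = Vb,
    varcomp = c(varcomp, residual = sig2),
    reml = as.numeric(lme4::REMLcrit(fit)),
    fitted = fitted_m, residuals = res, std_residuals = std,
    n = n, p = ncol(X), removed = integer(0), lme4 = fit),
    class = "herd_lmm")
}

## marginal covariance for given variance components (last = residual)
build_V <- function(theta, Zs, n) {
  V <- diag(theta[["residual"]], n)
  for (k in seq_along(Zs)) {
    if (theta[[k]] > 0) V <- V + theta[[k]] * tcrossprod(Zs[[k]])
  }
  V
}

## negative restricted log-likelihood (up to an additive constant) as a
## function of the variance components; independent of lme4 and used for
## the Satterthwaite covariance of the variance-component estimates
reml_nll <- function(theta, y, X, Zs) {
  n <- length(y)
  V <- build_V(theta, Zs, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(Inf)
  ldV <- 2 * sum(log(diag(R)))
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  XtViX <- crossprod(X, ViX)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(Inf)
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Viy)))
  r <- y - drop(X %*% beta)
  Vir <- backsolve(R, forwardsolve(t(R), r))
  0.5 * (ldV + 2 * sum(log(diag(Rx))) + sum(r * Vir))
}

## c' (X' V(theta)^-1 X)^-1 c
contrast_var <- function(theta, cvec, X, Zs, n) {
  V <- build_V(theta, Zs, n)
  R <- chol(V)
  ViX <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, ViX)
  drop(crossprod(cvec, solve(XtViX, cvec)))
}

fd_gradient <- function(f, x, rel = 1e-5) {
  h <- pmax(abs(x), 1e-8) * rel
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]; xm[j] <- max(xm[j] - h[j], 0)
    (f(xp) - f(xm)) / (xp[j] - xm[j])
  }, 0)
}

fd_hessian <- function(f, x, rel = 1e-5) {
  k <- length(x)
  h <- pmax(abs(x), 1e-8) * rel
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h[i]; xm[i] <- xm[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i < k) for (j in seq.int(i + 1, k)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
      xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
      xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
      xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Satterthwaite t-test of a fixed-effect contrast
#'
#' Tests `c'beta = 0` with the t statistic
#' `c'beta / sqrt(c' V(beta) c)` and Satterthwaite effective degrees of
#' freedom `df = 2 (c'Vc)^2 / Var(c'Vc)`, the denominator obtained by
#' the delta method over the REML variance-component covariance (inverse
#' observed information of the restricted log-likelihood, computed by
#' finite differences with relative step 1e-5).  Variance components
#' estimated on the zero boundary are held fixed and excluded from the
#' information matrix.
#'
#' @param fit a [herd_lmm()].
#' @param contrast either a numeric contrast vector over the fixed
#'   coefficients, or a list of two one-row data.frames
#'   `list(a, b)` whose fixed-design rows are differenced.
#' @param label optional contrast label.
#' @return one-row data.frame: `contrast`, `estimate`, `se`, `t`, `df`,
#'   `p` (two-sided).
#' @export
satterthwaite_contrast <- function(fit, contrast, label = NULL) {
  stopifnot(inherits(fit, "herd_lmm"))
  if (is.list(contrast) && !is.numeric(contrast)) {
    cvec <- design_row(fit, contrast[[1]]) - design_row(fit, contrast[[2]])
    if (is.null(label)) label <- "custom"
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != fit$p) stop("contrast length != number of fixed coefficients",
                                    call. = FALSE)
  }
  est <- drop(crossprod(cvec, fit$beta))
  theta <- fit$varcomp
  k <- length(theta)
  boundary_tol <- max(theta[["residual"]], 1e-12) * 1e-8
  active <- c(theta[-k] > boundary_tol, TRUE)
  satt <- function(active) {
    th_act <- theta[active]
    f_var <- function(ta) {
      th <- theta; th[active] <- ta
      contrast_var(th, cvec, fit$X, fit$Zs, fit$n)
    }
    f_nll <- function(ta) {
      th <- theta; th[active] <- ta
      reml_nll(th, fit$y, fit$X, fit$Zs)
    }
    vc_beta <- f_var(th_act)
    g <- fd_gradient(f_var, th_act)
    H <- fd_hessian(f_nll, th_act)
    A <- tryCatch(solve(H), error = function(e) NULL)
    denom <- if (is.null(A)) NA_real_ else drop(crossprod(g, A %*% g))
    list(vc_beta = vc_beta, denom = denom,
         df = 2 * vc_beta^2 / denom)
  }
  res <- satt(active)
  ## a variance component sitting epsilon-above the boundary makes the
  ## observed information singular; treat the smallest such component as
  ## on the boundary and retry
  while ((!is.finite(res$df) || res$df <= 0) && sum(active[-k]) > 0) {
    drop_i <- which(active[-k])[which.min(theta[-k][active[-k]])]
    active[drop_i] <- FALSE
    res <- satt(active)
  }
  vc_beta <- res$vc_beta
  df <- res$df
  if (!is.finite(df) || df <= 0) {
    stop("Satterthwaite df not positive (denominator ", signif(res$denom, 4),
         "); variance-component information may be singular", call. = FALSE)
  }
  se <- sqrt(vc_beta)
  tval <- est / se
  data.frame(contrast = label %||% "contrast", estimate = est, se = se,
             t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
             stringsAsFactors = FALSE)
}

## fixed-design row for a one-row data.frame of covariate values
design_row <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$fixed))
  ## carry factor levels from the training data
  for (v in all.vars(tt)) {
    if (is.character(fit$data[[v]]) || is.factor(fit$data[[v]])) {
      newdata[[v]] <- factor(newdata[[v]],
                             levels = levels(factor(fit$data[[v]])))
    }
  }
  mf <- stats::model.frame(tt, newdata, xlev = NULL)
  drop(stats::model.matrix(tt, mf))
}

#' Remove residual outliers and refit once
#'
#' One pass, as in small repeated-measures trimming: fit, compute
#' standardized marginal residuals, drop observations with |z| above the
#' 99% two-sided standard-normal bound (2.5758), refit once.
#'
#' @param fit a [herd_lmm()].
#' @param z_cut standardized-residual cutoff (default
#'   `qnorm(0.995)` = 2.5758).
#' @return a `herd_lmm` fitted to the retained rows, with `removed`
#'   holding the dropped row indices of the original data.
#' @export
remove_outliers_refit <- function(fit, z_cut = stats::qnorm(0.995)) {
  stopifnot(inherits(fit, "herd_lmm"))
  out <- which(abs(fit$std_residuals) > z_cut)
  if (length(out) == 0) {
    fit$removed <- integer(0)
    return(fit)
  }
  kept <- fit$data[-out, , drop = FALSE]
  for (r in fit$random) {
    g <- interaction(lapply(strsplit(r, ":", fixed = TRUE)[[1]],
                            function(v) kept[[v]]), drop = TRUE)
    if (nlevels(g) < 2) {
      stop("outlier removal would empty grouping '", r, "'", call. = FALSE)
    }
  }
  refit <- herd_lmm(fit$fixed, kept, fit$random)
  refit$removed <- out
  refit
}

#' @export
print.herd_lmm <- function(x, ...) {
  cat("Linear mixed model (REML), ", deparse(x$fixed), "\n", sep = "")
  cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  cat(sprintf("  n = %d (%d removed as outliers), REML criterion %.2f\n",
              x$n, length(x$removed), x$reml))
  cat("  variance components (sd):\n")
  sds <- sqrt(x$varcomp)
  for (nm in names(sds)) cat(sprintf("    %-18s %.4f\n", nm, sds[[nm]]))
  invisible(x)
}

#' @export
summary.herd_lmm <- function(object, ...) {
  coefs <- lapply(seq_len(object$p), function(j) {
    cv <- numeric(object$p); cv[j] <- 1
    satterthwaite_contrast(object, cv, label = colnames(object$X)[j])
  })
  out <- list(fit = object, coefficients = do.call(rbind, coefs))
  class(out) <- "summary.herd_lmm"
  out
}

#' @export
print.summary.herd_lmm <- function(x, ...) {
  print(x$fit)
  cat("  fixed effects (Satterthwaite t-tests):\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 5); tab$se <- signif(tab$se, 4)
  tab$t <- signif(tab$t, 4); tab$df <- round(tab$df, 1)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.herd_lmm <- function(object, ...) object$beta

#' @export
vcov.herd_lmm <- function(object, ...) object$vcov_beta

#' @export
fitted.herd_lmm <- function(object, ...) object$fitted

#' @export
residuals.herd_lmm <- function(object,
                               type = c("marginal", "standardized"), ...) {
  type <- match.arg(type)
  if (type == "marginal") object$residuals else object$std_residuals
}

#' @export
predict.herd_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  rows <- t(vapply(seq_len(nrow(newdata)), function(i) {
    design_row(object, newdata[i, , drop = FALSE])
  }, numeric(object$p)))
  drop(rows %*% object$beta)
}

#' @export
simulate.herd_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$varcomp
  out <- replicate(nsim, {
    y <- object$fitted + stats::rnorm(object$n, 0, sqrt(th[["residual"]]))
    for (k in seq_along(object$Zs)) {
      if (th[[k]] > 0) {
        u <- stats::rnorm(ncol(object$Zs[[k]]), 0, sqrt(th[[k]]))
        y <- y + drop(object$Zs[[k]] %*% u)
      }
    }
    y
  })
  as.data.frame(out)
}

#' @export
plot.herd_lmm <- function(x, ...) {
  stats::qqnorm(x$std_residuals,
                main = "Standardized marginal residuals", ...)
  stats::qqline(x$std_residuals)
  invisible(x)
}
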