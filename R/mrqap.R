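# Multiple regression quadratic assignment procedure (MRQAP).
#
# Point estimates come from ordinary least squares on the vectorized
# off-diagonal dyads; significance comes from node-label permutations,
# which respect the row/column exchangeability structure of dyadic data
# that makes classical OLS p-values invalid on networks.

# t statistic of the last column of X in OLS of y on X
tstat_last <- function(X, y) {
  q <- qr(X)
  if (q$rank < ncol(X)) return(NA_real_)
  b <- qr.coef(q, y)
  res <- y - X %*% b
  df <- length(y) - q$rank
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(q))
  b[length(b)] / sqrt(s2 * XtXinv[ncol(X), ncol(X)])
}

#' MRQAP: matrix regression with node-permutation inference
#'
#' Regresses a dependent dyadic matrix on one or more predictor matrices.
#' Coefficients are identical to OLS on the vectorized upper-triangle
#' dyads (masked dyads dropped listwise). Two-tailed p-values are obtained
#' by permuting node labels: by default with Dekker-style double
#' semi-partialing (`method = "dsp"`), in which each predictor is
#' residualized on the remaining predictors, the residual matrix has its
#' rows and columns permuted jointly, and the pivotal t statistic is
#' recomputed; `method = "y"` permutes the dependent matrix instead. The
#' observed statistic is counted in both numerator and denominator, so
#' `p >= 1/(n_perm + 1)` and p-values are never exactly zero.
#'
#' @param dep symmetric dependent matrix (e.g. [bsi_correlation_matrix()]).
#' @param predictors named list of symmetric predictor matrices of the
#'   same dimension (e.g. an SRI matrix and a [centroid_distance_matrix()]).
#' @param n_perm number of permutations (a value below 99 triggers a
#'   warning; inference would be too coarse).
#' @param seed integer seed for the permutation stream.
#' @param method `"dsp"` (double semi-partialing; default) or `"y"`
#'   (dependent-matrix permutation, which also yields an intercept
#'   p-value).
#' @return object of class `mrqap_result`: list with `coefficients`,
#'   `p_values` (two-tailed; intercept `NA` under `"dsp"`), `t_values`,
#'   `adj_r_squared`, `residual_se`, `df`, `n_dyads`, `n_perm`, `seed`,
#'   `method`.
#' @examples
#' set.seed(7)
#' n <- 12
#' a <- matrix(rnorm(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 0
#' y <- 2 * a; diag(y) <- 0
#' fit <- mrqap(y, list(assoc = a), n_perm = 199)
#' fit$coefficients
#' @export
mrqap <- function(dep, predictors, n_perm = 999, seed = 1L,
                  method = c("dsp", "y")) {
  method <- match.arg(method)
  if (!is.list(predictors) || !length(predictors)) {
    stop("'predictors' must be a non-empty list of matrices", call. = FALSE)
  }
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  dep <- as.matrix(dep)
  n <- nrow(dep)
  mats <- lapply(predictors, as.matrix)
  for (nm in names(mats)) {
    if (!all(dim(mats[[nm]]) == c(n, n))) {
      stop("predictor '", nm, "' is not conformable with the dependent matrix",
           call. = FALSE)
    }
    if (!is.null(rownames(mats[[nm]])) && !is.null(rownames(dep)) &&
        !identical(rownames(mats[[nm]]), rownames(dep))) {
      mats[[nm]] <- mats[[nm]][rownames(dep), rownames(dep)]
    }
  }
  if (n_perm < 99) warning("n_perm < 99: permutation p-values will be coarse")

  ut <- upper.tri(dep)
  y_full <- dep[ut]
  x_full <- lapply(mats, function(m) m[ut])
  valid <- !is.na(y_full)
  for (v in x_full) valid <- valid & !is.na(v)
  nd <- sum(valid)
  p_tot <- length(mats) + 1L
  if (nd <= p_tot) stop("too few unmasked dyads", call. = FALSE)

  X <- cbind(`(Intercept)` = 1, do.call(cbind, x_full))[valid, , drop = FALSE]
  y <- y_full[valid]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("predictors are collinear (design matrix is rank deficient)",
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  df <- nd - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  t_obs <- beta / se
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / sst
  adj_r2 <- 1 - (1 - r2) * (nd - 1) / df

  complete <- all(valid) && !anyNA(do.call(cbind, x_full))
  p_perm <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))

  with_seed(seed, {
    if (method == "y") {
      count <- numeric(ncol(X))
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        yp_m <- dep[perm, perm]
        yp <- yp_m[ut]
        keep <- valid & !is.na(yp)
        Xp <- cbind(1, do.call(cbind, x_full))[keep, , drop = FALSE]
        qp <- qr(Xp)
        bp <- qr.coef(qp, yp[keep])
        rp <- yp[keep] - Xp %*% bp
        s2 <- sum(rp^2) / (sum(keep) - ncol(Xp))
        tp <- bp / sqrt(s2 * diag(chol2inv(qr.R(qp))))
        count <- count + (abs(tp) >= abs(t_obs) - 1e-12)
      }
      p_perm[] <- (1 + count) / (n_perm + 1)
    } else {
      for (k in seq_along(mats)) {
        col <- k + 1L  # position in X
        Z <- X[, -col, drop = FALSE]
        xk <- X[, col]
        qz <- qr(Z)
        ek <- xk - Z %*% qr.coef(qz, xk)
        Em <- matrix(NA_real_, n, n)
        ev <- rep(NA_real_, sum(ut))
        ev[valid] <- ek
        Em[ut] <- ev
        Em[lower.tri(Em)] <- t(Em)[lower.tri(Em)]
        count <- 0L
        if (complete) {
          Q <- qr.Q(qz)
          ry <- y - Q %*% crossprod(Q, y)
          ryy <- sum(ry^2)
          for (b in seq_len(n_perm)) {
            perm <- sample.int(n)
            e <- Em[perm, perm][ut]
            re <- e - Q %*% crossprod(Q, e)
            s2e <- sum(re^2)
            if (s2e < 1e-300) next
            bhat <- sum(re * ry) / s2e
            sse <- ryy - bhat^2 * s2e
            tstar <- bhat / sqrt((sse / df) / s2e)
            if (abs(tstar) >= abs(t_obs[col]) - 1e-12) count <- count + 1L
          }
        } else {
          for (b in seq_len(n_perm)) {
            perm <- sample.int(n)
            e_full <- Em[perm, perm][ut]
            keep <- valid & !is.na(e_full)
            tstar <- tstat_last(cbind(Z[keep[valid], , drop = FALSE],
                                      e_full[keep]),
                                y_full[keep])
            if (!is.na(tstar) &&
                abs(tstar) >= abs(t_obs[col]) - 1e-12) count <- count + 1L
          }
        }
        p_perm[col] <- (1 + count) / (n_perm + 1)
      }
    }
  })

  structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 p_values = p_perm,
                 t_values = stats::setNames(as.numeric(t_obs), colnames(X)),
                 adj_r_squared = adj_r2,
                 residual_se = sqrt(sigma2),
                 df = df,
                 n_dyads = nd,
                 n_perm = n_perm,
                 seed = seed,
                 method = method),
            class = "mrqap_result")
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MRQAP (%s, %d node permutations, %d dyads)\n",
              x$method, x$n_perm, x$n_dyads))
  tab <- data.frame(Estimate = x$coefficients,
                    t = x$t_values,
                    `Two-tailed p` = x$p_values,
                    check.names = FALSE)
  print(format(tab, digits = 3))
  cat(sprintf("Adjusted R-squared = %.4g, Residual SE = %.4g, df = %d\n",
              x$adj_r_squared, x$residual_se, x$df))
  invisible(x)
}

#' Write an MRQAP result as JSON
#'
#' Shaped as a regression report: coefficients, two-tailed permutation
#' p-values, adjusted R-squared, residual SE, degrees of freedom,
#' permutation count and seed.
#'
#' @param result an [mrqap()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrqap_json <- function(result, path) {
  out <- list(coefficients = as.list(result$coefficients),
              p_values = as.list(result$p_values),
              adj_r_squared = result$adj_r_squared,
              residual_se = result$residual_se,
              df = result$df,
              n_perm = result$n_perm,
              seed = result$seed,
              method = result$method)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
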