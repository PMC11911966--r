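# Maximum-likelihood structural equation model with two latent exogenous
# variables (Diversity, Variability) measured by three indicators each, and
# two observed endogenous variables (SS, NBE). RAM parameterization:
# Sigma(theta) = F (I - A)^-1 S (I - A)^-T F^T, minimizing the ML
# discrepancy F_ML = log|Sigma| + tr(S_obs Sigma^-1) - log|S_obs| - p.

sem_matrices <- function(theta, nbe_direct = TRUE) {
  # order: 6 indicators, ss, nbe, Div, Var
  nv <- 10
  A <- matrix(0, nv, nv)
  lam <- theta[1:6]
  A[1:3, 9] <- lam[1:3]    # Diversity =~ richness + pd + fd
  A[4:6, 10] <- lam[4:6]   # Variability =~ tax + phy + fun
  A[7, 9] <- theta[7]      # SS ~ Diversity
  A[7, 10] <- theta[8]     # SS ~ Variability
  A[8, 7] <- theta[9]      # NBE ~ SS
  A[8, 10] <- theta[10]    # NBE ~ Variability
  k <- 10
  if (nbe_direct) { k <- 11; A[8, 9] <- theta[11] }  # NBE ~ Diversity
  S <- matrix(0, nv, nv)
  phi <- tanh(theta[k + 1])
  S[9, 9] <- S[10, 10] <- 1
  S[9, 10] <- S[10, 9] <- phi
  diag(S)[1:8] <- exp(theta[(k + 2):(k + 9)])
  list(A = A, S = S)
}

sem_implied <- function(theta, nbe_direct = TRUE) {
  m <- sem_matrices(theta, nbe_direct)
  B <- solve(diag(10) - m$A)
  full <- B %*% m$S %*% t(B)
  list(full = full, obs = full[1:8, 1:8], m = m)
}

sem_discrepancy <- function(theta, S_obs, nbe_direct = TRUE) {
  sigma <- tryCatch(sem_implied(theta, nbe_direct)$obs,
                    error = function(e) NULL)
  if (is.null(sigma)) return(1e10)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e10)
  log(det(sigma)) + sum(diag(S_obs %*% solve(sigma))) -
    log(det(S_obs)) - nrow(S_obs)
}

#' Fit the diversity-variability-stability SEM
#'
#' Measurement model: Diversity =~ richness + PD + FD and
#' Variability =~ taxonomic + phylogenetic + functional variability
#' (latent variances fixed to 1, latent correlation free). Structural
#' model: SS ~ Diversity + Variability; NBE ~ SS + Variability and,
#' optionally, a direct Diversity path. Variables are standardized and
#' incomplete rows dropped listwise before maximum-likelihood estimation;
#' standard errors come from the numerical Hessian of the discrepancy.
#' Non-convergence is reported via a warning and the \code{converged} flag.
#'
#' @param table analysis table with columns \code{richness}, \code{pd},
#'   \code{fd}, \code{var_tax}, \code{var_phy}, \code{var_fun},
#'   \code{nbe}, and the chosen stability column.
#' @param ss_metric stability column to use: \code{"ss_hhcv"},
#'   \code{"ss_fc"} or \code{"ss_dD"}.
#' @param nbe_direct_diversity include the direct Diversity -> NBE path
#'   (default TRUE).
#' @param min_n minimum number of complete rows (default 50).
#' @return object of class \code{sem_result}: \code{loadings},
#'   \code{paths} (estimate, std, se, z, p), \code{r2} for SS and NBE,
#'   \code{latent_correlation}, \code{n}, \code{converged}.
#' @export
fit_sem <- function(table, ss_metric = c("ss_dD", "ss_fc", "ss_hhcv"),
                    nbe_direct_diversity = TRUE, min_n = 50) {
  ss_metric <- match.arg(ss_metric)
  cols <- c("richness", "pd", "fd", "var_tax", "var_phy", "var_fun",
            ss_metric, "nbe")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stopf("analysis table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  dat <- table[, cols]
  dat <- dat[apply(is.finite(as.matrix(dat)), 1, all), ]
  n <- nrow(dat)
  if (n < min_n) stopf("need >= %d complete rows, have %d", min_n, n)
  X <- scale(as.matrix(dat))
  if (any(!is.finite(X))) stopf("a model variable has zero variance")
  S_obs <- stats::cov(X)
  ev <- eigen(S_obs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    stopf("indicators are collinear: sample covariance is singular, model not identified")

  k <- if (nbe_direct_diversity) 11 else 10
  theta0 <- c(rep(0.7, 6), rep(0, k - 6), atanh(0.3), rep(log(0.5), 8))
  opt <- stats::optim(theta0, sem_discrepancy, S_obs = S_obs,
                      nbe_direct = nbe_direct_diversity,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  converged <- opt$convergence == 0 && opt$value < 1e9
  if (!converged)
    warnf("SEM did not converge (optim code %d, discrepancy %.3g)",
          opt$convergence, opt$value)
  theta <- opt$par
  imp <- sem_implied(theta, nbe_direct_diversity)
  sds <- sqrt(diag(imp$full))
  vn <- c("richness", "pd", "fd", "var_tax", "var_phy", "var_fun",
          "ss", "nbe", "Diversity", "Variability")

  H <- tryCatch(stats::optimHess(theta, sem_discrepancy, S_obs = S_obs,
                                 nbe_direct = nbe_direct_diversity),
                error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  if (!is.null(H)) {
    covm <- tryCatch(solve(H) * 2 / (n - 1), error = function(e) NULL)
    if (!is.null(covm)) {
      dv <- diag(covm)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }

  path_idx <- if (nbe_direct_diversity) {
    data.frame(from = c("Diversity", "Variability", "ss", "Variability",
                        "Diversity"),
               to = c("ss", "ss", "nbe", "nbe", "nbe"),
               i = c(7, 8, 9, 10, 11))
  } else {
    data.frame(from = c("Diversity", "Variability", "ss", "Variability"),
               to = c("ss", "ss", "nbe", "nbe"), i = c(7, 8, 9, 10))
  }
  std_of <- function(est, from, to)
    est * sds[match(from, vn)] / sds[match(to, vn)]
  paths <- data.frame(
    from = path_idx$from, to = path_idx$to,
    estimate = theta[path_idx$i],
    std = std_of(theta[path_idx$i], path_idx$from, path_idx$to),
    se = se[path_idx$i])
  paths$z <- paths$estimate / paths$se
  paths$p <- 2 * stats::pnorm(-abs(paths$z))

  load_idx <- 1:6
  loadings <- data.frame(
    indicator = vn[1:6],
    latent = rep(c("Diversity", "Variability"), each = 3),
    estimate = theta[load_idx],
    std = theta[load_idx] / sds[1:6],
    se = se[load_idx])

  resid_var <- diag(imp$m$S)[7:8]
  r2 <- 1 - resid_var / diag(imp$full)[7:8]
  names(r2) <- c("ss", "nbe")

  structure(list(loadings = loadings, paths = paths, r2 = r2,
                 latent_correlation = tanh(theta[k + 1]),
                 ss_metric = ss_metric, n = n,
                 discrepancy = opt$value, converged = converged),
            class = "sem_result")
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("SEM (ML, n = %d, SS metric = %s, %s)\n", x$n, x$ss_metric,
              if (x$converged) "converged" else "NOT converged"))
  cat("\nStandardized paths:\n")
  print(cbind(x$paths[, c("from", "to")],
              round(x$paths[, c("std", "se", "p")], 4)), row.names = FALSE)
  cat(sprintf("\nR2: SS = %.3f, NBE = %.3f;  latent correlation = %.3f\n",
              x$r2["ss"], x$r2["nbe"], x$latent_correlation))
  invisible(x)
}
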