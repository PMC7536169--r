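# Psychometric evaluation suite: internal consistency, test-retest
# agreement, factorability diagnostics, minimum-residual EFA and
# FDR-corrected rank correlations.

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total).
#' Assumes tau-equivalence (equal item loadings); see [omega_total()] for
#' the factor-model alternative.
#'
#' @param items Numeric matrix or data frame, respondents x items.
#' @return Scalar alpha (at most 1; can be negative).
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(x + rnorm(100))  # shared row effect raises alpha
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2 || nrow(items) < 3) {
    stop("need at least 2 items and 3 respondents", call. = FALSE)
  }
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

# Squared multiple correlations, the standard communality start values.
smc <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-6, nrow(R))))
  1 - 1 / diag(inv)
}

# Minimum-residual (ULS) factor extraction: optimize uniquenesses psi to
# minimize the squared residuals of R - (Lambda Lambda' + diag(psi));
# given psi, the loss-minimizing Lambda comes from the leading
# eigenvectors of R - diag(psi).
minres_extract <- function(R, m, maxit = 1000) {
  p <- nrow(R)
  lambda_from_psi <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(ev), m)
    L
  }
  obj <- function(psi) {
    L <- lambda_from_psi(psi)
    resid <- R - L %*% t(L)
    diag(resid) <- 0
    sum(resid^2)
  }
  start <- pmin(pmax(1 - smc(R), 0.005), 0.995)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = 0.001, upper = 1,
                      control = list(maxit = maxit))
  if (fit$convergence != 0) {
    stop("minres extraction did not converge (optim code ",
         fit$convergence, "): ", fit$message, call. = FALSE)
  }
  psi <- fit$par
  heywood <- any(psi <= 0.001 + 1e-8)
  if (heywood) {
    warning("Heywood case: uniqueness clamped at lower bound", call. = FALSE)
  }
  L <- lambda_from_psi(psi)
  # orient each factor so its loading sum is positive
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, "*")
  dimnames(L) <- list(rownames(R), paste0("F", seq_len(m)))
  list(loadings = L, uniquenesses = stats::setNames(psi, rownames(R)),
       objective = fit$value, heywood = heywood)
}

#' McDonald's omega-total from a single common factor
#'
#' Fits a one-factor minimum-residual model to the item correlation
#' matrix and returns
#' omega_t = (sum lambda)^2 / ((sum lambda)^2 + sum psi).
#' Unlike alpha, omega does not assume equal loadings; the two agree
#' under tau-equivalence and diverge otherwise.
#'
#' @param items Respondents x items matrix or data frame.
#' @return Scalar omega-total in [0, 1] for proper solutions.
#' @export
omega_total <- function(items) {
  R <- stats::cor(as.matrix(items))
  fit <- minres_extract(R, 1)
  lam <- fit$loadings[, 1]
  sum(lam)^2 / (sum(lam)^2 + sum(fit$uniquenesses))
}

#' Two-way random absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Single-measure ICC from the two-way random-effects model with the
#' absolute-agreement definition, which penalizes systematic shifts
#' between occasions:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#'
#' @param test,retest Paired numeric score vectors (same respondents,
#'   two occasions).
#' @return List with `icc`, `df` (n - 1), mean squares and the paired
#'   sample size `n`.
#' @export
#' @examples
#' x <- rnorm(25); icc_absolute(x, x)$icc  # 1
icc_absolute <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  n <- length(test)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  Y <- cbind(test, retest)
  k <- 2
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  grand <- mean(Y)
  if (stats::var(row_means) == 0) {
    stop("zero between-subject variance: ICC undefined", call. = FALSE)
  }
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((Y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, df = n - 1, n = n, msr = msr, msc = msc, mse = mse)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Ratio of summed squared correlations to summed squared correlations
#' plus summed squared anti-image (partial) correlations, over all
#' off-diagonal pairs. Values above 0.6 are conventionally considered
#' adequate for factor analysis.
#'
#' @param R Correlation matrix (positive definite).
#' @return Scalar KMO in [0, 1].
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  inv <- solve(R)
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(partial[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' chi^2 = -(n - 1 - (2p + 5)/6) * ln det(R), df = p(p-1)/2.
#'
#' @param R Correlation matrix.
#' @param n Number of observations behind `R`.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' bartlett(diag(6), 100)  # chi2 = 0, p = 1
bartlett <- function(R, n) {
  R <- as.matrix(R)
  p <- nrow(R)
  det_R <- det(R)
  if (det_R <= 0) stop("correlation matrix is singular", call. = FALSE)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(det_R)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Parallel analysis eigenvalue thresholds
#'
#' Eigenvalue thresholds from resampled uncorrelated normal data of the
#' same dimensions: for each eigenvalue position, the given quantile
#' (default 95th percentile) over `n_rep` random data sets.
#'
#' @param n_obs,n_var Dimensions of the data.
#' @param n_rep Number of resamples (default 100).
#' @param quantile Percentile criterion (default 0.95).
#' @param seed Seed for the resampling.
#' @return Numeric vector of length `n_var`.
#' @export
parallel_thresholds <- function(n_obs, n_var, n_rep = 100,
                                quantile = 0.95, seed = 1) {
  set.seed(seed)
  ev <- replicate(n_rep, {
    eigen(stats::cor(matrix(stats::rnorm(n_obs * n_var), n_obs, n_var)),
          symmetric = TRUE, only.values = TRUE)$values
  })
  apply(ev, 1, stats::quantile, probs = quantile)
}

#' Exploratory factor analysis by the minimum-residual method
#'
#' Extracts factors minimizing the squared off-diagonal residuals of
#' R - Lambda Lambda' - Psi (ULS/minres), and reports the full
#' factorability and fit panel: eigenvalues, Kaiser count (eigenvalues
#' > 1), parallel-analysis count, proportion of variance explained,
#' RMSEA and BIC, KMO and Bartlett's test. Solutions with more than one
#' factor are varimax-rotated.
#'
#' @param x Data matrix (respondents x variables) or correlation matrix.
#' @param n_factors Number of factors; `NULL` (default) takes the
#'   parallel-analysis suggestion.
#' @param n_obs Number of observations; required when `x` is a
#'   correlation matrix.
#' @param n_rep,quantile,seed Parallel-analysis settings (100 resamples,
#'   95th percentile).
#' @return Object of class `tpt_factor_report`.
#' @export
efa_minres <- function(x, n_factors = NULL, n_obs = NULL, n_rep = 100,
                       quantile = 0.95, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-12 &&
      all(abs(diag(x) - 1) < 1e-12)) {
    R <- x
    if (is.null(n_obs)) stop("n_obs required with a correlation matrix",
                             call. = FALSE)
  } else {
    R <- stats::cor(x)
    n_obs <- nrow(x)
  }
  p <- nrow(R)
  if (is.null(rownames(R))) {
    dimnames(R) <- list(paste0("V", 1:p), paste0("V", 1:p))
  }
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  thr <- parallel_thresholds(n_obs, p, n_rep, quantile, seed)
  n_kaiser <- sum(eigenvalues > 1)
  above <- eigenvalues > thr
  n_parallel <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  m <- if (is.null(n_factors)) max(1L, n_parallel) else n_factors
  fit <- minres_extract(R, m)
  L <- fit$loadings
  if (m > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- L %*% rot$rotmat
    sgn <- ifelse(colSums(L) < 0, -1, 1)
    L <- sweep(L, 2, sgn, "*")
    dimnames(L) <- dimnames(fit$loadings)
  }
  psi <- fit$uniquenesses
  # Normal-theory ML discrepancy at the minres solution with a
  # Bartlett-style multiplier; df = ((p - m)^2 - (p + m)) / 2.
  Sigma <- fit$loadings %*% t(fit$loadings) + diag(psi)
  f_ml <- log(det(Sigma)) - log(det(R)) +
    sum(diag(R %*% solve(Sigma))) - p
  df <- ((p - m)^2 - (p + m)) / 2
  chi2 <- max(0, (n_obs - 1 - (2 * p + 5) / 6 - 2 * m / 3) * f_ml)
  rmsea <- if (df > 0) sqrt(max(chi2 / df - 1, 0) / (n_obs - 1)) else NA_real_
  bic <- if (df > 0) chi2 - df * log(n_obs) else NA_real_
  structure(list(
    loadings = L,
    uniquenesses = psi,
    n_factors = m,
    eigenvalues = eigenvalues,
    n_factors_kaiser = n_kaiser,
    n_factors_parallel = n_parallel,
    parallel_thresholds = thr,
    variance_explained = sum(fit$loadings^2) / p,
    rmsea = rmsea,
    bic = bic,
    chi2 = chi2,
    df = df,
    kmo = kmo(R),
    bartlett = bartlett(R, n_obs),
    n_obs = n_obs,
    heywood = fit$heywood
  ), class = "tpt_factor_report")
}

#' @export
print.tpt_factor_report <- function(x, digits = 2, ...) {
  cat(sprintf("Minres EFA: %d factor(s), %d observations\n",
              x$n_factors, x$n_obs))
  cat(sprintf("  Kaiser suggests %d, parallel analysis %d\n",
              x$n_factors_kaiser, x$n_factors_parallel))
  cat(sprintf("  KMO %.2f; Bartlett chi2(%d) = %.2f, p = %.3g\n",
              x$kmo, x$bartlett$df, x$bartlett$chi2, x$bartlett$p_value))
  cat(sprintf("  variance explained %.0f%%; RMSEA %.3f; BIC %.1f\n",
              100 * x$variance_explained, x$rmsea, x$bic))
  cat("Loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Applies the BH step-up rule at FDR level `q` over one family of
#' p-values: sort ascending, find the largest i with p_(i) <= i q / m,
#' and declare all smaller-or-equal p-values significant. Implemented
#' through [stats::p.adjust()]; this is the rule behind the
#' `significant` column of [spearman_bh()].
#'
#' @param p_values Numeric vector of raw p-values (one family).
#' @param q FDR level (default 0.05).
#' @return Logical vector of significance flags.
#' @export
#' @examples
#' bh_flags(c(0.01, 0.02, 0.03, 0.04), q = 0.05)  # all TRUE
bh_flags <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") < q
}

#' Spearman correlations with Benjamini-Hochberg correction
#'
#' All pairwise rank correlations among the columns (tie-corrected), or
#' between two column sets, with BH step-up adjustment applied over the
#' whole table as one family. Constant columns are excluded from the
#' family and reported.
#'
#' @param x Respondents x variables data frame or matrix.
#' @param y Optional second set of columns; default correlates `x`
#'   with itself (upper triangle).
#' @param q FDR level for the significance flags (default 0.05).
#' @return `tpt_correlation_report`: data frame of pairs with `rho`,
#'   `p_value`, `p_adjusted`, `significant`, plus attribute
#'   `excluded` naming constant columns.
#' @export
spearman_bh <- function(x, y = NULL, q = 0.05) {
  x <- as.data.frame(x)
  drop_const <- function(df) {
    const <- vapply(df, function(v) stats::var(v, na.rm = TRUE) == 0,
                    logical(1))
    list(df = df[!const], excluded = names(df)[const])
  }
  cx <- drop_const(x)
  excluded <- cx$excluded
  if (is.null(y)) {
    nm <- names(cx$df)
    pairs <- utils::combn(nm, 2)
    left <- pairs[1, ]; right <- pairs[2, ]
    get <- function(v) cx$df[[v]]
  } else {
    y <- as.data.frame(y)
    cy <- drop_const(y)
    excluded <- c(excluded, cy$excluded)
    grid <- expand.grid(a = names(cx$df), b = names(cy$df),
                        stringsAsFactors = FALSE)
    left <- grid$a; right <- grid$b
    get <- function(v) if (v %in% names(cx$df)) cx$df[[v]] else cy$df[[v]]
  }
  res <- lapply(seq_along(left), function(i) {
    ct <- suppressWarnings(
      stats::cor.test(get(left[i]), get(right[i]),
                      method = "spearman", exact = FALSE))
    data.frame(var1 = left[i], var2 = right[i],
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- bh_flags(out$p_value, q)
  attr(out, "excluded") <- excluded
  attr(out, "q") <- q
  class(out) <- c("tpt_correlation_report", "data.frame")
  out
}

#' Test-retest reliability panel
#'
#' ICC(A,1), Pearson r and Spearman rho between two score vectors from
#' the same respondents on two occasions.
#'
#' @param test,retest Paired numeric score vectors.
#' @return List with `icc` (full [icc_absolute()] output), `pearson_r`,
#'   `spearman_rho`.
#' @export
retest_reliability <- function(test, retest) {
  list(icc = icc_absolute(test, retest),
       pearson_r = stats::cor(test, retest),
       spearman_rho = stats::cor(test, retest, method = "spearman"))
}
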