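#' @title Statistical battery for auditing batch effects
#'
#' @description
#' Tools to quantify how much batch signal a feature matrix carries:
#' feature-wise two-sample Anderson-Darling tests between batch pairs,
#' feature-wise likelihood-ratio tests for batch in a linear model with
#' biological covariates, MANOVA with Pillai's trace, the kBET
#' k-nearest-neighbour batch-mixing test, and a cross-validated
#' k-nearest-neighbour batch-prediction score (a lightweight stand-in for a
#' full machine-learning battery).
#'
#' @name evaluation
NULL

# Scholz-Stephens k-sample Anderson-Darling statistic, midrank (tie-aware)
# version, plus the standardized statistic T = (A2 - (k-1)) / sigma_N.
ad_ksample_stat <- function(samples) {
  k <- length(samples)
  n <- lengths(samples)
  N <- sum(n)
  Z <- sort(unlist(samples))
  Zstar <- unique(Z)
  lj <- findInterval(Zstar, Z) - findInterval(Zstar, Z, left.open = TRUE)
  Bj <- findInterval(Zstar, Z, left.open = TRUE) + lj / 2
  A2 <- 0
  for (i in seq_len(k)) {
    s <- sort(samples[[i]])
    right <- findInterval(Zstar, s)
    fij <- right - findInterval(Zstar, s, left.open = TRUE)
    Mij <- right - fij / 2
    inner <- lj / N * (N * Mij - Bj * n[i])^2 / (Bj * (N - Bj) - N * lj / 4)
    A2 <- A2 + sum(inner) / n[i]
  }
  A2 <- A2 * (N - 1) / N

  H <- sum(1 / n)
  h <- sum(1 / seq_len(N - 1))
  hs <- cumsum(1 / ((N - 1):2))
  g <- sum(hs / (2:(N - 1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h +
    4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma_sq <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  list(A2 = A2, T = (A2 - (k - 1)) / sqrt(sigma_sq))
}

# interpolate the published critical-value table; p clipped to [0.001, 0.25]
ad_pvalue <- function(Tstat, k) {
  m <- k - 1
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  crit <- b0 + b1 / sqrt(m) + b2 / m
  sig <- c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005, 0.001)
  if (Tstat < min(crit)) return(max(sig))
  if (Tstat > max(crit)) return(min(sig))
  fit <- stats::lm(log(sig) ~ crit + I(crit^2))
  unname(exp(stats::predict(fit, data.frame(crit = Tstat))))
}

#' Two-sample Anderson-Darling test
#'
#' Scholz-Stephens k-sample statistic with k = 2 in its midrank (tie-aware)
#' form. The asymptotic p-value interpolates the published critical-value
#' table and is therefore clipped to [0.001, 0.25]; an exact permutation
#' p-value is available for small samples.
#'
#' @param a,b numeric samples, each of size >= 5.
#' @param exact if TRUE, compute a permutation p-value instead of the
#'   interpolated asymptotic one.
#' @param n_perm number of permutations for `exact = TRUE`.
#' @return list with `statistic` (standardized), `A2` (raw), and `p`.
#' @export
ad_two_sample <- function(a, b, exact = FALSE, n_perm = 1000) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 5 || length(b) < 5)
    stop("each sample needs at least 5 observations")
  st <- ad_ksample_stat(list(a, b))
  if (exact) {
    pool <- c(a, b)
    na <- length(a)
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pool), na)
      ad_ksample_stat(list(pool[idx], pool[-idx]))$T
    })
    p <- (1 + sum(perm >= st$T)) / (n_perm + 1)
  } else {
    p <- ad_pvalue(st$T, k = 2)
  }
  list(statistic = st$T, A2 = st$A2, p = p)
}

#' Feature-wise batch likelihood-ratio tests
#'
#' For each feature, fits a Gaussian linear model with batch and biological
#' covariates and tests batch by the likelihood-ratio statistic
#' `n * ln(RSS0 / RSS1)` against a chi-squared distribution with B - 1
#' degrees of freedom. Covariate p-values come from per-coefficient t-tests
#' in the full model.
#'
#' @param Y n x p feature matrix.
#' @param X n x q covariate design (no intercept column), or NULL.
#' @param batch batch factor.
#' @return list with `batch` (data frame: feature, statistic, p, neglog10p),
#'   `covariates` (p x q matrix of t-test p-values, or NULL), and `summary`
#'   (mean and SD of -log10 batch p across features).
#' @export
featurewise_batch_lrt <- function(Y, X = NULL, batch) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- check_batch(batch, n)
  X <- check_design(X, n)
  B <- nlevels(batch)
  W1 <- cbind(stats::model.matrix(~ 0 + batch), X)
  W0 <- cbind(`(Intercept)` = rep(1, n), X)
  qr1 <- qr(W1)
  if (qr1$rank < ncol(W1))
    stop("design is rank deficient; batch and covariates are collinear")
  RSS1 <- colSums(qr.resid(qr1, Y)^2)
  RSS0 <- colSums(qr.resid(qr(W0), Y)^2)
  stat <- n * log(RSS0 / RSS1)
  p <- stats::pchisq(stat, df = B - 1, lower.tail = FALSE)
  batch_df <- data.frame(feature = colnames(Y), statistic = stat,
                         p = p, neglog10p = -log10(p), row.names = NULL)
  cov_p <- NULL
  if (!is.null(X)) {
    coefs <- qr.coef(qr1, Y)
    sigma2 <- RSS1 / (n - ncol(W1))
    xtx_inv_diag <- diag(solve(crossprod(W1)))
    rows <- (B + 1):ncol(W1)
    tvals <- coefs[rows, , drop = FALSE] /
      sqrt(outer(xtx_inv_diag[rows], sigma2))
    cov_p <- t(2 * stats::pt(-abs(tvals), df = n - ncol(W1)))
    dimnames(cov_p) <- list(colnames(Y), colnames(X))
  }
  list(batch = batch_df, covariates = cov_p,
       summary = c(mean_neglog10p = mean(batch_df$neglog10p),
                   sd_neglog10p = stats::sd(batch_df$neglog10p)))
}

#' MANOVA with Pillai's trace
#'
#' Multivariate linear model of the feature matrix on batch plus biological
#' covariates; per term, Pillai's trace `V = tr(H (H + E)^-1)` and its
#' standard F approximation.
#'
#' @param Y n x p feature matrix (needs `n > p + model df`).
#' @param X covariate design or NULL.
#' @param batch batch factor.
#' @return data frame: term, df, pillai, approx_F, num_df, den_df, p,
#'   neglog10p.
#' @export
manova_pillai <- function(Y, X = NULL, batch) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- check_batch(batch, n)
  X <- check_design(X, n)
  q <- if (is.null(X)) 0 else ncol(X)
  if (n <= ncol(Y) + q + nlevels(batch))
    stop("too few subjects for MANOVA: need n > p + model df")
  dat <- data.frame(.batch = batch)
  rhs <- ".batch"
  if (!is.null(X)) {
    dat <- cbind(dat, as.data.frame(X))
    rhs <- paste(c(".batch", colnames(X)), collapse = " + ")
  }
  dat$.Y <- Y
  if (ncol(Y) == 1) {
    # univariate reduction: V = SSH / (SSH + SSE), F and p from the ANOVA
    dat$.y <- Y[, 1]
    an <- stats::anova(stats::lm(stats::as.formula(paste(".y ~", rhs)),
                                 data = dat))
    sse <- an[nrow(an), "Sum Sq"]
    an <- an[-nrow(an), , drop = FALSE]
    out <- data.frame(term = sub("^\\.batch$", "batch", rownames(an)),
                      df = an$Df, pillai = an$`Sum Sq` / (an$`Sum Sq` + sse),
                      approx_F = an$`F value`, num_df = an$Df,
                      den_df = nrow(Y) - sum(an$Df) - 1,
                      p = an$`Pr(>F)`, row.names = NULL)
    out$neglog10p <- -log10(out$p)
    return(out)
  }
  fit <- stats::manova(stats::as.formula(paste(".Y ~", rhs)), data = dat)
  sm <- tryCatch(summary(fit, test = "Pillai")$stats,
                 error = function(e)
                   stop("MANOVA failed (singular residual matrix?): ",
                        conditionMessage(e)))
  sm <- sm[rownames(sm) != "Residuals", , drop = FALSE]
  out <- data.frame(term = sub("^\\.batch$", "batch", rownames(sm)),
                    df = sm[, "Df"], pillai = sm[, "Pillai"],
                    approx_F = sm[, "approx F"], num_df = sm[, "num Df"],
                    den_df = sm[, "den Df"], p = sm[, "Pr(>F)"],
                    row.names = NULL)
  out$neglog10p <- -log10(out$p)
  out
}

#' kBET: k-nearest-neighbour batch-mixing test
#'
#' For each observation, compares the batch composition of its k0 nearest
#' neighbours (Euclidean, on feature-standardized data) with the global
#' batch proportions by a Pearson chi-squared test. Each repeat samples a
#' subset of observations and records the fraction whose neighbourhood test
#' rejects at `alpha`; the reported rate is the mean over repeats. The
#' overall p-value compares the observed rate one-sidedly against a
#' permutation null in which batch labels are shuffled (neighbour sets are
#' label-free and stay fixed); the expected rate is the mean permuted rate.
#'
#' @param Y n x p feature matrix.
#' @param batch batch factor (>= 2 levels).
#' @param n_repeats subset repeats (default 500).
#' @param k0 neighbourhood size; default `max(10, floor(0.1 n))`.
#' @param subset_frac fraction of observations sampled per repeat.
#' @param alpha neighbourhood-level significance threshold.
#' @param n_perm permutations for the overall test.
#' @return list with `observed` (mean rejection rate), `expected`
#'   (permutation-null mean rate), `p`, `k0`, and `per_point_p`
#'   (neighbourhood chi-squared p-value per observation).
#' @export
kbet <- function(Y, batch, n_repeats = 500, k0 = NULL, subset_frac = 0.1,
                 alpha = 0.05, n_perm = 100) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- droplevels(as.factor(batch))
  B <- nlevels(batch)
  if (B < 2) stop("kBET needs at least 2 batches")
  if (is.null(k0)) k0 <- max(10L, floor(0.1 * n))
  if (k0 >= n) stop("k0 must be smaller than the number of observations")

  sds <- apply(Y, 2, stats::sd)
  Ys <- sweep(Y, 2, colMeans(Y))
  Ys[, sds > 0] <- sweep(Ys[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  dm <- as.matrix(stats::dist(Ys))
  nn <- t(apply(dm, 1, function(d) order(d)[2:(k0 + 1)]))

  pr <- as.vector(table(batch)) / n
  expected_counts <- k0 * pr
  point_p <- function(lab_int) {
    stat <- 0
    for (b in seq_len(B)) {
      cb <- rowSums(matrix(lab_int[nn] == b, n, k0))
      stat <- stat + (cb - expected_counts[b])^2 / expected_counts[b]
    }
    stats::pchisq(stat, df = B - 1, lower.tail = FALSE)
  }
  rate <- function(pv) {
    m <- ceiling(subset_frac * n)
    mean(replicate(n_repeats, mean(pv[sample.int(n, m)] < alpha)))
  }
  pv_obs <- point_p(as.integer(batch))
  observed <- rate(pv_obs)
  perm_rates <- vapply(seq_len(n_perm), function(i)
    rate(point_p(sample(as.integer(batch)))), numeric(1))
  list(observed = observed, expected = mean(perm_rates),
       p = (1 + sum(perm_rates >= observed)) / (n_perm + 1),
       k0 = k0, per_point_p = pv_obs)
}

#' Cross-validated k-nearest-neighbour batch-prediction score
#'
#' How well can batch be predicted from the features alone? Repeated
#' stratified k-fold cross-validation of a 5-nearest-neighbour classifier;
#' accuracy near the majority-class baseline indicates little usable batch
#' signal. A deliberately lightweight stand-in for a full machine-learning
#' battery.
#'
#' @param Y n x p feature matrix.
#' @param batch batch factor.
#' @param folds,repeats cross-validation layout (default 10 x 10).
#' @param k number of neighbours.
#' @return list with `accuracy` (mean CV accuracy), `baseline`
#'   (majority-class proportion), `chance` (weighted random classifier
#'   accuracy, `sum(p_c^2)` -- the level a k-nearest-neighbour classifier
#'   approaches on perfectly mixed unbalanced batches), and `per_repeat`
#'   accuracies.
#' @export
batch_prediction_score <- function(Y, batch, folds = 10, repeats = 10, k = 5) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- droplevels(as.factor(batch))
  if (any(table(batch) < folds))
    stop("every batch needs at least `folds` subjects")
  Ys <- scale(Y)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    ord <- order(batch, stats::runif(n))
    fold <- integer(n)
    fold[ord] <- rep_len(seq_len(folds), n)
    correct <- 0
    for (f in seq_len(folds)) {
      test <- fold == f
      pred <- class::knn(Ys[!test, , drop = FALSE], Ys[test, , drop = FALSE],
                         batch[!test], k = k)
      correct <- correct + sum(pred == batch[test])
    }
    acc[r] <- correct / n
  }
  list(accuracy = mean(acc),
       baseline = max(table(batch)) / n,
       chance = sum((table(batch) / n)^2),
       per_repeat = acc)
}

#' Run the full evaluation battery
#'
#' @param Y n x p feature matrix.
#' @param X covariate design or NULL.
#' @param batch batch factor.
#' @param kbet_repeats,kbet_perm,prediction_repeats sizes of the stochastic
#'   components.
#' @return object of class `harmonization_report` with blocks `ad`
#'   (Anderson-Darling mean/SD of p across features and batch pairs), `lrt`,
#'   `manova`, `kbet`, and `prediction`.
#' @export
evaluate_harmonization <- function(Y, X = NULL, batch, kbet_repeats = 500,
                                   kbet_perm = 100, prediction_repeats = 10) {
  Y <- as_feature_matrix(Y)
  batch <- check_batch(batch, nrow(Y))
  X <- check_design(X, nrow(Y))
  pairs <- utils::combn(levels(batch), 2)
  ad_p <- matrix(NA_real_, ncol(Y), ncol(pairs),
                 dimnames = list(colnames(Y),
                                 apply(pairs, 2, paste, collapse = " vs ")))
  for (j in seq_len(ncol(pairs))) {
    ia <- batch == pairs[1, j]
    ib <- batch == pairs[2, j]
    for (k in seq_len(ncol(Y)))
      ad_p[k, j] <- ad_two_sample(Y[ia, k], Y[ib, k])$p
  }
  lrt <- featurewise_batch_lrt(Y, X, batch)
  mv <- manova_pillai(Y, X, batch)
  kb <- kbet(Y, batch, n_repeats = kbet_repeats, n_perm = kbet_perm)
  pred <- batch_prediction_score(Y, batch, repeats = prediction_repeats)
  structure(list(ad = list(mean_p = mean(ad_p), sd_p = stats::sd(ad_p),
                           per_feature = ad_p),
                 lrt = lrt, manova = mv,
                 kbet = kb[c("observed", "expected", "p", "k0")],
                 prediction = pred[c("accuracy", "baseline", "chance")]),
            class = "harmonization_report")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Batch-effect evaluation report\n")
  cat(sprintf("  Anderson-Darling (feature x batch-pair): mean p %.3f (SD %.3f)\n",
              x$ad$mean_p, x$ad$sd_p))
  cat(sprintf("  Batch LRT: mean -log10 p %.2f (SD %.2f)\n",
              x$lrt$summary["mean_neglog10p"], x$lrt$summary["sd_neglog10p"]))
  b <- x$manova[x$manova$term == "batch", ]
  cat(sprintf("  MANOVA (Pillai) batch: V %.3f, -log10 p %.2f\n",
              b$pillai, b$neglog10p))
  cat(sprintf("  kBET: rejection %.3f (null expectation %.3f), p %.3f\n",
              x$kbet$observed, x$kbet$expected, x$kbet$p))
  cat(sprintf("  kNN batch prediction: accuracy %.3f (majority baseline %.3f)\n",
              x$prediction$accuracy, x$prediction$baseline))
  invisible(x)
}
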