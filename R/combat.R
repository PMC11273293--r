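#' @title ComBat empirical-Bayes location/scale batch-effect model
#'
#' @description
#' The classical ComBat model treats each feature as
#' \deqn{y_{ijk} = \alpha_k + x_{ij}' \beta_k + \gamma_{ik} + \delta_{ik} e_{ijk}}
#' where \eqn{\gamma_{ik}} is an additive (mean) batch effect and
#' \eqn{\delta_{ik}} a multiplicative batch effect on the residual scale.
#' Per-feature estimates are stabilized by empirical-Bayes shrinkage toward
#' cross-feature priors (normal for \eqn{\gamma}, inverse-gamma for
#' \eqn{\delta^2}), with prior hyperparameters estimated by method of moments
#' across features. These functions implement the full pipeline:
#' least-squares fit, standardization, moment priors, iterative conditional
#' posterior means, and adjustment (to the pooled distribution or to a chosen
#' target batch).
#'
#' The same model is reused on raw features, on CVAE latent means, and on
#' reconstruction residuals by the harmonization pipeline.
#'
#' @name combat
NULL

check_batch <- function(batch, n) {
  batch <- as.factor(batch)
  if (length(batch) != n)
    stop("batch labels must have one entry per row of the feature matrix")
  batch <- droplevels(batch)
  ni <- table(batch)
  if (any(ni < 2))
    stop("every batch must contain at least 2 subjects; too small: ",
         paste(names(ni)[ni < 2], collapse = ", "))
  batch
}

as_feature_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("feature matrix must be numeric")
  if (anyNA(Y)) stop("feature matrix contains missing values")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  Y
}

check_design <- function(X, n) {
  if (is.null(X)) return(NULL)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate design and feature matrix row counts differ")
  if (anyNA(X)) stop("covariate design contains missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

#' Least-squares stage of the ComBat model
#'
#' Fits, feature by feature, an intercept, covariate coefficients and additive
#' batch effects under the sample-size-weighted identifiability constraint
#' \eqn{\sum_i n_i \gamma_{ik} = 0}, and pools residual variances across all
#' subjects.
#'
#' @param Y numeric n x p feature matrix (subjects in rows).
#' @param X optional n x q covariate design matrix (no intercept column;
#'   categorical covariates already dummy coded).
#' @param batch factor (or coercible) of batch labels, one per subject; every
#'   level needs at least two subjects.
#' @return list with `alpha` (p intercepts), `beta` (q x p coefficients or
#'   NULL), `gamma_hat` (B x p additive batch effects, original units),
#'   `sigma_sq` (p pooled residual variances, denominator n), `n_i` (batch
#'   sizes), `batch_levels`, and `degenerate` (names of features with zero
#'   residual variance).
#' @export
fit_feature_models <- function(Y, X = NULL, batch) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- check_batch(batch, n)
  X <- check_design(X, n)
  B <- nlevels(batch)
  ni <- as.vector(table(batch))

  D <- stats::model.matrix(~ 0 + batch)
  colnames(D) <- levels(batch)
  W <- cbind(D, X)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    dropped <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("design is rank deficient (covariates collinear with batch or ",
         "each other); offending columns: ", paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrW, Y)
  batch_coef <- coefs[seq_len(B), , drop = FALSE]
  # weighted grand mean => sum_i n_i gamma_hat = 0 by construction
  alpha <- as.vector(crossprod(ni / n, batch_coef))
  gamma_hat <- sweep(batch_coef, 2, alpha)
  beta <- if (ncol(W) > B) coefs[(B + 1):ncol(W), , drop = FALSE] else NULL
  resid <- Y - W %*% coefs
  sigma_sq <- colSums(resid^2) / n
  names(alpha) <- names(sigma_sq) <- colnames(Y)
  rownames(gamma_hat) <- levels(batch)

  list(alpha = alpha, beta = beta, gamma_hat = gamma_hat,
       sigma_sq = sigma_sq, n_i = stats::setNames(ni, levels(batch)),
       batch_levels = levels(batch),
       degenerate = colnames(Y)[sigma_sq <= .Machine$double.eps])
}

stand_mean_matrix <- function(fit, X, n) {
  M <- matrix(fit$alpha, n, length(fit$alpha), byrow = TRUE)
  if (!is.null(fit$beta)) M <- M + X %*% fit$beta
  M
}

#' Standardize features to pooled residual sigma units
#'
#' Computes \eqn{Z_{ijk} = (y_{ijk} - \hat\alpha_k - x_{ij}'\hat\beta_k)/\hat\sigma_k}.
#' On this scale the within-batch mean of Z equals
#' \eqn{\hat\gamma_{ik}/\hat\sigma_k}.
#'
#' @param Y,X,batch as in [fit_feature_models()].
#' @param fit the least-squares stage returned by [fit_feature_models()].
#' @return n x p standardized matrix.
#' @export
standardize_features <- function(Y, fit, X = NULL, batch) {
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  X <- check_design(X, n)
  if (length(fit$degenerate))
    stop("cannot standardize: zero pooled residual variance for feature(s) ",
         paste(fit$degenerate, collapse = ", "))
  Z <- (Y - stand_mean_matrix(fit, X, n)) /
    matrix(sqrt(fit$sigma_sq), n, ncol(Y), byrow = TRUE)
  Z
}

#' Method-of-moments prior hyperparameters for empirical Bayes
#'
#' For each batch the additive effects across features define a normal prior
#' (mean `gamma_bar`, variance `tau_sq`); the multiplicative effects define an
#' inverse-gamma prior whose shape/scale `(lambda, theta)` solve the
#' mean/variance moment equations \eqn{m = \theta/(\lambda-1)},
#' \eqn{v = \theta^2/((\lambda-1)^2(\lambda-2))}, i.e.
#' \eqn{\lambda = m^2/v + 2}, \eqn{\theta = m(\lambda - 1)}.
#'
#' @param gamma_hat B x p additive batch effects (standardized scale).
#' @param delta_sq_hat B x p multiplicative batch effects.
#' @return list with per-batch vectors `gamma_bar`, `tau_sq`, `lambda`,
#'   `theta`, and logical `scale_eb` flagging batches where the inverse-gamma
#'   moments are usable (undefined or degenerate moments disable shrinkage of
#'   the scale component for that batch, with a warning).
#' @export
estimate_priors <- function(gamma_hat, delta_sq_hat) {
  if (ncol(gamma_hat) < 2)
    stop("cross-feature moment priors need at least 2 features")
  gamma_bar <- rowMeans(gamma_hat)
  tau_sq <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta_sq_hat)
  v <- apply(delta_sq_hat, 1, stats::var)
  scale_eb <- rep(TRUE, nrow(gamma_hat))
  lambda <- m^2 / v + 2
  theta <- m * (lambda - 1)
  if (any(v == 0)) {
    warning("zero cross-feature variance of delta^2 in batch(es) ",
            paste(rownames(gamma_hat)[v == 0], collapse = ", "),
            "; scale shrinkage disabled there")
    scale_eb[v == 0] <- FALSE
  }
  bad <- scale_eb & lambda <= 2
  if (any(bad)) {
    warning("inverse-gamma prior has undefined variance (shape <= 2) in ",
            "batch(es) ", paste(rownames(gamma_hat)[bad], collapse = ", "),
            "; scale shrinkage disabled there")
    scale_eb[bad] <- FALSE
  }
  list(gamma_bar = gamma_bar, tau_sq = tau_sq,
       lambda = lambda, theta = theta, scale_eb = scale_eb)
}

#' Iterative conditional posterior means for batch effects
#'
#' Alternates the conditional posterior-mean updates
#' \deqn{\gamma^*_{ik} = \frac{n_i \bar\tau^2_i \hat\gamma_{ik} + \delta^{*2}_{ik} \bar\gamma_i}{n_i \bar\tau^2_i + \delta^{*2}_{ik}}}
#' \deqn{\delta^{*2}_{ik} = \frac{\theta_i + \tfrac12 \sum_j (Z_{ijk} - \gamma^*_{ik})^2}{n_i/2 + \lambda_i - 1}}
#' until the maximum absolute parameter change falls below `tol`.
#'
#' @param Z standardized n x p matrix (from [standardize_features()]).
#' @param batch batch factor aligned with Z rows.
#' @param gamma_hat,delta_sq_hat per-batch raw estimates on the standardized
#'   scale.
#' @param priors output of [estimate_priors()].
#' @param tol convergence tolerance on the maximum absolute change.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return list with `gamma_star` and `delta_sq_star` (B x p).
#' @export
eb_posterior <- function(Z, batch, gamma_hat, delta_sq_hat, priors,
                         tol = 1e-4, max_iter = 500) {
  stopifnot(tol > 0)
  batch <- droplevels(as.factor(batch))
  B <- nrow(gamma_hat)
  if (B != nlevels(batch))
    stop("gamma_hat must have one row per batch level")
  gamma_star <- gamma_hat
  delta_sq_star <- delta_sq_hat
  for (i in seq_len(B)) {
    Zi <- Z[batch == levels(batch)[i], , drop = FALSE]
    n_i <- nrow(Zi)
    g_hat <- gamma_hat[i, ]
    d_hat <- delta_sq_hat[i, ]
    t2 <- priors$tau_sq[i]
    gbar <- priors$gamma_bar[i]
    g_old <- g_hat
    d_old <- d_hat
    use_scale <- priors$scale_eb[i]
    for (it in seq_len(max_iter + 1L)) {
      g_new <- (n_i * t2 * g_hat + d_old * gbar) / (n_i * t2 + d_old)
      if (use_scale) {
        ss <- colSums((Zi - matrix(g_new, n_i, ncol(Z), byrow = TRUE))^2)
        d_new <- (priors$theta[i] + 0.5 * ss) /
          (n_i / 2 + priors$lambda[i] - 1)
      } else {
        d_new <- d_hat
      }
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
      if (it > max_iter)
        stop("empirical Bayes iteration did not converge in ", max_iter,
             " iterations (last max change ", format(change), ")")
    }
    gamma_star[i, ] <- g_old
    delta_sq_star[i, ] <- d_old
  }
  if (any(delta_sq_star <= 0))
    stop("non-positive posterior delta^2; data degenerate")
  list(gamma_star = gamma_star, delta_sq_star = delta_sq_star)
}

#' Fit the full ComBat model
#'
#' Chains the least-squares stage, standardization, per-batch moments of the
#' standardized data, method-of-moments priors and the iterative posterior
#' means. Batch-effect estimates (`gamma_hat`, `gamma_star`) are stored on
#' the standardized (pooled-sigma-unit) scale; multiply by `sqrt(sigma_sq)`
#' for original units.
#'
#' @inheritParams fit_feature_models
#' @param eb logical; with `FALSE` the shrinkage stage is skipped and the
#'   starred estimates equal the raw per-batch moments.
#' @param tol,max_iter passed to [eb_posterior()].
#' @return object of class `combat_model`.
#' @export
combat_fit <- function(Y, X = NULL, batch, eb = TRUE,
                       tol = 1e-4, max_iter = 500) {
  Y <- as_feature_matrix(Y)
  batch <- check_batch(batch, nrow(Y))
  if (nlevels(batch) < 2)
    stop("need at least 2 batches to harmonize")
  X <- check_design(X, nrow(Y))
  fit <- fit_feature_models(Y, X, batch)
  if (length(fit$degenerate))
    stop("constant (zero residual variance) feature(s): ",
         paste(fit$degenerate, collapse = ", "))
  Z <- standardize_features(Y, fit, X, batch)
  B <- nlevels(batch)
  p <- ncol(Y)
  gamma_hat <- matrix(NA_real_, B, p, dimnames = list(levels(batch), colnames(Y)))
  delta_sq_hat <- gamma_hat
  for (i in seq_len(B)) {
    Zi <- Z[batch == levels(batch)[i], , drop = FALSE]
    mu_i <- colMeans(Zi)
    gamma_hat[i, ] <- mu_i
    # within-batch variance with denominator n_i (reference convention)
    delta_sq_hat[i, ] <- colMeans(sweep(Zi, 2, mu_i)^2)
  }
  if (eb) {
    priors <- estimate_priors(gamma_hat, delta_sq_hat)
    post <- eb_posterior(Z, batch, gamma_hat, delta_sq_hat, priors,
                         tol = tol, max_iter = max_iter)
    gamma_star <- post$gamma_star
    delta_sq_star <- post$delta_sq_star
  } else {
    priors <- NULL
    gamma_star <- gamma_hat
    delta_sq_star <- delta_sq_hat
  }
  structure(list(alpha = fit$alpha, beta = fit$beta,
                 sigma_sq = fit$sigma_sq,
                 gamma_hat = gamma_hat, gamma_star = gamma_star,
                 delta_sq_hat = delta_sq_hat, delta_sq_star = delta_sq_star,
                 priors = priors, eb = eb,
                 n_i = fit$n_i, batch_levels = levels(batch),
                 feature_names = colnames(Y),
                 covariate_names = colnames(X)),
            class = "combat_model")
}

#' Remove (or retarget) estimated batch effects
#'
#' With `target = "pooled"` each observation is mapped to the pooled
#' distribution:
#' \deqn{y^{ComBat}_{ijk} = \hat\alpha_k + x_{ij}'\hat\beta_k + \frac{\hat\sigma_k}{\delta^*_{ik}}\,(Z_{ijk} - \gamma^*_{ik}).}
#' With `target = b` the batch-b effects are re-added after pooling, so the
#' output lives in batch b's estimated distribution (the counterfactual used
#' by the decoder-retargeting step of the harmonization pipeline). With
#' `target = "own"` each subject is mapped back to its own batch, which is the
#' identity.
#'
#' @param model a `combat_model`.
#' @param Y,X,batch data aligned as at fit time; batch levels must have been
#'   seen during fitting.
#' @param target `"pooled"`, `"own"`, or one of the fitted batch levels.
#' @return adjusted n x p matrix.
#' @export
combat_apply <- function(model, Y, X = NULL, batch, target = "pooled") {
  stopifnot(inherits(model, "combat_model"))
  Y <- as_feature_matrix(Y)
  n <- nrow(Y)
  batch <- droplevels(as.factor(batch))
  if (length(batch) != n) stop("batch labels misaligned with feature matrix")
  unseen <- setdiff(levels(batch), model$batch_levels)
  if (length(unseen))
    stop("batch level(s) not seen at fit time: ", paste(unseen, collapse = ", "))
  X <- check_design(X, n)
  if (is.null(model$beta) != is.null(X) ||
      (!is.null(X) && ncol(X) != nrow(model$beta)))
    stop("covariate design does not match the fitted model schema")

  sm <- stand_mean_matrix(model, X, n)
  sig <- matrix(sqrt(model$sigma_sq), n, ncol(Y), byrow = TRUE)
  Z <- (Y - sm) / sig
  idx <- match(as.character(batch), model$batch_levels)
  Zadj <- (Z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_sq_star[idx, , drop = FALSE])
  if (identical(target, "pooled")) {
    out <- sm + sig * Zadj
  } else {
    tgt <- if (identical(target, "own")) idx else {
      if (!target %in% model$batch_levels)
        stop("target batch '", target, "' was not seen at fit time")
      rep(match(target, model$batch_levels), n)
    }
    out <- sm + sig * (sqrt(model$delta_sq_star[tgt, , drop = FALSE]) * Zadj +
                         model$gamma_star[tgt, , drop = FALSE])
  }
  dimnames(out) <- dimnames(Y)
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat model:", length(x$alpha), "features,",
      length(x$batch_levels), "batches (",
      paste(paste0(x$batch_levels, "=", x$n_i), collapse = ", "), ")\n")
  cat("  covariates:",
      if (is.null(x$beta)) "none" else paste(x$covariate_names, collapse = ", "),
      "\n  empirical Bayes shrinkage:", if (x$eb) "on" else "off", "\n")
  invisible(x)
}
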