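#' @title CVAE + ComBat harmonization pipeline
#'
#' @description
#' The pipeline (1) standardizes features and min-max scales covariates,
#' (2) trains the CVAE, (3) computes every subject's noiseless latent mean,
#' (4) fits ComBat on the latent means (batch + biological covariates),
#' (5) computes noiseless reconstructions under each subject's observed
#' batch and fits ComBat on the reconstruction residuals, and at apply time
#' (6) decodes harmonized latent means under the target batch indicator,
#' adds the harmonized residuals and inverts the feature normalization.
#' Because residuals are carried through, self-harmonization (every subject
#' mapped back to its own batch) is the identity.
#'
#' @name harmonizer
NULL

#' Normalize features and covariates
#'
#' Features are standardized to mean 0 / variance 1 across subjects;
#' covariate columns are linearly mapped to the [0, 1] range. Both
#' transforms are stored for exact inversion and reuse on new subjects.
#'
#' @param Y n x p feature matrix.
#' @param X n x q covariate design matrix (may be NULL).
#' @return list with `Y_norm`, `X_norm` and `transforms` (feature mean/SD,
#'   covariate min/max).
#' @export
normalize_inputs <- function(Y, X = NULL) {
  Y <- as_feature_matrix(Y)
  f_mean <- colMeans(Y)
  f_sd <- apply(Y, 2, stats::sd)
  if (any(f_sd == 0))
    stop("constant feature column(s): ",
         paste(colnames(Y)[f_sd == 0], collapse = ", "))
  Y_norm <- sweep(sweep(Y, 2, f_mean), 2, f_sd, "/")
  X_norm <- NULL
  c_min <- c_max <- NULL
  if (!is.null(X)) {
    X <- check_design(X, nrow(Y))
    c_min <- apply(X, 2, min)
    c_max <- apply(X, 2, max)
    if (any(c_max == c_min))
      stop("constant covariate column(s): ",
           paste(colnames(X)[c_max == c_min], collapse = ", "))
    X_norm <- sweep(sweep(X, 2, c_min), 2, c_max - c_min, "/")
  }
  list(Y_norm = Y_norm, X_norm = X_norm,
       transforms = list(feature_mean = f_mean, feature_sd = f_sd,
                         cov_min = c_min, cov_max = c_max))
}

apply_feature_norm <- function(Y, tr)
  sweep(sweep(Y, 2, tr$feature_mean), 2, tr$feature_sd, "/")

invert_feature_norm <- function(Y_norm, tr)
  sweep(sweep(Y_norm, 2, tr$feature_sd, "*"), 2, tr$feature_mean, "+")

apply_cov_norm <- function(X, tr, warn_extrapolate = TRUE) {
  if (is.null(X)) return(NULL)
  X_norm <- sweep(sweep(X, 2, tr$cov_min), 2, tr$cov_max - tr$cov_min, "/")
  if (warn_extrapolate && (any(X_norm < 0) || any(X_norm > 1)))
    warning("covariate values outside the training range; extrapolating")
  X_norm
}

batch_onehot <- function(batch, levels) {
  M <- matrix(0, length(batch), length(levels),
              dimnames = list(NULL, levels))
  M[cbind(seq_along(batch), match(as.character(batch), levels))] <- 1
  M
}

#' Fit the full harmonization model
#'
#' @param Y n x p feature matrix (raw units).
#' @param X n x q numeric covariate design (no intercept; categorical
#'   covariates dummy coded), or NULL.
#' @param batch batch labels (factor, >= 2 levels, each with >= 2 subjects).
#' @param cvae_cfg optional [cvae_config()] override.
#' @param training a [training_config()].
#' @param eb logical, empirical-Bayes shrinkage in both ComBat stages.
#' @param reference_batch batch level whose indicator the decoder receives
#'   when harmonizing to the pooled distribution; defaults to the largest
#'   batch.
#' @return object of class `vaecombat_model` bundling the normalization
#'   transforms, trained CVAE, latent-space ComBat model, residual ComBat
#'   model and the training loss trace.
#' @export
vaecombat_fit <- function(Y, X = NULL, batch, cvae_cfg = NULL,
                          training = training_config(), eb = TRUE,
                          reference_batch = NULL) {
  Y <- as_feature_matrix(Y)
  batch <- check_batch(batch, nrow(Y))
  if (nlevels(batch) < 2) stop("need at least 2 batches to harmonize")
  X <- check_design(X, nrow(Y))
  norm <- normalize_inputs(Y, X)
  Bm <- batch_onehot(batch, levels(batch))
  q <- if (is.null(X)) 0L else ncol(X)
  if (is.null(cvae_cfg))
    cvae_cfg <- cvae_config(ncol(Y), q, nlevels(batch))

  trained <- train_cvae(norm$Y_norm, norm$X_norm, Bm, cvae_cfg, training)
  enc <- cvae_encode(trained$params, norm$Y_norm, norm$X_norm, Bm)
  mu <- enc$mu
  colnames(mu) <- paste0("latent", seq_len(ncol(mu)))
  if (all(apply(mu, 2, stats::sd) < 1e-3))
    warning("latent means are nearly constant across subjects (posterior ",
            "collapse / KL vanishing); harmonization will rely on the ",
            "residual ComBat stage")
  latent_combat <- combat_fit(mu, norm$X_norm, batch, eb = eb)
  recon <- cvae_decode(trained$params, mu, norm$X_norm, Bm)
  residual <- norm$Y_norm - recon
  colnames(residual) <- colnames(Y)
  residual_combat <- combat_fit(residual, norm$X_norm, batch, eb = eb)

  if (is.null(reference_batch))
    reference_batch <- names(which.max(table(batch)))
  if (!reference_batch %in% levels(batch))
    stop("reference_batch must be one of the fitted batch levels")

  structure(list(transforms = norm$transforms,
                 cvae = trained$params, cvae_config = cvae_cfg,
                 latent_combat = latent_combat,
                 residual_combat = residual_combat,
                 trace = trained$trace,
                 batch_levels = levels(batch),
                 feature_names = colnames(Y),
                 covariate_names = colnames(X),
                 reference_batch = reference_batch,
                 eb = eb, training = training),
            class = "vaecombat_model")
}

#' Harmonize a feature matrix with a fitted model
#'
#' For `target_batch = "pooled"` (the default) latent means and residuals
#' are ComBat-adjusted to the pooled distribution and the decoder receives
#' the model's reference-batch indicator, so every subject is decoded under
#' identical batch conditioning. A specific batch level retargets all three
#' components to that batch's distribution; `"own"` maps every subject back
#' to its own batch and returns the input unchanged (self-harmonization
#' identity).
#'
#' @param model a [vaecombat_fit()] model.
#' @param Y,X,batch data aligned as at fit time (columns must match the
#'   training schema; batch levels must have been seen at fit time).
#' @param target_batch `"pooled"`, `"own"`, or a fitted batch level.
#' @return harmonized n x p matrix in the original feature units.
#' @export
vaecombat_apply <- function(model, Y, X = NULL, batch,
                            target_batch = "pooled") {
  stopifnot(inherits(model, "vaecombat_model"))
  Y <- as_feature_matrix(Y)
  if (!identical(colnames(Y), model$feature_names))
    stop("feature columns do not match the training schema")
  X <- check_design(X, nrow(Y))
  if (!identical(colnames(X), model$covariate_names))
    stop("covariate columns do not match the training schema")
  batch <- droplevels(as.factor(batch))
  unseen <- setdiff(levels(batch), model$batch_levels)
  if (length(unseen))
    stop("batch level(s) not seen at fit time: ", paste(unseen, collapse = ", "))
  if (!identical(target_batch, "pooled") && !identical(target_batch, "own") &&
      !target_batch %in% model$batch_levels)
    stop("target_batch must be 'pooled', 'own', or a fitted batch level")

  tr <- model$transforms
  Y_norm <- apply_feature_norm(Y, tr)
  X_norm <- apply_cov_norm(X, tr)
  Bm_obs <- batch_onehot(batch, model$batch_levels)

  enc <- cvae_encode(model$cvae, Y_norm, X_norm, Bm_obs)
  mu <- enc$mu
  colnames(mu) <- model$latent_combat$feature_names
  recon_obs <- cvae_decode(model$cvae, mu, X_norm, Bm_obs)
  residual <- Y_norm - recon_obs
  colnames(residual) <- colnames(Y)

  mu_c <- combat_apply(model$latent_combat, mu, X_norm, batch,
                       target = target_batch)
  res_c <- combat_apply(model$residual_combat, residual, X_norm, batch,
                        target = target_batch)
  dec_level <- switch(target_batch,
                      pooled = rep(model$reference_batch, nrow(Y)),
                      own = as.character(batch),
                      rep(target_batch, nrow(Y)))
  Bm_target <- batch_onehot(dec_level, model$batch_levels)
  Y_harm_norm <- cvae_decode(model$cvae, mu_c, X_norm, Bm_target) + res_c
  out <- invert_feature_norm(Y_harm_norm, tr)
  dimnames(out) <- dimnames(Y)
  out
}

#' One-call internal harmonization
#'
#' Convenience wrapper: fit on the full dataset and harmonize it to the
#' pooled distribution.
#'
#' @inheritParams vaecombat_fit
#' @param ... passed to [vaecombat_fit()].
#' @return list with `harmonized` (n x p matrix) and `model`.
#' @export
vaecombat <- function(Y, X = NULL, batch, ...) {
  model <- vaecombat_fit(Y, X, batch, ...)
  list(harmonized = vaecombat_apply(model, Y, X, batch), model = model)
}

#' External harmonization by stratified cross-fitting
#'
#' Subjects are partitioned into `k` batch-stratified folds; each fold is
#' harmonized by a model trained on the other folds (with the AdamW
#' optimizer, the external-mode default), so every subject is harmonized
#' exactly once by a model that never saw it.
#'
#' @inheritParams vaecombat_fit
#' @param k number of folds; every batch must have at least `k` subjects so
#'   each training fold contains every batch.
#' @param seed master seed; fold assignment and per-fold training seeds
#'   derive from it.
#' @return list with `harmonized` (row-aligned with the input), `folds`
#'   (fold id per subject) and `models` (the k fitted models).
#' @export
vaecombat_crossfit <- function(Y, X = NULL, batch, k = 10,
                               cvae_cfg = NULL,
                               training = training_config(optimizer = "adamw"),
                               eb = TRUE, seed = 1L) {
  Y <- as_feature_matrix(Y)
  batch <- check_batch(batch, nrow(Y))
  X <- check_design(X, nrow(Y))
  ni <- table(batch)
  if (any(ni < k))
    stop("every batch needs at least k = ", k, " subjects for ", k,
         "-fold cross-fitting; too small: ",
         paste(names(ni)[ni < k], collapse = ", "))
  n <- nrow(Y)
  set.seed(seed)
  # shuffle within batch, then cycle fold labels through the batch-ordered
  # sequence: per-batch and overall fold sizes each differ by at most 1
  ord <- order(batch, stats::runif(n))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)

  harmonized <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    cfg_f <- training
    cfg_f$seed <- as.integer(seed + f)
    models[[f]] <- vaecombat_fit(Y[!test, , drop = FALSE],
                                 if (!is.null(X)) X[!test, , drop = FALSE],
                                 batch[!test], cvae_cfg = cvae_cfg,
                                 training = cfg_f, eb = eb)
    harmonized[test, ] <- vaecombat_apply(models[[f]],
                                          Y[test, , drop = FALSE],
                                          if (!is.null(X)) X[test, , drop = FALSE],
                                          batch[test])
  }
  list(harmonized = harmonized, folds = folds, models = models)
}

#' @export
print.vaecombat_model <- function(x, ...) {
  cat("CVAE+ComBat harmonization model\n")
  cat("  features:", length(x$feature_names),
      " covariates:", length(x$covariate_names) %||% 0,
      " batches:", paste(x$batch_levels, collapse = ", "), "\n")
  cat("  latent dimensions:", x$cvae_config$latent_dim,
      " hidden ladder:", paste(x$cvae_config$hidden_sizes, collapse = "-"), "\n")
  cat("  reference batch (pooled decoding):", x$reference_batch,
      "  EB shrinkage:", if (x$eb) "on" else "off", "\n")
  ft <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final epoch losses: reconstruction %.2f, prior %.2f (lambda %.4g)\n",
              ft$reconstruction, ft$prior, ft$lambda))
  invisible(x)
}
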