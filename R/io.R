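#' @title Reading datasets, writing results, and model persistence
#' @name io
NULL

MODEL_SCHEMA_VERSION <- "1.0"

#' Build a numeric covariate design from a covariate data frame
#'
#' Continuous columns pass through; factors/characters are dummy coded with
#' the first level as reference (regression identifiability). Level orders
#' are recorded so apply-time data can be encoded identically.
#'
#' @param covariates data frame of biological covariates.
#' @param levels optional recorded level order from a previous call.
#' @return numeric matrix with attribute `"levels"`.
#' @export
build_design <- function(covariates, levels = NULL) {
  cols <- list()
  lev <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      lv <- if (!is.null(levels) && nm %in% names(levels)) levels[[nm]]
            else if (is.factor(v)) base::levels(v) else sort(unique(as.character(v)))
      v <- factor(as.character(v), levels = lv)
      if (anyNA(v)) stop("covariate '", nm, "' has values outside the ",
                         "recorded levels")
      lev[[nm]] <- lv
      if (length(lv) > 1) {
        M <- stats::model.matrix(~ v)[, -1, drop = FALSE]
        colnames(M) <- paste0(nm, lv[-1])
        cols[[nm]] <- M
      }
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "levels") <- lev
  X
}

#' Read an aligned dataset from delimited text files
#'
#' The features file holds one row per subject (ID column plus numeric
#' feature columns); the covariates file holds the ID column, the batch
#' column and biological covariates. Rows are realigned by ID, which must
#' match one-to-one.
#'
#' @param features_file,covariates_file paths to delimited text files with
#'   header rows.
#' @param batch_col name of the batch column in the covariates file.
#' @param id_col name of the shared subject-ID column.
#' @param sep field separator (declared, not sniffed): `","` or `"\t"`.
#' @return list with `Y` (feature matrix), `covariates` (data frame without
#'   ID/batch), `X` (numeric design from [build_design()]), and `batch`
#'   (factor).
#' @export
read_dataset <- function(features_file, covariates_file, batch_col = "batch",
                         id_col = "id", sep = ",") {
  feat <- utils::read.table(features_file, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  cov <- utils::read.table(covariates_file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in c(id_col)) {
    if (!nm %in% names(feat)) stop("features file lacks ID column '", nm, "'")
    if (!nm %in% names(cov)) stop("covariates file lacks ID column '", nm, "'")
  }
  if (!batch_col %in% names(cov))
    stop("covariates file lacks batch column '", batch_col, "'")
  ids <- as.character(feat[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate subject IDs in features file")
  cov_ids <- as.character(cov[[id_col]])
  if (anyDuplicated(cov_ids)) stop("duplicate subject IDs in covariates file")
  if (!setequal(ids, cov_ids))
    stop("subject IDs do not match between features and covariates files")
  cov <- cov[match(ids, cov_ids), , drop = FALSE]

  Y <- as.matrix(feat[, setdiff(names(feat), id_col), drop = FALSE])
  if (!is.numeric(Y)) {
    bad <- which(!vapply(feat[setdiff(names(feat), id_col)], is.numeric,
                         logical(1)))
    stop("non-numeric feature column(s): ",
         paste(names(bad), collapse = ", "))
  }
  if (anyNA(Y)) {
    w <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop("missing feature value at row ", ids[w[1]], ", column ",
         colnames(Y)[w[2]])
  }
  rownames(Y) <- ids
  batch <- factor(cov[[batch_col]])
  covariates <- cov[, setdiff(names(cov), c(id_col, batch_col)), drop = FALSE]
  if (anyNA(covariates)) {
    w <- which(vapply(covariates, anyNA, logical(1)))
    stop("missing covariate value(s) in column(s): ",
         paste(names(covariates)[w], collapse = ", "))
  }
  X <- if (ncol(covariates)) build_design(covariates) else NULL
  list(Y = Y, covariates = covariates, X = X, batch = batch, ids = ids)
}

#' Write a feature matrix as delimited text
#'
#' Deterministic column order (ID first, then features in matrix order).
#'
#' @param Y feature matrix with row names as subject IDs.
#' @param file output path.
#' @param id_col ID column name.
#' @param sep field separator.
#' @export
write_features <- function(Y, file, id_col = "id", sep = ",") {
  df <- data.frame(rownames(Y) %||% seq_len(nrow(Y)), Y,
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

flatten_for_json <- function(x) {
  if (is.matrix(x)) list(.matrix = TRUE, dim = dim(x),
                         dimnames = dimnames(x), data = as.vector(x))
  else if (is.list(x) && !is.data.frame(x)) lapply(x, flatten_for_json)
  else x
}

unflatten_from_json <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    M <- matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
    if (!is.null(x$dimnames))
      dimnames(M) <- lapply(x$dimnames, function(d) unlist(d) %||% NULL)
    M
  } else if (is.list(x)) lapply(x, unflatten_from_json)
  else x
}

#' Save a fitted harmonization model to a versioned text archive
#'
#' Flat key-to-array JSON; matrices are stored with dimensions and
#' dimnames, so a reloaded model reproduces harmonized output exactly.
#'
#' @param model a `vaecombat_model`.
#' @param file output path (JSON).
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "vaecombat_model"))
  cvae <- model$cvae
  payload <- list(
    schema = "vaecombat_model",
    schema_version = MODEL_SCHEMA_VERSION,
    transforms = flatten_for_json(model$transforms),
    cvae_config = unclass(model$cvae_config),
    cvae = flatten_for_json(lapply(unclass(cvae), identity)),
    latent_combat = flatten_for_json(unclass(model$latent_combat)),
    residual_combat = flatten_for_json(unclass(model$residual_combat)),
    batch_levels = model$batch_levels,
    feature_names = model$feature_names,
    covariate_names = model$covariate_names,
    reference_batch = model$reference_batch,
    eb = model$eb,
    training = unclass(model$training))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(file)
}

restore_combat <- function(x) {
  x <- unflatten_from_json(x)
  for (nm in c("alpha", "sigma_sq", "n_i"))
    x[[nm]] <- unlist(x[[nm]])
  for (nm in c("gamma_bar", "tau_sq", "lambda", "theta", "scale_eb"))
    if (!is.null(x$priors)) x$priors[[nm]] <- unlist(x$priors[[nm]])
  x$batch_levels <- unlist(x$batch_levels)
  x$feature_names <- unlist(x$feature_names)
  x$covariate_names <- unlist(x$covariate_names)
  class(x) <- "combat_model"
  x
}

#' Load a saved harmonization model
#'
#' @param file path written by [save_model()]; mismatched schema versions
#'   are refused.
#' @return a `vaecombat_model`.
#' @export
load_model <- function(file) {
  payload <- jsonlite::read_json(file)
  if (!identical(payload$schema, "vaecombat_model"))
    stop("not a harmonization model archive")
  if (!identical(payload$schema_version, MODEL_SCHEMA_VERSION))
    stop("model archive schema version ", payload$schema_version,
         " does not match supported version ", MODEL_SCHEMA_VERSION)
  cfg <- payload$cvae_config
  cfg <- cvae_config(cfg$p, cfg$q, cfg$batch_dim,
                     latent_dim = cfg$latent_dim,
                     hidden_sizes = unlist(cfg$hidden_sizes))
  cvae <- unflatten_from_json(payload$cvae)
  # bias vectors round-trip as lists
  cvae <- lapply(cvae, function(x) if (is.list(x)) unlist(x) else x)
  attr(cvae, "config") <- cfg
  class(cvae) <- "cvae_params"
  tr <- unflatten_from_json(payload$transforms)
  tr <- lapply(tr, function(x) if (is.list(x)) unlist(x) else x)
  tcfg <- payload$training
  training <- training_config(tcfg$lambda_final, tcfg$pretrain_epochs,
                              tcfg$cyclic_epochs, tcfg$cycle_length,
                              tcfg$final_epochs, tcfg$schedule,
                              tcfg$optimizer, tcfg$learning_rate,
                              tcfg$weight_decay, tcfg$minibatch_size,
                              tcfg$seed)
  structure(list(transforms = tr, cvae = cvae, cvae_config = cfg,
                 latent_combat = restore_combat(payload$latent_combat),
                 residual_combat = restore_combat(payload$residual_combat),
                 trace = NULL,
                 batch_levels = unlist(payload$batch_levels),
                 feature_names = unlist(payload$feature_names),
                 covariate_names = unlist(payload$covariate_names),
                 reference_batch = payload$reference_batch,
                 eb = payload$eb, training = training),
            class = "vaecombat_model")
}

#' Write an evaluation report as JSON
#'
#' @param report a `harmonization_report`.
#' @param file output path.
#' @export
report_to_json <- function(report, file) {
  out <- list(anderson_darling = report$ad[c("mean_p", "sd_p")],
              linear_regression = list(
                batch = report$lrt$summary,
                per_feature = report$lrt$batch),
              manova = report$manova,
              kbet = report$kbet,
              batch_prediction = report$prediction)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' Write an evaluation report as Markdown
#'
#' @param report a `harmonization_report`.
#' @param file output path.
#' @export
report_to_markdown <- function(report, file) {
  b <- report$manova[report$manova$term == "batch", ]
  lines <- c(
    "# Batch-effect evaluation report", "",
    "## Linear regression (feature-wise batch LRT)",
    sprintf("- mean -log10 p: %.3f (SD %.3f)",
            report$lrt$summary["mean_neglog10p"],
            report$lrt$summary["sd_neglog10p"]), "",
    "## MANOVA (Pillai's trace)",
    sprintf("- batch: V = %.4f, -log10 p = %.3f", b$pillai, b$neglog10p), "",
    "## Anderson-Darling (feature x batch-pair)",
    sprintf("- mean p: %.3f (SD %.3f)", report$ad$mean_p, report$ad$sd_p), "",
    "## kBET",
    sprintf("- rejection rate: %.3f (null expectation %.3f), p = %.3f",
            report$kbet$observed, report$kbet$expected, report$kbet$p), "",
    "## Batch prediction (kNN)",
    sprintf("- CV accuracy: %.3f (majority baseline %.3f)",
            report$prediction$accuracy, report$prediction$baseline))
  writeLines(lines, file)
  invisible(file)
}
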