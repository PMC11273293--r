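#' @title CVAE optimization with cyclic KL annealing
#'
#' @description
#' Training runs for 40 epochs by default: 5 pre-training epochs with the KL
#' weight at zero, 30 epochs of cyclic annealing in which the weight ramps
#' linearly from 0 to its final value over each 5-epoch cycle, and 5 final
#' epochs at the final value. The cyclic ramp exists to escape posterior
#' collapse (KL vanishing): early low-weight phases let the decoder learn to
#' use the latent code before the prior is enforced.
#'
#' @name training
NULL

#' Training configuration
#'
#' @param lambda_final final KL weight (default 0.1).
#' @param pretrain_epochs,cyclic_epochs,cycle_length,final_epochs phase
#'   lengths of the annealing schedule (defaults 5 / 30 / 5 / 5);
#'   `cyclic_epochs` must be divisible by `cycle_length`.
#' @param schedule `"cyclic"` or `"constant"` (the latter holds
#'   `lambda_final` for all epochs).
#' @param optimizer `"adam"` (internal harmonization) or `"adamw"` (external
#'   harmonization; decoupled weight decay).
#' @param learning_rate Adam step size (default 0.01).
#' @param weight_decay AdamW decoupled decay (default 0.01, the conventional
#'   default; recorded in the loss-trace header).
#' @param minibatch_size subjects per minibatch (default 64; a short final
#'   minibatch is kept).
#' @param seed master seed governing initialization, per-epoch shuffling and
#'   the reparameterization draws.
#' @return object of class `training_config`.
#' @export
training_config <- function(lambda_final = 0.1, pretrain_epochs = 5,
                            cyclic_epochs = 30, cycle_length = 5,
                            final_epochs = 5,
                            schedule = c("cyclic", "constant"),
                            optimizer = c("adam", "adamw"),
                            learning_rate = 0.01, weight_decay = 0.01,
                            minibatch_size = 64, seed = 1L) {
  schedule <- match.arg(schedule)
  optimizer <- match.arg(optimizer)
  stopifnot(lambda_final >= 0, pretrain_epochs > 0, cyclic_epochs > 0,
            cycle_length > 0, final_epochs > 0, learning_rate > 0,
            weight_decay >= 0, minibatch_size >= 1)
  if (cyclic_epochs %% cycle_length != 0)
    stop("cyclic_epochs must be divisible by cycle_length")
  structure(list(lambda_final = lambda_final,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 cyclic_epochs = as.integer(cyclic_epochs),
                 cycle_length = as.integer(cycle_length),
                 final_epochs = as.integer(final_epochs),
                 schedule = schedule, optimizer = optimizer,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 minibatch_size = as.integer(minibatch_size),
                 seed = as.integer(seed)),
            class = "training_config")
}

total_epochs <- function(config)
  config$pretrain_epochs + config$cyclic_epochs + config$final_epochs

#' KL weight for a given epoch
#'
#' Cyclic schedule: zero during pre-training; within each annealing cycle the
#' weight rises linearly, reaching `lambda_final` on the cycle's last epoch
#' (`lambda_final * ((e mod L) + 1) / L` with `e` counted from the start of
#' the annealing phase and `L` the cycle length); `lambda_final` throughout
#' the final phase. Constant schedule: `lambda_final` everywhere.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total`.
#' @param config a [training_config()].
#' @return the KL weight for that epoch.
#' @export
lambda_schedule <- function(epoch, config) {
  tot <- total_epochs(config)
  if (any(epoch < 0 | epoch >= tot))
    stop("epoch out of range [0, ", tot - 1, "]")
  if (config$schedule == "constant")
    return(rep_len(config$lambda_final, length(epoch)))
  out <- numeric(length(epoch))
  in_cycle <- epoch >= config$pretrain_epochs &
    epoch < config$pretrain_epochs + config$cyclic_epochs
  e <- epoch[in_cycle] - config$pretrain_epochs
  out[in_cycle] <- config$lambda_final *
    ((e %% config$cycle_length) + 1) / config$cycle_length
  out[epoch >= config$pretrain_epochs + config$cyclic_epochs] <-
    config$lambda_final
  out
}

adam_update <- function(params, grads, state, config) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  lr <- config$learning_rate
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    step <- lr * mhat / (sqrt(vhat) + eps)
    if (config$optimizer == "adamw")
      step <- step + lr * config$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

#' Train the CVAE
#'
#' Minibatch gradient descent on the summed reconstruction + weighted-KL
#' loss, under the annealing schedule of [lambda_schedule()]. Deterministic
#' for a fixed `config$seed`: initialization, per-epoch shuffling and the
#' latent draws are all derived from it.
#'
#' @param Y_norm n x p feature matrix, standardized (mean 0, variance 1).
#' @param X_norm n x q covariates, min-max normalized (may be NULL/0-column).
#' @param B_onehot n x B batch indicator matrix (all levels).
#' @param cvae_cfg a [cvae_config()]; defaults to the planned architecture.
#' @param config a [training_config()].
#' @return list with `params` (trained `cvae_params`) and `trace`, a data
#'   frame of per-epoch (lambda, reconstruction, prior, total) losses with
#'   the optimizer settings in `attr(trace, "optimizer")`.
#' @export
train_cvae <- function(Y_norm, X_norm, B_onehot, cvae_cfg = NULL,
                       config = training_config()) {
  Y_norm <- as.matrix(Y_norm)
  n <- nrow(Y_norm)
  q <- if (is.null(X_norm)) 0L else ncol(as.matrix(X_norm))
  if (q > 0) X_norm <- as.matrix(X_norm)
  B_onehot <- as.matrix(B_onehot)
  if (is.null(cvae_cfg))
    cvae_cfg <- cvae_config(ncol(Y_norm), q, ncol(B_onehot))

  params <- cvae_init(cvae_cfg, seed = config$seed)
  state <- list(t = 0L,
                m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  tot <- total_epochs(config)
  set.seed(config$seed)
  epoch_seeds <- sample.int(.Machine$integer.max - 1L, tot)
  trace <- data.frame(epoch = seq_len(tot) - 1L, lambda = NA_real_,
                      reconstruction = NA_real_, prior = NA_real_,
                      total = NA_real_)
  d <- cvae_cfg$latent_dim

  for (ep in seq_len(tot)) {
    lam <- lambda_schedule(ep - 1L, config)
    set.seed(epoch_seeds[ep])
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$minibatch_size)
    recon_sum <- prior_sum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$minibatch_size - 1L, n)]
      eps <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      res <- cvae_grad(params,
                       Y_norm[idx, , drop = FALSE],
                       if (q > 0) X_norm[idx, , drop = FALSE] else NULL,
                       B_onehot[idx, , drop = FALSE],
                       eps, lam)
      if (!is.finite(res$loss$total))
        stop("non-finite training loss at epoch ", ep - 1,
             "; learning rate may be too high or inputs degenerate")
      recon_sum <- recon_sum + res$loss$reconstruction
      prior_sum <- prior_sum + res$loss$prior
      upd <- adam_update(params, res$grads, state, config)
      # adam_update strips attributes via list assignment; restore class/config
      attributes(upd$params) <- attributes(params)
      params <- upd$params
      state <- upd$state
    }
    trace$lambda[ep] <- lam
    trace$reconstruction[ep] <- recon_sum
    trace$prior[ep] <- prior_sum
    trace$total[ep] <- recon_sum + lam * prior_sum
  }
  attr(trace, "optimizer") <- c(optimizer = config$optimizer,
                                learning_rate = config$learning_rate,
                                weight_decay = if (config$optimizer == "adamw")
                                  config$weight_decay else 0)
  list(params = params, trace = trace)
}
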