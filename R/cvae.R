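#' @title Conditional variational autoencoder for feature vectors
#'
#' @description
#' A small fully connected CVAE. The encoder receives the concatenation
#' `[y, x, b]` of the (normalized) feature vector, biological covariates and
#' batch indicators, passes it through four tanh hidden layers, and emits a
#' latent mean and log-variance through two linear heads on a shared trunk.
#' The decoder mirrors the hidden ladder in reverse, receives `[z, x, b]`,
#' and reconstructs the feature vector through a linear output layer. All
#' stochasticity flows through the reparameterized latent draw
#' `z = mu + sigma * eps`.
#'
#' @name cvae
NULL

#' Plan the CVAE architecture
#'
#' The latent size defaults to the power of two nearest to `p/4` (e.g. 16
#' latent dimensions for 62 input features). Four hidden layers per side are
#' sized by rounded linear interpolation between the feature width and the
#' latent width, so that each layer sits approximately halfway between its
#' neighbours; the decoder mirrors the ladder.
#'
#' @param p number of features.
#' @param q number of covariate columns.
#' @param batch_dim number of batch indicator columns (one-hot, all levels).
#' @param latent_dim optional override of the latent size.
#' @param hidden_sizes optional override of the 4 encoder-side hidden sizes
#'   (strictly decreasing).
#' @param n_hidden number of hidden layers per side.
#' @return object of class `cvae_config`.
#' @export
cvae_config <- function(p, q, batch_dim, latent_dim = NULL,
                        hidden_sizes = NULL, n_hidden = 4) {
  stopifnot(p >= 2, q >= 0, batch_dim >= 1, n_hidden >= 1)
  if (is.null(latent_dim)) {
    if (p / 4 < 1) {
      warning("p/4 < 1; using minimum latent size 2")
      latent_dim <- 2L
    } else {
      latent_dim <- as.integer(2^round(log2(p / 4)))
      latent_dim <- max(latent_dim, 2L)
    }
  }
  latent_dim <- as.integer(latent_dim)
  if (latent_dim >= p)
    warning("latent size ", latent_dim, " is not smaller than the ",
            p, " input features")
  if (is.null(hidden_sizes)) {
    steps <- seq_len(n_hidden) / (n_hidden + 1)
    hidden_sizes <- as.integer(round(p + (latent_dim - p) * steps))
    # enforce a decreasing ladder after rounding (strict where p - latent_dim
    # leaves room; tiny inputs may force ties at the latent width)
    for (i in seq_along(hidden_sizes)) {
      upper <- if (i == 1) p else hidden_sizes[i - 1]
      hidden_sizes[i] <- max(min(hidden_sizes[i], upper - 1L), latent_dim)
    }
  } else {
    hidden_sizes <- as.integer(hidden_sizes)
    if (any(diff(hidden_sizes) >= 0) && length(hidden_sizes) > 1)
      stop("hidden sizes must be strictly decreasing on the encoder side")
  }
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) != n_hidden)
    stop("hidden_sizes must have length ", n_hidden)
  structure(list(p = as.integer(p), q = as.integer(q),
                 batch_dim = as.integer(batch_dim),
                 latent_dim = latent_dim, hidden_sizes = hidden_sizes,
                 activation = "tanh"),
            class = "cvae_config")
}

#' @export
print.cvae_config <- function(x, ...) {
  cat("CVAE architecture: ", x$p, " features + ", x$q, " covariates + ",
      x$batch_dim, " batch indicators\n", sep = "")
  cat("  encoder: ", paste(c(x$p + x$q + x$batch_dim, x$hidden_sizes),
                           collapse = " -> "),
      " -> (", x$latent_dim, ", ", x$latent_dim, ") [mu, log-variance]\n",
      sep = "")
  cat("  decoder: ", paste(c(x$latent_dim + x$q + x$batch_dim,
                             rev(x$hidden_sizes), x$p), collapse = " -> "),
      "\n  activation: tanh between hidden layers; linear heads/output\n",
      sep = "")
  invisible(x)
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), +1/sqrt(fan_in))
init_linear <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
       b = stats::runif(fan_out, -bound, bound))
}

#' Initialize CVAE parameters
#'
#' @param config a [cvae_config()].
#' @param seed integer seed for the fan-in uniform initialization.
#' @return named list of weight matrices and bias vectors
#'   (class `cvae_params`), with the config attached.
#' @export
cvae_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cvae_config"))
  set.seed(seed)
  enc_sizes <- c(config$p + config$q + config$batch_dim, config$hidden_sizes)
  dec_sizes <- c(config$latent_dim + config$q + config$batch_dim,
                 rev(config$hidden_sizes), config$p)
  params <- list()
  for (i in seq_along(config$hidden_sizes)) {
    l <- init_linear(enc_sizes[i], enc_sizes[i + 1])
    params[[paste0("enc_W", i)]] <- l$W
    params[[paste0("enc_b", i)]] <- l$b
  }
  h_last <- utils::tail(enc_sizes, 1)
  l <- init_linear(h_last, config$latent_dim)
  params$enc_Wmu <- l$W; params$enc_bmu <- l$b
  l <- init_linear(h_last, config$latent_dim)
  params$enc_Wlv <- l$W; params$enc_blv <- l$b
  for (i in seq_len(length(dec_sizes) - 2)) {
    l <- init_linear(dec_sizes[i], dec_sizes[i + 1])
    params[[paste0("dec_W", i)]] <- l$W
    params[[paste0("dec_b", i)]] <- l$b
  }
  l <- init_linear(dec_sizes[length(dec_sizes) - 1], config$p)
  params$dec_Wout <- l$W; params$dec_bout <- l$b
  attr(params, "config") <- config
  class(params) <- "cvae_params"
  params
}

as_row_matrix <- function(v, width, what) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- as.matrix(v)
  if (ncol(v) != width)
    stop(what, " has ", ncol(v), " columns; expected ", width)
  v
}

affine <- function(A, W, b) sweep(A %*% W, 2, b, "+")

#' Encode feature vectors to latent Gaussians
#'
#' Deterministic map from `[y, x, b]` to the latent mean and scale.
#' Accepts single vectors or row-wise matrices.
#'
#' @param params trained or initialized [cvae_init()] parameters.
#' @param Y features (n x p or length-p vector), normalized.
#' @param X covariates (n x q), min-max normalized.
#' @param Bm batch indicator matrix (n x batch_dim).
#' @return list with `mu`, `logvar`, `sigma` (each n x latent_dim);
#'   `sigma = exp(logvar / 2)` is strictly positive.
#' @export
cvae_encode <- function(params, Y, X, Bm) {
  cfg <- attr(params, "config")
  Y <- as_row_matrix(Y, cfg$p, "feature input")
  X <- if (cfg$q > 0) as_row_matrix(X, cfg$q, "covariate input") else NULL
  Bm <- as_row_matrix(Bm, cfg$batch_dim, "batch indicator input")
  A <- cbind(Y, X, Bm)
  for (i in seq_along(cfg$hidden_sizes))
    A <- tanh(affine(A, params[[paste0("enc_W", i)]], params[[paste0("enc_b", i)]]))
  mu <- affine(A, params$enc_Wmu, params$enc_bmu)
  logvar <- affine(A, params$enc_Wlv, params$enc_blv)
  list(mu = mu, logvar = logvar, sigma = exp(logvar / 2))
}

#' Draw reparameterized latent samples
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)` from R's RNG stream, so draws
#' are reproducible under `set.seed()`.
#'
#' @param mu,sigma latent means and scales (matrices or vectors of equal
#'   shape); `sigma` must be non-negative.
#' @return sample of the same shape as `mu`.
#' @export
sample_latent <- function(mu, sigma) {
  if (any(sigma < 0)) stop("latent sigma must be non-negative")
  eps <- stats::rnorm(length(mu))
  if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  mu + sigma * eps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode latent vectors to feature reconstructions
#'
#' Deterministic map from `[z, x, b]` through the mirrored hidden ladder to a
#' linear output layer.
#'
#' @param params CVAE parameters.
#' @param Z latent input (n x latent_dim).
#' @param X,Bm conditioning covariates and batch indicators.
#' @return n x p reconstruction matrix.
#' @export
cvae_decode <- function(params, Z, X, Bm) {
  cfg <- attr(params, "config")
  Z <- as_row_matrix(Z, cfg$latent_dim, "latent input")
  X <- if (cfg$q > 0) as_row_matrix(X, cfg$q, "covariate input") else NULL
  Bm <- as_row_matrix(Bm, cfg$batch_dim, "batch indicator input")
  A <- cbind(Z, X, Bm)
  for (i in seq_along(cfg$hidden_sizes))
    A <- tanh(affine(A, params[[paste0("dec_W", i)]], params[[paste0("dec_b", i)]]))
  affine(A, params$dec_Wout, params$dec_bout)
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' Closed form \eqn{\tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - 1 - \ln\sigma_d^2)};
#' non-negative, zero iff `mu = 0`, `sigma = 1`.
#'
#' @param mu,sigma latent mean(s) and scale(s); row-wise for matrices.
#' @return scalar for vector input, per-row vector for matrix input.
#' @export
kl_divergence <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  term <- mu^2 + sigma^2 - 1 - 2 * log(sigma)
  if (is.matrix(mu)) rowSums(term) / 2 else sum(term) / 2
}

#' CVAE loss: summed squared reconstruction error plus weighted KL
#'
#' Both components are unaveraged sums over features and subjects, matching
#' the convention that the total objective is the sum of per-subject losses;
#' averaging would silently rescale the effective KL weight.
#'
#' @param Y,Y_hat observed and reconstructed features (same shape).
#' @param mu,sigma latent means/scales for the same subjects.
#' @param lambda non-negative KL weight.
#' @return list with `reconstruction`, `prior` and `total`.
#' @export
cvae_loss <- function(Y, Y_hat, mu, sigma, lambda) {
  stopifnot(lambda >= 0)
  recon <- sum((Y - Y_hat)^2)
  prior <- sum(kl_divergence(mu, sigma))
  list(reconstruction = recon, prior = prior,
       total = recon + lambda * prior)
}

# Forward pass with caches, then backprop of the summed loss.
# Returns list(loss = <cvae_loss list>, grads = named list like params).
cvae_grad <- function(params, Y, X, Bm, eps, lambda) {
  cfg <- attr(params, "config")
  nh <- length(cfg$hidden_sizes)
  enc_in <- cbind(Y, if (cfg$q > 0) X, Bm)
  # encoder forward
  enc_act <- vector("list", nh + 1)
  enc_act[[1]] <- enc_in
  for (i in seq_len(nh))
    enc_act[[i + 1]] <- tanh(affine(enc_act[[i]],
                                    params[[paste0("enc_W", i)]],
                                    params[[paste0("enc_b", i)]]))
  H <- enc_act[[nh + 1]]
  mu <- affine(H, params$enc_Wmu, params$enc_bmu)
  logvar <- affine(H, params$enc_Wlv, params$enc_blv)
  sigma <- exp(logvar / 2)
  z <- mu + sigma * eps
  # decoder forward
  dec_in <- cbind(z, if (cfg$q > 0) X, Bm)
  dec_act <- vector("list", nh + 1)
  dec_act[[1]] <- dec_in
  for (i in seq_len(nh))
    dec_act[[i + 1]] <- tanh(affine(dec_act[[i]],
                                    params[[paste0("dec_W", i)]],
                                    params[[paste0("dec_b", i)]]))
  Y_hat <- affine(dec_act[[nh + 1]], params$dec_Wout, params$dec_bout)

  loss <- cvae_loss(Y, Y_hat, mu, sigma, lambda)
  grads <- list()

  # decoder backward
  dout <- 2 * (Y_hat - Y)
  grads$dec_Wout <- crossprod(dec_act[[nh + 1]], dout)
  grads$dec_bout <- colSums(dout)
  dA <- dout %*% t(params$dec_Wout)
  for (i in rev(seq_len(nh))) {
    dZpre <- dA * (1 - dec_act[[i + 1]]^2)
    grads[[paste0("dec_W", i)]] <- crossprod(dec_act[[i]], dZpre)
    grads[[paste0("dec_b", i)]] <- colSums(dZpre)
    dA <- dZpre %*% t(params[[paste0("dec_W", i)]])
  }
  dz <- dA[, seq_len(cfg$latent_dim), drop = FALSE]

  # latent backward: z = mu + exp(logvar/2) * eps, plus KL terms
  dmu <- dz + lambda * mu
  dlogvar <- dz * eps * sigma / 2 + lambda * (sigma^2 - 1) / 2

  # encoder backward through the two heads and the shared trunk
  grads$enc_Wmu <- crossprod(H, dmu)
  grads$enc_bmu <- colSums(dmu)
  grads$enc_Wlv <- crossprod(H, dlogvar)
  grads$enc_blv <- colSums(dlogvar)
  dA <- dmu %*% t(params$enc_Wmu) + dlogvar %*% t(params$enc_Wlv)
  for (i in rev(seq_len(nh))) {
    dZpre <- dA * (1 - enc_act[[i + 1]]^2)
    grads[[paste0("enc_W", i)]] <- crossprod(enc_act[[i]], dZpre)
    grads[[paste0("enc_b", i)]] <- colSums(dZpre)
    dA <- dZpre %*% t(params[[paste0("enc_W", i)]])
  }
  list(loss = loss, grads = grads, mu = mu, sigma = sigma, Y_hat = Y_hat)
}
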