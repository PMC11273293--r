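# small seeded datasets used across the unit tests

small_gaussian <- function(n = 60, p = 5, B = 3, seed = 1, shift = 0,
                           scale_mult = 1) {
  set.seed(seed)
  batch <- factor(rep(paste0("b", seq_len(B)), length.out = n))
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  for (i in seq_len(B)) {
    rows <- batch == levels(batch)[i]
    Y[rows, ] <- Y[rows, ] * scale_mult^(i - 1) + shift * (i - 1)
  }
  list(Y = Y, batch = batch)
}

tiny_fixture <- function(name = "additive+scale", n_scale = 0.4, seed = NULL)
  make_fixture(name, n_scale = n_scale, seed = seed)

quick_training <- function(seed = 1, ...)
  training_config(seed = seed, ...)
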