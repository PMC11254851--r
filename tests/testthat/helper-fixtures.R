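# Shared fixtures, built in code. Small graphs keep the engine tests fast;
# the generator fixtures are seeded so every run sees identical cohorts.

tiny_attia_config <- function() {
  attianet_config(filters = c(3, 4), kernels = c(7, 5), pools = c(2, 2),
                  spatial_filters = 2, head = c(5, 3))
}

tiny_resnet_config <- function(dropout = 0) {
  resnet1d_config(stem_filters = 6L, stem_kernels = 7L,
                  channels = c(6L, 8L, 10L, 12L, 14L), kernel = 9L,
                  reduction = 4L, dropout = dropout, head_width = 5L)
}

# a short annotated record with deterministic content
fixture_record <- function(age = 50, rate = 100, duration = 2, seed = 123)
  synthesize_record(age, rate = rate, duration = duration, seed = seed)

# small cached cohort at a given rate/duration
fixture_cache <- function(n = 60, rate = 100, duration = 2, seed = 99,
                          model = age_morphology_model()) {
  co <- generate_cohort(n, rate = rate, duration = duration, model = model,
                        seed = seed)
  cohort_cache(co$records, co$table)
}

# direct (slow, index-by-index) 1D same-padding convolution used as the
# independent oracle for the engine's convolution kernels
reference_conv1d <- function(x, W, b, k, stride = 1) {
  cin <- nrow(x); L <- ncol(x); cout <- nrow(W)
  lo <- ceiling(L / stride)
  pad <- max(0, (lo - 1) * stride + k - L)
  pl <- pad %/% 2
  y <- matrix(0, cout, lo)
  for (t in seq_len(lo)) {
    acc <- numeric(cout)
    for (j in seq_len(k)) {
      src <- (t - 1) * stride - pl + j - 1  # 0-based input index
      if (src < 0 || src >= L) next
      # W row layout: channel fastest within tap blocks
      acc <- acc + W[, ((j - 1) * cin + 1):(j * cin), drop = FALSE] %*%
        x[, src + 1]
    }
    y[, t] <- acc + b
  }
  y
}
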