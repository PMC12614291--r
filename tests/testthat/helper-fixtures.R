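# Shared fixtures: tiny geometries keep the unit tests fast; the end-to-end
# acceptance checks use the package defaults.

tiny_denoiser_config <- function(...) {
  denoiser_config(input_shape = c(8L, 8L), depth = 2L, base_width = 4L,
                  time_embedding_dim = 8L, groups = 2L,
                  attention_levels = 2L, ...)
}

paper_schedules <- function() {
  list(linear = make_schedule("linear", 1000),
       cosine = make_schedule("cosine", 1000),
       sigmoid = make_schedule("sigmoid", 1000))
}

norm_img <- function(m) {
  attr(m, "units") <- "normalized"
  m
}

rand_norm_image <- function(shape, seed) {
  withr::with_seed(seed, norm_img(matrix(stats::runif(prod(shape), -1, 1),
                                         shape[1], shape[2])))
}
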