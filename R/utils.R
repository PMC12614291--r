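# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring global RNG state after.
# seed = NULL runs the code against the current RNG stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# Fan a global seed out into named sub-seeds so that e.g. data generation can
# be varied independently of weight initialization. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + 97 * offset) %% 2147483629) + 1L
}

stop_param <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intensity-unit bookkeeping: images carry a "units" attribute ("HU" or
# "normalized") set by preprocess()/to_hu() and the phantom generator, so that
# HU-space metrics can refuse normalized inputs.
set_units <- function(x, units) {
  attr(x, "units") <- units
  x
}

get_units <- function(x) attr(x, "units", exact = TRUE)

assert_hu_units <- function(x, what = "image") {
  u <- get_units(x)
  if (!is.null(u) && identical(u, "normalized")) {
    stop_param(what, " is in normalized [-1, 1] units; HU-space operations ",
               "require Hounsfield units (see to_hu())")
  }
  invisible(TRUE)
}

assert_same_shape <- function(a, b, what = c("a", "b")) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) {
    stop_param("shape mismatch: ", what[1], " is [", paste(da, collapse = "x"),
               "] but ", what[2], " is [", paste(db, collapse = "x"), "]")
  }
  invisible(TRUE)
}
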