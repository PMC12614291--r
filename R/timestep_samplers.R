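#' Training-time timestep distributions
#'
#' Constructs the distribution over timesteps \eqn{t \in \{1..T\}} used when
#' drawing training targets. The classic choice is uniform; the exponential and
#' triangular alternatives put more probability mass on low timesteps, where
#' the image is mostly denoised and fine detail is being formed — the regime in
#' which the denoising loss converges slowest.
#'
#' Probability mass functions:
#' \describe{
#'   \item{uniform}{\eqn{p(t) = 1/T}.}
#'   \item{exponential}{\eqn{p(t) \propto e^{-t/\tau}} with decay scale `tau`
#'     (default \eqn{T/4}).}
#'   \item{triangular}{\eqn{p(t) \propto T - t + 1}, linearly decreasing with
#'     its peak at \eqn{t = 1}.}
#' }
#'
#' @param kind one of `"uniform"`, `"exponential"`, `"triangular"`.
#' @param n_steps number of timesteps \eqn{T}.
#' @param tau decay scale of the exponential kind; ignored otherwise.
#' @return An object of class `timestep_distribution` with fields `kind`,
#'   `n_steps`, `tau`, `pmf` (length `n_steps`, sums to 1) and `cdf`.
#' @examples
#' d <- timestep_distribution("triangular", n_steps = 3)
#' timestep_pmf(d) # 3/6, 2/6, 1/6
#' @export
timestep_distribution <- function(kind = c("uniform", "exponential", "triangular"),
                                  n_steps,
                                  tau = n_steps / 4) {
  kind <- match.arg(kind)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop_param("n_steps must be >= 1")
  tt <- seq_len(n_steps)
  w <- switch(kind,
    uniform = rep(1, n_steps),
    exponential = {
      if (!is.numeric(tau) || tau <= 0) stop_param("tau must be > 0")
      # subtract the minimum exponent for numerical stability
      exp(-(tt - 1) / tau)
    },
    triangular = n_steps - tt + 1
  )
  pmf <- w / sum(w)
  structure(
    list(kind = kind, n_steps = n_steps,
         tau = if (kind == "exponential") tau else NULL,
         pmf = pmf, cdf = cumsum(pmf)),
    class = "timestep_distribution"
  )
}

#' Probability mass function of a timestep distribution
#'
#' @param dist a [timestep_distribution()] object.
#' @return Numeric vector of length `n_steps`; non-negative, sums to 1.
#' @export
timestep_pmf <- function(dist) {
  stopifnot(inherits(dist, "timestep_distribution"))
  dist$pmf
}

#' Draw training timesteps
#'
#' Draws `n` i.i.d. timesteps from the distribution by inverse-CDF sampling on
#' the tabulated pmf; exact for any distribution kind and reproducible given a
#' seed.
#'
#' @param dist a [timestep_distribution()] object.
#' @param n number of draws (>= 1).
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return Integer vector of length `n` with values in `1:n_steps`.
#' @export
sample_timesteps <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "timestep_distribution"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_param("n must be >= 1")
  u <- with_seed_opt(seed, stats::runif(n))
  findInterval(u, dist$cdf, left.open = TRUE) + 1L
}

#' @export
print.timestep_distribution <- function(x, ...) {
  cat(sprintf("<timestep_distribution> kind=%s T=%d%s mean=%.1f\n",
              x$kind, x$n_steps,
              if (!is.null(x$tau)) sprintf(" tau=%.1f", x$tau) else "",
              sum(seq_len(x$n_steps) * x$pmf)))
  invisible(x)
}
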