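#' Generate fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis of zero-mean, unit-variance fractional Gaussian noise
#' (the stationary increment process of fractional Brownian motion with
#' Hurst exponent `H`) via the Davies-Harte circulant-embedding method.
#' The target autocovariance is reproduced exactly; if the circulant
#' embedding is not nonnegative-definite the function fails rather than
#' truncating eigenvalues.
#'
#' @param H Hurst exponent, in (0, 1). `H = 0.5` gives white noise;
#'   `H > 0.5` persistent long-range correlated noise.
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- gen_fgn(0.8, 1024, seed = 1)
#' @export
gen_fgn <- function(H, n, seed = NULL) {
  stopifnot(is.numeric(H), length(H) == 1, H > 0, H < 1,
            is.numeric(n), length(n) == 1, n >= 2)
  n <- as.integer(n)
  draw <- function() {
    # pad the embedding to a 2-3-5-smooth FFT length and keep the first n
    # samples: any contiguous stretch of fGn is fGn (stationarity)
    ng <- max(n, stats::nextn(2L * (n - 1L), c(2, 3, 5)) %/% 2L + 1L)
    m <- 2L * (ng - 1L)
    k <- 0:(ng - 1L)
    acov <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    circ <- c(acov, acov[(ng - 1L):2L])
    lambda <- Re(stats::fft(circ))
    if (min(lambda) < -1e-8 * max(lambda))
      stop("circulant embedding is not nonnegative definite for H = ", H,
           ", n = ", n, " (min eigenvalue ", signif(min(lambda), 3), ")")
    lambda <- pmax(lambda, 0)
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    w <- stats::fft(sqrt(lambda / (2 * m)) * z)
    # real and imaginary parts are two independent fGn draws; use the real part
    Re(w)[seq_len(n)] * sqrt(2)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Theoretical lag-1 autocorrelation of fractional Gaussian noise
#'
#' @param H Hurst exponent.
#' @return `2^(2H - 1) - 1`.
#' @keywords internal
fgn_acf1 <- function(H) 2^(2 * H - 1) - 1
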