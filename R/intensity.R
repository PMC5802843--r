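#' Fit a negative-binomial model to puncta intensities
#'
#' Rolling-circle amplification terminates stochastically and irreversibly,
#' so puncta intensities follow a negative-binomial distribution with large
#' overdispersion (coefficients of variation typically between one and
#' two). The model is parameterized as (mean `mu`, dispersion `r`) with
#' variance `mu + mu^2 / r`, giving `cv^2 = 1/mu + 1/r`. Continuous
#' intensities are binned by rounding to the nearest integer; the fit uses
#' a method-of-moments start refined by maximum likelihood with the mean
#' fixed at the sample mean (bounded scalar search on `r`, tolerance 1e-6).
#'
#' @param intensities numeric vector of >= 50 non-negative intensities.
#' @return an object of class `plish_nbfit` with elements `mean`,
#'   `dispersion`, `cv`, `n`, `dispersion_defined` and `loglik`. Constant
#'   data yield `cv = 0` with `dispersion_defined = FALSE` rather than an
#'   error.
#' @export
fit_puncta_intensities <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) < 50L) stop("need at least 50 intensity values")
  if (any(x < 0)) stop("intensities must be non-negative")
  mu <- mean(x)
  s2 <- var(x)
  if (s2 == 0) {
    return(structure(list(mean = mu, dispersion = NA_real_, cv = 0,
                          n = length(x), dispersion_defined = FALSE,
                          loglik = NA_real_),
                     class = "plish_nbfit"))
  }
  counts <- round(x)
  ## method-of-moments start: var = mu + mu^2/r  =>  r = mu^2/(var - mu)
  r0 <- if (s2 > mu) mu^2 / (s2 - mu) else 100
  negloglik <- function(log_r) {
    -sum(dnbinom(counts, size = exp(log_r), mu = mu, log = TRUE))
  }
  opt <- optimize(negloglik, interval = log(r0) + c(-8, 8), tol = 1e-6)
  r <- exp(opt$minimum)
  cv <- sqrt(1 / mu + 1 / r)
  structure(list(mean = mu, dispersion = r, cv = cv, n = length(x),
                 dispersion_defined = TRUE, loglik = -opt$objective),
            class = "plish_nbfit")
}

#' @export
print.plish_nbfit <- function(x, ...) {
  cat("Negative-binomial puncta-intensity fit\n")
  cat(sprintf("  n = %d, mean = %.2f", x$n, x$mean))
  if (x$dispersion_defined) {
    cat(sprintf(", dispersion r = %.4f, cv = %.3f\n", x$dispersion, x$cv))
  } else {
    cat(", constant data: cv = 0, dispersion undefined\n")
  }
  invisible(x)
}

#' @export
coef.plish_nbfit <- function(object, ...) {
  c(mean = object$mean, dispersion = object$dispersion, cv = object$cv)
}

#' Median peak-to-background ratio of puncta
#'
#' @param puncta_peaks peak amplitudes of detected puncta.
#' @param background_pixels background pixel intensities.
#' @return `median(puncta_peaks) / median(background_pixels)`; `Inf` (with
#'   a warning) when the background median is zero.
#' @export
signal_to_background <- function(puncta_peaks, background_pixels) {
  if (length(puncta_peaks) == 0L || length(background_pixels) == 0L) {
    stop("both puncta peaks and background pixels must be non-empty")
  }
  bg <- median(background_pixels)
  if (bg == 0) {
    warning("background median is zero; ratio is infinite")
    return(Inf)
  }
  median(puncta_peaks) / bg
}

## dispersion r giving a target cv at a given mean: 1/r = cv^2 - 1/mu
nb_dispersion_for_cv <- function(mean, cv) {
  inv_r <- cv^2 - 1 / mean
  if (inv_r <= 0) {
    stop("requested cv is below the Poisson limit for this mean")
  }
  1 / inv_r
}
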