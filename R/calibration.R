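#' Construct a copies-per-FPKM calibration model
#'
#' Single-cell qPCR benchmarking of in situ detection ties transcript
#' abundance to RNA-seq units through a Poisson sampling model: a gene at
#' FPKM `f` has on average `c * f` transcript copies per cell, and the
#' fraction of cells carrying at least one copy is `1 - exp(-c * f)`. The
#' reference fit for HCT116 cells gives `c = 2.5` copies per cell per FPKM.
#'
#' @param copies_per_fpkm the calibration constant `c` (> 0).
#' @return an object of class `plish_calibration`.
#' @seealso [fit_copies_per_fpkm()] to estimate `c` from data.
#' @export
#' @examples
#' m <- calibration_model(2.5)
#' expected_copies(2, m)       # 5 copies per cell
#' detection_fraction(1, m)    # 0.918
calibration_model <- function(copies_per_fpkm = 2.5) {
  stopifnot(is.numeric(copies_per_fpkm), length(copies_per_fpkm) == 1L)
  if (!is.finite(copies_per_fpkm) || copies_per_fpkm <= 0) {
    stop("copies_per_fpkm must be a positive number")
  }
  structure(list(copies_per_fpkm = unname(copies_per_fpkm),
                 fitted = FALSE, data = NULL, loglik = NA_real_),
            class = "plish_calibration")
}

#' Expected transcript copies per cell at a given FPKM
#'
#' @param fpkm non-negative FPKM value(s).
#' @param model a `plish_calibration`.
#' @return expected copies per cell, `c * fpkm`.
#' @export
expected_copies <- function(fpkm, model = calibration_model()) {
  if (any(fpkm < 0)) stop("fpkm must be non-negative")
  model$copies_per_fpkm * fpkm
}

#' Fraction of cells with at least one transcript under Poisson sampling
#'
#' @inheritParams expected_copies
#' @return `1 - exp(-c * fpkm)`, in `[0, 1)`.
#' @export
detection_fraction <- function(fpkm, model = calibration_model()) {
  if (any(fpkm < 0)) stop("fpkm must be non-negative")
  1 - exp(-model$copies_per_fpkm * fpkm)
}

#' Fit the copies-per-FPKM calibration constant
#'
#' Estimates `c` from fraction-positive data, one row per gene (or
#' condition): at FPKM `f`, `n_positive` of `n_cells` cells contained at
#' least one transcript. The default is the binomial maximum-likelihood
#' estimate under `P(positive) = 1 - exp(-c * f)`; `method = "ls"` instead
#' minimizes squared error on the observed fractions.
#'
#' @param points data.frame with columns `fpkm`, `n_cells`, `n_positive`.
#' @param method `"mle"` (binomial likelihood) or `"ls"` (least squares on
#'   fractions).
#' @return a fitted `plish_calibration` with the estimate in
#'   `$copies_per_fpkm`.
#' @export
fit_copies_per_fpkm <- function(points, method = c("mle", "ls")) {
  method <- match.arg(method)
  stopifnot(all(c("fpkm", "n_cells", "n_positive") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 calibration points")
  if (any(points$fpkm < 0) || any(points$n_positive < 0) ||
      any(points$n_positive > points$n_cells)) {
    stop("invalid calibration points")
  }
  frac <- points$n_positive / points$n_cells
  informative <- points$fpkm > 0 & frac > 0 & frac < 1
  if (!any(informative)) {
    stop("calibration is non-identifiable: every point is saturated ",
         "(all fractions 0 or 1)")
  }
  f <- points$fpkm; n <- points$n_cells; x <- points$n_positive
  negloglik <- function(c0) {
    p <- pmin(pmax(1 - exp(-c0 * f), 1e-12), 1 - 1e-12)
    -sum(x * log(p) + (n - x) * log1p(-p))
  }
  ssq <- function(c0) sum((frac - (1 - exp(-c0 * f)))^2)
  obj <- if (method == "mle") negloglik else ssq
  ## bracket: c solves mean fraction at mean fpkm within a wide window
  upper <- max(1, -log(1e-9) / min(f[informative]))
  opt <- optimize(obj, interval = c(1e-9, upper), tol = 1e-9)
  m <- calibration_model(opt$minimum)
  m$fitted <- TRUE
  m$data <- points
  m$method <- method
  m$loglik <- if (method == "mle") -opt$objective else NA_real_
  m
}

#' @export
print.plish_calibration <- function(x, digits = 4, ...) {
  cat("Poisson copies-per-FPKM calibration\n")
  cat(sprintf("  c = %s copies/cell/FPKM%s\n",
              format(x$copies_per_fpkm, digits = digits),
              if (isTRUE(x$fitted))
                sprintf(" (fitted, %s, %d points)", x$method, nrow(x$data))
              else " (fixed)"))
  cat(sprintf("  detection fraction at FPKM 1: %.1f%%\n",
              100 * detection_fraction(1, x)))
  invisible(x)
}

#' @export
coef.plish_calibration <- function(object, ...) {
  c(copies_per_fpkm = object$copies_per_fpkm)
}

#' Predict copies per cell or detection fraction from a calibration
#'
#' @param object a `plish_calibration`.
#' @param fpkm FPKM values to predict at.
#' @param type `"copies"` for expected copies per cell, `"fraction"` for
#'   the fraction of positive cells.
#' @param ... unused.
#' @export
predict.plish_calibration <- function(object, fpkm,
                                      type = c("copies", "fraction"), ...) {
  type <- match.arg(type)
  switch(type,
         copies = expected_copies(fpkm, object),
         fraction = detection_fraction(fpkm, object))
}
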