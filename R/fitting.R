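# Transfer-function fitting: Hill fits, power-law fits, and threshold
# extraction from families of dose-response curves.

#' Fit a Hill function to a dose-response curve
#'
#' Least squares on log-transformed outputs (uniform weights in log space;
#' luminescence spans orders of magnitude and dose grids are log-spaced) of
#' `vmax * (basal + (1 - basal) * x^n / (x^n + K^n))`. `basal` is fixed at 0
#' unless `fit_basal = TRUE`. Reports both the `(K, n)` parameterization and
#' the aggregate form `x^n / (x^n + Khat)` with `Khat = K^n`, the canonical
#' reporting form for bioluminescence transfer functions.
#'
#' Initialization is data-driven: `vmax` starts at the maximum output, `K`
#' at the input where the curve crosses half its maximum (interpolated in
#' log-input space), and `n` at the median local log-log slope over the
#' sub-half-maximal region. Naive starts (n = 1, K at the grid's geometric
#' median) converge to a spurious local optimum on wide log grids, so they
#' are used only as fallbacks. On convergence failure five further seeded
#' random starts are tried before giving up with diagnostics.
#'
#' @param dr a [dose_response()] (>= 4 points, positive outputs).
#' @param fix_n optional fixed Hill coefficient.
#' @param fit_basal estimate a basal leak fraction (default `FALSE`).
#' @return An object of class `hill_fit`: list with `vmax`, `K`, `n`,
#'   `basal`, `Khat`, `rss` (residual sum of squares in log space), and
#'   `converged`.
#' @export
#' @examples
#' x <- 10^seq(-1, 3, length.out = 30)
#' fit_hill(dose_response(x, x / (x + 11)))
fit_hill <- function(dr, fix_n = NULL, fit_basal = FALSE) {
  stopifnot(inherits(dr, "dose_response"))
  x <- dr$input; y <- dr$output
  if (length(x) < 4) stop("need at least 4 points")
  if (any(y <= 0)) stop("outputs must be strictly positive")
  if (any(x <= 0)) stop("inputs must be strictly positive")
  ly <- log(y)

  model <- function(p) {
    # p = (log_vmax, log_K, log_n, qlogis(basal))
    vmax <- exp(p[1]); K <- exp(p[2])
    n <- if (is.null(fix_n)) exp(p[3]) else fix_n
    basal <- if (fit_basal) stats::plogis(p[4]) else 0
    xn <- x^n
    log(vmax * (basal + (1 - basal) * xn / (xn + K^n)))
  }
  # data-driven start: K at the half-max crossing, n from the low-dose
  # log-log slope (the power-law regime of a Hill curve has slope n)
  K0 <- tryCatch({
    ymax <- max(y)
    exp(approx(x = cummax(y), y = log(x), xout = ymax / 2,
               ties = "ordered")$y)
  }, error = function(e) NA_real_)
  if (!is.finite(K0)) K0 <- exp(median(log(x)))
  n0 <- if (is.null(fix_n)) {
    low <- which(y <= max(y) / 2)
    est <- if (length(low) >= 3) {
      sl <- diff(log(y[low])) / diff(log(x[low]))
      median(sl[is.finite(sl)])
    } else 1
    if (!is.finite(est)) est <- 1
    min(max(est, 0.3), 6)
  } else 1
  start <- c(log(max(y)), log(K0), log(n0), stats::qlogis(0.01))

  try_fit <- function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, fn = function(p) ly - model(p),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
             error = function(e) NULL)
  }
  fit <- try_fit(start)
  ok <- function(f) !is.null(f) && f$info %in% 1:4
  if (!ok(fit)) {
    seeds <- withr_seed_starts(start, 5)
    for (s in seeds) {
      cand <- try_fit(s)
      if (ok(cand) && (!ok(fit) || cand$deviance < fit$deviance)) fit <- cand
    }
  }
  if (is.null(fit))
    stop("Hill fit failed: optimizer error on all starts")
  p <- fit$par
  vmax <- exp(p[1]); K <- exp(p[2])
  n <- if (is.null(fix_n)) exp(p[3]) else fix_n
  basal <- if (fit_basal) stats::plogis(p[4]) else 0
  structure(list(vmax = vmax, K = K, n = n, basal = basal,
                 Khat = K^n, rss = fit$deviance,
                 converged = fit$info %in% 1:4,
                 message = fit$message),
            class = "hill_fit")
}

# deterministic perturbed restarts (RNG state preserved)
withr_seed_starts <- function(start, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20260929L)
  lapply(seq_len(k), function(i) start + rnorm(length(start), sd = 1))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: vmax = %.4g, K = %.4g, n = %.4g (Khat = K^n = %.4g)",
    x$vmax, x$K, x$n, x$Khat))
  if (x$basal > 0) cat(sprintf(", basal = %.3g", x$basal))
  cat(sprintf("\n  log-space RSS = %.4g, converged = %s\n",
              x$rss, x$converged))
  invisible(x)
}

#' Fit a power law by log-log regression
#'
#' Ordinary least squares of `log(y)` on `log(x)`, i.e. `y = a * x^n`.
#'
#' @param x,y strictly positive series of equal length (>= 3 points).
#' @return An object of class `power_law_fit`: list with prefactor `a`,
#'   exponent `n`, and `r2`.
#' @export
#' @examples
#' fit_power_law(1:10, 2 * (1:10)^1.45)
fit_power_law <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(x <= 0) || any(y <= 0)) stop("values must be strictly positive")
  fit <- lm(log(y) ~ log(x))
  # R^2 computed directly; summary.lm warns on exact fits
  ly <- log(y)
  rss <- sum(fit$residuals^2)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  structure(list(a = unname(exp(coef(fit)[1])), n = unname(coef(fit)[2]),
                 r2 = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law: y = %.4g * x^%.4g (R^2 = %.4f)\n", x$a, x$n, x$r2))
  invisible(x)
}

#' Detection thresholds across a family of dose-response curves
#'
#' Applies [detection_threshold()] to each curve in a list (one curve per
#' co-input level, e.g. per AHL concentration) and returns the
#' (co-input, threshold) pairs sorted by co-input. A per-curve threshold
#' failure is re-raised with the curve's identity attached.
#'
#' @param curves list of [dose_response()] objects; each must carry a
#'   numeric co-input in its metadata (first metadata element, or the one
#'   named by `co_input`).
#' @param co_input name of the metadata field holding the co-input level.
#' @return Data frame with columns `co_input`, `threshold`.
#' @export
threshold_series <- function(curves, co_input = "ahl") {
  if (length(curves) == 0) stop("need at least one curve")
  rows <- lapply(seq_along(curves), function(i) {
    dr <- curves[[i]]
    md <- attr(dr, "metadata")
    ci <- if (!is.null(md[[co_input]])) md[[co_input]] else
      stop(sprintf("curve %d has no metadata field '%s'", i, co_input))
    thr <- tryCatch(detection_threshold(dr), error = function(e)
      stop(sprintf("curve %d (%s = %g): %s", i, co_input, ci,
                   conditionMessage(e)), call. = FALSE))
    data.frame(co_input = ci, threshold = thr)
  })
  out <- do.call(rbind, rows)
  out[order(out$co_input), , drop = FALSE]
}
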