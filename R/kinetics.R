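#' Pyrophosphate standard curve
#'
#' Calibration points relating known PPi concentrations (the assay kit's
#' 0-60 uM range) to measured signal. Signals are interpolated back to
#' concentrations with [interpolate_concentration()]; extrapolation outside
#' the calibrated range is refused.
#'
#' @param concentration_uM Known concentrations, strictly increasing, >= 2
#'   points.
#' @param signal Measured signals, strictly monotone (so the curve is
#'   invertible).
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(concentration_uM, signal) {
  stopifnot(length(concentration_uM) == length(signal),
            length(concentration_uM) >= 2)
  if (any(diff(concentration_uM) <= 0))
    stop("standard concentrations must be strictly increasing")
  if (!(all(diff(signal) > 0) || all(diff(signal) < 0)))
    stop("standard signals must be strictly monotone for interpolation")
  structure(list(concentration_uM = concentration_uM, signal = signal),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: %d points, %.3g-%.3g uM\n",
              length(x$signal), min(x$concentration_uM),
              max(x$concentration_uM)))
  invisible(x)
}

#' Interpolate PPi concentration from signal
#'
#' Piecewise-linear interpolation between the bracketing calibration points.
#' Signals outside the calibrated signal range raise an error rather than
#' silently extrapolating.
#'
#' @param curve A [standard_curve()].
#' @param signal Numeric vector of signals.
#' @return Concentrations in uM.
#' @export
interpolate_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"))
  lo <- min(curve$signal)
  hi <- max(curve$signal)
  if (any(signal < lo - 1e-12 | signal > hi + 1e-12))
    stop(sprintf("signal outside the calibrated range [%.4g, %.4g]; refusing to extrapolate",
                 lo, hi))
  approx(curve$signal, curve$concentration_uM, xout = signal,
         ties = "ordered")$y
}

#' Initial rate from a time course
#'
#' Converts signal to product concentration through the standard curve (when
#' given) and fits a least-squares line over the initial linear window,
#' taken as the longest prefix of timepoints with R^2 >= `r2_threshold`
#' (minimum 3 points). A negative fitted slope is floored at zero with a
#' warning.
#'
#' @param time_min Timepoints in minutes (>= 3).
#' @param signal Measured signals (or concentrations when `curve` is NULL).
#' @param curve Optional [standard_curve()] for signal-to-uM conversion.
#' @param r2_threshold Linearity requirement for the prefix (default 0.95).
#' @return A list of class `initial_rate`: `rate` (uM/min), `n_points`,
#'   `r_squared`.
#' @export
initial_rate <- function(time_min, signal, curve = NULL, r2_threshold = 0.95) {
  stopifnot(length(time_min) == length(signal), length(time_min) >= 3)
  ord <- order(time_min)
  time_min <- time_min[ord]
  conc <- if (is.null(curve)) signal[ord]
          else interpolate_concentration(curve, signal[ord])
  n <- length(conc)
  prefix_r2 <- vapply(3:n, function(k) {
    y <- conc[1:k]
    if (var(y) == 0) return(1)  # flat series counts as perfectly linear
    r2 <- quiet_perfect(summary(lm(y ~ time_min[1:k]))$r.squared)
    if (is.nan(r2)) 1 else r2
  }, numeric(1))
  ok <- which(prefix_r2 >= r2_threshold)
  best_k <- if (length(ok)) max(ok) + 2L else 3L
  best_r2 <- prefix_r2[best_k - 2L]
  y <- conc[1:best_k]
  if (var(y) == 0) {
    slope <- 0
  } else {
    slope <- unname(coef(lm(y ~ time_min[1:best_k]))[2])
  }
  if (slope < 0) {
    warning("negative initial slope; rate floored at 0")
    slope <- 0
  }
  structure(list(rate = slope, n_points = best_k, r_squared = best_r2),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf("Initial rate %.4g uM/min over %d points (R^2 = %.3f)\n",
              x$rate, x$n_points, x$r_squared))
  invisible(x)
}

#' Fit the Michaelis-Menten model to initial rates
#'
#' Nonlinear least squares on v = vmax [S] / (Km + [S]), with
#' vmax = kcat [E0]. Initialization: vmax0 = max(v), Km0 = median([S]);
#' Levenberg-Marquardt iterations run to a 1e-10 parameter tolerance.
#' Standard errors come from the fit's Gauss-Newton covariance
#' approximation; the kcat/Km efficiency standard error uses the delta
#' method.
#'
#' @param v Initial rates, uM/min (or a list of `initial_rate` objects).
#' @param S Substrate concentrations, uM (>= 3 distinct values).
#' @param E0 Total enzyme concentration, uM (> 0).
#' @return An object of class `mm_fit` with components `Km`, `vmax`, `kcat`,
#'   `efficiency` (kcat/Km, 1/(min uM)), their standard errors, `rss`, `n`,
#'   `E0`, the underlying `nls` fit and the data.
#' @examples
#' S <- c(1, 2, 5, 10, 20, 40)
#' fit <- fit_mm(2 * S / (5 + S), S, E0 = 0.25)
#' coef(fit)
#' @export
fit_mm <- function(v, S, E0) {
  if (is.list(v)) v <- vapply(v, function(r) r$rate, numeric(1))
  stopifnot(length(v) == length(S))
  if (length(unique(S)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  if (!is.numeric(E0) || length(E0) != 1 || E0 <= 0) stop("E0 must be > 0")
  dat <- data.frame(v = v, S = S)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax * S / (Km + S), data = dat,
      start = list(vmax = max(v), Km = median(S)),
      control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-15,
                                           maxiter = 500)
    ),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e))
  )
  cf <- coef(fit)
  se <- tryCatch(
    quiet_perfect(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) c(vmax = NA_real_, Km = NA_real_))
  km <- unname(cf["Km"])
  vmax <- unname(cf["vmax"])
  kcat <- vmax / E0
  eff <- kcat / km
  # delta method for kcat/Km = vmax / (E0 Km)
  vc <- tryCatch(quiet_perfect(vcov(fit)),
                 error = function(e) matrix(NA_real_, 2, 2))
  grad <- c(vmax = 1 / (E0 * km), Km = -vmax / (E0 * km^2))
  eff_se <- tryCatch(sqrt(drop(t(grad[colnames(vc)]) %*% vc %*%
                                 grad[colnames(vc)])),
                     error = function(e) NA_real_)
  at_bound <- km <= 1e-10
  if (at_bound) warning("Km estimate collapsed to the zero boundary; fit is suspect")
  structure(
    list(Km = km, Km_se = unname(se["Km"]),
         vmax = vmax, vmax_se = unname(se["vmax"]),
         kcat = kcat, kcat_se = unname(se["vmax"]) / E0,
         efficiency = eff, efficiency_se = eff_se,
         rss = sum(resid(fit)^2), n = nrow(dat), E0 = E0,
         at_bound = at_bound, fit = fit, data = dat),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, digits = 3, ...) {
  cat("Michaelis-Menten fit (n =", x$n, "rates)\n")
  cat(sprintf("  Km    = %.*g +/- %.2g uM\n", digits, x$Km, x$Km_se))
  cat(sprintf("  vmax  = %.*g +/- %.2g uM/min\n", digits, x$vmax, x$vmax_se))
  cat(sprintf("  kcat  = %.*g +/- %.2g 1/min (E0 = %g uM)\n",
              digits, x$kcat, x$kcat_se, x$E0))
  cat(sprintf("  kcat/Km = %.*g 1/(min uM)\n", digits, x$efficiency))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(Km = object$Km, vmax = object$vmax, kcat = object$kcat,
    efficiency = object$efficiency)
}

#' @export
vcov.mm_fit <- function(object, ...) vcov(object$fit)

#' @export
residuals.mm_fit <- function(object, ...) residuals(object$fit)

#' @export
fitted.mm_fit <- function(object, ...) fitted(object$fit)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S
       else if (is.data.frame(newdata)) newdata$S else newdata
  object$vmax * S / (object$Km + S)
}

#' @export
summary.mm_fit <- function(object, ...) {
  tab <- rbind(
    Km = c(object$Km, object$Km_se),
    vmax = c(object$vmax, object$vmax_se),
    kcat = c(object$kcat, object$kcat_se),
    `kcat/Km` = c(object$efficiency, object$efficiency_se)
  )
  colnames(tab) <- c("Estimate", "Std. Error")
  out <- list(coefficients = tab, rss = object$rss, n = object$n,
              E0 = object$E0)
  class(out) <- "summary.mm_fit"
  out
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("RSS %.4g on %d rates, E0 = %g uM\n", x$rss, x$n, x$E0))
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...) {
  plot(x$data$S, x$data$v, xlab = "[S] (uM)", ylab = "v (uM/min)",
       pch = 19, ...)
  s <- seq(0, max(x$data$S) * 1.05, length.out = 200)
  lines(s, predict(x, s))
  invisible(x)
}

#' @export
simulate.mm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$rss / max(1, object$n - 2))
  mu <- fitted(object)
  as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, sigma)))
}

#' Catalytic-efficiency table with fold comparisons
#'
#' Computes kcat/Km at full precision for a set of enzymes and the fold
#' ratio of a chosen reference enzyme over every other entry. Efficiencies
#' are displayed rounded half-up to one decimal; folds are computed from the
#' UNROUNDED efficiencies and displayed as integers (rounding the folds from
#' already-rounded table values would distort them, e.g. 21-fold would
#' become 16).
#'
#' @param fits Either a list of `mm_fit` objects or a data frame with
#'   columns `enzyme`, `Km`, `kcat` (an optional `substrate` column is
#'   carried through).
#' @param reference Enzyme name used as fold numerator; default the highest
#'   efficiency.
#' @return Data frame of class `efficiency_report`: `enzyme`, (`substrate`),
#'   `Km`, `kcat`, `efficiency`, `efficiency_display`, `fold_vs_reference`
#'   (unrounded) and `fold_display`.
#' @examples
#' tab <- data.frame(enzyme = c("ApLS", "AaLNS"), Km = c(3.8, 6.7),
#'                   kcat = c(6.0, 0.5))
#' efficiency_report(tab, reference = "ApLS")
#' @export
efficiency_report <- function(fits, reference = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) {
    stopifnot(all(vapply(fits, inherits, logical(1), "mm_fit")))
    df <- data.frame(
      enzyme = names(fits) %||% paste0("enzyme", seq_along(fits)),
      Km = vapply(fits, `[[`, numeric(1), "Km"),
      kcat = vapply(fits, `[[`, numeric(1), "kcat")
    )
  } else {
    df <- as.data.frame(fits)
    stopifnot(all(c("enzyme", "Km", "kcat") %in% names(df)))
  }
  if (any(df$Km <= 0)) stop("all Km must be > 0")
  df$efficiency <- df$kcat / df$Km
  df$efficiency_display <- round_half_up(df$efficiency, 1)
  ref <- reference %||% df$enzyme[which.max(df$efficiency)]
  i <- match(ref, df$enzyme)
  if (is.na(i)) stop("reference enzyme not in table: ", ref)
  df$fold_vs_reference <- df$efficiency[i] / df$efficiency
  df$fold_display <- round_half_up(df$fold_vs_reference)
  attr(df, "reference") <- ref
  class(df) <- c("efficiency_report", "data.frame")
  df
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat("Catalytic efficiencies (reference:", attr(x, "reference"), ")\n")
  show <- as.data.frame(x)
  show$efficiency <- signif(show$efficiency, 4)
  show$fold_vs_reference <- signif(show$fold_vs_reference, 3)
  print(show, row.names = FALSE)
  invisible(x)
}

#' End-to-end kinetic characterization from assay tables
#'
#' Reads standards and assay time courses (the CSV layouts produced by
#' [simulate_assay()]), derives one initial rate per series via the standard
#' curve, and fits the Michaelis-Menten model per enzyme.
#'
#' @param standards Data frame with `concentration_uM`, `signal` (or a CSV
#'   path).
#' @param assays Data frame with `series_id`, `substrate_uM`, `time_min`,
#'   `signal`, `enzyme_uM` (or a CSV path).
#' @return An `mm_fit` (single enzyme concentration assumed per table).
#' @export
kinetics_pipeline <- function(standards, assays) {
  if (is.character(standards)) standards <- utils::read.csv(standards)
  if (is.character(assays)) assays <- utils::read.csv(assays)
  curve <- standard_curve(standards$concentration_uM, standards$signal)
  series <- split(assays, assays$series_id)
  v <- vapply(series, function(s)
    initial_rate(s$time_min, s$signal, curve)$rate, numeric(1))
  S <- vapply(series, function(s) s$substrate_uM[1], numeric(1))
  E0 <- unique(assays$enzyme_uM)
  if (length(E0) != 1) stop("expected a single enzyme concentration per table")
  fit_mm(v, S, E0)
}
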