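#' Area under a melting-curve peak
#'
#' Trapezoidal integral of the background-corrected signal over a
#' temperature window. Baselines: `"zero"` integrates the raw signal;
#' `"linear"` subtracts the straight line between the window's endpoint
#' signals. The resulting area is clipped at 0.
#'
#' @param curve A melting curve: data frame with ascending `temperature`
#'   and `signal` columns (see [simulate_melting_curve()] or
#'   [read_melting_curve()]).
#' @param window Length-2 numeric temperature interval, inside the grid
#'   span and containing at least two grid points.
#' @param baseline `"zero"` (default) or `"linear"`.
#' @return Peak area (non-negative scalar).
#' @export
peak_auc <- function(curve, window, baseline = c("zero", "linear")) {
  baseline <- match.arg(baseline)
  if (!is.data.frame(curve) || !all(c("temperature", "signal") %in% names(curve))) {
    abort("`curve` must have `temperature` and `signal` columns.")
  }
  if (length(window) != 2L || window[1L] >= window[2L]) {
    abort("`window` must be an increasing temperature interval.")
  }
  if (window[1L] < min(curve$temperature) || window[2L] > max(curve$temperature)) {
    abort("`window` must lie within the temperature grid span.")
  }
  keep <- curve$temperature >= window[1L] & curve$temperature <= window[2L]
  if (sum(keep) < 2L) abort("Empty window: fewer than two grid points inside.")
  x <- curve$temperature[keep]
  y <- curve$signal[keep]
  if (baseline == "linear") {
    base <- y[1L] + (y[length(y)] - y[1L]) * (x - x[1L]) / (x[length(x)] - x[1L])
    y <- y - base
  }
  max(pracma::trapz(x, y), 0)
}

#' Methylated-peak AUC metric for a melting curve
#'
#' Computes the area of the methylated-template peak and, by default,
#' normalizes it by the total area of both peaks, so the metric is the
#' methylated area fraction in `[0, 1]`.
#'
#' @inheritParams peak_auc
#' @param unmeth_window,meth_window Temperature windows bracketing the
#'   unmethylated- and methylated-template peaks; the defaults bracket
#'   the simulator's peak centers (78 and 86 deg C).
#' @param normalize Divide the methylated area by the total area
#'   (default `TRUE`); `FALSE` returns the raw methylated-peak AUC.
#' @return The AUC metric (scalar).
#' @export
hrm_metric <- function(curve, unmeth_window = c(73, 82), meth_window = c(82, 91),
                       baseline = c("zero", "linear"), normalize = TRUE) {
  baseline <- match.arg(baseline)
  a_meth <- peak_auc(curve, meth_window, baseline)
  if (!normalize) return(a_meth)
  a_unmeth <- peak_auc(curve, unmeth_window, baseline)
  total <- a_meth + a_unmeth
  if (total == 0) abort("Total peak area is zero; metric undefined.")
  a_meth / total
}

#' Fit the percent-methylation calibration line
#'
#' Ordinary least squares of known percent methylation on the AUC metric
#' of the standards (typically 0%, 50% and 100% methylated templates).
#'
#' @param standards Data frame with columns `known_percent` (in
#'   `[0, 100]`, at least two distinct values) and `metric`.
#' @return An object of class `hrm_calibration`: `slope`, `intercept`,
#'   `r_squared`, `residuals`, `standards` and the underlying `lm` fit.
#' @examples
#' fit_calibration(tibble::tibble(known_percent = c(0, 50, 100),
#'                                metric = c(0, 0.5, 1)))
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("known_percent", "metric") %in% names(standards))) {
    abort("`standards` must have columns `known_percent` and `metric`.")
  }
  if (length(unique(standards$known_percent)) < 2L) {
    abort("At least 2 distinct known percents are required.")
  }
  if (length(unique(standards$metric)) < 2L) {
    abort("non-identifiable calibration: identical metric values across standards.")
  }
  fit <- lm(known_percent ~ metric, data = standards)
  sst <- sum((standards$known_percent - mean(standards$known_percent))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(
      slope = unname(coef(fit)[["metric"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      residuals = unname(stats::residuals(fit)),
      standards = tibble::as_tibble(standards),
      model = fit
    ),
    class = "hrm_calibration"
  )
}

#' @export
print.hrm_calibration <- function(x, ...) {
  cat(sprintf(
    "<hrm_calibration> percent = %.4g + %.4g * metric (r^2 = %.4f, %d standards)\n",
    x$intercept, x$slope, x$r_squared, nrow(x$standards)
  ))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x An `hrm_calibration` object.
#' @param ... Unused.
#' @export
tidy.hrm_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "metric"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_calibration
#' @export
glance.hrm_calibration <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    n_standards = nrow(x$standards),
    sigma = sqrt(mean(x$residuals^2))
  )
}

#' Percent methylation from a calibrated AUC metric
#'
#' Applies the calibration line and clips the prediction into
#' `[0, 100]`, flagging samples whose raw prediction fell outside
#' (extrapolation beyond the standards).
#'
#' @param metric Numeric vector of AUC metrics.
#' @param model An [fit_calibration()] object.
#' @return A tibble `metric`, `percent` (clipped into `[0, 100]`),
#'   `extrapolated`.
#' @export
percent_methylation <- function(metric, model) {
  if (!inherits(model, "hrm_calibration")) {
    abort("`model` must come from fit_calibration().")
  }
  raw <- model$intercept + model$slope * metric
  tibble::tibble(
    metric = metric,
    percent = pmin(pmax(raw, 0), 100),
    extrapolated = raw < 0 | raw > 100
  )
}

#' Read a melting curve from CSV
#'
#' Expects two columns: temperature and the negative derivative signal
#' (`-dF/dT`), with or without a header.
#'
#' @param path CSV file path.
#' @param sample_id Optional label.
#' @return A `melting_curve` tibble.
#' @export
read_melting_curve <- function(path, sample_id = NULL) {
  first <- readr::read_lines(path, n_max = 1L)
  has_header <- !grepl("^[-0-9.eE+]+,", first)
  curve <- readr::read_csv(path,
    col_names = if (has_header) TRUE else c("temperature", "signal"),
    skip = 0L, show_col_types = FALSE, progress = FALSE
  )
  names(curve)[1:2] <- c("temperature", "signal")
  if (is.unsorted(curve$temperature, strictly = TRUE)) {
    abort("Temperature grid must be strictly ascending.")
  }
  attr(curve, "sample_id") <- sample_id
  class(curve) <- c("melting_curve", class(curve))
  curve
}

#' Write a melting curve to CSV
#' @param curve A `melting_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  readr::write_csv(curve[, c("temperature", "signal")], path, progress = FALSE)
  invisible(path)
}
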