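#' Gamma pass rate versus collimator positional offset
#'
#' Simulates mis-positioning of the collimator: for each offset along one
#' axis the GRID dose plane is re-simulated with the block displaced
#' (lateral axes: transverse displacement of the hole pattern; z: a
#' change of effective snout extension, which alters the projection
#' geometry), and a 2D gamma comparison against the fixed reference
#' plane is scored.
#'
#' @param spec a [collimator_spec()].
#' @param model a [beam_model()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param offsets offsets in mm (should include 0).
#' @param reference reference [dose_plane()], held fixed as the
#'   "measurement"; default is the unshifted simulation.
#' @param criteria a [gamma_criteria()].
#' @param depth measurement depth (mm).
#' @param xlim,ylim,spacing lateral simulation window.
#' @param search_step,search_radius gamma search controls (see
#'   [gamma_2d()]).
#' @param mu monitor units.
#' @return data.frame of class `shift_series` with `axis`, `offset` (mm)
#'   and `pass_rate` (%).
#' @export
shift_sweep <- function(spec, model, axis = c("x", "y", "z"),
                        offsets = seq(-4, 4, by = 1),
                        reference = NULL,
                        criteria = gamma_criteria(),
                        depth = 100, xlim = c(-55, 55), ylim = c(-55, 55),
                        spacing = 1, search_step = NULL,
                        search_radius = NULL, mu = 100) {
  axis <- match.arg(axis)
  if (anyDuplicated(offsets)) stop("shift_sweep: offsets must be distinct",
                                   call. = FALSE)
  if (is.null(reference))
    reference <- simulate_plane(spec, model, depth = depth, mu = mu,
                                xlim = xlim, ylim = ylim, spacing = spacing)
  rates <- vapply(offsets, function(off) {
    shift <- c(x = 0, y = 0, z = 0)
    shift[axis] <- off
    shifted <- simulate_plane(spec, model, depth = depth, mu = mu,
                              xlim = xlim, ylim = ylim, spacing = spacing,
                              collimator_shift = unname(shift))
    gamma_2d(reference, shifted, criteria, search_step = search_step,
             search_radius = search_radius)$pass_rate
  }, numeric(1))
  structure(data.frame(axis = axis, offset = offsets, pass_rate = rates),
            class = c("shift_series", "data.frame"))
}

#' Gaussian fit of gamma pass rate versus offset
#'
#' Least-squares fit of \eqn{G(d) = A \exp(-(d - \mu)^2 / (2\sigma^2))}
#' to a shift series, the empirical model used to summarize how the
#' gamma score decays with collimator mis-positioning. Initialization:
#' A at the maximum rate (bounded at 100%), center at the argmax offset,
#' sigma at half the offset span.
#'
#' @param series a [shift_sweep()] result, or any data.frame with
#'   `offset` and `pass_rate` columns.
#' @return Object of class `gamma_gaussian_fit` with components
#'   `amplitude` (%), `center` (mm), `sigma` (mm), `fitted`,
#'   `residuals`, `converged` and `axis`.
#' @export
fit_gamma_gaussian <- function(series) {
  d <- series$offset
  y <- series$pass_rate
  if (length(d) < 4) stop("fit_gamma_gaussian: need at least 4 points",
                          call. = FALSE)
  if (max(y) - min(y) < 1e-9)
    stop("fit_gamma_gaussian: constant pass rates cannot be fitted",
         call. = FALSE)
  span <- diff(range(d))
  ## a start with mu exactly at the symmetry point of symmetric data makes
  ## the mu gradient column vanish, so a jittered start is also tried
  starts <- list(
    list(A = min(max(y), 100), mu = d[which.max(y)],
         sigma = max(span / 2, 1e-3)),
    list(A = min(max(y), 100), mu = d[which.max(y)] + 0.01 * max(span, 1),
         sigma = max(span / 3, 1e-3)))
  df <- data.frame(d = d, y = y)
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(d - mu)^2 / (2 * sigma^2)), data = df,
                        start = start,
                        lower = c(1e-6, -Inf, 1e-6), upper = c(100, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::nls(y ~ A * exp(-(d - mu)^2 / (2 * sigma^2)), data = df,
                   start = start, algorithm = "port",
                   lower = c(A = 1e-6, mu = -Inf, sigma = 1e-6),
                   upper = c(A = 100, mu = Inf, sigma = Inf),
                   control = stats::nls.control(maxiter = 500,
                                                warnOnly = FALSE)),
        error = function(e) NULL)
    }
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit_gamma_gaussian: fit did not converge", call. = FALSE)
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["A"]), center = unname(cf["mu"]),
                 sigma = abs(unname(cf["sigma"])),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 converged = TRUE,
                 axis = if (!is.null(series$axis)) as.character(series$axis[1])
                        else NA_character_,
                 data = df),
            class = "gamma_gaussian_fit")
}

#' Construct a Gaussian gamma-score model from known parameters
#'
#' @param amplitude peak pass rate A (%), in (0, 100].
#' @param center offset of the maximum (mm).
#' @param sigma Gaussian width (mm), > 0.
#' @param axis optional axis label.
#' @return A `gamma_gaussian_fit` object.
#' @export
gamma_gaussian <- function(amplitude, center = 0, sigma, axis = NA_character_) {
  if (amplitude <= 0 || amplitude > 100)
    stop("gamma_gaussian: amplitude must be in (0, 100]", call. = FALSE)
  if (sigma <= 0) stop("gamma_gaussian: sigma must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, center = center, sigma = sigma,
                 fitted = NULL, residuals = NULL, converged = NA,
                 axis = axis, data = NULL),
            class = "gamma_gaussian_fit")
}

#' @export
print.gamma_gaussian_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<gamma_gaussian_fit>%s G(d) = %s%% * exp(-(d - %s mm)^2 / (2 * %s mm^2))\n",
              if (is.na(x$axis)) "" else paste0(" [", x$axis, "]"),
              signif(x$amplitude, digits), signif(x$center, digits),
              signif(x$sigma^2, digits)))
  invisible(x)
}

#' @export
coef.gamma_gaussian_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center = object$center,
    sigma = object$sigma)
}

#' @export
predict.gamma_gaussian_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d
       else if (is.data.frame(newdata)) newdata$offset %||% newdata$d
       else as.numeric(newdata)
  object$amplitude * exp(-(d - object$center)^2 / (2 * object$sigma^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.gamma_gaussian_fit <- function(x, ...) {
  if (is.null(x$data)) {
    d <- seq(x$center - 4 * x$sigma, x$center + 4 * x$sigma, length.out = 200)
    graphics::plot(d, predict(x, d), type = "l", xlab = "Offset (mm)",
                   ylab = "Gamma pass rate (%)", ...)
  } else {
    graphics::plot(x$data$d, x$data$y, xlab = "Offset (mm)",
                   ylab = "Gamma pass rate (%)", ...)
    d <- seq(min(x$data$d), max(x$data$d), length.out = 200)
    graphics::lines(d, predict(x, d))
  }
  invisible(x)
}

#' Positional tolerance at a pass-rate threshold
#'
#' Half-width about the fitted center within which the fitted Gaussian
#' gamma-score curve stays at or above the threshold pass rate:
#' \deqn{w = \sigma \sqrt{2 \ln(A / t)}.}
#' Undefined (error) when the fitted amplitude does not exceed the
#' threshold.
#'
#' @param fit a [fit_gamma_gaussian()] / [gamma_gaussian()] object.
#' @param pass_threshold threshold pass rate (%), default 90.
#' @return Tolerance half-width in mm.
#' @export
tolerance_at <- function(fit, pass_threshold = 90) {
  a <- fit$amplitude
  if (a < pass_threshold)
    stop(sprintf("tolerance_at: fitted amplitude %.2f%% never reaches the %.0f%% threshold",
                 a, pass_threshold), call. = FALSE)
  fit$sigma * sqrt(2 * log(a / pass_threshold))
}
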