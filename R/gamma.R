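#' Gamma comparison criteria
#'
#' @param dose_diff dose-difference criterion, percent of the
#'   normalization dose (global criterion).
#' @param dta distance-to-agreement criterion, mm.
#' @param low_dose_threshold percent of the normalization dose below
#'   which reference points are excluded from scoring (10 is routine;
#'   50 is used for low-resolution chamber arrays).
#' @param normalization `"global_max"` (maximum of the reference plane)
#'   or an explicit dose value.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff = 3, dta = 3, low_dose_threshold = 10,
                           normalization = "global_max") {
  if (dose_diff <= 0 || dta <= 0)
    stop("gamma_criteria: dose_diff and dta must be positive", call. = FALSE)
  if (low_dose_threshold < 0 || low_dose_threshold >= 100)
    stop("gamma_criteria: low_dose_threshold must be in [0, 100)",
         call. = FALSE)
  if (!identical(normalization, "global_max") &&
      !(is.numeric(normalization) && normalization > 0))
    stop("gamma_criteria: normalization must be \"global_max\" or a positive dose",
         call. = FALSE)
  structure(list(dose_diff = dose_diff, dta = dta,
                 low_dose_threshold = low_dose_threshold,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, threshold %g%%, normalization %s\n",
              x$dose_diff, x$dta, x$low_dose_threshold,
              if (identical(x$normalization, "global_max")) "global max"
              else format(x$normalization)))
  invisible(x)
}

#' 2D gamma-index comparison
#'
#' Computes the gamma index of an evaluated dose plane against a
#' reference plane:
#' \deqn{\gamma(e) = \min_r \sqrt{ \frac{|r - e|^2}{\mathrm{DTA}^2} +
#'   \frac{(D_e(e) - D_r(r))^2}{(\Delta D)^2} }}
#' with a global dose-difference denominator
#' \eqn{\Delta D = } `dose_diff`% of the normalization dose. The minimum
#' is searched over reference positions within `search_radius` of each
#' evaluated point, sampling the (bilinearly interpolated) reference at
#' `search_step` spacing. Evaluated points where the reference dose is
#' below the low-dose threshold are excluded from scoring. A point
#' passes when \eqn{\gamma \le 1} (boundary passes).
#'
#' @param reference,evaluated [dose_plane()] objects with overlapping
#'   extent. Gamma is evaluated at the evaluated plane's grid points.
#' @param criteria a [gamma_criteria()].
#' @param search_step search-grid spacing, mm (default `dta / 10`).
#' @param search_radius maximum distance searched, mm (default
#'   `3 * dta`).
#' @return Object of class `gamma_result`: `gamma_map` (matrix, `NA` at
#'   excluded points), `pass_rate` (percent), `n_evaluated`,
#'   `n_passing`, and the criteria.
#' @export
gamma_2d <- function(reference, evaluated, criteria = gamma_criteria(),
                     search_step = NULL, search_radius = NULL) {
  if (is.null(search_step)) search_step <- criteria$dta / 10
  if (is.null(search_radius)) search_radius <- 3 * criteria$dta
  d_norm <- if (identical(criteria$normalization, "global_max"))
    max(reference$values) else criteria$normalization
  if (!is.finite(d_norm) || d_norm <= 0)
    stop("gamma_2d: zero or invalid normalization dose", call. = FALSE)
  dd_abs <- criteria$dose_diff / 100 * d_norm
  thresh <- criteria$low_dose_threshold / 100 * d_norm

  xs <- plane_x(evaluated); ys <- plane_y(evaluated)
  ## reference interpolated at the evaluated points (offset zero)
  ref0 <- bilinear_sample(reference, xs, ys)
  if (all(is.na(ref0)))
    stop("gamma_2d: planes do not overlap", call. = FALSE)
  eval_v <- evaluated$values
  include <- !is.na(ref0) & ref0 >= thresh

  offs <- sort(unique(c(0, seq(-search_radius, search_radius,
                               by = search_step))))
  gamma2 <- matrix(Inf, nrow(eval_v), ncol(eval_v))
  r2max <- search_radius^2
  for (ox in offs) {
    oy_ok <- offs[offs^2 + ox^2 <= r2max + 1e-9]
    if (!length(oy_ok)) next
    for (oy in oy_ok) {
      rs <- bilinear_sample(reference, xs + ox, ys + oy)
      g2 <- (ox^2 + oy^2) / criteria$dta^2 + (eval_v - rs)^2 / dd_abs^2
      gamma2 <- pmin(gamma2, g2, na.rm = TRUE)
    }
  }
  gamma_map <- sqrt(gamma2)
  gamma_map[!include] <- NA_real_
  gamma_map[is.infinite(gamma_map)] <- NA_real_
  n_eval <- sum(!is.na(gamma_map))
  n_pass <- sum(gamma_map <= 1, na.rm = TRUE)
  structure(list(gamma_map = gamma_map,
                 pass_rate = if (n_eval > 0) 100 * n_pass / n_eval else NA_real_,
                 n_evaluated = n_eval, n_passing = n_pass,
                 normalization_dose = d_norm, criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f%% pass (%d / %d points at %g%%/%g mm, threshold %g%%)\n",
              x$pass_rate, x$n_passing, x$n_evaluated,
              x$criteria$dose_diff, x$criteria$dta,
              x$criteria$low_dose_threshold))
  invisible(x)
}

#' Normalize scintillator counts to percent of maximum
#'
#' Relative counts (0-1000 for the scintillation camera) are scaled so
#' the maximum pixel reads exactly 100%.
#'
#' @param counts non-negative numeric matrix of pixel counts.
#' @return Matrix of percentages with maximum exactly 100.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("normalize_counts: counts must be non-negative",
                            call. = FALSE)
  m <- max(counts)
  if (m <= 0) stop("normalize_counts: all-zero counts", call. = FALSE)
  counts / m * 100
}
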