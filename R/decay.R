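#' Population of events versus existence time
#'
#' \eqn{N(t)}: the number of events whose existence time exceeds t,
#' evaluated at t = 0 and at every distinct observed existence time. The
#' curve is non-increasing with \eqn{N(0) =} total events and
#' \eqn{N(t_{max}) = 0}.
#'
#' @param events A [build_events()] tibble, or a numeric vector of existence
#'   times in ps.
#' @return Tibble of class \code{nanosite_popcurve} with columns
#'   \code{t_ns} and \code{n}.
#' @export
population_curve <- function(events) {
  dur_ps <- if (is.numeric(events)) events else events$existence_ps
  if (length(dur_ps) == 0)
    return(structure(tibble(t_ns = numeric(), n = numeric()),
                     class = c("nanosite_popcurve", class(tibble()))))
  t_ns <- c(0, sort(unique(dur_ps))) / 1000
  n <- vapply(t_ns, function(t) sum(dur_ps / 1000 > t), numeric(1))
  out <- tibble(t_ns = t_ns, n = n)
  class(out) <- c("nanosite_popcurve", class(out))
  out
}

#' Fit the single-exponential population decay
#'
#' Nonlinear least-squares fit of \eqn{N(t) = N_0 e^{-\lambda t}} to a
#' population curve, with the decay rate \eqn{\lambda} in ns^-1. The start
#' values come from a log-linear regression on the strictly positive part of
#' the curve. The fit range may be restricted (some analyses fit only an
#' intermediate window of existence times).
#'
#' @param curve A [population_curve()] tibble (columns \code{t_ns},
#'   \code{n}), needing at least 3 distinct times.
#' @param fit_range Optional \code{c(t_min, t_max)} in ns.
#' @return Object of class \code{nanosite_decay}: list with \code{n0},
#'   \code{lambda} (ns^-1), \code{residual_norm}, \code{fit_range},
#'   \code{n_points}, \code{curve}.
#' @export
fit_decay <- function(curve, fit_range = NULL) {
  stopifnot(all(c("t_ns", "n") %in% names(curve)))
  dat <- curve
  if (!is.null(fit_range))
    dat <- dat[dat$t_ns >= fit_range[1] & dat$t_ns <= fit_range[2], ]
  if (length(unique(dat$t_ns)) < 3)
    ns_abort("need at least 3 distinct existence times to fit a decay",
             "insufficient_data_error")
  pos <- dat$n > 0
  if (sum(pos) < 2)
    ns_abort("too few positive population values for a decay fit",
             "insufficient_data_error")
  lf <- stats::lm(log(n) ~ t_ns, data = dat[pos, ])
  start <- list(n0 = exp(coef(lf)[[1]]),
                lambda = max(1e-6, -coef(lf)[[2]]))
  fit <- tryCatch(
    minpack.lm::nlsLM(n ~ n0 * exp(-lambda * t_ns), data = dat,
                      start = start, lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) ns_abort(paste0("decay fit did not converge: ",
                                        conditionMessage(e)), "fit_error"))
  cf <- coef(fit)
  structure(list(n0 = unname(cf["n0"]), lambda = unname(cf["lambda"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fit_range = fit_range %||% range(dat$t_ns),
                 n_points = nrow(dat), curve = dat),
            class = "nanosite_decay")
}

#' @export
print.nanosite_decay <- function(x, ...) {
  cat(sprintf("<decay fit: N0 = %.4g, lambda = %.4g ns^-1, ||resid|| = %.3g (%d points)>\n",
              x$n0, x$lambda, x$residual_norm, x$n_points))
  invisible(x)
}

#' Location statistics of events within the monolayer
#'
#' Boxplot-style quantiles of per-event median distances from the gold-core
#' centre of mass: boxes extend from the 25th to the 75th quantile, whiskers
#' from the 5th to the 95th, with the median as the centre line.
#'
#' @param events A [build_events()] tibble or numeric vector of per-event
#'   median core distances (nm).
#' @return Tibble with columns \code{q05}, \code{q25}, \code{median},
#'   \code{q75}, \code{q95}, \code{n_sites}.
#' @export
location_stats <- function(events) {
  x <- if (is.numeric(events)) events else events$median_core_nm
  if (length(x) == 0)
    ns_abort("no events: location statistics undefined",
             "insufficient_data_error")
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  tibble(q05 = q[1], q25 = q[2], median = q[3], q75 = q[4], q95 = q[5],
         n_sites = length(x))
}
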