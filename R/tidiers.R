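#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: \code{tidy()} returns one row per parameter with
#' columns \code{term}, \code{estimate}; \code{glance()} returns a one-row
#' model summary.
#'
#' @param x A fitted object (\code{nanosite_decay}, \code{nanosite_acf_fit},
#'   \code{nanosite_tumbling}, \code{nanosite_t1}).
#' @param ... Unused.
#' @return A tibble.
#' @name nanosite-tidiers
NULL

#' @rdname nanosite-tidiers
#' @method tidy nanosite_decay
#' @export
tidy.nanosite_decay <- function(x, ...) {
  tibble(term = c("n0", "lambda_ns_inv"), estimate = c(x$n0, x$lambda))
}

#' @rdname nanosite-tidiers
#' @method glance nanosite_decay
#' @export
glance.nanosite_decay <- function(x, ...) {
  tibble(n0 = x$n0, lambda = x$lambda, residual_norm = x$residual_norm,
         n_points = x$n_points)
}

#' @rdname nanosite-tidiers
#' @method tidy nanosite_acf_fit
#' @export
tidy.nanosite_acf_fit <- function(x, ...) {
  tibble(term = c("s2", "a1", "a2", "tau1_ps", "tau2_ps"),
         estimate = c(x$s2, x$a1, x$a2, x$tau1_ps, x$tau2_ps))
}

#' @rdname nanosite-tidiers
#' @method glance nanosite_acf_fit
#' @export
glance.nanosite_acf_fit <- function(x, ...) {
  tibble(s2 = x$s2, a1 = x$a1, a2 = x$a2, tau1_ps = x$tau1_ps,
         tau2_ps = x$tau2_ps, residual_norm = x$residual_norm)
}

#' @rdname nanosite-tidiers
#' @method tidy nanosite_tumbling
#' @export
tidy.nanosite_tumbling <- function(x, ...) {
  tibble(term = c("d_rot_s_inv", "tau_r_ns", "radius_nm"),
         estimate = c(x$d_rot, x$tau_r_ns, x$radius_nm))
}

#' @rdname nanosite-tidiers
#' @method glance nanosite_tumbling
#' @export
glance.nanosite_tumbling <- function(x, ...) {
  tibble(d_rot = x$d_rot, tau_r_ns = x$tau_r_ns, radius_nm = x$radius_nm,
         temperature_k = x$temperature_k, viscosity_pa_s = x$viscosity_pa_s)
}

#' @rdname nanosite-tidiers
#' @method tidy nanosite_t1
#' @export
tidy.nanosite_t1 <- function(x, ...) {
  tibble(term = "t1_s", estimate = x$t1_s)
}

#' @rdname nanosite-tidiers
#' @method glance nanosite_t1
#' @export
glance.nanosite_t1 <- function(x, ...) {
  tibble(t1_s = x$t1_s, n_h = x$n_h, freq_1h_mhz = x$freq_1h_mhz,
         freq_13c_mhz = x$freq_13c_mhz)
}
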