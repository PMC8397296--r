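#' Synthetic CH-vector time series with known relaxation parameters
#'
#' Generates a unit-vector time series whose P2 orientational autocorrelation
#' approaches, as \code{dt -> 0}, the model-free product form
#' \deqn{C(t) = e^{-6 D_{rot} t} [S^2 + (1 - S^2) e^{-t/\tau_e}]}
#' used as ground truth for the relaxation pipeline. The overall motion is
#' small-step isotropic rotational diffusion with coefficient `d_rot`. The
#' internal motion is an azimuthal jump process on a cone: the body-frame
#' vector sits at polar angle theta with \eqn{P_2(\cos\theta) = \sqrt{S^2}}
#' and its azimuth is resampled uniformly at rate \eqn{1/\tau_e}, which gives
#' the bracketed internal ACF exactly (in expectation) for any
#' \eqn{S^2 \in [0, 1]}.
#'
#' @param d_rot Overall rotational diffusion coefficient (s^-1), > 0 (may be
#'   0 to disable overall tumbling).
#' @param s2 Plateau order parameter in [0, 1].
#' @param tau_e Internal correlation time (ps), > 0.
#' @param dt Time step (ps).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param n_vectors Number of independent vectors (averaging mimics the
#'   equivalent carbons of many ligands).
#' @return An \code{n_frames x 3 x n_vectors} array of unit vectors (a matrix
#'   if \code{n_vectors = 1} is requested via `drop = TRUE` semantics: always
#'   the array; use \code{[, , k]} to extract one series).
#' @export
generate_tumbling_vectors <- function(d_rot, s2, tau_e, dt, n_frames,
                                      seed = 1L, n_vectors = 1L) {
  if (s2 < 0 || s2 > 1)
    ns_abort("order parameter s2 must lie in [0, 1]", "parameter_error")
  stopifnot(d_rot >= 0, tau_e > 0, dt > 0, n_frames >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  # cone polar angle: P2(cos theta) = sqrt(s2)
  ct <- sqrt((2 * sqrt(s2) + 1) / 3)
  st <- sqrt(max(0, 1 - ct^2))
  sig <- sqrt(2 * d_rot * 1e-12 * dt)  # rotation-vector component sd per step
  p_jump <- 1 - exp(-dt / tau_e)
  out <- array(NA_real_, c(n_frames, 3, n_vectors))
  for (vv in seq_len(n_vectors)) {
    R <- .rand_rotation()
    phi <- runif(1, 0, 2 * pi)
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        R <- .rotation_from_vec(rnorm(3, sd = sig)) %*% R
        if (runif(1) < p_jump) phi <- runif(1, 0, 2 * pi)
      }
      ub <- c(st * cos(phi), st * sin(phi), ct)
      out[f, , vv] <- R %*% ub
    }
  }
  out
}

# rotation matrix from a rotation vector (axis * angle), Rodrigues formula
.rotation_from_vec <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-14) return(diag(3))
  k <- rv / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# uniform random rotation (for an isotropic initial orientation)
.rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' P2 orientational autocorrelation of unit-vector series
#'
#' \eqn{C(\tau) = \langle P_2(u(t) \cdot u(t+\tau)) \rangle} averaged over
#' time origins and over all supplied vector series. \eqn{C(0) = 1} by
#' construction.
#'
#' @param vectors An \code{n_frames x 3} matrix or \code{n_frames x 3 x k}
#'   array of (not necessarily normalised) vectors.
#' @param dt Frame spacing (ps).
#' @param max_lag Largest lag (ps); default half the series.
#' @return Tibble with columns \code{lag_ps} and \code{acf}.
#' @export
p2_acf <- function(vectors, dt, max_lag = NULL) {
  if (length(dim(vectors)) == 2)
    vectors <- array(vectors, c(dim(vectors), 1))
  nf <- dim(vectors)[1]
  nk <- dim(vectors)[3]
  max_lag <- max_lag %||% (floor(nf / 2) * dt)
  lags <- 0:min(nf - 1, floor(max_lag / dt))
  acc <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (k in seq_len(nk)) {
    U <- vectors[, , k]
    nrmU <- sqrt(rowSums(U * U))
    if (any(nrmU < 1e-12))
      ns_abort("zero-length vector in P2 autocorrelation input", "geometry_error")
    U <- U / nrmU
    for (j in seq_along(lags)) {
      L <- lags[j]
      dots <- rowSums(U[seq_len(nf - L), , drop = FALSE] *
                        U[seq_len(nf - L) + L, , drop = FALSE])
      acc[j] <- acc[j] + sum(1.5 * dots^2 - 0.5)
      cnt[j] <- cnt[j] + (nf - L)
    }
  }
  tibble(lag_ps = lags * dt, acf = acc / cnt)
}
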