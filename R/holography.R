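#' SLM grid model
#'
#' Square phase-only spatial light modulator with a unit-disc aperture.
#' The focal-plane complex field is the discrete Fourier transform of
#' \code{aperture * exp(1i * phase)}; focal-plane coordinates are integer
#' DFT bins with the zero-order (undiffracted) component at bin (0, 0).
#'
#' @param n pixels per side (>= 64).
#' @param aperture optional n x n amplitude mask in [0, 1]; defaults to a
#'   hard disc of radius n/2.
#' @return An \code{slm_grid} object with elements \code{n},
#'   \code{aperture}.
#' @export
slm_grid <- function(n = 64L, aperture = NULL) {
  n <- as.integer(n)
  if (n < 64L) stop("`n` must be >= 64")
  if (is.null(aperture)) {
    cx <- (seq_len(n) - 1L) - (n - 1) / 2
    r <- sqrt(outer(cx^2, cx^2, "+"))
    aperture <- (r <= n / 2) * 1
  }
  if (!all(dim(aperture) == c(n, n))) stop("aperture must be n x n")
  if (any(aperture < 0 | aperture > 1)) stop("aperture values must be in [0, 1]")
  structure(list(n = n, aperture = aperture), class = "slm_grid")
}

# map centered site coordinates (u, v) in (-n/2, n/2) to 1-based array
# indices of the unshifted DFT layout
.site_index <- function(sites, n) {
  sites <- matrix(as.numeric(sites), ncol = 2L)
  if (any(abs(sites) >= n / 2)) stop("site outside the addressable grid")
  if (any(sites != round(sites))) stop("sites must be integer DFT bins")
  cbind(sites[, 1L] %% n + 1L, sites[, 2L] %% n + 1L)
}

#' Propagate a phase mask to the focal plane
#'
#' FFT far-field model: \code{intensity = |DFT(aperture * exp(1i phase))|^2 / n^2}.
#' With this scaling the total focal-plane energy equals the total
#' aperture energy (Parseval).
#'
#' @param mask n x n phase matrix, radians.
#' @param grid an \code{slm_grid}.
#' @return n x n intensity matrix in the unshifted DFT layout (zero-order
#'   at element [1, 1]; use centered site coordinates with
#'   \code{site_intensities}).
#' @export
propagate <- function(mask, grid) {
  if (!inherits(grid, "slm_grid")) stop("`grid` must be an slm_grid")
  if (!all(dim(mask) == c(grid$n, grid$n))) stop("mask/grid shape mismatch")
  f <- stats::fft(grid$aperture * exp(1i * mask))
  Mod(f)^2 / grid$n^2
}

#' Read site intensities from a focal-plane intensity map
#'
#' @param intensity output of \code{propagate}.
#' @param sites m x 2 matrix of centered (u, v) bins.
#' @return numeric vector of site intensities.
#' @export
site_intensities <- function(intensity, sites) {
  idx <- .site_index(sites, nrow(intensity))
  intensity[idx]
}

#' Weighted Gerchberg-Saxton hologram synthesis
#'
#' Iterative Fourier-transform algorithm for multi-spot phase masks with
#' per-site weighting. Each iteration propagates the current mask,
#' measures the complex amplitude at every target site, updates the
#' per-site weight \code{w_m <- w_m * mean(|a|) / |a_m|}, replaces the
#' focal field by weighted target amplitudes at the sites (zero
#' elsewhere), inverse-transforms, and keeps only the phase over the
#' aperture. The per-site compensation factors \code{xi} act as fixed
#' multiplicative prefactors on the target amplitudes and are NOT updated
#' across the k iterations.
#'
#' Site (0, 0) is reserved for the zero-order spot and cannot be a
#' target (in practice the undiffracted light is steered onto a
#' non-fluorescent structure or defocused).
#'
#' @param sites m x 2 integer matrix of target bins (u, v), origin at the
#'   zero order, all distinct, none equal to (0, 0).
#' @param grid an \code{slm_grid}.
#' @param desired_weights relative target intensities (mean-normalized
#'   internally); default uniform.
#' @param xi per-site intensity compensation factors (see
#'   \code{\link{compute_xi}}); default 1.
#' @param k_max number of iterations (>= 1).
#' @param convergence_tol stop early when the relative site-intensity
#'   spread \code{1 - min/max} (after removing desired weights and xi)
#'   drops below this; 0 disables early stopping.
#' @param damping exponent on the weight update, in (0, 1]. The raw
#'   update (\code{damping = 1}) can oscillate when few sites share the
#'   energy (the amplitude response to a weight change has gain ~2 for a
#'   pair of coupled spots); the default 0.5 keeps every case contractive
#'   at a negligible cost in convergence speed.
#' @param seed seed for the uniform random initial phase.
#' @return n x n phase mask in [0, 2pi) with attributes
#'   \code{iterations} and \code{site_amplitudes}.
#' @export
wgs <- function(sites, grid, desired_weights = NULL, xi = 1,
                k_max = 30L, convergence_tol = 0, damping = 0.5,
                seed = 1L) {
  if (!inherits(grid, "slm_grid")) stop("`grid` must be an slm_grid")
  sites <- matrix(as.numeric(sites), ncol = 2L)
  m <- nrow(sites)
  if (m < 1L) stop("at least one target site is required")
  if (anyDuplicated(paste(sites[, 1], sites[, 2]))) stop("sites must be distinct")
  if (any(sites[, 1] == 0 & sites[, 2] == 0)) {
    stop("site (0, 0) is reserved for the zero-order component")
  }
  if (k_max < 1L) stop("`k_max` must be >= 1")
  idx <- .site_index(sites, grid$n)
  if (is.null(desired_weights)) desired_weights <- rep(1, m)
  if (length(desired_weights) != m || any(desired_weights <= 0)) {
    stop("`desired_weights` must be positive, one per site")
  }
  desired_weights <- desired_weights / mean(desired_weights)
  xi <- rep_len(xi, m)
  target_amp <- sqrt(desired_weights) * xi

  set.seed(seed)
  phase <- matrix(stats::runif(grid$n^2, 0, 2 * pi), grid$n, grid$n)
  w <- rep(1, m)
  amps <- rep(NA_real_, m)
  it <- 0L
  for (k in seq_len(k_max)) {
    it <- k
    f <- stats::fft(grid$aperture * exp(1i * phase))
    a <- f[idx]
    amps <- Mod(a)
    rel <- amps / target_amp          # amplitude relative to its target
    if (convergence_tol > 0 &&
        1 - (min(rel) / max(rel))^2 <= convergence_tol) break
    w <- w * (mean(rel) / rel)^damping
    focal <- matrix(0 + 0i, grid$n, grid$n)
    focal[idx] <- w * target_amp * exp(1i * Arg(a))
    back <- stats::fft(focal, inverse = TRUE)
    phase <- Arg(back) %% (2 * pi)
  }
  structure(phase %% (2 * pi), iterations = it, site_amplitudes = amps,
            class = c("phase_mask", "matrix", "array"))
}

#' Per-site intensity compensation factors
#'
#' Given the measured fluorescence intensity \code{I_m} at each
#' illumination site and their average \code{Ibar}, the compensation
#' factor is \deqn{\xi_m = \mathrm{clip}((\bar I / I_m)^{\rho}, 0.5, 4)}
#' which boosts dim sites (e.g. under a blood vessel, or in the distal
#' part of the field of view where diffraction efficiency drops) and
#' attenuates bright ones. \code{rho} controls the feedback strength.
#'
#' @param site_intensities measured intensities, all > 0.
#' @param rho exponent in [0.5, 2].
#' @return xi factors, hard-clipped to [0.5, 4].
#' @export
compute_xi <- function(site_intensities, rho = 1) {
  if (any(!is.finite(site_intensities)) || any(site_intensities <= 0)) {
    stop("all site intensities must be positive (site occluded?)")
  }
  if (rho < 0.5 || rho > 2) stop("`rho` must be in [0.5, 2]")
  pmin(pmax((mean(site_intensities) / site_intensities)^rho, 0.5), 4)
}

#' Radial diffraction-efficiency model
#'
#' Gaussian fall-off of diffraction efficiency with distance from the
#' zero order: \code{eta(r) = exp(-(r / fov_radius)^2 * log(1 / eta_edge))},
#' so \code{eta(0) = 1} and \code{eta(fov_radius) = eta_edge}. The field
#' of view is conventionally bounded where the efficiency reaches 40%.
#'
#' @param fov_radius radius (grid bins) where efficiency = \code{eta_edge}.
#' @param eta_edge efficiency at the FOV edge, default 0.40.
#' @return a monotone non-increasing function \code{eta(r)} with
#'   \code{eta(0) = 1}.
#' @export
efficiency_model <- function(fov_radius, eta_edge = 0.40) {
  if (fov_radius <= 0) stop("`fov_radius` must be > 0")
  if (eta_edge <= 0 || eta_edge > 1) stop("`eta_edge` must be in (0, 1]")
  force(fov_radius); force(eta_edge)
  function(r) exp(-(r / fov_radius)^2 * log(1 / eta_edge))
}

#' Closed-loop per-site intensity compensation
#'
#' Iterates hologram synthesis and simulated measurement: synthesize a
#' mask with the current xi factors, measure site intensities as the FFT
#' propagation attenuated by the radial efficiency \code{eta(r)}, and
#' multiplicatively update xi until the relative spread of the measured
#' intensities falls below \code{tolerance} or \code{feedback_rounds} is
#' reached. Convergence is checked before any update, so a uniform
#' efficiency is a fixed point (xi stays 1). xi is hard-clipped to
#' [0.5, 4] at every round; if larger compensation would be needed the
#' best mask is returned with \code{converged = FALSE}.
#'
#' Because xi multiplies the target amplitude, the measured site
#' intensity responds quadratically to it; the update
#' \code{xi <- clip(xi * (mean(I)/I)^rho)} therefore contracts fastest
#' at \code{rho = 0.5} (one-step convergence under an ideal quadratic
#' response), while \code{rho = 1} makes the loop oscillate between
#' overshoot and undershoot. The default is \code{rho = 0.5}.
#'
#' @param sites m x 2 integer target bins.
#' @param grid an \code{slm_grid}.
#' @param efficiency function eta(r) (e.g. \code{efficiency_model}).
#' @param desired_weights relative target intensities, default uniform.
#' @param rho compensation exponent in [0.5, 2].
#' @param feedback_rounds maximum synthesis/measure rounds.
#' @param tolerance relative intensity spread (max - min)/mean for
#'   convergence.
#' @param k_max WGS iterations per round.
#' @param seed initial-phase seed.
#' @return list with \code{mask}, \code{xi}, \code{intensities} (measured,
#'   desired weights divided out), \code{converged}, \code{rounds}.
#' @export
feedback_compensation <- function(sites, grid, efficiency,
                                  desired_weights = NULL,
                                  rho = 0.5, feedback_rounds = 8L,
                                  tolerance = 0.05, k_max = 30L,
                                  seed = 1L) {
  sites <- matrix(as.numeric(sites), ncol = 2L)
  m <- nrow(sites)
  if (is.null(desired_weights)) desired_weights <- rep(1, m)
  dw <- desired_weights / mean(desired_weights)
  r_site <- sqrt(rowSums(sites^2))
  eta <- efficiency(r_site)
  if (any(eta <= 0 | eta > 1)) stop("efficiency must return values in (0, 1]")

  xi <- rep(1, m)
  best <- NULL
  for (round in seq_len(feedback_rounds)) {
    mask <- wgs(sites, grid, desired_weights = dw, xi = xi,
                k_max = k_max, seed = seed)
    meas <- site_intensities(propagate(mask, grid), sites) * eta / dw
    spread <- (max(meas) - min(meas)) / mean(meas)
    if (is.null(best) || spread < best$spread) {
      best <- list(mask = mask, xi = xi, intensities = meas,
                   spread = spread, rounds = round)
    }
    if (spread <= tolerance) {
      return(list(mask = mask, xi = xi, intensities = meas,
                  converged = TRUE, rounds = round))
    }
    xi <- pmin(pmax(xi * (mean(meas) / meas)^rho, 0.5), 4)
  }
  warning("feedback compensation did not reach tolerance; returning best round")
  list(mask = best$mask, xi = best$xi, intensities = best$intensities,
       converged = FALSE, rounds = best$rounds)
}

#' Fit the scan-plane to SLM-plane calibration transform
#'
#' Least-squares affine map (2 x 2 matrix + offset) between coordinates
#' identified in the scanning reference image and the corresponding
#' holographic focal-plane coordinates; used to target illumination spots
#' on ROIs selected in the scan image with sub-micrometric precision.
#'
#' @param scan_xy m x 2 scan-plane coordinates (m >= 3, non-collinear).
#' @param slm_xy m x 2 matched focal-plane coordinates.
#' @return list of class \code{affine_cal}: \code{A} (2 x 2),
#'   \code{offset} (length 2), \code{residual_rms}.
#' @export
fit_calibration <- function(scan_xy, slm_xy) {
  scan_xy <- as.matrix(scan_xy); slm_xy <- as.matrix(slm_xy)
  if (nrow(scan_xy) < 3L) stop("at least 3 point pairs are required")
  if (!all(dim(scan_xy) == dim(slm_xy))) stop("point sets must match in shape")
  X <- cbind(1, scan_xy)
  if (qr(X)$rank < 3L) stop("calibration points are collinear (degenerate geometry)")
  beta <- qr.solve(X, slm_xy)            # 3 x 2: offset row + linear part
  fitted <- X %*% beta
  res <- slm_xy - fitted
  structure(list(A = t(beta[2:3, , drop = FALSE]),
                 offset = as.numeric(beta[1L, ]),
                 residual_rms = sqrt(mean(res^2))),
            class = "affine_cal")
}

#' @export
predict.affine_cal <- function(object, newdata, ...) {
  p <- as.matrix(newdata)
  t(object$A %*% t(p) + object$offset)
}

#' Per-target dwell time
#'
#' In scanless (parallel holographic) imaging every target is illuminated
#' for the whole frame, so the dwell time is the inverse of the
#' acquisition frequency, independent of the number of targets. In
#' scanning mode the frame time is divided across all pixels.
#'
#' @param mode "scanless" or "scanning".
#' @param f_acq acquisition frequency, Hz.
#' @param n_pixels pixels per frame (scanning mode only, > 0).
#' @return dwell time in seconds.
#' @export
dwell_time <- function(mode = c("scanless", "scanning"), f_acq, n_pixels = NULL) {
  mode <- match.arg(mode)
  if (f_acq <= 0) stop("`f_acq` must be > 0")
  if (mode == "scanless") return(1 / f_acq)
  if (is.null(n_pixels) || n_pixels <= 0) {
    stop("`n_pixels` must be > 0 in scanning mode")
  }
  1 / (f_acq * n_pixels)
}
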