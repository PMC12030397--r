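#' Parameters for variable-frequency complex demodulation
#'
#' @param fw Half-bandwidth of each component in Hz (default 0.04, which
#'   places component centers at 0.04, 0.12, 0.20, ... Hz).
#' @param n_components Number of components (default 8).
#' @param lpf_length Taps of the demodulation low-pass FIR; default scales as
#'   `2 * ceiling(2 * fs / fw) + 1` so the transition band stays narrower
#'   than `fw`.
#' @return A list of class `vfcdm_params`.
#' @export
vfcdm_params <- function(fw = 0.04, n_components = 8, lpf_length = NULL) {
  if (fw <= 0) stop("fw must be positive")
  structure(list(fw = fw, n_components = as.integer(n_components),
                 lpf_length = lpf_length),
            class = "vfcdm_params")
}

# complex zero-phase FIR low-pass of a complex series
fir_zp_complex <- function(z, h) {
  complex(real = fir_zero_phase(Re(z), h), imaginary = fir_zero_phase(Im(z), h))
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Variable-frequency complex demodulation (VFCDM)
#'
#' Two-stage time-frequency decomposition into narrowband components with
#' instantaneous amplitudes:
#'
#' 1. Fixed-frequency complex demodulation at centers
#'    `f_k = (2k - 1) * fw`: the signal is multiplied by
#'    `exp(-i 2 pi f_k t)`, low-passed at `fw`, and the band signal
#'    reconstructed as `2 Re(z_k exp(+i 2 pi f_k t))`.
#' 2. Each band is refined by demodulating along its instantaneous-frequency
#'    track (derivative of the stage-1 analytic phase, smoothed and clamped
#'    to the band) and low-passing again.
#'
#' Components whose nominal center lies at or above Nyquist cannot be
#' demodulated without aliasing and are returned as zero signals with edges
#' truncated at Nyquist; the component count is kept so that "component k"
#' always refers to the same nominal band.
#'
#' @param x A zero-mean (high-passed or detrended) `uniform_signal`.
#' @param params A `vfcdm_params` object.
#' @return A `component_set` with `method = "VFCDM"`.
#' @export
vfcdm <- function(x, params = vfcdm_params()) {
  stopifnot(inherits(x, "uniform_signal"))
  fs <- x$fs; fw <- params$fw
  if (fw >= fs / 2) stop("fw must be below Nyquist")
  v <- x$values - mean(x$values)
  n <- length(v)
  ntaps <- params$lpf_length
  if (is.null(ntaps)) ntaps <- 2L * ceiling(2 * fs / fw) + 1L
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  if (n < 8L * ntaps)
    stop(sprintf("signal too short for VFCDM: need >= %d samples", 8L * ntaps))
  h <- signal::fir1(ntaps - 1L, fw / (fs / 2), type = "low")
  tt <- (seq_len(n) - 1L) / fs
  dt <- 1 / fs

  comps <- vector("list", params$n_components)
  centers <- (2 * seq_len(params$n_components) - 1) * fw
  edges <- cbind(pmax(0, centers - fw), pmin(fs / 2, centers + fw))
  for (k in seq_len(params$n_components)) {
    fk <- centers[k]
    if (fk >= fs / 2) {  # center at/above Nyquist: demodulation would alias
      comps[[k]] <- uniform_signal(numeric(n), fs, x$t0,
                                   sprintf("VFCDM band %d (empty)", k))
      next
    }
    z1 <- fir_zp_complex(v * exp(-2i * pi * fk * tt), h)
    # stage 2: instantaneous frequency of the band, weighted by the local
    # analytic power so that stretches without band content keep the track
    # at the nominal center instead of wandering on phase noise
    phi <- unwrap_phase(Arg(z1))
    dphi <- c(phi[2] - phi[1], (phi[3:n] - phi[1:(n - 2)]) / 2, phi[n] - phi[n - 1])
    dev <- dphi / (2 * pi * dt)
    wgt <- Mod(z1)^2
    num <- fir_zero_phase(wgt * dev, h)
    den <- fir_zero_phase(wgt, h)
    finst <- fk + num / (den + 1e-3 * mean(wgt) + .Machine$double.eps)
    # clamp the track to the inner quarter-band: a band whose only content
    # is leakage from a strong neighbour would otherwise ride its track to
    # the band edge and pull that neighbour into its pass band
    finst <- pmin(pmax(finst, max(0, fk - fw / 4)), min(fk + fw / 4, fs / 2))
    theta <- 2 * pi * (cumsum(finst) - finst[1]) * dt
    z2 <- fir_zp_complex(v * exp(-1i * theta), h)
    comps[[k]] <- uniform_signal(2 * Re(z2 * exp(1i * theta)), fs, x$t0,
                                 sprintf("VFCDM band %d", k))
  }
  component_set(comps, centers, edges, "VFCDM")
}
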