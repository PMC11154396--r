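# Gaussian smoothing by an analytic transfer function in the Fourier domain,
# with periodic boundaries. Used for random-field synthesis (tissue blobs)
# and for the spatially correlated model-error field of the detection map;
# periodic wrap is the standard spectral-synthesis convention for stationary
# random fields and avoids edge artefacts.
gaussian_smooth_fft <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  h <- nrow(m)
  w <- ncol(m)
  fy <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1)[seq_len(h)] / h
  fx <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1)[seq_len(w)] / w
  transfer <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(fft(fft(m) * transfer, inverse = TRUE)) / (h * w)
}
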