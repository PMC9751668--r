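#' @include grid.R
NULL

## Gaussian smoothing of a 3D array with a physically specified sigma (mm),
## implemented as an FFT convolution with a separable, wrapped, unit-sum
## kernel. Anisotropic voxel spacing is respected by converting the mm
## sigma to a per-axis voxel sigma. sigma = 0 is the exact identity.
gaussianBlur <- function(arr, sigmaMM, spacing) {
  if (sigmaMM <= 0) return(arr)
  d <- dim(arr)
  k1 <- function(n, sp) {
    sig <- sigmaMM / sp
    x <- c(0:(n %/% 2), if (n > 1) -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (x / sig)^2)
    k / sum(k)
  }
  kern <- outer(outer(k1(d[1], spacing[1]), k1(d[2], spacing[2]), "*"),
                k1(d[3], spacing[3]), "*")
  out <- Re(stats::fft(stats::fft(arr) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
  ## FFT round-off can leave tiny negatives on a nonnegative input
  pmax(out, 0)
}
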