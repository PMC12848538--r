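#' Simulate a diffusion-weighted acquisition from a tensor field
#'
#' The noiseless signal of volume i follows the single-tensor model
#' `S_i = S0 * exp(-b_i * g_i' D g_i)`. Rician noise is applied through the
#' two-channel Gaussian construction `sqrt((S + e1)^2 + e2^2)` with
#' independent zero-mean Gaussians `e1, e2` of scale `noiseSigma` (the
#' magnitude of a complex Gaussian perturbation, the standard model for
#' magnitude MRI). A given `seed` fully determines the output.
#'
#' @param tensors a [TensorField-class] (positive definite in-mask).
#' @param gtab a [GradientTable-class]; defaults to the packaged 8 b=0 +
#'   64-direction b=1000 s/mm^2 scheme.
#' @param s0 non-diffusion-weighted signal level.
#' @param noiseSigma Rician noise scale (0 for noiseless data).
#' @param seed RNG seed; one seeded generator drives the whole call.
#' @return a [DWIVolume-class].
#' @examples
#' tf <- directorsToTensors(makePatternField("uniform", c(5, 5, 5)))
#' dwi <- simulateDWI(tf, noiseSigma = 0)
#' range(imgData(dwi)[, , , 1])   # b=0 volume equals s0 exactly
#' @export
simulateDWI <- function(tensors, gtab = defaultGradientTable(), s0 = 1000,
                        noiseSigma = 0, seed = NULL) {
  stopifnot(is(tensors, "TensorField"), is(gtab, "GradientTable"))
  if (!is.numeric(noiseSigma) || noiseSigma < 0)
    stop("noiseSigma must be non-negative")
  d <- dim(tensors@values)[1:3]
  t6 <- matrix(tensors@values, ncol = 6L)
  q <- tensorQuadForm(t6, gtab@bvecs)            # voxels x volumes
  S <- s0 * exp(-sweep(q, 2, gtab@bvals, `*`))
  if (noiseSigma > 0) {
    S <- withSeed(seed, {
      e1 <- stats::rnorm(length(S), 0, noiseSigma)
      e2 <- stats::rnorm(length(S), 0, noiseSigma)
      sqrt((S + e1)^2 + e2^2)
    })
  }
  new("DWIVolume", data = array(S, c(d, nVolumes(gtab))), gtab = gtab,
      mask = tensors@mask, spacing = tensors@spacing,
      meta = list(s0 = s0, noiseSigma = noiseSigma))
}

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@data)
  cat("DWIVolume:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "volumes,", sum(object@mask), "in-mask voxels\n")
  cat("  spacing (mm):", paste(object@spacing, collapse = " x "),
      " axes:", object@axes, "\n")
})
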