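#' Stimulation protocol constructor
#'
#' Classifies a pulse frequency into the excitatory/inhibitory polarity
#' convention: high-frequency trains (> 5 Hz) are excitatory (+1),
#' low-frequency trains (<= 1 Hz) inhibitory (-1). Frequencies in (1, 5] Hz
#' are rejected as unclassified.
#'
#' @param frequencyHz positive pulse frequency in Hz.
#' @return A \code{\linkS4class{StimProtocol}}.
#' @export
stimProtocol <- function(frequencyHz) {
  if (!is.numeric(frequencyHz) || length(frequencyHz) != 1L ||
      !is.finite(frequencyHz) || frequencyHz <= 0)
    stop("frequencyHz must be a positive number")
  if (frequencyHz > 5) pol <- 1
  else if (frequencyHz <= 1) pol <- -1
  else stop("frequency in (1, 5] Hz is unclassified under the ",
            "excitatory/inhibitory convention")
  new("StimProtocol", frequencyHz = frequencyHz, polarity = pol)
}

#' @describeIn stimProtocol polarity accessor (+1 excitatory, -1 inhibitory).
#' @param protocol a \code{StimProtocol}.
#' @export
polarity <- function(protocol) protocol@polarity

#' Simplified induced E-field magnitude
#'
#' Desk-scale stand-in for a finite-element E-field solution: a Gaussian
#' falloff with tangential distance from the coil axis times an exponential
#' decay with depth below the scalp,
#' \code{peak * exp(-r^2 / (2 sigma^2)) * exp(-d / depthDecay)}.
#' With \code{anisotropy < 1} the tangential footprint is elongated along
#' the coil handle (the effective across-handle sigma is
#' \code{anisotropy * sigma}), which makes the field - and everything
#' downstream - orientation sensitive, as a figure-8 coil's field is.
#'
#' @param frame a \code{CoilFrame} from \code{\link{coilFrame}}.
#' @param grid the \code{VoxelGrid} to evaluate on.
#' @param peak field magnitude at the coil axis on the scalp, V/m.
#' @param sigma tangential Gaussian width, mm.
#' @param depthDecay exponential depth decay length, mm.
#' @param anisotropy across-handle/along-handle sigma ratio in (0, 1].
#' @return A nonnegative \code{BrainMap} of field magnitudes.
#' @export
syntheticEField <- function(frame, grid, peak = 100, sigma = 12,
                            depthDecay = 18, anisotropy = 1) {
  if (peak < 0 || sigma <= 0 || depthDecay <= 0 || anisotropy <= 0 ||
      anisotropy > 1)
    stop("E-field parameters must be positive (anisotropy in (0, 1])")
  rel <- sweep(grid@coords, 2L, frame$center)
  depth <- as.numeric(rel %*% (-frame$normal))
  if (anisotropy == 1) {
    r2 <- rowSums(rel^2) - depth^2
    r2 <- pmax(r2, 0)
  } else {
    across <- .unit(.cross(frame$normal, frame$handleDir))
    u <- as.numeric(rel %*% frame$handleDir)
    w <- as.numeric(rel %*% across)
    r2 <- u^2 + (w / anisotropy)^2
  }
  vals <- peak * exp(-r2 / (2 * sigma^2)) * exp(-pmax(depth, 0) / depthDecay)
  BrainMap(grid, vals)
}

#' Threshold an E-field map to its suprathreshold support
#'
#' The support is the set of gray-matter voxels whose magnitude reaches
#' \code{percent}\% of the robust peak, defined as the 99.9th percentile of
#' the strictly positive gray-matter magnitudes (robust against isolated
#' solver spikes).
#'
#' @param efield nonnegative \code{BrainMap}.
#' @param percent threshold in [0, 100).
#' @return Integer voxel indices (into the masked-voxel vector).
#' @export
thresholdEField <- function(efield, percent) {
  if (percent < 0 || percent >= 100) stop("percent must be in [0, 100)")
  vals <- efield@values
  if (any(vals < 0)) stop("E-field magnitudes must be nonnegative")
  pos <- vals[vals > 0]
  if (length(pos) == 0L)
    stop("no stimulation: E-field is zero over the gray-matter mask")
  peak <- quantile(pos, 0.999, names = FALSE, type = 7)
  cut <- percent / 100 * peak
  support <- which(vals > 0 & vals >= cut)
  if (length(support) == 0L)
    stop("no stimulation: all voxels fall below the threshold")
  support
}

#' Signed local-effect vector of a placement
#'
#' Builds the sparse signed vector of direct stimulation effects: the
#' suprathreshold voxels carry +w (excitatory protocols) or -w (inhibitory
#' protocols), zero elsewhere. By default w is the E-field magnitude at the
#' voxel (E-field weighting); \code{weighting = "uniform"} uses w = 1.
#'
#' @param efield nonnegative \code{BrainMap}.
#' @param percent threshold percent, see \code{\link{thresholdEField}}.
#' @param protocol a \code{StimProtocol}.
#' @param weighting "magnitude" (default) or "uniform".
#' @return A \code{\linkS4class{LocalEffect}}.
#' @export
localEffectVector <- function(efield, percent, protocol,
                              weighting = c("magnitude", "uniform")) {
  weighting <- match.arg(weighting)
  support <- thresholdEField(efield, percent)
  w <- if (weighting == "magnitude") efield@values[support]
       else rep(1, length(support))
  new("LocalEffect", grid = efield@grid, support = as.integer(support),
      weights = protocol@polarity * w)
}
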