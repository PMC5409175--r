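# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring global state afterwards.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Add imaging noise to a volume
#'
#' MR magnitude noise is Rician: the output is
#' `sqrt((S + sigma*N1)^2 + (sigma*N2)^2)`; CT noise is additive Gaussian.
#' Note the Rician identity `E[M^2] = S^2 + 2 sigma^2`, so organ means can
#' be background-corrected as `sqrt(mean(M^2) - 2 sigma^2)`.
#'
#' @param vol an [ImageVolume-class].
#' @param model `"rician"` or `"gaussian"`.
#' @param sigma noise standard deviation (image units).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @export
addImageNoise <- function(vol, model = c("rician", "gaussian"), sigma,
                          seed = NULL) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(vol)
  d <- dim(vol@voxels)
  v <- withSeed(seed, {
    if (model == "gaussian") vol@voxels + array(rnorm(prod(d), 0, sigma), d)
    else sqrt((vol@voxels + array(rnorm(prod(d), 0, sigma), d))^2 +
              array(rnorm(prod(d), 0, sigma), d)^2)
  })
  imageVolume(v, affine = vol@affine, modality = vol@modality,
              frame = vol@frame)
}

#' Rician background correction of a mean signal
#' @param meanSq mean of squared magnitudes in a region.
#' @param sigma noise sigma.
#' @export
riceCorrectedMean <- function(meanSq, sigma) sqrt(pmax(meanSq - 2 * sigma^2, 0))

#' Multi-level Otsu thresholds
#'
#' Exhaustive search over a histogram for the thresholds maximizing
#' between-class variance.
#'
#' @param values numeric vector.
#' @param nClasses number of classes (2 or 3).
#' @param nBins histogram bins.
#' @return numeric vector of `nClasses - 1` thresholds.
#' @export
otsuThresholds <- function(values, nClasses = 2, nBins = 128) {
  rng <- range(values)
  if (diff(rng) == 0) stop("constant input has no Otsu threshold")
  h <- tabulate(pmin(pmax(floor((values - rng[1]) / diff(rng) * nBins) + 1, 1),
                     nBins), nBins)
  mids <- rng[1] + (seq_len(nBins) - 0.5) * diff(rng) / nBins
  p <- h / sum(h)
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  totalMean <- cm[nBins]
  classStat <- function(a, b) { # class = bins (a, b]
    w <- cw[b] - if (a > 0) cw[a] else 0
    if (w <= 0) return(0)
    m <- (cm[b] - if (a > 0) cm[a] else 0) / w
    w * (m - totalMean)^2
  }
  if (nClasses == 2) {
    best <- -Inf; bi <- 1
    for (t in 1:(nBins - 1)) {
      v <- classStat(0, t) + classStat(t, nBins)
      if (v > best) { best <- v; bi <- t }
    }
    return(rng[1] + bi * diff(rng) / nBins)
  }
  if (nClasses != 3) stop("nClasses must be 2 or 3")
  best <- -Inf; bi <- c(1, 2)
  for (t1 in 1:(nBins - 2)) {
    s1 <- classStat(0, t1)
    for (t2 in (t1 + 1):(nBins - 1)) {
      v <- s1 + classStat(t1, t2) + classStat(t2, nBins)
      if (v > best) { best <- v; bi <- c(t1, t2) }
    }
  }
  rng[1] + bi * diff(rng) / nBins
}

#' Contrast-to-noise ratio of a structure against surrounding tissue
#'
#' CNR = |mean(structure) - mean(shell)| / sigma, where the shell is the
#' reference structure (default `"body"`) within `shellMm` of the target's
#' bounding box and sigma is the noise level.
#'
#' @param vol an ImageVolume.
#' @param truth a [StructureSet-class] on the same grid.
#' @param name target structure name.
#' @param sigma noise standard deviation used by the renderer.
#' @param reference surrounding-tissue structure name.
#' @param shellMm shell half-width around the target bounding box.
#' @export
contrastToNoise <- function(vol, truth, name, sigma, reference = "body",
                            shellMm = 2) {
  m <- structureMask(truth, name)
  idx <- which(m, arr.ind = TRUE)
  sp <- voxelSpacing(vol)
  pad <- ceiling(shellMm / sp)
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, dim(vol@voxels))
  box <- array(FALSE, dim(vol@voxels))
  box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  surround <- box & structureMask(truth, reference) & truth@labels ==
    truth@labelNames[[reference]]
  if (!any(surround)) stop("no surrounding tissue near '", name, "'")
  abs(mean(vol@voxels[m]) - mean(vol@voxels[surround])) / sigma
}

# Largest 26-connected component of a logical mask that contains the
# highest-valued voxel of `weights` inside the mask.
peakComponent <- function(mask, weights = NULL) {
  if (!any(mask)) stop("empty mask")
  num <- array(0, dim(mask)); num[mask] <- 1
  if (is.null(weights)) weights <- num
  w <- weights; w[!mask] <- -Inf
  seed <- arrayInd(which.max(w), dim(mask))
  array(region_grow_cpp(as.numeric(num), as.integer(dim(mask)),
                        as.integer(seed - 1L), 0.5, 1.5), dim(mask))
}
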