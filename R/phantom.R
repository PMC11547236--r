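# Synthetic test volumes with the intensity structure the algorithm
# assumes: bright bodies, dimmer bridges, dark background, then blur
# (sharpness) and additive noise (contrast resolution), in that order
# so the two scan-quality axes stay independent.

#' Render a phantom volume with ground truth
#'
#' Renders spherical bodies at their core intensities, joined by
#' cylindrical bridge slabs at their (lower) bridge intensities, over a
#' uniform background; applies Gaussian blur, then additive Gaussian
#' noise clipped to \code{[0, 65535]}, seeded deterministically from
#' \code{rngSeed}. The ground truth labels each body's voxels with the
#' body's index; bridge voxels are split by nearest body centre
#' between the two bodies the bridge joins (the breadth-first growth
#' boundary approximates equidistance, so nearest-centre is the fair
#' reference, a convention rather than anatomy).
#'
#' @param spec a [PhantomSpec].
#' @return A list with \code{volume} (an [IntensityVolume]),
#'   \code{groundTruth} (a [LabelVolume], one label per body) and
#'   \code{spec}.
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSigma = 0, blurSigma = 0))
#' table(labelArray(ph$groundTruth))
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@size
  nbody <- length(spec@bodies)
  for (i in seq_len(nbody)) for (j in seq_len(nbody)) {
    if (i >= j) next
    ci <- spec@bodies[[i]]; cj <- spec@bodies[[j]]
    if (sqrt(sum((ci$centre - cj$centre)^2)) <= ci$radius + cj$radius)
      stop("bodies ", i, " and ", j, " overlap")
  }

  n <- prod(d)
  zc <- array(seq_len(d[1L]), d)
  yc <- array(rep(seq_len(d[2L]), each = d[1L]), d)
  xc <- array(rep(seq_len(d[3L]), each = d[1L] * d[2L]), d)
  img <- array(spec@backgroundIntensity, d)
  truth <- array(0L, d)

  dist_to_segment <- function(p1, p2) {
    v <- p2 - p1
    len2 <- sum(v^2)
    t <- ((zc - p1[1L]) * v[1L] + (yc - p1[2L]) * v[2L] +
            (xc - p1[3L]) * v[3L]) / len2
    t <- pmin(pmax(t, 0), 1)
    sqrt((zc - (p1[1L] + t * v[1L]))^2 +
         (yc - (p1[2L] + t * v[2L]))^2 +
         (xc - (p1[3L] + t * v[3L]))^2)
  }

  for (br in spec@bridges) {
    pa <- spec@bodies[[br$a]]$centre
    pb <- spec@bodies[[br$b]]$centre
    inside <- dist_to_segment(pa, pb) <= br$thickness / 2
    img[inside] <- br$intensity
    da <- sqrt((zc - pa[1L])^2 + (yc - pa[2L])^2 + (xc - pa[3L])^2)
    db <- sqrt((zc - pb[1L])^2 + (yc - pb[2L])^2 + (xc - pb[3L])^2)
    assign_here <- inside & truth == 0L
    truth[assign_here] <- ifelse(da[assign_here] <= db[assign_here],
                                 br$a, br$b)
  }
  for (i in seq_len(nbody)) {
    b <- spec@bodies[[i]]
    inside <- (zc - b$centre[1L])^2 + (yc - b$centre[2L])^2 +
      (xc - b$centre[3L])^2 <= b$radius^2
    img[inside] <- b$intensity
    truth[inside] <- i
  }

  if (spec@blurSigma > 0)
    img <- .gaussianBlur3D(img, spec@blurSigma)

  if (spec@noiseSigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed))
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec@rngSeed)
    img <- img + stats::rnorm(n, 0, spec@noiseSigma)
  }

  img <- floor(pmin(pmax(img, 0), 65535) + 0.5)
  dim(img) <- d
  list(volume = IntensityVolume(img), groundTruth = LabelVolume(truth),
       spec = spec)
}

# separable 3D Gaussian blur; truncated kernel renormalized at the
# edges so constant regions stay constant
.gaussianBlur3D <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    num <- array(0, d)
    den <- array(0, d)
    for (j in -r:r) {
      w <- k[j + r + 1L]
      src <- seq_len(d[axis]) + j
      ok <- src >= 1L & src <= d[axis]
      if (!any(ok)) next
      dst_idx <- which(ok)
      src_idx <- src[ok]
      if (axis == 1L) {
        num[dst_idx, , ] <- num[dst_idx, , ] + w * a[src_idx, , ]
        den[dst_idx, , ] <- den[dst_idx, , ] + w
      } else if (axis == 2L) {
        num[, dst_idx, ] <- num[, dst_idx, ] + w * a[, src_idx, ]
        den[, dst_idx, ] <- den[, dst_idx, ] + w
      } else {
        num[, , dst_idx] <- num[, , dst_idx] + w * a[, , src_idx]
        den[, , dst_idx] <- den[, , dst_idx] + w
      }
    }
    num / den
  }
  conv_axis(conv_axis(conv_axis(arr, 1L), 2L), 3L)
}
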