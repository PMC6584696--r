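#' Detect corner-like features for tracking
#'
#' Shi-Tomasi minimum-eigenvalue corner response with greedy non-maximum
#' selection: strongest features first, enforcing a minimum spacing, up to a
#' maximum count.
#'
#' @param img numeric matrix in [0, 255].
#' @param maxFeatures maximum number of features.
#' @param minSpacing minimum spacing between accepted features, px.
#' @param qualityLevel minimum response relative to the strongest feature.
#' @return n x 2 matrix of 0-based (row, col) positions.
#' @export
detectFeatures <- function(img, maxFeatures = 500L, minSpacing = 8,
                           qualityLevel = 0.01) {
  r <- cpp_min_eig(img / GMAX, 2L)
  # exclude a small border
  m <- 4L
  r[c(seq_len(m), nrow(r) - seq_len(m) + 1L), ] <- 0
  r[, c(seq_len(m), ncol(r) - seq_len(m) + 1L)] <- 0
  thr <- qualityLevel * max(r)
  idx <- which(r > thr)
  if (!length(idx)) return(matrix(numeric(), 0L, 2L))
  idx <- idx[order(-r[idx])]
  rows <- (idx - 1L) %% nrow(r)
  cols <- (idx - 1L) %/% nrow(r)
  gw <- max(1, minSpacing)
  occ <- new.env(hash = TRUE)
  keep <- integer()
  for (i in seq_along(idx)) {
    cr <- floor(rows[i] / gw); cc <- floor(cols[i] / gw)
    clash <- FALSE
    for (dr in -1:1) {
      for (dc in -1:1) {
        k <- paste(cr + dr, cc + dc)
        pts <- occ[[k]]
        if (!is.null(pts) &&
            any((pts[, 1L] - rows[i])^2 + (pts[, 2L] - cols[i])^2 <
                minSpacing^2)) {
          clash <- TRUE
          break
        }
      }
      if (clash) break
    }
    if (clash) next
    k <- paste(cr, cc)
    occ[[k]] <- rbind(occ[[k]], c(rows[i], cols[i]))
    keep <- c(keep, i)
    if (length(keep) >= maxFeatures) break
  }
  cbind(rows[keep], cols[keep])
}

# Least-squares similarity fit (4 dof) mapping src -> dst with
# median-absolute-deviation outlier gating; returns c(tx, ty, theta, scale).
.fitSimilarity <- function(src, dst) {
  fit <- function(s, d) {
    x <- s[, 1L]; y <- s[, 2L]; u <- d[, 1L]; v <- d[, 2L]
    n <- length(x)
    A <- rbind(cbind(x, -y, 1, 0), cbind(y, x, 0, 1))
    b <- c(u, v)
    qr.solve(A, b)
  }
  if (nrow(src) < 3L) return(NULL)
  co <- fit(src, dst)
  for (it in 1:2) {
    pred <- cbind(co[1L] * src[, 1L] - co[2L] * src[, 2L] + co[3L],
                  co[2L] * src[, 1L] + co[1L] * src[, 2L] + co[4L])
    res <- sqrt(rowSums((pred - dst)^2))
    gate <- max(3 * 1.4826 * stats::median(res), 0.3)
    keep <- res <= gate
    if (sum(keep) < 3L) break
    src <- src[keep, , drop = FALSE]
    dst <- dst[keep, , drop = FALSE]
    co <- fit(src, dst)
  }
  c(co[3L], co[4L], atan2(co[2L], co[1L]), sqrt(co[1L]^2 + co[2L]^2))
}

#' Estimate per-frame motion transforms
#'
#' Corner features detected in the first frame are tracked into every later
#' frame by sparse pyramidal iterative Lucas-Kanade optical flow, and a
#' similarity transform (translation, rotation, scale) is fitted to the
#' correspondences by least squares with median-absolute-deviation outlier
#' gating. Frames are intensity-normalized (zero mean, unit variance)
#' before tracking so that global brightness flicker does not violate the
#' brightness-constancy assumption. Tracking against the anchor frame
#' avoids the error accumulation of chaining consecutive pairs; the
#' returned transform for frame t maps frame-t coordinates into frame-1
#' coordinates, so its translation equals minus the scene displacement of
#' frame t. Frames with too few tracked features inherit the previous
#' frame's transform; if the first frame has too few features the function
#' warns and returns identities.
#'
#' @param seq an [ImageSequence-class] with >= 2 frames.
#' @param params parameter list from [hvmParams()].
#' @return nFrames x 4 matrix with columns `tx`, `ty` (px), `theta` (rad),
#'   `scale`; row 1 is the identity `(0, 0, 0, 1)`.
#' @export
estimateTransforms <- function(seq, params = hvmParams()) {
  fr <- frames(seq)
  stopifnot(length(fr) >= 2L)
  n <- length(fr)
  out <- matrix(rep(c(0, 0, 0, 1), each = n), n, 4L,
                dimnames = list(NULL, c("tx", "ty", "theta", "scale")))
  norm1 <- function(f) {
    s <- stats::sd(f)
    if (s < 1e-9) f - mean(f) else (f - mean(f)) / s
  }
  pts <- detectFeatures(fr[[1L]], params$stab_max_features,
                        params$stab_min_spacing)
  if (nrow(pts) < params$stab_min_features) {
    warning("too few trackable features in the first frame; returning identity transforms")
    return(out)
  }
  anchor <- norm1(fr[[1L]])
  last <- c(0, 0, 0, 1)
  for (t in 2:n) {
    tr <- cpp_lk_track(anchor, norm1(fr[[t]]), pts[, 1L], pts[, 2L],
                       params$stab_window, params$stab_pyr_levels,
                       params$stab_iterations, params$stab_eps)
    ok <- tr[, 3L] > 0
    cur <- NULL
    if (sum(ok) >= params$stab_min_features)
      cur <- .fitSimilarity(tr[ok, 1:2, drop = FALSE],
                            pts[ok, , drop = FALSE])
    if (is.null(cur)) cur <- last else last <- cur
    out[t, ] <- cur
  }
  out
}

#' Smooth a transform trajectory
#'
#' Centered moving average of each cumulative component (tx, ty, theta,
#' log scale) with a symmetric window that shrinks near the sequence ends.
#' Because the smoothing is applied to the cumulative trajectory and only
#' the residual raw - smoothed is later corrected, slow physiological
#' panning is preserved while frame-to-frame jitter is removed. A window
#' larger than the sequence is clamped with a warning.
#'
#' @param transforms nFrames x 4 matrix from [estimateTransforms()].
#' @param window odd window length in frames (>= 1).
#' @return smoothed matrix of the same shape.
#' @export
smoothTrajectory <- function(transforms, window = 15L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- nrow(transforms)
  if (window > n) {
    warning("smoothing window larger than sequence; clamping")
    window <- if (n %% 2L == 1L) n else n - 1L
  }
  hw <- (window - 1L) %/% 2L
  smoothVec <- function(v) {
    vapply(seq_len(n), function(i) {
      h <- min(hw, i - 1L, n - i)
      mean(v[(i - h):(i + h)])
    }, numeric(1))
  }
  out <- transforms
  out[, 1L] <- smoothVec(transforms[, 1L])
  out[, 2L] <- smoothVec(transforms[, 2L])
  out[, 3L] <- smoothVec(transforms[, 3L])
  out[, 4L] <- exp(smoothVec(log(transforms[, 4L])))
  out
}

#' Warp frames by correction transforms and crop to the common valid region
#'
#' Each frame is warped (bilinear interpolation) by its correction
#' transform; pixels sampled outside the source frame are invalid. The
#' output is cropped to the intersection of all frames' valid regions and
#' the field of view follows from the cropped raster.
#'
#' @param seq an [ImageSequence-class].
#' @param corrections nFrames x 4 transform matrix (identity rows leave
#'   frames untouched).
#' @return stabilized, cropped [ImageSequence-class].
#' @export
applyAndCrop <- function(seq, corrections) {
  fr <- frames(seq)
  stopifnot(nrow(corrections) == length(fr))
  d <- dim(fr[[1L]])
  corners <- cbind(c(0, 0, d[1L] - 1, d[1L] - 1), c(0, d[2L] - 1, 0, d[2L] - 1))
  lo <- c(0, 0); hi <- c(d[1L] - 1, d[2L] - 1)
  warped <- vector("list", length(fr))
  for (t in seq_along(fr)) {
    par <- corrections[t, ]
    if (all(abs(par - c(0, 0, 0, 1)) < 1e-12)) {
      warped[[t]] <- fr[[t]]
      next
    }
    M <- transformMatrix(invertTransform(par))
    warped[[t]] <- cpp_warp_similarity(fr[[t]], M)
    # inscribed axis-aligned rectangle of the warped frame's valid quad
    q <- applyTransformToPoints(par, corners)
    ord <- order(q[, 1L]); qr <- q[ord, ]
    lo[1L] <- max(lo[1L], qr[2L, 1L]); hi[1L] <- min(hi[1L], qr[3L, 1L])
    ord <- order(q[, 2L]); qc <- q[ord, ]
    lo[2L] <- max(lo[2L], qc[2L, 2L]); hi[2L] <- min(hi[2L], qc[3L, 2L])
  }
  r0 <- ceiling(lo[1L]) + 1L; r1 <- floor(hi[1L]) + 1L  # 1-based crop
  c0 <- ceiling(lo[2L]) + 1L; c1 <- floor(hi[2L]) + 1L
  if (r1 - r0 < 8L || c1 - c0 < 8L)
    stop("stabilization failed, excessive motion (empty valid region)")
  cropped <- lapply(warped, function(f) {
    g <- f[r0:r1, c0:c1, drop = FALSE]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  imageSequence(cropped, frameRate = frameRate(seq),
                pixelPitch = pixelPitch(seq))
}

#' Stabilize an image sequence
#'
#' Full stabilization chain: estimate cumulative similarity transforms from
#' sparse optical flow, smooth the trajectory, and warp every frame by the
#' residual correction (inverse smoothed trajectory composed with the raw
#' cumulative transform), cropping to the common valid region.
#'
#' @param seq an [ImageSequence-class] with >= 2 frames.
#' @param params parameter list from [hvmParams()].
#' @return list with `sequence` (stabilized [ImageSequence-class]), `raw`
#'   and `smoothed` trajectory matrices, and `corrections`.
#' @export
stabilizeSequence <- function(seq, params = hvmParams()) {
  raw <- estimateTransforms(seq, params)
  sm <- smoothTrajectory(raw, as.integer(params$smoothing_window))
  corr <- t(vapply(seq_len(nrow(raw)), function(t)
    composeTransforms(invertTransform(sm[t, ]), raw[t, ]), numeric(4)))
  colnames(corr) <- colnames(raw)
  list(sequence = applyAndCrop(seq, corr), raw = raw, smoothed = sm,
       corrections = corr)
}
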