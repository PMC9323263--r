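## DNA-PAINT channel inference: per-frame spot localization (difference-of-
## Gaussians detection + integrated-Gaussian least-squares subpixel fits),
## fiducial-based drift correction, super-resolution rendering, docking-site
## clustering, and registration of the known asymmetric docking pattern to
## recover each origami's in-plane orientation.

## Separable Gaussian smoothing via banded convolution matrices.
smoothMatrix <- function(n, sigmaPx) {
  half <- max(1L, ceiling(3 * sigmaPx))
  k <- stats::dnorm(-half:half, sd = sigmaPx)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in -half:half) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) K[cbind(idx + d, idx)] <- k[d + half + 1]
    else K[cbind(idx, idx - d)] <- k[d + half + 1]
  }
  ## renormalize rows (edge truncation)
  K / rowSums(K)
}

## Integrated-Gaussian Gauss-Newton fit on a square window (photon units).
## Returns c(x, y, sigma, N, bg, converged) with x, y in pixel units
## relative to the window center.
fitGaussianSpot <- function(W, initSigmaPx = 1.3) {
  w <- nrow(W)
  h <- (w - 1) / 2
  edges <- seq(-h - 0.5, h + 0.5)
  bg <- min(stats::median(c(W[1, ], W[w, ], W[, 1], W[, w])), min(W) + 1e-9)
  N <- max(sum(W) - bg * w^2, 10)
  ## centroid init
  cs <- pmax(W - bg, 0)
  xs <- seq(-h, h)
  x <- sum(cs * matrix(xs, w, w)) / sum(cs)
  y <- sum(cs * matrix(xs, w, w, byrow = TRUE)) / sum(cs)
  s <- initSigmaPx
  massAndGrad <- function(c0, s) {
    u <- (edges - c0) / s
    P <- stats::pnorm(u); D <- stats::dnorm(u)
    list(m = diff(P), dc = -diff(D) / s, ds = -diff(D * u) / s)
  }
  for (it in 1:10) {
    gx <- massAndGrad(x, s); gy <- massAndGrad(y, s)
    M <- outer(gx$m, gy$m)
    model <- N * M + bg
    r <- as.numeric(W - model)
    J <- cbind(as.numeric(N * outer(gx$dc, gy$m)),
               as.numeric(N * outer(gx$m, gy$dc)),
               as.numeric(N * (outer(gx$ds, gy$m) + outer(gx$m, gy$ds))),
               as.numeric(M),
               1)
    ## inverse-variance (shot-noise) weights make the LSQ fit approach the
    ## CRLB-style precision the uncertainty column reports
    w <- 1 / sqrt(pmax(as.numeric(model), 0.25))
    r <- r * w
    J <- J * w
    step <- tryCatch(qr.solve(J, r), error = function(e) rep(0, 5))
    step[1:2] <- pmin(pmax(step[1:2], -1), 1)
    x <- x + step[1]; y <- y + step[2]
    s <- min(max(s + step[3], 0.4), 5)
    N <- max(N + step[4], 1)
    bg <- max(bg + step[5], 0)
    if (max(abs(step[1:2])) < 1e-4 && it > 3) break
  }
  c(x = x, y = y, sigma = s, N = N, bg = bg)
}

#' Localize spots in a movie stack
#'
#' Difference-of-Gaussians detection above a robust threshold followed by an
#' integrated-Gaussian least-squares subpixel fit per spot, in the spirit of
#' standard SMLM localizers. Localization precision is estimated with the
#' Thompson-style formula including the 2x EMCCD excess-noise factor.
#'
#' @param stack fov x fov x frames array (ADU) or a single matrix.
#' @param camera a [CameraModel-class] (ADU -> photon conversion).
#' @param k detection threshold in robust SDs of the filtered frame.
#' @param pitch pixel pitch at the sample, nm.
#' @param initSigma initial PSF SD, nm.
#' @param minPhotons discard fits below this photon count.
#' @return data.frame with ThunderSTORM-compatible columns: \code{frame},
#'   \code{x_nm}, \code{y_nm}, \code{sigma_nm}, \code{intensity_photon},
#'   \code{offset_photon}, \code{uncertainty_nm}. Coordinates have their
#'   origin at the field-of-view corner (pixel i center = (i - 0.5) pitch).
#' @export
localizeFrames <- function(stack, camera = cameraModel(), k = 6,
                           pitch = 160, initSigma = 210, minPhotons = 100) {
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1))
  n <- dim(stack)[1]
  nf <- dim(stack)[3]
  conv <- camera@sensitivity / camera@gain
  sPx <- initSigma / pitch
  K1 <- smoothMatrix(n, max(0.8, 0.8 * sPx))
  K2 <- smoothMatrix(n, 2.5 * sPx)
  win <- 11L
  hw <- (win - 1L) %/% 2L
  buf <- matrix(NA_real_, 512, 7)
  nr <- 0L
  for (t in seq_len(nf)) {
    ph <- (stack[, , t] - camera@baseline) * conv
    dog <- K1 %*% ph %*% t(K1) - K2 %*% ph %*% t(K2)
    thr <- stats::median(dog) + k * stats::mad(dog)
    ## local maxima in 3x3 above threshold, away from the border
    cand <- which(dog > thr, arr.ind = TRUE)
    cand <- cand[cand[, 1] > hw & cand[, 1] <= n - hw &
                 cand[, 2] > hw & cand[, 2] <= n - hw, , drop = FALSE]
    if (nrow(cand) == 0L) next
    keep <- vapply(seq_len(nrow(cand)), function(r) {
      i <- cand[r, 1]; j <- cand[r, 2]
      dog[i, j] == max(dog[(i - 1):(i + 1), (j - 1):(j + 1)])
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      W <- ph[(i - hw):(i + hw), (j - hw):(j + hw)]
      f <- fitGaussianSpot(W, sPx)
      if (f["N"] < minPhotons || abs(f["x"]) > hw || abs(f["y"]) > hw) next
      sN <- f["sigma"] * pitch
      a <- pitch
      bgVar <- 2 * max(f["bg"], 0) +
        (camera@readNoise / camera@gain)^2   # photons^2 per pixel
      prec <- sqrt(2 * (sN^2 + a^2 / 12) / f["N"] +
                   8 * pi * sN^4 * bgVar / (a^2 * f["N"]^2))
      nr <- nr + 1L
      if (nr > nrow(buf)) buf <- rbind(buf, matrix(NA_real_, nrow(buf), 7))
      buf[nr, ] <- c(t, (i - 0.5 + f[["x"]]) * pitch,
                     (j - 0.5 + f[["y"]]) * pitch,
                     sN, f[["N"]], f[["bg"]], prec)
    }
  }
  out <- data.frame(frame = integer(nr), x_nm = numeric(nr),
                    y_nm = numeric(nr), sigma_nm = numeric(nr),
                    intensity_photon = numeric(nr),
                    offset_photon = numeric(nr), uncertainty_nm = numeric(nr))
  if (nr > 0L) {
    out$frame <- as.integer(buf[seq_len(nr), 1])
    out[, 2:7] <- buf[seq_len(nr), 2:7]
  }
  out
}

#' Quality-filter a localization table
#'
#' Keeps localizations from single fully-bright binding events: because a
#' whole origami is smaller than a camera pixel, frames in which two docking
#' sites are bright simultaneously produce one merged spot whose fitted
#' photon count is the sum -- an upper brightness cut rejects those, and a
#' lower cut rejects dim partial-frame events, both of which would otherwise
#' bias the site centroids.
#'
#' @param table localization table.
#' @param minPhotons,maxPhotons photon window; when NULL a band around the
#'   modal single-event brightness is estimated from the data (0.78x to
#'   1.15x the intensity mode).
#' @param maxUncertainty precision cut, nm.
#' @return filtered table.
#' @export
filterLocalizations <- function(table, minPhotons = NULL, maxPhotons = NULL,
                                maxUncertainty = 8) {
  tab <- table[table$uncertainty_nm <= maxUncertainty, , drop = FALSE]
  if (nrow(tab) == 0L) return(tab)
  if (is.null(minPhotons) || is.null(maxPhotons)) {
    d <- stats::density(tab$intensity_photon, bw = "SJ")
    mode <- d$x[which.max(d$y)]
    if (is.null(minPhotons)) minPhotons <- 0.78 * mode
    if (is.null(maxPhotons)) maxPhotons <- 1.15 * mode
  }
  tab[tab$intensity_photon >= minPhotons &
      tab$intensity_photon <= maxPhotons, , drop = FALSE]
}

#' Identify fiducial tracks in a localization table
#'
#' Fiducials are bright, permanently visible beads: localizations that
#' cluster at (nearly) the same position in a large fraction of frames.
#'
#' @param table a localization table ([localizeFrames()]).
#' @param nFrames total frame count of the movie.
#' @param minFraction minimum fraction of frames a fiducial must appear in.
#' @param radius spatial linking radius, nm.
#' @return data.frame with columns \code{fiducial}, \code{frame},
#'   \code{x_nm}, \code{y_nm}.
#' @export
identifyFiducials <- function(table, nFrames, minFraction = 0.7,
                              radius = 300) {
  if (nrow(table) == 0L)
    return(data.frame(fiducial = integer(), frame = integer(),
                      x_nm = numeric(), y_nm = numeric()))
  ## spatial binning on two offset grids (so a track straddling a bin edge
  ## is still caught), then merge duplicate detections
  seeds <- NULL
  for (off in c(0, 0.5)) {
    key <- paste(floor(table$x_nm / radius + off),
                 floor(table$y_nm / radius + off))
    for (g in unique(key)) {
      idx <- which(key == g)
      if (length(unique(table$frame[idx])) >= minFraction * nFrames)
        seeds <- rbind(seeds, c(stats::median(table$x_nm[idx]),
                                stats::median(table$y_nm[idx])))
    }
  }
  if (is.null(seeds))
    return(data.frame(fiducial = integer(), frame = integer(),
                      x_nm = numeric(), y_nm = numeric()))
  ## deduplicate seed positions
  keep <- rep(TRUE, nrow(seeds))
  for (a in seq_len(nrow(seeds))) if (keep[a] && a < nrow(seeds))
    for (b in (a + 1):nrow(seeds))
      if (keep[b] && sqrt(sum((seeds[a, ] - seeds[b, ])^2)) < radius)
        keep[b] <- FALSE
  seeds <- seeds[keep, , drop = FALSE]
  out <- NULL
  for (f in seq_len(nrow(seeds))) {
    idx <- which(abs(table$x_nm - seeds[f, 1]) < radius / 2 &
                 abs(table$y_nm - seeds[f, 2]) < radius / 2)
    out <- rbind(out, data.frame(fiducial = f, frame = table$frame[idx],
                                 x_nm = table$x_nm[idx],
                                 y_nm = table$y_nm[idx]))
  }
  out
}

#' Drift-correct a localization table with fiducial tracks
#'
#' Estimates the per-frame stage displacement as the mean over fiducials of
#' each fiducial's displacement from its own time-averaged position, fills
#' short gaps by linear interpolation, smooths with a running mean and
#' subtracts it from all localizations.
#'
#' @param table localization table.
#' @param fiducialTracks output of [identifyFiducials()].
#' @param nFrames total frame count.
#' @param window running-mean smoothing window, frames.
#' @return list with \code{table} (corrected, fiducial rows included) and
#'   \code{drift} (nFrames x 2 estimate, nm).
#' @export
driftCorrect <- function(table, fiducialTracks, nFrames, window = 25) {
  if (nrow(fiducialTracks) == 0L)
    stop("no fiducial visible; cannot drift-correct")
  disp <- matrix(NA_real_, nFrames, 2)
  cnt <- numeric(nFrames)
  acc <- matrix(0, nFrames, 2)
  for (f in unique(fiducialTracks$fiducial)) {
    tr <- fiducialTracks[fiducialTracks$fiducial == f, ]
    ## one displacement per frame (average duplicates)
    dx <- tapply(tr$x_nm, tr$frame, mean) - mean(tr$x_nm)
    dy <- tapply(tr$y_nm, tr$frame, mean) - mean(tr$y_nm)
    fr <- as.integer(names(dx))
    acc[fr, 1] <- acc[fr, 1] + dx
    acc[fr, 2] <- acc[fr, 2] + dy
    cnt[fr] <- cnt[fr] + 1
  }
  seen <- cnt > 0
  gap <- max(diff(c(0, which(seen), nFrames + 1))) - 1
  if (gap > window)
    stop("fiducial gap of ", gap, " frames exceeds the smoothing window")
  disp <- acc / pmax(cnt, 1)
  disp[!seen, ] <- NA
  frames <- seq_len(nFrames)
  for (c in 1:2)
    disp[, c] <- stats::approx(frames[seen], disp[seen, c], xout = frames,
                               rule = 2)$y
  ## running mean
  kern <- rep(1 / window, window)
  pad <- function(v) c(rep(v[1], window), v, rep(v[length(v)], window))
  sm <- apply(disp, 2, function(v) {
    s <- stats::filter(pad(v), kern, sides = 2)
    as.numeric(s[(window + 1):(window + nFrames)])
  })
  ## zero-mean correction so fiducial residuals center on their mean pos
  corrected <- table
  corrected$x_nm <- corrected$x_nm - sm[corrected$frame, 1]
  corrected$y_nm <- corrected$y_nm - sm[corrected$frame, 2]
  list(table = corrected, drift = sm)
}

#' Render a super-resolved image from localizations
#'
#' Simple 2D histogram rendering; the summed weights equal the number of
#' localizations.
#'
#' @param table localization table.
#' @param pixel rendering pixel size, nm (> 0).
#' @param xlim,ylim rendering range, nm (defaults to the data range).
#' @return matrix of counts with attributes \code{origin} (nm of the first
#'   pixel edge) and \code{pixel}.
#' @export
renderSr <- function(table, pixel = 5, xlim = NULL, ylim = NULL) {
  if (pixel <= 0) stop("pixel size must be positive")
  if (is.null(xlim)) xlim <- range(table$x_nm) + c(-pixel, pixel)
  if (is.null(ylim)) ylim <- range(table$y_nm) + c(-pixel, pixel)
  bx <- seq(xlim[1], xlim[2] + pixel, by = pixel)
  by <- seq(ylim[1], ylim[2] + pixel, by = pixel)
  ix <- findInterval(table$x_nm, bx, all.inside = TRUE)
  iy <- findInterval(table$y_nm, by, all.inside = TRUE)
  img <- matrix(0, length(bx) - 1L, length(by) - 1L)
  for (r in seq_along(ix)) img[ix[r], iy[r]] <- img[ix[r], iy[r]] + 1
  attr(img, "origin") <- c(bx[1], by[1])
  attr(img, "pixel") <- pixel
  img
}

#' Cluster localizations into docking-site centroids
#'
#' Minimal density-based clustering (DBSCAN-style): core points have >=
#' \code{minPts} neighbors within \code{eps}; connected cores form clusters
#' and border points join their nearest core cluster.
#'
#' @param table localization table restricted to one origami region.
#' @param eps neighborhood radius, nm (6 nm default).
#' @param minPts minimum neighbors (including self) for a core point.
#' @return data.frame with columns \code{x}, \code{y}, \code{count}, one
#'   row per site, ordered by decreasing count.
#' @export
clusterSites <- function(table, eps = 6, minPts = 5) {
  np <- nrow(table)
  if (np < 3L) stop("need at least 3 localizations to cluster")
  P <- cbind(table$x_nm, table$y_nm)
  D <- as.matrix(stats::dist(P))
  nb <- D <= eps
  core <- rowSums(nb) >= minPts
  if (!any(core)) stop("no dense clusters found")
  lab <- integer(np)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    lab[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nbrs <- which(nb[j, ])
      for (q in nbrs) {
        if (lab[q] == 0L) {
          lab[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  ## density clusters can chain neighboring sites through bridge points
  ## (residual multi-emitter localizations); split over-extended clusters
  ## recursively with 2-means while both halves are well separated
  splitRec <- function(idx) {
    P0 <- P[idx, , drop = FALSE]
    n0 <- nrow(P0)
    rms <- sqrt(mean(rowSums(sweep(P0, 2, colMeans(P0))^2)))
    if (n0 < 2L * minPts || rms <= 9) return(list(idx))
    km <- tryCatch(stats::kmeans(P0, 2, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km) || min(table(km$cluster)) < minPts) return(list(idx))
    sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
    if (sep < 15) return(list(idx))
    c(splitRec(idx[km$cluster == 1]), splitRec(idx[km$cluster == 2]))
  }
  parts <- unlist(lapply(seq_len(cl), function(c) splitRec(which(lab == c))),
                  recursive = FALSE)
  ## component-wise medians: robust against the residual multi-emitter
  ## localizations that land between sites
  cents <- do.call(rbind, lapply(parts, function(idx) {
    data.frame(x = stats::median(P[idx, 1]), y = stats::median(P[idx, 2]),
               count = length(idx))
  }))
  cents[order(-cents$count), ]
}

## Pose cost: translate the (rotated/mirrored) template to best match, then
## RMS of centroid -> nearest-site distances plus a penalty per unmatched
## template site.
poseCost <- function(cents, sites, angle, mirror, penalty = 20,
                     matchRadius = 15) {
  s <- sites
  if (mirror) s[, 1] <- -s[, 1]
  a <- deg2rad(angle)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sr <- s %*% t(R)
  tr <- colMeans(cents) - colMeans(sr)
  for (it in 1:3) {
    st <- sweep(sr, 2, tr, "+")
    D <- outer(cents[, 1], st[, 1], "-")^2 + outer(cents[, 2], st[, 2], "-")^2
    nnIdx <- max.col(-D)
    tr <- tr + colMeans(cents - st[nnIdx, , drop = FALSE])
  }
  st <- sweep(sr, 2, tr, "+")
  D <- sqrt(outer(cents[, 1], st[, 1], "-")^2 +
            outer(cents[, 2], st[, 2], "-")^2)
  nnD <- apply(D, 1, min)
  nnIdx <- max.col(-D)
  matched <- unique(nnIdx[nnD <= matchRadius])
  rms <- if (any(nnD <= matchRadius))
    sqrt(mean(nnD[nnD <= matchRadius]^2)) else Inf
  list(cost = sqrt(mean(pmin(nnD, matchRadius * 2)^2)) +
         penalty * (nrow(sites) - length(matched)) / nrow(sites),
       rms = rms, matched = length(matched), translation = tr)
}

#' Register the docking pattern to site centroids
#'
#' Exhaustive search over in-plane rotation (0.5 degree steps) and mirror
#' parity, translation by iterated nearest-neighbor centroid alignment,
#' with an unmatched-site penalty; the best pose is refined by Nelder-Mead.
#'
#' @param centroids output of [clusterSites()] (>= 3 rows).
#' @param layout an [OrigamiLayout-class] template.
#' @param step coarse rotation step, degrees.
#' @param penalty unmatched-site penalty, nm (per missing site, scaled by
#'   the template size).
#' @param matchRadius nearest-neighbor match radius, nm.
#' @param rejectRms registration is rejected if the refined RMS residual
#'   exceeds this, nm, or fewer than \code{minMatched} sites matched.
#' @param minMatched minimum matched template sites.
#' @return an [OrigamiRegistration-class].
#' @export
registerPattern <- function(centroids, layout = defaultOrigamiLayout(),
                            step = 0.5, penalty = 20, matchRadius = 10,
                            rejectRms = 10, minMatched = 4L) {
  cents <- as.matrix(centroids[, c("x", "y")])
  if (nrow(cents) < 3L) stop("need at least 3 centroids to register")
  sites <- layout@sites
  best <- NULL
  for (mirror in c(FALSE, TRUE)) {
    for (a in seq(0, 360 - step, by = step)) {
      pc <- poseCost(cents, sites, a, mirror, penalty, matchRadius)
      if (is.null(best) || pc$cost < best$cost) {
        best <- pc; best$angle <- a; best$mirror <- mirror
      }
    }
  }
  ## local refinement of the rotation angle
  f <- function(a) poseCost(cents, sites, a, best$mirror, penalty,
                            matchRadius)$cost
  op <- stats::optimize(f, interval = best$angle + c(-step, step))
  fin <- poseCost(cents, sites, op$minimum, best$mirror, penalty,
                  matchRadius)
  registered <- is.finite(fin$rms) && fin$rms <= rejectRms &&
    fin$matched >= minMatched
  new("OrigamiRegistration", phiOrigami = wrapAngle360(op$minimum),
      translation = as.numeric(fin$translation), mirror = best$mirror,
      rms = if (is.finite(fin$rms)) fin$rms else NA_real_,
      matched = as.integer(fin$matched), registered = registered)
}
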