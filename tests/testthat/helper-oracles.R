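## Independent oracles used by the tests. These deliberately re-derive the
## quantities they check through a different route than the implementation.

## Direct-quadrature evaluation of the defocused dipole image integrals in
## polar pupil coordinates: Gauss-Legendre in the aperture angle (split at
## the critical angle, where the integrand has a kink) and trapezoid in
## azimuth. Returns intensities at the given (x, y) positions (nm).
quadDipoleImage <- function(theta, phi, defocus, optics, xs, ys,
                            nTheta = 200, nPsi = 360) {
  n1 <- optics@nSample; n2 <- optics@nImmersion
  k0 <- 2 * pi / optics@wavelength
  thMax <- asin(optics@na / n2)
  thC <- asin(n1 / n2)
  gl <- function(n) {                  # Golub-Welsch Gauss-Legendre
    i <- 1:(n - 1); b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n); J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  seg <- function(a, b, n) {
    g <- gl(n); list(x = (g$x + 1) / 2 * (b - a) + a, w = g$w / 2 * (b - a))
  }
  s1 <- seg(0, thC, nTheta); s2 <- seg(thC, thMax, nTheta)
  th2 <- c(s1$x, s2$x); wth <- c(s1$w, s2$w)
  psi <- seq(0, 2 * pi, length.out = nPsi + 1)[1:nPsi]
  dpsi <- 2 * pi / nPsi
  mu <- c(sin(theta * pi / 180) * cos(phi * pi / 180),
          sin(theta * pi / 180) * sin(phi * pi / 180),
          cos(theta * pi / 180))
  np <- length(xs)
  Ex <- matrix(0 + 0i, np, 1); Ey <- matrix(0 + 0i, np, 1)
  for (a in seq_along(th2)) {
    t2 <- th2[a]; st2 <- sin(t2); ct2 <- cos(t2)
    st1 <- n2 * st2 / n1
    ct1 <- sqrt(as.complex(1 - st1^2))
    ts <- 2 * n1 * ct1 / (n1 * ct1 + n2 * ct2)
    tp <- 2 * n1 * ct1 / (n2 * ct1 + n1 * ct2)
    amp <- exp(1i * k0 * n1 * ct1 * optics@emitterHeight) *
      exp(1i * k0 * n2 * ct2 * defocus) / sqrt(ct2)
    kr <- k0 * n2 * st2
    jac <- (k0 * n2)^2 * st2 * ct2 * wth[a] * dpsi
    cp <- cos(psi); sp <- sin(psi)
    Es <- ts * (-mu[1] * sp + mu[2] * cp)
    Ep <- tp * ((mu[1] * cp + mu[2] * sp) * ct1 - mu[3] * st1)
    ex <- amp * (Ep * cp - Es * sp)
    ey <- amp * (Ep * sp + Es * cp)
    ph <- exp(1i * kr * (outer(xs, cp) + outer(ys, sp)))
    Ex <- Ex + jac * (ph %*% ex)
    Ey <- Ey + jac * (ph %*% ey)
  }
  as.numeric(Mod(Ex)^2 + Mod(Ey)^2)
}

## Exhaustive grid search for the line through wrapped angles: minimizes the
## summed squared wrapped residuals over (slope, intercept) at fixed
## resolution.
gridSearchLine <- function(b, thetaWrapped, slopeRange, res = 0.01) {
  slopes <- seq(slopeRange[1], slopeRange[2], by = res)
  best <- c(Inf, NA, NA)
  for (s in slopes) {
    ## optimal intercept for fixed slope via circular mean of residuals
    r <- (thetaWrapped - s * b) %% 360
    ang <- atan2(mean(sin(r * pi / 180)), mean(cos(r * pi / 180))) * 180 / pi
    cand <- seq(ang - 1, ang + 1, by = res)
    for (ic in cand) {
      d <- ((thetaWrapped - s * b - ic + 180) %% 360) - 180
      ss <- sum(d^2)
      if (ss < best[1]) best <- c(ss, s, ic)
    }
  }
  list(slope = best[2], intercept = best[3] %% 360)
}

## Brute-force single-linkage clustering of axes at a geodesic threshold:
## repeatedly merge the two closest clusters until the minimum inter-cluster
## single-link distance exceeds the cut.
bruteSingleLinkage <- function(axes, threshold) {
  u <- axes / sqrt(rowSums(axes^2))
  d <- rad2deg(acos(pmin(abs(tcrossprod(u)), 1)))
  n <- nrow(u)
  groups <- as.list(seq_len(n))
  repeat {
    best <- c(Inf, 0, 0)
    if (length(groups) == 1L) break
    for (a in 1:(length(groups) - 1)) for (b in (a + 1):length(groups)) {
      dd <- min(d[groups[[a]], groups[[b]]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    if (best[1] > threshold) break
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

## Brute-force rigid pose search for exact (noise-free) centroids: mean
## nearest-neighbor cost over a fine rotation grid, both parities.
brutePose <- function(cents, sites, res = 0.1) {
  best <- list(cost = Inf)
  for (mirror in c(FALSE, TRUE)) {
    s <- sites
    if (mirror) s[, 1] <- -s[, 1]
    for (a in seq(0, 360 - res, by = res)) {
      th <- a * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sr <- s %*% t(R)
      sr <- sweep(sr, 2, colMeans(sr) - colMeans(cents), "-")
      D <- sqrt(outer(cents[, 1], sr[, 1], "-")^2 +
                outer(cents[, 2], sr[, 2], "-")^2)
      cost <- mean(apply(D, 1, min))
      if (cost < best$cost) best <- list(cost = cost, angle = a,
                                         mirror = mirror)
    }
  }
  best
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180
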