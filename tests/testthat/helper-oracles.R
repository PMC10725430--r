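# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, sharing no code path with the package.

# Natural cubic spline through (xk, yk), solved with the Thomas algorithm for
# the tridiagonal second-derivative system; linear extrapolation with the end
# slopes outside the knot range.
natural_spline_eval <- function(xk, yk, x) {
  n <- length(xk)
  h <- diff(xk)
  a <- numeric(n); b <- numeric(n); cc <- numeric(n); d <- numeric(n)
  b[1] <- 1; b[n] <- 1
  for (i in 2:(n - 1)) {
    a[i] <- h[i - 1]; b[i] <- 2 * (h[i - 1] + h[i]); cc[i] <- h[i]
    d[i] <- 6 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1])
  }
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  m <- numeric(n)
  m[n] <- d[n] / b[n]
  for (i in (n - 1):1) m[i] <- (d[i] - cc[i] * m[i + 1]) / b[i]
  vapply(x, function(xx) {
    if (xx <= xk[1]) {
      s <- (yk[2] - yk[1]) / h[1] - h[1] * (2 * m[1] + m[2]) / 6
      return(yk[1] + s * (xx - xk[1]))
    }
    if (xx >= xk[n]) {
      s <- (yk[n] - yk[n - 1]) / h[n - 1] + h[n - 1] * (m[n - 1] + 2 * m[n]) / 6
      return(yk[n] + s * (xx - xk[n]))
    }
    i <- findInterval(xx, xk)
    hh <- xk[i + 1] - xk[i]
    A <- (xk[i + 1] - xx) / hh; B <- (xx - xk[i]) / hh
    A * yk[i] + B * yk[i + 1] +
      ((A^3 - A) * m[i] + (B^3 - B) * m[i + 1]) * hh^2 / 6
  }, numeric(1))
}

# Dense-sampling Sholl oracle: sample each segment at nsamp points and count
# sign changes of the outside indicator (distance >= r), per radius.
oracle_sholl <- function(trc, radii, nsamp = 10000) {
  seg <- gliaquant:::tracing_segments(trc)
  c0 <- trc$soma_center
  tt <- seq(0, 1, length.out = nsamp)
  lo <- c(); hi <- c()
  for (i in seq_along(seg$child)) {
    p <- seg$from[i, ] - c0; q <- seg$to[i, ] - c0
    d <- sqrt((p[1] + tt * (q[1] - p[1]))^2 +
                (p[2] + tt * (q[2] - p[2]))^2 +
                (p[3] + tt * (q[3] - p[3]))^2)
    lo <- c(lo, pmin(d[-nsamp], d[-1]))
    hi <- c(hi, pmax(d[-nsamp], d[-1]))
  }
  # a consecutive-sample pair crosses level r iff min < r <= max
  vapply(radii, function(r) sum(lo < r) - sum(hi < r), numeric(1))
}

# Gift-wrapping convex hull + shoelace, independent of grDevices::chull.
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- if (cur == start && length(hull) == 1) setdiff(1:n, cur) else setdiff(1:n, cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && d_j > d_nxt)) nxt <- j
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("hull did not close")
  }
  h <- pts[hull, , drop = FALSE]
  m <- nrow(h)
  j <- c(2:m, 1)
  abs(sum(h[, 1] * h[j, 2] - h[j, 1] * h[, 2])) / 2
}

# Exhaustive Mann-Whitney enumeration on the actual values: U counts (x, y)
# pairs with x > y (ties 0.5); the null distribution enumerates every
# labeling of the pooled values.
oracle_mw_exact <- function(x, y, tails = "two") {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  u <- u_stat(x, y)
  p_less <- mean(u_all <= u)
  p_greater <- mean(u_all >= u)
  switch(tails,
         two = min(1, 2 * min(p_less, p_greater)),
         less = p_less,
         greater = p_greater)
}

# Build a tracing from a compact node table.
make_tracing <- function(...) {
  df <- as.data.frame(rbind(...))
  names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")
  tracing(df)
}

# A stack with a planted bright sphere, an 8-pixel in-plane square and a
# 99-voxel 3D blob over low-amplitude noise; used by the segmentation tests.
planted_stack <- function(seed, nz = 40, ny = 256, nx = 256, res = 0.2,
                          r_um = 3, noise_sd = 1) {
  set.seed(seed)
  vox <- array(abs(stats::rnorm(nz * ny * nx, 0, noise_sd)), dim = c(nz, ny, nx))
  zc <- nz %/% 2; yc <- ny %/% 2; xc <- nx %/% 2
  for (z in seq_len(nz)) {
    dz <- (z - zc) * res
    if (abs(dz) > r_um) next
    rr <- sqrt(outer((((1:ny) - yc) * res)^2, (((1:nx) - xc) * res)^2, "+") + dz^2)
    vox[z, , ][rr <= r_um] <- 100
  }
  blob <- arrayInd(1:99, c(5, 5, 4))
  for (k in 1:99) vox[6 + blob[k, 3], 30 + blob[k, 1], 30 + blob[k, 2]] <- 100
  vox[12, 200:203, 200:201] <- 100           # 8-pixel square, one plane
  image_stack(vox, lateral_res = res, z_step = res)
}
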