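# Independent brute-force oracles. Deliberately naive (loops, explicit
# shifts, repeated sums): these must not share code paths with the package.

# Queue-based flood-fill labeling; returns list of component pixel-index sets.
oracle_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  seen <- matrix(FALSE, ny, nx)
  comps <- list()
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    px <- integer(0)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- c(px, (p[2] - 1L) * ny + p[1])
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= ny && c >= 1 && c <= nx &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(px)
  }
  comps
}

# Zero-fill integer shift: out[y + dy, x + dx] = m[y, x].
oracle_shift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    r <- i + dy; c <- j + dx
    if (r >= 1 && r <= ny && c >= 1 && c <= nx) out[r, c] <- m[i, j]
  }
  out
}

# Full CDA by explicit enumeration and shifting.
oracle_cda <- function(int1, m1, m2, conf, max_radius,
                       min_retained_fraction = 0.9, weighted = TRUE) {
  w <- if (weighted) int1 * m1 else m1 * 1
  m1_d0 <- sum(w * conf * m2) / sum(w * conf)
  n_mask <- sum(m1)
  null_vals <- numeric(0); dys <- integer(0); dxs <- integer(0)
  for (dy in -floor(max_radius):floor(max_radius)) {
    for (dx in -floor(max_radius):floor(max_radius)) {
      r <- sqrt(dy^2 + dx^2)
      if (r == 0 || r > max_radius) next
      ms <- oracle_shift(m1 * 1, dy, dx)
      if (sum(ms * conf) / n_mask < min_retained_fraction) next
      ws <- oracle_shift(w, dy, dx)
      den <- sum(ws * conf)
      if (den <= 0) next
      null_vals <- c(null_vals, sum(ws * conf * m2) / den)
      dys <- c(dys, dy); dxs <- c(dxs, dx)
    }
  }
  list(m1_d0 = m1_d0, null_values = null_vals,
       m1_random = mean(null_vals),
       m1_effective = m1_d0 - mean(null_vals),
       dy = dys, dx = dxs)
}

# Direct 3x3 Sobel correlation with replicate padding, nested loops.
oracle_sobel_magnitude <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  at <- function(i, j) m[min(max(i, 1), ny), min(max(j, 1), nx)]
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- at(i + di, j + dj)
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Exhaustive Otsu over the same 256-bin grid, recomputing class weights
# and means from the raw counts at every candidate split.
oracle_otsu <- function(v, levels = 256) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf; best_thr <- NA
  for (s in 1:(levels - 1)) {
    left <- bin <= s
    n0 <- sum(left); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- mean(mids[bin[left]])
    mu1 <- mean(mids[bin[!left]])
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_thr <- breaks[s + 1] }
  }
  best_thr
}

# One-way ANOVA from the defining sums of squares.
oracle_anova1 <- function(v, g) {
  g <- factor(g)
  grand <- mean(v)
  mi <- tapply(v, g, mean)
  ni <- table(g)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((v - mi[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(v) - nlevels(g)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Two-way ANOVA by least-squares model comparison (QR residuals, no aov):
# each term's SS is the RSS drop when adding it to the model without it
# (type II).
oracle_anova2 <- function(v, a, b) {
  a <- factor(a); b <- factor(b)
  rss <- function(form) {
    X <- model.matrix(form, data.frame(a = a, b = b))
    sum(qr.resid(qr(X), v)^2)
  }
  rss_ab <- rss(~ a + b)
  rss_full <- rss(~ a * b)
  list(ss_a = rss(~ b) - rss_ab,
       ss_b = rss(~ a) - rss_ab,
       ss_int = rss_ab - rss_full,
       ss_res = rss_full,
       df = c(nlevels(a) - 1, nlevels(b) - 1,
              (nlevels(a) - 1) * (nlevels(b) - 1),
              length(v) - nlevels(a) * nlevels(b)))
}

# Random small binary scene for CDA equivalence tests; regenerates until
# the instance admits a valid CDA run.
random_cda_instance <- function(seed, size = 16, max_radius = 3) {
  set.seed(seed)
  repeat {
    ny <- sample(8:size, 1); nx <- sample(8:size, 1)
    conf <- matrix(runif(ny * nx) < 0.85, ny, nx)
    m1 <- conf & matrix(runif(ny * nx) < 0.35, ny, nx)
    m2 <- conf & matrix(runif(ny * nx) < 0.35, ny, nx)
    int1 <- matrix(runif(ny * nx, 0.1, 10), ny, nx)
    if (sum(m1) < 5) next
    ok <- tryCatch({
      cdaq::cda_effective_colocalization(
        cdaq::coloc_input(int1, m1, m2, conf),
        max_radius = max_radius, min_retained_fraction = 0.5)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(list(int1 = int1, m1 = m1, m2 = m2, conf = conf,
                        max_radius = max_radius))
  }
}
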