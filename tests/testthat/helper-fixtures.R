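# Fixtures built in code: rasterized shapes with known closed-form geometry
# and small synthetic record tables.

# Filled disk of radius r px, centered, with `pad` background pixels around.
mask_disk <- function(r = 50, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  c0 <- r + pad + 1
  outer(1:n, 1:n, function(y, x) (x - c0)^2 + (y - c0)^2 <= r^2)
}

# Filled axis-aligned rectangle h x w px.
mask_rect <- function(w = 100, h = 50, pad = 5) {
  M <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  M[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  M
}

# Filled rectangle w x h rotated by `angle` (radians), rasterized analytically.
mask_rot_rect <- function(w = 100, h = 50, angle = pi / 6, pad = 5) {
  half_diag <- sqrt(w^2 + h^2) / 2
  n <- ceiling(2 * half_diag) + 2 * pad
  c0 <- n / 2
  g <- expand.grid(y = 1:n, x = 1:n)
  u <- (g$x - c0) * cos(angle) + (g$y - c0) * sin(angle)
  v <- -(g$x - c0) * sin(angle) + (g$y - c0) * cos(angle)
  matrix(abs(u) <= w / 2 & abs(v) <= h / 2, n, n)
}

# Filled ellipse with semi-axes a, b px.
mask_ellipse <- function(a = 60, b = 30, pad = 5) {
  n <- 2 * max(a, b) + 2 * pad + 1
  c0 <- max(a, b) + pad + 1
  outer(1:n, 1:n, function(y, x) ((x - c0) / a)^2 + ((y - c0) / b)^2 <= 1)
}

# Five-armed star r(theta) = r0 * (0.7 + 0.3 cos(5 theta)).
mask_star <- function(r0 = 45, pad = 5) {
  n <- 2 * r0 + 2 * pad + 1
  c0 <- r0 + pad + 1
  outer(1:n, 1:n, function(y, x) {
    dx <- x - c0; dy <- y - c0
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    r <= r0 * (0.7 + 0.3 * cos(5 * th))
  })
}

# Straight 1-px line of `len` px.
mask_line <- function(len = 200) {
  M <- matrix(FALSE, 5, len + 4)
  M[3, 3:(len + 2)] <- TRUE
  M
}

# Quadric Koch-type curve of theoretical box dimension log(8)/log(4) = 1.5:
# L-system F -> F+F-F-FF+F+F-F with 90-degree turns, rasterized 1 px wide.
mask_koch <- function(iterations = 4, seg = 1) {
  s <- "F"
  for (i in seq_len(iterations)) {
    s <- gsub("F", "f+f-f-ff+f+f-f", s)
    s <- toupper(s)
  }
  x <- 0; y <- 0; dir <- 0
  pts <- matrix(0, nrow = 1, ncol = 2)
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "F") {
      x <- x + seg * round(cos(dir * pi / 2))
      y <- y + seg * round(sin(dir * pi / 2))
      pts <- rbind(pts, c(x, y))
    } else if (ch == "+") dir <- (dir + 1) %% 4 else dir <- (dir - 1) %% 4
  }
  xs <- pts[, 1] - min(pts[, 1]) + 3
  ys <- pts[, 2] - min(pts[, 2]) + 3
  M <- matrix(FALSE, max(ys) + 3, max(xs) + 3)
  for (i in seq_len(nrow(pts) - 1)) {
    n <- max(abs(xs[i + 1] - xs[i]), abs(ys[i + 1] - ys[i]), 1)
    for (t in 0:n) {
      M[round(ys[i] + t * (ys[i + 1] - ys[i]) / n),
        round(xs[i] + t * (xs[i + 1] - xs[i]) / n)] <- TRUE
    }
  }
  M
}

# Measure a logical mask directly (uniform intensity 1 inside).
measure_mask <- function(M, pixel_size = 1) {
  measure_particles(matrix(as.integer(M), nrow(M)), M * 1, pixel_size = pixel_size)
}

# A small well-separated two-cluster table with known labels.
two_cluster_records <- function(n_per = 100, seed = 42,
                                mu = list(c(50, 0.8), c(300, 0.45)), sd = 10) {
  spec <- population_spec(
    component_means = mu,
    component_sds = list(c(sd, 0.05), c(sd, 0.05)),
    weights = c(0.5, 0.5), n = 2 * n_per, seed = seed
  )
  sample_population(spec)
}
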