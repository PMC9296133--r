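# Independent oracles used across tests.

# Exhaustive grid search over (A, tau) for the recovery model
# f(t) = A * (1 - exp(-tau * t)); returns the best grid point and its RSS.
frap_grid_oracle <- function(t, y, n_grid = 200,
                             A_range = c(0, 1.5), tau_range = c(1e-4, 1)) {
  As <- seq(A_range[1], A_range[2], length.out = n_grid)
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  E <- 1 - exp(-outer(taus, t))            # n_tau x n_t
  sy2 <- sum(y^2)
  syE <- as.vector(E %*% y)                # per tau
  sE2 <- rowSums(E^2)
  # rss(A, tau) = sum(y^2) - 2 A sum(yE) + A^2 sum(E^2)
  rss <- outer(As^2, sE2) - 2 * outer(As, syE) + sy2
  ij <- arrayInd(which.min(rss), dim(rss))
  list(A = As[ij[1]], tau = taus[ij[2]], rss = min(rss),
       A_step = diff(As[1:2]),
       tau_ratio = taus[2] / taus[1])
}

# Disk rasterized on the same 0-based grid the generators use.
disk_mask <- function(img_px, cx, cy, r_px) {
  xs <- matrix(rep(0:(img_px - 1), each = img_px), img_px)
  ys <- matrix(rep(0:(img_px - 1), times = img_px), img_px)
  (xs - cx)^2 + (ys - cy)^2 <= r_px^2
}

# Closed-form area of a regular n-gon inscribed in a circle of radius r.
inscribed_ngon_area <- function(n, r) 0.5 * n * r^2 * sin(2 * pi / n)

# Riemann-sum sphere volume over the slice grid z = k * d, |z| < r,
# with exact circle areas (the polygon-free limit of the integrator).
riemann_sphere_volume <- function(r, d) {
  kmax <- ceiling(r / d)
  z <- (-kmax:kmax) * d
  z <- z[abs(z) < r]
  sum(pi * (r^2 - z^2)) * d
}
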