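# shared fixtures, built in code; kept small so the suite stays fast

dawn_redwood_coefs <- c(a0 = 0.598, a1 = 1.900, a2 = 1.417, a3 = 1.279)

# diameter-height samples drawn exactly from the M2 taper
m2_samples <- function(n, a = dawn_redwood_coefs, sigma = 0, seed = 1) {
  with_seed(seed, {
    D <- runif(n, 20, 40)
    H <- runif(n, 20, 30)
    h <- runif(n, 0.3, 0.8 * H)
    d <- sqrt(a[1] * D^a[2] * (H - h)^a[3] / H^a[4])
    if (sigma > 0) d <- d + rnorm(n, 0, sigma)
    data.frame(D = D, H = H, h = h, d = d)
  })
}

# a conical crown of points: apex at (x0, y0, h_apex) (included exactly),
# base radius r_base
cone_points <- function(x0, y0, h_apex, r_base = 1.5, depth = 5, n = 200,
                        seed = 1) {
  with_seed(seed, {
    s <- sqrt(runif(n - 1))
    th <- runif(n - 1, 0, 2 * pi)
    rbind(data.frame(x = x0, y = y0, zn = h_apex),
          data.frame(x = x0 + r_base * s * cos(th),
                     y = y0 + r_base * s * sin(th),
                     zn = h_apex - depth * s))
  })
}

# points stratified on a circle (angular jitter keeps them irregular but
# with no large gaps)
ring_points <- function(cx, cy, r, n = 100, seed = 1) {
  with_seed(seed, {
    th <- 2 * pi * (seq_len(n) - runif(n)) / n
    data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
  })
}

# a small plot truth shared across segmentation tests
small_truth <- function(seed = 11, taper = list(model = "M4",
                                                coefficients = 1.417)) {
  sp <- species_params(mean_dbh = 30, sd_dbh = 3, mean_height = 25,
                       sd_height = 1.5, lean_sd = 0.03)
  generate_plot(sp, row_spacing = 6, col_spacing = 6, plot_size = 18,
                thinning = 0, jitter_sd = 0.05, taper = taper, seed = seed)
}
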