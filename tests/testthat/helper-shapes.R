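# Fixture builders shared across tests. All geometry oracles here are
# closed forms, independent of the slicing implementation.

# Axis-aligned L x w rectangle centred at `centre`, with distinct
# vertices along every edge.
rect_contour <- function(L = 10, w = 4, centre = c(0, 0), n_edge = 12) {
  xs <- seq(-L / 2, L / 2, length.out = n_edge)
  ys <- seq(-w / 2, w / 2, length.out = n_edge)
  pts <- rbind(cbind(xs, -w / 2),
               cbind(L / 2, ys[-1]),
               cbind(rev(xs)[-1], w / 2),
               cbind(-L / 2, rev(ys)[-1]))
  pts <- pts[-nrow(pts), ]
  contour(sweep(pts, 2, centre, "+"))
}

# Ellipse polygon with semi-axes (a, b), rotated by theta.
ellipse_contour <- function(a = 6, b = 2, theta = 0, n = 200) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  transform_contour(contour(cbind(a * cos(t), b * sin(t))), angle = theta)
}

# Closed-form slice-formula limits for a spherocylinder of total length
# L and cap radius r:
#   integral of w(x) dx  = 2 r (L - 2 r) + pi r^2
#   V = pi r^2 (L - 2 r) + (4/3) pi r^3
#   S = pi * integral w = pi (2 r (L - 2 r) + pi r^2)
spherocyl_oracle <- function(L = 12, r = 2) {
  int_w <- 2 * r * (L - 2 * r) + pi * r^2
  list(length = L,
       width = int_w / L,
       volume = pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3,
       surface = pi * int_w)
}

# A reduced titration panel: base + n_amm ammonium + n_glu glucose
# cultures, growth rates spread over the titration range.
titration_panel <- function(seed, n_amm = 5, n_glu = 4, n_cells = 50) {
  mus_a <- seq(0.08, 0.20, length.out = n_amm)
  mus_g <- seq(0.13, 0.23, length.out = n_glu)
  panel <- list(culture_spec("base", "EMM2", 0.26, n_cells = n_cells,
                             seed = seed * 1009 + 1))
  for (i in seq_len(n_amm))
    panel <- c(panel, list(culture_spec("ammonium_titration",
                                        sprintf("amm %d", i), mus_a[i],
                                        n_cells = n_cells,
                                        seed = seed * 1009 + 1 + i)))
  for (i in seq_len(n_glu))
    panel <- c(panel, list(culture_spec("glucose_titration",
                                        sprintf("glu %d", i), mus_g[i],
                                        n_cells = n_cells,
                                        seed = seed * 1009 + 100 + i)))
  panel
}
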