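# Shared in-code fixtures.

# Straight horizontal rod mesh: n ribs, constant half-width (px units).
straight_mesh <- function(n = 51, half_width_px = 3.5, pixel_size = 0.1,
                          x0 = 0, y0 = 10, cell_id = "rod") {
  xs <- seq(x0, x0 + n - 1)
  cell_mesh(cell_id,
            ribs = data.frame(x_left = xs, y_left = y0 - half_width_px,
                              x_right = xs, y_right = y0 + half_width_px),
            centerline = data.frame(x = xs, y = rep(y0, n)),
            pixel_size = pixel_size)
}

# Rigid rotation + translation of a mesh (about the origin).
transform_mesh <- function(mesh, angle = 0, dx = 0, dy = 0) {
  rot <- function(x, y) list(x = x * cos(angle) - y * sin(angle) + dx,
                             y = x * sin(angle) + y * cos(angle) + dy)
  r <- mesh$ribs; cl <- mesh$centerline
  a <- rot(r$x_left, r$y_left); b <- rot(r$x_right, r$y_right)
  cc <- rot(cl$x, cl$y)
  cell_mesh(mesh$cell_id,
            ribs = data.frame(x_left = a$x, y_left = a$y,
                              x_right = b$x, y_right = b$y),
            centerline = data.frame(x = cc$x, y = cc$y),
            pixel_size = mesh$pixel_size)
}

# Minimal synthetic profile object.
make_profile <- function(values, cell_id = "p",
                         centers = seq(0, 1, length.out = length(values))) {
  structure(list(cell_id = cell_id, segment_centers = centers,
                 values = values, raw_total = sum(values), background = 0),
            class = "intensity_profile")
}

# Brute-force two-sided Mann-Whitney p-value by enumeration of all
# assignments of the pooled sample to groups (doubled one-tail, capped at 1).
# Independent oracle for rank_sum_test's exact mode.
brute_force_ranksum <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - m * (m + 1) / 2
  }
  u_obs <- u_stat(seq_len(m))
  combs <- combn(m + n, m)
  us <- apply(combs, 2, u_stat)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
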