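#' Cell outline mesh
#'
#' Ordered rib (left/right outline point pairs) plus centerline description
#' of one segmented cell, in 0-based pixel coordinates (origin top-left, x
#' rightwards, y downwards), with the pixel size carried along. This is the
#' geometry source for length, width and profile extraction.
#'
#' @param cell_id Identifier.
#' @param ribs Data frame with columns `x_left`, `y_left`, `x_right`,
#'   `y_right` (>= 3 rows).
#' @param centerline Data frame with columns `x`, `y`; one point per rib.
#' @param pixel_size Pixel size in um per px.
#' @return Object of class `cell_mesh`.
#' @export
cell_mesh <- function(cell_id, ribs, centerline, pixel_size) {
  ribs <- as.data.frame(ribs)
  centerline <- as.data.frame(centerline)
  need <- c("x_left", "y_left", "x_right", "y_right")
  if (!all(need %in% names(ribs))) stop_input("ribs must have columns ", paste(need, collapse = ", "))
  if (nrow(ribs) < 3) stop_input("a mesh needs at least 3 ribs")
  if (nrow(centerline) != nrow(ribs))
    stop_input("centerline must have one point per rib")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_input("pixel_size must be > 0")
  structure(list(cell_id = as.character(cell_id), ribs = ribs,
                 centerline = centerline, pixel_size = pixel_size),
            class = "cell_mesh")
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh %s: %d ribs, pixel %.3g um, length %.2f um>\n",
              x$cell_id, nrow(x$ribs), x$pixel_size, cell_length(x)))
  invisible(x)
}

#' Render one cell as a fluorescence image plus mesh
#'
#' Draws a spherocylindrical cell of the ground-truth length and fixed width
#' as diffuse cytoplasmic signal over a uniform background, blurred by a
#' Gaussian point-spread function. Each cluster is added as a 2D Gaussian
#' spot of the stated amplitude and PSF width at its relative position on
#' the centerline. A constriction is rendered as a 40% local width reduction
#' over a 0.4 um window. The returned mesh (ribs + centerline) matches the
#' drawn shape, so recomputing the cell length from the mesh recovers the
#' truth length.
#'
#' @param truth One row of a `cell_truth` data frame (or a list with the same
#'   fields).
#' @param pixel_size um per pixel.
#' @param psf_sigma PSF standard deviation (um).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer seed for the noise.
#' @param cell_width Cell diameter (um).
#' @param cytoplasm Diffuse cytoplasmic signal level (intensity units).
#' @param background Uniform camera background level.
#' @param pad Padding around the cell (um); must leave room for the
#'   background annulus.
#' @return List of class `rendered_cell`: `image` (matrix, rows = y),
#'   `mesh` (a [cell_mesh()]), and `truth`.
#' @export
render_cell <- function(truth, pixel_size = 0.1, psf_sigma = 0.15,
                        noise_sd = 0.1, seed = 1L, cell_width = 0.7,
                        cytoplasm = 1, background = 0.2, pad = 1) {
  truth <- as.list(truth)
  L <- truth$length
  if (is.null(L) || L <= 0) stop_input("truth$length must be > 0")
  cl_pos <- truth$cluster_position
  has_cl <- isTRUE(truth$has_cluster) && !is.na(cl_pos %||% NA)
  if (has_cl && (cl_pos < 0 || cl_pos > 1))
    stop_input("cluster positions must lie in [0, 1]")
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  if (psf_sigma < 0) stop_input("psf_sigma must be >= 0")

  pad_px <- ceiling(pad / pixel_size)
  nx <- ceiling(L / pixel_size) + 2L * pad_px
  ny <- ceiling(cell_width / pixel_size) + 2L * pad_px
  yc <- (ny - 1) / 2           # 0-based pixel coords of the centerline
  x0 <- pad_px

  # centerline samples at ~1 px spacing, endpoints exact
  n_ribs <- max(3L, round(L / pixel_size) + 1L)
  s <- seq(0, L, length.out = n_ribs)           # arclength from pole A, um
  xs <- x0 + s / pixel_size                     # px

  r <- radius_profile(s, L, cell_width / 2,
                      if (isTRUE(truth$has_constriction))
                        truth$constriction_position else NA_real_)

  # body mask column by column (cell is drawn axis-aligned)
  img <- matrix(background, nrow = ny, ncol = nx)
  px_x <- 0:(nx - 1)
  r_at_col <- approx(xs, r, xout = px_x, yleft = 0, yright = 0)$y / pixel_size
  yy <- 0:(ny - 1)
  body <- outer(yy, r_at_col, function(y, rr) abs(y - yc) <= rr & rr > 0)
  sig <- matrix(0, nrow = ny, ncol = nx)
  sig[body] <- cytoplasm
  if (psf_sigma > 0)
    sig <- EBImage::gblur(sig, sigma = psf_sigma / pixel_size)
  img <- img + sig

  if (has_cl) {
    amp <- truth$cluster_amplitude %||% 5
    sx <- x0 + cl_pos * L / pixel_size
    sp <- max(psf_sigma, pixel_size / 2) / pixel_size
    gx <- exp(-(px_x - sx)^2 / (2 * sp^2))
    gy <- exp(-(yy - yc)^2 / (2 * sp^2))
    img <- img + amp * (gy %o% gx)
  }

  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(nx * ny, 0, noise_sd), ny, nx))

  mesh <- cell_mesh(truth$cell_id %||% "cell",
                    ribs = data.frame(x_left = xs, y_left = yc - r / pixel_size,
                                      x_right = xs, y_right = yc + r / pixel_size),
                    centerline = data.frame(x = xs, y = rep(yc, n_ribs)),
                    pixel_size = pixel_size)
  structure(list(image = img, mesh = mesh, truth = truth),
            class = "rendered_cell")
}

# Local half-width along the cell: spherocylinder caps plus an optional
# triangular constriction notch (40% depth over a 0.4 um window).
radius_profile <- function(s, L, r0, constriction_pos = NA_real_,
                           depth = 0.4, window = 0.4) {
  d <- pmin(s, L - s)                      # distance to nearest pole, um
  r <- ifelse(d >= r0, r0, sqrt(pmax(r0^2 - (r0 - d)^2, 0)))
  r <- pmax(r, 0.02 * r0)                  # keep outline non-degenerate
  if (!is.na(constriction_pos)) {
    xc <- constriction_pos * L
    half <- window / 2
    notch <- pmax(0, 1 - abs(s - xc) / half)
    r <- r * (1 - depth * notch)
  }
  r
}

#' Render a whole population
#'
#' Convenience wrapper rendering every cell of a `cell_truth` table with a
#' per-cell seed derived from `seed`.
#'
#' @param truths A `cell_truth` data frame from [sample_cell_population()].
#' @param seed Base seed; cell i uses `seed + i`.
#' @param ... Passed to [render_cell()].
#' @return List of `rendered_cell` objects.
#' @export
render_population <- function(truths, seed = 1L, ...) {
  lapply(seq_len(nrow(truths)), function(i)
    render_cell(truths[i, ], seed = seed + i, ...))
}
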