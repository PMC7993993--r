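#' Cell length from the centerline
#'
#' Sum of Euclidean distances between consecutive centerline points, scaled
#' by the pixel size. Invariant under rigid rotation/translation of the mesh.
#'
#' @param mesh A [cell_mesh()].
#' @return Length in um.
#' @export
cell_length <- function(mesh) {
  cl <- mesh$centerline
  if (nrow(cl) < 2) stop_input("centerline needs at least 2 points")
  sum(sqrt(diff(cl$x)^2 + diff(cl$y)^2)) * mesh$pixel_size
}

#' Width profile along the cell
#'
#' Distance between the left and right outline point of each rib, in um.
#'
#' @param mesh A [cell_mesh()].
#' @return Numeric vector, one width per rib.
#' @export
width_profile <- function(mesh) {
  r <- mesh$ribs
  sqrt((r$x_left - r$x_right)^2 + (r$y_left - r$y_right)^2) * mesh$pixel_size
}

#' Relative rib positions along the centerline
#'
#' Normalized arclength (0 at pole A = first rib, 1 at pole B) of each
#' centerline point.
#'
#' @param mesh A [cell_mesh()].
#' @return Numeric vector in `[0, 1]`.
#' @export
relative_positions <- function(mesh) {
  cl <- mesh$centerline
  s <- c(0, cumsum(sqrt(diff(cl$x)^2 + diff(cl$y)^2)))
  if (s[length(s)] == 0) stop_input("degenerate centerline")
  s / s[length(s)]
}

#' Detect a division constriction in a width profile
#'
#' Finds the deepest interior local minimum of the width profile within the
#' central band of the cell whose depth -- defined as `1 - width / median
#' flank width` with flanks taken at least 0.1 relative units away from the
#' candidate -- reaches `min_depth`. Returns a non-call (`present = FALSE`)
#' when no minimum qualifies (e.g. a flat profile).
#'
#' @param widths Width per rib (um), as from [width_profile()].
#' @param positions Relative rib positions in `[0, 1]`, as from
#'   [relative_positions()].
#' @param min_depth Minimum relative depth to call a constriction.
#' @param central_band Fraction of cell length, centered at midcell, searched
#'   for the constriction.
#' @param cell_id Carried into the call.
#' @return A one-row data frame of class `constriction_call`: `cell_id`,
#'   `present`, `relative_position`, `depth`.
#' @export
detect_constriction <- function(widths, positions, min_depth = 0.10,
                                central_band = 0.90, cell_id = NA_character_) {
  if (length(widths) == 0 || length(widths) != length(positions))
    stop_input("widths and positions must be non-empty and aligned")
  if (min_depth <= 0 || min_depth >= 1) stop_input("min_depth must be in (0,1)")
  if (central_band <= 0 || central_band > 1)
    stop_input("central_band must be in (0,1]")
  half <- central_band / 2
  n <- length(widths)
  no_call <- data.frame(cell_id = cell_id, present = FALSE,
                        relative_position = NA_real_, depth = NA_real_)
  class(no_call) <- c("constriction_call", "data.frame")
  if (n < 3) return(no_call)

  idx <- 2:(n - 1)
  is_min <- widths[idx] < widths[idx - 1] & widths[idx] <= widths[idx + 1]
  cand <- idx[is_min & abs(positions[idx] - 0.5) <= half]
  if (length(cand) == 0) return(no_call)

  depth <- vapply(cand, function(i) {
    flank <- widths[abs(positions - positions[i]) >= 0.10]
    if (length(flank) == 0) flank <- widths
    1 - widths[i] / median(flank)
  }, numeric(1))
  ok <- depth >= min_depth
  if (!any(ok)) return(no_call)
  best <- cand[ok][which.max(depth[ok])]
  out <- data.frame(cell_id = cell_id, present = TRUE,
                    relative_position = positions[best],
                    depth = max(depth[ok]))
  class(out) <- c("constriction_call", "data.frame")
  out
}

#' Call a minicell
#'
#' A minicell is a short, DNA-free cell produced by division away from
#' midcell. With a DNA channel available a cell is a minicell iff it is
#' shorter than the cutoff and DNA-free; without one (`has_dna = NA`) the
#' call is length-only.
#'
#' @param length Cell length (um), vectorized.
#' @param has_dna Logical (NA for length-only mode).
#' @param cutoff Length cutoff in um (default 2.0).
#' @return Logical vector.
#' @export
classify_minicell <- function(length, has_dna = NA, cutoff = 2.0) {
  if (any(length <= 0)) stop_input("length must be > 0")
  short <- length < cutoff
  ifelse(is.na(has_dna), short, short & !has_dna)
}

#' Population length summary in boxplot convention
#'
#' Mean, SD, median, quartiles (25th/75th percentile, linear-interpolation
#' rule), whiskers at the 10th and 90th percentile, and the points outside
#' the whiskers as outliers.
#'
#' @param lengths Numeric vector of lengths (um), n >= 1.
#' @return Object of class `length_summary`.
#' @export
summarize_lengths <- function(lengths) {
  if (length(lengths) == 0 || !is.numeric(lengths))
    stop_input("lengths must be a non-empty numeric vector")
  q <- unname(quantile(lengths, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  structure(list(n = length(lengths),
                 mean = mean(lengths),
                 sd = if (length(lengths) > 1) sd(lengths) else 0,
                 median = q[3], q25 = q[2], q75 = q[4],
                 whisker_low = q[1], whisker_high = q[5],
                 outliers = lengths[lengths < q[1] | lengths > q[5]]),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("Lengths (n = %d): %.2f +/- %.2f um; median %.2f [%.2f, %.2f], whiskers [%.2f, %.2f], %d outliers\n",
              x$n, x$mean, x$sd, x$median, x$q25, x$q75,
              x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact enumeration (doubled one-tail, capped at 1) when the combined sample
#' size is at most 20 and there are no ties; otherwise the tie-corrected
#' normal approximation.
#'
#' @param a,b Numeric samples (non-empty).
#' @param mode `"auto"` (default rule above), `"exact"`, or
#'   `"normal_approx"`.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop_input("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(mode,
    auto = (length(a) + length(b) <= 20) && !ties,
    exact = {
      if (ties) warning("ties present; falling back to the normal approximation")
      !ties
    },
    normal_approx = FALSE)
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}
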