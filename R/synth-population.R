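#' Sample a synthetic cell population with known ground truth
#'
#' Draws per-cell ground truth (length, DNA content, cluster position and
#' amplitude, constriction) from a [population_params()] description. Lengths
#' are normal truncated below at 0.5 um; a `minicell_fraction` share of cells
#' is replaced by DNA-free minicells with length uniform in 0.6--1.5 um.
#' Cluster presence is Bernoulli(`cluster_prevalence`) (minicells never carry
#' one); the cluster position is drawn from the localization mixture:
#' midcell uniform in `[0.45, 0.55]`, off-center uniform over the nucleoid
#' excluding the midcell band, subpolar uniform over the DNA-free caps.
#'
#' @param params A [population_params()] object.
#' @param n Number of cells (>= 1).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @param amplitude_mean,amplitude_sd,amplitude_floor Cluster amplitude
#'   distribution (intensity units relative to a cytoplasmic level of 1);
#'   normal truncated below at `amplitude_floor`.
#' @return A data frame of class `cell_truth`, one row per cell, with columns
#'   `cell_id`, `length`, `has_dna`, `has_cluster`, `cluster_position`
#'   (NA when absent), `cluster_amplitude`, `localization` (truth label),
#'   `has_constriction`, `constriction_position`, `is_minicell`.
#' @export
sample_cell_population <- function(params, n, seed = 1L,
                                   amplitude_mean = 6,
                                   amplitude_sd = 1,
                                   amplitude_floor = 3) {
  if (!inherits(params, "population_params"))
    stop_input("params must be a population_params object")
  if (!is.numeric(n) || n < 1) stop_input("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    len <- rnorm_trunc(n, params$length_mean, params$length_sd, lower = 0.5)
    is_mini <- runif(n) < params$minicell_fraction
    len[is_mini] <- runif(sum(is_mini), 0.6, 1.5)
    has_dna <- !is_mini

    has_cluster <- runif(n) < params$cluster_prevalence & !is_mini
    loc <- rep(NA_character_, n)
    pos <- rep(NA_real_, n)
    amp <- rep(NA_real_, n)
    k <- sum(has_cluster)
    if (k > 0) {
      classes <- sample(names(params$localization_mixture), k, replace = TRUE,
                        prob = params$localization_mixture)
      pos[has_cluster] <- draw_positions(classes, params$nucleoid_span)
      loc[has_cluster] <- classes
      amp[has_cluster] <- rnorm_trunc(k, amplitude_mean, amplitude_sd,
                                      lower = amplitude_floor)
    }

    has_con <- runif(n) < params$constriction_frequency & !is_mini
    cpos <- rep(NA_real_, n)
    m <- sum(has_con)
    if (m > 0) {
      cpos[has_con] <- if (params$constriction_position_model == "midcell_tight") {
        pmin(pmax(rnorm(m, 0.5, 0.02), 0.40), 0.60)
      } else {
        half <- params$nucleoid_span / 2
        runif(m, 0.5 - half, 0.5 + half)
      }
    }

    out <- data.frame(cell_id = sprintf("cell_%04d", seq_len(n)),
                      length = len,
                      has_dna = has_dna,
                      has_cluster = has_cluster,
                      cluster_position = pos,
                      cluster_amplitude = amp,
                      localization = loc,
                      has_constriction = has_con,
                      constriction_position = cpos,
                      is_minicell = is_mini,
                      stringsAsFactors = FALSE)
    attr(out, "params") <- params
    attr(out, "seed") <- seed
    class(out) <- c("cell_truth", "data.frame")
    out
  })
}

# Normal truncated below at `lower` by resampling; exact when sd == 0.
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# Draw relative cluster positions given localization class labels.
draw_positions <- function(classes, nucleoid_span) {
  k <- length(classes)
  pos <- numeric(k)
  half <- nucleoid_span / 2
  for (i in seq_len(k)) {
    pos[i] <- switch(classes[i],
      midcell = runif(1, 0.45, 0.55),
      off_center = {
        # nucleoid minus the midcell band, both arms equally likely by area
        lo <- 0.5 - half
        p <- runif(1, lo, 0.5 + half - 0.10)
        if (p > 0.45) p + 0.10 else p
      },
      subpolar = {
        cap <- 0.5 - half
        p <- runif(1, 0, 2 * cap)
        if (p > cap) 1 - (p - cap) else p
      })
  }
  pos
}
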