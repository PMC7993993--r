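#' Simulate a time-lapse of dividing cells with cluster inheritance
#'
#' Generates a frame series of non-motile rod cells, each lineage in its own
#' image lane, dividing once at a random early frame. At division the
#' parent's fluorescent cluster either undergoes fission -- both daughters
#' receive a portion, with the split ratio uniform in `[0.3, 0.7]` -- with
#' probability `fission_probability`, or segregates undivided into one
#' (random) daughter. A daughter left without a cluster regenerates one
#' after `regeneration_delay` minutes.
#'
#' @param params A [population_params()] for parent lengths.
#' @param fission_probability Probability of cluster fission per division.
#' @param n_divisions Number of simulated lineages (one division each).
#' @param frame_interval Minutes between frames.
#' @param regeneration_delay Minutes from division to a cluster reappearing
#'   in an empty daughter.
#' @param n_frames Number of frames (default: enough to see regeneration).
#' @param seed Integer seed.
#' @param parent_signal Integrated cluster intensity of a parent cluster.
#' @param regenerated_signal Intensity of a freshly regenerated cluster.
#' @return Object of class `timelapse_sim` with elements `frames` (data
#'   frame: `frame`, `time_min`, `cell_id`, `lane`, `x0`, `x1`, `y0`, `y1`
#'   bounding extents in um, `cluster_signal`) and `truth` (one row per
#'   division: `parent_id`, `frame`, `fission`, `split_ratio`,
#'   `receiving_daughter`), plus the generation settings.
#' @export
simulate_timelapse <- function(params, fission_probability = 0.8,
                               n_divisions = 50, frame_interval = 20,
                               regeneration_delay = 120, n_frames = NULL,
                               seed = 1L, parent_signal = 100,
                               regenerated_signal = 30) {
  check_prob(fission_probability, "fission_probability")
  if (frame_interval <= 0) stop_input("frame_interval must be > 0")
  if (n_divisions < 1) stop_input("n_divisions must be >= 1")
  regen_frames <- ceiling(regeneration_delay / frame_interval)

  with_seed(seed, {
    div_frame <- sample(2:4, n_divisions, replace = TRUE)
    if (is.null(n_frames)) n_frames <- max(div_frame) + regen_frames + 1L
    L <- rnorm_trunc(n_divisions, params$length_mean, params$length_sd, 0.5)
    fission <- runif(n_divisions) < fission_probability
    ratio <- ifelse(fission, runif(n_divisions, 0.3, 0.7), NA_real_)
    receiver <- ifelse(fission, NA_integer_, sample(1:2, n_divisions, TRUE))

    rows <- vector("list", n_divisions)
    lane_h <- 2  # um of vertical extent per lane; lanes never overlap
    for (i in seq_len(n_divisions)) {
      y0 <- (i - 1) * 2 * lane_h
      pid <- sprintf("lin%03d_P", i)
      d1 <- sprintf("lin%03d_D1", i); d2 <- sprintf("lin%03d_D2", i)
      sig1 <- if (fission[i]) parent_signal * ratio[i]
              else if (receiver[i] == 1) parent_signal else 0
      sig2 <- if (fission[i]) parent_signal * (1 - ratio[i])
              else if (receiver[i] == 2) parent_signal else 0
      fr <- lapply(seq_len(n_frames), function(f) {
        if (f < div_frame[i]) {
          data.frame(frame = f, cell_id = pid, lane = i,
                     x0 = 0, x1 = L[i], cluster_signal = parent_signal)
        } else {
          k <- f - div_frame[i]
          s1 <- if (sig1 == 0 && k >= regen_frames) regenerated_signal else sig1
          s2 <- if (sig2 == 0 && k >= regen_frames) regenerated_signal else sig2
          data.frame(frame = c(f, f), cell_id = c(d1, d2), lane = i,
                     x0 = c(0, L[i] / 2), x1 = c(L[i] / 2, L[i]),
                     cluster_signal = c(s1, s2))
        }
      })
      rows[[i]] <- do.call(rbind, fr)
      rows[[i]]$y0 <- y0
      rows[[i]]$y1 <- y0 + lane_h
    }
    frames <- do.call(rbind, rows)
    frames$time_min <- (frames$frame - 1) * frame_interval
    frames <- frames[order(frames$frame, frames$lane, frames$x0), ]
    rownames(frames) <- NULL

    truth <- data.frame(parent_id = sprintf("lin%03d_P", seq_len(n_divisions)),
                        frame = div_frame, fission = fission,
                        split_ratio = ratio, receiving_daughter = receiver)
    structure(list(frames = frames, truth = truth,
                   frame_interval = frame_interval,
                   regeneration_delay = regeneration_delay,
                   fission_probability = fission_probability, seed = seed),
              class = "timelapse_sim")
  })
}

#' @export
print.timelapse_sim <- function(x, ...) {
  cat(sprintf("<timelapse_sim: %d lineages, %d frames @ %g min, P(fission) = %.2f>\n",
              nrow(x$truth), max(x$frames$frame), x$frame_interval,
              x$fission_probability))
  invisible(x)
}
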