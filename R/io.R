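# Mesh / trace / image interchange. CSV: comma-separated, UTF-8, "."
# decimal, header row; comment header lines start with "#" and carry
# key=value metadata (pixel size, seed, tool version).

meta_header <- function(kind, extra = character(0)) {
  c(sprintf("# pomogram %s v1", kind),
    sprintf("# version=%s", as.character(utils::packageVersion("pomogram"))),
    extra)
}

#' Write cell meshes to CSV
#'
#' One row per rib: `cell_id`, `rib_index`, `x_left`, `y_left`, `x_right`,
#' `y_right`, `x_center`, `y_center` (0-based pixel coordinates, origin
#' top-left, x rightwards, y downwards). Pixel size and seed go into `#`
#' metadata header lines.
#'
#' @param meshes List of [cell_mesh()] objects (one shared pixel size).
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @export
write_mesh_csv <- function(meshes, path, seed = NULL) {
  if (length(meshes) == 0) stop_input("no meshes to write")
  ps <- unique(vapply(meshes, function(m) m$pixel_size, numeric(1)))
  if (length(ps) != 1) stop_input("meshes must share one pixel_size")
  rows <- do.call(rbind, lapply(meshes, function(m) {
    data.frame(cell_id = m$cell_id, rib_index = seq_len(nrow(m$ribs)),
               x_left = m$ribs$x_left, y_left = m$ribs$y_left,
               x_right = m$ribs$x_right, y_right = m$ribs$y_right,
               x_center = m$centerline$x, y_center = m$centerline$y)
  }))
  hdr <- meta_header("mesh", c(sprintf("# pixel_size_um_per_px=%.10g", ps),
                               if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed))))
  writeLines(hdr, path)
  suppressWarnings(write.table(rows, path, sep = ",", row.names = FALSE,
                               col.names = TRUE, append = TRUE, quote = FALSE))
  invisible(path)
}

read_meta <- function(path) {
  lines <- readLines(path, n = 20)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^# *([A-Za-z_]+)=(.*)$", lines))
  kv <- Filter(function(m) length(m) == 3, kv)
  stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
}

#' Read cell meshes from CSV
#'
#' Counterpart of [write_mesh_csv()]; validates the schema, rib-index
#' monotonicity and the minimum of 3 ribs per cell.
#'
#' @param path Mesh CSV path.
#' @return List of [cell_mesh()] objects.
#' @export
read_mesh_csv <- function(path) {
  meta <- read_meta(path)
  ps <- as.numeric(meta$pixel_size_um_per_px %||% NA)
  if (is.na(ps)) stop_input("mesh file lacks pixel_size_um_per_px metadata")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell_id", "rib_index", "x_left", "y_left", "x_right", "y_right",
            "x_center", "y_center")
  if (!all(need %in% names(df)))
    stop_input("mesh CSV missing columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
         function(d) {
           if (any(diff(d$rib_index) <= 0))
             stop_input("non-monotone rib indices for cell ", d$cell_id[1])
           cell_mesh(d$cell_id[1],
                     ribs = d[, c("x_left", "y_left", "x_right", "y_right")],
                     centerline = data.frame(x = d$x_center, y = d$y_center),
                     pixel_size = ps)
         })
}

#' Write plate traces to CSV (long format) plus a well map
#'
#' The trace file has columns `time_s`, `well`, `A340`; the well map (same
#' path with suffix `_wells.csv`, or `well_map_path`) carries `well`,
#' `enzyme_conc`, `aap`, `aap_conc`, `dna_conc`, `is_control`.
#'
#' @param traces List of [plate_trace()] objects.
#' @param path Trace CSV path.
#' @param well_map_path Optional well-map path.
#' @param seed Optional seed recorded in the header.
#' @export
write_trace_csv <- function(traces, path, well_map_path = NULL, seed = NULL) {
  if (length(traces) == 0) stop_input("no traces to write")
  long <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$times_s, well = tr$well, A340 = tr$a340)))
  hdr <- meta_header("trace",
                     if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)))
  writeLines(hdr, path)
  suppressWarnings(write.table(long, path, sep = ",", row.names = FALSE,
                               col.names = TRUE, append = TRUE, quote = FALSE))
  wm <- do.call(rbind, lapply(traces, function(tr)
    data.frame(well = tr$well, enzyme_conc = tr$enzyme_conc, aap = tr$aap,
               aap_conc = tr$aap_conc, dna_conc = tr$dna_conc,
               is_control = tr$is_control)))
  wmp <- well_map_path %||% sub("\\.csv$", "_wells.csv", path)
  write.csv(wm, wmp, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plate traces from CSV
#'
#' @param path Trace CSV (long format `time_s`, `well`, `A340`).
#' @param well_map_path Well-map CSV; defaults to `path` with a `_wells.csv`
#'   suffix, metadata defaults are used if the file is absent.
#' @return Named list of [plate_trace()] objects, one per well.
#' @export
read_trace_csv <- function(path, well_map_path = NULL) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "well", "A340") %in% names(df)))
    stop_input("trace CSV must have columns time_s, well, A340")
  wmp <- well_map_path %||% sub("\\.csv$", "_wells.csv", path)
  wm <- if (file.exists(wmp)) read.csv(wmp, stringsAsFactors = FALSE) else NULL
  out <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_s), ]
    m <- if (!is.null(wm) && d$well[1] %in% wm$well)
      wm[wm$well == d$well[1], ][1, ] else NULL
    plate_trace(d$time_s, d$A340, well = d$well[1],
                enzyme_conc = m$enzyme_conc %||% 0,
                aap = m$aap %||% "none", aap_conc = m$aap_conc %||% 0,
                dna_conc = m$dna_conc %||% 0,
                is_control = isTRUE(m$is_control))
  })
  out[unique(df$well)]
}

#' Write an intensity image as TIFF
#'
#' Stores the matrix as 32-bit float TIFF after dividing by `scale`
#' (tiff files carry values in `[0, 1]`); the scale is appended to the file
#' name's sidecar `<path>.scale.txt` so [read_image_tiff()] can undo it.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @export
write_image_tiff <- function(image, path) {
  scale <- max(image, 1e-12)
  tiff::writeTIFF(pmax(image, 0) / scale, path, bits.per.sample = 32L)
  writeLines(sprintf("%.12g", scale), paste0(path, ".scale.txt"))
  invisible(path)
}

#' Read an intensity image written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @return Numeric matrix on the original intensity scale.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sc_file <- paste0(path, ".scale.txt")
  if (file.exists(sc_file)) img <- img * as.numeric(readLines(sc_file, n = 1))
  img
}
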