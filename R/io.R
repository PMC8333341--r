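#' Plain-text serialization
#'
#' Maps and montages are exchanged as CSV tables plus a JSON sidecar
#' carrying acquisition metadata (alpha triplet, b, mask quantile, pixel
#' size). Text formats keep runs inspectable and diffable; converting
#' to/from microscope TIFFs is left to the acquisition side.
#'
#' @name polforce-io
#' @keywords internal
NULL

#' Write an orientation map to CSV + JSON sidecar
#'
#' @param map an `orientation_map`.
#' @param prefix output path prefix; writes `<prefix>.csv` (per-pixel
#'   table) and `<prefix>.json`.
#' @return the prefix, invisibly.
#' @export
write_orientation_map <- function(map, prefix) {
  stopifnot(inherits(map, "orientation_map"))
  d <- dim(map$phi)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tab <- data.frame(idx,
                    phi = as.numeric(map$phi),
                    theta = as.numeric(map$theta),
                    A = as.numeric(map$A),
                    c = as.numeric(map$c),
                    i_max = as.numeric(map$i_max),
                    valid = as.logical(map$valid))
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(dims = d, alphas = as.numeric(map$alphas),
               b = map$params$b, undef_tol = map$params$undef_tol,
               mask_quantile = map$mask_quantile,
               pixel_size_nm = map$pixel_size_nm,
               n_clipped = map$n_clipped)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an orientation map written by [write_orientation_map()]
#' @param prefix path prefix used when writing.
#' @return an `orientation_map`.
#' @export
read_orientation_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  d <- as.integer(meta$dims)
  mk <- function(v) matrix(v, d[1], d[2])
  orientation_map(mk(tab$phi), mk(tab$theta), mk(tab$A), mk(tab$c),
                  mk(tab$i_max), mk(tab$valid),
                  alphas = do.call(alpha_triplet, as.list(meta$alphas)),
                  params = dipole_params(meta$b, meta$undef_tol),
                  mask_quantile = meta$mask_quantile,
                  pixel_size_nm = meta$pixel_size_nm,
                  n_clipped = as.integer(meta$n_clipped))
}

#' Write a raw montage to CSV + JSON sidecar
#'
#' @param m a [sim_montage()].
#' @param prefix output path prefix.
#' @export
write_montage <- function(m, prefix) {
  stopifnot(inherits(m, "sim_montage"))
  d <- dim(m$frames)
  tab <- data.frame(expand.grid(row = seq_len(d[1]), col = seq_len(d[2]),
                                frame = seq_len(d[3])),
                    value = as.numeric(m$frames))
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(dims = d, alphas = as.numeric(m$alphas), phases = m$phases,
               camera_baseline = m$camera_baseline,
               pixel_size_nm = m$pixel_size_nm, layout = m$layout,
               timestamp_min = m$timestamp_min)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a montage written by [write_montage()]
#' @param prefix path prefix used when writing.
#' @export
read_montage <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  d <- as.integer(meta$dims)
  sim_montage(array(tab$value, d),
              alphas = do.call(alpha_triplet, as.list(meta$alphas)),
              phases = as.integer(meta$phases),
              camera_baseline = meta$camera_baseline,
              pixel_size_nm = meta$pixel_size_nm, layout = meta$layout,
              timestamp_min = meta$timestamp_min)
}

#' Write a platelet track to CSV
#' @param track a [platelet_track()].
#' @param path output file.
#' @export
write_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
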