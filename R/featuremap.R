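#' Cut a cleaned recording into non-overlapping windows
#'
#' @param rec an `eeg_recording`.
#' @param win_s window length in seconds (default 10; step equals the
#'   length, so windows never overlap).
#' @return list of channel x sample matrices, possibly empty; each carries
#'   a `t_start_s` attribute.
#' @export
window_signal <- function(rec, win_s = 10) {
  stopifnot_scalar_pos(win_s, "win_s")
  spw <- round(win_s * rec$fs)
  n_win <- floor(ncol(rec$data) / spw)
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    w <- rec$data[, ((i - 1) * spw + 1):(i * spw), drop = FALSE]
    attr(w, "t_start_s") <- (i - 1) * win_s
    out[[i]] <- w
  }
  out
}

#' Render one multichannel window as a grayscale feature map
#'
#' The channels x time amplitude matrix is clipped to `+/- clip_uv`,
#' intensity-mapped symmetrically (0 uV maps to mid-gray, the clip bounds to
#' black/white) and resampled to a `size x size` 8-bit image:
#' nearest-neighbour vertically (each channel occupies a solid band of rows)
#' and linear interpolation horizontally.
#'
#' @param window channels x samples matrix (19 channels expected).
#' @param size output image side in pixels (default 400).
#' @param clip_uv symmetric amplitude clip in microvolts (default 70, the
#'   rejection threshold).
#' @param n_channels expected channel count (default 19).
#' @return integer matrix `size x size` with values in 0..255.
#' @export
render_feature_map <- function(window, size = 400, clip_uv = 70,
                               n_channels = 19) {
  if (!is.matrix(window) || nrow(window) != n_channels)
    stop(sprintf("window must have %d channel rows", n_channels))
  nc <- nrow(window); ns <- ncol(window)
  if (ns < 2) stop("window too short to render")
  # horizontal: linear interpolation onto `size` equally spaced time points
  tx <- seq(1, ns, length.out = size)
  lo <- pmin(floor(tx), ns - 1L); frac <- tx - lo
  hmat <- window[, lo, drop = FALSE] * rep(1 - frac, each = nc) +
    window[, lo + 1L, drop = FALSE] * rep(frac, each = nc)
  # vertical: nearest-neighbour band per channel
  rows <- pmin(nc, floor((seq_len(size) - 0.5) * nc / size) + 1L)
  img <- hmat[rows, , drop = FALSE]
  img <- pmax(pmin(img, clip_uv), -clip_uv)
  px <- round(127.5 + 127.5 * img / clip_uv)
  storage.mode(px) <- "integer"
  px
}

#' Write a rendered feature map as a PNG file
#' @param px integer matrix from [render_feature_map()].
#' @param path output path.
#' @export
write_feature_map_png <- function(px, path) {
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Extract all feature-map images for one subject
#'
#' Cuts the cleaned recording into 10 s windows and writes one PNG per
#' window, named `{subject_id}_{window:02d}.png`, plus a manifest row per
#' image. A 600 s cleaned recording yields 60 images.
#'
#' @param rec cleaned `eeg_recording`.
#' @param out_dir output directory (NULL keeps images in memory).
#' @param group group label recorded in the manifest.
#' @param win_s window length (default 10 s).
#' @param size image side in pixels (default 400).
#' @param clip_uv amplitude clip (default 70).
#' @return list with `manifest` (data.frame: subject_id, group,
#'   window_index, t_start_s, path) and `images` (list of pixel matrices
#'   when `out_dir` is NULL).
#' @export
extract_subject_maps <- function(rec, out_dir = NULL, group = NA_character_,
                                 win_s = 10, size = 400, clip_uv = 70) {
  wins <- window_signal(rec, win_s)
  if (length(wins) == 0) warning(rec$subject_id, ": no full windows; 0 images")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list(); imgs <- list()
  for (i in seq_along(wins)) {
    px <- render_feature_map(wins[[i]], size = size, clip_uv = clip_uv,
                             n_channels = nrow(rec$data))
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, sprintf("%s_%02d.png", rec$subject_id, i - 1))
      write_feature_map_png(px, path)
    } else {
      imgs[[i]] <- px
    }
    rows[[i]] <- data.frame(subject_id = rec$subject_id, group = group,
                            window_index = i - 1L,
                            t_start_s = attr(wins[[i]], "t_start_s"),
                            path = path, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0),
               window_index = integer(0), t_start_s = numeric(0),
               path = character(0))
  out <- list(manifest = manifest)
  if (is.null(out_dir)) out$images <- imgs
  out
}

#' Extract feature maps for a whole cohort
#'
#' @param clean named list of cleaned recordings (see [preprocess_cohort()]).
#' @param roster cohort roster with `subject_id` and `group` columns.
#' @param out_dir PNG output directory (NULL keeps images in memory).
#' @inheritParams extract_subject_maps
#' @return list with the combined `manifest` and (in-memory mode) `images`,
#'   a list parallel to the manifest rows.
#' @export
extract_cohort_maps <- function(clean, roster, out_dir = NULL, win_s = 10,
                                size = 400, clip_uv = 70) {
  mans <- list(); imgs <- list()
  for (sid in names(clean)) {
    grp <- roster$group[match(sid, roster$subject_id)]
    res <- extract_subject_maps(clean[[sid]], out_dir = out_dir, group = grp,
                                win_s = win_s, size = size, clip_uv = clip_uv)
    mans[[sid]] <- res$manifest
    if (is.null(out_dir)) imgs <- c(imgs, res$images)
  }
  manifest <- do.call(rbind, mans)
  rownames(manifest) <- NULL
  out <- list(manifest = manifest)
  if (is.null(out_dir)) out$images <- imgs
  out
}
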