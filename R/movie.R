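# Optional image layer: render traces as a stack of diffraction-limited
# Gaussian spots and recover per-spot traces by aperture photometry.

# Jittered-grid spot placement with a hard minimum spacing. Errors when the
# field cannot hold n spots at that spacing.
place_spots <- function(n, field_size, min_spacing) {
  ny <- field_size[1L]; nx <- field_size[2L]
  margin <- ceiling(min_spacing)
  sx <- seq(margin + 1, nx - margin, by = min_spacing)
  sy <- seq(margin + 1, ny - margin, by = min_spacing)
  if (length(sx) * length(sy) < n)
    stop(sprintf("field %dx%d too small for %d spots at spacing %.1f px",
                 ny, nx, n, min_spacing))
  grid <- expand.grid(x = sx, y = sy)[seq_len(n), , drop = FALSE]
  as.matrix(grid)
}

# Discrete PSF kernel over the full field for one spot, normalized to unit
# sum so the rendered spot integrates exactly to the trace value.
spot_kernel <- function(pos, field_size, psf_sigma) {
  ny <- field_size[1L]; nx <- field_size[2L]
  gx <- stats::dnorm(seq_len(nx), mean = pos[1L], sd = psf_sigma)
  gy <- stats::dnorm(seq_len(ny), mean = pos[2L], sd = psf_sigma)
  k <- outer(gy, gx)
  k / sum(k)
}

#' Render traces as a synthetic fluorescence movie
#'
#' Each frame is the sum of symmetric 2-D Gaussian spots whose integrated
#' intensities equal the per-frame trace values, on a constant camera
#' baseline, plus optional per-pixel Gaussian noise. Spot positions are
#' assigned on a jittered grid with minimum spacing `4 * psf_sigma` (or
#' supplied explicitly) and returned as ground truth.
#'
#' @param traces Numeric matrix, one row per spot, one column per frame
#'   (e.g. the `content` matrix of an `"sv_experiment"`).
#' @param psf_sigma Gaussian PSF standard deviation, pixels.
#' @param field_size `c(ny, nx)` frame size in pixels.
#' @param positions Optional `n x 2` matrix of (x, y) spot centers;
#'   placed automatically when `NULL`.
#' @param min_spacing Minimum center-to-center spacing for automatic
#'   placement, pixels; at least `4 * psf_sigma`. Use a larger value when
#'   extraction will use apertures wider than `2 * psf_sigma`.
#' @param camera_baseline Constant per-pixel offset, a.u.
#' @param noise_sd Per-pixel additive Gaussian noise SD (0 = noiseless).
#' @return An object of class `"sv_movie"`: list with `frames`
#'   (`ny x nx x n_frames` array), `positions`, `psf_sigma`,
#'   `camera_baseline`.
#' @export
render_movie <- function(traces, psf_sigma = 1.2, field_size = c(64, 64),
                         positions = NULL, min_spacing = 4 * psf_sigma,
                         camera_baseline = 10, noise_sd = 0) {
  traces <- as.matrix(traces)
  n <- nrow(traces); nf <- ncol(traces)
  if (is.null(positions)) {
    positions <- place_spots(n, field_size, max(min_spacing, 4 * psf_sigma))
  } else {
    positions <- as.matrix(positions)
    if (nrow(positions) != n) stop("one position per trace row is required")
    if (n > 1) {
      dmin <- min(stats::dist(positions))
      if (dmin < 4 * psf_sigma)
        stop(sprintf("spot positions closer than 4*psf_sigma (%.1f px)",
                     4 * psf_sigma))
    }
  }
  ny <- field_size[1L]; nx <- field_size[2L]
  kern <- lapply(seq_len(n), function(i)
    spot_kernel(positions[i, ], field_size, psf_sigma))
  frames <- array(camera_baseline, dim = c(ny, nx, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(camera_baseline, ny, nx)
    for (i in seq_len(n)) fr <- fr + traces[i, f] * kern[[i]]
    if (noise_sd > 0) fr <- fr + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    frames[, , f] <- fr
  }
  structure(list(frames = frames, positions = positions,
                 psf_sigma = psf_sigma, camera_baseline = camera_baseline),
            class = "sv_movie")
}

# Local maxima of a mean image above a noise-scaled threshold.
find_spots <- function(mean_img, threshold_k = 5) {
  ny <- nrow(mean_img); nx <- ncol(mean_img)
  bg <- stats::median(mean_img)
  noise <- stats::mad(mean_img)
  thr <- bg + threshold_k * max(noise, .Machine$double.eps)
  hits <- NULL
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
    v <- mean_img[y, x]
    if (v > thr && v == max(mean_img[(y - 1):(y + 1), (x - 1):(x + 1)]))
      hits <- rbind(hits, c(x, y))
  }
  if (is.null(hits)) hits <- matrix(numeric(0), ncol = 2)
  colnames(hits) <- c("x", "y")
  hits
}

#' Extract per-spot intensity traces from a movie
#'
#' Per-spot intensity is the background-subtracted sum over a fixed-radius
#' circular aperture centered on the spot; the background is the camera
#' baseline estimated per frame as the median of pixels outside all
#' apertures. Spots whose apertures overlap are flagged and excluded from
#' the returned traces.
#'
#' @param movie An `"sv_movie"`, or a `ny x nx x n_frames` array.
#' @param positions Optional `n x 2` (x, y) spot centers; detected on the
#'   mean image via local-maximum finding when `NULL`.
#' @param aperture_radius Aperture radius in pixels.
#' @return List with `traces` (matrix, one row per kept spot), `positions`
#'   (kept spots), `excluded` (indices of overlapping spots).
#' @export
extract_traces <- function(movie, positions = NULL, aperture_radius = NULL) {
  frames <- if (inherits(movie, "sv_movie")) movie$frames else movie
  psf <- if (inherits(movie, "sv_movie")) movie$psf_sigma else 1.2
  if (is.null(aperture_radius)) aperture_radius <- 3 * psf
  ny <- dim(frames)[1L]; nx <- dim(frames)[2L]; nf <- dim(frames)[3L]
  if (is.null(positions)) {
    mean_img <- apply(frames, c(1, 2), mean)
    positions <- find_spots(mean_img)
  }
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 0L)
    return(list(traces = matrix(numeric(0), nrow = 0, ncol = nf),
                positions = positions, excluded = integer(0)))

  excluded <- integer(0)
  if (n > 1) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    excluded <- as.integer(which(apply(d < 2 * aperture_radius, 1L, any)))
  }
  keep <- setdiff(seq_len(n), excluded)

  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  masks <- lapply(keep, function(i) {
    (xs - positions[i, 1L])^2 + (ys - positions[i, 2L])^2 <= aperture_radius^2
  })
  in_any <- Reduce(`|`, masks, matrix(FALSE, ny, nx))

  traces <- matrix(NA_real_, nrow = length(keep), ncol = nf)
  for (f in seq_len(nf)) {
    fr <- frames[, , f]
    bg <- stats::median(fr[!in_any])
    for (j in seq_along(masks))
      traces[j, f] <- sum(fr[masks[[j]]]) - bg * sum(masks[[j]])
  }
  list(traces = traces, positions = positions[keep, , drop = FALSE],
       excluded = excluded)
}
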