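# 2D-gel Y-arc quantification: a parametric lane conformed to the arc of
# branched replication intermediates, sampled into an ordered intensity
# histogram, loading-normalized by the 1N spot.

#' Parametric arc model over a gel image
#'
#' A smooth curve (natural cubic spline through the control points,
#' chord-length parametrized) resampled at `n_points` arc-length-uniform
#' positions, with a cross-sectional lane width. Control points are ordered
#' from the small-Y to the large-Y end of the arc.
#'
#' @param control_points Numeric matrix (`>= 3` rows) of `(x, y)` image
#'   coordinates in pixels (x = column, y = row, 1-based).
#' @param lane_width_px Cross-sectional integration width in pixels
#'   (default 7).
#' @param n_points Number of sampling positions along the arc
#'   (default 450).
#' @return An object of class `arc_model` with the spline functions, total
#'   `arc_length` and an arc-length inversion table.
#' @export
arc_model <- function(control_points, lane_width_px = 7, n_points = 450) {
  cp <- as.matrix(control_points)
  if (nrow(cp) < 3) stop("need >= 3 control points", call. = FALSE)
  chord <- sqrt(diff(cp[, 1])^2 + diff(cp[, 2])^2)
  if (any(chord == 0)) stop("repeated control points", call. = FALSE)
  t_knot <- c(0, cumsum(chord))
  fx <- stats::splinefun(t_knot, cp[, 1], method = "natural")
  fy <- stats::splinefun(t_knot, cp[, 2], method = "natural")
  t_dense <- seq(0, max(t_knot), length.out = 200 * nrow(cp))
  seg <- sqrt(diff(fx(t_dense))^2 + diff(fy(t_dense))^2)
  s_dense <- c(0, cumsum(seg))
  structure(list(control_points = cp, lane_width_px = lane_width_px,
                 n_points = n_points, fx = fx, fy = fy,
                 t_dense = t_dense, s_dense = s_dense,
                 arc_length = max(s_dense)),
            class = "arc_model")
}

# n arc-length-uniform positions with unit tangents.
arc_points <- function(arc, n = arc$n_points) {
  s <- seq(0, arc$arc_length, length.out = n)
  t <- stats::approx(arc$s_dense, arc$t_dense, s, ties = "ordered")$y
  dx <- arc$fx(t, deriv = 1); dy <- arc$fy(t, deriv = 1)
  nrm <- sqrt(dx^2 + dy^2)
  data.frame(s = s, x = arc$fx(t), y = arc$fy(t),
             tx = dx / nrm, ty = dy / nrm)
}

bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 1 | x > nc | y < 1 | y > nr))
    stop("sampling position outside image bounds", call. = FALSE)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  dx <- x - x0; dy <- y - y0
  img[cbind(y0, x0)] * (1 - dx) * (1 - dy) +
    img[cbind(y0, x0 + 1L)] * dx * (1 - dy) +
    img[cbind(y0 + 1L, x0)] * (1 - dx) * dy +
    img[cbind(y0 + 1L, x0 + 1L)] * dx * dy
}

#' Sample intensity along the arc
#'
#' At each of the arc's `n_points` arc-length-uniform positions, intensity
#' is the sum of bilinearly interpolated image values along the local normal
#' segment of `lane_width_px`, at 1-px steps. Deterministic.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param arc An [arc_model()].
#' @return An `arc_profile`: list with `intensities` (length `n_points`)
#'   and `loading_1n` (`NA` until set, see [quantify_1n_spot()]).
#' @export
sample_arc <- function(image, arc) {
  pts <- arc_points(arc)
  w <- max(1L, round(arc$lane_width_px))
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, by = 1)
  intensities <- vapply(seq_len(nrow(pts)), function(k) {
    nx <- -pts$ty[k]; ny <- pts$tx[k]
    sum(bilinear(image, pts$x[k] + offs * nx, pts$y[k] + offs * ny))
  }, numeric(1))
  arc_profile(intensities)
}

#' Construct an arc profile
#' @param intensities Ordered intensity vector along the arc.
#' @param loading_1n 1N-spot loading value (positive scalar or `NA`).
#' @export
arc_profile <- function(intensities, loading_1n = NA_real_) {
  structure(list(intensities = as.numeric(intensities),
                 loading_1n = loading_1n,
                 n_points = length(intensities)),
            class = "arc_profile")
}

#' Quantify the 1N spot (loading control)
#'
#' Sum of intensities inside the spot rectangle minus the local background,
#' estimated as the median of a surrounding frame times the spot area.
#'
#' @param image Numeric matrix.
#' @param spot_region Integer rectangle `c(x0, x1, y0, y1)` (inclusive
#'   pixel bounds).
#' @param frame_px Width of the surrounding background frame (default 3).
#' @return Background-corrected spot integral (scalar).
#' @export
quantify_1n_spot <- function(image, spot_region, frame_px = 3) {
  r <- round(spot_region)
  x0 <- r[1]; x1 <- r[2]; y0 <- r[3]; y1 <- r[4]
  if (x0 > x1 || y0 > y1) return(0)
  if (x0 < 1 || y0 < 1 || x1 > ncol(image) || y1 > nrow(image))
    stop("spot region outside image bounds", call. = FALSE)
  inner <- image[y0:y1, x0:x1, drop = FALSE]
  fx0 <- max(1, x0 - frame_px); fx1 <- min(ncol(image), x1 + frame_px)
  fy0 <- max(1, y0 - frame_px); fy1 <- min(nrow(image), y1 + frame_px)
  outer_block <- image[fy0:fy1, fx0:fx1, drop = FALSE]
  in_mask <- matrix(FALSE, nrow(outer_block), ncol(outer_block))
  in_mask[(y0 - fy0 + 1):(y1 - fy0 + 1), (x0 - fx0 + 1):(x1 - fx0 + 1)] <- TRUE
  frame_vals <- outer_block[!in_mask]
  bg <- if (length(frame_vals)) stats::median(frame_vals) else 0
  sum(inner) - bg * length(inner)
}

#' Between-condition Y-arc ratio profile
#'
#' Loading-normalized per-point ratios
#' `(a_i / loading_a) / (b_i / loading_b)` with a mean and sd summary over
#' an index range. Points where the normalized denominator falls below
#' `floor_frac` of its maximum are masked from the summary (ratios against
#' background are meaningless).
#'
#' @param profile_a,profile_b `arc_profile`s of equal `n_points` with
#'   positive `loading_1n`.
#' @param index_range Integer range of profile indices summarized
#'   (default all).
#' @param floor_frac Masking floor as a fraction of the normalized
#'   denominator's maximum (default 0.05).
#' @return List with `ratio` (length `n_points`, `NA` where masked),
#'   `masked`, `mean`, `sd`, `index_range`.
#' @export
ratio_profile <- function(profile_a, profile_b, index_range = NULL,
                          floor_frac = 0.05) {
  if (profile_a$n_points != profile_b$n_points)
    stop("profiles have different n_points", call. = FALSE)
  if (!isTRUE(profile_a$loading_1n > 0) || !isTRUE(profile_b$loading_1n > 0))
    stop("loading values must be positive", call. = FALSE)
  if (is.null(index_range)) index_range <- c(1L, profile_a$n_points)
  a <- profile_a$intensities / profile_a$loading_1n
  b <- profile_b$intensities / profile_b$loading_1n
  masked <- b < floor_frac * max(b)
  ratio <- ifelse(masked, NA_real_, a / b)
  idx <- seq(index_range[1], index_range[2])
  kept <- idx[!masked[idx]]
  if (!length(kept))
    stop("all points masked in index range: summary undefined",
         call. = FALSE)
  list(ratio = ratio, masked = masked,
       mean = mean(ratio[kept]), sd = stats::sd(ratio[kept]),
       index_range = index_range)
}

#' Write an arc profile or ratio profile as delimited text
#' @param profile An `arc_profile` or the list returned by
#'   [ratio_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- if (inherits(profile, "arc_profile")) {
    data.frame(index = seq_len(profile$n_points),
               intensity = profile$intensities)
  } else {
    data.frame(index = seq_along(profile$ratio), ratio = profile$ratio)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
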