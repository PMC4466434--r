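# Differential ChIP-Seq arithmetic: depth scaling, subtraction
# normalizations, per-region quantification, the two-zone oriC-aware
# background model, and strict fold-over-background peak calling.

#' Scale coverage tracks to a common mean depth
#'
#' Each track is multiplied by `target_mean / mean(track)`. Subtraction
#' normalizations are depth-sensitive, so tracks are brought to a common
#' depth first; disable (for strict replication of equal-depth designs) by
#' simply not calling this step.
#'
#' @param tracks List of [coverage_track()]s.
#' @param target_mean Common mean after scaling; defaults to the mean of the
#'   input track means.
#' @return List of rescaled tracks.
#' @export
scale_to_common_depth <- function(tracks, target_mean = NULL) {
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  means <- vapply(tracks, function(t) mean(t$values), numeric(1))
  if (any(means <= 0))
    stop("cannot depth-scale a track with nonpositive total signal",
         call. = FALSE)
  if (is.null(target_mean)) target_mean <- mean(means)
  lapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    t$values <- t$values * (target_mean / means[i])
    t
  })
}

subtract_tracks <- function(a, b, label) {
  if (!same_genome(a, b))
    stop("tracks are on different genomes", call. = FALSE)
  coverage_track(a$values - b$values, a$genome, role = a$role,
                 condition = a$condition, label = label)
}

#' Input-normalize a ChIP track
#'
#' Per-base subtraction of the input (total DNA) signal from the IP signal;
#' negatives are retained.
#'
#' @param ip,input [coverage_track()]s on the same genome.
#' @return A [coverage_track()] of the difference.
#' @export
normalize_chip <- function(ip, input) {
  subtract_tracks(ip, input, label = paste0(ip$label, "-input"))
}

#' Subtract mock-IP (nonspecific) signal
#'
#' Both arguments must already be input-normalized; the mock difference
#' removes antibody stickiness shared between the specific and mock IPs.
#'
#' @param norm_ip,norm_mock Input-normalized [coverage_track()]s.
#' @return A [coverage_track()].
#' @export
mock_correct <- function(norm_ip, norm_mock) {
  subtract_tracks(norm_ip, norm_mock,
                  label = paste0(norm_ip$label, "-mock"))
}

#' Between-condition differential signal
#'
#' Subtracts the helicase-present normalized signal from the
#' helicase-depleted normalized signal at each base, so positive values mark
#' positions where replisome occupancy increases upon depletion.
#'
#' @param norm_depleted Normalized track for the depleted condition.
#' @param norm_present Normalized track for the unperturbed condition.
#' @return A [coverage_track()] with `condition = "depleted-minus-present"`.
#' @export
differential <- function(norm_depleted, norm_present) {
  out <- subtract_tracks(norm_depleted, norm_present, label = "differential")
  out$condition <- "depleted-minus-present"
  out
}

region_values <- function(track, region) {
  L <- track$genome$length_bp
  len <- region$end - region$start
  idx <- (seq(region$start, length.out = len) %% L) + 1
  track$values[idx]
}

#' Quantify signal over genes and intergenic regions
#'
#' For each region: maximum signal, mean signal, area under the curve (sum
#' of per-base values) and length-normalized AUC, plus the head-on /
#' co-directional orientation. Values are computed on the raw (possibly
#' negative) signal without clamping.
#'
#' @param track A [coverage_track()].
#' @param regions Region table ([gene_regions()]).
#' @param genome Genome (defaults to the track's genome).
#' @param force_midpoint Passed to [classify_orientation()].
#' @return A `data.frame` with one row per region: `id`, `start`, `end`,
#'   `strand`, `kind`, `length`, `orientation`, `max_signal`, `mean_signal`,
#'   `auc`, `nauc`.
#' @export
quantify_regions <- function(track, regions, genome = track$genome,
                             force_midpoint = FALSE) {
  stopifnot_genome(genome)
  len <- regions$end - regions$start
  if (any(len < 1)) stop("zero-length region", call. = FALSE)
  L <- genome$length_bp
  v <- track$values
  mx <- numeric(nrow(regions)); auc <- numeric(nrow(regions))
  for (k in seq_len(nrow(regions))) {
    idx <- (seq(regions$start[k], length.out = len[k]) %% L) + 1
    rv <- v[idx]
    mx[k] <- max(rv)
    auc[k] <- sum(rv)
  }
  data.frame(
    id = regions$id, start = regions$start, end = regions$end,
    strand = regions$strand, kind = regions$kind, length = len,
    orientation = classify_orientation(regions, genome, force_midpoint),
    max_signal = mx, mean_signal = auc / len, auc = auc, nauc = auc / len,
    stringsAsFactors = FALSE)
}

# Tile each replichore into windows of window_bp by fork travel distance.
zone_windows <- function(genome, window_bp, proximal_bp) {
  arcs <- replichore_lengths(genome)
  L <- genome$length_bp
  out <- list()
  for (side in c("right", "left")) {
    alen <- arcs[[side]]
    n_win <- max(1L, ceiling(alen / window_bp))
    d0 <- (seq_len(n_win) - 1) * window_bp
    d1 <- pmin(d0 + window_bp, alen)
    # genomic coordinates of the window (start inclusive, end exclusive)
    if (side == "right") {
      gs <- (genome$ori_bp + d0) %% L
      ge <- gs + (d1 - d0)
    } else {
      gs <- (genome$ori_bp - d1) %% L
      ge <- gs + (d1 - d0)
    }
    out[[side]] <- data.frame(
      replichore = side, d_start = d0, d_end = d1, start = gs, end = ge)
  }
  win <- rbind(out$right, out$left)
  dmid <- (win$d_start + win$d_end) / 2
  win$zone <- ifelse(dmid < proximal_bp, "proximal", "distal")
  win$window_id <- seq_len(nrow(win))
  win
}

#' Two-zone background estimation from peak-free windows
#'
#' Background is estimated independently for the ori-proximal zone (fork
#' travel distance < `proximal_bp`, where the copy-number gradient raises
#' the baseline) and the distal zone. Each replichore is tiled into
#' `window_bp` windows; per zone, the procedure iterates: initialize the
#' zone background as the median of per-window signal maxima, flag windows
#' whose maximum exceeds `threshold` times the current background as
#' peak-bearing, recompute the background as the mean of the maxima over
#' unflagged (peak-free) windows, and repeat until the flagged set is
#' stable.
#'
#' @param track A [coverage_track()].
#' @param genome Genome (defaults to the track's).
#' @param window_bp Window size in bp (default 100000).
#' @param proximal_bp Extent of the ori-proximal zone (default 300000).
#' @param threshold Peak flagging fold threshold (default 5).
#' @param max_iter Iteration cap (default 25).
#' @return An object of class `background_model`: `proximal_bg`,
#'   `distal_bg`, `window_bp`, `proximal_bp`, `threshold`, `windows` (the
#'   window table with maxima and flags), `iterations`.
#' @export
estimate_background <- function(track, genome = track$genome,
                                window_bp = 100000, proximal_bp = 300000,
                                threshold = 5, max_iter = 25) {
  stopifnot_genome(genome)
  if (genome$length_bp < 2 * window_bp)
    stop("genome shorter than two windows", call. = FALSE)
  win <- zone_windows(genome, window_bp, proximal_bp)
  L <- genome$length_bp
  win$max <- vapply(seq_len(nrow(win)), function(k) {
    len <- win$end[k] - win$start[k]
    idx <- (seq(win$start[k], length.out = len) %% L) + 1
    max(track$values[idx])
  }, numeric(1))
  win$flagged <- FALSE
  bgs <- c(proximal = NA_real_, distal = NA_real_)
  iters <- c(proximal = 0L, distal = 0L)
  for (zone in c("proximal", "distal")) {
    zi <- win$zone == zone
    if (!any(zi))
      stop("background estimation failed: the ", zone,
           " zone contains no windows (check proximal_bp against the ",
           "replichore lengths)", call. = FALSE)
    wmax <- win$max[zi]
    bg <- stats::median(wmax)
    flagged <- rep(FALSE, length(wmax))
    for (it in seq_len(max_iter)) {
      new_flagged <- wmax > threshold * bg
      if (all(new_flagged))
        stop("background estimation failed: no peak-free ", zone,
             " windows (all ", length(wmax), " windows exceed ", threshold,
             "x the running background)", call. = FALSE)
      bg <- mean(wmax[!new_flagged])
      iters[zone] <- it
      if (identical(new_flagged, flagged)) break
      flagged <- new_flagged
    }
    win$flagged[zi] <- flagged
    bgs[zone] <- bg
  }
  structure(list(proximal_bg = bgs[["proximal"]],
                 distal_bg = bgs[["distal"]],
                 window_bp = window_bp, proximal_bp = proximal_bp,
                 threshold = threshold, windows = win,
                 iterations = iters),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model: proximal=%.4g (%d/%d peak-free), distal=%.4g (%d/%d peak-free), window=%d bp>\n",
    x$proximal_bg,
    sum(!x$windows$flagged & x$windows$zone == "proximal"),
    sum(x$windows$zone == "proximal"),
    x$distal_bg,
    sum(!x$windows$flagged & x$windows$zone == "distal"),
    sum(x$windows$zone == "distal"),
    as.integer(x$window_bp)))
  invisible(x)
}

#' Call peak-containing regions by fold over zone background
#'
#' A region is peak-containing when its maximum signal exceeds `threshold`
#' times the background of its zone (strict inequality). Zone membership is
#' by the region midpoint's fork travel distance.
#'
#' @param quants Region quantification table from [quantify_regions()].
#' @param background A `background_model` from [estimate_background()].
#' @param genome The genome the quantification was computed on.
#' @param threshold Fold threshold (default 5).
#' @return `quants` with added columns `zone`, `fold_over_background`,
#'   `called`.
#' @export
call_peaks <- function(quants, background, genome, threshold = 5) {
  stopifnot_genome(genome)
  if (background$proximal_bg <= 0 || background$distal_bg <= 0)
    stop("nonpositive background; cannot compute folds", call. = FALSE)
  mid <- floor(region_midpoints(quants, genome))
  d <- distance_from_ori(mid, genome)
  zone <- ifelse(d < background$proximal_bp, "proximal", "distal")
  bg <- ifelse(zone == "proximal", background$proximal_bg,
               background$distal_bg)
  quants$zone <- zone
  quants$fold_over_background <- quants$max_signal / bg
  quants$called <- quants$fold_over_background > threshold
  quants
}

#' Association vectors and their Pearson correlation
#'
#' `association_vector` extracts one quantification column as a named
#' vector in locus order; `correlate` is the Pearson product-moment
#' correlation between two such vectors over the same ordered locus set.
#'
#' @param quants Quantification table.
#' @param value Column to extract (default `"max_signal"`).
#' @return Named numeric vector.
#' @export
association_vector <- function(quants, value = "max_signal") {
  stats::setNames(quants[[value]], quants$id)
}

#' @rdname association_vector
#' @param vec_a,vec_b Equal-length numeric vectors, `n >= 3`.
#' @export
correlate <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b))
    stop("vectors must have equal length", call. = FALSE)
  if (length(vec_a) < 3)
    stop("need at least 3 paired loci", call. = FALSE)
  if (stats::sd(vec_a) == 0 || stats::sd(vec_b) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(vec_a, vec_b)
}

#' Write a region quantification / peak table
#'
#' Tab-delimited with a `#`-prefixed header naming the package version and
#' the calling parameters.
#'
#' @param table Data frame (from [quantify_regions()] / [call_peaks()]).
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @export
write_region_table <- function(table, path, params = list()) {
  hdr <- sprintf("# repliconflict %s | %s",
                 as.character(utils::packageVersion("repliconflict")),
                 paste(names(params), unlist(params), sep = "=",
                       collapse = " "))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  suppressWarnings(utils::write.table(
    table, path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  invisible(path)
}

#' Read a region table written by [write_region_table()]
#' @param path Table path.
#' @export
read_region_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
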