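# Seeded generative models for every input the pipeline consumes:
# ChIP/input/mock coverage with the coverage structure of exponentially
# growing cells, qPCR Ct tables, and 2D-gel images.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a named substream seed from a master seed; stays below 2^31.
substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

#' Define a ChIP-Seq simulation scenario
#'
#' The generative model has four layers: (i) a marker-frequency copy-number
#' gradient `R^(1 - d/d_max)` from ori to ter (exponentially growing cells
#' replicate ori-proximal DNA more often); (ii) transcription-dependent
#' stalling enrichment inside listed genes, scaled by a condition multiplier
#' when the accessory helicase is depleted; (iii) nonspecific mock-IP
#' stickiness; (iv) multinomial sampling of sonication-sized fragments.
#'
#' @param genome A [circular_genome()].
#' @param annotation Region table ([gene_regions()]).
#' @param ori_ter_ratio Copy number at ori relative to ter, `R >= 1`
#'   (default 2, the marker-frequency ratio of one overlapping round of
#'   replication).
#' @param stall_table `data.frame(id, strength, shape)` with
#'   `strength >= 0` and `shape` in `"uniform"`, `"three_prime_ramp"`; ids
#'   must exist in `annotation`. `NULL` for a stall-free scenario.
#' @param condition_multiplier Factor applied to stall strengths under
#'   helicase depletion (default 3: depletion roughly triples replisome
#'   dwell at a strong head-on reporter).
#' @param mock_sticky `data.frame(start, end, stickiness)` of nonspecific
#'   sticky intervals seen by mock IPs (and IPs), or `NULL`.
#' @param fragment_len_mean,fragment_len_sd Lognormal fragment length
#'   moments on the bp scale (defaults 250 and 100, sonication-like).
#' @param n_fragments Fragments per sample (default 750000, typical
#'   per-sample depth of a bacterial ChIP-Seq run).
#' @param seed Master seed for the scenario.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(genome, annotation,
                                ori_ter_ratio = 2,
                                stall_table = NULL,
                                condition_multiplier = 3,
                                mock_sticky = NULL,
                                fragment_len_mean = 250,
                                fragment_len_sd = 100,
                                n_fragments = 750000,
                                seed = 1) {
  stopifnot_genome(genome)
  if (ori_ter_ratio < 1) stop("ori_ter_ratio must be >= 1", call. = FALSE)
  if (n_fragments < 0) stop("n_fragments must be >= 0", call. = FALSE)
  if (!is.null(stall_table)) {
    if (!all(c("id", "strength", "shape") %in% names(stall_table)))
      stop("stall_table needs columns id, strength, shape", call. = FALSE)
    if (any(!is.finite(stall_table$strength)) || any(stall_table$strength < 0))
      stop("stall strengths must be finite and >= 0", call. = FALSE)
    if (!all(stall_table$shape %in% c("uniform", "three_prime_ramp")))
      stop("shape must be 'uniform' or 'three_prime_ramp'", call. = FALSE)
    missing_ids <- setdiff(stall_table$id, annotation$id)
    if (length(missing_ids))
      stop("stall_table ids absent from annotation: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  structure(list(genome = genome, annotation = annotation,
                 ori_ter_ratio = ori_ter_ratio, stall_table = stall_table,
                 condition_multiplier = condition_multiplier,
                 mock_sticky = mock_sticky,
                 fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd,
                 n_fragments = n_fragments, seed = seed),
            class = "simulation_scenario")
}

#' Relative copy number under the ori-to-ter gradient
#'
#' `R^(1 - d/d_max)` where `d` is the fork travel distance to the position
#' and `d_max` the length of its replichore; ranges from `R` at ori to 1 at
#' ter.
#'
#' @param position Coordinate vector.
#' @param scenario A [simulation_scenario()].
#' @return Relative copy number in `[1, R]`.
#' @export
copy_number_baseline <- function(position, scenario) {
  g <- scenario$genome
  arcs <- replichore_lengths(g)
  d <- distance_from_ori(position, g)
  side <- replichore_of(position, g)
  dmax <- ifelse(side == "right", arcs[["right"]], arcs[["left"]])
  scenario$ori_ter_ratio ^ (1 - d / dmax)
}

# Full-genome baseline vector (per-base copy number).
baseline_vector <- function(scenario) {
  copy_number_baseline(seq_len(scenario$genome$length_bp) - 1, scenario)
}

#' Per-base stalling enrichment profile
#'
#' `e(x) = 1` outside listed genes; inside gene `g`,
#' `e(x) = 1 + s_g * m * w(x)` where `m` is the condition multiplier (1 when
#' the helicase is present) and `w` the shape weight: `uniform` gives 1
#' everywhere; `three_prime_ramp` rises linearly from ~0 at the
#' transcription start to ~2 at the 3' end (mean exactly 1), the within-gene
#' shape of signal piling up where forks penetrate a head-on gene.
#' Overlapping listed genes contribute additively on the `e - 1` scale.
#'
#' @param scenario A [simulation_scenario()].
#' @param condition `"helicase_present"` or `"helicase_depleted"`.
#' @return Numeric vector of length L, all values `>= 1`.
#' @export
stall_enrichment_profile <- function(scenario,
    condition = c("helicase_present", "helicase_depleted")) {
  condition <- match.arg(condition)
  L <- scenario$genome$length_bp
  e <- rep(1, L)
  st <- scenario$stall_table
  if (is.null(st) || nrow(st) == 0L) return(e)
  m <- if (condition == "helicase_depleted") scenario$condition_multiplier
       else 1
  ann <- scenario$annotation
  for (k in seq_len(nrow(st))) {
    row <- ann[ann$id == st$id[k], , drop = FALSE][1, ]
    len <- row$end - row$start
    idx <- (seq(row$start, length.out = len) %% L) + 1
    w <- if (st$shape[k] == "uniform") rep(1, len) else {
      if (!row$strand %in% c("+", "-"))
        stop("three_prime_ramp requires a stranded gene: ", row$id,
             call. = FALSE)
      ramp <- 2 * (seq_len(len) - 0.5) / len   # mean exactly 1
      if (row$strand == "+") ramp else rev(ramp)
    }
    e[idx] <- e[idx] + st$strength[k] * m * w
  }
  e
}

# Nonspecific stickiness vector (0 outside sticky intervals).
sticky_vector <- function(scenario) {
  L <- scenario$genome$length_bp
  s <- numeric(L)
  ms <- scenario$mock_sticky
  if (is.null(ms) || nrow(ms) == 0L) return(s)
  for (k in seq_len(nrow(ms))) {
    len <- ms$end[k] - ms$start[k]
    idx <- (seq(ms$start[k], length.out = len) %% L) + 1
    s[idx] <- s[idx] + ms$stickiness[k]
  }
  s
}

lognormal_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one ChIP-Seq sample
#'
#' Fragment midpoints are drawn with probability proportional to
#' `baseline(x) * f(x)`, where `f` is the stalling enrichment for `"ip"`
#' samples, 1 for `"input"`, and `1 + stickiness(x)` for `"mock"` (mock IPs
#' also see sticky intervals but never the specific stalling signal, and IP
#' samples see both). Fragment lengths are lognormal, truncated at 1 bp;
#' intervals wrap the circle. Identical `(scenario, role, condition, seed)`
#' gives bit-identical output.
#'
#' @param scenario A [simulation_scenario()].
#' @param role `"ip"`, `"input"` or `"mock"`.
#' @param condition `"helicase_present"` or `"helicase_depleted"`.
#' @param seed Sample seed; defaults to a named substream of the scenario
#'   seed.
#' @return List with `fragments` (`data.frame(start, end)`) and `track`
#'   (a [coverage_track()]).
#' @export
simulate_chip_sample <- function(scenario,
    role = c("ip", "input", "mock"),
    condition = c("helicase_present", "helicase_depleted"),
    seed = NULL) {
  role <- match.arg(role)
  condition <- match.arg(condition)
  if (is.null(seed))
    seed <- substream_seed(scenario$seed, paste(role, condition))
  L <- scenario$genome$length_bp
  n <- scenario$n_fragments
  if (n == 0L) {
    frags <- data.frame(start = numeric(0), end = numeric(0))
    return(list(fragments = frags,
                track = pileup(frags, scenario$genome, role = role,
                               condition = condition)))
  }
  w <- baseline_vector(scenario)
  f <- switch(role,
    ip = stall_enrichment_profile(scenario, condition) *
         (1 + sticky_vector(scenario)),
    input = 1,
    mock = 1 + sticky_vector(scenario))
  w <- w * f
  if (all(w <= 0))
    stop("degenerate sampling weights: all probability mass zero",
         call. = FALSE)
  lp <- lognormal_params(scenario$fragment_len_mean, scenario$fragment_len_sd)
  frags <- with_seed(seed, {
    mid <- sample.int(L, n, replace = TRUE, prob = w) - 1L
    len <- pmax(1, round(stats::rlnorm(n, lp$meanlog, lp$sdlog)))
    len <- pmin(len, L)
    start <- (mid - len %/% 2) %% L
    data.frame(start = start, end = start + len)
  })
  list(fragments = frags,
       track = pileup(frags, scenario$genome, role = role,
                      condition = condition,
                      label = paste(role, condition, sep = "_")))
}

#' Design and simulate a qPCR plate
#'
#' `qpcr_design` fixes the ground truth: per-locus amplification efficiency
#' `E` and true relative template abundances per (locus, fraction).
#' `simulate_qpcr` inverts the amplification law:
#' `Ct = -log_E(abundance) + per-fraction offset + N(0, ct_noise_sd)`.
#' The per-fraction offsets model arbitrary template loading and cancel in
#' the double-ratio enrichment statistic.
#'
#' @param abundances `data.frame(locus, fraction, abundance)`, all
#'   abundances `> 0`; `fraction` is typically `"chip"` / `"input"`.
#' @param efficiency Single value or named per-locus vector in `(1, 2]`.
#' @param ct_noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param seed Seed for the noise draws.
#' @return `qpcr_design` returns an object of class `qpcr_design`;
#'   `simulate_qpcr` returns a `data.frame(locus, fraction, ct)`.
#' @export
qpcr_design <- function(abundances, efficiency = 2, ct_noise_sd = 0,
                        seed = 1) {
  if (any(abundances$abundance <= 0))
    stop("abundances must be positive", call. = FALSE)
  if (any(efficiency <= 1 | efficiency > 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  structure(list(abundances = abundances, efficiency = efficiency,
                 ct_noise_sd = ct_noise_sd, seed = seed),
            class = "qpcr_design")
}

#' @rdname qpcr_design
#' @param design A `qpcr_design`.
#' @export
simulate_qpcr <- function(design) {
  ab <- design$abundances
  E <- design$efficiency
  Elocus <- if (length(E) == 1L) rep(E, nrow(ab)) else E[ab$locus]
  fracs <- unique(ab$fraction)
  with_seed(design$seed, {
    offset <- stats::setNames(stats::runif(length(fracs), 18, 24), fracs)
    ct <- -log(ab$abundance) / log(Elocus) + offset[ab$fraction] +
      stats::rnorm(nrow(ab), 0, design$ct_noise_sd)
    data.frame(locus = ab$locus, fraction = ab$fraction, ct = ct,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a 2D-gel image
#'
#' Renders a Gaussian ridge along a parametric arc with per-point
#' amplitudes, plus an isotropic 2D Gaussian 1N spot of given integral,
#' plus Gaussian pixel noise. The ridge is built from closely spaced
#' isotropic kernels so that a cross-sectional integral at any arc position
#' is proportional to the local amplitude.
#'
#' @param arc An [arc_model()].
#' @param amplitude_profile Numeric vector of length `arc$n_points`.
#' @param spot_1n Integral of the 1N spot (loading control), `>= 0`.
#' @param noise_sd Gaussian pixel noise sd.
#' @param seed Seed for the noise.
#' @param dim Image dimensions `c(nrow, ncol)` in pixels.
#' @param spot_center 1N spot center `c(x, y)` in pixels.
#' @param spot_sd 1N spot Gaussian sd in pixels (default 3).
#' @param ridge_sd Ridge cross-sectional sd in pixels (default
#'   `arc$lane_width_px / 4`).
#' @return Numeric matrix (`dim[1]` rows = y, `dim[2]` cols = x).
#' @export
simulate_gel_image <- function(arc, amplitude_profile, spot_1n = 0,
                               noise_sd = 0, seed = 1,
                               dim = c(256, 256),
                               spot_center = c(20, dim[1] - 20),
                               spot_sd = 3,
                               ridge_sd = arc$lane_width_px / 4) {
  if (length(amplitude_profile) != arc$n_points)
    stop("amplitude profile length must match arc n_points", call. = FALSE)
  img <- matrix(0, dim[1], dim[2])
  # dense arc positions at ~0.5 px spacing
  n_dense <- max(arc$n_points, ceiling(arc$arc_length / 0.5))
  dense <- arc_points(arc, n_dense)
  amp <- stats::approx(seq(0, 1, length.out = arc$n_points),
                       amplitude_profile,
                       seq(0, 1, length.out = n_dense))$y
  spacing <- arc$arc_length / (n_dense - 1)
  half <- ceiling(4 * ridge_sd)
  if (any(dense$x < half + 1) || any(dense$x > dim[2] - half) ||
      any(dense$y < half + 1) || any(dense$y > dim[1] - half))
    stop("arc exits image bounds after width expansion", call. = FALSE)
  off <- seq(-half, half)
  for (k in seq_len(n_dense)) {
    if (amp[k] == 0) next
    cx <- dense$x[k]; cy <- dense$y[k]
    xs <- round(cx) + off; ys <- round(cy) + off
    kx <- stats::dnorm(xs, cx, ridge_sd)
    ky <- stats::dnorm(ys, cy, ridge_sd)
    img[ys, xs] <- img[ys, xs] +
      (amp[k] * spacing) * outer(ky, kx)
  }
  if (spot_1n > 0) {
    half_s <- ceiling(5 * spot_sd)
    xs <- round(spot_center[1]) + seq(-half_s, half_s)
    ys <- round(spot_center[2]) + seq(-half_s, half_s)
    xs <- xs[xs >= 1 & xs <= dim[2]]; ys <- ys[ys >= 1 & ys <= dim[1]]
    kx <- stats::dnorm(xs, spot_center[1], spot_sd)
    ky <- stats::dnorm(ys, spot_center[2], spot_sd)
    img[ys, xs] <- img[ys, xs] + spot_1n * outer(ky, kx)
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed,
      matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img)))
  img
}

#' Write / read a 16-bit grayscale gel image
#'
#' Intensities are divided by `scale`, clamped to the 16-bit range and
#' written as 16-bit grayscale TIFF; read multiplies back.
#'
#' @param img Numeric matrix.
#' @param path TIFF path.
#' @param scale Intensity units per 16-bit full scale (default the image
#'   maximum, so the full dynamic range is used).
#' @export
write_gel_tiff <- function(img, path, scale = max(img, 1e-12)) {
  m <- pmin(pmax(img / scale, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_gel_tiff
#' @export
read_gel_tiff <- function(path, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * scale
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes of fixed length around the circle separated
#' by fixed gaps, assigning strands so that each gene is head-on with
#' probability `head_on_frac` (bacterial genomes are co-orientation biased;
#' about a quarter of genes head-on is typical for a Firmicute). Seeded and
#' deterministic.
#'
#' @param genome A [circular_genome()].
#' @param n_genes Number of genes.
#' @param gene_len Gene length in bp (default 1000).
#' @param gap Intergenic gap between consecutive genes in bp (default 200).
#' @param head_on_frac Probability a gene is head-on (default 0.26).
#' @param seed Seed for the strand draws.
#' @return A region table ([gene_regions()]) with ids `g1, g2, ...`.
#' @export
synthetic_annotation <- function(genome, n_genes = 200, gene_len = 1000,
                                 gap = 200, head_on_frac = 0.26, seed = 1) {
  stopifnot_genome(genome)
  span <- n_genes * (gene_len + gap)
  if (span > genome$length_bp)
    stop("annotation does not fit on the genome", call. = FALSE)
  start <- (seq_len(n_genes) - 1) * (gene_len + gap)
  end <- start + gene_len
  mid <- floor((start + end) / 2)
  side <- replichore_of(mid, genome)
  co_strand <- ifelse(side == "right", "+", "-")   # co-directional strand
  ho_strand <- ifelse(side == "right", "-", "+")
  strand <- with_seed(seed, ifelse(
    stats::runif(n_genes) < head_on_frac, ho_strand, co_strand))
  gene_regions(paste0("g", seq_len(n_genes)), start, end, strand, "gene",
               genome)
}
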