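#' Circular bacterial chromosome geometry
#'
#' A `circular_genome` describes a circular chromosome replicated
#' bidirectionally from a single origin (*oriC*) toward a terminus (*ter*).
#' The two arcs between ori and ter are the replichores: the *right*
#' replichore is traversed from ori toward ter in the direction of increasing
#' coordinate, the *left* replichore is the complementary arc. All
#' coordinates are 0-based and reduced modulo the genome length; intervals
#' are half-open.
#'
#' @param length_bp Genome length in base pairs (positive integer).
#' @param ori_bp Coordinate of the replication origin (default 0).
#' @param ter_bp Coordinate of the terminus. Defaults to the antipode of
#'   `ori_bp`, which is approximately true for most bacterial chromosomes.
#' @param name Sequence name used in track output (default `"chr"`).
#'
#' @return An object of class `circular_genome` with fields `length_bp`,
#'   `ori_bp`, `ter_bp`, `name`.
#' @examples
#' g <- circular_genome(4e6, ori_bp = 0, ter_bp = 2e6)
#' distance_from_ori(3e6, g)  # 1e6, reached by the leftward fork
#' @export
circular_genome <- function(length_bp, ori_bp = 0, ter_bp = NULL,
                            name = "chr") {
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp < 2)
    stop("length_bp must be a single integer >= 2", call. = FALSE)
  length_bp <- as.integer(round(length_bp))
  ori_bp <- as.integer(round(ori_bp)) %% length_bp
  if (is.null(ter_bp)) ter_bp <- (ori_bp + length_bp %/% 2L) %% length_bp
  ter_bp <- as.integer(round(ter_bp)) %% length_bp
  if (ori_bp == ter_bp)
    stop("ori_bp and ter_bp must differ", call. = FALSE)
  structure(
    list(length_bp = length_bp, ori_bp = ori_bp, ter_bp = ter_bp,
         name = as.character(name)),
    class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome '%s': %s bp, ori=%s, ter=%s>\n",
              x$name, format(x$length_bp, big.mark = ","),
              format(x$ori_bp, big.mark = ","),
              format(x$ter_bp, big.mark = ",")))
  invisible(x)
}

stopifnot_genome <- function(genome) {
  if (!inherits(genome, "circular_genome"))
    stop("expected a circular_genome object", call. = FALSE)
}

check_positions <- function(position, genome) {
  if (any(!is.finite(position)) || any(position < 0) ||
      any(position >= genome$length_bp))
    stop("position out of range [0, L)", call. = FALSE)
}

# Lengths of the right (ori -> ter, increasing coordinate) and left arcs.
replichore_lengths <- function(genome) {
  right <- (genome$ter_bp - genome$ori_bp) %% genome$length_bp
  c(right = right, left = genome$length_bp - right)
}

#' Replichore membership of genomic positions
#'
#' @param position Vector of 0-based coordinates in `[0, L)`.
#' @param genome A [circular_genome()].
#' @return Character vector, `"right"` or `"left"`. The terminus itself is
#'   reported as `"right"` (the boundary position is reached by both forks).
#' @export
replichore_of <- function(position, genome) {
  stopifnot_genome(genome)
  check_positions(position, genome)
  arcs <- replichore_lengths(genome)
  offs <- (position - genome$ori_bp) %% genome$length_bp
  ifelse(offs <= arcs[["right"]], "right", "left")
}

#' Fork travel distance from the origin
#'
#' Number of base pairs a replication fork starting at *oriC* travels to
#' reach `position` along the replichore containing it.
#'
#' @inheritParams replichore_of
#' @return Numeric vector of distances in bp, each in
#'   `[0, max(replichore lengths)]`.
#' @export
distance_from_ori <- function(position, genome) {
  stopifnot_genome(genome)
  check_positions(position, genome)
  arcs <- replichore_lengths(genome)
  offs <- (position - genome$ori_bp) %% genome$length_bp
  ifelse(offs <= arcs[["right"]], offs, genome$length_bp - offs)
}

#' Construct a table of genomic regions
#'
#' Regions are genes or intergenic intervals on the circle, stored 0-based
#' half-open. A region may wrap the origin of the coordinate system, in
#' which case `end` exceeds the genome length (`end <= start + L`).
#'
#' @param id Character vector of region labels.
#' @param start,end 0-based half-open interval bounds; `end > start`.
#' @param strand One of `"+"`, `"-"`, `"none"` per region. Intergenic
#'   regions must have strand `"none"`.
#' @param kind `"gene"` or `"intergenic"`.
#' @param genome A [circular_genome()]; used to validate coordinates.
#' @return A `data.frame` with columns `id`, `start`, `end`, `strand`,
#'   `kind` and attribute-free plain storage.
#' @export
gene_regions <- function(id, start, end, strand = "+", kind = "gene",
                         genome = NULL) {
  n <- length(id)
  start <- as.numeric(start); end <- as.numeric(end)
  strand <- rep_len(as.character(strand), n)
  kind <- rep_len(as.character(kind), n)
  if (any(end - start < 1))
    stop("regions must have length >= 1", call. = FALSE)
  if (!all(strand %in% c("+", "-", "none")))
    stop("strand must be '+', '-' or 'none'", call. = FALSE)
  if (!all(kind %in% c("gene", "intergenic")))
    stop("kind must be 'gene' or 'intergenic'", call. = FALSE)
  if (any(kind == "intergenic" & strand != "none"))
    stop("intergenic regions must have strand 'none'", call. = FALSE)
  if (!is.null(genome)) {
    stopifnot_genome(genome)
    L <- genome$length_bp
    if (any(start < 0) || any(start >= L) || any(end > start + L))
      stop("region coordinates outside genome", call. = FALSE)
  }
  data.frame(id = as.character(id), start = start, end = end,
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

region_lengths <- function(regions) regions$end - regions$start

region_midpoints <- function(regions, genome) {
  (regions$start + (regions$end - regions$start) / 2) %% genome$length_bp
}

# TRUE where coordinate `coord` lies strictly inside the half-open region
# (a region starting exactly at ori/ter does not span it).
region_spans_coord <- function(regions, coord, genome) {
  L <- genome$length_bp
  off <- (coord - regions$start) %% L
  len <- regions$end - regions$start
  off > 0 & off < len
}

#' Head-on / co-directional classification of transcribed regions
#'
#' A gene is *co-directional* when RNA polymerase moves with the replication
#' fork of its replichore (leading-strand gene), *head-on* when it moves
#' against it (lagging-strand gene). On the right replichore the fork moves
#' in the direction of increasing coordinate, so `+`-strand genes there are
#' co-directional; on the left replichore the converse holds. Classification
#' uses the replichore containing the region midpoint. Regions with strand
#' `"none"`, or spanning *oriC* or *ter*, are `ambiguous` unless
#' `force_midpoint = TRUE`, in which case ori/ter-spanning stranded regions
#' are classified by their midpoint anyway.
#'
#' @param regions A region table from [gene_regions()] (or one row subset).
#' @param genome A [circular_genome()].
#' @param force_midpoint Classify ori/ter-spanning stranded regions by
#'   midpoint instead of returning `ambiguous` (default `FALSE`).
#' @return Character vector with values `"head_on"`, `"co_directional"`,
#'   `"ambiguous"`.
#' @export
classify_orientation <- function(regions, genome, force_midpoint = FALSE) {
  stopifnot_genome(genome)
  L <- genome$length_bp
  if (any(regions$start < 0) || any(regions$start >= L) ||
      any(regions$end > regions$start + L))
    stop("region coordinates outside genome", call. = FALSE)
  mid <- region_midpoints(regions, genome)
  side <- replichore_of(floor(mid), genome)
  cd <- (side == "right" & regions$strand == "+") |
        (side == "left"  & regions$strand == "-")
  out <- ifelse(cd, "co_directional", "head_on")
  spans <- region_spans_coord(regions, genome$ori_bp, genome) |
           region_spans_coord(regions, genome$ter_bp, genome)
  out[regions$strand == "none"] <- "ambiguous"
  if (!force_midpoint) out[spans & regions$strand != "none"] <- "ambiguous"
  out
}

#' Orientation census of an annotation
#'
#' Counts and fractions of head-on, co-directional and ambiguous regions,
#' the summary used to compare the co-orientation bias of genomes.
#'
#' @inheritParams classify_orientation
#' @return A list with `counts` and `fractions` (named numeric vectors over
#'   `head_on`, `co_directional`, `ambiguous`) and `n`.
#' @export
orientation_census <- function(regions, genome, force_midpoint = FALSE) {
  if (nrow(regions) == 0L)
    stop("orientation_census requires a nonempty region table", call. = FALSE)
  cls <- classify_orientation(regions, genome, force_midpoint)
  lev <- c("head_on", "co_directional", "ambiguous")
  counts <- vapply(lev, function(l) sum(cls == l), numeric(1))
  list(counts = counts, fractions = counts / nrow(regions),
       n = nrow(regions))
}
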