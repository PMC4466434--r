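#' Per-base coverage track on a circular genome
#'
#' Dense per-base signal over the whole chromosome, together with sample
#' metadata. Values may be negative after subtraction normalizations.
#'
#' @param values Numeric vector of length `genome$length_bp`.
#' @param genome A [circular_genome()].
#' @param role Sample role: `"ip"`, `"input"`, `"mock"` or `NA`.
#' @param condition `"helicase_present"`, `"helicase_depleted"` or `NA`.
#' @param label Free-text track label.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, genome, role = NA_character_,
                           condition = NA_character_, label = "") {
  stopifnot_genome(genome)
  values <- as.numeric(values)
  if (length(values) != genome$length_bp)
    stop("values length must equal genome length", call. = FALSE)
  if (any(!is.finite(values)))
    stop("coverage values must be finite", call. = FALSE)
  structure(list(genome = genome, values = values, role = role,
                 condition = condition, label = label),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track '%s' (%s, %s): L=%s, mean=%.4g, max=%.4g>\n",
    x$label, x$role, x$condition,
    format(x$genome$length_bp, big.mark = ","),
    mean(x$values), max(x$values)))
  invisible(x)
}

same_genome <- function(a, b) {
  a$genome$length_bp == b$genome$length_bp && a$genome$name == b$genome$name
}

#' Pile up fragment intervals into per-base coverage
#'
#' Each fragment is a half-open interval `[start, end)` on the circle;
#' intervals with `end > L` wrap past the coordinate origin. The coverage at
#' a base is the number of fragments overlapping it, so the track sum equals
#' the total fragment length.
#'
#' @param fragments A `data.frame` (or 2-column matrix) with columns
#'   `start`, `end`: 0-based half-open, `end > start`, `end <= start + L`.
#' @param genome A [circular_genome()].
#' @param ... Passed to [coverage_track()] (`role`, `condition`, `label`).
#' @return A [coverage_track()].
#' @examples
#' g <- circular_genome(10, ter_bp = 5)
#' pileup(data.frame(start = c(0, 3), end = c(5, 8)), g)$values
#' @export
pileup <- function(fragments, genome, ...) {
  stopifnot_genome(genome)
  L <- genome$length_bp
  if (is.matrix(fragments))
    fragments <- data.frame(start = fragments[, 1], end = fragments[, 2])
  if (nrow(fragments) == 0L)
    return(coverage_track(numeric(L), genome, ...))
  s <- fragments$start %% L
  len <- fragments$end - fragments$start
  if (any(len < 1) || any(len > L))
    stop("fragment lengths must be in [1, L]", call. = FALSE)
  e <- s + len
  wraps <- e > L
  # split wrapping fragments at the coordinate origin
  a <- c(s, rep(0, sum(wraps)))
  b <- c(pmin(e, L), e[wraps] - L)
  d <- numeric(L)
  add <- tabulate(a + 1L, nbins = L)
  drop_at <- b[b < L] + 1L
  drp <- if (length(drop_at)) tabulate(drop_at, nbins = L) else numeric(L)
  coverage_track(cumsum(add - drp), genome, ...)
}

#' Write / read coverage in fixedStep wiggle dialect
#'
#' The on-disk dialect is 1-based `fixedStep` with `step=1` covering the
#' whole chromosome; values round-trip exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @return `write_wiggle` returns `path` invisibly; `read_wiggle` returns a
#'   [coverage_track()].
#' @export
write_wiggle <- function(track, path) {
  header <- sprintf("fixedStep chrom=%s start=1 step=1", track$genome$name)
  con <- file(path, "w")
  writeLines(c(sprintf("track type=wiggle_0 name=\"%s\"", track$label),
               header), con)
  close(con)
  data.table::fwrite(data.table::data.table(v = track$values), path,
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_wiggle
#' @param genome A [circular_genome()] the file must match.
#' @param ... Passed to [coverage_track()].
#' @export
read_wiggle <- function(path, genome, ...) {
  stopifnot_genome(genome)
  L <- genome$length_bp
  lines <- readLines(path)
  values <- numeric(L)
  seen <- logical(L)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, "track")) { i <- i + 1L; next }
    if (startsWith(line, "fixedStep")) {
      flds <- strsplit(trimws(line), "\\s+")[[1]][-1]
      kv <- strsplit(flds, "=")
      keys <- vapply(kv, `[[`, "", 1L)
      vals <- vapply(kv, `[[`, "", 2L)
      start1 <- as.integer(vals[keys == "start"])
      step <- if ("step" %in% keys) as.integer(vals[keys == "step"]) else 1L
      if (step != 1L)
        stop("only step=1 fixedStep is supported", call. = FALSE)
      j <- i + 1L
      while (j <= n && !grepl("^(fixedStep|track|variableStep)", lines[[j]]))
        j <- j + 1L
      block <- as.numeric(lines[i + seq_len(j - i - 1L)])
      idx0 <- (start1 - 1L) + seq_along(block) - 1L   # 0-based
      if (length(block) && (start1 < 1L || max(idx0) >= L))
        stop("wiggle block exceeds genome length", call. = FALSE)
      values[idx0 + 1L] <- block
      seen[idx0 + 1L] <- TRUE
      i <- j
    } else if (startsWith(line, "variableStep")) {
      stop("variableStep wiggle is not supported", call. = FALSE)
    } else {
      stop("malformed wiggle: data outside a fixedStep block", call. = FALSE)
    }
  }
  coverage_track(values, genome, ...)
}

#' Read bedGraph coverage
#'
#' bedGraph rows are 0-based half-open `chrom start end value`.
#'
#' @inheritParams read_wiggle
#' @param path bedGraph file path.
#' @export
read_bedgraph <- function(path, genome, ...) {
  stopifnot_genome(genome)
  L <- genome$length_bp
  bg <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (nrow(bg) && (min(bg$start) < 0 || max(bg$end) > L))
    stop("bedGraph interval exceeds genome length", call. = FALSE)
  values <- numeric(L)
  for (k in seq_len(nrow(bg)))
    values[(bg$start[k] + 1L):bg$end[k]] <- bg$value[k]
  coverage_track(values, genome, ...)
}

#' Write fragments as BED
#' @param fragments Fragment table (`start`, `end`, 0-based half-open;
#'   wrapping fragments are split into two BED rows).
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, genome, path) {
  L <- genome$length_bp
  s <- fragments$start %% L
  e <- s + (fragments$end - fragments$start)
  wraps <- e > L
  bed <- data.table::data.table(
    chrom = genome$name,
    start = c(s, rep(0, sum(wraps))),
    end = c(pmin(e, L), e[wraps] - L))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an annotation into a region table
#'
#' Accepts GFF3 (1-based inclusive; `gene` features by default) or BED
#' (0-based half-open, 6 columns for strand). Parsing is delegated to
#' rtracklayer; coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path Annotation file (`.gff`, `.gff3`, or `.bed`).
#' @param genome A [circular_genome()].
#' @param feature_types GFF3 feature types to keep (default `"gene"`).
#' @return A region table as from [gene_regions()], `kind = "gene"`.
#' @export
read_regions <- function(path, genome, feature_types = "gene") {
  stopifnot_genome(genome)
  gr <- rtracklayer::import(path)
  if (length(gr) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature_types]
  md <- S4Vectors::mcols(gr)
  id <- if ("Name" %in% names(md) && !all(is.na(md$Name))) md$Name
        else if ("ID" %in% names(md)) md$ID
        else if ("name" %in% names(md)) md$name
        else paste0("region_", seq_along(gr))
  id[is.na(id)] <- paste0("region_", which(is.na(id)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "none"
  start0 <- BiocGenerics::start(gr) - 1L   # GRanges is 1-based inclusive
  end0 <- BiocGenerics::end(gr)
  if (length(gr) && (min(start0) < 0 || max(end0) > genome$length_bp))
    stop("annotation coordinates outside genome", call. = FALSE)
  gene_regions(as.character(id), start0, end0, strand, "gene", genome)
}

# Merge gene intervals on the circle into disjoint covered arcs.
# Returns a matrix with columns start,end (end may exceed L for one
# wrapping arc) or NULL if the union covers the whole circle.
merge_on_circle <- function(regions, genome) {
  L <- genome$length_bp
  s <- regions$start %% L
  e <- s + (regions$end - regions$start)
  pieces_s <- c(s, rep(0, sum(e > L)))
  pieces_e <- c(pmin(e, L), e[e > L] - L)
  o <- order(pieces_s, pieces_e)
  ps <- pieces_s[o]; pe <- pieces_e[o]
  ms <- numeric(0); me <- numeric(0)
  for (k in seq_along(ps)) {
    if (length(ms) && ps[k] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], pe[k])
    } else {
      ms <- c(ms, ps[k]); me <- c(me, pe[k])
    }
  }
  if (length(ms) == 1L && ms[1] == 0 && me[1] == L) return(NULL)
  # join across the coordinate origin
  if (length(ms) > 1L && ms[1] == 0 && me[length(me)] == L) {
    ms[length(ms)] <- ms[length(ms)]          # last arc wraps into first
    me[length(me)] <- L + me[1]
    ms <- ms[-1]; me <- me[-1]
  }
  cbind(start = ms, end = me)
}

#' Derive intergenic regions from a gene annotation
#'
#' Intergenic regions are the complement of the merged gene union on the
#' circle, split at gene boundaries. Only gaps strictly longer than
#' `min_len` bp are retained (the quantification rule keeps intergenic
#' regions greater than 5 nucleotides).
#'
#' @param genes Gene region table.
#' @param genome A [circular_genome()].
#' @param min_len Strict lower bound on retained gap length (default 5).
#' @return Region table with `kind = "intergenic"`, strand `"none"`,
#'   ids `ig_1, ig_2, ...` in coordinate order.
#' @export
derive_intergenic <- function(genes, genome, min_len = 5) {
  stopifnot_genome(genome)
  L <- genome$length_bp
  if (nrow(genes) == 0L)
    return(gene_regions("ig_1", 0, L, "none", "intergenic", genome))
  merged <- merge_on_circle(genes, genome)
  if (is.null(merged))
    return(gene_regions(character(0), numeric(0), numeric(0),
                        character(0), character(0)))
  n <- nrow(merged)
  gs <- numeric(0); ge <- numeric(0)
  for (k in seq_len(n)) {
    nxt <- if (k == n) 1L else k + 1L
    gap_start <- merged[k, "end"] %% L
    gap_len <- (merged[nxt, "start"] - merged[k, "end"]) %% L
    if (n == 1L)  # single arc: the gap is the rest of the circle
      gap_len <- L - (merged[1, "end"] - merged[1, "start"])
    if (gap_len > min_len) {
      gs <- c(gs, gap_start)
      ge <- c(ge, gap_start + gap_len)
    }
  }
  if (!length(gs))
    return(gene_regions(character(0), numeric(0), numeric(0),
                        character(0), character(0)))
  o <- order(gs)
  gene_regions(paste0("ig_", seq_along(gs)), gs[o], ge[o], "none",
               "intergenic", genome)
}
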