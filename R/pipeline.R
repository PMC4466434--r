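# Orchestration: simulate or ingest coverage, normalize, form the
# differential, quantify regions, fit the background, call peaks, report.

#' Build a validated pipeline run configuration
#'
#' Exactly one of `scenario` (a [simulation_scenario()]) or `files` (named
#' list of coverage file paths with elements `ip_depleted`, `input_depleted`,
#' `ip_present`, `input_present`, optionally `mock_depleted`,
#' `mock_present`) must be supplied.
#'
#' @param genome A [circular_genome()].
#' @param annotation Region table of genes, or a path readable by
#'   [read_regions()].
#' @param scenario Optional [simulation_scenario()].
#' @param files Optional named list of coverage file paths (wiggle or
#'   bedGraph, dispatched on extension).
#' @param depth_scale Scale tracks to a common mean before subtraction
#'   (default `TRUE`; disable for strict replication of equal-depth
#'   designs).
#' @param use_mock Subtract mock-IP signal after input normalization
#'   (default `FALSE`; mock correction belongs to epitope-tag ChIP
#'   workflows, not replicative-helicase ChIP).
#' @param window_bp,proximal_bp,bg_threshold Background model parameters
#'   (defaults 100 kb windows, 300 kb proximal zone, 5-fold flagging).
#' @param peak_threshold Strict fold threshold for peak calls (default 5;
#'   must be > 1).
#' @param min_intergenic Strict minimum intergenic length quantified
#'   (default 5 nt).
#' @param outdir Output directory (created); `NULL` for no file output.
#' @param seed Master seed; all sample simulations draw named substreams
#'   from it.
#' @param verbose Print stage messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genome, annotation, scenario = NULL, files = NULL,
                       depth_scale = TRUE, use_mock = FALSE,
                       window_bp = 100000, proximal_bp = 300000,
                       bg_threshold = 5, peak_threshold = 5,
                       min_intergenic = 5, outdir = NULL, seed = 1,
                       verbose = FALSE) {
  stopifnot_genome(genome)
  if (is.null(scenario) == is.null(files))
    stop("supply exactly one of scenario or files", call. = FALSE)
  if (peak_threshold <= 1) stop("peak_threshold must be > 1", call. = FALSE)
  if (window_bp < 10000) stop("window_bp must be >= 10 kb", call. = FALSE)
  if (is.character(annotation)) annotation <- read_regions(annotation, genome)
  if (!is.null(files)) {
    need <- c("ip_depleted", "input_depleted", "ip_present", "input_present")
    if (!all(need %in% names(files)))
      stop("files must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(genome = genome, annotation = annotation,
                 scenario = scenario, files = files,
                 depth_scale = depth_scale, use_mock = use_mock,
                 window_bp = window_bp, proximal_bp = proximal_bp,
                 bg_threshold = bg_threshold,
                 peak_threshold = peak_threshold,
                 min_intergenic = min_intergenic, outdir = outdir,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

read_any_coverage <- function(path, genome, role, condition) {
  if (grepl("\\.(bedgraph|bdg)$", path, ignore.case = TRUE))
    read_bedgraph(path, genome, role = role, condition = condition,
                  label = basename(path))
  else
    read_wiggle(path, genome, role = role, condition = condition,
                label = basename(path))
}

load_tracks <- function(config) {
  g <- config$genome
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- config$seed   # all substreams flow from the run seed
    get1 <- function(role, cond)
      simulate_chip_sample(sc, role, cond)$track
    tr <- list(
      ip_depleted = get1("ip", "helicase_depleted"),
      input_depleted = get1("input", "helicase_depleted"),
      ip_present = get1("ip", "helicase_present"),
      input_present = get1("input", "helicase_present"))
    if (config$use_mock) {
      tr$mock_depleted <- get1("mock", "helicase_depleted")
      tr$mock_present <- get1("mock", "helicase_present")
    }
    tr
  } else {
    roles <- list(ip_depleted = c("ip", "helicase_depleted"),
                  input_depleted = c("input", "helicase_depleted"),
                  ip_present = c("ip", "helicase_present"),
                  input_present = c("input", "helicase_present"),
                  mock_depleted = c("mock", "helicase_depleted"),
                  mock_present = c("mock", "helicase_present"))
    out <- list()
    for (nm in names(config$files)) {
      r <- roles[[nm]]
      out[[nm]] <- read_any_coverage(config$files[[nm]], g, r[1], r[2])
    }
    out
  }
}

#' Run the full differential stalling analysis
#'
#' Stages: load or simulate coverage, optional common-depth scaling,
#' input normalization per condition, optional mock correction,
#' depleted-minus-present differential, per-region quantification over all
#' genes plus qualifying intergenic regions, two-zone background
#' estimation on the differential, strict fold-over-background peak
#' calling. With an `outdir`, writes normalized and differential wiggle
#' tracks, the full region table, the called-peak table, a background
#' report (JSON) and a parameter log. Identical config and seed give
#' byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `tracks`, `normalized` (per condition),
#'   `differential`, `regions`, `region_table`, `peak_table`,
#'   `background`, `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop("expected a run_config", call. = FALSE)
  g <- config$genome
  say <- function(...) if (config$verbose) message(sprintf(...))
  logl <- c(sprintf("repliconflict %s",
                    as.character(utils::packageVersion("repliconflict"))),
            sprintf("seed=%s depth_scale=%s use_mock=%s", config$seed,
                    config$depth_scale, config$use_mock),
            sprintf("window_bp=%s proximal_bp=%s bg_threshold=%s peak_threshold=%s min_intergenic=%s",
                    config$window_bp, config$proximal_bp,
                    config$bg_threshold, config$peak_threshold,
                    config$min_intergenic),
            sprintf("genome: L=%d ori=%d ter=%d", g$length_bp, g$ori_bp,
                    g$ter_bp))

  say("loading/simulating coverage")
  tracks <- load_tracks(config)
  if (config$depth_scale) {
    say("scaling to common depth")
    core <- c("ip_depleted", "input_depleted", "ip_present", "input_present")
    scaled <- scale_to_common_depth(tracks[core])
    names(scaled) <- core
    tracks[core] <- scaled
  }

  say("normalizing")
  norm_dep <- normalize_chip(tracks$ip_depleted, tracks$input_depleted)
  norm_pres <- normalize_chip(tracks$ip_present, tracks$input_present)
  if (config$use_mock) {
    if (is.null(tracks$mock_depleted) || is.null(tracks$mock_present))
      stop("stage normalize: use_mock=TRUE but no mock tracks supplied",
           call. = FALSE)
    norm_dep <- mock_correct(norm_dep,
      normalize_chip(tracks$mock_depleted, tracks$input_depleted))
    norm_pres <- mock_correct(norm_pres,
      normalize_chip(tracks$mock_present, tracks$input_present))
  }
  diff <- differential(norm_dep, norm_pres)
  logl <- c(logl, "differential sign: depleted minus present")

  say("quantifying regions")
  genes <- config$annotation
  intergenic <- derive_intergenic(genes, g, config$min_intergenic)
  regions <- rbind(genes, intergenic)
  quants <- quantify_regions(diff, regions, g)

  say("estimating background")
  bg <- estimate_background(diff, g, window_bp = config$window_bp,
                            proximal_bp = config$proximal_bp,
                            threshold = config$bg_threshold)
  logl <- c(logl, sprintf("background: proximal=%.6g distal=%.6g",
                          bg$proximal_bg, bg$distal_bg))

  say("calling peaks")
  region_table <- call_peaks(quants, bg, g, config$peak_threshold)
  peak_table <- region_table[region_table$called, , drop = FALSE]
  peak_table <- peak_table[order(-peak_table$fold_over_background), ,
                           drop = FALSE]
  logl <- c(logl, sprintf("regions quantified: %d (%d genes, %d intergenic)",
                          nrow(region_table), nrow(genes), nrow(intergenic)),
            sprintf("peak-containing regions: %d", nrow(peak_table)))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    write_wiggle(norm_dep, out("normalized_depleted.wig"))
    write_wiggle(norm_pres, out("normalized_present.wig"))
    write_wiggle(diff, out("differential.wig"))
    params <- list(seed = config$seed, peak_threshold = config$peak_threshold,
                   window_bp = config$window_bp,
                   proximal_bp = config$proximal_bp)
    write_region_table(region_table, out("all_regions.tsv"), params)
    write_region_table(peak_table, out("peak_regions.tsv"), params)
    jsonlite::write_json(
      list(proximal_bg = bg$proximal_bg, distal_bg = bg$distal_bg,
           window_bp = bg$window_bp, proximal_bp = bg$proximal_bp,
           peak_free_windows = as.list(table(
             bg$windows$zone[!bg$windows$flagged]))),
      out("background.json"), auto_unbox = TRUE, digits = NA)
    writeLines(logl, out("run.log"))
  }

  invisible(list(tracks = tracks,
                 normalized = list(depleted = norm_dep, present = norm_pres),
                 differential = diff, regions = regions,
                 region_table = region_table, peak_table = peak_table,
                 background = bg, log = logl))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: a `genome` block (`length`, `ori`,
#' `ter`, `name`), an `annotation` block (`file:` path or `synthetic:`
#' arguments for [synthetic_annotation()]), and either a `scenario` block
#' ([simulation_scenario()] arguments, with `stalls` as a list of
#' `{id, strength, shape}` entries) or a `files` block, plus any top-level
#' [run_config()] options.
#'
#' @param path YAML file path.
#' @param outdir,seed Optional overrides of the file's values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  g <- circular_genome(y$genome$length,
                       ori_bp = y$genome$ori %||% 0,
                       ter_bp = y$genome$ter,
                       name = y$genome$name %||% "chr")
  ann <- if (!is.null(y$annotation$file)) {
    read_regions(y$annotation$file, g)
  } else {
    do.call(synthetic_annotation,
            c(list(genome = g), y$annotation$synthetic))
  }
  scenario <- NULL
  if (!is.null(y$scenario)) {
    st <- NULL
    if (!is.null(y$scenario$stalls))
      st <- do.call(rbind, lapply(y$scenario$stalls, as.data.frame))
    args <- y$scenario
    args$stalls <- NULL
    scenario <- do.call(simulation_scenario,
                        c(list(genome = g, annotation = ann,
                               stall_table = st), args))
  }
  opts <- y[setdiff(names(y), c("genome", "annotation", "scenario",
                                "files"))]
  cfg <- do.call(run_config,
                 c(list(genome = g, annotation = ann, scenario = scenario,
                        files = y$files), opts))
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
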