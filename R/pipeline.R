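#' Configuration for an end-to-end run
#'
#' Exactly one of `sim` (simulate the inputs) or `input` (paths to existing
#' files) must be supplied. The single run seed is fanned out to every
#' stochastic stage via per-stage derived seeds, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param seed Integer run seed.
#' @param outdir Output directory for intermediate files and the report.
#' @param sim A [sim_config()], or `NULL` when mapping existing files.
#' @param input A list with paths `r1`, `r2`, `genome`, and optionally
#'   `truth`, or `NULL` when simulating.
#' @param trim A [trim_policy()].
#' @param map A [map_policy()].
#' @param cpm_min CPM threshold for true junctions (default 1).
#' @param subsample_n Subsample pairs to this depth before trimming, or
#'   `NULL` to use all pairs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, outdir, sim = NULL, input = NULL,
                       trim = trim_policy(), map = map_policy(),
                       cpm_min = 1.0, subsample_n = NULL) {
  if (is.null(sim) == is.null(input)) {
    stop("config error: exactly one of 'sim' and 'input' must be given")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(input)) {
    miss <- setdiff(c("r1", "r2", "genome"), names(input))
    if (length(miss)) stop("config error: input is missing ",
                           paste(miss, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 input = input, trim = trim, map = map, cpm_min = cpm_min,
                 subsample_n = if (is.null(subsample_n)) NULL
                               else as.numeric(subsample_n)),
            class = "run_config")
}

#' Run the full junction-recovery pipeline
#'
#' Executes simulate (or load) -> subsample -> trim -> map -> call in
#' order, writing every intermediate file under `config$outdir` and
#' returning a run report. When simulation truth is available, recovery
#' metrics are included.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log messages.
#' @return A list of class `run_report`: `trim_stats`, `n_mapped`,
#'   `junctions` (the classified [junction_table()]), `uis`, `recovery`
#'   (or `NULL`), `files`, `timing_s` (named per-stage wall times).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[tradiskit] ", ...)
  timing <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  files <- list()

  truth <- NULL
  genome <- NULL
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- derive_seed(config$seed, 1L)
    out <- tick("simulate", simulate_library(sim_cfg, config$outdir))
    genome <- out$genome
    truth <- out$truth
    pairs <- out$pairs
    files <- out[c("genome_fasta", "fastq_r1", "fastq_r2", "truth_tsv")]
    log_stage("simulate: ", length(pairs), " pairs, ", nrow(truth),
              " truth sites, genome ", sum(nchar(genome)), " bp")
  } else {
    pairs <- tick("load", read_fastq_pairs(config$input$r1, config$input$r2))
    genome <- read_fasta(config$input$genome)
    if (!is.null(config$input$truth)) truth <- read_truth(config$input$truth)
    files <- config$input
    log_stage("load: ", length(pairs), " pairs from ", config$input$r1)
  }

  if (!is.null(config$subsample_n)) {
    pairs <- tick("subsample",
                  subsample_pairs(pairs, config$subsample_n,
                                  seed = derive_seed(config$seed, 2L)))
    files$subsampled_r1 <- file.path(config$outdir, "subsampled_R1.fastq")
    files$subsampled_r2 <- file.path(config$outdir, "subsampled_R2.fastq")
    write_fastq_pairs(pairs, files$subsampled_r1, files$subsampled_r2)
    log_stage("subsample: ", length(pairs), " pairs retained")
  }

  trimmed <- tick("trim", filter_pairs(pairs, config$trim))
  files$trimmed_r1 <- file.path(config$outdir, "trimmed_R1.fastq")
  files$kept_r2 <- file.path(config$outdir, "kept_R2.fastq")
  write_fastq_pairs(trimmed$pairs, files$trimmed_r1, files$kept_r2)
  log_stage("trim: ", trimmed$stats$n_kept, "/", trimmed$stats$n_input,
            " usable (fraction ",
            sprintf("%.4f", trimmed$stats$usable_fraction), ")")

  index <- build_index(genome, config$map)
  aln <- tick("map", map_reads(trimmed$pairs$r1, index))
  files$alignments <- file.path(config$outdir, "alignments.tsv")
  write.table(aln, files$alignments, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("map: ", nrow(aln), "/", length(trimmed$pairs),
            " reads mapped uniquely")

  junc <- tick("call", classify_true(putative_junctions(aln), config$cpm_min))
  files$junctions <- file.path(config$outdir, "junctions.tsv")
  write_junction_table(junc, files$junctions, "tsv")
  uis <- uis_count(junc)
  log_stage("call: ", nrow(junc), " putative junctions, ", uis,
            " true junctions (UIS) at cpm >= ", config$cpm_min)

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_metrics(junc, truth, nchar(genome))
    log_stage("recovery: precision ", sprintf("%.4f", recovery$precision),
              ", recall ", sprintf("%.4f", recovery$recall))
  }

  report <- structure(list(
    trim_stats = trimmed$stats,
    n_mapped = nrow(aln),
    junctions = junc,
    uis = uis,
    recovery = recovery,
    files = files,
    timing_s = timing
  ), class = "run_report")
  # downstream counts can never exceed upstream counts
  stopifnot(report$n_mapped <= trimmed$stats$n_kept,
            sum(junc$count) == report$n_mapped)
  report
}

# keys accepted in each section of a YAML run configuration
config_schema <- function() {
  list(
    top = c("seed", "outdir", "sim", "input", "trim", "map", "cpm_min",
            "subsample_n"),
    sim = setdiff(names(formals(sim_config)), "seed"),
    input = c("r1", "r2", "genome", "truth"),
    trim = names(formals(trim_policy)),
    map = names(formals(map_policy))
  )
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected by name; omitted keys take the package
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stop("config error: unknown key '", unknown[1], "' in ", where)
    }
  }
  check_keys(raw, schema$top, "top level")
  if (is.null(raw$seed)) stop("config error: 'seed' is required")
  if (is.null(raw$outdir)) stop("config error: 'outdir' is required")
  sim <- NULL
  if (!is.null(raw$sim)) {
    check_keys(raw$sim, schema$sim, "'sim'")
    sim <- do.call(sim_config, c(raw$sim, list(seed = raw$seed)))
  }
  if (!is.null(raw$input)) check_keys(raw$input, schema$input, "'input'")
  trim <- if (is.null(raw$trim)) trim_policy() else {
    check_keys(raw$trim, schema$trim, "'trim'")
    do.call(trim_policy, raw$trim)
  }
  map <- if (is.null(raw$map)) map_policy() else {
    check_keys(raw$map, schema$map, "'map'")
    do.call(map_policy, raw$map)
  }
  run_config(seed = raw$seed, outdir = raw$outdir, sim = sim,
             input = raw$input, trim = trim, map = map,
             cpm_min = if (is.null(raw$cpm_min)) 1.0 else raw$cpm_min,
             subsample_n = raw$subsample_n)
}

#' Save a run configuration to YAML
#'
#' Writes only the tunable fields, so that [load_config()] of the result
#' reconstructs an identical configuration.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(seed = config$seed, outdir = config$outdir)
  if (!is.null(config$sim)) {
    s <- unclass(config$sim)
    s$seed <- NULL
    out$sim <- s
  }
  if (!is.null(config$input)) out$input <- config$input
  out$trim <- config$trim[names(formals(trim_policy))]
  out$map <- config$map[names(formals(map_policy))]
  out$cpm_min <- config$cpm_min
  if (!is.null(config$subsample_n)) out$subsample_n <- config$subsample_n
  yaml::write_yaml(out, path)
  invisible(path)
}
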