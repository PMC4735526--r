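# End-to-end CLIP analysis driver: tags + control -> k-mer enrichment ->
# top motifs + logo counts -> spacing distribution -> bipartite site
# calls, from a single config, with stage-scoped logging, TSV outputs
# and a JSON report.

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.log_stage <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %-10s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}

#' Build a pipeline configuration
#'
#' Collects every tunable of the CLIP analysis with the defaults of the
#' T-STAR study design: 6-mers, raw p < 0.05, top 15 motifs, bipartite
#' separation strictly above 15 intervening nucleotides with a 30-nt
#' ceiling.  All values are echoed into the report for provenance.
#'
#' @param tags,control paths to FASTA files (must exist).
#' @param out_dir output directory (created if missing).
#' @param k k-mer length.
#' @param alpha significance level for enrichment.
#' @param top_n number of top motifs.
#' @param flank logo context (nt) on each side of the k-mer.
#' @param min_separation,max_separation bipartite-site separation bounds
#'   (intervening nt).
#' @param spacing_max_distance largest individually binned separation in
#'   the spacing distribution.
#' @param seed integer seed recorded in the report (the analysis stages
#'   are deterministic; the seed matters when the config is used to
#'   generate inputs).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(tags, control, out_dir = "clip_analysis",
                            k = 6L, alpha = 0.05, top_n = 15L,
                            flank = 10L, min_separation = 16L,
                            max_separation = 30L,
                            spacing_max_distance = 50L, seed = 1L) {
  for (f in c(tags, control))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(list(tags = tags, control = control, out_dir = out_dir,
                 k = as.integer(k), alpha = alpha,
                 top_n = as.integer(top_n), flank = as.integer(flank),
                 min_separation = as.integer(min_separation),
                 max_separation = as.integer(max_separation),
                 spacing_max_distance = as.integer(spacing_max_distance),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key/value file
#'
#' Recognized keys are the arguments of \code{\link{pipeline_config}};
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Run the CLIP analysis pipeline
#'
#' Stages, in order: ingest (FASTA, normalized to RNA), k-mer enrichment
#' against the control, top-motif selection, logo count matrix, spacing
#' distributions (CLIP vs control), bipartite site calls.  Each stage
#' writes a TSV under \code{out_dir}; identical config and inputs give
#' byte-identical TSVs.  A JSON report collects summary statistics,
#' output paths, MD5 checksums of every TSV, the full config and the
#' package version.  Any stage error aborts with the stage name; outputs
#' of completed stages are preserved.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress log messages.
#' @return The report, invisibly, as a list of class
#'   \code{analysis_report} (also written to \code{out_dir/report.json}).
#' @export
run_clip_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  logfile <- file.path(config$out_dir, "pipeline.log")
  log <- function(stage, msg) {
    line <- sprintf("[%s] %-10s %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    cat(line, "\n", file = logfile, append = TRUE)
    if (!quiet) message(line)
    invisible(NULL)
  }
  stage <- "ingest"
  report <- list(started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 package_version = as.character(
                   utils::packageVersion("starbind")),
                 config = unclass(config), seed = config$seed)
  out <- function(f) file.path(config$out_dir, f)
  res <- tryCatch({
    log(stage, sprintf("seed %d; reading %s / %s", config$seed,
                       config$tags, config$control))
    clip <- read_fasta(config$tags, alphabet = "RNA")
    control <- read_fasta(config$control, alphabet = "RNA")
    if (length(clip) == 0L) stop("tag set is empty")
    if (length(control) == 0L) stop("control set is empty")

    stage <- "kmer"
    log(stage, sprintf("k = %d, alpha = %g", config$k, config$alpha))
    enr <- enrich_kmers(clip, control, k = config$k, alpha = config$alpha)
    .write_tsv(as.data.frame(enr)[, c("kmer", "obs_count", "obs_total",
                                      "bg_count", "bg_total", "ratio",
                                      "chi2", "p_value")],
               out("kmer_enrichment.tsv"))

    stage <- "top_kmers"
    top <- withCallingHandlers(
      select_top_kmers(enr, n = config$top_n),
      warning = function(w) {
        log(stage, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    .write_tsv(as.data.frame(top)[, c("kmer", "ratio", "chi2", "p_value")],
               out("top_kmers.tsv"))
    log(stage, sprintf("%d motifs, best %s", nrow(top),
                       if (nrow(top)) top$kmer[1] else "-"))

    stage <- "logo"
    logo <- if (nrow(top)) {
      withCallingHandlers(
        build_logo_counts(clip, top$kmer, flank = config$flank),
        warning = function(w) {
          log(stage, conditionMessage(w)); invokeRestart("muffleWarning")
        })
    } else NULL
    if (!is.null(logo)) {
      lm <- data.frame(base = rownames(logo$counts), logo$counts,
                       check.names = FALSE)
      .write_tsv(lm, out("logo_counts.tsv"))
    }

    stage <- "spacing"
    sp <- compare_spacing(clip, control,
                          max_distance = config$spacing_max_distance)
    .write_tsv(sp, out("spacing.tsv"))

    stage <- "bipartite"
    clip_site <- has_bipartite_site(clip, config$min_separation,
                                    config$max_separation)
    control_site <- has_bipartite_site(control, config$min_separation,
                                       config$max_separation)
    site_tbl <- data.frame(
      set = c("clip", "control"),
      n_tags = c(length(clip), length(control)),
      n_with_site = c(sum(clip_site), sum(control_site)),
      fraction_with_site = c(mean(clip_site), mean(control_site)))
    .write_tsv(site_tbl, out("bipartite_sites.tsv"))
    log(stage, sprintf("site fraction: clip %.3f vs control %.3f",
                       mean(clip_site), mean(control_site)))

    list(enr = enr, top = top, logo = logo, sp = sp, site_tbl = site_tbl,
         n_clip = length(clip), n_control = length(control))
  }, error = function(e) {
    log(stage, paste("ERROR:", conditionMessage(e)))
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- c(kmer_enrichment = out("kmer_enrichment.tsv"),
             top_kmers = out("top_kmers.tsv"),
             logo_counts = if (!is.null(res$logo))
               out("logo_counts.tsv") else NULL,
             spacing = out("spacing.tsv"),
             bipartite_sites = out("bipartite_sites.tsv"))
  report$outputs <- as.list(files)
  report$checksums <- as.list(tools::md5sum(unlist(files)))
  report$summary <- list(
    n_tags = res$n_clip,
    n_control = res$n_control,
    n_significant_kmers = sum(res$enr$significant),
    top_kmers = res$top$kmer,
    clip_site_fraction = res$site_tbl$fraction_with_site[1],
    control_site_fraction = res$site_tbl$fraction_with_site[2])
  report$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  class(report) <- "analysis_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!quiet)
    .log_stage("report", file.path(config$out_dir, "report.json"), logfile)
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "analysis_report: %d tags vs %d controls\n",
    "  significant k-mers: %d; top: %s\n",
    "  bipartite-site fraction: clip %.3f, control %.3f\n"),
    s$n_tags, s$n_control, s$n_significant_kmers,
    paste(utils::head(s$top_kmers, 5), collapse = " "),
    s$clip_site_fraction, s$control_site_fraction))
  invisible(x)
}
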