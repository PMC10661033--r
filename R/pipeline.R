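# End-to-end orchestration: simulation (or reading FASTQ/SAM/pileup input)
# -> merge -> align -> pileup -> profile -> combined profile, spectrum,
# window statistics, per-read multiplicities -> TSV artifacts plus a
# machine-readable JSON summary and a plain-text log. Identical
# configuration and seed give an identical summary.

#' Build a pipeline run configuration
#'
#' Exactly one input mode is active: `"simulate"` (a `simulation_config` is
#' supplied), `"fastq"` (paired FASTQ paths), `"sam"` (pre-aligned SAM text)
#' or `"pileup"` (samtools-style text pileup).
#'
#' @param mode Input mode.
#' @param reference A `reference_amplicon` (required in every mode).
#' @param guides Guide tibble (at least one guide).
#' @param sim A `simulation_config` (simulate mode).
#' @param fastq1,fastq2 Mate FASTQ paths (fastq mode).
#' @param sam SAM path (sam mode).
#' @param pileup Text-pileup path (pileup mode).
#' @param background Optional background profile tibble (or TSV path) to
#'   subtract before the window statistics.
#' @param n_reads Number of read pairs to sample in simulate mode.
#' @param window_center 1-based center for window statistics; defaults to
#'   the first guide's PAM 3' end.
#' @param window_halfwidth Half-width for window statistics, bp.
#' @param combine_halfwidth Relative-coordinate range of the combined
#'   profile, bp.
#' @param coverage_frac Coverage fraction for [estimate_window_extent()].
#' @param generations Generations elapsed, or a passage tibble for
#'   [generations_from_passages()].
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param seed Seed for read sampling.
#' @param write_plots Whether [run_pipeline()] writes PNG figures.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "fastq", "sam", "pileup"),
                       reference, guides, sim = NULL,
                       fastq1 = NULL, fastq2 = NULL, sam = NULL, pileup = NULL,
                       background = NULL, n_reads = 1000L,
                       window_center = NULL, window_halfwidth = 50L,
                       combine_halfwidth = 100L, coverage_frac = 0.99,
                       generations = 20.5,
                       min_overlap = 20L, max_mismatch_frac = 0.1,
                       seed = 1L, write_plots = FALSE) {
  mode <- match.arg(mode)
  reference <- as_reference(reference)
  guides <- as_tibble(guides)
  if (nrow(guides) == 0L) abort("at least one guide is required.")
  validate_guides(guides, reference)
  need <- switch(mode,
                 simulate = !is.null(sim),
                 fastq = !is.null(fastq1) && !is.null(fastq2),
                 sam = !is.null(sam),
                 pileup = !is.null(pileup))
  if (!need) abort(sprintf("mode '%s' is missing its input.", mode))
  if (is.null(window_center)) window_center <- guides$pam3_pos[1]
  gens <- if (is.data.frame(generations)) generations_from_passages(generations)
          else as.numeric(generations)
  structure(
    list(mode = mode, reference = reference, guides = guides, sim = sim,
         fastq1 = fastq1, fastq2 = fastq2, sam = sam, pileup = pileup,
         background = background, n_reads = as.integer(n_reads),
         window_center = as.integer(window_center),
         window_halfwidth = as.numeric(window_halfwidth),
         combine_halfwidth = as.numeric(combine_halfwidth),
         coverage_frac = coverage_frac, generations = gens,
         min_overlap = as.integer(min_overlap),
         max_mismatch_frac = max_mismatch_frac,
         seed = as.integer(seed), write_plots = isTRUE(write_plots)),
    class = "run_config"
  )
}

#' Run the full profiling pipeline
#'
#' Executes the stages applicable to the configured input mode, writes TSV
#' artifacts, a JSON summary and a log into `out_dir`, and returns the
#' summary. The summary carries the mean window substitution rate, the
#' generations used, the per-generation rate (s.p.b.), the A/T spectrum
#' share, the estimated window extent and the per-read multiplicity
#' fractions.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return The summary as a named list (invisibly returns the same object
#'   written to `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("crisprofile_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  say("crisprofile %s | mode=%s seed=%d", as.character(utils::packageVersion("crisprofile")),
      config$mode, config$seed)
  say("reference %s (%d bp), %d guide(s); window %d±%g bp; generations %.4g",
      config$reference$id, config$reference$length, nrow(config$guides),
      config$window_center, config$window_halfwidth, config$generations)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  n_unmerged <- NA_integer_
  counts <- NULL
  if (config$mode %in% c("simulate", "fastq", "sam")) {
    if (config$mode == "simulate") {
      pool <- stage("simulate", simulate_mutagenesis(config$sim))
      say("simulated %d genomes carrying %d substitutions",
          length(pool$sequences), nrow(pool$mutations))
      write_reference_fasta(config$reference, file.path(out_dir, "reference.fasta"))
      write_truth_tsv(pool, file.path(out_dir, "truth.tsv"))
      write_config_text(config$sim, file.path(out_dir, "sim_config.txt"))
      reads <- stage("sample_reads",
                     sample_reads(pool, config$n_reads, seed = config$seed))
      write_reads_fastq(reads, file.path(out_dir, "reads"))
    } else if (config$mode == "fastq") {
      reads <- stage("read_fastq", read_reads_fastq(config$fastq1, config$fastq2))
      say("read %d read pairs", nrow(reads))
    }
    if (config$mode == "sam") {
      alignments <- stage("read_sam", read_sam(config$sam, config$reference))
      say("read %d SAM records (%d aligned)", nrow(alignments),
          sum(alignments$aligned))
    } else {
      merged <- stage("merge", merge_read_pairs(
        reads, min_overlap = config$min_overlap,
        max_mismatch_frac = config$max_mismatch_frac))
      n_unmerged <- sum(!merged$merged)
      say("merged %d/%d pairs (%d unmerged dropped)",
          sum(merged$merged), nrow(merged), n_unmerged)
      alignments <- stage("align",
                          suppressMessages(align_reads(merged, config$reference)))
      say("aligned %d reads (%d passed identity filter)",
          nrow(alignments), sum(alignments$aligned))
    }
    write_sam(alignments, config$reference, file.path(out_dir, "alignments.sam"))
    counts <- substitutions_per_read(alignments[alignments$aligned, ])
    readr::write_tsv(tibble(query_id = alignments$query_id[alignments$aligned],
                            substitutions = counts),
                     file.path(out_dir, "per_read_counts.tsv"))
    pile <- stage("pileup", build_pileup(alignments, config$reference))
    write_pileup(pile, file.path(out_dir, "pileup.txt"),
                 chrom = config$reference$id)
  } else {
    pile <- stage("read_pileup", read_pileup(config$pileup))
    say("read %d pileup columns", nrow(pile))
  }

  prof <- stage("profile", mutation_profile(pile))
  if (!is.null(config$background)) {
    bg <- if (is.character(config$background)) read_profile_tsv(config$background)
          else config$background
    prof <- stage("subtract_background", subtract_background(prof, bg))
    say("background profile subtracted")
  }
  write_profile_tsv(prof, file.path(out_dir, "profile.tsv"))

  combined <- stage("combine", combine_profiles(
    rep(list(prof), nrow(config$guides)), config$guides,
    halfwidth = config$combine_halfwidth))
  write_combined_tsv(combined, file.path(out_dir, "combined.tsv"))
  spec <- stage("spectrum", spectrum(prof, config$window_center,
                                     config$window_halfwidth))
  write_spectrum_tsv(spec, file.path(out_dir, "spectrum.tsv"))

  mean_rate <- stage("window", window_average(prof, config$window_center,
                                              config$window_halfwidth))
  extent <- tryCatch(estimate_window_extent(combined, config$coverage_frac),
                     error = function(e) tibble(left = NA_integer_,
                                                right = NA_integer_,
                                                width_bp = NA_integer_))
  spb <- per_generation_rate(mean_rate, config$generations)
  read_summary <- if (!is.null(counts) && length(counts) > 0) {
    per_read_count_summary(counts)
  } else list(frac_ge1 = NA_real_, frac_ge2 = NA_real_)

  if (config$write_plots) {
    ggplot2::ggsave(file.path(out_dir, "profile.png"), plot_profile(prof),
                    width = 8, height = 3, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "combined.png"), autoplot(combined),
                    width = 8, height = 3, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "spectrum.png"), autoplot(spec),
                    width = 8, height = 4, dpi = 150)
  }

  summary <- list(
    mode = config$mode, seed = config$seed,
    n_unmerged = n_unmerged,
    window_center = config$window_center,
    window_halfwidth = config$window_halfwidth,
    mean_window_rate = mean_rate,
    generations = config$generations,
    per_generation_rate = spb,
    at_fraction = spec$at_fraction,
    window_extent = list(left = extent$left, right = extent$right,
                         width_bp = extent$width_bp),
    frac_reads_ge1 = read_summary$frac_ge1,
    frac_reads_ge2 = read_summary$frac_ge2
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("summary: mean window rate %.4g, s.p.b. %.4g, A/T %.3g%%, extent %s bp",
      mean_rate, spb, 100 * spec$at_fraction, extent$width_bp)
  writeLines(log_lines, log_path)
  invisible(summary)
}
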