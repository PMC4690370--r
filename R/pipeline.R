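## ---------------------------------------------------------------------------
## End-to-end orchestration: simulate -> diff -> effects -> methylome -> loci,
## with configuration echo and deterministic, file-based reports.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list.  Every run echoes
#' its effective configuration (plus the package version) into the output
#' directory, so reports are reproducible from the echo alone.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; the strain-pair and kinetics stages derive their
#'   seeds from it unless overridden via `profile`/`kinetics_seed`.
#' @param profile A [generator_profile()] for the strain pair (default
#'   [default_strain_profile()] reseeded from `seed`).
#' @param k Anchor k-mer size for the genome comparison.
#' @param qv_call_threshold Modification-QV detection threshold.
#' @param min_count Overspecification threshold for motif counts.
#' @param window Upstream window for the 0A-box scan, bases.
#' @param simulate_kinetics Run the methylome stage on simulated kinetics?
#'   When `FALSE` the stage is skipped with a warning.
#' @param kinetics_seed,kinetics_length,kinetics_gc Kinetics stand-in
#'   parameters (see [kinetics_profile()]).
#' @return A `pipeline_config` list.
#' @export
straindelta_config <- function(outdir, seed = 42L, profile = NULL,
                               k = 31L, qv_call_threshold = 30,
                               min_count = 30L, window = 300L,
                               simulate_kinetics = TRUE,
                               kinetics_seed = NULL,
                               kinetics_length = 600000L,
                               kinetics_gc = 0.5) {
  stopifnot(k >= 11L, qv_call_threshold > 0, min_count >= 0, window > 0)
  seed <- as.integer(seed)
  if (is.null(profile)) profile <- default_strain_profile(seed = seed)
  if (is.null(kinetics_seed)) kinetics_seed <- (seed %% 2000000000L) + 7L
  structure(list(outdir = outdir, seed = seed, profile = profile, k = as.integer(k),
                 qv_call_threshold = qv_call_threshold,
                 min_count = as.integer(min_count), window = as.integer(window),
                 simulate_kinetics = isTRUE(simulate_kinetics),
                 kinetics_seed = as.integer(kinetics_seed),
                 kinetics_length = as.integer(kinetics_length),
                 kinetics_gc = kinetics_gc,
                 version = as.character(utils::packageVersion("straindelta"))),
            class = "pipeline_config")
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Simulates a strain pair, calls and classifies variants, characterizes the
#' deletion's direct-repeat signature, summarizes simulated methylome
#' kinetics (per-motif detection report, cytosine-context IPD comparison with
#' Welch tests), scans 0A boxes and intergenic gaps, and writes all reports
#' plus a human-readable summary and the effective configuration to
#' `config$outdir`.  Fixed configuration and seeds give byte-identical
#' outputs.
#'
#' @param config A [straindelta_config()].
#' @return Invisibly, a list with the in-memory results (`variants`,
#'   `effects`, `class_counts`, `repeat_signature`, `methylome`,
#'   `context_ipd`, `boxes`, `gaps`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)

  .stage_msg("simulate", "generating strain pair (seed %d)", config$profile$seed)
  sim <- simulate_strain_pair(config$profile)
  write_genome_fasta(sim$reference, p("reference.fasta"))
  write_genome_fasta(sim$mutant, p("mutant.fasta"))
  write_annotations_gff3(sim$annotations, sim$reference, p("annotations.gff3"))
  write_truth_vcf(sim$truth, sim$reference, p("truth.vcf"))

  .stage_msg("diff", "calling variants (k = %d)", config$k)
  calls <- call_variants(sim$reference, sim$mutant, k = config$k)
  write_variants_vcf(calls, sim$reference, p("variants.vcf"))

  .stage_msg("effects", "classifying %d calls", nrow(calls))
  effects <- classify_variants(calls, sim$annotations, sim$reference)
  write_effects_tsv(effects, p("variant_table.tsv"))
  counts <- summarize_effects(effects)
  jsonlite::write_json(as.list(counts), p("class_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  repeat_sig <- NULL
  dels <- which(effects$type == "deletion")
  if (length(dels)) {
    repeat_sig <- flanking_repeat(sim$reference, calls[dels[1L], ],
                                  sim$annotations)
    jsonlite::write_json(repeat_sig, p("repeat_signature.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }

  methylome <- NULL; context_ipd <- NULL
  if (config$simulate_kinetics) {
    .stage_msg("methylome", "simulating kinetics (%d bp, seed %d)",
               config$kinetics_length, config$kinetics_seed)
    kp <- kinetics_profile(seed = config$kinetics_seed,
                           genome_length = config$kinetics_length,
                           gc_fraction = config$kinetics_gc)
    motifs <- default_m6a_motifs()
    methylome <- lapply(motifs, function(m)
      motif_summary(kp$genome, m, kp$track,
                    qv_threshold = config$qv_call_threshold))
    write_methylome_tsv(methylome, p("methylome_table.tsv"))
    ctx <- lapply(setNames(nm = CYTOSINE_CONTEXTS), function(cx)
      context_mean_ipd(kp$genome, kp$track, cx))
    welch <- list(
      CGCG_firstC_vs_C_other = unclass(welch_t(ctx$CGCG_firstC, ctx$C_other)),
      CGCG_firstC_vs_CG = unclass(welch_t(ctx$CGCG_firstC, ctx$CG_firstC)),
      CGCG_secondC_vs_C_other = unclass(welch_t(ctx$CGCG_secondC, ctx$C_other)),
      CGCG_secondC_vs_CG = unclass(welch_t(ctx$CGCG_secondC, ctx$CG_firstC)))
    context_ipd <- list(contexts = ctx, welch = welch)
    jsonlite::write_json(context_ipd, p("context_ipd.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    warning("methylome stage skipped: kinetics simulation disabled")
    .stage_msg("methylome", "skipped (no kinetics)")
  }

  .stage_msg("loci", "scanning 0A boxes (window %d) and gaps", config$window)
  boxes <- scan_0a_boxes(sim$reference, sim$annotations, window = config$window)
  write.table(boxes, p("zeroa_boxes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gaps <- intergenic_gaps(sim$annotations)
  write.table(gaps, p("intergenic_gaps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  cfg_echo <- config
  cfg_echo$profile <- unclass(cfg_echo$profile)
  jsonlite::write_json(unclass(cfg_echo), p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  summary_lines <- c(
    sprintf("straindelta %s pipeline summary", config$version),
    sprintf("reference: %d bp, %d genes", nchar(sim$reference$seq),
            nrow(sim$annotations)),
    sprintf("variants called: %d (%d substitutions, %d deletions, %d insertions)",
            nrow(calls), sum(calls$type == "substitution"),
            sum(calls$type == "deletion"), sum(calls$type == "insertion")),
    paste("class counts:",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")),
    if (!is.null(repeat_sig))
      sprintf("deletion flanking repeat: %d bp (%s), in frame: %s",
              repeat_sig$repeat_length, repeat_sig$repeat_sequence,
              repeat_sig$in_frame) else
      "no deletion call",
    if (!is.null(methylome))
      sprintf("methylome motifs summarized: %d", length(methylome)) else
      "methylome stage skipped",
    sprintf("0A-box hits: %d; intergenic gaps: %d", nrow(boxes), nrow(gaps)))
  writeLines(summary_lines, p("summary.txt"))

  invisible(list(variants = calls, effects = effects, class_counts = counts,
                 repeat_signature = repeat_sig, methylome = methylome,
                 context_ipd = context_ipd, boxes = boxes, gaps = gaps,
                 truth = sim$truth,
                 paths = list(outdir = config$outdir)))
}
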