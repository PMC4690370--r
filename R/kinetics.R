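## ---------------------------------------------------------------------------
## Simulated SMRT kinetics: per-position, per-strand interpulse-duration (IPD)
## ratios and modification QVs with the statistical structure the methylome
## analyses assume.
## ---------------------------------------------------------------------------

#' Kinetics simulation model
#'
#' IPD ratios are drawn log-normally per position and strand, with the
#' arithmetic mean set by the most specific matching cytosine context
#' (first/second C of `CGCG`, `CG`, other `C`) and `background_mean_ipd`
#' elsewhere.  The log-normal is parameterized so that the *arithmetic* mean
#' equals the configured mean (mu = log(m) - sigma^2/2), because downstream
#' summaries report plain averages.  Modification QVs at m6A motif sites
#' separate methylated from unmethylated sites: each duplex site is methylated
#' with its motif's detection fraction and then draws from the modified QV
#' distribution on every motif-bearing strand, all other records draw from the
#' unmodified distribution (truncated at zero).
#'
#' Default context means (`CGCG` first C 1.25, second C 1.11, `CG` 0.89,
#' other C 0.86, background 1.00) are the working values of the cytosine
#' methylation analysis; `lognormal_sigma = 0.25` is a stated model assumption
#' (no dispersion is prescribed by the analysis the defaults mirror).
#'
#' @param background_mean_ipd Mean IPD ratio at non-cytosine positions.
#' @param context_means Named vector over
#'   `C_other`, `CG_firstC`, `CGCG_firstC`, `CGCG_secondC`.
#' @param lognormal_sigma Log-scale standard deviation of the IPD draw.
#' @param m6a_detection_fraction Named vector, motif pattern to per-site
#'   methylation probability; defaults to [default_m6a_motifs()] fractions.
#' @param qv_modified_mean,qv_unmodified_mean,qv_sd Modification-QV normal
#'   parameters (Phred-like units).
#' @param qv_call_threshold QV at or above which a site counts as detected.
#' @param coverage_mean Mean per-strand coverage (Poisson).
#' @return A `kinetics_model` list.
#' @export
kinetics_model <- function(background_mean_ipd = 1.0,
                           context_means = c(C_other = 0.86, CG_firstC = 0.89,
                                             CGCG_firstC = 1.25,
                                             CGCG_secondC = 1.11),
                           lognormal_sigma = 0.25,
                           m6a_detection_fraction = NULL,
                           qv_modified_mean = 86, qv_unmodified_mean = 5,
                           qv_sd = 8, qv_call_threshold = 30,
                           coverage_mean = 58) {
  if (is.null(m6a_detection_fraction))
    m6a_detection_fraction <- vapply(default_m6a_motifs(),
                                     attr, numeric(1), "detection_fraction")
  stopifnot(background_mean_ipd > 0, all(context_means > 0),
            lognormal_sigma > 0,
            all(m6a_detection_fraction >= 0 & m6a_detection_fraction <= 1),
            qv_modified_mean > qv_call_threshold,
            qv_call_threshold > qv_unmodified_mean,
            coverage_mean > 0)
  if (!all(CYTOSINE_CONTEXTS %in% names(context_means)))
    stop("context_means must name all of: ",
         paste(CYTOSINE_CONTEXTS, collapse = ", "))
  structure(list(background_mean_ipd = background_mean_ipd,
                 context_means = context_means[CYTOSINE_CONTEXTS],
                 lognormal_sigma = lognormal_sigma,
                 m6a_detection_fraction = m6a_detection_fraction,
                 qv_modified_mean = qv_modified_mean,
                 qv_unmodified_mean = qv_unmodified_mean,
                 qv_sd = qv_sd, qv_call_threshold = qv_call_threshold,
                 coverage_mean = coverage_mean),
            class = "kinetics_model")
}

#' Construct an IPD track
#'
#' Per-position, per-strand kinetics observations: IPD ratio, modification QV
#' and coverage, stored as `length x 2` matrices (columns `+`, `-`).
#'
#' @param ipd,mod_qv,coverage Numeric `L x 2` matrices.
#' @return An `ipd_track` object.
#' @export
ipd_track <- function(ipd, mod_qv, coverage) {
  stopifnot(is.matrix(ipd), ncol(ipd) == 2L,
            identical(dim(ipd), dim(mod_qv)),
            identical(dim(ipd), dim(coverage)))
  if (any(ipd <= 0)) stop("IPD ratios must be positive")
  if (any(mod_qv < 0) || any(coverage < 0))
    stop("modification QV and coverage must be non-negative")
  structure(list(length = nrow(ipd), ipd = ipd, mod_qv = mod_qv,
                 coverage = coverage), class = "ipd_track")
}

#' @export
print.ipd_track <- function(x, ...) {
  cat(sprintf("<ipd_track> %s positions x 2 strands; mean IPD %.3f, mean QV %.1f\n",
              format(x$length, big.mark = ","), mean(x$ipd), mean(x$mod_qv)))
  invisible(x)
}

#' Simulate an SMRT kinetics track for a genome
#'
#' @param genome A [genome_record()].
#' @param model A [kinetics_model()].
#' @param motifs List of [iupac_motif()] m6A motifs whose sites receive
#'   modification QVs (default [default_m6a_motifs()]); detection fractions
#'   come from `model$m6a_detection_fraction` (falling back to each motif's
#'   own `detection_fraction` attribute).
#' @param seed Integer RNG seed (default 7).
#' @return An [ipd_track()].
#' @export
simulate_kinetics <- function(genome, model = kinetics_model(),
                              motifs = default_m6a_motifs(), seed = 7L) {
  stopifnot(inherits(model, "kinetics_model"))
  set.seed(as.integer(seed))
  L <- nchar(genome$seq)
  cm <- .context_matrix(genome)
  means <- matrix(model$background_mean_ipd, L, 2L)
  for (code in 1:4)
    means[cm == code] <- model$context_means[[CYTOSINE_CONTEXTS[code]]]
  sigma <- model$lognormal_sigma
  mu <- log(means) - sigma^2 / 2
  ipd <- matrix(rlnorm(2L * L, as.vector(mu), sigma), L, 2L)
  qv <- matrix(pmax(0, rnorm(2L * L, model$qv_unmodified_mean, model$qv_sd)),
               L, 2L)
  for (motif in motifs) {
    hits <- scan_motif(genome, motif)
    if (is.null(hits) || nrow(hits) == 0L) next
    frac <- model$m6a_detection_fraction[[motif$pattern]]
    if (is.null(frac) || is.na(frac))
      frac <- attr(motif, "detection_fraction")
    if (is.null(frac)) frac <- 1
    key <- .footprint_key(hits, nchar(motif$pattern), L)
    sites <- unique(key)
    modified <- sites[runif(length(sites)) < frac]
    sel <- key %in% modified
    if (!any(sel)) next
    mc <- .modified_coord(hits[sel, , drop = FALSE], motif, L)
    si <- ifelse(hits$strand[sel] == "+", 1L, 2L)
    qv[cbind(mc, si)] <- pmax(0, rnorm(length(mc), model$qv_modified_mean,
                                       model$qv_sd))
  }
  cov <- matrix(rpois(2L * L, model$coverage_mean), L, 2L)
  ipd_track(ipd, qv, cov)
}

#' Write an IPD track as TSV
#'
#' Columns: `position`, `strand`, `ipd_ratio`, `mod_qv`, `coverage`; one row
#' per position and strand.
#'
#' @param track An [ipd_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kinetics_tsv <- function(track, path) {
  dt <- data.table::data.table(
    position = rep(seq_len(track$length), 2L),
    strand = rep(c("+", "-"), each = track$length),
    ipd_ratio = c(track$ipd[, 1L], track$ipd[, 2L]),
    mod_qv = c(track$mod_qv[, 1L], track$mod_qv[, 2L]),
    coverage = c(track$coverage[, 1L], track$coverage[, 2L]))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read an IPD track from TSV
#'
#' @param path TSV written by [write_kinetics_tsv()] (or any file with the
#'   same five columns).
#' @return An [ipd_track()].
#' @export
read_kinetics_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  req <- c("position", "strand", "ipd_ratio", "mod_qv", "coverage")
  if (!all(req %in% names(dt)))
    stop("kinetics TSV needs columns: ", paste(req, collapse = ", "))
  L <- max(dt$position)
  mk <- function(col, fill) {
    m <- matrix(fill, L, 2L)
    si <- ifelse(dt$strand == "+", 1L, 2L)
    m[cbind(dt$position, si)] <- dt[[col]]
    m
  }
  ipd_track(mk("ipd_ratio", 1), mk("mod_qv", 0), mk("coverage", 0))
}
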