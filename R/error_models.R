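#' Platform error models for amplicon read simulation
#'
#' A platform error model bundles per-base substitution, insertion and
#' deletion probabilities, a homopolymer multiplier that scales indel
#' probabilities inside runs of three or more identical bases (the dominant
#' error context of pyrosequencing), a positional mean-quality decay
#' function, the quality spread, the read length and whether reads are
#' paired.
#'
#' Injected errors are quality-correlated: within each simulated read the
#' per-base error probability is scaled by the base's error probability
#' implied by its drawn Phred score, renormalized so the read-average
#' equals the nominal rate. Low-quality bases therefore carry more errors,
#' as on real instruments, while realized error rates still converge to the
#' nominal rates.
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base error
#'   probabilities, each in \[0, 0.1\].
#' @param homopolymer_multiplier factor (>= 1) applied to indel
#'   probabilities inside homopolymer runs of length >= 3.
#' @param quality_decay function mapping 1-based read position to mean
#'   Phred score; must be non-increasing.
#' @param quality_sd per-base Phred standard deviation around the
#'   positional mean.
#' @param read_quality_sd per-read Phred offset standard deviation (whole
#'   reads are shifted up or down, emulating cluster-to-cluster quality
#'   variation; this is what makes read-level QC informative).
#' @param read_length number of sequenced cycles (bases per read).
#' @param paired logical; paired-end sequencing.
#'
#' @return a list of class `platform_error_model`.
#' @export
platform_error_model <- function(substitution_rate = 0.001,
                                 insertion_rate = 1e-4,
                                 deletion_rate = 1e-4,
                                 homopolymer_multiplier = 1,
                                 quality_decay = function(pos) rep(35, length(pos)),
                                 quality_sd = 3,
                                 read_quality_sd = 0,
                                 read_length = 150L,
                                 paired = FALSE) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates > 0.1))
    stop("error rates must lie in [0, 0.1]")
  if (homopolymer_multiplier < 1)
    stop("homopolymer_multiplier must be >= 1")
  if (!is.function(quality_decay))
    stop("quality_decay must be a function(position) -> mean Phred")
  qd <- quality_decay(seq_len(read_length))
  if (any(diff(qd) > 1e-9))
    stop("quality_decay must be non-increasing in position")
  structure(list(
    substitution_rate = substitution_rate,
    insertion_rate = insertion_rate,
    deletion_rate = deletion_rate,
    homopolymer_multiplier = homopolymer_multiplier,
    quality_decay = quality_decay,
    quality_sd = quality_sd,
    read_quality_sd = read_quality_sd,
    read_length = as.integer(read_length),
    paired = isTRUE(paired)), class = "platform_error_model")
}

#' @rdname platform_error_model
#' @details `miseq_error_model()` is substitution-dominated with a gentle
#'   positional quality decay (Phred 38 down to 28 over the read);
#'   `pyro454_error_model()` is indel-rich with a 4x homopolymer indel
#'   boost and a steeper decay (Phred 34 down to 20), emulating
#'   pyrosequencing's difficulty with runs of identical nucleotides.
#'   Neither preset claims to match a specific instrument's measured
#'   rates; both are configurable.
#' @export
miseq_error_model <- function(read_length = 150L, paired = TRUE) {
  platform_error_model(
    substitution_rate = 1e-3, insertion_rate = 1e-5, deletion_rate = 1e-5,
    homopolymer_multiplier = 1,
    quality_decay = function(pos) 38 - 8 * (pos - 1) / max(read_length - 1, 1),
    quality_sd = 3, read_quality_sd = 2, read_length = read_length,
    paired = paired)
}

#' @rdname platform_error_model
#' @export
pyro454_error_model <- function(read_length = 220L) {
  platform_error_model(
    substitution_rate = 5e-4, insertion_rate = 2e-3, deletion_rate = 2e-3,
    homopolymer_multiplier = 4,
    quality_decay = function(pos) 34 - 8 * (pos - 1) / max(read_length - 1, 1),
    quality_sd = 4, read_quality_sd = 3, read_length = read_length,
    paired = FALSE)
}
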