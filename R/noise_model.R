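#' Measurement-noise model for the simulator
#'
#' Describes how noise-free kinetic trajectories become observed data:
#' transcript abundances are drawn negative-binomially around library-scaled
#' expected values; protein reporter intensities receive multiplicative
#' log-normal noise plus a per-run (batch) offset on the log scale; each
#' protein can additionally drop out of a whole run with a probability that
#' decreases with its abundance, mirroring the replicate-overlap structure of
#' isobaric-labelling experiments where a protein is either quantified in a
#' run or absent from it entirely.
#'
#' Setting `nb_dispersion = 0` and `lognormal_sigma = 0` (see [no_noise()])
#' makes the generator fully deterministic: matrices contain the exact
#' expected values and replicate columns are identical.
#'
#' @param nb_dispersion Negative-binomial overdispersion phi of transcript
#'   counts (variance = mu + phi mu^2); 0 disables count noise.
#' @param lognormal_sigma SD of multiplicative protein noise on the natural
#'   log scale (0.15 ~ a 15% CV, typical of reporter-ion quantification).
#' @param batch_sd SD of per-run offsets on the natural log scale; offsets are
#'   drawn once per run unless `batch_offsets` is given.
#' @param batch_offsets Optional fixed per-run offsets (length = replicates).
#' @param missing_logistic Length-2 numeric `(intercept, slope)` of the
#'   logistic model `P(run missing) = plogis(intercept + slope * log2(mean
#'   run intensity))`; `c(-Inf, 0)` disables missingness.
#' @param library_sd SD of per-sample transcript library-size factors on the
#'   natural log scale; factors are drawn once per sample unless
#'   `library_sizes` is given.
#' @param library_sizes Optional fixed per-sample scaling factors for the
#'   transcript layer (length = samples, condition-major order).
#' @param count_scale Multiplier mapping mRNA concentration (a.u.) to expected
#'   read counts.
#'
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(nb_dispersion = 0.05,
                        lognormal_sigma = 0.15,
                        batch_sd = 0.3,
                        batch_offsets = NULL,
                        missing_logistic = c(4, -0.45),
                        library_sd = 0.15,
                        library_sizes = NULL,
                        count_scale = 10) {
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0)
    stop("nb_dispersion must be >= 0")
  if (!is.numeric(lognormal_sigma) || lognormal_sigma < 0)
    stop("lognormal_sigma must be >= 0")
  if (length(missing_logistic) != 2 || any(is.na(missing_logistic)))
    stop("missing_logistic must be (intercept, slope)")
  if (count_scale <= 0) stop("count_scale must be > 0")
  structure(list(nb_dispersion = nb_dispersion,
                 lognormal_sigma = lognormal_sigma,
                 batch_sd = batch_sd,
                 batch_offsets = batch_offsets,
                 missing_logistic = as.numeric(missing_logistic),
                 library_sd = library_sd,
                 library_sizes = library_sizes,
                 count_scale = count_scale),
            class = "noise_model")
}

#' Fully deterministic noise settings
#'
#' @return A [noise_model()] with all noise sources disabled: no count or
#'   intensity noise, no batch offsets, equal library sizes, no missingness.
#' @export
no_noise <- function() {
  noise_model(nb_dispersion = 0, lognormal_sigma = 0, batch_sd = 0,
              missing_logistic = c(-Inf, 0), library_sd = 0)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model:\n")
  cat(sprintf("  transcript NB dispersion: %g; count scale: %g; library-size sd (ln): %g\n",
              x$nb_dispersion, x$count_scale, x$library_sd))
  cat(sprintf("  protein lognormal sigma (ln): %g; batch sd (ln): %g\n",
              x$lognormal_sigma, x$batch_sd))
  cat(sprintf("  run-dropout logistic: intercept %g, slope %g on log2 intensity\n",
              x$missing_logistic[1], x$missing_logistic[2]))
  invisible(x)
}
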