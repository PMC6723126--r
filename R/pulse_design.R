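#' Time-course design for a light-pulse experiment
#'
#' Describes the sampling scheme of a pulse-chase style experiment: mycelium
#' (or any culture) receives a brief light pulse and is returned to darkness;
#' samples are harvested at fixed times after the pulse, separately for the
#' transcript and the protein layer, alongside a never-illuminated dark
#' control. Each biological replicate of the protein layer corresponds to one
#' isobaric-labelling (TMT) run pooling all conditions, so the replicate id
#' doubles as the batch id.
#'
#' Condition labels follow the field convention `5L <t>D` (5 min light, then
#' `t` min dark), written without spaces (`5L0D`, `5L10D`, ...) so they are
#' valid column names; the control is `DD`.
#'
#' @param transcript_times Ordered minutes-after-pulse at which the transcript
#'   layer is sampled. Default `c(0, 10, 25, 55, 115)`.
#' @param protein_times Ordered minutes-after-pulse for the protein layer.
#'   Default `c(10, 25, 55, 115, 235)`.
#' @param pulse_minutes Duration of the light pulse in minutes (> 0).
#' @param control_label Name of the dark control condition.
#' @param n_replicates Biological replicates per layer (>= 2).
#' @param seed Integer seed attached to the design; used as the default seed
#'   by [simulate_light_pulse()].
#'
#' @return An object of class `pulse_design`.
#' @examples
#' d <- pulse_design()
#' design_conditions(d, "protein")
#' @export
pulse_design <- function(transcript_times = c(0, 10, 25, 55, 115),
                         protein_times = c(10, 25, 55, 115, 235),
                         pulse_minutes = 5,
                         control_label = "DD",
                         n_replicates = 3,
                         seed = 1L) {
  stopifnot(is.numeric(transcript_times), is.numeric(protein_times),
            length(transcript_times) >= 1, length(protein_times) >= 1)
  if (any(transcript_times < 0) || any(protein_times < 0))
    stop("sampling times must be nonnegative minutes after the pulse")
  if (any(diff(transcript_times) <= 0) || any(diff(protein_times) <= 0))
    stop("sampling times must be strictly increasing")
  if (!is.numeric(pulse_minutes) || length(pulse_minutes) != 1 || pulse_minutes <= 0)
    stop("pulse_minutes must be a single positive number")
  if (!is.character(control_label) || length(control_label) != 1 || !nzchar(control_label))
    stop("control_label must be a non-empty string")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (control_label %in% c(.cond_label(transcript_times), .cond_label(protein_times)))
    stop("control_label collides with a pulse condition label")
  structure(
    list(transcript_times = as.numeric(transcript_times),
         protein_times = as.numeric(protein_times),
         pulse_minutes = as.numeric(pulse_minutes),
         control_label = control_label,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "pulse_design")
}

# "5L<t>D" labels, control handled separately
.cond_label <- function(minutes) paste0("5L", format(minutes, trim = TRUE, scientific = FALSE), "D")

.layer_times <- function(design, layer) {
  switch(match.arg(layer, c("transcript", "protein")),
         transcript = design$transcript_times,
         protein = design$protein_times)
}

#' Conditions of one omics layer
#'
#' @param design A [pulse_design()].
#' @param layer `"transcript"` or `"protein"`.
#' @return A data.frame with columns `condition`, `minutes` (NA for the dark
#'   control) and `is_control`, control first.
#' @export
design_conditions <- function(design, layer = c("transcript", "protein")) {
  stopifnot(inherits(design, "pulse_design"))
  times <- .layer_times(design, match.arg(layer))
  data.frame(condition = c(design$control_label, .cond_label(times)),
             minutes = c(NA_real_, times),
             is_control = c(TRUE, rep(FALSE, length(times))),
             stringsAsFactors = FALSE)
}

#' Sample sheet of one omics layer
#'
#' Expands the design into one row per sample (condition x replicate). The
#' `batch` column equals the replicate id: each protein replicate is one
#' labelling run and each transcript replicate one library batch.
#'
#' @inheritParams design_conditions
#' @return data.frame with columns `sample`, `condition`, `minutes`,
#'   `replicate`, `batch`, `is_control`.
#' @export
sample_table <- function(design, layer = c("transcript", "protein")) {
  conds <- design_conditions(design, layer)
  reps <- seq_len(design$n_replicates)
  out <- expand.grid(replicate = reps, condition = conds$condition,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$condition, conds$condition), out$replicate), ]
  out$minutes <- conds$minutes[match(out$condition, conds$condition)]
  out$is_control <- conds$is_control[match(out$condition, conds$condition)]
  out$batch <- paste0("R", out$replicate)
  out$sample <- paste0(out$condition, "_R", out$replicate)
  rownames(out) <- NULL
  out[, c("sample", "condition", "minutes", "replicate", "batch", "is_control")]
}

#' @export
print.pulse_design <- function(x, ...) {
  cat("Light-pulse time-course design\n")
  cat(sprintf("  pulse: %g min light, then dark\n", x$pulse_minutes))
  cat(sprintf("  transcript times (min after pulse): %s\n",
              paste(x$transcript_times, collapse = ", ")))
  cat(sprintf("  protein times    (min after pulse): %s\n",
              paste(x$protein_times, collapse = ", ")))
  cat(sprintf("  control: %s; replicates per layer: %d; seed: %d\n",
              x$control_label, x$n_replicates, x$seed))
  invisible(x)
}
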