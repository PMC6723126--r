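# round-half-up at `digits` decimals (round() rounds half to even)
.round_halfup <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a percent, field style
#'
#' Percentages below 10 are reported with two decimals, others with one,
#' always rounding half-up; up/down splits within a regulated set are
#' conventionally reported as whole percents (`digits = 0`).
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Override the decimal rule with a fixed number of digits.
#' @return Numeric percent value.
#' @export
percent_of <- function(num, den, digits = NULL) {
  if (den == 0) return(0)
  x <- 100 * num / den
  if (is.null(digits)) digits <- if (x < 10) 2 else 1
  .round_halfup(x, digits)
}

#' Summary report of a combined light-response analysis
#'
#' Computes the standard narrative numbers from layer-wise counts: percent of
#' the genome and of the evaluated features regulated per layer, up/down
#' splits (whole percents), the protein final-time-point peak fraction, and
#' an echo of the category partition. All percents are recomputable from the
#' counts by [percent_of()].
#'
#' @param partition A [partition_categories()] result.
#' @param n_mrna_up,n_mrna_down Up/downregulated transcript counts (must sum
#'   to the partition's regulated mRNA count).
#' @param n_protein_up,n_protein_down Up/downregulated protein counts.
#' @param n_protein_final_peak Number of regulated proteins peaking at the
#'   final time point (optional; `NA` to omit).
#' @return List of class `light_summary`.
#' @export
light_summary <- function(partition, n_mrna_up, n_mrna_down,
                          n_protein_up, n_protein_down,
                          n_protein_final_peak = NA_integer_) {
  stopifnot(inherits(partition, "category_partition"))
  if (n_mrna_up + n_mrna_down != partition$n_mrna_regulated)
    stop("mRNA up + down must equal the regulated count")
  if (n_protein_up + n_protein_down != partition$n_protein_regulated)
    stop("protein up + down must equal the regulated count")
  p <- partition
  out <- list(
    genome_size = p$n_genome,
    n_mrna_evaluated = p$n_mrna_evaluated,
    n_protein_evaluated = p$n_protein_evaluated,
    n_mrna_regulated = p$n_mrna_regulated,
    n_protein_regulated = p$n_protein_regulated,
    n_mrna_up = n_mrna_up, n_mrna_down = n_mrna_down,
    n_protein_up = n_protein_up, n_protein_down = n_protein_down,
    pct_genome_mrna_regulated = percent_of(p$n_mrna_regulated, p$n_genome),
    pct_genome_mrna_evaluated = percent_of(p$n_mrna_evaluated, p$n_genome),
    pct_genome_protein_evaluated = percent_of(p$n_protein_evaluated, p$n_genome),
    pct_evaluated_mrna_regulated = percent_of(p$n_mrna_regulated, p$n_mrna_evaluated),
    pct_evaluated_protein_regulated = percent_of(p$n_protein_regulated, p$n_protein_evaluated),
    pct_mrna_up = percent_of(n_mrna_up, p$n_mrna_regulated, digits = 0),
    pct_mrna_down = percent_of(n_mrna_down, p$n_mrna_regulated, digits = 0),
    pct_protein_up = percent_of(n_protein_up, p$n_protein_regulated, digits = 0),
    pct_protein_down = percent_of(n_protein_down, p$n_protein_regulated, digits = 0),
    n_protein_final_peak = n_protein_final_peak,
    pct_protein_final_peak = if (is.na(n_protein_final_peak)) NA_real_ else
      .round_halfup(100 * n_protein_final_peak / p$n_protein_regulated, 1),
    partition = p)
  class(out) <- "light_summary"
  out
}

#' Summarize regulation calls of both layers
#'
#' Convenience wrapper deriving the counts for [light_summary()] from
#' `regulation_calls` objects and a partition.
#'
#' @param transcript_calls,protein_calls `regulation_calls` data.frames.
#' @param partition A [partition_categories()] result.
#' @return A `light_summary`.
#' @export
summarize_calls <- function(transcript_calls, protein_calls, partition) {
  tr <- transcript_calls[transcript_calls$regulated, , drop = FALSE]
  pr <- protein_calls[protein_calls$regulated, , drop = FALSE]
  pts <- peak_time_summary(protein_calls)
  light_summary(partition,
                n_mrna_up = sum(tr$direction == "up"),
                n_mrna_down = sum(tr$direction == "down"),
                n_protein_up = sum(pr$direction == "up"),
                n_protein_down = sum(pr$direction == "down"),
                n_protein_final_peak = pts$n_final)
}

#' @export
print.light_summary <- function(x, ...) {
  cat("Light-response summary\n")
  cat(sprintf("  mRNAs: %d regulated of %d evaluated (%.4g%% of evaluated, %.4g%% of genome %d)\n",
              x$n_mrna_regulated, x$n_mrna_evaluated,
              x$pct_evaluated_mrna_regulated, x$pct_genome_mrna_regulated,
              x$genome_size))
  cat(sprintf("    up %d (%g%%), down %d (%g%%)\n", x$n_mrna_up, x$pct_mrna_up,
              x$n_mrna_down, x$pct_mrna_down))
  cat(sprintf("  proteins: %d regulated of %d evaluated (%.4g%%)\n",
              x$n_protein_regulated, x$n_protein_evaluated,
              x$pct_evaluated_protein_regulated))
  cat(sprintf("    up %d (%g%%), down %d (%g%%)\n", x$n_protein_up,
              x$pct_protein_up, x$n_protein_down, x$pct_protein_down))
  if (!is.na(x$n_protein_final_peak))
    cat(sprintf("    peak at final time point: %d (%g%%)\n",
                x$n_protein_final_peak, x$pct_protein_final_peak))
  cat(sprintf("  pairs %d; protein-only %d; mRNA-only with protein data %d; no protein data %d\n",
              x$partition$n_pairs, x$partition$n_protein_only,
              x$partition$n_mrna_only_with_protein_data,
              x$partition$n_mrna_only_no_protein_data))
  invisible(x)
}
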