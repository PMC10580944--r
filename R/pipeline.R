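# half-up rounding for human-facing percentages/correlations
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Basic genome statistics
#'
#' Length counts every character including N; GC percent excludes N from
#' both numerator and denominator. The percent is reported rounded half-up
#' to 2 decimals; `gc_fraction` keeps full precision.
#'
#' @param rec A [seq_record] or DNA string.
#' @return List with `length_bp`, `gc_percent` (2 decimals; `NA` for an
#'   all-N sequence) and `gc_fraction` (full precision).
#' @examples
#' genome_stats("ATGC")$gc_percent  # 50
#' @export
genome_stats <- function(rec) {
  rec <- as_seq_record(rec)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(rec$seq),
                                        letters = c("A", "C", "G", "T"))
  acgt <- sum(counts)
  if (acgt == 0L)
    return(list(length_bp = rec$length, gc_percent = NA_real_,
                gc_fraction = NA_real_))
  gc <- (counts[["C"]] + counts[["G"]]) / acgt
  list(length_bp = rec$length, gc_percent = round_half_up(100 * gc, 2L),
       gc_fraction = gc)
}

#' Run the full compositional analysis pipeline
#'
#' Executes genome stats, the sliding-window tetranucleotide scan with
#' anomaly calling, and the GC-skew origin/terminus prediction; writes the
#' window table, flagged-region BED, per-feature table (when an annotation
#' is given), skew table, and a JSON run summary. Analyses contain no
#' randomness, so re-running with the same inputs reproduces identical
#' files.
#'
#' @param genome Path to a FASTA file, or a [seq_record].
#' @param features Optional path to an annotation (or a feature
#'   data.frame as from [read_features()]).
#' @param features_format `"tsv"` or `"gff3"`.
#' @param out_prefix Output path prefix; when `NULL` nothing is written.
#' @param window,step Tetranucleotide scan window/step (default 10000/1000).
#' @param skew_window,skew_step GC-skew window/step (default 500/100).
#' @param threshold Fixed anomaly threshold, or `NULL` for median - 3 MAD.
#' @return An object of class `run_summary` (also written as
#'   `<prefix>.summary.json`).
#' @export
run_all <- function(genome, features = NULL, features_format = "tsv",
                    out_prefix = NULL, window = 10000L, step = 1000L,
                    skew_window = 500L, skew_step = 100L, threshold = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage: ", conditionMessage(e), call. = FALSE))
  }
  rec <- stage("input", {
    if (inherits(genome, "seq_record")) genome else read_fasta(genome)
  })
  feats <- stage("input", {
    if (is.null(features)) NULL
    else if (is.data.frame(features)) validate_features(features, rec)
    else read_features(features, features_format, record = rec)
  })
  stats <- stage("stats", genome_stats(rec))
  profile <- stage("tetra-scan", window_profile(rec, window, step))
  anomalies <- stage("tetra-scan", call_anomalies(profile, feats, threshold))
  skew <- stage("gc-skew", skew_profile(rec, skew_window, skew_step))

  r <- profile$windows$r
  i_min <- if (all(is.na(r))) NA_integer_ else which.min(r)
  summary <- structure(list(
    genome_id = rec$id,
    length_bp = stats$length_bp,
    gc_percent = stats$gc_percent,
    n_windows = nrow(profile$windows),
    min_r = if (is.na(i_min)) NA_real_ else round_half_up(r[i_min], 2L),
    min_r_window = if (is.na(i_min)) NULL else
      list(start = profile$windows$start[i_min] + 1L,
           end = profile$windows$end[i_min]),
    threshold = anomalies$threshold,
    flagged_regions = if (nrow(anomalies$regions)) data.frame(
      start = anomalies$regions$start + 1L, end = anomalies$regions$end,
      min_r = anomalies$regions$min_r) else data.frame(),
    flagged_features = anomalies$features$feature_id[anomalies$features$flagged],
    origin_pos = skew$origin_pos,
    terminus_pos = skew$terminus_pos,
    version = as.character(packageVersion("phagesig")),
    config = list(window = as.integer(window), step = as.integer(step),
                  skew_window = as.integer(skew_window),
                  skew_step = as.integer(skew_step),
                  threshold = if (is.null(threshold)) "median-3MAD" else threshold,
                  features = !is.null(feats))),
    class = "run_summary")

  if (!is.null(out_prefix)) stage("output", {
    wtab <- data.frame(start = profile$windows$start,
                       end = profile$windows$end,
                       name = paste0("win_", seq_along(r)),
                       score = round_half_up(r, 4L))
    write_interval_table(wtab, paste0(out_prefix, ".windows.tsv"), "tsv")
    if (nrow(anomalies$regions)) {
      btab <- data.frame(start = anomalies$regions$start,
                         end = anomalies$regions$end,
                         name = paste0("anomaly_", seq_len(nrow(anomalies$regions))),
                         score = round_half_up(anomalies$regions$min_r, 4L))
      write_interval_table(btab, paste0(out_prefix, ".flagged.bed"), "bed",
                           chrom = rec$id)
    }
    if (nrow(anomalies$features))
      write.table(anomalies$features, paste0(out_prefix, ".features.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(skew$table, paste0(out_prefix, ".skew.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(summary),
                         paste0(out_prefix, ".summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat("phagesig run summary\n")
  cat(sprintf("  genome:   %s (%d bp, GC %.2f%%)\n",
              x$genome_id, x$length_bp, x$gc_percent))
  cat(sprintf("  windows:  %d; min r = %.2f", x$n_windows, x$min_r))
  if (!is.null(x$min_r_window))
    cat(sprintf(" at %d-%d", x$min_r_window$start, x$min_r_window$end))
  cat("\n")
  cat(sprintf("  anomaly threshold r < %.4f; %d region(s) flagged\n",
              x$threshold, nrow(x$flagged_regions)))
  if (length(x$flagged_features))
    cat("  flagged features:", paste(x$flagged_features, collapse = ", "), "\n")
  cat(sprintf("  replication origin %d nt, terminus %d nt (cumulative GC skew)\n",
              x$origin_pos, x$terminus_pos))
  invisible(x)
}
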