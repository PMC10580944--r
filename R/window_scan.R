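#' Sliding windows over a sequence
#'
#' Window starts at 0, step, 2·step, ... while start < L; each window ends
#' at `min(start + window, L)`. With `include_truncated = TRUE` (the
#' default) the truncated terminal windows are kept, so the number of
#' windows is `ceiling(L / step)`; a 40,452 bp genome at 10 kb / 1 kb gives
#' 41 windows.
#'
#' @param L Sequence length (>= 1).
#' @param window Window size in bp (default 10000).
#' @param step Step size in bp (default 1000); `window >= step >= 1`.
#' @param include_truncated Keep terminal windows shorter than `window`?
#' @return Data.frame with columns `start` (0-based) and `end` (exclusive).
#' @export
make_windows <- function(L, window = 10000L, step = 1000L,
                         include_truncated = TRUE) {
  L <- as.integer(L); window <- as.integer(window); step <- as.integer(step)
  if (is.na(L) || L < 1L) stop("L must be >= 1")
  if (is.na(window) || is.na(step) || step < 1L || window < step)
    stop("window/step must satisfy window >= step >= 1")
  starts <- seq.int(0L, L - 1L, by = step)
  ends <- pmin(starts + window, L)
  if (!include_truncated) {
    keep <- (ends - starts) == window
    starts <- starts[keep]; ends <- ends[keep]
  }
  data.frame(start = starts, end = ends)
}

#' Sliding-window tetranucleotide correlation profile
#'
#' Computes the tetranucleotide composition of the whole genome once (on
#' the rc-extended genome) and of every sliding window (each on its own
#' rc-extended subsequence), and the Pearson correlation r of each window
#' against the genome. Windows whose composition vector has zero variance
#' carry a missing r; a window identical in composition to the genome
#' returns exactly 1.0.
#'
#' Two correlation methods are available. `"frequency"` (the default)
#' correlates the 256 tetranucleotide frequency vectors directly, so
#' differences at any compositional order (GC content, dinucleotide bias,
#' tetramer preference) depress r. `"zscore"` correlates the maximal-order
#' Markov Z-score vectors ([tetra_signature()]); because each window's
#' Z-scores are standardized against that window's own di-/trinucleotide
#' counts, this variant responds only to tetramer structure beyond order 2
#' and is blind to foreign regions whose divergence is (like most GC-shift
#' driven horizontal transfers) of low order. See the package vignette for
#' the full argument.
#'
#' @param rec A [seq_record] or DNA string.
#' @param method `"frequency"` (default) or `"zscore"`; see Details.
#' @inheritParams make_windows
#' @return An object of class `tetra_profile`: list with `windows`
#'   (data.frame `start`, `end`, `r`), `genome_signature` (Z-score
#'   signature of the whole genome), `spec`.
#' @export
window_profile <- function(rec, window = 10000L, step = 1000L,
                           include_truncated = TRUE,
                           method = c("frequency", "zscore")) {
  method <- match.arg(method)
  rec <- as_seq_record(rec)
  wins <- make_windows(rec$length, window, step, include_truncated)
  subs <- substring(rec$seq, wins$start + 1L, wins$end)
  rcs <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(subs)))
  ext <- paste0(subs, "N", rcs)
  dss <- Biostrings::DNAStringSet(c(rc_extend(rec$seq), ext))
  o2 <- Biostrings::oligonucleotideFrequency(dss, width = 2L)
  o3 <- Biostrings::oligonucleotideFrequency(dss, width = 3L)
  o4 <- Biostrings::oligonucleotideFrequency(dss, width = 4L)
  vecs <- if (method == "zscore") {
    lapply(seq_len(nrow(o2)), function(i)
      zscores_from_counts(o2[i, ], o3[i, ], o4[i, ])$z)
  } else {
    lapply(seq_len(nrow(o4)), function(i) {
      tot <- sum(o4[i, ])
      if (tot == 0) rep(0, 256L) else as.numeric(o4[i, ]) / tot
    })
  }
  vg <- vecs[[1L]]
  r <- vapply(vecs[-1L], function(vw) {
    if (stats::sd(vw) == 0 || stats::sd(vg) == 0) return(NA_real_)
    if (identical(vw, vg)) return(1.0)
    cor(vw, vg)
  }, numeric(1))
  zzg <- zscores_from_counts(o2[1L, ], o3[1L, ], o4[1L, ])
  genome_sig <- structure(
    list(z = setNames(zzg$z, colnames(o4)), obs = o4[1L, ],
         exp = zzg$exp, var = zzg$var),
    class = "tetra_signature")
  structure(list(windows = cbind(wins, r = r),
                 method = method,
                 genome_signature = genome_sig,
                 genome_id = rec$id, genome_length = rec$length,
                 spec = list(window = as.integer(window),
                             step = as.integer(step),
                             include_truncated = include_truncated)),
            class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  r <- x$windows$r
  cat("<tetra_profile> ", x$genome_id, ": ", nrow(x$windows),
      " windows (", x$spec$window, "/", x$spec$step, " bp)\n", sep = "")
  if (any(!is.na(r))) {
    i <- which.min(r)
    cat(sprintf("  r: min %.4f at [%d, %d], median %.4f\n",
                min(r, na.rm = TRUE), x$windows$start[i] + 1L,
                x$windows$end[i], median(r, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.tetra_profile <- function(object, ...) {
  r <- object$windows$r
  out <- list(n_windows = nrow(object$windows),
              n_missing = sum(is.na(r)),
              min_r = if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE),
              median_r = median(r, na.rm = TRUE),
              mad_r = mad(r, na.rm = TRUE))
  class(out) <- "summary.tetra_profile"
  out
}

#' @export
print.summary.tetra_profile <- function(x, ...) {
  cat("Sliding-window tetranucleotide correlation profile\n")
  cat(sprintf("  windows: %d (%d with undefined r)\n", x$n_windows, x$n_missing))
  cat(sprintf("  r: min %.4f, median %.4f, MAD %.4f\n",
              x$min_r, x$median_r, x$mad_r))
  invisible(x)
}

#' Plot a correlation profile
#'
#' Window correlation r against window midpoint, with the anomaly threshold
#' drawn when supplied.
#'
#' @param x A `tetra_profile`.
#' @param threshold Optional threshold line (e.g. from [call_anomalies()]).
#' @param ... Passed to [plot()].
#' @export
plot.tetra_profile <- function(x, threshold = NULL, ...) {
  mid <- (x$windows$start + x$windows$end) / 2
  plot(mid, x$windows$r, type = "b", pch = 20,
       xlab = "genome position (bp)",
       ylab = "tetranucleotide correlation r", ...)
  if (!is.null(threshold)) abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Call compositionally anomalous regions and map them to features
#'
#' Windows with r below the threshold are flagged and merged into maximal
#' regions (merged when overlapping or separated by at most `step`). The
#' default threshold is the robust rule `median(r) - 3 * MAD(r)` (MAD with
#' the usual 1.4826 consistency constant); pass a fixed value to override.
#' Each feature is scored by the minimum r over the windows overlapping it
#' (a feature is as anomalous as its worst window) and flagged when that
#' score falls below the threshold. Windows with missing r are excluded
#' from the threshold computation and never flagged.
#'
#' Correlations are not comparable across window lengths (short windows
#' attenuate r through counting noise), so windows shorter than `min_len`
#' are excluded from the threshold estimate and never flagged. The default
#' `min_len` is the profile's nominal window size capped at the genome
#' length, i.e. only full-length windows are flaggable except on a genome
#' shorter than one window.
#'
#' @param profile A `tetra_profile` from [window_profile()].
#' @param features Optional feature data.frame from [read_features()].
#' @param threshold Fixed numeric threshold, or `NULL` for the robust rule.
#' @param min_len Minimum window length eligible for flagging; `NULL` for
#'   the default above, 0 to consider every window.
#' @return An object of class `anomaly_call`: list with `regions`
#'   (data.frame `start`, `end`, `min_r`), `features` (data.frame
#'   `feature_id`, `min_r`, `flagged`), `threshold`.
#' @export
call_anomalies <- function(profile, features = NULL, threshold = NULL,
                           min_len = NULL) {
  stopifnot(inherits(profile, "tetra_profile"))
  w <- profile$windows
  ok <- !is.na(w$r)
  if (!any(ok)) stop("degenerate profile: all window correlations missing")
  if (is.null(min_len))
    min_len <- min(profile$spec$window, profile$genome_length)
  eligible <- ok & (w$end - w$start) >= min_len
  cut <- if (is.null(threshold)) {
    if (!any(eligible)) -Inf
    else median(w$r[eligible]) - 3 * mad(w$r[eligible])
  } else as.numeric(threshold)
  flagged <- eligible & w$r < cut
  step <- profile$spec$step
  regions <- merge_flagged(w[flagged, , drop = FALSE], gap = step)

  feat_out <- data.frame(feature_id = character(), min_r = numeric(),
                         flagged = logical(), stringsAsFactors = FALSE)
  if (!is.null(features) && nrow(features) > 0L) {
    fmin <- vapply(seq_len(nrow(features)), function(i) {
      hit <- eligible & w$start < features$end[i] & w$end > features$start[i]
      if (!any(hit)) return(NA_real_)
      min(w$r[hit])
    }, numeric(1))
    feat_out <- data.frame(feature_id = features$feature_id, min_r = fmin,
                           flagged = !is.na(fmin) & fmin < cut,
                           stringsAsFactors = FALSE)
  }
  structure(list(regions = regions, features = feat_out, threshold = cut),
            class = "anomaly_call")
}

# Merge flagged windows into maximal regions; adjacent = gap <= `gap` bp.
merge_flagged <- function(flagged, gap) {
  empty <- data.frame(start = integer(), end = integer(), min_r = numeric())
  if (nrow(flagged) == 0L) return(empty)
  flagged <- flagged[order(flagged$start), , drop = FALSE]
  starts <- flagged$start[1L]; ends <- flagged$end[1L]; mins <- flagged$r[1L]
  for (i in seq_len(nrow(flagged))[-1L]) {
    j <- length(starts)
    if (flagged$start[i] - ends[j] <= gap) {
      ends[j] <- max(ends[j], flagged$end[i])
      mins[j] <- min(mins[j], flagged$r[i])
    } else {
      starts <- c(starts, flagged$start[i])
      ends <- c(ends, flagged$end[i])
      mins <- c(mins, flagged$r[i])
    }
  }
  data.frame(start = starts, end = ends, min_r = mins)
}

#' @export
print.anomaly_call <- function(x, ...) {
  cat("<anomaly_call> threshold r <", format(x$threshold, digits = 4), "\n")
  if (nrow(x$regions) == 0L) {
    cat("  no anomalous regions\n")
  } else {
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("  region %d: %d-%d (min r = %.4f)\n", i,
                  x$regions$start[i] + 1L, x$regions$end[i],
                  x$regions$min_r[i]))
  }
  if (nrow(x$features) > 0L)
    cat("  flagged features:",
        if (any(x$features$flagged))
          paste(x$features$feature_id[x$features$flagged], collapse = ", ")
        else "none", "\n")
  invisible(x)
}
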