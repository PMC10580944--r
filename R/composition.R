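#' Reverse complement of a DNA string
#'
#' Watson–Crick complement, reversed; N is self-complementary.
#'
#' @param seq Normalized DNA string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Reverse-complement extension
#'
#' Concatenates a sequence with its reverse complement, separated by a
#' single N so that no k-mer spans the junction. Counting k-mers on the
#' extension makes the resulting signature strand-independent: a sequence
#' and its reverse complement yield identical counts.
#'
#' @param seq Normalized DNA string of length L.
#' @return A string of length 2L + 1.
#' @examples
#' rc_extend("AAAA")  # "AAAANTTTT"
#' @export
rc_extend <- function(seq) {
  paste0(seq, "N", reverse_complement(seq))
}

#' Count k-mers in a sequence
#'
#' Sliding count of every k-length window consisting solely of A/C/G/T;
#' windows containing N (or any degraded character) are tallied in
#' `n_skipped`, so `sum(counts) + n_skipped == L - k + 1`.
#'
#' @param seq Normalized DNA string.
#' @param k Word size, one of 2, 3, 4.
#' @return An object of class `kmer_counts`: list with `k`, `counts`
#'   (named integer vector of length 4^k in lexicographic A<C<G<T order)
#'   and `n_skipped`.
#' @export
count_kmers <- function(seq, k) {
  if (!(length(k) == 1L && k %in% c(2L, 3L, 4L)))
    stop("k must be one of 2, 3, 4")
  seq <- if (inherits(seq, "seq_record")) seq$seq else seq
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  n_windows <- max(nchar(seq) - k + 1L, 0L)
  structure(list(k = as.integer(k), counts = counts,
                 n_skipped = n_windows - sum(counts)),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> k=", x$k, ", ", sum(x$counts), " words counted, ",
      x$n_skipped, " windows skipped (N)\n", sep = "")
  invisible(x)
}

# Z-scores from raw count vectors of the same rc-extended sequence.
# E(n1n2n3n4) = N(n1n2n3) N(n2n3n4) / N(n2n3); Var = E (N2-N3p)(N2-N3s)/N2^2;
# conventions: E = Var = Z = 0 wherever N(n2n3) = 0, Z = 0 wherever Var = 0.
# Index arithmetic relies on lexicographic A<C<G<T ordering of all tables.
zscores_from_counts <- function(n2, n3, n4) {
  n2 <- as.numeric(n2); n3 <- as.numeric(n3); n4 <- as.numeric(n4)
  t0 <- 0:255
  i_pre  <- t0 %/% 4L + 1L          # n1n2n3
  i_suf  <- t0 %% 64L + 1L          # n2n3n4
  i_mid  <- (t0 %% 64L) %/% 4L + 1L # n2n3
  denom <- n2[i_mid]
  e <- ifelse(denom > 0, n3[i_pre] * n3[i_suf] / denom, 0)
  v <- ifelse(denom > 0,
              e * (denom - n3[i_pre]) * (denom - n3[i_suf]) / denom^2, 0)
  z <- ifelse(v > 0, (n4 - e) / sqrt(v), 0)
  list(z = z, exp = e, var = v)
}

#' Tetranucleotide Z-scores under the maximal-order Markov model
#'
#' For each tetranucleotide w = n1n2n3n4 the expected count under the
#' maximal-order (trinucleotide-conditional) Markov model is
#' `E(w) = N(n1n2n3) N(n2n3n4) / N(n2n3)`, with variance approximation
#' `Var(w) = E(w) (N(n2n3)-N(n1n2n3)) (N(n2n3)-N(n2n3n4)) / N(n2n3)^2`,
#' and `Z(w) = (N(w) - E(w)) / sqrt(Var(w))`. By convention Z(w) = 0
#' wherever Var(w) = 0 (including N(n2n3) = 0), so no division by zero is
#' reachable for any input.
#'
#' All three count tables must come from the same rc-extended sequence;
#' consistency is checked through the table-sum invariant.
#'
#' @param c2,c3,c4 `kmer_counts` for k = 2, 3, 4 of one rc-extended sequence.
#' @return An object of class `tetra_signature`: list with `z`, `obs`,
#'   `exp`, `var`, each length 256 in lexicographic order.
#' @seealso [tetra_signature()] for the one-call version.
#' @export
tetra_zscores <- function(c2, c3, c4) {
  stopifnot(inherits(c2, "kmer_counts"), inherits(c3, "kmer_counts"),
            inherits(c4, "kmer_counts"))
  if (c2$k != 2L || c3$k != 3L || c4$k != 4L)
    stop("expected kmer_counts with k = 2, 3, 4 in that order")
  implied_L <- c(sum(c2$counts) + c2$n_skipped + 1L,
                 sum(c3$counts) + c3$n_skipped + 2L,
                 sum(c4$counts) + c4$n_skipped + 3L)
  if (length(unique(implied_L)) != 1L)
    stop("count tables imply different source-sequence lengths: ",
         paste(implied_L, collapse = ", "))
  zz <- zscores_from_counts(c2$counts, c3$counts, c4$counts)
  structure(list(z = setNames(zz$z, names(c4$counts)),
                 obs = c4$counts, exp = zz$exp, var = zz$var),
            class = "tetra_signature")
}

#' @export
print.tetra_signature <- function(x, ...) {
  cat("<tetra_signature> 256 tetranucleotide Z-scores\n")
  cat(sprintf("  mean(Z) = %.3f, sd(Z) = %.3f, range [%.2f, %.2f]\n",
              mean(x$z), stats::sd(x$z), min(x$z), max(x$z)))
  ext <- order(abs(x$z), decreasing = TRUE)[1:5]
  cat("  most deviant:",
      paste(sprintf("%s (%.2f)", names(x$z)[ext], x$z[ext]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tetranucleotide signature of a sequence
#'
#' Convenience wrapper: rc-extends the sequence, counts 2/3/4-mers and
#' returns [tetra_zscores()]. The signature of a sequence equals the
#' signature of its reverse complement exactly.
#'
#' @param seq A [seq_record] or DNA string.
#' @return A `tetra_signature`.
#' @export
tetra_signature <- function(seq) {
  seq <- if (inherits(seq, "seq_record")) seq$seq else seq
  ext <- rc_extend(seq)
  tetra_zscores(count_kmers(ext, 2L), count_kmers(ext, 3L),
                count_kmers(ext, 4L))
}

#' Pearson correlation of two tetranucleotide signatures
#'
#' Returns the Pearson product-moment correlation of the two Z-score
#' vectors. Identical vectors return exactly 1.0; if either vector has zero
#' variance the correlation is undefined and `NA` is returned.
#'
#' @param a,b `tetra_signature` objects (or bare numeric vectors of equal
#'   length).
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
signature_correlation <- function(a, b) {
  za <- if (inherits(a, "tetra_signature")) a$z else a
  zb <- if (inherits(b, "tetra_signature")) b$z else b
  if (length(za) != length(zb))
    stop("signature length mismatch: ", length(za), " vs ", length(zb))
  if (stats::sd(za) == 0 || stats::sd(zb) == 0) return(NA_real_)
  if (identical(unname(za), unname(zb))) return(1.0)
  unname(cor(za, zb))
}
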