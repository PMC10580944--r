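# shared fixtures: all generated in code, nothing read from disk

write_tmp_fasta <- function(lines, ext = ".fasta") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force k-mer oracle: enumerate every substring
brute_kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  lv <- sort(do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                         stringsAsFactors = FALSE)))
  if (n < k) return(setNames(integer(4^k), lv))
  subs <- substring(seq, 1:(n - k + 1), k:n)
  valid <- !grepl("[^ACGT]", subs)
  counts <- table(factor(subs[valid], levels = lv))
  setNames(as.integer(counts), lv)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a tetra_profile built by hand (for caller logic tests)
fake_profile <- function(r, window = 10000L, step = 1000L, L = NULL) {
  n <- length(r)
  starts <- (seq_len(n) - 1L) * step
  if (is.null(L)) L <- starts[n] + window
  structure(list(windows = data.frame(start = starts,
                                      end = pmin(starts + window, L),
                                      r = r),
                 method = "frequency",
                 genome_signature = NULL, genome_id = "fake",
                 genome_length = L,
                 spec = list(window = window, step = step,
                             include_truncated = TRUE)),
            class = "tetra_profile")
}

default_truth_start <- 28000L
default_truth_end <- 34000L
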