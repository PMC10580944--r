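BASES <- c("A", "C", "G", "T")

# contexts of length m in lexicographic order, "" for m = 0
markov_contexts <- function(m) {
  if (m == 0L) return("")
  do.call(paste0, rev(lapply(seq_len(m), function(i)
    rep(rep(BASES, each = 4^(i - 1L)), times = 4^(m - i)))))
}

new_markov_model <- function(order, transition, initial) {
  K <- 4^order
  stopifnot(nrow(transition) == K, ncol(transition) == 4L,
            length(initial) == K)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must be non-negative and sum to 1")
  rownames(transition) <- markov_contexts(order)
  colnames(transition) <- BASES
  structure(list(order = as.integer(order), transition = transition,
                 initial = setNames(initial, markov_contexts(order))),
            class = "markov_model")
}

#' Homogeneous Markov model from a target GC content
#'
#' Builds a context-independent model (replicated across all contexts of
#' the requested order) with `P(G) = gc/2 * (1 + skew)`,
#' `P(C) = gc/2 * (1 - skew)`, `P(A) = P(T) = (1 - gc)/2`. The initial
#' context distribution is the stationary one (products of the base
#' probabilities).
#'
#' @param gc Target GC content in (0, 1).
#' @param order Markov order m in 0, 1, 2.
#' @param skew G-vs-C skew in (-1, 1); positive means G-rich.
#' @return A `markov_model`.
#' @examples
#' markov_from_gc(0.5764, order = 2)
#' @export
markov_from_gc <- function(gc, order = 2L, skew = 0) {
  if (!(is.numeric(gc) && length(gc) == 1L && gc > 0 && gc < 1))
    stop("gc must lie strictly between 0 and 1")
  if (!(order %in% 0:2)) stop("order must be 0, 1 or 2")
  if (!(is.numeric(skew) && abs(skew) < 1)) stop("|skew| must be < 1")
  p <- c(A = (1 - gc) / 2, C = gc / 2 * (1 - skew),
         G = gc / 2 * (1 + skew), T = (1 - gc) / 2)
  K <- 4^order
  trans <- matrix(rep(p, each = K), nrow = K)
  init <- vapply(strsplit(markov_contexts(order), ""), function(ctx)
    prod(p[ctx]), numeric(1))
  if (order == 0L) init <- 1
  m <- new_markov_model(order, trans, init)
  attr(m, "gc") <- gc
  m
}

#' Fit a Markov model to a sequence
#'
#' Maximum-likelihood transition estimates from (order+1)-mer counts with
#' add-one smoothing (rows renormalized); the initial context distribution
#' is the empirical order-mer frequency.
#'
#' @param seq A [seq_record] or DNA string of length >= `10 * 4^(order+1)`.
#' @param order Markov order in 0, 1, 2.
#' @return A `markov_model`.
#' @export
fit_markov <- function(seq, order = 2L) {
  seq <- if (inherits(seq, "seq_record")) seq$seq else seq
  if (!(order %in% 0:2)) stop("order must be 0, 1 or 2")
  min_len <- 10 * 4^(order + 1)
  if (nchar(seq) < min_len)
    stop("sequence too short to fit order-", order, " model (need >= ",
         min_len, " bp)")
  k <- order + 1L
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = k)
  # rows = contexts (first `order` bases), cols = next base; lexicographic
  cmat <- matrix(as.numeric(counts), ncol = 4L, byrow = TRUE) + 1
  trans <- cmat / rowSums(cmat)
  init <- if (order == 0L) 1 else {
    ic <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(seq), width = order) + 1
    as.numeric(ic) / sum(ic)
  }
  new_markov_model(order, trans, init)
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order ", x$order, " (", nrow(x$transition),
      " contexts)\n", sep = "")
  gc <- stationary_gc(x)
  cat(sprintf("  stationary GC ~ %.4f\n", gc))
  invisible(x)
}

# mononucleotide frequencies implied by initial-context-weighted transitions
stationary_gc <- function(model) {
  p <- as.numeric(model$initial %*% model$transition)
  p[2L] + p[3L]
}

#' Simulate a sequence from a Markov model
#'
#' The first m bases are drawn from the initial context distribution, the
#' rest from the transition table. Reproducible for a fixed seed; with
#' `seed = NULL` the current RNG stream is used (callers that need several
#' dependent draws seed once themselves).
#'
#' @param model A `markov_model`.
#' @param L Length in bp (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A DNA string of length `L`.
#' @export
simulate_markov <- function(model, L, seed = NULL) {
  stopifnot(inherits(model, "markov_model"))
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- model$order
  K <- 4^m
  homogeneous <- K == 1L ||
    all(abs(sweep(model$transition, 2L, model$transition[1L, ])) < 1e-12)
  if (homogeneous) {
    return(paste(sample(BASES, L, replace = TRUE,
                        prob = model$transition[1L, ]), collapse = ""))
  }
  out <- integer(L)
  ctx <- sample.int(K, 1L, prob = model$initial) - 1L
  # decode initial context into its m bases (most significant first)
  for (i in seq_len(min(m, L)))
    out[i] <- (ctx %/% 4^(m - i)) %% 4L + 1L
  if (L > m) {
    cp <- t(apply(model$transition, 1L, cumsum))
    u <- runif(L - m)
    for (i in seq_len(L - m)) {
      b <- 1L + sum(u[i] > cp[ctx + 1L, ])
      out[m + i] <- b
      ctx <- (ctx * 4L + (b - 1L)) %% K
    }
  }
  paste(BASES[out], collapse = "")
}

#' @rdname simulate_markov
#' @param object A `markov_model` (for the [stats::simulate()] method).
#' @param nsim Number of sequences to simulate.
#' @param ... Must contain `L`; passed on to [simulate_markov()].
#' @return The `simulate` method returns a character vector of `nsim`
#'   sequences.
#' @export
simulate.markov_model <- function(object, nsim = 1, seed = NULL, ...) {
  args <- list(...)
  if (is.null(args$L)) stop("simulate.markov_model needs L = <length>")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nsim), function(i)
    simulate_markov(object, args$L, seed = NULL), character(1))
}

#' Build a chimeric genome with known foreign inserts
#'
#' Simulates a background genome of length `L`, replaces each requested
#' span with sequence simulated from a compositionally distinct donor
#' model, and returns the genome together with the ground-truth insert
#' table and a toy ORF annotation (consecutive non-overlapping tiles of
#' `orf_size` bp named `ORF_1`, `ORF_2`, ...), so downstream anomaly calls
#' can be checked against truth.
#'
#' The defaults emulate a ~40 kb phage genome at GC 57.64% carrying one
#' 6 kb horizontally acquired module at GC 35%.
#'
#' @param background,donor `markov_model`s for the backbone and inserts.
#' @param L Genome length (default 40452).
#' @param insert_spans List of `c(start, length)` pairs (0-based starts),
#'   pairwise disjoint and within `[0, L)`. Default: one 6 kb insert at
#'   28000.
#' @param seed Integer seed (one stream drives background and inserts).
#' @param orf_size Toy ORF tile width in bp.
#' @param genome_id Identifier for the simulated record.
#' @return List with `record` ([seq_record]), `truth` (class
#'   `chimera_truth`: data.frame `start`, `end`, `donor_label` plus model
#'   GC attributes), `features` (toy ORF data.frame as from
#'   [read_features()]).
#' @export
make_chimera <- function(background = markov_from_gc(0.5764, order = 2L),
                         donor = markov_from_gc(0.35, order = 2L),
                         L = 40452L,
                         insert_spans = list(c(28000L, 6000L)),
                         seed = 1L, orf_size = 600L,
                         genome_id = "chimera") {
  L <- as.integer(L)
  spans <- do.call(rbind, lapply(insert_spans, function(s) {
    stopifnot(length(s) == 2L)
    data.frame(start = as.integer(s[1L]), end = as.integer(s[1L] + s[2L]))
  }))
  if (is.null(spans)) spans <- data.frame(start = integer(), end = integer())
  if (nrow(spans) > 0L) {
    spans <- spans[order(spans$start), , drop = FALSE]
    if (any(spans$start < 0L) || any(spans$end > L))
      stop("insert span outside [0, L)")
    if (nrow(spans) > 1L &&
        any(spans$start[-1L] < spans$end[-nrow(spans)]))
      stop("insert spans overlap")
  }
  set.seed(seed)
  genome <- simulate_markov(background, L, seed = NULL)
  for (i in seq_len(nrow(spans))) {
    ins <- simulate_markov(donor, spans$end[i] - spans$start[i], seed = NULL)
    substr(genome, spans$start[i] + 1L, spans$end[i]) <- ins
  }
  truth <- data.frame(start = spans$start, end = spans$end,
                      donor_label = if (nrow(spans)) paste0("donor_", seq_len(nrow(spans)))
                                    else character())
  attr(truth, "background_gc") <- stationary_gc(background)
  attr(truth, "donor_gc") <- stationary_gc(donor)
  attr(truth, "seed") <- seed
  class(truth) <- c("chimera_truth", class(truth))
  n_orf <- L %/% as.integer(orf_size)
  features <- data.frame(
    feature_id = paste0("ORF_", seq_len(n_orf)),
    start = (seq_len(n_orf) - 1L) * as.integer(orf_size),
    end = seq_len(n_orf) * as.integer(orf_size),
    strand = "+", stringsAsFactors = FALSE)
  list(record = seq_record(genome_id, genome), truth = truth,
       features = features)
}

#' Write the three chimera outputs (FASTA, truth TSV, features TSV)
#'
#' @param chimera Result of [make_chimera()].
#' @param out_prefix Path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.truth.tsv`, `<prefix>.features.tsv` (feature/truth TSVs are
#'   1-based inclusive).
#' @return Character vector of the three paths, invisibly.
#' @export
write_chimera <- function(chimera, out_prefix) {
  paths <- paste0(out_prefix, c(".fasta", ".truth.tsv", ".features.tsv"))
  write_fasta(chimera$record, paths[1L])
  truth <- data.frame(donor_label = chimera$truth$donor_label,
                      start = chimera$truth$start + 1L,
                      end = chimera$truth$end)
  write.table(truth, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  feats <- data.frame(feature_id = chimera$features$feature_id,
                      start = chimera$features$start + 1L,
                      end = chimera$features$end,
                      strand = chimera$features$strand)
  write.table(feats, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
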