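#' Sequence record constructor
#'
#' Normalizes a DNA sequence and wraps it with an identifier. Normalization
#' uppercases, maps U to T, and degrades every other IUPAC ambiguity code
#' (and any unexpected character) to N, with a warning stating how many
#' characters were degraded. Normalizing an already-normalized sequence is
#' the identity.
#'
#' @param id Record identifier (single string).
#' @param seq DNA sequence (single string over any IUPAC alphabet).
#' @return An object of class `seq_record` with elements `id`, `seq`
#'   (uppercase over `{A,C,G,T,N}`), and `length`.
#' @examples
#' seq_record("x", "acgu")  # normalized to ACGT
#' @export
seq_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("zero-length sequence for record '", id, "'")
  norm <- as.character(normalize_sequence(seq))
  structure(list(id = id, seq = norm, length = nchar(norm)),
            class = "seq_record")
}

#' @rdname seq_record
#' @param x A string to normalize.
#' @return `normalize_sequence()` returns the normalized string with an
#'   attribute `n_degraded` counting characters mapped to N.
#' @export
normalize_sequence <- function(x) {
  up <- chartr("U", "T", toupper(x))
  bad <- gsub("[ACGTN]", "", up)
  n_bad <- nchar(bad)
  if (n_bad > 0L) {
    up <- gsub("[^ACGTN]", "N", up)
    warning(n_bad, " non-ACGTN character(s) degraded to N", call. = FALSE)
  }
  structure(up, n_degraded = n_bad)
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, ": ", x$length, " bp\n", sep = "")
  head_seq <- substr(x$seq, 1, 60)
  cat("  ", head_seq, if (x$length > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

# Accept either a seq_record or a bare string everywhere downstream.
as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) x else seq_record(id, x)
}

#' Read the first record of a FASTA file
#'
#' Reads a FASTA file and returns its first record as a normalized
#' [seq_record]. A multi-record file triggers a warning naming the record
#' that was kept; phage assemblies are expected to be single-contig.
#'
#' @param path Path to a FASTA file with at least one non-empty record.
#' @return A [seq_record].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  if (length(set) > 1L)
    warning("FASTA has ", length(set), " records; using the first ('",
            names(set)[1L], "')", call. = FALSE)
  id <- sub("\\s.*$", "", names(set)[1L])
  seq <- as.character(set[[1L]])
  if (nchar(seq) == 0L) stop("first FASTA record has zero length: ", path)
  seq_record(id, seq)
}

#' Write a sequence record as FASTA
#'
#' @param rec A [seq_record] (or bare sequence string).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(rec, path, width = 70L) {
  rec <- as_seq_record(rec)
  set <- Biostrings::DNAStringSet(rec$seq)
  names(set) <- rec$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read feature intervals (ORF annotation)
#'
#' Reads an annotation either as a 4-column TSV
#' (`feature_id`, `start`, `end`, `strand`; coordinates 1-based inclusive,
#' header optional) or as GFF3 (lines of type `CDS` or `gene`). Intervals
#' are converted to the internal 0-based half-open convention and sorted by
#' start. A TSV whose fourth column is not a strand symbol (e.g. a score
#' written by [write_interval_table()]) is accepted with strand ".".
#'
#' @param path Annotation file path.
#' @param fmt `"tsv"` or `"gff3"`.
#' @param record Optional [seq_record]; when supplied, intervals are checked
#'   to lie within `[0, L)`.
#' @return A data.frame with columns `feature_id`, `start` (0-based),
#'   `end` (exclusive), `strand`; zero rows for an empty annotation file.
#' @export
read_features <- function(path, fmt = c("tsv", "gff3"), record = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  feats <- if (fmt == "tsv") read_features_tsv(path) else read_features_gff3(path)
  validate_features(feats, record)
}

read_features_tsv <- function(path) {
  empty <- data.frame(feature_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("TSV feature rows need >= 3 columns")
  # header row: second column not numeric
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][2L]))))
    fields <- fields[-1L]
  if (length(fields) == 0L) return(empty)
  id <- vapply(fields, `[`, "", 1L)
  s1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(s1) || anyNA(e1)) stop("non-integer coordinates in feature TSV")
  col4 <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else ".", "")
  strand <- ifelse(col4 %in% c("+", "-", "."), col4, ".")
  data.frame(feature_id = id, start = s1 - 1L, end = e1, strand = strand,
             stringsAsFactors = FALSE)
}

read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  if (length(gr) == 0L)
    return(data.frame(feature_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
        else if ("Name" %in% names(mc) && !all(is.na(mc$Name))) as.character(mc$Name)
        else paste0("feature_", seq_along(gr))
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(feature_id = id,
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand, stringsAsFactors = FALSE)
}

validate_features <- function(feats, record = NULL) {
  if (nrow(feats) == 0L) return(feats)
  if (any(feats$end <= feats$start))
    stop("feature interval with end <= start after coordinate conversion")
  if (anyDuplicated(feats$feature_id))
    stop("duplicate feature ids: ",
         paste(unique(feats$feature_id[duplicated(feats$feature_id)]),
               collapse = ", "))
  if (any(feats$start < 0L)) stop("feature start before sequence origin")
  if (!is.null(record)) {
    record <- as_seq_record(record)
    if (any(feats$end > record$length))
      stop("feature extends past sequence end (L = ", record$length, ")")
  }
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Write scored intervals as BED or TSV
#'
#' BED output is 0-based half-open (`chrom start end name score`); TSV
#' output is 1-based inclusive with a header row
#' (`name`, `start`, `end`, `score`). Both round-trip through
#' [read_features()] (`fmt = "tsv"`) losslessly for coordinates.
#'
#' @param intervals Data.frame with columns `start` (0-based), `end`
#'   (exclusive), `name`, `score`.
#' @param path Output path.
#' @param fmt `"bed"` or `"tsv"`.
#' @param chrom Chromosome/sequence name for the BED first column.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(intervals, path, fmt = c("bed", "tsv"),
                                 chrom = "chr") {
  fmt <- match.arg(fmt)
  stopifnot(all(c("start", "end", "name", "score") %in% names(intervals)))
  if (fmt == "bed") {
    out <- data.frame(chrom = chrom, start = intervals$start,
                      end = intervals$end, name = intervals$name,
                      score = intervals$score)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    out <- data.frame(name = intervals$name, start = intervals$start + 1L,
                      end = intervals$end, score = intervals$score)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}
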