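#' Read a FASTA file into a contig set
#'
#' Loads a (optionally gzip-compressed) FASTA file as a
#' \code{DNAStringSet}. Sequence identifiers are the first whitespace-token
#' of each header and must be unique; sequences are uppercased and any
#' non-ACGTN IUPAC code is converted to N on load.
#'
#' @param path Path to a FASTA file, plain or gzipped.
#' @return A named \code{DNAStringSet}, one element per record, in file
#'   order.
#' @export
read_fasta <- function(path) {
  stop_if_not_scalar_chr(path, "path")
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readDNAStringSet(path, format = "fasta")
  normalize_loaded_set(x, path)
}

#' Read a FASTQ file into a contig set
#'
#' Per-base qualities are discarded: nothing downstream of I/O consumes
#' them.
#'
#' @inheritParams read_fasta
#' @return A named \code{DNAStringSet}.
#' @export
read_fastq <- function(path) {
  stop_if_not_scalar_chr(path, "path")
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readDNAStringSet(path, format = "fastq")
  normalize_loaded_set(x, path)
}

normalize_loaded_set <- function(x, path) {
  if (length(x) == 0L) stop("no sequence records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("malformed header (empty id) in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(width(x) == 0L)) stop("zero-length sequence record in ", path)
  x <- DNAStringSet(toupper(as.character(x)))
  x <- replaceAmbiguities(x, new = "N")
  names(x) <- ids
  x
}

#' Write a contig set to FASTA
#'
#' Inverse of \code{\link{read_fasta}}: ids and sequences round-trip
#' bit-exact. Lines are wrapped at 60 columns; a \code{.gz} suffix selects
#' gzip output.
#'
#' @param records A non-empty named \code{DNAStringSet} (or named character
#'   vector).
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_dss(records)
  if (length(records) == 0L) stop("refusing to write an empty record set")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  writeXStringSet(records, filepath = path, format = "fasta", width = 60L,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a contig set to FASTQ
#'
#' Emits a constant placeholder quality (\code{I}) for every base, the
#' conventional encoding for synthetic error-free long reads.
#'
#' @inheritParams write_fasta
#' @return The output path, invisibly.
#' @export
write_fastq <- function(records, path) {
  records <- as_dss(records)
  if (length(records) == 0L) stop("refusing to write an empty record set")
  quals <- Biostrings::BStringSet(vapply(width(records), function(w) {
    paste(rep("I", w), collapse = "")
  }, character(1)))
  writeXStringSet(records, filepath = path, format = "fastq",
                  qualities = quals, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Mask low-complexity sequence
#'
#' Flags low-complexity regions with a symmetric sliding-window DUST-style
#' score: every window of \code{window} bases is scored
#' \code{10 * sum(c_t * (c_t - 1) / 2) / (n - 1)} over its overlapping
#' trinucleotide counts \code{c_t} (triplets containing N are ignored), and
#' windows scoring above \code{score_threshold} are masked. Overlapping
#' masked windows are merged. The defaults (64 / 20) match the conventional
#' DUST operating point for genomic k-mer databases.
#'
#' @param record A single sequence (character scalar, \code{DNAString} or
#'   length-one \code{DNAStringSet}).
#' @param window Window length in bases (>= 3).
#' @param score_threshold Score above which a window is masked.
#' @return An object of class \code{masked_seq}: a list with \code{seq}
#'   (the uppercase input sequence), \code{intervals} (0-based half-open
#'   masked intervals) and \code{masked_fraction}.
#' @export
mask_low_complexity <- function(record, window = 64L, score_threshold = 20) {
  seq <- seq_chr(record)
  if (window < 3L) stop("window must be >= 3")
  n <- nchar(seq)
  if (n < window) {
    warning("sequence shorter than window; returning empty mask")
    ivs <- matrix(integer(0), ncol = 2L)
  } else {
    ivs <- cpp_dust_intervals(seq, as.integer(window), score_threshold)
  }
  colnames(ivs) <- c("start", "end")
  structure(list(seq = seq, intervals = ivs,
                 masked_fraction = interval_total(ivs) / n),
            class = "masked_seq")
}

#' Apply a low-complexity mask to a sequence
#'
#' @param mask A \code{masked_seq} from \code{\link{mask_low_complexity}},
#'   or a sequence (in which case the mask is computed first with default
#'   parameters).
#' @param hard If \code{TRUE} masked bases become N; otherwise they are
#'   lowercased (soft mask).
#' @return A character scalar.
#' @export
apply_mask <- function(mask, hard = TRUE) {
  if (!inherits(mask, "masked_seq")) mask <- mask_low_complexity(mask)
  seq <- mask$seq
  if (nrow(mask$intervals) == 0L) return(seq)
  r <- charToRaw(seq)
  for (i in seq_len(nrow(mask$intervals))) {
    idx <- (mask$intervals[i, 1L] + 1L):mask$intervals[i, 2L]
    if (hard) {
      r[idx] <- charToRaw("N")[1L]
    } else {
      r[idx] <- charToRaw(tolower(rawToChar(r[idx])))
    }
  }
  rawToChar(r)
}

#' @export
print.masked_seq <- function(x, ...) {
  cat(sprintf("masked_seq: %d bases, %d interval(s), %.1f%% masked\n",
              nchar(x$seq), nrow(x$intervals), 100 * x$masked_fraction))
  invisible(x)
}
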