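#' Greedy exact-overlap reassembly of a read bin
#'
#' Iteratively merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least \code{min_overlap} bases until none
#' remains, handling both read orientations (each sequence is tracked with
#' its reverse complement) and absorbing reads contained verbatim in
#' another sequence. Ties are broken deterministically (longest overlap,
#' then lexicographically smallest read-id pair). Each resulting contig is
#' then tested for circularity and trimmed of the duplicated wrap overlap.
#' Designed for near-exact long reads; repeats longer than
#' \code{min_overlap} may fragment the result.
#'
#' @param reads Named \code{DNAStringSet}.
#' @param min_overlap Minimum exact overlap in bases, default 500.
#' @return An object of class \code{assembly_result}: list with
#'   \code{contigs} (named \code{DNAStringSet}), \code{topology}
#'   (\code{"linear"}/\code{"circular"} per contig) and \code{reads}
#'   (constituent read ids per contig).
#' @export
greedy_assemble <- function(reads, min_overlap = 500L) {
  reads <- as_dss(reads)
  if (length(reads) == 0L) {
    return(structure(list(contigs = DNAStringSet(), topology = character(0),
                          reads = list()),
                     class = "assembly_result"))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read_%d", seq_along(reads))
  res <- cpp_greedy_assemble(as.character(reads), names(reads),
                             as.integer(min_overlap))
  seqs <- res$seq
  topology <- character(length(seqs))
  read_sets <- lapply(res$reads, function(idx) names(reads)[idx + 1L])
  for (i in seq_along(seqs)) {
    circ <- detect_circularity(seqs[i], min_overlap)
    topology[i] <- if (circ$circular) "circular" else "linear"
    if (circ$circular) seqs[i] <- as.character(circ$trimmed)
  }
  ord <- order(-nchar(seqs), res$key)
  contigs <- DNAStringSet(seqs[ord])
  names(contigs) <- sprintf("contig_%03d", seq_along(contigs))
  structure(list(contigs = contigs, topology = topology[ord],
                 reads = read_sets[ord]),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result: %d contig(s), span %d, %d circular\n",
              length(x$contigs), sum(width(x$contigs)),
              sum(x$topology == "circular")))
  invisible(x)
}

#' Detect a circular contig by its suffix-prefix self-overlap
#'
#' A contig is circular when its start is repeated at its end: the longest
#' self-overlap of at least \code{min_overlap} bases (at most half the
#' contig, >= 99\% identity, anchored on an exact prefix seed) flags
#' circularity, and one copy of the duplicated overlap is trimmed.
#'
#' @param contig A single sequence, longer than \code{2 * min_overlap}.
#' @param min_overlap Minimum self-overlap, default 500.
#' @param max_mismatch_frac Mismatches tolerated in the overlap, default
#'   0.01.
#' @return A list with \code{circular} (logical), \code{overlap} (bases)
#'   and \code{trimmed} (length-one \code{DNAStringSet}; the input when
#'   linear).
#' @export
detect_circularity <- function(contig, min_overlap = 500L,
                               max_mismatch_frac = 0.01) {
  seq <- seq_chr(contig)
  ov <- 0L
  if (nchar(seq) > 2L * min_overlap) {
    ov <- cpp_self_overlap(seq, as.integer(min_overlap), max_mismatch_frac)
  }
  trimmed <- if (ov > 0L) substr(seq, 1L, nchar(seq) - ov) else seq
  out <- DNAStringSet(trimmed)
  names(out) <- if (!is.null(names(as_dss(contig)))) {
    names(as_dss(contig))[1]
  } else {
    "contig"
  }
  list(circular = ov > 0L, overlap = as.integer(ov), trimmed = out)
}

#' Filter reassembled contigs by marker or reference evidence
#'
#' Reassembled contigs are retained only when they contain a single-copy
#' marker gene or show sufficient similarity to the family reference
#' genomes — the same evidence rule applied to the original bin contigs
#' (read coverage is trivially complete for a reassembly of the bin's own
#' reads and is not re-tested).
#'
#' @param result An \code{assembly_result}.
#' @param marker_panel Clade-appropriate marker panel.
#' @param family_refs Family reference genomes.
#' @param ... Passed to \code{\link{find_markers}} /
#'   \code{\link{reference_similarity}} threshold arguments
#'   (\code{marker_min_identity}, \code{marker_min_cov},
#'   \code{ref_min_identity}, \code{ref_min_breadth}).
#' @return A named \code{DNAStringSet} of retained contigs, with
#'   \code{topology} attribute.
#' @export
filter_reassembly <- function(result, marker_panel, family_refs,
                              marker_min_identity = 0.90,
                              marker_min_cov = 0.80,
                              ref_min_identity = 0.90,
                              ref_min_breadth = 0.50) {
  stopifnot(inherits(result, "assembly_result"))
  if (length(result$contigs) == 0L) return(DNAStringSet())
  keep <- vapply(seq_along(result$contigs), function(i) {
    ctg <- result$contigs[i]
    marker <- isTRUE(as.logical(suppressWarnings(
      find_markers(ctg, marker_panel, marker_min_identity, marker_min_cov))))
    if (marker) return(TRUE)
    isTRUE(as.logical(reference_similarity(ctg, family_refs,
                                           ref_min_identity,
                                           ref_min_breadth)))
  }, logical(1))
  out <- result$contigs[keep]
  attr(out, "topology") <- result$topology[keep]
  out
}
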