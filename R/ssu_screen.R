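#' Scan assembly contigs for SSU rRNA regions
#'
#' Seed-and-extend search of every contig (both strands) against a
#' multi-domain SSU reference panel. Exact shared 15-mers anchor candidate
#' diagonals; each diagonal is scored gap-free (match +1, mismatch -3, so
#' segments are positive-scoring exactly above 75\% identity) and maximal
#' local segments with identity >= \code{min_identity} over >=
#' \code{min_len} bases are reported as candidate hits. Coordinates are
#' 0-based half-open on the forward contig strand.
#'
#' @param contigs Named \code{DNAStringSet} of assembly contigs.
#' @param panel Named \code{DNAStringSet} SSU reference panel.
#' @param min_identity Candidate-stage identity floor (default 0.75).
#' @param min_len Candidate-stage aligned-length floor (default 300).
#' @param seed_k Seed k-mer length.
#' @return Data frame of hits: \code{contig_id}, \code{start}, \code{end},
#'   \code{strand}, \code{aligned_length}, \code{identity}, \code{score},
#'   \code{panel_ref_id}, \code{retained} (\code{NA} until
#'   \code{\link{retain_hits}}).
#' @export
scan_ssu <- function(contigs, panel, min_identity = 0.75, min_len = 300L,
                     seed_k = 15L) {
  contigs <- as_dss(contigs)
  panel <- as_dss(panel)
  if (length(panel) == 0L) stop("empty SSU reference panel")
  if (length(contigs) == 0L) stop("no contigs to scan")
  pnames <- names(panel)
  fwd <- as.character(panel)
  rev <- vapply(fwd, revcomp_chr, character(1))
  queries <- c(fwd, rev)
  strands <- c(rep("+", length(panel)), rep("-", length(panel)))
  qnames <- c(pnames, pnames)
  out <- list()
  for (ci in seq_along(contigs)) {
    sseq <- as.character(contigs[[ci]])
    seeds <- cpp_multi_seed_matches(queries, sseq, as.integer(seed_k), 1L)
    for (qi in seq_along(queries)) {
      if (nrow(seeds[[qi]]) == 0L) next
      segs <- diagonal_segments(queries[qi], sseq, seeds[[qi]],
                                min_len = min_len,
                                min_identity = min_identity,
                                mismatch_pen = 3)
      if (nrow(segs) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = names(contigs)[ci],
        start = segs$sstart, end = segs$send, strand = strands[qi],
        aligned_length = segs$length, identity = segs$identity,
        score = segs$score, panel_ref_id = qnames[qi],
        retained = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      aligned_length = integer(0), identity = numeric(0),
                      score = numeric(0), panel_ref_id = character(0),
                      retained = logical(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig_id, hits$start, -hits$score,
                     hits$panel_ref_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Apply the SSU hit retention rule
#'
#' A hit is retained when its aligned length strictly exceeds
#' \code{min_aligned} (default 1,000 bases) or its alignment score reaches
#' \code{min_score}. The score branch (match +1 / mismatch -3 segment
#' score, threshold 1000) stands in for a profile e-value cutoff and is
#' calibrated so that an exact match of at least 1,000 bases always
#' passes. Nothing is deleted; the \code{retained} flag is set.
#'
#' @param hits Hit table from \code{\link{scan_ssu}}.
#' @param min_aligned Aligned-length threshold (exclusive).
#' @param min_score Alignment-score threshold (inclusive).
#' @return The hit table with \code{retained} filled in.
#' @export
retain_hits <- function(hits, min_aligned = 1000L, min_score = 1000) {
  if (nrow(hits) == 0L) return(hits)
  hits$retained <- hits$aligned_length > min_aligned | hits$score >= min_score
  hits
}

#' Extract putative SSU sequences from retained hits
#'
#' Retained hits on one contig are merged into loci (overlapping intervals
#' collapsed); each locus is extracted with the strand of its best-scoring
#' hit, reverse-complemented for minus-strand loci.
#'
#' @param hits Hit table after \code{\link{retain_hits}}.
#' @param contigs The scanned contigs.
#' @return A named \code{DNAStringSet} of locus sequences, names of the
#'   form \code{contig:start-end(strand)}.
#' @export
extract_ssu_loci <- function(hits, contigs) {
  contigs <- as_dss(contigs)
  hits <- hits[!is.na(hits$retained) & hits$retained, , drop = FALSE]
  if (nrow(hits) == 0L) return(DNAStringSet())
  out <- character(0)
  for (cid in unique(hits$contig_id)) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    merged <- merge_intervals(cbind(h$start, h$end))
    for (i in seq_len(nrow(merged))) {
      s <- merged[i, 1L]
      e <- merged[i, 2L]
      inside <- h[h$start < e & h$end > s, , drop = FALSE]
      strand <- inside$strand[which.max(inside$score)]
      seq <- substr(as.character(contigs[[cid]]), s + 1L, e)
      if (strand == "-") seq <- revcomp_chr(seq)
      out[sprintf("%s:%d-%d(%s)", cid, s, e, strand)] <- seq
    }
  }
  DNAStringSet(out)
}

#' Collapse redundant SSU sequences
#'
#' Greedy longest-first clustering (ties broken lexicographically by id): a
#' sequence joins an existing representative when its global identity
#' (matched bases over the longer sequence, best diagonal, either strand)
#' strictly exceeds \code{identity_threshold}; otherwise it founds a new
#' representative. Representatives are therefore pairwise at most
#' \code{identity_threshold} identical.
#'
#' @param seqs Named \code{DNAStringSet} of SSU sequences.
#' @param identity_threshold Clustering threshold in (0.5, 1], default
#'   0.99.
#' @return An object of class \code{ssu_set}: list with
#'   \code{representatives} (\code{DNAStringSet}) and \code{membership}
#'   (data frame seq_id -> rep_id).
#' @export
collapse_redundant <- function(seqs, identity_threshold = 0.99) {
  seqs <- as_dss(seqs)
  if (identity_threshold <= 0.5 || identity_threshold > 1) {
    stop("identity_threshold must be in (0.5, 1]")
  }
  if (length(seqs) == 0L) {
    return(structure(list(representatives = DNAStringSet(),
                          membership = data.frame(seq_id = character(0),
                                                  rep_id = character(0))),
                     class = "ssu_set"))
  }
  ord <- order(-width(seqs), names(seqs))
  reps <- character(0)
  member <- character(length(seqs))
  names(member) <- names(seqs)
  for (i in ord) {
    id <- names(seqs)[i]
    s <- as.character(seqs[[i]])
    assigned <- NA_character_
    for (r in reps) {
      if (global_identity(as.character(seqs[[r]]), s) > identity_threshold) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    member[id] <- assigned
  }
  structure(list(representatives = seqs[reps],
                 membership = data.frame(seq_id = names(member),
                                         rep_id = unname(member),
                                         stringsAsFactors = FALSE)),
            class = "ssu_set")
}

#' @export
print.ssu_set <- function(x, ...) {
  cat(sprintf("ssu_set: %d sequence(s), %d representative(s)\n",
              nrow(x$membership), length(x$representatives)))
  invisible(x)
}

# Identity of one SSU representative against every panel member, for the
# consensus classification stage.
panel_hit_table <- function(rep_seq, panel) {
  panel <- as_dss(panel)
  ident <- vapply(seq_along(panel), function(i) {
    global_identity(seq_chr(rep_seq), as.character(panel[[i]]))
  }, numeric(1))
  data.frame(ref_id = names(panel), identity = ident,
             stringsAsFactors = FALSE)
}
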