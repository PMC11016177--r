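#' Per-base read coverage of a contig by its bin's reads
#'
#' Places each binned read on the contig by exact-seed diagonal chaining
#' (both strands): shared 31-mers, sampled along the read, nominate
#' diagonals; each diagonal's gap-free high-identity segments contribute
#' covered intervals. A read only partially homologous to the contig (for
#' instance spanning a horizontally transferred insertion) therefore
#' covers only the homologous interval — the property the full-coverage
#' filter relies on.
#'
#' @param contig A single sequence.
#' @param bin_reads \code{DNAStringSet} of the family bin's reads.
#' @param seed_k Seed k-mer length.
#' @param stride Read-position sampling stride for seeds.
#' @param min_seg_identity,min_seg_len Segment acceptance thresholds.
#' @return An object of class \code{coverage_profile}: list with
#'   \code{contig_id}, \code{length}, \code{depth} (per-base integer),
#'   \code{breadth} (fraction of bases with depth >= 1) and the covered
#'   \code{intervals}.
#' @export
coverage_profile <- function(contig, bin_reads, seed_k = 31L, stride = 25L,
                             min_seg_identity = 0.90, min_seg_len = 50L) {
  sseq <- seq_chr(contig)
  cid <- if (!is.null(names(as_dss(contig)))) names(as_dss(contig))[1] else "contig"
  L <- nchar(sseq)
  bin_reads <- as_dss(bin_reads)
  ivs <- matrix(integer(0), ncol = 2L)
  if (length(bin_reads) > 0L) {
    fwd <- as.character(bin_reads)
    rev <- vapply(fwd, revcomp_chr, character(1))
    queries <- c(fwd, rev)
    seeds <- cpp_multi_seed_matches(queries, sseq, as.integer(seed_k),
                                    as.integer(stride))
    acc <- list()
    for (qi in seq_along(queries)) {
      if (nrow(seeds[[qi]]) == 0L) next
      segs <- diagonal_segments(queries[qi], sseq, seeds[[qi]],
                                min_len = min_seg_len,
                                min_identity = min_seg_identity,
                                mismatch_pen = 9)
      if (nrow(segs) == 0L) next
      acc[[length(acc) + 1L]] <- cbind(segs$sstart, segs$send)
    }
    if (length(acc) > 0L) ivs <- do.call(rbind, acc)
  }
  merged <- merge_intervals(ivs)
  depth <- integer(L)
  if (nrow(ivs) > 0L) {
    add <- tabulate(ivs[, 1L] + 1L, L + 1L)
    sub <- tabulate(pmin(ivs[, 2L], L) + 1L, L + 1L)
    depth <- cumsum(add - sub)[seq_len(L)]
  }
  structure(list(contig_id = cid, length = L, depth = depth,
                 breadth = if (L > 0L) sum(depth > 0L) / L else 0,
                 intervals = merged),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s: %d bases, breadth %.4f, mean depth %.1f\n",
              x$contig_id, x$length, x$breadth, mean(x$depth)))
  invisible(x)
}

# "Fully covered" with a small terminal tolerance: every uncovered base
# must lie within `terminal_slack` bases of a contig end (reads cannot
# overhang the ends of a contig).
is_fully_covered <- function(profile, terminal_slack = 25L) {
  L <- profile$length
  if (L == 0L) return(FALSE)
  uncovered <- which(profile$depth == 0L)
  length(uncovered) == 0L ||
    all(uncovered <= terminal_slack | uncovered > L - terminal_slack)
}

#' Does a contig contain a single-copy marker gene?
#'
#' Nucleotide-level search of the clade-appropriate marker panel against
#' the contig (both strands, seed-and-extend): \code{TRUE} when any panel
#' marker aligns at identity >= \code{min_identity} over at least
#' \code{min_cov} of the marker's length.
#'
#' @param contig A single sequence.
#' @param marker_panel \code{DNAStringSet} of single-copy marker genes.
#' @param min_identity Minimum alignment identity, default 0.90.
#' @param min_cov Minimum fraction of the marker covered, default 0.80.
#' @return Logical scalar; the per-marker best hits are attached as the
#'   \code{"details"} attribute.
#' @export
find_markers <- function(contig, marker_panel, min_identity = 0.90,
                         min_cov = 0.80) {
  marker_panel <- as_dss(marker_panel)
  if (length(marker_panel) == 0L) {
    warning("empty marker panel")
    return(structure(FALSE, details = data.frame()))
  }
  counts <- marker_hit_counts(contig, marker_panel, min_identity, min_cov)
  structure(any(counts$n_hits > 0L), details = counts)
}

# Per-marker hit counts on one contig (used by find_markers and the
# completeness proxy). A hit is a diagonal segment at >= min_identity
# covering >= min_cov of the marker; disjoint placements count separately.
marker_hit_counts <- function(contig, marker_panel, min_identity = 0.90,
                              min_cov = 0.80, seed_k = 15L) {
  sseq <- seq_chr(contig)
  pen <- mismatch_pen_for(min_identity)
  marker_panel <- as_dss(marker_panel)
  fwd <- as.character(marker_panel)
  rev <- vapply(fwd, revcomp_chr, character(1))
  queries <- c(fwd, rev)
  seeds <- cpp_multi_seed_matches(queries, sseq, as.integer(seed_k), 1L)
  n <- length(marker_panel)
  n_hits <- integer(n)
  best_identity <- numeric(n)
  best_cov <- numeric(n)
  for (mi in seq_len(n)) {
    placements <- matrix(integer(0), ncol = 2L)
    for (qi in c(mi, mi + n)) {
      if (nrow(seeds[[qi]]) == 0L) next
      mlen <- nchar(queries[qi])
      segs <- diagonal_segments(queries[qi], sseq, seeds[[qi]],
                                min_len = max(30L, floor(min_cov * mlen)),
                                min_identity = min_identity,
                                mismatch_pen = pen)
      if (nrow(segs) == 0L) next
      ok <- segs$length / mlen >= min_cov
      if (any(ok)) {
        placements <- rbind(placements,
                            cbind(segs$sstart[ok], segs$send[ok]))
        best_identity[mi] <- max(best_identity[mi], segs$identity[ok])
        best_cov[mi] <- max(best_cov[mi], segs$length[ok] / mlen)
      }
    }
    n_hits[mi] <- nrow(merge_intervals(placements))
  }
  data.frame(marker_id = names(marker_panel), n_hits = n_hits,
             best_identity = best_identity, best_coverage = best_cov,
             stringsAsFactors = FALSE)
}

#' Is a contig similar to the family's reference genomes?
#'
#' Aligns the contig (both strands) against each family reference genome by
#' seed-and-extend and unions the contig intervals covered at identity >=
#' \code{min_identity}; \code{TRUE} when the union covers at least
#' \code{min_breadth} of the contig. An empty reference set (novel family)
#' returns \code{FALSE}.
#'
#' @param contig A single sequence.
#' @param family_refs \code{DNAStringSet} of family reference genomes (may
#'   be empty).
#' @param min_identity Minimum alignment identity, default 0.90.
#' @param min_breadth Minimum covered fraction of the contig, default 0.50.
#' @param stride Contig-position sampling stride for seeds.
#' @return Logical scalar with the covered fraction as attribute
#'   \code{"breadth"}.
#' @export
reference_similarity <- function(contig, family_refs, min_identity = 0.90,
                                 min_breadth = 0.50, stride = 10L) {
  family_refs <- as_dss(family_refs)
  cseq <- seq_chr(contig)
  L <- nchar(cseq)
  if (length(family_refs) == 0L || L == 0L) {
    return(structure(FALSE, breadth = 0))
  }
  crev <- revcomp_chr(cseq)
  pen <- mismatch_pen_for(min_identity)
  ivs <- matrix(integer(0), ncol = 2L)
  for (ri in seq_along(family_refs)) {
    rseq <- as.character(family_refs[[ri]])
    for (orient in 1:2) {
      q <- if (orient == 1L) cseq else crev
      seeds <- cpp_multi_seed_matches(q, rseq, 15L, as.integer(stride))[[1L]]
      if (nrow(seeds) == 0L) next
      segs <- diagonal_segments(q, rseq, seeds, min_len = 100L,
                                min_identity = min_identity,
                                mismatch_pen = pen)
      if (nrow(segs) == 0L) next
      qs <- segs$qstart
      qe <- segs$qend
      if (orient == 2L) { # map minus-strand query coords back to the contig
        tmp <- L - qe
        qe <- L - qs
        qs <- tmp
      }
      ivs <- rbind(ivs, cbind(qs, qe))
    }
  }
  merged <- merge_intervals(ivs)
  breadth <- interval_total(merged) / L
  structure(breadth >= min_breadth, breadth = breadth)
}

#' Refine a family bin with the contig retention filters
#'
#' A contig stays in the bin only when (a) the bin's classified reads cover
#' it end to end (guarding against host contigs that merely share a
#' horizontally transferred insertion with the cobiont) and (b) it either
#' contains a single-copy marker gene or is sufficiently similar to the
#' family's reference genomes.
#'
#' @param bin_contigs Named \code{DNAStringSet}: the candidate contigs of
#'   one family bin.
#' @param bin_reads \code{DNAStringSet} of the family's classified reads.
#' @param marker_panel Clade-appropriate marker panel for the family.
#' @param family_refs Family reference genomes (may be empty).
#' @param terminal_slack Uncovered bases tolerated at each contig end.
#' @param marker_min_identity,marker_min_cov Marker-search thresholds.
#' @param ref_min_identity,ref_min_breadth Reference-similarity thresholds.
#' @return A list with \code{retained} (\code{DNAStringSet}) and
#'   \code{decisions}, a data frame with one row per contig
#'   (fully_covered, has_marker, similar_to_reference, retained, reasons).
#' @export
refine_bin <- function(bin_contigs, bin_reads, marker_panel, family_refs,
                       terminal_slack = 25L,
                       marker_min_identity = 0.90, marker_min_cov = 0.80,
                       ref_min_identity = 0.90, ref_min_breadth = 0.50) {
  bin_contigs <- as_dss(bin_contigs)
  if (length(bin_contigs) == 0L) stop("empty bin")
  rows <- vector("list", length(bin_contigs))
  for (i in seq_along(bin_contigs)) {
    ctg <- bin_contigs[i]
    prof <- coverage_profile(ctg, bin_reads)
    covered <- is_fully_covered(prof, terminal_slack)
    if (prof$breadth == 0) {
      # contig untouched by the bin's reads: evidence checks are moot
      marker <- FALSE
      similar <- FALSE
    } else {
      marker <- isTRUE(as.logical(suppressWarnings(
        find_markers(ctg, marker_panel, marker_min_identity,
                     marker_min_cov))))
      similar <- isTRUE(as.logical(
        reference_similarity(ctg, family_refs, ref_min_identity,
                             ref_min_breadth)))
    }
    retained <- covered && (marker || similar)
    reasons <- c(
      if (!covered) "not fully covered by bin reads",
      if (covered && !marker && !similar) "no marker and no reference similarity",
      if (retained && marker) "marker gene present",
      if (retained && !marker && similar) "reference similarity")
    rows[[i]] <- data.frame(
      contig_id = names(bin_contigs)[i], breadth = prof$breadth,
      fully_covered = covered, has_marker = marker,
      similar_to_reference = similar, retained = retained,
      reasons = paste(reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  decisions <- do.call(rbind, rows)
  list(retained = bin_contigs[decisions$retained], decisions = decisions)
}
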