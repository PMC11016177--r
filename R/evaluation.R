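#' Length-normalised precision, recall and F1 of a bin
#'
#' Bases, not sequence counts, are scored: precision is the fraction of
#' bin bases whose sequence truly originates from the family, recall the
#' fraction of the family's truth bases captured by the bin, and
#' F1 = (2 * precision * recall) / (precision + recall). An empty bin has
#' precision 0 by convention (and hence F1 = 0).
#'
#' @param bin_ids Character vector of sequence ids in the bin.
#' @param truth Data frame with columns \code{id} (or \code{contig_id} /
#'   \code{read_id}), \code{family} and \code{length} covering every bin
#'   member.
#' @param family The family label evaluated.
#' @return Named numeric vector \code{c(precision, recall, f1)}.
#' @export
length_weighted_prf <- function(bin_ids, truth, family) {
  idcol <- intersect(c("id", "contig_id", "read_id"), names(truth))[1]
  if (is.na(idcol)) stop("truth table needs an id column")
  stopifnot(all(c("family", "length") %in% names(truth)))
  if (!family %in% truth$family) {
    stop("family absent from truth table: ", family)
  }
  idx <- match(bin_ids, truth[[idcol]])
  if (anyNA(idx)) {
    stop("bin member(s) missing from truth: ",
         paste(bin_ids[is.na(idx)], collapse = ", "))
  }
  bin_len <- truth$length[idx]
  correct <- sum(bin_len[truth$family[idx] == family])
  total_bin <- sum(bin_len)
  total_truth <- sum(truth$length[truth$family == family])
  precision <- if (total_bin == 0) 0 else correct / total_bin
  recall <- correct / total_truth
  f1 <- if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Assembly N50
#'
#' The largest length L such that contigs of length >= L together span at
#' least half the assembly.
#'
#' @param contigs A \code{DNAStringSet} or a numeric vector of lengths.
#' @return N50 in bases.
#' @export
n50 <- function(contigs) {
  lens <- if (is.numeric(contigs)) contigs else width(as_dss(contigs))
  if (length(lens) == 0L) stop("empty contig set")
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  lens[which(cumsum(lens) >= total / 2)[1L]]
}

#' Marker-based completeness proxy of a bin
#'
#' Counts how many of the clade's single-copy markers occur in the bin's
#' contigs: 0 placements -> missing, exactly 1 -> complete single-copy,
#' >= 2 -> complete duplicated. Fractions are over the panel size.
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param marker_panel The clade's marker panel.
#' @param min_identity,min_cov Marker-hit thresholds (see
#'   \code{\link{find_markers}}).
#' @return Named numeric vector \code{c(single, duplicated, missing)}
#'   (fractions summing to 1) with the per-marker placement counts as
#'   attribute \code{"counts"}.
#' @export
completeness_proxy <- function(contigs, marker_panel, min_identity = 0.90,
                               min_cov = 0.80) {
  marker_panel <- as_dss(marker_panel)
  if (length(marker_panel) == 0L) stop("empty marker panel")
  contigs <- as_dss(contigs)
  counts <- integer(length(marker_panel))
  for (i in seq_along(contigs)) {
    hits <- marker_hit_counts(contigs[i], marker_panel, min_identity, min_cov)
    counts <- counts + hits$n_hits
  }
  np <- length(marker_panel)
  out <- c(single = sum(counts == 1L) / np,
           duplicated = sum(counts >= 2L) / np,
           missing = sum(counts == 0L) / np)
  attr(out, "counts") <- setNames(counts, names(marker_panel))
  out
}

#' Assess refined family bins against truth
#'
#' One row per family: length-normalised precision/recall/F1 of the bin's
#' contigs against the truth table, plus span, N50 and the marker
#' completeness triple.
#'
#' @param bins Named list: family -> retained \code{DNAStringSet}.
#' @param truth_contigs Truth table with \code{contig_id}, \code{family},
#'   \code{length}.
#' @param marker_panels Named list: family -> marker panel.
#' @return Data frame, one row per family.
#' @export
assess_bins <- function(bins, truth_contigs, marker_panels) {
  rows <- lapply(names(bins), function(fam) {
    ctgs <- as_dss(bins[[fam]])
    prf <- length_weighted_prf(names(ctgs), truth_contigs, fam)
    span <- sum(width(ctgs))
    comp <- if (!is.null(marker_panels[[fam]]) && length(ctgs) > 0L) {
      completeness_proxy(ctgs, marker_panels[[fam]])
    } else {
      c(single = NA_real_, duplicated = NA_real_, missing = NA_real_)
    }
    data.frame(family = fam,
               n_contigs = length(ctgs),
               precision = unname(prf["precision"]),
               recall = unname(prf["recall"]),
               f1 = unname(prf["f1"]),
               span = span,
               n50 = if (length(ctgs) > 0L) n50(ctgs) else 0L,
               complete_single = unname(comp["single"]),
               complete_duplicated = unname(comp["duplicated"]),
               missing = unname(comp["missing"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$family), , drop = FALSE]
}
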