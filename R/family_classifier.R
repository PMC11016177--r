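#' Build a masked k-mer classification database
#'
#' Every input genome is low-complexity hard-masked, then decomposed into
#' canonical k-mers (lexicographic minimum of forward and
#' reverse-complement; k-mers crossing a masked base or an N are skipped).
#' Each k-mer is stored with its taxon label; a k-mer observed under two or
#' more labels is stored with the lowest common ancestor of those labels.
#' The database is order-independent in its inputs.
#'
#' @param genomes Named list: taxon label (family node id, the host family
#'   for host-relative genomes) -> \code{DNAStringSet} of reference
#'   genomes.
#' @param tree A \code{taxonomy_tree} containing every label.
#' @param host_family Family node id of the host species.
#' @param k K-mer length, default 50.
#' @param mask Apply low-complexity masking before k-mer extraction.
#' @param dust_window,dust_threshold Masking parameters.
#' @return An object of class \code{kmer_db}: list with \code{k},
#'   \code{kmers}, \code{labels} (parallel character vectors),
#'   \code{label_levels}, \code{tree}, \code{host_family} and a per-genome
#'   \code{manifest}.
#' @export
build_kmer_db <- function(genomes, tree, host_family, k = 50L, mask = TRUE,
                          dust_window = 64L, dust_threshold = 20) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named list (label -> DNAStringSet)")
  }
  for (lab in names(genomes)) {
    if (is.na(match(lab, tree$nodes$id))) {
      stop("label not in taxonomy: ", lab)
    }
  }
  kvec <- character(0)
  lvec <- character(0)
  manifest <- list()
  for (lab in sort(names(genomes))) {
    gs <- as_dss(genomes[[lab]])
    for (gi in seq_along(gs)) {
      g <- as.character(gs[[gi]])
      if (nchar(g) < k) stop("genome shorter than k: ", names(gs)[gi])
      masked_frac <- 0
      if (mask) {
        m <- mask_low_complexity(g, dust_window, dust_threshold)
        masked_frac <- m$masked_fraction
        g <- apply_mask(m, hard = TRUE)
      }
      km <- cpp_canonical_kmers(g, as.integer(k), TRUE)
      if (length(km) == 0L) {
        warning("no k-mers extracted from ", names(gs)[gi],
                " (fully masked?)")
      }
      kvec <- c(kvec, km)
      lvec <- c(lvec, rep(lab, length(km)))
      manifest[[length(manifest) + 1L]] <- data.frame(
        genome_id = names(gs)[gi], label = lab, n_kmers = length(km),
        masked_fraction = masked_frac, stringsAsFactors = FALSE)
    }
  }
  # collapse duplicate (kmer, label) pairs, then LCA-label multi-label kmers
  ord <- order(kvec, lvec)
  kvec <- kvec[ord]
  lvec <- lvec[ord]
  n <- length(kvec)
  if (n > 0L) {
    keep <- c(TRUE, !(kvec[-1L] == kvec[-n] & lvec[-1L] == lvec[-n]))
    kvec <- kvec[keep]
    lvec <- lvec[keep]
    n <- length(kvec)
  }
  if (n > 1L) {
    grp <- cumsum(c(TRUE, kvec[-1L] != kvec[-n]))
    sizes <- tabulate(grp)
    multi <- which(sizes > 1L)
    if (length(multi) > 0L) {
      first_of_grp <- which(c(TRUE, kvec[-1L] != kvec[-n]))
      lca_cache <- new.env(parent = emptyenv())
      new_labels <- lvec
      drop <- logical(n)
      for (g in multi) {
        idx <- first_of_grp[g] + seq_len(sizes[g]) - 1L
        labs <- sort(unique(lvec[idx]))
        key <- paste(labs, collapse = "|")
        lca <- if (!is.null(lca_cache[[key]])) {
          lca_cache[[key]]
        } else {
          v <- taxon_lca(tree, labs)
          lca_cache[[key]] <- v
          v
        }
        new_labels[idx[1L]] <- lca
        drop[idx[-1L]] <- TRUE
      }
      kvec <- kvec[!drop]
      lvec <- new_labels[!drop]
    }
  }
  structure(list(k = as.integer(k), kmers = kvec, labels = lvec,
                 label_levels = sort(unique(lvec)), tree = tree,
                 host_family = host_family,
                 manifest = do.call(rbind, manifest)),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("kmer_db: k = %d, %d k-mers, %d label(s), host family '%s'\n",
              x$k, length(x$kmers), length(x$label_levels), x$host_family))
  invisible(x)
}

#' Serialize a k-mer database to TSV
#'
#' @param db A \code{kmer_db}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_kmer_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv0(data.frame(kmer = db$kmers, label = db$labels,
                        stringsAsFactors = FALSE),
             file.path(dir, "kmers.tsv"))
  write_tsv0(db$manifest, file.path(dir, "manifest.tsv"))
  yaml::write_yaml(list(format_version = 1L, k = db$k,
                        host_family = db$host_family),
                   file.path(dir, "db.yaml"))
  write_taxonomy_bundle(db$tree, file.path(dir, "taxonomy"))
  invisible(dir)
}

#' Read a k-mer database written by \code{\link{write_kmer_db}}
#'
#' @param dir Database directory.
#' @return A \code{kmer_db}.
#' @export
read_kmer_db <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "db.yaml"))
  km <- read.delim(file.path(dir, "kmers.tsv"), stringsAsFactors = FALSE)
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  tree <- read_taxonomy_bundle(file.path(dir, "taxonomy"))
  structure(list(k = as.integer(meta$k), kmers = km$kmer, labels = km$label,
                 label_levels = sort(unique(km$label)), tree = tree,
                 host_family = meta$host_family, manifest = manifest),
            class = "kmer_db")
}

# Kraken-style resolution of one vote vector: the winner is the deepest
# node on the maximum-scoring root-to-leaf path, where a node's path score
# sums the votes of itself and its labelled ancestors; ties resolve to the
# LCA of the tied nodes.
resolve_votes <- function(votes, total, db, min_confidence, anc_map = NULL) {
  labs <- names(votes)[votes > 0L]
  if (length(labs) == 0L || total == 0L) {
    return(list(label = "UNCLASSIFIED", resolved = "UNCLASSIFIED",
                confidence = 0, score = 0))
  }
  anc <- if (is.null(anc_map)) {
    setNames(lapply(labs, function(l) as.character(lineage(db$tree, l))),
             labs)
  } else {
    anc_map[labs]
  }
  score <- vapply(labs, function(l) {
    sum(votes[intersect(labs, anc[[l]])])
  }, numeric(1))
  best <- max(score)
  tied <- labs[score == best]
  winner <- if (length(tied) == 1L) tied else taxon_lca(db$tree, tied)
  confidence <- best / total
  if (confidence < min_confidence) {
    return(list(label = "UNCLASSIFIED", resolved = "UNCLASSIFIED",
                confidence = confidence, score = best))
  }
  fam <- family_of(db$tree, winner)
  resolved <- if (is.na(fam)) {
    winner # above family: reported, binned to no family
  } else if (fam == db$host_family) {
    "HOST"
  } else {
    fam
  }
  list(label = winner, resolved = resolved, confidence = confidence,
       score = best)
}

#' Classify reads against a k-mer database
#'
#' Tallies, for every read, the canonical k-mers matching each database
#' label, then resolves the votes taxonomically: the read is assigned the
#' deepest taxon on the maximum-scoring root-to-leaf path (ties resolve to
#' their lowest common ancestor), mapped to its family, \code{HOST} for
#' the host family, or left at an above-family node for conflicting
#' (e.g. chimeric) evidence. Reads with no matching k-mer, shorter than k,
#' or with winning support below \code{min_confidence} (fraction of the
#' read's k-mers) are \code{UNCLASSIFIED}.
#'
#' @param db A \code{kmer_db}.
#' @param reads Named \code{DNAStringSet}.
#' @param min_confidence Minimum winning-votes fraction, default 0.10.
#' @return Data frame: \code{read_id}, \code{label} (winning taxon),
#'   \code{resolved} (family id, \code{HOST}, above-family taxon, or
#'   \code{UNCLASSIFIED}), \code{confidence}, \code{votes},
#'   \code{kmers_total}; the per-label vote matrix is attached as the
#'   \code{"votes"} attribute.
#' @export
classify_reads <- function(db, reads, min_confidence = 0.10) {
  reads <- as_dss(reads)
  labs <- db$label_levels
  lab_idx <- match(db$labels, labs)
  res <- cpp_classify_reads(db$kmers, lab_idx, as.character(reads),
                            db$k, length(labs))
  votes <- res$votes
  colnames(votes) <- labs
  out <- data.frame(read_id = names(reads),
                    label = character(length(reads)),
                    resolved = character(length(reads)),
                    confidence = numeric(length(reads)),
                    votes = integer(length(reads)),
                    kmers_total = res$total,
                    stringsAsFactors = FALSE)
  anc_map <- setNames(lapply(labs, function(l) {
    as.character(lineage(db$tree, l))
  }), labs)
  for (i in seq_along(reads)) {
    v <- setNames(votes[i, ], labs)
    r <- resolve_votes(v, res$total[i], db, min_confidence, anc_map)
    out$label[i] <- r$label
    out$resolved[i] <- r$resolved
    out$confidence[i] <- r$confidence
    out$votes[i] <- as.integer(r$score)
  }
  attr(out, "votes") <- votes
  out
}

#' Classify a single read
#'
#' @inheritParams classify_reads
#' @param read One sequence.
#' @return A list with \code{read_id}, \code{label}, \code{resolved},
#'   \code{confidence}, \code{votes} (named per-label k-mer counts) and
#'   \code{kmers_total}.
#' @export
classify_read <- function(db, read, min_confidence = 0.10) {
  read <- as_dss(read)
  if (is.null(names(read))) names(read) <- "read"
  res <- classify_reads(db, read, min_confidence)
  v <- attr(res, "votes")[1L, ]
  list(read_id = res$read_id[1L], label = res$label[1L],
       resolved = res$resolved[1L], confidence = res$confidence[1L],
       votes = v, kmers_total = res$kmers_total[1L])
}

#' Bin reads by family
#'
#' Classifies all reads and groups them into per-family bins; host,
#' unclassified and above-family (ambiguous) reads are tracked separately
#' and never enter a family bin.
#'
#' @inheritParams classify_reads
#' @return A list with \code{bins} (named list: family -> read ids),
#'   \code{host}, \code{unclassified}, \code{ambiguous} (read id vectors)
#'   and the full \code{classification} table.
#' @export
bin_reads <- function(db, reads, min_confidence = 0.10) {
  reads <- as_dss(reads)
  if (length(reads) == 0L) {
    return(list(bins = list(), host = character(0),
                unclassified = character(0), ambiguous = character(0),
                classification = data.frame()))
  }
  cls <- classify_reads(db, reads, min_confidence)
  is_family <- vapply(cls$resolved, function(r) {
    !r %in% c("HOST", "UNCLASSIFIED") &&
      !is.na(match(r, db$tree$nodes$id)) &&
      db$tree$nodes$rank[match(r, db$tree$nodes$id)] == "family"
  }, logical(1))
  bins <- split(cls$read_id[is_family], cls$resolved[is_family])
  ambiguous <- cls$read_id[!is_family & !cls$resolved %in%
                             c("HOST", "UNCLASSIFIED")]
  list(bins = bins,
       host = cls$read_id[cls$resolved == "HOST"],
       unclassified = cls$read_id[cls$resolved == "UNCLASSIFIED"],
       ambiguous = ambiguous,
       classification = cls)
}
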