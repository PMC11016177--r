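# Shared fixtures and independent oracles for the test suite. Expensive
# fixtures are memoized per test session.

.fixture_cache <- new.env(parent = emptyenv())

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Deterministic substitutions at given 1-based positions (A->C->G->T->A).
mutate_at <- function(seq, positions) {
  r <- charToRaw(seq)
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) {
    r[p] <- charToRaw(rot[[rawToChar(r[p])]])
  }
  rawToChar(r)
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Small four-species community (host + 2 assembled cobionts + 1
# reads-only cobiont) used by most integration tests.
small_spec <- function(...) {
  sp <- data.frame(
    name = c("Hosta parva", "Wolbachia parva", "Lactococcus parvus",
             "Nosema parva"),
    family = c("Hostidae", "Anaplasmataceae", "Streptococcaceae",
               "Nosemataceae"),
    silva_family = c(NA, "Ehrlichiaceae", NA, NA),
    domain = c("Eukaryota", "Bacteria", "Bacteria", "Eukaryota"),
    genome_length = c(80000L, 40000L, 30000L, 25000L),
    gc = c(0.38, 0.35, 0.45, 0.30),
    bias_seed = c(11L, 12L, 13L, 14L),
    weight = c(100, 20, 10, 2),
    is_host = c(TRUE, FALSE, FALSE, FALSE),
    omit_from_assembly = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  community_spec(sp, coverage_total = 40, fragmentation = 3L,
                 n_panel_refs = 8L, n_markers = 8L, ...)
}

get_small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_community(small_spec(), seed = 42)
  }
  .fixture_cache$small
}

# Default five-species fixture written to disk plus a full pipeline run;
# shared by the end-to-end acceptance checks.
get_default_run <- function() {
  if (is.null(.fixture_cache$default_run)) {
    dir <- file.path(tempdir(), "ssusieve_default_fixture")
    fx <- simulate_community(default_community_spec(), seed = 1,
                             out_dir = dir)
    cfg <- pipeline_config(
      assembly = file.path(dir, "assembly.fasta"),
      reads = file.path(dir, "reads.fastq.gz"),
      host_species = "Apis synthetica",
      reference_bundle = file.path(dir, "ref_bundle"),
      output_dir = file.path(tempdir(), "ssusieve_default_run"),
      seed = 7)
    run <- run_pipeline(cfg, quiet = TRUE)
    ev <- evaluate_run(run, fx$contig_truth, fx$read_truth)
    .fixture_cache$default_run <- list(fx = fx, run = run, ev = ev)
  }
  .fixture_cache$default_run
}

tile_reads <- function(genome, read_len = 2000L, step = 500L,
                       prefix = "r") {
  L <- nchar(genome)
  starts <- seq(0L, max(0L, L - read_len), by = step)
  if (starts[length(starts)] + read_len < L) starts <- c(starts, L - read_len)
  seqs <- substring(genome, starts + 1L, pmin(L, starts + read_len))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("%s%03d", prefix,
                                                  seq_along(seqs))))
}

# --- naive sliding-window DUST oracle --------------------------------------

naive_dust_intervals <- function(seq, window = 64L, threshold = 20) {
  n <- nchar(seq)
  if (n < window) return(matrix(integer(0), ncol = 2L))
  masked <- logical(n)
  for (s in 0:(n - window)) {
    win <- substr(seq, s + 1L, s + window)
    tris <- substring(win, 1:(window - 2L), 3:window)
    tris <- tris[!grepl("N", tris, fixed = TRUE)]
    l <- length(tris)
    if (l < 2L) next
    cnt <- table(tris)
    score <- 10 * sum(cnt * (cnt - 1) / 2) / (l - 1)
    if (score > threshold) masked[(s + 1L):(s + window)] <- TRUE
  }
  if (!any(masked)) return(matrix(integer(0), ncol = 2L))
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

# de Bruijn B(4, n) sequence over ACGT (maximal-entropy fixture).
debruijn_dna <- function(len, order = 4L) {
  k <- 4L
  a <- integer(k * order + 1L)
  out <- integer(0)
  db <- function(t, p) {
    if (t > order) {
      if (order %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j < k) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  s <- paste(c("A", "C", "G", "T")[out + 1L], collapse = "")
  substr(strrep(s, ceiling(len / nchar(s))), 1L, len)
}

# --- Smith-Waterman oracle (Biostrings) ------------------------------------

sw_local <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3),
    gapOpening = 5, gapExtension = 2)
}

# --- brute-force consensus-classification oracle ---------------------------

oracle_consensus <- function(hits, tree, ref_taxa, min_identity = 0.90,
                             top_n = 20L, concordance = 0.80) {
  keep <- hits[hits$identity > min_identity, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(list(family = "UNASSIGNED", support = 0, n = 0L))
  }
  keep <- keep[order(-keep$identity, keep$ref_id), , drop = FALSE]
  keep <- keep[seq_len(min(top_n, nrow(keep))), , drop = FALSE]
  fam_votes <- character(0)
  fam_at <- function(node) {
    while (!is.na(node)) {
      i <- match(node, tree$nodes$id)
      if (tree$nodes$rank[i] == "family") return(node)
      node <- tree$nodes$parent[i]
    }
    NA_character_
  }
  for (rid in keep$ref_id) {
    nm <- ref_taxa[[rid]]
    f <- NA_character_
    if (!is.null(nm) && !is.na(nm)) {
      n1 <- tree$nodes$id[match(nm, tree$nodes$name)]
      syn <- tree$synonyms[tree$synonyms$system == "silva", , drop = FALSE]
      n2 <- syn$id[match(nm, syn$name)]
      f1 <- if (!is.na(n1)) fam_at(n1) else NA_character_
      f2 <- if (!is.na(n2)) fam_at(n2) else NA_character_
      f <- if (!is.na(f1) && !is.na(f2)) {
        if (f1 == f2) f1 else NA_character_
      } else if (!is.na(f1)) f1 else f2
    }
    fam_votes <- c(fam_votes, f)
  }
  n <- length(fam_votes)
  votes <- fam_votes[!is.na(fam_votes)]
  if (length(votes) == 0L) {
    return(list(family = "UNASSIGNED", support = 0, n = n))
  }
  tab <- sort(table(votes), decreasing = TRUE)
  best_n <- max(tab)
  best <- sort(names(tab)[tab == best_n])[1L]
  support <- best_n / n
  list(family = if (support >= concordance) best else "UNASSIGNED",
       support = support, n = n)
}

# Toy two-kingdom taxonomy with three bacterial families, used by the
# consensus tests.
toy_tree <- function() {
  nodes <- data.frame(
    id = c("root", "Bacteria",
           "FamF", "GenF", "FamG", "GenG", "FamH", "GenH"),
    parent = c(NA, "root",
               "Bacteria", "FamF", "Bacteria", "FamG", "Bacteria", "FamH"),
    rank = c("no rank", "superkingdom",
             "family", "genus", "family", "genus", "family", "genus"),
    name = c("root", "Bacteria",
             "FamF", "GenF", "FamG", "GenG", "FamH", "GenH"),
    stringsAsFactors = FALSE)
  taxonomy_tree(nodes)
}

# --- brute-force k-mer classification oracle -------------------------------

oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  unname(pmin(km, rc))
}

# Explicit set-intersection classifier over per-label k-mer sets, with the
# same LCA and root-to-leaf path-vote semantics written out longhand.
oracle_classify <- function(read, label_kmer_sets, tree, host_family, k,
                            min_confidence = 0.10) {
  rk <- oracle_kmers(read, k)
  total <- length(rk)
  if (total == 0L) return("UNCLASSIFIED")
  labels <- names(label_kmer_sets)
  votes <- setNames(numeric(length(labels)), labels)
  lca2 <- function(ids) {
    paths <- lapply(ids, function(id) {
      p <- character(0)
      while (!is.na(id)) {
        p <- c(id, p)
        id <- tree$nodes$parent[match(id, tree$nodes$id)]
      }
      p
    })
    pref <- paths[[1L]]
    for (q in paths[-1L]) {
      m <- min(length(pref), length(q))
      same <- pref[seq_len(m)] == q[seq_len(m)]
      m <- if (all(same)) m else min(which(!same)) - 1L
      pref <- pref[seq_len(m)]
    }
    pref[length(pref)]
  }
  extra <- list()
  for (kmer in rk) {
    holders <- labels[vapply(labels, function(l) {
      kmer %in% label_kmer_sets[[l]]
    }, logical(1))]
    if (length(holders) == 1L) {
      votes[holders] <- votes[holders] + 1
    } else if (length(holders) > 1L) {
      anc <- lca2(holders)
      extra[[anc]] <- if (is.null(extra[[anc]])) 1 else extra[[anc]] + 1
    }
  }
  for (nm in names(extra)) {
    if (nm %in% names(votes)) {
      votes[nm] <- votes[nm] + extra[[nm]]
    } else {
      votes[nm] <- extra[[nm]]
    }
  }
  votes <- votes[votes > 0]
  if (length(votes) == 0L) return("UNCLASSIFIED")
  anc_of <- function(id) {
    p <- character(0)
    while (!is.na(id)) {
      p <- c(p, id)
      id <- tree$nodes$parent[match(id, tree$nodes$id)]
    }
    p
  }
  score <- vapply(names(votes), function(l) {
    sum(votes[names(votes) %in% anc_of(l)])
  }, numeric(1))
  best <- max(score)
  if (best / total < min_confidence) return("UNCLASSIFIED")
  tied <- names(votes)[score == best]
  winner <- if (length(tied) == 1L) tied else lca2(tied)
  fam <- winner
  while (!is.na(fam) && tree$nodes$rank[match(fam, tree$nodes$id)] != "family") {
    fam <- tree$nodes$parent[match(fam, tree$nodes$id)]
  }
  if (is.na(fam)) winner else if (fam == host_family) "HOST" else fam
}
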