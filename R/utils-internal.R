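# Internal helpers shared across modules. All coordinates are 0-based,
# half-open throughout the package.

# Coerce to DNAStringSet, preserving names.
as_dss <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(DNAStringSet(x))
  if (is(x, "DNAString")) return(DNAStringSet(as.character(x)))
  stop("cannot coerce object of class ", class(x)[1], " to DNAStringSet")
}

# Single sequence as an uppercase character scalar.
seq_chr <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(toupper(x))
  }
  x <- as_dss(x)
  stopifnot(length(x) == 1L)
  as.character(x[[1L]])
}

revcomp_chr <- function(x) cpp_revcomp(x)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Used for seed-derived parameter draws
# (e.g. composition bias tables) that must not perturb the main stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Merge 0-based half-open intervals given as a 2-column matrix.
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- matrix(0L, nrow = nrow(m), ncol = 2L)
  j <- 1L
  out[1L, ] <- m[1L, 1:2]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], m[i, 2L])
      } else {
        j <- j + 1L
        out[j, ] <- m[i, 1:2]
      }
    }
  }
  out <- out[seq_len(j), , drop = FALSE]
  colnames(out) <- c("start", "end")
  out
}

interval_total <- function(m) {
  if (nrow(m) == 0L) return(0L)
  sum(m[, 2L] - m[, 1L])
}

# Per-base match vector between two equal-length character scalars.
char_matches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  as.integer(ra == rb & ra != charToRaw("N")[1L])
}

# Gap-free local alignment segments between query and subject along exact
# shared-k-mer diagonals. Scoring: match +1, mismatch -`mismatch_pen`; each
# diagonal's maximal positive segments are reported with subject/query
# 0-based half-open coordinates, identity and score. Substitution-only
# divergence keeps homologous sequence on a single diagonal, which is the
# regime the synthetic fixtures generate.
diagonal_segments <- function(qseq, sseq, seeds, min_len = 30L,
                              min_identity = 0, mismatch_pen = 3,
                              min_diag_seeds = 1L) {
  empty <- data.frame(sstart = integer(0), send = integer(0),
                      qstart = integer(0), qend = integer(0),
                      length = integer(0), matches = integer(0),
                      identity = numeric(0), score = numeric(0))
  if (is.null(seeds) || nrow(seeds) == 0L) return(empty)
  qn <- nchar(qseq)
  sn <- nchar(sseq)
  diags <- seeds[, 2L] - seeds[, 1L]
  tab <- table(diags)
  use <- as.integer(names(tab))[tab >= min_diag_seeds]
  rows <- vector("list", length(use))
  for (i in seq_along(use)) {
    d <- use[i]
    s0 <- max(0L, d)
    s1 <- min(sn, d + qn)
    if (s1 - s0 < min_len) next
    q0 <- s0 - d
    m <- char_matches(substr(qseq, q0 + 1L, q0 + (s1 - s0)),
                      substr(sseq, s0 + 1L, s1))
    segs <- cpp_max_segments(m, 1, mismatch_pen, 25)
    if (nrow(segs) == 0L) next
    len <- segs[, 2L] - segs[, 1L]
    ident <- segs[, 4L] / len
    keep <- len >= min_len & ident >= min_identity
    if (!any(keep)) next
    segs <- segs[keep, , drop = FALSE]
    len <- len[keep]
    ident <- ident[keep]
    rows[[i]] <- data.frame(
      sstart = as.integer(s0 + segs[, 1L]),
      send = as.integer(s0 + segs[, 2L]),
      qstart = as.integer(q0 + segs[, 1L]),
      qend = as.integer(q0 + segs[, 2L]),
      length = as.integer(len),
      matches = as.integer(segs[, 4L]),
      identity = ident,
      score = segs[, 3L])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# Global identity between two sequences: best single diagonal (either
# orientation of `b`), matched bases divided by the longer sequence length.
global_identity <- function(a, b, seed_k = 15L) {
  a <- seq_chr(a)
  b <- seq_chr(b)
  best <- 0
  for (bb in c(b, revcomp_chr(b))) {
    seeds <- cpp_multi_seed_matches(bb, a, seed_k, 1L)[[1L]]
    if (nrow(seeds) == 0L) next
    diags <- unique(seeds[, 2L] - seeds[, 1L])
    qn <- nchar(bb)
    sn <- nchar(a)
    for (d in diags) {
      s0 <- max(0L, d)
      s1 <- min(sn, d + qn)
      if (s1 <= s0) next
      q0 <- s0 - d
      m <- char_matches(substr(bb, q0 + 1L, q0 + (s1 - s0)),
                        substr(a, s0 + 1L, s1))
      ident <- sum(m) / max(qn, sn)
      if (ident > best) best <- ident
    }
  }
  best
}

# Mismatch penalty making gap-free segment scores positive exactly above
# the requested identity threshold (match +1).
mismatch_pen_for <- function(min_identity) {
  if (min_identity >= 0.999) return(999)
  min_identity / (1 - min_identity)
}

stop_if_not_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty character scalar")
  }
}
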