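stratified_reads <- function(genome, n, read_len = 2000L, circular = FALSE,
                             seed = 1) {
  set.seed(seed)
  L <- nchar(genome)
  if (circular) {
    starts <- (round(seq(0, L - 1, length.out = n)) +
                 sample(-50:50, n, replace = TRUE)) %% L
    g2 <- paste0(genome, genome)
    seqs <- substring(g2, starts + 1, starts + read_len)
  } else {
    starts <- round(seq(0, L - read_len, length.out = n)) +
      c(0, sample(-50:50, n - 2, replace = TRUE), 0)
    starts <- pmin(pmax(starts, 0), L - read_len)
    seqs <- substring(genome, starts + 1, starts + read_len)
  }
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  seqs[flip] <- vapply(seqs[flip], rc_chr, character(1))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("rd%04d", seq_len(n))))
}

test_that("reads tiling a linear genome reassemble into one faithful contig", {
  set.seed(81)
  g <- rand_dna(60000)
  reads <- stratified_reads(g, 600, seed = 2) # 20x coverage of 2 kb reads
  asm <- greedy_assemble(reads, min_overlap = 500)
  expect_equal(length(asm$contigs), 1L)
  expect_equal(asm$topology, "linear")
  ctg <- as.character(asm$contigs[[1]])
  expect_true(ctg == g || ctg == rc_chr(g))
  expect_setequal(asm$reads[[1]], names(reads))
})

test_that("reads without overlap stay separate contigs", {
  set.seed(82)
  reads <- Biostrings::DNAStringSet(c(a = rand_dna(2000), b = rand_dna(2000)))
  asm <- greedy_assemble(reads)
  expect_equal(length(asm$contigs), 2L)
  expect_equal(sort(unname(Biostrings::width(asm$contigs))), c(2000L, 2000L))
})

test_that("sub-threshold overlaps do not merge", {
  set.seed(83)
  g <- rand_dna(4000)
  a <- substr(g, 1, 2200)        # overlap of 400 < 500
  b <- substr(g, 1801, 4000)
  asm <- greedy_assemble(Biostrings::DNAStringSet(c(a = a, b = b)),
                         min_overlap = 500)
  expect_equal(length(asm$contigs), 2L)
  asm2 <- greedy_assemble(Biostrings::DNAStringSet(c(a = a, b = b)),
                          min_overlap = 300)
  expect_equal(length(asm2$contigs), 1L)
  expect_equal(as.character(asm2$contigs[[1]]), g)
})

test_that("contained reads are absorbed", {
  set.seed(84)
  g <- rand_dna(5000)
  reads <- Biostrings::DNAStringSet(c(big = g, small = substr(g, 1000, 2600),
                                      small_rc = rc_chr(substr(g, 3000, 4800))))
  asm <- greedy_assemble(reads)
  expect_equal(length(asm$contigs), 1L)
  expect_equal(Biostrings::width(asm$contigs), 5000L)
  expect_setequal(asm$reads[[1]], c("big", "small", "small_rc"))
})

test_that("assembly output is deterministic", {
  set.seed(85)
  g <- rand_dna(30000)
  reads <- stratified_reads(g, 300, seed = 3)
  a1 <- greedy_assemble(reads)
  a2 <- greedy_assemble(reads)
  expect_identical(as.character(a1$contigs), as.character(a2$contigs))
  expect_identical(a1$reads, a2$reads)
})

test_that("a circular genome reassembles, is flagged, and trims to truth", {
  set.seed(86)
  g <- rand_dna(30000)
  reads <- stratified_reads(g, 300, circular = TRUE, seed = 4)
  asm <- greedy_assemble(reads, min_overlap = 500)
  expect_equal(length(asm$contigs), 1L)
  expect_equal(asm$topology, "circular")
  ctg <- as.character(asm$contigs[[1]])
  expect_equal(nchar(ctg), 30000L)
  doubled <- paste0(g, g)
  expect_true(grepl(ctg, doubled, fixed = TRUE) ||
                grepl(rc_chr(ctg), doubled, fixed = TRUE))
})

test_that("circularity detection flags exact terminal repeats only", {
  set.seed(87)
  g <- rand_dna(20000)
  wrapped <- paste0(g, substr(g, 1, 1000))
  res <- detect_circularity(wrapped)
  expect_true(res$circular)
  expect_equal(res$overlap, 1000L)
  expect_equal(as.character(res$trimmed[[1]]), g)
  # a random linear sequence is not circular
  expect_false(detect_circularity(rand_dna(20000))$circular)
  # an overlap below the threshold does not count
  short_wrap <- paste0(g, substr(g, 1, 400))
  expect_false(detect_circularity(short_wrap, min_overlap = 500)$circular)
  expect_true(detect_circularity(short_wrap, min_overlap = 300)$circular)
})

test_that("reassembly filtering keeps evidence-bearing contigs only", {
  set.seed(88)
  marker <- rand_dna(900)
  good <- paste0(rand_dna(3000), marker, rand_dna(3000))
  junk <- rand_dna(4000)
  result <- structure(list(
    contigs = Biostrings::DNAStringSet(c(good = good, junk = junk)),
    topology = c("linear", "linear"),
    reads = list(c("r1"), c("r2"))), class = "assembly_result")
  kept <- filter_reassembly(result, Biostrings::DNAStringSet(c(mk = marker)),
                            Biostrings::DNAStringSet())
  expect_equal(names(kept), "good")
  # similarity evidence rescues a contig without markers
  kept2 <- filter_reassembly(result, Biostrings::DNAStringSet(),
                             Biostrings::DNAStringSet(c(ref = junk)))
  expect_equal(names(kept2), "junk")
  empty <- structure(list(contigs = Biostrings::DNAStringSet(),
                          topology = character(0), reads = list()),
                     class = "assembly_result")
  expect_equal(length(filter_reassembly(empty,
                                        Biostrings::DNAStringSet(c(mk = marker)),
                                        Biostrings::DNAStringSet())), 0L)
})

test_that("fixture bin reassemblies are pure and faithful", {
  fx <- get_small_fixture()
  db <- build_kmer_db(fx$family_refs[c("Anaplasmataceae", "Streptococcaceae",
                                       "Hostidae")],
                      fx$tree, "Hostidae")
  rb <- bin_reads(db, fx$reads)
  truth <- setNames(fx$read_truth$species, fx$read_truth$read_id)
  for (fam in c("Anaplasmataceae", "Streptococcaceae")) {
    asm <- greedy_assemble(fx$reads[rb$bins[[fam]]])
    # purity: constituent reads never cross species
    expect_equal(length(unique(truth[unlist(asm$reads)])), 1L)
    sp <- unique(truth[unlist(asm$reads)])
    g <- as.character(fx$genomes[[sp]])
    span <- sum(Biostrings::width(asm$contigs))
    expect_lt(abs(span - nchar(g)) / nchar(g), 0.01)
    expect_gte(ssusieve:::global_identity(g, as.character(asm$contigs[[1]])),
               0.999)
  }
})
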