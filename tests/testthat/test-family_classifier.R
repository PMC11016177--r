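two_family_db <- function(seed = 55, glen = 8000, k = 50, mask = FALSE) {
  set.seed(seed)
  tr <- toy_tree()
  gA <- Biostrings::DNAStringSet(c(genomeA = rand_dna(glen)))
  gB <- Biostrings::DNAStringSet(c(genomeB = rand_dna(glen)))
  gH <- Biostrings::DNAStringSet(c(genomeH = rand_dna(glen)))
  db <- build_kmer_db(list(FamF = gA, FamG = gB, FamH = gH), tr,
                      host_family = "FamH", k = k, mask = mask)
  list(db = db, tr = tr, gA = gA, gB = gB, gH = gH)
}

test_that("k-mer counts match sequence length arithmetic", {
  set.seed(50)
  g <- Biostrings::DNAStringSet(c(g1 = rand_dna(10000)))
  tr <- toy_tree()
  db <- build_kmer_db(list(FamF = g), tr, "FamH", k = 50, mask = FALSE)
  expect_lte(length(db$kmers), 10000 - 50 + 1)
  expect_gt(length(db$kmers), 9000) # random sequence: few collisions
  expect_false(anyDuplicated(db$kmers) > 0)
  expect_equal(db$manifest$n_kmers, length(db$kmers))
})

test_that("k-mers shared between two families take their LCA label", {
  set.seed(51)
  tr <- toy_tree()
  g <- rand_dna(5000)
  db <- build_kmer_db(list(FamF = Biostrings::DNAStringSet(c(x = g)),
                           FamG = Biostrings::DNAStringSet(c(y = g))),
                      tr, "FamH", k = 50, mask = FALSE)
  expect_true(all(db$labels == "Bacteria"))
})

test_that("a fully masked genome contributes nothing, with a warning", {
  tr <- toy_tree()
  g <- Biostrings::DNAStringSet(c(poly = strrep("A", 5000)))
  expect_warning(db <- build_kmer_db(list(FamF = g), tr, "FamH", k = 50),
                 "masked")
  expect_equal(length(db$kmers), 0L)
})

test_that("database construction is order-independent", {
  set.seed(52)
  tr <- toy_tree()
  gs <- list(FamF = Biostrings::DNAStringSet(c(a = rand_dna(4000))),
             FamG = Biostrings::DNAStringSet(c(b = rand_dna(4000))),
             FamH = Biostrings::DNAStringSet(c(c = rand_dna(4000))))
  db1 <- build_kmer_db(gs, tr, "FamH", k = 50, mask = FALSE)
  db2 <- build_kmer_db(rev(gs), tr, "FamH", k = 50, mask = FALSE)
  expect_identical(db1$kmers, db2$kmers)
  expect_identical(db1$labels, db2$labels)
})

test_that("a read drawn verbatim from one genome classifies with confidence 1", {
  x <- two_family_db()
  read <- substr(as.character(x$gA[[1]]), 1001, 3000)
  res <- classify_read(x$db, Biostrings::DNAStringSet(c(r = read)))
  expect_equal(res$resolved, "FamF")
  expect_equal(res$confidence, 1.0)
  expect_equal(unname(res$votes["FamF"]), 2000L - 50L + 1L)
  # host-genome reads resolve to HOST
  hread <- substr(as.character(x$gH[[1]]), 501, 2500)
  hres <- classify_read(x$db, Biostrings::DNAStringSet(c(r = hread)))
  expect_equal(hres$resolved, "HOST")
})

test_that("reads foreign to the database are UNCLASSIFIED with zero shared k-mers", {
  x <- two_family_db()
  set.seed(56)
  foreign <- rand_dna(2000)
  res <- classify_read(x$db, Biostrings::DNAStringSet(c(r = foreign)))
  expect_equal(res$resolved, "UNCLASSIFIED")
  # brute-force set intersection confirms no shared canonical 50-mer
  expect_equal(length(intersect(oracle_kmers(foreign, 50), x$db$kmers)), 0L)
  # reads shorter than k cannot vote
  short <- classify_read(x$db, Biostrings::DNAStringSet(c(r = rand_dna(40))))
  expect_equal(short$resolved, "UNCLASSIFIED")
  expect_equal(short$kmers_total, 0L)
})

test_that("an equal-evidence chimera resolves to the LCA, above family", {
  x <- two_family_db()
  chimera <- paste0(substr(as.character(x$gA[[1]]), 1, 2000),
                    substr(as.character(x$gB[[1]]), 1, 2000))
  res <- classify_read(x$db, Biostrings::DNAStringSet(c(r = chimera)))
  expect_equal(res$label, "Bacteria")
  expect_equal(res$resolved, "Bacteria")
  # hand vote arithmetic: each half contributes 2000 - 50 + 1 votes
  expect_equal(unname(res$votes["FamF"]), 1951L)
  expect_equal(unname(res$votes["FamG"]), 1951L)
  # and such a read is binned to no family
  rb <- bin_reads(x$db, Biostrings::DNAStringSet(c(r = chimera)))
  expect_equal(length(rb$bins), 0L)
  expect_equal(rb$ambiguous, "r")
})

test_that("low-confidence vote fractions are left unclassified", {
  x <- two_family_db()
  # 100 matching bases in a 4000-base read: ~1.3% of k-mers vote
  read <- paste0(substr(as.character(x$gA[[1]]), 1, 100), {
    set.seed(57)
    rand_dna(3900)
  })
  res <- classify_read(x$db, Biostrings::DNAStringSet(c(r = read)))
  expect_equal(res$resolved, "UNCLASSIFIED")
  expect_gt(res$confidence, 0)
  expect_lt(res$confidence, 0.10)
  # the same read passes at a permissive threshold
  res2 <- classify_read(x$db, Biostrings::DNAStringSet(c(r = read)),
                        min_confidence = 0.005)
  expect_equal(res2$resolved, "FamF")
})

test_that("classification agrees with the explicit set-intersection oracle", {
  x <- two_family_db(seed = 58, glen = 6000)
  label_sets <- list(FamF = oracle_kmers(as.character(x$gA[[1]]), 50),
                     FamG = oracle_kmers(as.character(x$gB[[1]]), 50),
                     FamH = oracle_kmers(as.character(x$gH[[1]]), 50))
  set.seed(59)
  sources <- c("A", "B", "H", "random", "mutA", "chimera")
  for (i in 1:60) {
    src <- sample(sources, 1)
    read <- switch(src,
      A = substr(as.character(x$gA[[1]]), s <- sample(4000, 1), s + 1500),
      B = substr(as.character(x$gB[[1]]), s <- sample(4000, 1), s + 1500),
      H = substr(as.character(x$gH[[1]]), s <- sample(4000, 1), s + 1500),
      random = rand_dna(1500),
      mutA = mutate_sequence(
        substr(as.character(x$gA[[1]]), s <- sample(4000, 1), s + 1500),
        0.02),
      chimera = paste0(
        substr(as.character(x$gA[[1]]), s <- sample(4000, 1), s + 700),
        substr(as.character(x$gB[[1]]), s2 <- sample(4000, 1), s2 + 700)))
    got <- classify_read(x$db, Biostrings::DNAStringSet(c(r = read)))
    want <- oracle_classify(read, label_sets, x$tr, "FamH", 50)
    expect_equal(got$resolved, want, info = paste("source:", src))
  }
})

test_that("binning routes every read to at most one family", {
  fx <- get_small_fixture()
  db <- build_kmer_db(fx$family_refs[c("Anaplasmataceae", "Streptococcaceae",
                                       "Hostidae")],
                      fx$tree, "Hostidae")
  rb <- bin_reads(db, fx$reads)
  all_binned <- unlist(rb$bins)
  expect_false(anyDuplicated(all_binned) > 0)
  expect_equal(sort(unname(c(all_binned, rb$host, rb$unclassified,
                             rb$ambiguous))),
               sort(names(fx$reads)))
  # binned reads match truth exactly on this fixture
  truth <- setNames(fx$read_truth$family, fx$read_truth$read_id)
  for (fam in names(rb$bins)) {
    expect_true(all(truth[rb$bins[[fam]]] == fam))
  }
  # reads of the assembly-omitted species stay unclassified (their family
  # has no reference genomes in this database)
  nosema <- fx$read_truth$read_id[fx$read_truth$species == "Nosema parva"]
  expect_true(all(nosema %in% rb$unclassified))
})

test_that("binning the omitted species' family captures its reads", {
  fx <- get_small_fixture()
  db <- build_kmer_db(fx$family_refs[c("Anaplasmataceae", "Nosemataceae",
                                       "Hostidae")],
                      fx$tree, "Hostidae")
  rb <- bin_reads(db, fx$reads)
  nosema <- fx$read_truth$read_id[fx$read_truth$species == "Nosema parva"]
  expect_true(all(nosema %in% rb$bins[["Nosemataceae"]]))
})

test_that("empty read sets produce empty bins", {
  x <- two_family_db()
  rb <- bin_reads(x$db, Biostrings::DNAStringSet())
  expect_equal(length(rb$bins), 0L)
  expect_equal(length(rb$host), 0L)
})

test_that("databases round-trip through their TSV serialization", {
  x <- two_family_db(glen = 2000)
  d <- tempfile()
  write_kmer_db(x$db, d)
  db2 <- read_kmer_db(d)
  expect_identical(db2$kmers, x$db$kmers)
  expect_identical(db2$labels, x$db$labels)
  expect_equal(db2$k, x$db$k)
  expect_equal(db2$host_family, x$db$host_family)
  read <- substr(as.character(x$gA[[1]]), 1, 500)
  expect_equal(classify_read(db2, read)$resolved, "FamF")
})
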