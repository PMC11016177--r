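test_that("simulated genomes hit their GC target", {
  g <- simulate_genome(100000, gc = 0.30, bias_seed = 3, seed = 1)
  gc <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 100000
  expect_gte(gc, 0.28)
  expect_lte(gc, 0.32)
})

test_that("genome simulation is deterministic per seed", {
  g1 <- simulate_genome(20000, gc = 0.45, bias_seed = 9, seed = 5)
  g2 <- simulate_genome(20000, gc = 0.45, bias_seed = 9, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
})

test_that("unbiased genomes have a uniform tetranucleotide spectrum", {
  g <- as.character(simulate_genome(100000, gc = 0.5, bias_seed = 0,
                                    seed = 11)[[1]])
  # non-overlapping 4-mers are an i.i.d. multinomial sample
  starts <- seq(1, nchar(g) - 3, by = 4)
  quads <- substring(g, starts, starts + 3)
  counts <- table(factor(quads, levels = sort(unique(quads))))
  expect_equal(length(counts), 256L)
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("composition bias separates genomes of equal GC", {
  g1 <- simulate_genome(50000, gc = 0.4, bias_seed = 21, seed = 1)
  g2 <- simulate_genome(50000, gc = 0.4, bias_seed = 22, seed = 1)
  f1 <- Biostrings::oligonucleotideFrequency(g1, 3)[1, ]
  f2 <- Biostrings::oligonucleotideFrequency(g2, 3)[1, ]
  expect_lt(stats::cor(f1, f2), 0.99)
})

test_that("embedded elements are recorded with exact coordinates", {
  set.seed(4)
  genome <- Biostrings::DNAStringSet(c(g = rand_dna(100000)))
  ssu <- Biostrings::DNAStringSet(c(ssu1 = rand_dna(1500)))
  res <- embed_elements(genome, ssu)
  expect_equal(Biostrings::width(res$genome), 101500L)
  el <- res$elements
  expect_equal(nrow(el), 1L)
  got <- substr(as.character(res$genome[[1]]), el$start + 1, el$end)
  if (el$strand == "-") got <- rc_chr(got)
  expect_equal(got, as.character(ssu[[1]]))
})

test_that("multiple insertions never overlap and round-trip by strand", {
  set.seed(8)
  genome <- Biostrings::DNAStringSet(c(g = rand_dna(60000)))
  ssu <- Biostrings::DNAStringSet(c(s1 = rand_dna(1600)))
  markers <- Biostrings::DNAStringSet(
    setNames(vapply(1:12, function(i) rand_dna(700), character(1)),
             sprintf("m%02d", 1:12)))
  res <- embed_elements(genome, ssu, markers)
  el <- res$elements
  expect_equal(nrow(el), 13L)
  expect_true(all(el$start[-1] >= el$end[-nrow(el)])) # sorted, disjoint
  expect_true(any(el$strand == "-")) # both strands exercised at this seed
  gchr <- as.character(res$genome[[1]])
  all_el <- c(ssu, markers)
  for (i in seq_len(nrow(el))) {
    got <- substr(gchr, el$start[i] + 1, el$end[i])
    if (el$strand[i] == "-") got <- rc_chr(got)
    expect_equal(got, as.character(all_el[[el$id[i]]]))
  }
})

test_that("element embedding rejects short SSUs and crowded genomes", {
  genome <- Biostrings::DNAStringSet(c(g = rand_dna(5000)))
  expect_error(embed_elements(genome,
                              Biostrings::DNAStringSet(c(s = rand_dna(800)))),
               "1,200")
  many <- Biostrings::DNAStringSet(
    setNames(rep(rand_dna(1300), 40), sprintf("s%d", 1:40)))
  expect_error(embed_elements(genome, many), "too short")
})

test_that("read depth is proportional to abundance weights", {
  sp <- data.frame(
    name = c("big sp", "small sp"), family = c("FamA", "FamB"),
    domain = c("Bacteria", "Bacteria"),
    genome_length = c(30000L, 30000L), gc = c(0.4, 0.4),
    bias_seed = c(1L, 2L), weight = c(9, 1),
    is_host = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cs <- community_spec(sp, coverage_total = 60, hgt_length = 0L)
  set.seed(3)
  genomes <- Biostrings::DNAStringSet(c(
    "big sp" = rand_dna(30000), "small sp" = rand_dna(30000)))
  rd <- simulate_reads(cs, genomes, seed = 3)
  cov <- tapply(rd$truth$length, rd$truth$species, sum) / 30000
  ratio <- cov[["big sp"]] / cov[["small sp"]]
  expect_gt(ratio, 9 * 0.85)
  expect_lt(ratio, 9 * 1.15)
})

test_that("zero or negative abundance weights are rejected", {
  sp <- data.frame(name = "x y", family = "F", domain = "Bacteria",
                   genome_length = 20000L, gc = 0.5, bias_seed = 1L,
                   weight = 0, is_host = TRUE, stringsAsFactors = FALSE)
  expect_error(community_spec(sp), "weights")
})

test_that("read simulation is deterministic and completely labelled", {
  fx <- get_small_fixture()
  expect_equal(nrow(fx$read_truth), length(fx$reads))
  expect_true(all(fx$read_truth$read_id == names(fx$reads)))
  expect_false(any(is.na(fx$read_truth$family)))
  fx2 <- simulate_community(small_spec(), seed = 42)
  expect_identical(as.character(fx$reads), as.character(fx2$reads))
  expect_identical(as.character(fx$assembly), as.character(fx2$assembly))
})

test_that("realized coverage tracks the configured depth at >= 20x", {
  fx <- get_small_fixture()
  sp <- fx$spec$species
  covs <- fx$spec$coverage_total * sp$weight / sum(sp$weight)
  glen <- setNames(Biostrings::width(fx$genomes), names(fx$genomes))
  for (i in which(covs >= 20)) {
    nm <- sp$name[i]
    realized <- sum(fx$read_truth$length[fx$read_truth$species == nm]) /
      glen[[nm]]
    expect_gt(realized, covs[i] * 0.85)
    expect_lt(realized, covs[i] * 1.15)
  }
})

test_that("assembly fragmentation partitions each genome", {
  set.seed(12)
  genomes <- Biostrings::DNAStringSet(c("sp one" = rand_dna(100000)))
  st <- data.frame(name = "sp one", family = "FamA",
                   stringsAsFactors = FALSE)
  a1 <- simulate_assembly(genomes, st, fragmentation = 1L)
  expect_equal(length(a1$contigs), 1L)
  expect_equal(as.character(a1$contigs[[1]]), as.character(genomes[[1]]))
  a5 <- simulate_assembly(genomes, st, fragmentation = 5L)
  expect_equal(length(a5$contigs), 5L)
  expect_equal(paste(as.character(a5$contigs), collapse = ""),
               as.character(genomes[[1]]))
  expect_equal(sum(a5$truth$length), 100000L)
})

test_that("omitted species are absent from contigs but present in reads", {
  fx <- get_small_fixture()
  expect_false("Nosema parva" %in% fx$contig_truth$species)
  expect_true("Nosema parva" %in% fx$read_truth$species)
})

test_that("assembly breakpoints never split embedded elements", {
  fx <- get_small_fixture()
  for (i in seq_len(nrow(fx$contig_truth))) {
    ct <- fx$contig_truth[i, ]
    el <- fx$element_truth[fx$element_truth$species == ct$species, ]
    # every element lies entirely inside or outside each contig interval
    cut <- el$start < ct$end & el$end > ct$end
    expect_false(any(cut))
  }
})

test_that("the host carries a cobiont-derived insertion with exact record", {
  fx <- get_small_fixture()
  ht <- fx$hgt_truth
  expect_false(is.null(ht))
  host <- as.character(fx$genomes[[ht$host_species]])
  donor <- as.character(fx$genomes[[ht$donor_species]])
  expect_equal(substr(host, ht$host_start + 1, ht$host_end),
               substr(donor, ht$donor_start + 1, ht$donor_end))
})
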