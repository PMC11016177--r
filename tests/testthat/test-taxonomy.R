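test_that("lineage walks root to taxon with ranks", {
  tr <- toy_tree()
  l <- lineage(tr, "GenF")
  expect_equal(as.character(l), c("root", "Bacteria", "FamF", "GenF"))
  expect_equal(attr(l, "ranks"),
               c("no rank", "superkingdom", "family", "genus"))
  expect_equal(family_of(tr, "GenF"), "FamF")
  root_l <- lineage(tr, "root")
  expect_equal(length(root_l), 1L)
  expect_true(is.na(family_of(tr, "root")))
  expect_error(lineage(tr, "nope"), "unknown")
})

test_that("a lineage without a family rank returns absent, not an error", {
  nodes <- data.frame(
    id = c("root", "CladeX", "sp x"),
    parent = c(NA, "root", "CladeX"),
    rank = c("no rank", "clade", "species"),
    name = c("root", "CladeX", "sp x"), stringsAsFactors = FALSE)
  tr <- taxonomy_tree(nodes)
  expect_true(is.na(family_of(tr, "sp x")))
})

test_that("taxonomy construction validates root and parents", {
  nodes <- data.frame(id = c("a", "b"), parent = c(NA, NA),
                      rank = "no rank", name = c("a", "b"),
                      stringsAsFactors = FALSE)
  expect_error(taxonomy_tree(nodes), "exactly one root")
  nodes2 <- data.frame(id = c("root", "b"), parent = c(NA, "ghost"),
                       rank = "no rank", name = c("root", "b"),
                       stringsAsFactors = FALSE)
  expect_error(taxonomy_tree(nodes2), "unknown parent")
})

test_that("lowest common ancestors are computed on the harmonized tree", {
  tr <- toy_tree()
  expect_equal(taxon_lca(tr, c("GenF", "GenG")), "Bacteria")
  expect_equal(taxon_lca(tr, c("GenF", "FamF")), "FamF")
  expect_equal(taxon_lca(tr, "FamH"), "FamH")
})

make_ref_taxa <- function(ids, genera) setNames(genera, ids)

test_that("the consensus rule assigns families at the printed thresholds", {
  tr <- toy_tree()
  mk_hits <- function(fams, idents) {
    data.frame(ref_id = sprintf("r%02d", seq_along(fams)),
               identity = idents, stringsAsFactors = FALSE)
  }
  # 20 concordant hits above the identity filter
  fams <- rep("GenF", 20)
  hits <- mk_hits(fams, seq(0.99, 0.95, length.out = 20))
  rt <- make_ref_taxa(hits$ref_id, fams)
  call <- consensus_family(hits, tr, rt)
  expect_equal(call$family, "FamF")
  expect_equal(call$support, 1.0)
  expect_equal(call$n_hits_considered, 20L)

  # 16/20 = 0.80: equality passes
  fams <- c(rep("GenF", 16), rep("GenG", 4))
  hits <- mk_hits(fams, seq(0.99, 0.95, length.out = 20))
  call <- consensus_family(hits, tr, make_ref_taxa(hits$ref_id, fams))
  expect_equal(call$family, "FamF")
  expect_equal(call$support, 0.80)

  # 15/20 = 0.75: below threshold
  fams <- c(rep("GenF", 15), rep("GenG", 5))
  hits <- mk_hits(fams, seq(0.99, 0.95, length.out = 20))
  call <- consensus_family(hits, tr, make_ref_taxa(hits$ref_id, fams))
  expect_equal(call$family, "UNASSIGNED")
  expect_equal(call$support, 0.75)

  # fewer than 20 retained hits: vote over what is available
  fams <- c(rep("GenF", 4), "GenG")
  hits <- mk_hits(fams, c(0.99, 0.98, 0.97, 0.96, 0.95))
  call <- consensus_family(hits, tr, make_ref_taxa(hits$ref_id, fams))
  expect_equal(call$family, "FamF")
  expect_equal(call$support, 0.80)
  expect_equal(call$n_hits_considered, 5L)

  # empty input
  call <- consensus_family(hits[0, ], tr, character(0))
  expect_equal(call$family, "UNASSIGNED")
  expect_equal(call$n_hits_considered, 0L)

  # the identity filter is strict: hits at exactly 0.90 are dropped
  hits <- mk_hits(rep("GenF", 3), c(0.95, 0.90, 0.90))
  call <- consensus_family(hits, tr, make_ref_taxa(hits$ref_id,
                                                   rep("GenF", 3)))
  expect_equal(call$n_hits_considered, 1L)
})

test_that("label systems disagreeing on the family cancel a hit's vote", {
  nodes <- data.frame(
    id = c("root", "Bacteria", "FamF", "GenF", "FamG"),
    parent = c(NA, "root", "Bacteria", "FamF", "Bacteria"),
    rank = c("no rank", "superkingdom", "family", "genus", "family"),
    name = c("root", "Bacteria", "FamF", "GenF", "FamG"),
    stringsAsFactors = FALSE)
  # under the SILVA system the name "GenF" maps to family G
  syn <- data.frame(name = "GenF", id = "FamG", system = "silva",
                    stringsAsFactors = FALSE)
  tr <- taxonomy_tree(nodes, syn)
  hits <- data.frame(ref_id = c("r1", "r2"), identity = c(0.99, 0.98),
                     stringsAsFactors = FALSE)
  call <- consensus_family(hits, tr, c(r1 = "GenF", r2 = "GenF"))
  # both hits discordant: no family reaches any support
  expect_equal(call$family, "UNASSIGNED")
  expect_equal(call$support, 0)
  expect_true(all(is.na(call$table$family)))
})

test_that("consensus matches a brute-force oracle on randomized hit tables", {
  tr <- toy_tree()
  genera <- c("GenF", "GenG", "GenH")
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    hits <- data.frame(
      ref_id = sprintf("r%02d", sample(99, n)),
      identity = round(runif(n, 0.85, 1.0), 4),
      stringsAsFactors = FALSE)
    rt <- setNames(sample(c(genera, "unknown taxon"), n, replace = TRUE,
                          prob = c(0.3, 0.3, 0.3, 0.1)), hits$ref_id)
    got <- consensus_family(hits, tr, rt)
    want <- oracle_consensus(hits, tr, rt)
    expect_equal(got$family, want$family)
    expect_equal(got$support, want$support)
    expect_equal(got$n_hits_considered, want$n)
  }
})

test_that("adding a hit of the winning family never unassigns the call", {
  tr <- toy_tree()
  genera <- c("GenF", "GenG")
  set.seed(78)
  checked <- 0L
  for (i in 1:100) {
    n <- sample(2:25, 1)
    hits <- data.frame(ref_id = sprintf("r%02d", sample(90, n)),
                       identity = round(runif(n, 0.91, 1.0), 4),
                       stringsAsFactors = FALSE)
    rt <- setNames(sample(genera, n, replace = TRUE, prob = c(0.85, 0.15)),
                   hits$ref_id)
    call <- consensus_family(hits, tr, rt)
    if (call$family == "UNASSIGNED") next
    genus_of_winner <- if (call$family == "FamF") "GenF" else "GenG"
    hits2 <- rbind(hits, data.frame(ref_id = "r99", identity = 0.999,
                                    stringsAsFactors = FALSE))
    rt2 <- c(rt, r99 = genus_of_winner)
    call2 <- consensus_family(hits2, tr, rt2)
    expect_equal(call2$family, call$family)
    expect_gte(call2$support, call$support)
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("the family catalogue separates cobionts, host and unassigned", {
  tr <- toy_tree()
  mk_call <- function(fam, id) {
    structure(list(ssu_id = id, family = fam, support = 1,
                   n_hits_considered = 20L, table = data.frame()),
              class = "classification_call")
  }
  calls <- list(mk_call("FamF", "s1"), mk_call("FamF", "s2"),
                mk_call("FamG", "s3"), mk_call("FamH", "s4"),
                mk_call("UNASSIGNED", "s5"))
  res <- family_catalogue(calls, tr, host_family = "FamH")
  expect_setequal(res$cobiont_families, c("FamF", "FamG"))
  expect_true(res$catalogue$is_host[res$catalogue$family == "FamH"])
  expect_equal(res$catalogue$n_ssu[res$catalogue$family == "FamF"], 2L)
  expect_equal(res$unassigned$ssu_id, "s5")
  # all-host calls leave an empty cobiont list
  res2 <- family_catalogue(list(mk_call("FamH", "x")), tr, "FamH")
  expect_equal(length(res2$cobiont_families), 0L)
  expect_error(family_catalogue(calls, tr, "NotAFamily"), "not in taxonomy")
})

test_that("taxonomies round-trip through the TSV bundle", {
  fx <- get_small_fixture()
  d <- tempfile()
  write_taxonomy_bundle(fx$tree, d)
  tr2 <- read_taxonomy_bundle(d)
  expect_equal(tr2$nodes$id, fx$tree$nodes$id)
  expect_equal(tr2$nodes$parent, fx$tree$nodes$parent)
  expect_equal(tr2$synonyms$name, fx$tree$synonyms$name)
  expect_equal(resolve_taxon(tr2, "Ehrlichiaceae", "silva"),
               "Anaplasmataceae")
  expect_true(is.na(resolve_taxon(tr2, "Ehrlichiaceae", "ncbi")))
})
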