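#' Construct a rank-aware taxonomy tree
#'
#' One harmonized node set carries two label systems: primary (NCBI-style)
#' node names, plus a synonym table mapping alternative (SILVA-style)
#' names onto the same nodes. The tree must have a single root and every
#' node must reach it.
#'
#' @param nodes Data frame with columns \code{id}, \code{parent} (\code{NA}
#'   for the root), \code{rank}, \code{name}.
#' @param synonyms Optional data frame with columns \code{name}, \code{id},
#'   \code{system}.
#' @return An object of class \code{taxonomy_tree}.
#' @export
taxonomy_tree <- function(nodes, synonyms = NULL) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent", "rank", "name") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  roots <- nodes$id[is.na(nodes$parent) | nodes$parent == nodes$id]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root")
  known <- nodes$parent %in% nodes$id | is.na(nodes$parent)
  if (!all(known)) {
    stop("unknown parent(s): ",
         paste(unique(nodes$parent[!known]), collapse = ", "))
  }
  if (is.null(synonyms)) {
    synonyms <- data.frame(name = character(0), id = character(0),
                           system = character(0), stringsAsFactors = FALSE)
  }
  tree <- structure(list(nodes = nodes, synonyms = synonyms,
                         root = roots[1L]),
                    class = "taxonomy_tree")
  # every node must reach the root
  for (id in nodes$id) lineage(tree, id)
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, %d synonym(s), root '%s'\n",
              nrow(x$nodes), nrow(x$synonyms), x$root))
  invisible(x)
}

#' Root-to-taxon lineage
#'
#' @param tree A \code{taxonomy_tree}.
#' @param taxon A node id.
#' @return Character vector of node ids from the root down to \code{taxon},
#'   with the per-node ranks as the \code{ranks} attribute.
#' @export
lineage <- function(tree, taxon) {
  idx <- match(taxon, tree$nodes$id)
  if (is.na(idx)) stop("unknown taxon: ", taxon)
  path <- character(0)
  ranks <- character(0)
  guard <- 0L
  while (!is.na(idx)) {
    path <- c(tree$nodes$id[idx], path)
    ranks <- c(tree$nodes$rank[idx], ranks)
    parent <- tree$nodes$parent[idx]
    if (is.na(parent) || parent == tree$nodes$id[idx]) break
    idx <- match(parent, tree$nodes$id)
    guard <- guard + 1L
    if (guard > nrow(tree$nodes)) stop("cycle in taxonomy at ", taxon)
  }
  if (path[1L] != tree$root) stop("node does not reach the root: ", taxon)
  attr(path, "ranks") <- ranks
  path
}

#' Family of a taxon
#'
#' @inheritParams lineage
#' @return The family-rank node id on the taxon's lineage, or \code{NA}
#'   when the lineage has no family rank (e.g. nodes above family).
#' @export
family_of <- function(tree, taxon) {
  l <- lineage(tree, taxon)
  fam <- l[attr(l, "ranks") == "family"]
  if (length(fam) == 0L) NA_character_ else fam[1L]
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree A \code{taxonomy_tree}.
#' @param taxa Character vector of node ids.
#' @return The deepest node ancestral to (or equal to) all of \code{taxa}.
#' @export
taxon_lca <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("no taxa given")
  paths <- lapply(taxa, function(t) as.character(lineage(tree, t)))
  pref <- paths[[1L]]
  for (p in paths[-1L]) {
    k <- min(length(pref), length(p))
    eq <- pref[seq_len(k)] == p[seq_len(k)]
    k <- if (all(eq)) k else min(which(!eq)) - 1L
    pref <- pref[seq_len(k)]
  }
  pref[length(pref)]
}

#' Resolve a taxon name under a label system
#'
#' Primary node names belong to the \code{"ncbi"} system; the synonym table
#' supplies additional systems (e.g. \code{"silva"}). With
#' \code{system = "any"}, primary names are tried first, then synonyms.
#'
#' @param tree A \code{taxonomy_tree}.
#' @param name A taxon name.
#' @param system \code{"ncbi"}, \code{"silva"}, or \code{"any"}.
#' @return The node id, or \code{NA_character_} when unresolvable.
#' @export
resolve_taxon <- function(tree, name, system = "any") {
  if (system %in% c("ncbi", "any")) {
    idx <- match(name, tree$nodes$name)
    if (!is.na(idx)) return(tree$nodes$id[idx])
    if (system == "ncbi") return(NA_character_)
  }
  syn <- tree$synonyms
  if (system != "any") syn <- syn[syn$system == system, , drop = FALSE]
  idx <- match(name, syn$name)
  if (!is.na(idx)) syn$id[idx] else NA_character_
}

#' Family-level consensus classification of an SSU region
#'
#' Implements the consensus rule for assigning one SSU query to a family:
#' reference hits are filtered to nucleotide identity strictly above
#' \code{min_identity}, sorted by identity (ties broken by reference id),
#' and the best \code{top_n} are polled. Each polled hit votes for a
#' family only when both label systems resolve its taxon to the same
#' harmonized family node (a taxon resolvable in only one system counts
#' under that system). The family is assigned when at least
#' \code{concordance} of the polled hits agree — 16 of 20 passes at the
#' default 0.80 — otherwise the call is \code{UNASSIGNED}. When fewer than
#' \code{top_n} hits survive the identity filter, all of them are polled.
#'
#' @param hits Data frame with columns \code{ref_id} and \code{identity}
#'   (fractions in [0, 1]).
#' @param tree A \code{taxonomy_tree}.
#' @param ref_taxa Named character vector mapping reference ids to taxon
#'   names.
#' @param min_identity Identity filter (exclusive), default 0.90.
#' @param top_n Number of best hits polled, default 20.
#' @param concordance Required agreement fraction (inclusive), default
#'   0.80.
#' @param ssu_id Optional query id carried into the call record.
#' @return An object of class \code{classification_call}: list with
#'   \code{ssu_id}, \code{family} (node id or \code{"UNASSIGNED"}),
#'   \code{support}, \code{n_hits_considered} and the polled per-hit
#'   \code{table}.
#' @export
consensus_family <- function(hits, tree, ref_taxa, min_identity = 0.90,
                             top_n = 20L, concordance = 0.80,
                             ssu_id = NA_character_) {
  call0 <- function(family, support, n, tab) {
    structure(list(ssu_id = ssu_id, family = family, support = support,
                   n_hits_considered = n, table = tab),
              class = "classification_call")
  }
  empty_tab <- data.frame(ref_id = character(0), identity = numeric(0),
                          family = character(0), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(call0("UNASSIGNED", 0, 0L, empty_tab))
  }
  hits <- hits[hits$identity > min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) return(call0("UNASSIGNED", 0, 0L, empty_tab))
  hits <- hits[order(-hits$identity, hits$ref_id), , drop = FALSE]
  hits <- head(hits, top_n)
  fams <- vapply(hits$ref_id, function(rid) {
    taxon_name <- ref_taxa[[rid]]
    if (is.null(taxon_name) || is.na(taxon_name)) return(NA_character_)
    n_ncbi <- resolve_taxon(tree, taxon_name, "ncbi")
    n_silva <- resolve_taxon(tree, taxon_name, "silva")
    f_ncbi <- if (!is.na(n_ncbi)) family_of(tree, n_ncbi) else NA_character_
    f_silva <- if (!is.na(n_silva)) family_of(tree, n_silva) else NA_character_
    if (!is.na(f_ncbi) && !is.na(f_silva)) {
      if (f_ncbi == f_silva) f_ncbi else NA_character_
    } else if (!is.na(f_ncbi)) {
      f_ncbi
    } else {
      f_silva
    }
  }, character(1))
  tab <- data.frame(ref_id = hits$ref_id, identity = hits$identity,
                    family = unname(fams), stringsAsFactors = FALSE)
  n <- nrow(tab)
  votes <- table(fams[!is.na(fams)])
  if (length(votes) == 0L) return(call0("UNASSIGNED", 0, n, tab))
  best <- names(votes)[order(-votes, names(votes))][1L]
  support <- as.numeric(votes[best]) / n
  fam <- if (support >= concordance) best else "UNASSIGNED"
  call0(fam, support, n, tab)
}

#' @export
print.classification_call <- function(x, ...) {
  cat(sprintf("classification_call %s: %s (support %.2f over %d hits)\n",
              x$ssu_id, x$family, x$support, x$n_hits_considered))
  invisible(x)
}

#' Catalogue the cobiont families implied by SSU classifications
#'
#' @param calls List of \code{classification_call} objects.
#' @param tree A \code{taxonomy_tree}.
#' @param host_family Family node id of the host species.
#' @return A list with \code{catalogue} (data frame: family, n_ssu,
#'   is_host), \code{cobiont_families} (character vector) and
#'   \code{unassigned} (data frame of unassigned call ids).
#' @export
family_catalogue <- function(calls, tree, host_family) {
  if (is.na(match(host_family, tree$nodes$id))) {
    stop("host family not in taxonomy: ", host_family)
  }
  fams <- vapply(calls, function(c) c$family, character(1))
  ids <- vapply(calls, function(c) {
    if (is.na(c$ssu_id)) "" else c$ssu_id
  }, character(1))
  assigned <- fams[fams != "UNASSIGNED"]
  tab <- table(assigned)
  catalogue <- data.frame(family = names(tab), n_ssu = as.integer(tab),
                          is_host = names(tab) == host_family,
                          stringsAsFactors = FALSE)
  catalogue <- catalogue[order(-catalogue$is_host, catalogue$family), ,
                         drop = FALSE]
  rownames(catalogue) <- NULL
  list(catalogue = catalogue,
       cobiont_families = setdiff(catalogue$family, host_family),
       unassigned = data.frame(ssu_id = ids[fams == "UNASSIGNED"],
                               stringsAsFactors = FALSE))
}

#' Write a taxonomy as a nodes/names/synonyms TSV trio
#'
#' @param tree A \code{taxonomy_tree}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_taxonomy_bundle <- function(tree, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv0(tree$nodes[, c("id", "parent", "rank")],
             file.path(dir, "nodes.tsv"))
  write_tsv0(tree$nodes[, c("id", "name")], file.path(dir, "names.tsv"))
  write_tsv0(tree$synonyms, file.path(dir, "synonyms.tsv"))
  invisible(dir)
}

#' Read a taxonomy written by \code{\link{write_taxonomy_bundle}}
#'
#' @param dir Directory holding \code{nodes.tsv}, \code{names.tsv} and
#'   \code{synonyms.tsv}.
#' @return A \code{taxonomy_tree}.
#' @export
read_taxonomy_bundle <- function(dir) {
  nodes <- read.delim(file.path(dir, "nodes.tsv"), stringsAsFactors = FALSE)
  names_df <- read.delim(file.path(dir, "names.tsv"),
                         stringsAsFactors = FALSE)
  nodes$name <- names_df$name[match(nodes$id, names_df$id)]
  nodes$parent[nodes$parent == ""] <- NA_character_
  syn_path <- file.path(dir, "synonyms.tsv")
  syn <- if (file.exists(syn_path)) {
    s <- read.delim(syn_path, stringsAsFactors = FALSE,
                    colClasses = "character")
    if (nrow(s) == 0L) NULL else s
  } else {
    NULL
  }
  taxonomy_tree(nodes, syn)
}
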