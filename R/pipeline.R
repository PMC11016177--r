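default_pipeline_params <- function() {
  list(ssu_min_identity = 0.75, ssu_min_len = 300L,
       retain_min_aligned = 1000L, retain_min_score = 1000,
       collapse_identity = 0.99,
       class_min_identity = 0.90, class_top_n = 20L,
       class_concordance = 0.80,
       k = 50L, min_confidence = 0.10,
       terminal_slack = 25L,
       marker_min_identity = 0.90, marker_min_cov = 0.80,
       ref_min_identity = 0.90, ref_min_breadth = 0.50,
       min_overlap = 500L)
}

#' Assemble a pipeline configuration
#'
#' @param assembly Path to the draft assembly FASTA.
#' @param reads Path to the read file (FASTA or FASTQ, optionally
#'   gzipped).
#' @param host_species Full scientific name of the host species,
#'   resolvable in the reference bundle's taxonomy.
#' @param reference_bundle Directory with the SSU panel
#'   (\code{ssu_panel.fasta} + \code{ssu_taxonomy.tsv}), the taxonomy TSV
#'   trio, and per-family \code{family_refs/} and \code{markers/} FASTA
#'   files.
#' @param output_dir Run directory (created by \code{\link{run_pipeline}}).
#' @param seed Integer seed recorded with the run.
#' @param params Named list of parameter overrides; see
#'   \code{ssusieve:::default_pipeline_params()} for names and defaults.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(assembly, reads, host_species, reference_bundle,
                            output_dir, seed = 1L, params = list()) {
  p <- default_pipeline_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown) > 0L) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(params)] <- params
  structure(list(assembly = assembly, reads = reads,
                 host_species = host_species,
                 reference_bundle = reference_bundle,
                 output_dir = output_dir, seed = as.integer(seed),
                 params = p),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys \code{assembly}, \code{reads},
#'   \code{host_species}, \code{reference_bundle}, \code{output_dir} and
#'   optional \code{seed} and \code{params}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (key in c("assembly", "reads", "host_species", "reference_bundle",
                "output_dir")) {
    if (is.null(y[[key]])) stop("config lacks required key: ", key)
  }
  pipeline_config(y$assembly, y$reads, y$host_species, y$reference_bundle,
                  y$output_dir, seed = if (is.null(y$seed)) 1L else y$seed,
                  params = if (is.null(y$params)) list() else y$params)
}

#' Validate a pipeline configuration
#'
#' Checks input paths, loadability of the reference bundle, documented
#' parameter ranges, and that the host species resolves to a family in the
#' bundle taxonomy. Fails before any stage runs.
#'
#' @param config A \code{pipeline_config}.
#' @return The validated config (with the resolved host family attached as
#'   attribute \code{"host_family"}), invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (key in c("assembly", "reads")) {
    if (!file.exists(config[[key]])) {
      stop("validation: ", key, " path does not exist: ", config[[key]])
    }
  }
  if (!dir.exists(config$reference_bundle)) {
    stop("validation: reference bundle directory does not exist: ",
         config$reference_bundle)
  }
  p <- config$params
  if (p$class_concordance <= 0 || p$class_concordance > 1 ||
      p$min_confidence < 0 || p$min_confidence > 1 ||
      p$k < 15L || p$collapse_identity <= 0.5 || p$collapse_identity > 1) {
    stop("validation: parameter out of documented range")
  }
  bundle <- load_reference_bundle(config$reference_bundle)
  host_node <- resolve_taxon(bundle$tree, config$host_species)
  if (is.na(host_node)) {
    stop("validation: host species not in taxonomy: ", config$host_species)
  }
  host_family <- family_of(bundle$tree, host_node)
  if (is.na(host_family)) {
    stop("validation: host species has no family rank: ",
         config$host_species)
  }
  attr(config, "host_family") <- host_family
  invisible(config)
}

load_reference_bundle <- function(dir) {
  panel_path <- file.path(dir, "ssu_panel.fasta")
  if (!file.exists(panel_path)) stop("bundle lacks ssu_panel.fasta")
  panel <- read_fasta(panel_path)
  tax <- read.delim(file.path(dir, "ssu_taxonomy.tsv"),
                    stringsAsFactors = FALSE)
  ref_taxa <- setNames(tax$taxon, tax$ref_id)
  tree <- read_taxonomy_bundle(dir)
  read_family_dir <- function(sub) {
    d <- file.path(dir, sub)
    out <- list()
    if (dir.exists(d)) {
      fams <- tree$nodes$id[tree$nodes$rank == "family"]
      slug <- gsub("[^A-Za-z0-9]+", "_", fams)
      for (f in list.files(d, pattern = "\\.fasta$")) {
        s <- sub("\\.fasta$", "", f)
        fam <- fams[match(s, slug)]
        if (is.na(fam)) fam <- s
        out[[fam]] <- read_fasta(file.path(d, f))
      }
    }
    out
  }
  list(panel = panel, ref_taxa = ref_taxa, tree = tree,
       family_refs = read_family_dir("family_refs"),
       markers = read_family_dir("markers"))
}

stage_msg <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the cobiont separation pipeline
#'
#' Executes, in order: SSU scan of the assembly, hit retention, locus
#' extraction and redundancy collapse, family-level consensus
#' classification, cobiont cataloguing, masked k-mer database construction
#' over the catalogued families' reference genomes plus host relatives,
#' read classification and binning, per-family contig refinement
#' (full-coverage + marker/similarity filters), per-family greedy
#' reassembly with circularity detection and evidence filtering, and a
#' final per-family assessment. Every intermediate is persisted as TSV or
#' FASTA under \code{output_dir}; a rerun with the same config and seed
#' produces byte-identical tables.
#'
#' @param config A \code{pipeline_config}.
#' @param resume Reuse the persisted read-classification table of a
#'   partial earlier run when present.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class \code{ssusieve_run} (invisibly): all stage
#'   results plus the run directory.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  config <- validate_config(config)
  host_family <- attr(config, "host_family")
  p <- config$params
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  set.seed(config$seed)
  yaml::write_yaml(list(assembly = config$assembly, reads = config$reads,
                        host_species = config$host_species,
                        reference_bundle = config$reference_bundle,
                        seed = config$seed, params = p),
                   out("config.yaml"))

  stage_msg(quiet, "load", "reading assembly and reads")
  assembly <- read_fasta(config$assembly)
  reads <- if (grepl("\\.(fq|fastq)(\\.gz)?$", config$reads)) {
    read_fastq(config$reads)
  } else {
    read_fasta(config$reads)
  }
  bundle <- load_reference_bundle(config$reference_bundle)
  stage_msg(quiet, "load", "%d contigs, %d reads, %d panel sequences",
            length(assembly), length(reads), length(bundle$panel))

  stage_msg(quiet, "ssu_scan", "scanning %d contigs", length(assembly))
  hits <- scan_ssu(assembly, bundle$panel, p$ssu_min_identity, p$ssu_min_len)
  hits <- retain_hits(hits, p$retain_min_aligned, p$retain_min_score)
  write_tsv0(hits, out("ssu_hits.tsv"))
  stage_msg(quiet, "ssu_scan", "%d hits, %d retained", nrow(hits),
            sum(hits$retained))

  loci <- extract_ssu_loci(hits, assembly)
  cset <- collapse_redundant(loci, p$collapse_identity)
  reps <- cset$representatives
  if (length(reps) > 0L) write_fasta(reps, out("ssu_representatives.fasta"))
  write_tsv0(cset$membership, out("ssu_clusters.tsv"))
  stage_msg(quiet, "ssu_collapse", "%d loci -> %d representatives",
            length(loci), length(reps))

  calls <- lapply(seq_along(reps), function(i) {
    tab <- panel_hit_table(reps[i], bundle$panel)
    consensus_family(tab, bundle$tree, bundle$ref_taxa,
                     p$class_min_identity, p$class_top_n,
                     p$class_concordance, ssu_id = names(reps)[i])
  })
  calls_df <- data.frame(
    ssu_id = vapply(calls, function(x) x$ssu_id, character(1)),
    family = vapply(calls, function(x) x$family, character(1)),
    support = vapply(calls, function(x) x$support, numeric(1)),
    n_hits_considered = vapply(calls, function(x) x$n_hits_considered,
                               integer(1)),
    stringsAsFactors = FALSE)
  write_tsv0(calls_df, out("ssu_classification.tsv"))

  cat_res <- family_catalogue(calls, bundle$tree, host_family)
  write_tsv0(cat_res$catalogue, out("catalogue.tsv"))
  cobionts <- cat_res$cobiont_families
  stage_msg(quiet, "catalogue", "%d cobiont famil%s: %s; host family %s",
            length(cobionts), if (length(cobionts) == 1L) "y" else "ies",
            paste(cobionts, collapse = ", "), host_family)

  db_families <- unique(c(cobionts, host_family))
  db_genomes <- bundle$family_refs[intersect(db_families,
                                             names(bundle$family_refs))]
  missing_refs <- setdiff(db_families, names(db_genomes))
  if (length(missing_refs) > 0L) {
    stage_msg(quiet, "kmer_db", "no reference genomes for: %s",
              paste(missing_refs, collapse = ", "))
  }
  if (length(db_genomes) == 0L) stop("no reference genomes for any family")
  db <- build_kmer_db(db_genomes, bundle$tree, host_family, p$k)
  write_tsv0(db$manifest, out("kmer_db_manifest.tsv"))
  stage_msg(quiet, "kmer_db", "%d k-mers over %d label(s)",
            length(db$kmers), length(db$label_levels))

  cls_path <- out("read_classification.tsv")
  if (resume && file.exists(cls_path)) {
    stage_msg(quiet, "bin_reads", "resuming from persisted classification")
    cls <- read.delim(cls_path, stringsAsFactors = FALSE)
    is_family <- vapply(cls$resolved, function(r) {
      !r %in% c("HOST", "UNCLASSIFIED") &&
        !is.na(match(r, db$tree$nodes$id)) &&
        db$tree$nodes$rank[match(r, db$tree$nodes$id)] == "family"
    }, logical(1))
    rb <- list(bins = split(cls$read_id[is_family], cls$resolved[is_family]),
               host = cls$read_id[cls$resolved == "HOST"],
               unclassified = cls$read_id[cls$resolved == "UNCLASSIFIED"],
               ambiguous = cls$read_id[!is_family & !cls$resolved %in%
                                         c("HOST", "UNCLASSIFIED")],
               classification = cls)
  } else {
    stage_msg(quiet, "bin_reads", "classifying %d reads", length(reads))
    rb <- bin_reads(db, reads, p$min_confidence)
    write_tsv0(rb$classification, cls_path)
  }
  dir.create(out("bins"), showWarnings = FALSE)
  for (fam in names(rb$bins)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", fam)
    writeLines(rb$bins[[fam]], out("bins", paste0(slug, "_reads.txt")))
    write_fastq(reads[rb$bins[[fam]]],
                out("bins", paste0(slug, "_reads.fastq")))
  }
  stage_msg(quiet, "bin_reads",
            "%d binned / %d host / %d unclassified / %d ambiguous",
            sum(lengths(rb$bins)), length(rb$host), length(rb$unclassified),
            length(rb$ambiguous))

  dir.create(out("refined"), showWarnings = FALSE)
  dir.create(out("reassembly"), showWarnings = FALSE)
  refined <- list()
  reassembled <- list()
  for (fam in cobionts) {
    slug <- gsub("[^A-Za-z0-9]+", "_", fam)
    fam_reads <- reads[rb$bins[[fam]]]
    markers <- bundle$markers[[fam]]
    if (is.null(markers)) markers <- DNAStringSet()
    refs <- bundle$family_refs[[fam]]
    if (is.null(refs)) refs <- DNAStringSet()
    stage_msg(quiet, "refine", "%s: %d reads vs %d contigs", fam,
              length(fam_reads), length(assembly))
    rf <- refine_bin(assembly, fam_reads, markers, refs,
                     terminal_slack = p$terminal_slack,
                     marker_min_identity = p$marker_min_identity,
                     marker_min_cov = p$marker_min_cov,
                     ref_min_identity = p$ref_min_identity,
                     ref_min_breadth = p$ref_min_breadth)
    rf$decisions <- rf$decisions[rf$decisions$breadth > 0, , drop = FALSE]
    refined[[fam]] <- rf
    write_tsv0(rf$decisions, out("refined", paste0(slug, "_decisions.tsv")))
    if (length(rf$retained) > 0L) {
      write_fasta(rf$retained, out("refined", paste0(slug, ".fasta")))
    }
    stage_msg(quiet, "refine", "%s: %d contig(s) retained", fam,
              length(rf$retained))

    asm <- greedy_assemble(fam_reads, p$min_overlap)
    kept <- filter_reassembly(asm, markers, refs,
                              marker_min_identity = p$marker_min_identity,
                              marker_min_cov = p$marker_min_cov,
                              ref_min_identity = p$ref_min_identity,
                              ref_min_breadth = p$ref_min_breadth)
    reassembled[[fam]] <- list(assembly = asm, retained = kept)
    if (length(kept) > 0L) {
      topo <- attr(kept, "topology")
      labelled <- kept
      names(labelled) <- sprintf("%s circular=%s", names(kept),
                                 ifelse(topo == "circular", "true", "false"))
      write_fasta(labelled, out("reassembly", paste0(slug, ".fasta")))
    }
    stage_msg(quiet, "reassemble", "%s: %d contig(s), %d circular", fam,
              length(kept), sum(attr(kept, "topology") == "circular"))
  }

  assessment <- data.frame(
    family = cobionts,
    n_contigs = vapply(cobionts, function(f) length(refined[[f]]$retained),
                       integer(1)),
    n_reads = vapply(cobionts, function(f) length(rb$bins[[f]]), integer(1)),
    span = vapply(cobionts, function(f) {
      sum(width(refined[[f]]$retained))
    }, numeric(1)),
    n50 = vapply(cobionts, function(f) {
      if (length(refined[[f]]$retained) > 0L) {
        as.numeric(n50(refined[[f]]$retained))
      } else {
        0
      }
    }, numeric(1)),
    reassembly_span = vapply(cobionts, function(f) {
      sum(width(reassembled[[f]]$retained))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  comp <- lapply(cobionts, function(f) {
    mk <- bundle$markers[[f]]
    if (is.null(mk) || length(refined[[f]]$retained) == 0L) {
      c(single = NA_real_, duplicated = NA_real_, missing = NA_real_)
    } else {
      completeness_proxy(refined[[f]]$retained, mk,
                         p$marker_min_identity, p$marker_min_cov)
    }
  })
  assessment$complete_single <- vapply(comp, `[[`, numeric(1), "single")
  assessment$complete_duplicated <- vapply(comp, `[[`, numeric(1),
                                           "duplicated")
  assessment$missing <- vapply(comp, `[[`, numeric(1), "missing")
  write_tsv0(assessment, out("assessment.tsv"))

  report <- c(
    sprintf("host species: %s (family %s)", config$host_species, host_family),
    sprintf("cobiont families in catalogue: %s",
            if (length(cobionts) > 0L) paste(cobionts, collapse = ", ")
            else "none"),
    sprintf("unassigned SSU loci: %d", nrow(cat_res$unassigned)),
    sprintf("reads: %d host, %d binned, %d unclassified, %d ambiguous",
            length(rb$host), sum(lengths(rb$bins)), length(rb$unclassified),
            length(rb$ambiguous)),
    vapply(cobionts, function(f) {
      a <- assessment[assessment$family == f, ]
      sprintf("%s: %d contig(s), span %d, N50 %d, reassembly span %d",
              f, a$n_contigs, as.integer(a$span), as.integer(a$n50),
              as.integer(a$reassembly_span))
    }, character(1)))
  writeLines(report, out("report.txt"))

  run <- structure(list(dir = config$output_dir, config = config,
                        host_family = host_family, hits = hits,
                        ssu_set = cset, calls = calls, catalogue = cat_res,
                        db_manifest = db$manifest, binning = rb,
                        refined = refined, reassembled = reassembled,
                        assessment = assessment, report = report),
                   class = "ssusieve_run")
  invisible(run)
}

#' @export
print.ssusieve_run <- function(x, ...) {
  cat("ssusieve_run:", x$dir, "\n")
  cat(paste0("  ", x$report, collapse = "\n"), "\n")
  invisible(x)
}

#' Evaluate a pipeline run against known truth
#'
#' Scores each catalogued cobiont family's refined bin (and read bin) with
#' length-normalised precision/recall/F1 against truth tables, and reports
#' truth families that are present in the reads but absent from the
#' catalogue — the expected outcome for taxa too scarce to assemble, which
#' leave no SSU in the assembly.
#'
#' @param run An \code{ssusieve_run}.
#' @param truth_contigs Truth table for assembly contigs
#'   (\code{contig_id}, \code{family}, \code{length}).
#' @param truth_reads Optional truth table for reads (\code{read_id},
#'   \code{family}, \code{length}).
#' @return A list with \code{contig_eval} and \code{read_eval} data frames
#'   (precision/recall/F1 per family) and \code{missing_families}, plus a
#'   written \code{evaluation.tsv} and report lines appended to the run
#'   directory.
#' @export
evaluate_run <- function(run, truth_contigs, truth_reads = NULL) {
  stopifnot(inherits(run, "ssusieve_run"))
  fams <- names(run$refined)
  contig_eval <- do.call(rbind, lapply(fams, function(f) {
    prf <- length_weighted_prf(names(run$refined[[f]]$retained),
                               truth_contigs, f)
    data.frame(family = f, level = "contig",
               precision = unname(prf["precision"]),
               recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
               stringsAsFactors = FALSE)
  }))
  read_eval <- NULL
  missing <- character(0)
  report <- character(0)
  if (!is.null(truth_reads)) {
    read_eval <- do.call(rbind, lapply(fams, function(f) {
      prf <- length_weighted_prf(run$binning$bins[[f]], truth_reads, f)
      data.frame(family = f, level = "read",
                 precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
                 stringsAsFactors = FALSE)
    }))
    catalogued <- run$catalogue$catalogue$family
    missing <- setdiff(unique(truth_reads$family),
                       c(catalogued, run$host_family))
    for (f in missing) {
      report <- c(report, sprintf(
        "family %s present in reads but absent from the assembly catalogue (no SSU in contigs; likely unassembled low-abundance taxon)",
        f))
    }
  }
  eval_df <- rbind(contig_eval, read_eval)
  write_tsv0(eval_df, file.path(run$dir, "evaluation.tsv"))
  if (length(report) > 0L) {
    writeLines(c(run$report, report), file.path(run$dir, "report.txt"))
  }
  list(contig_eval = contig_eval, read_eval = read_eval,
       missing_families = missing, report = report)
}
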