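#' Describe a synthetic mixed-species community
#'
#' A community specification lists the host and cobiont species to
#' simulate (genome length, GC, composition-bias seed, abundance weight,
#' taxonomy labels) together with sequencing and fixture parameters. The
#' per-species sequencing depth is \code{coverage_total * weight /
#' sum(weights)}.
#'
#' @param species A data frame with columns \code{name}, \code{family},
#'   \code{silva_family} (alternative family label, \code{NA} when the two
#'   label systems agree), \code{domain}, \code{genome_length}, \code{gc},
#'   \code{bias_seed}, \code{weight}, \code{is_host},
#'   \code{omit_from_assembly}.
#' @param read_length_mean Mean simulated read length (bases).
#' @param coverage_total Total fold-coverage distributed across species in
#'   proportion to their abundance weights.
#' @param fragmentation Contigs per genome in the simulated draft assembly.
#' @param ssu_length Length of the synthetic SSU genes.
#' @param n_panel_refs SSU reference-panel members per family.
#' @param panel_divergence,ssu_divergence Substitution rates of panel
#'   members and embedded SSU copies relative to each family's SSU
#'   ancestor.
#' @param n_markers,marker_length,marker_divergence Single-copy marker
#'   panel size, marker length, and substitution rate of embedded copies.
#' @param ref_divergence Substitution rate of the family reference genomes
#'   relative to the true species genomes.
#' @param hgt_length Length of the cobiont-derived horizontal insertion
#'   planted in the host genome (0 disables it).
#' @param error_rate Per-base read error (substitution) rate; 0 emulates
#'   HiFi-accurate reads.
#' @param rng_seed Default seed for \code{\link{simulate_community}}.
#' @return An object of class \code{community_spec}.
#' @export
community_spec <- function(species,
                           read_length_mean = 8000L,
                           coverage_total = 137,
                           fragmentation = 4L,
                           ssu_length = 1600L,
                           n_panel_refs = 24L,
                           panel_divergence = 0.02,
                           ssu_divergence = 0.03,
                           n_markers = 20L,
                           marker_length = 900L,
                           marker_divergence = 0.01,
                           ref_divergence = 0.015,
                           hgt_length = 800L,
                           error_rate = 0,
                           rng_seed = 1L) {
  stopifnot(is.data.frame(species))
  needed <- c("name", "family", "domain", "genome_length", "gc",
              "bias_seed", "weight", "is_host")
  missing_cols <- setdiff(needed, names(species))
  if (length(missing_cols) > 0L) {
    stop("species table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"silva_family" %in% names(species)) species$silva_family <- NA_character_
  if (!"omit_from_assembly" %in% names(species)) {
    species$omit_from_assembly <- FALSE
  }
  if (anyDuplicated(species$name)) stop("species names must be unique")
  if (any(species$weight <= 0)) stop("abundance weights must be > 0")
  if (any(species$genome_length < 20000L)) {
    stop("genome_length must be >= 20 kb for every species")
  }
  if (sum(species$is_host) != 1L) stop("exactly one species must be the host")
  if (any(species$gc <= 0 | species$gc >= 1)) stop("gc must be in (0, 1)")
  structure(list(species = species,
                 read_length_mean = as.integer(read_length_mean),
                 coverage_total = coverage_total,
                 fragmentation = as.integer(fragmentation),
                 ssu_length = as.integer(ssu_length),
                 n_panel_refs = as.integer(n_panel_refs),
                 panel_divergence = panel_divergence,
                 ssu_divergence = ssu_divergence,
                 n_markers = as.integer(n_markers),
                 marker_length = as.integer(marker_length),
                 marker_divergence = marker_divergence,
                 ref_divergence = ref_divergence,
                 hgt_length = as.integer(hgt_length),
                 error_rate = error_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

#' Default five-species mock community
#'
#' One eukaryote host surrogate plus three bacterial cobionts and one
#' divergent (microsporidian-like) eukaryotic cobiont at staggered
#' abundances 100:20:10:5:2, emulating a low-complexity single-host
#' metagenome. The lowest-abundance species is omitted from the simulated
#' draft assembly (present in reads only), reproducing the
#' unassembled-taxon failure mode. One family carries a differing
#' SILVA-style family label to exercise the dual-taxonomy consensus.
#'
#' @param ... Overrides passed on to \code{\link{community_spec}}.
#' @return A \code{community_spec}.
#' @export
default_community_spec <- function(...) {
  species <- data.frame(
    name = c("Apis synthetica", "Wolbachia synthetica",
             "Lactobacillus syntheticus", "Snodgrassella synthetica",
             "Nosema synthetica"),
    family = c("Apidae", "Anaplasmataceae", "Lactobacillaceae",
               "Neisseriaceae", "Nosemataceae"),
    silva_family = c(NA, "Ehrlichiaceae", NA, NA, NA),
    domain = c("Eukaryota", "Bacteria", "Bacteria", "Bacteria", "Eukaryota"),
    genome_length = c(500000L, 80000L, 60000L, 40000L, 30000L),
    gc = c(0.38, 0.35, 0.42, 0.45, 0.30),
    bias_seed = c(101L, 102L, 103L, 104L, 105L),
    weight = c(100, 20, 10, 5, 2),
    is_host = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    omit_from_assembly = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  community_spec(species, ...)
}

#' Simulate a genome with controlled composition
#'
#' Draws a sequence from a second-order Markov chain whose next-base
#' probabilities are a GC-constrained baseline perturbed per dinucleotide
#' context by log-normal noise seeded from \code{bias_seed}. The
#' perturbation is renormalised within the AT and GC base groups, so the
#' expected GC content equals \code{gc} exactly while the trinucleotide
#' spectrum is species-specific. \code{bias_seed = 0} disables the bias
#' (i.i.d. bases at the target GC).
#'
#' @param length Genome length in bases.
#' @param gc Target GC fraction, in (0, 1).
#' @param bias_seed Integer seed of the composition-bias table; 0 for no
#'   bias.
#' @param bias_sd Standard deviation of the log-probability perturbation.
#' @param seed Optional RNG seed; when \code{NULL} the current stream is
#'   used.
#' @param name Sequence name.
#' @return A length-one named \code{DNAStringSet}.
#' @export
simulate_genome <- function(length, gc = 0.5, bias_seed = 0L, bias_sd = 0.4,
                            seed = NULL, name = "genome") {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (length < 1L) stop("length must be positive")
  if (!is.null(seed)) set.seed(seed)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) # A C G T
  trans <- matrix(rep(base_p, each = 16L), nrow = 16L)
  if (bias_seed != 0L && bias_sd > 0) {
    eps <- with_local_seed(bias_seed,
                           matrix(rnorm(64L, 0, bias_sd), nrow = 16L))
    w <- trans * exp(eps)
    at <- w[, c(1L, 4L)] / rowSums(w[, c(1L, 4L)]) * (1 - gc)
    gcw <- w[, c(2L, 3L)] / rowSums(w[, c(2L, 3L)]) * gc
    trans <- cbind(at[, 1L], gcw[, 1L], gcw[, 2L], at[, 2L])
  }
  out <- DNAStringSet(cpp_markov_seq(trans, as.integer(length)))
  names(out) <- name
  out
}

#' Apply random substitutions to a sequence
#'
#' Substitution-only mutation at the given per-base rate; each mutated base
#' is replaced by a different nucleotide. Used to generate reference
#' genomes, SSU panel members and embedded gene copies at controlled
#' divergence.
#'
#' @param seq A single sequence.
#' @param rate Per-base substitution probability.
#' @param seed Optional RNG seed.
#' @return A character scalar.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- seq_chr(seq)
  n <- nchar(s)
  if (rate <= 0 || n == 0L) return(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  r <- charToRaw(s)
  bases <- charToRaw("ACGT")
  for (p in pos) {
    alt <- bases[bases != r[p]]
    r[p] <- alt[sample.int(length(alt), 1L)]
  }
  rawToChar(r)
}

#' Embed SSU and marker genes into a genome
#'
#' Inserts the SSU gene(s) and marker genes at randomly chosen,
#' well-separated insertion points (outside any \code{avoid} interval),
#' each on a random strand, and records the exact post-insertion
#' coordinates. Insertions cannot overlap by construction; proposed points
#' closer than the separation limit are redrawn.
#'
#' @param genome A single sequence.
#' @param ssu A \code{DNAStringSet} of SSU copies to embed (each >= 1200
#'   bases).
#' @param markers A \code{DNAStringSet} of marker genes (may be empty).
#' @param seed Optional RNG seed.
#' @param avoid Optional 2-column matrix of 0-based half-open intervals of
#'   the input genome that must not receive an insertion.
#' @param min_sep Minimum separation between insertion points (bases).
#' @return A list with \code{genome} (length-one \code{DNAStringSet}) and
#'   \code{elements}, a data frame of (id, type, start, end, strand) with
#'   0-based half-open coordinates on the output genome.
#' @export
embed_elements <- function(genome, ssu, markers = DNAStringSet(), seed = NULL,
                           avoid = NULL, min_sep = 200L) {
  if (!is.null(seed)) set.seed(seed)
  g <- seq_chr(genome)
  gname <- if (!is.null(names(as_dss(genome)))) names(as_dss(genome))[1] else "genome"
  ssu <- as_dss(ssu)
  markers <- as_dss(markers)
  if (length(ssu) < 1L) stop("at least one SSU copy is required")
  if (any(width(ssu) < 1200L)) stop("SSU sequences must be >= 1,200 bases")
  elements <- c(ssu, markers)
  types <- c(rep("ssu", length(ssu)), rep("marker", length(markers)))
  n <- length(elements)
  L <- nchar(g)
  margin <- 100L
  if (L < 2L * margin + n * (min_sep + 1L)) {
    stop("genome too short to host ", n, " elements")
  }
  ok_point <- function(p, chosen) {
    if (any(abs(chosen - p) < min_sep)) return(FALSE)
    if (!is.null(avoid) && nrow(avoid) > 0L &&
        any(p > avoid[, 1L] - min_sep & p < avoid[, 2L] + min_sep)) {
      return(FALSE)
    }
    TRUE
  }
  chosen <- integer(0)
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      p <- sample.int(L - 2L * margin, 1L) + margin
      if (ok_point(p, chosen)) break
      if (try == 10000L) stop("could not place elements without overlap")
    }
    chosen <- c(chosen, p)
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ord <- order(chosen)
  pieces <- character(2L * n + 1L)
  coords <- integer(n)
  prev <- 0L
  shift <- 0L
  for (j in seq_len(n)) {
    i <- ord[j]
    p <- chosen[i]
    el <- as.character(elements[[i]])
    if (strands[i] == "-") el <- revcomp_chr(el)
    pieces[2L * j - 1L] <- substr(g, prev + 1L, p)
    pieces[2L * j] <- el
    coords[i] <- p + shift
    shift <- shift + nchar(el)
    prev <- p
  }
  pieces[2L * n + 1L] <- substr(g, prev + 1L, L)
  out <- DNAStringSet(paste(pieces, collapse = ""))
  names(out) <- gname
  widths <- width(elements)
  tab <- data.frame(id = names(elements), type = types,
                    start = coords, end = coords + widths,
                    strand = strands, stringsAsFactors = FALSE)
  list(genome = out, elements = tab[order(tab$start), , drop = FALSE])
}

#' Simulate long reads from a community
#'
#' Error-free (HiFi-surrogate) reads are drawn per species at depth
#' proportional to its abundance weight. Start positions are stratified:
#' evenly spaced over the genome with bounded jitter, so that a genome
#' sampled above ~1.5x depth is tiled without gaps and the
#' full-read-coverage contig filter is decidable at desk-scale depth. Read
#' strands are random; a nonzero \code{error_rate} injects substitutions.
#'
#' @param community A \code{community_spec}.
#' @param genomes Named \code{DNAStringSet} of the final (element-bearing)
#'   species genomes, names matching \code{community$species$name}.
#' @param seed Optional RNG seed.
#' @param circular Character vector of species whose genomes are circular
#'   (reads may wrap the origin).
#' @return A list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{truth}, a data frame of per-read origin labels and coordinates.
#' @export
simulate_reads <- function(community, genomes, seed = NULL,
                           circular = character(0)) {
  if (!is.null(seed)) set.seed(seed)
  sp <- community$species
  if (any(sp$weight <= 0)) stop("abundance weights must be > 0")
  stopifnot(all(sp$name %in% names(genomes)))
  if (community$coverage_total <= 0) stop("coverage_total must be > 0")
  covs <- community$coverage_total * sp$weight / sum(sp$weight)
  rl <- community$read_length_mean
  all_reads <- vector("list", nrow(sp))
  all_truth <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    g <- as.character(genomes[[sp$name[i]]])
    L <- nchar(g)
    is_circ <- sp$name[i] %in% circular
    n <- max(1L, round(covs[i] * L / rl))
    lens <- pmin(L, pmax(1000L, round(rnorm(n, rl, 0.1 * rl))))
    spacing <- L / n
    jit <- round(runif(n, -spacing / 4, spacing / 4))
    if (is_circ) {
      starts <- (round(seq(0, L - 1, length.out = n)) + jit) %% L
      g2 <- paste0(g, g)
      seqs <- substr(rep(g2, n), starts + 1L, starts + lens)
      ends <- starts + lens
    } else {
      frac <- if (n == 1L) 0 else seq(0, 1, length.out = n)
      starts <- round(frac * (L - lens)) + jit
      starts <- pmin(pmax(starts, 0L), L - lens)
      starts[1L] <- 0L
      starts[n] <- L - lens[n]
      seqs <- substr(rep(g, n), starts + 1L, starts + lens)
      ends <- starts + lens
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    flip <- strands == "-"
    if (any(flip)) seqs[flip] <- vapply(seqs[flip], revcomp_chr, character(1))
    if (community$error_rate > 0) {
      seqs <- vapply(seqs, mutate_sequence, character(1),
                     rate = community$error_rate)
    }
    slug <- gsub("[^A-Za-z0-9]+", "_", sp$name[i])
    ids <- sprintf("%s_read_%05d", slug, seq_len(n))
    all_reads[[i]] <- setNames(seqs, ids)
    all_truth[[i]] <- data.frame(
      read_id = ids, species = sp$name[i], family = sp$family[i],
      start = as.integer(starts), end = as.integer(ends),
      strand = strands, length = as.integer(lens),
      stringsAsFactors = FALSE)
  }
  reads <- DNAStringSet(unlist(all_reads))
  list(reads = reads, truth = do.call(rbind, all_truth))
}

#' Simulate a draft assembly from the true genomes
#'
#' Cuts each genome into \code{fragmentation} contiguous pieces at random
#' breakpoints (kept outside \code{avoid} intervals such as embedded genes,
#' so planted elements are never split), optionally omitting whole species
#' to emulate taxa that the assembler missed.
#'
#' @param genomes Named \code{DNAStringSet} of species genomes.
#' @param species_table Data frame with \code{name} and \code{family}
#'   columns covering the genomes.
#' @param fragmentation Pieces per genome (>= 1).
#' @param seed Optional RNG seed.
#' @param omit_species Species names absent from the output contigs.
#' @param avoid Named list (by species) of 2-column interval matrices that
#'   breakpoints must avoid.
#' @return A list with \code{contigs} (named \code{DNAStringSet}) and
#'   \code{truth}, a data frame of per-contig origin labels and genome
#'   coordinates.
#' @export
simulate_assembly <- function(genomes, species_table, fragmentation = 4L,
                              seed = NULL, omit_species = character(0),
                              avoid = list()) {
  if (!is.null(seed)) set.seed(seed)
  if (fragmentation < 1L) stop("fragmentation must be >= 1")
  keep <- setdiff(names(genomes), omit_species)
  out_seq <- list()
  out_truth <- list()
  for (nm in keep) {
    g <- as.character(genomes[[nm]])
    L <- nchar(g)
    fam <- species_table$family[match(nm, species_table$name)]
    f <- fragmentation
    bad <- avoid[[nm]]
    pick_breaks <- function() {
      if (f == 1L) return(integer(0))
      for (try in 1:2000) {
        b <- sort(sample.int(L - 4000L, f - 1L) + 2000L)
        if (any(diff(c(0L, b, L)) < 2000L)) next
        if (!is.null(bad) && nrow(bad) > 0L &&
            any(vapply(b, function(p) {
              any(p > bad[, 1L] - 50L & p < bad[, 2L] + 50L)
            }, logical(1)))) next
        return(b)
      }
      stop("could not place assembly breakpoints for ", nm)
    }
    b <- pick_breaks()
    bounds <- c(0L, b, L)
    slug <- gsub("[^A-Za-z0-9]+", "_", nm)
    for (i in seq_len(length(bounds) - 1L)) {
      cid <- sprintf("%s_ctg%02d", slug, i)
      out_seq[[cid]] <- substr(g, bounds[i] + 1L, bounds[i + 1L])
      out_truth[[cid]] <- data.frame(
        contig_id = cid, species = nm, family = fam,
        start = bounds[i], end = bounds[i + 1L],
        length = bounds[i + 1L] - bounds[i], stringsAsFactors = FALSE)
    }
  }
  contigs <- DNAStringSet(unlist(out_seq))
  list(contigs = contigs, truth = do.call(rbind, unname(out_truth)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a complete truth-labelled community fixture
#'
#' Builds, from one specification and seed: the fixture taxonomy (two label
#' systems over one node set), per-family SSU reference panels and
#' single-copy marker panels, species genomes with embedded SSU and marker
#' genes (the host receives two identical SSU copies and, when
#' \code{hgt_length > 0}, one cobiont-derived horizontal insertion),
#' family reference genomes at controlled divergence, stratified error-free
#' reads, a fragmented draft assembly, and complete truth tables. The
#' bundle is the package's stand-in for the external SSU/taxonomy/reference
#' databases.
#'
#' @param spec A \code{community_spec}.
#' @param seed Integer seed; defaults to \code{spec$rng_seed}.
#' @param out_dir Optional directory; when given, genomes, reads, assembly,
#'   truth tables and the reference bundle are written there.
#' @return An object of class \code{community_fixture}: a list holding the
#'   taxonomy tree, genomes, reads, assembly, truth tables, SSU panel +
#'   panel taxon map, per-family reference genomes and marker panels, and
#'   the host species/family.
#' @export
simulate_community <- function(spec, seed = spec$rng_seed, out_dir = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(seed)
  sp <- spec$species
  host_idx <- which(sp$is_host)
  families <- unique(sp$family)
  tree <- fixture_taxonomy(sp)

  # per-family SSU ancestors, panels and marker panels
  ssu_base <- list()
  panel <- list()
  ref_taxa <- character(0)
  marker_panels <- list()
  for (fam in families) {
    fam_slug <- gsub("[^A-Za-z0-9]+", "_", fam)
    base <- random_dna(spec$ssu_length)
    ssu_base[[fam]] <- base
    refs <- vapply(seq_len(spec$n_panel_refs), function(i) {
      mutate_sequence(base, spec$panel_divergence)
    }, character(1))
    ids <- sprintf("SSUREF_%s_%02d", fam_slug, seq_len(spec$n_panel_refs))
    panel[[fam]] <- setNames(refs, ids)
    genus <- strsplit(sp$name[match(fam, sp$family)], " ")[[1]][1]
    ref_taxa[ids] <- genus
    mk <- vapply(seq_len(spec$n_markers), function(i) {
      random_dna(spec$marker_length)
    }, character(1))
    names(mk) <- sprintf("MARKER_%s_%02d", fam_slug, seq_len(spec$n_markers))
    marker_panels[[fam]] <- DNAStringSet(mk)
  }
  panel_set <- DNAStringSet(unlist(unname(panel)))

  # species genomes: backbone + embedded elements (+ host HGT insertion)
  genomes <- DNAStringSet()
  elements <- list()
  hgt_truth <- NULL
  build_one <- function(i, avoid = NULL, backbone = NULL) {
    if (is.null(backbone)) {
      backbone <- simulate_genome(sp$genome_length[i], sp$gc[i],
                                  sp$bias_seed[i], name = sp$name[i])
    }
    n_ssu <- if (sp$is_host[i]) 2L else 1L
    emb_ssu <- mutate_sequence(ssu_base[[sp$family[i]]], spec$ssu_divergence)
    ssu_set <- DNAStringSet(rep(emb_ssu, n_ssu))
    names(ssu_set) <- sprintf("SSU_%s_%d",
                              gsub("[^A-Za-z0-9]+", "_", sp$name[i]),
                              seq_len(n_ssu))
    mk <- marker_panels[[sp$family[i]]]
    emb_mk <- DNAStringSet(vapply(as.character(mk), mutate_sequence,
                                  character(1), rate = spec$marker_divergence))
    names(emb_mk) <- names(mk)
    embed_elements(backbone, ssu_set, emb_mk, avoid = avoid)
  }
  cob_order <- c(setdiff(seq_len(nrow(sp)), host_idx), host_idx)
  for (i in cob_order) {
    if (i != host_idx) {
      res <- build_one(i)
    } else {
      backbone <- simulate_genome(sp$genome_length[i], sp$gc[i],
                                  sp$bias_seed[i], name = sp$name[i])
      avoid <- NULL
      if (spec$hgt_length > 0L && nrow(sp) > 1L) {
        donor_i <- cob_order[1L]
        donor <- as.character(genomes[[sp$name[donor_i]]])
        don_el <- elements[[sp$name[donor_i]]]
        for (try in 1:1000) {
          s <- sample.int(nchar(donor) - spec$hgt_length, 1L)
          if (!any(s < don_el$end & s + spec$hgt_length > don_el$start)) break
        }
        insert <- substr(donor, s + 1L, s + spec$hgt_length)
        p <- sample.int(nchar(as.character(backbone[[1]])) - 2000L, 1L) + 1000L
        gchr <- as.character(backbone[[1]])
        backbone <- DNAStringSet(paste0(substr(gchr, 1L, p), insert,
                                        substr(gchr, p + 1L, nchar(gchr))))
        names(backbone) <- sp$name[i]
        avoid <- matrix(c(p, p + spec$hgt_length), ncol = 2L)
        hgt_truth <- data.frame(
          host_species = sp$name[i], donor_species = sp$name[donor_i],
          donor_start = s, donor_end = s + spec$hgt_length,
          host_start = p, host_end = p + spec$hgt_length,
          stringsAsFactors = FALSE)
      }
      res <- build_one(i, avoid = avoid, backbone = backbone)
      if (!is.null(hgt_truth)) {
        # element insertions upstream of the HGT site shift its coordinates
        shift <- sum(res$elements$end[res$elements$start < hgt_truth$host_start] -
                     res$elements$start[res$elements$start < hgt_truth$host_start])
        hgt_truth$host_start <- hgt_truth$host_start + shift
        hgt_truth$host_end <- hgt_truth$host_end + shift
      }
    }
    genomes <- c(genomes, res$genome)
    el <- res$elements
    el$species <- sp$name[i]
    elements[[sp$name[i]]] <- el
  }
  genomes <- genomes[sp$name]
  element_truth <- do.call(rbind, unname(elements))

  # family reference genomes (one mutated copy per species, grouped by family)
  family_refs <- list()
  for (fam in families) {
    members <- sp$name[sp$family == fam]
    refs <- DNAStringSet(vapply(members, function(nm) {
      mutate_sequence(as.character(genomes[[nm]]), spec$ref_divergence)
    }, character(1)))
    names(refs) <- sprintf("REF_%s_%d", gsub("[^A-Za-z0-9]+", "_", fam),
                           seq_along(members))
    family_refs[[fam]] <- refs
  }

  rd <- simulate_reads(spec, genomes)
  avoid_iv <- lapply(setNames(sp$name, sp$name), function(nm) {
    el <- elements[[nm]]
    m <- cbind(el$start, el$end)
    if (!is.null(hgt_truth) && nm == hgt_truth$host_species) {
      m <- rbind(m, c(hgt_truth$host_start, hgt_truth$host_end))
    }
    m
  })
  asm <- simulate_assembly(genomes, sp, spec$fragmentation,
                           omit_species = sp$name[sp$omit_from_assembly],
                           avoid = avoid_iv)

  fixture <- structure(list(
    spec = spec, seed = seed, tree = tree, genomes = genomes,
    reads = rd$reads, read_truth = rd$truth,
    assembly = asm$contigs, contig_truth = asm$truth,
    element_truth = element_truth, hgt_truth = hgt_truth,
    ssu_panel = panel_set, ref_taxa = ref_taxa,
    family_refs = family_refs, marker_panels = marker_panels,
    host_species = sp$name[host_idx], host_family = sp$family[host_idx]),
    class = "community_fixture")
  if (!is.null(out_dir)) write_fixture_bundle(fixture, out_dir)
  fixture
}

fixture_taxonomy <- function(sp) {
  nodes <- data.frame(id = "root", parent = NA_character_, rank = "no rank",
                      name = "root", stringsAsFactors = FALSE)
  add <- function(nodes, id, parent, rank) {
    if (!id %in% nodes$id) {
      nodes <- rbind(nodes, data.frame(id = id, parent = parent, rank = rank,
                                       name = id, stringsAsFactors = FALSE))
    }
    nodes
  }
  syn <- data.frame(name = character(0), id = character(0),
                    system = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sp))) {
    genus <- strsplit(sp$name[i], " ")[[1]][1]
    nodes <- add(nodes, sp$domain[i], "root", "superkingdom")
    nodes <- add(nodes, sp$family[i], sp$domain[i], "family")
    nodes <- add(nodes, genus, sp$family[i], "genus")
    nodes <- add(nodes, sp$name[i], genus, "species")
    if (!is.na(sp$silva_family[i]) && sp$silva_family[i] != sp$family[i]) {
      syn <- rbind(syn, data.frame(name = sp$silva_family[i],
                                   id = sp$family[i], system = "silva",
                                   stringsAsFactors = FALSE))
    }
  }
  taxonomy_tree(nodes, syn)
}

write_fixture_bundle <- function(fixture, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fixture$genomes, file.path(out_dir, "genomes.fasta"))
  write_fastq(fixture$reads, file.path(out_dir, "reads.fastq.gz"))
  write_fasta(fixture$assembly, file.path(out_dir, "assembly.fasta"))
  write_tsv0(fixture$read_truth, file.path(out_dir, "truth_reads.tsv"))
  write_tsv0(fixture$contig_truth, file.path(out_dir, "truth_contigs.tsv"))
  write_tsv0(fixture$element_truth, file.path(out_dir, "truth_elements.tsv"))
  ref_dir <- file.path(out_dir, "ref_bundle")
  dir.create(file.path(ref_dir, "family_refs"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(ref_dir, "markers"), showWarnings = FALSE)
  write_fasta(fixture$ssu_panel, file.path(ref_dir, "ssu_panel.fasta"))
  write_tsv0(data.frame(ref_id = names(fixture$ref_taxa),
                        taxon = unname(fixture$ref_taxa),
                        stringsAsFactors = FALSE),
             file.path(ref_dir, "ssu_taxonomy.tsv"))
  write_taxonomy_bundle(fixture$tree, ref_dir)
  for (fam in names(fixture$family_refs)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", fam)
    write_fasta(fixture$family_refs[[fam]],
                file.path(ref_dir, "family_refs", paste0(slug, ".fasta")))
    write_fasta(fixture$marker_panels[[fam]],
                file.path(ref_dir, "markers", paste0(slug, ".fasta")))
  }
  meta <- list(host_species = fixture$host_species,
               host_family = fixture$host_family, seed = fixture$seed)
  yaml::write_yaml(meta, file.path(out_dir, "fixture.yaml"))
  invisible(out_dir)
}

write_tsv0 <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.community_fixture <- function(x, ...) {
  cat(sprintf("community_fixture: %d species, %d reads, %d contigs\n",
              nrow(x$spec$species), length(x$reads), length(x$assembly)))
  invisible(x)
}
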