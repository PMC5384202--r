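with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate a synthetic annotated reference genome
#'
#' A small circular mitogenome stand-in: a control region, one
#' protein-coding gene (so synonymous/non-synonymous classification is
#' exercised), rRNA/tRNA filler and an `other` remainder.  Small enough
#' that exhaustive oracles stay cheap, but with the same partition
#' structure as the real genome.
#'
#' @param length total length in bp (default 2000).
#' @param control_length control-region length, placed at `1..control_length`.
#' @param gene_length protein-gene length (multiple of 3), placed directly
#'   after the control region.
#' @param seed RNG seed.
#' @return a `reference_system`; the control interval is attached as
#'   attribute `control_interval`.
#' @export
synthetic_reference <- function(length = 2000L, control_length = 400L,
                                gene_length = 1200L, seed = NULL) {
  stopifnot(gene_length %% 3L == 0L,
            control_length + gene_length < length)
  with_seed_if(seed, {
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                        prob = c(0.31, 0.31, 0.13, 0.25)), collapse = "")
    gene_start <- control_length + 1L
    gene_end <- control_length + gene_length
    rest_len <- length - gene_end
    rrna_len <- floor(rest_len * 0.75)
    ann <- data.frame(
      start = c(1L, seq(gene_start, gene_end, by = 3L),
                seq(gene_start + 1L, gene_end, by = 3L),
                seq(gene_start + 2L, gene_end, by = 3L),
                gene_end + 1L),
      end = c(control_length, seq(gene_start, gene_end, by = 3L),
              seq(gene_start + 1L, gene_end, by = 3L),
              seq(gene_start + 2L, gene_end, by = 3L),
              gene_end + rrna_len),
      partition = c("control", rep("codon1", gene_length / 3L),
                    rep("codon2", gene_length / 3L),
                    rep("codon3", gene_length / 3L), "rRNA_tRNA"),
      stringsAsFactors = FALSE
    )
    ref <- reference_system(seq, ann, name = "synthetic")
    attr(ref, "control_interval") <- as_intervals(c(1L, control_length))
    ref
  })
}

#' Simulate an ultrametric genealogy
#'
#' Either a star genealogy (all tips attached directly to the root — the
#' shape underlying the rho clock's simplest calibration) or a Kingman
#' coalescent genealogy (exponential epoch durations with rate
#' `choose(k, 2)`, random pair merges) rescaled so the root sits exactly at
#' `tmrca` years.
#'
#' @param n number of tips.
#' @param tmrca root age in years.
#' @param model `"star"` or `"kingman"`.
#' @param seed RNG seed.
#' @param tip_labels optional tip names (default `t1..tn`).
#' @return an ultrametric `ape::phylo` with branch lengths in years.
#' @export
simulate_genealogy <- function(n, tmrca, model = c("star", "kingman"),
                               seed = NULL, tip_labels = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1, tmrca > 0)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  stopifnot(length(tip_labels) == n)
  if (n == 1L) {
    phy <- list(edge = matrix(c(2L, 1L), 1L), edge.length = tmrca,
                tip.label = tip_labels, Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }
  if (model == "star") {
    phy <- ape::stree(n, type = "star", tip.label = tip_labels)
    phy$edge.length <- rep(tmrca, nrow(phy$edge))
    return(phy)
  }
  with_seed_if(seed, {
    heights <- numeric(2L * n - 1L)
    active <- seq_len(n)
    parent <- integer(2L * n - 1L)
    h <- 0
    nxt <- n + 1L
    for (k in n:2) {
      h <- h + stats::rexp(1L, rate = k * (k - 1) / 2)
      pick <- sample(length(active), 2L)
      heights[nxt] <- h
      parent[active[pick]] <- nxt
      active <- c(active[-pick], nxt)
      nxt <- nxt + 1L
    }
    scale <- tmrca / h
    heights <- heights * scale
    # renumber internals so the root (created last) becomes n+1
    total <- 2L * n - 1L
    remap <- c(seq_len(n), rev(seq(n + 1L, total)))
    child <- which(parent > 0L)
    edge <- cbind(remap[parent[child]], remap[child])
    phy <- list(edge = edge,
                edge.length = heights[parent[child]] - heights[child],
                tip.label = tip_labels, Nnode = n - 1L)
    class(phy) <- "phylo"
    ape::reorder.phylo(phy, "cladewise")
  })
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Drop Poisson mutations onto a genealogy
#'
#' Mutation counts per edge are Poisson with mean `mu * L * branch_years`;
#' positions are uniform over the non-`N` sites without within-edge
#' repeats; derived alleles follow a configurable transition:transversion
#' ratio (20:1 by default, mtDNA-like).  Repeat hits across edges are
#' allowed (and produce homoplasy that exercises the tree builder's
#' conflict resolution).
#'
#' @param genealogy `ape::phylo` with branch lengths in years.
#' @param mu per-site per-year mutation rate.
#' @param ref a `reference_system`.
#' @param seed RNG seed.
#' @param ts_tv transition:transversion ratio.
#' @param root_haplotype variant labels applied to the reference at the
#'   genealogy's root (e.g. the clade's defining motif chain).
#' @return object of class `simulated_clade`: `profiles` (one
#'   `haplotype_profile` per tip), `events` (list of per-edge event labels,
#'   ordered as `genealogy$edge`), `genealogy`, `root_haplotype`, `ref`.
#' @export
drop_mutations <- function(genealogy, mu, ref, seed = NULL, ts_tv = 20,
                           root_haplotype = character()) {
  stopifnot(inherits(genealogy, "phylo"), mu >= 0)
  with_seed_if(seed, {
    L <- ref$length
    rc <- ref_chars(ref)
    usable <- which(rc != "N")
    root_seq <- rc
    if (length(root_haplotype)) {
      v <- parse_variant_label(root_haplotype)
      stopifnot(all(v$kind %in% c("transition", "transversion")))
      root_seq[v$position] <- v$derived
    }
    n <- length(genealogy$tip.label)
    seqs <- vector("list", n + genealogy$Nnode)
    seqs[[n + 1L]] <- root_seq
    events <- vector("list", nrow(genealogy$edge))
    # cladewise order guarantees parents are visited before children
    phy <- ape::reorder.phylo(genealogy, "cladewise")
    for (i in seq_len(nrow(phy$edge))) {
      par <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
      s <- seqs[[par]]
      k <- stats::rpois(1L, mu * L * phy$edge.length[i])
      k <- min(k, length(usable))
      evs <- character(0)
      if (k > 0L) {
        pos <- sample(usable, k)
        for (p in pos) {
          a <- s[p]
          ts <- stats::runif(1L) < ts_tv / (ts_tv + 1)
          d <- if (ts) transition_partner[[a]] else {
            sample(setdiff(c("A", "C", "G", "T"),
                           c(a, transition_partner[[a]])), 1L)
          }
          evs <- c(evs, substitution_label(p, a, d))
          s[p] <- d
        }
      }
      events[[i]] <- evs
      seqs[[ch]] <- s
    }
    profiles <- lapply(seq_len(n), function(tip) {
      rec <- sample_record(phy$tip.label[tip],
                           sequence = paste(seqs[[tip]], collapse = ""))
      score_against_reference(rec, ref)
    })
    structure(
      list(profiles = profiles, events = events, genealogy = phy,
           root_haplotype = sort_variant_labels(root_haplotype), ref = ref),
      class = "simulated_clade"
    )
  })
}

#' Convert a simulated clade into a haplogroup tree
#'
#' Maps the true genealogy and its per-edge mutation events onto the
#' `haplogroup_tree` structure, so rho statistics can be computed on the
#' generating tree itself (the ground truth for calibration studies).
#'
#' @param sim a `simulated_clade` from [drop_mutations()].
#' @return a `haplogroup_tree` whose root edge carries the clade's root
#'   haplotype.
#' @export
as_haplogroup_tree <- function(sim) {
  stopifnot(inherits(sim, "simulated_clade"))
  phy <- sim$genealogy
  n <- length(phy$tip.label)
  total <- n + phy$Nnode
  # haplogroup-tree node i corresponds to phylo node i; root = n + 1
  parent <- integer(total)
  events <- rep(list(character()), total)
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2L]] <- phy$edge[i, 1L]
    events[[phy$edge[i, 2L]]] <- sim$events[[i]]
  }
  parent[n + 1L] <- 0L
  events[[n + 1L]] <- sim$root_haplotype
  samp <- rep(NA_character_, total)
  samp[seq_len(n)] <- phy$tip.label
  structure(
    list(parent = parent, events = events,
         clade = rep(NA_character_, total), sample = samp,
         n_tips = n, L = sim$ref$length),
    class = "haplogroup_tree"
  )
}

# sample distinct motif positions, control region upweighted (hypervariable
# in real mtDNA), avoiding `taken`; min_control forces that many
# control-region sites (clade motifs must stay classifiable from
# control-region-only data)
sample_motif_positions <- function(ref, k, taken = integer(),
                                   control_weight = 5, min_control = 0L) {
  control <- attr(ref, "control_interval")
  w <- rep(1, ref$length)
  in_ctrl <- if (!is.null(control)) {
    positions_in_intervals(seq_len(ref$length), control)
  } else rep(FALSE, ref$length)
  w[in_ctrl] <- control_weight
  w[taken] <- 0
  w[ref_chars(ref) == "N"] <- 0
  forced <- integer()
  if (min_control > 0L) {
    avail <- which(in_ctrl & w > 0)
    forced <- sample(avail, min_control)
    w[forced] <- 0
  }
  c(forced, sample(ref$length, k - length(forced), prob = w))
}

motif_labels_at <- function(ref, pos, ts_tv = 20) {
  rc <- ref_chars(ref)
  vapply(pos, function(p) {
    a <- rc[p]
    ts <- stats::runif(1L) < ts_tv / (ts_tv + 1)
    d <- if (ts) transition_partner[[a]] else {
      sample(setdiff(c("A", "C", "G", "T"), c(a, transition_partner[[a]])), 1L)
    }
    substitution_label(p, a, d)
  }, "")
}

#' Default synthetic-survey configuration
#'
#' Emulates the structure of a continental mtDNA haplogroup survey: eight
#' populations across the Near East, South Asia, Europe and Central Asia
#' (25 samples each), three major clades with distinct coalescence ages
#' (18, 10 and 6 kya — an older Asian expansion, a younger
#' Mediterranean-European one, and a South-Asia-specific minor clade) and
#' east-west frequency gradients; 40% of samples carry control-region data
#' only.  The per-genome mutation rate `mu * L` matches the whole-mtDNA
#' complete clock (~2.8e-4 substitutions per genome per year).
#'
#' @return a configuration list understood by [simulate_study()].
#' @export
default_study_config <- function() {
  populations <- data.frame(
    population = c("Iran", "Anatolia", "Indus", "India",
                   "Mediterranean", "SE_Europe", "Turan", "Tian_Shan"),
    region = c("Near East", "Near East", "South Asia", "South Asia",
               "Europe", "Europe", "Central Asia", "Central Asia"),
    latitude = c(32.0, 39.0, 27.0, 21.0, 40.5, 42.5, 39.5, 42.9),
    longitude = c(53.0, 35.0, 68.0, 78.5, 15.0, 25.0, 64.5, 74.6),
    n = rep(25L, 8L),
    stringsAsFactors = FALSE
  )
  freqs <- rbind(
    a = c(Iran = 0.32, Anatolia = 0.24, Indus = 0.32, India = 0.20,
          Mediterranean = 0.08, SE_Europe = 0.08, Turan = 0.16, Tian_Shan = 0.12),
    b = c(Iran = 0.12, Anatolia = 0.12, Indus = 0.08, India = 0.04,
          Mediterranean = 0.24, SE_Europe = 0.20, Turan = 0.08, Tian_Shan = 0.04),
    c = c(Iran = 0.00, Anatolia = 0.00, Indus = 0.16, India = 0.12,
          Mediterranean = 0.00, SE_Europe = 0.00, Turan = 0.00, Tian_Shan = 0.00)
  )
  list(
    populations = populations,
    clade_frequencies = freqs,
    clade_ages = c(a = 18000, b = 10000, c = 6000),
    root_motif_size = 11L,
    clade_motif_size = 5L,
    control_weight = 5,
    partial_fraction = 0.4,
    mu = 1.4e-7,
    ts_tv = 20,
    model = "kingman",
    root_name = "U",
    reference = NULL
  )
}

#' Simulate a complete phylogeographic survey
#'
#' End-to-end synthetic inputs for the pipeline with known ground truth:
#' an annotated reference, clade-defining motifs (control region
#' upweighted), per-clade coalescent genealogies with Poisson mutations,
#' geo-referenced populations with configured clade-frequency gradients,
#' non-carrier background samples, and a configurable fraction of
#' control-region-only records.
#'
#' @param config configuration list; missing entries fall back to
#'   [default_study_config()].
#' @param seed RNG seed (regenerating with the same seed is bit-identical).
#' @return object of class `simulated_study`: `records`, `metadata`,
#'   `ref`, `truth` (`labels`, `ages`, `motifs`, `frequencies`,
#'   `clade_trees`) and `config`.
#' @export
simulate_study <- function(config = list(), seed = NULL) {
  cfg <- default_study_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(config)] <- config  # shallow: tables replace wholesale
  pops <- cfg$populations
  freqs <- cfg$clade_frequencies
  if (any(colSums(freqs) > 1 + 1e-9)) {
    stop("clade frequencies per population must sum to <= 1")
  }
  stopifnot(identical(sort(colnames(freqs)), sort(pops$population)))
  with_seed_if(seed, {
    ref <- if (is.null(cfg$reference)) synthetic_reference() else cfg$reference
    clades <- rownames(freqs)
    taken <- integer()
    root_pos <- sample_motif_positions(ref, cfg$root_motif_size, taken,
                                       cfg$control_weight)
    taken <- c(taken, root_pos)
    root_motif <- sort_variant_labels(motif_labels_at(ref, root_pos, cfg$ts_tv))
    motifs <- list()
    motifs[[cfg$root_name]] <- root_motif
    for (cl in clades) {
      pos <- sample_motif_positions(ref, cfg$clade_motif_size, taken,
                                    cfg$control_weight, min_control = 1L)
      taken <- c(taken, pos)
      motifs[[paste0(cfg$root_name, cl)]] <-
        sort_variant_labels(motif_labels_at(ref, pos, cfg$ts_tv))
    }

    # deterministic per-population carrier counts: round(n * frequency)
    counts <- round(sweep(freqs, 2L, pops$n[match(colnames(freqs), pops$population)], `*`))
    labels <- character(); populations <- character(); sample_ids <- character()
    for (p in pops$population) {
      n <- pops$n[pops$population == p]
      k <- counts[, p]
      lab <- c(rep(clades, k), rep("background", n - sum(k)))
      labels <- c(labels, lab)
      populations <- c(populations, rep(p, n))
    }
    sample_ids <- sprintf("S%03d", seq_along(labels))

    profiles <- vector("list", length(sample_ids))
    names(profiles) <- sample_ids
    clade_trees <- list()
    for (cl in clades) {
      members <- sample_ids[labels == cl]
      if (!length(members)) next
      full_name <- paste0(cfg$root_name, cl)
      gen <- simulate_genealogy(length(members), cfg$clade_ages[[cl]],
                                model = cfg$model, tip_labels = members)
      sim <- drop_mutations(gen, cfg$mu, ref, ts_tv = cfg$ts_tv,
                            root_haplotype = c(root_motif, motifs[[full_name]]))
      clade_trees[[full_name]] <- sim
      for (pr in sim$profiles) profiles[[pr$sample_id]] <- pr
    }
    # background samples: unrelated haplotypes avoiding motif sites
    for (sid in sample_ids[labels == "background"]) {
      k <- stats::rpois(1L, 3)
      pos <- sample(setdiff(seq_len(ref$length), taken), k)
      profiles[[sid]] <- haplotype_profile(
        sid, motif_labels_at(ref, pos, cfg$ts_tv), L = ref$length)
    }

    n_total <- length(sample_ids)
    n_partial <- round(cfg$partial_fraction * n_total)
    partial_ids <- sample(sample_ids, n_partial)
    control <- attr(ref, "control_interval")
    records <- vector("list", n_total)
    for (i in seq_along(sample_ids)) {
      sid <- sample_ids[i]
      pr <- profiles[[sid]]
      if (sid %in% partial_ids) {
        pr <- restrict_profile(pr, control)
        profiles[[sid]] <- pr
      }
      pm <- pops[pops$population == populations[i], ]
      records[[i]] <- sample_record(
        sid, sequence = apply_profile(pr, ref),
        covered_range = pr$covered_range, population = pm$population,
        region = pm$region, latitude = pm$latitude, longitude = pm$longitude
      )
    }
    metadata <- data.frame(
      sample_id = sample_ids, population = populations,
      region = pops$region[match(populations, pops$population)],
      latitude = pops$latitude[match(populations, pops$population)],
      longitude = pops$longitude[match(populations, pops$population)],
      covered_range = vapply(profiles, function(p) format_intervals(p$covered_range), ""),
      stringsAsFactors = FALSE
    )
    truth_freq <- do.call(rbind, lapply(pops$population, function(p) {
      data.frame(population = p, clade = paste0(cfg$root_name, clades),
                 frequency = 100 * counts[, p] / pops$n[pops$population == p],
                 stringsAsFactors = FALSE)
    }))
    structure(
      list(records = records, metadata = metadata, ref = ref,
           profiles = profiles,
           truth = list(
             labels = data.frame(
               sample_id = sample_ids,
               clade = ifelse(labels == "background", "background",
                              paste0(cfg$root_name, labels)),
               partial = sample_ids %in% partial_ids,
               stringsAsFactors = FALSE),
             ages = stats::setNames(cfg$clade_ages,
                                    paste0(cfg$root_name, names(cfg$clade_ages))),
             motifs = motifs,
             frequencies = truth_freq,
             clade_trees = clade_trees),
           config = cfg),
      class = "simulated_study"
    )
  })
}

#' Write a simulated survey to disk
#'
#' Emits exactly the formats the pipeline consumes: FASTA sequences,
#' metadata TSV, BED-like partition annotation, reference FASTA, motif
#' table, plus truth tables (labels, ages, frequencies).
#'
#' @param sim a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the written paths.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "samples.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    reference = file.path(dir, "reference.fasta"),
    annotation = file.path(dir, "annotation.bed"),
    motifs = file.path(dir, "true_motifs.tsv"),
    labels = file.path(dir, "true_labels.tsv"),
    ages = file.path(dir, "true_ages.tsv"),
    frequencies = file.path(dir, "true_frequencies.tsv")
  )
  write_sample_fasta(sim$records, paths["fasta"])
  write_metadata(sim$metadata, paths["metadata"])
  write_sample_fasta(list(sample_record(sim$ref$name, sim$ref$sequence)),
                     paths["reference"])
  write_annotation_bed(sim$ref, paths["annotation"])
  write_motif_table(sim$truth$motifs, paths["motifs"])
  utils::write.table(sim$truth$labels, paths["labels"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(clade = names(sim$truth$ages), age_years = sim$truth$ages),
    paths["ages"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$frequencies, paths["frequencies"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
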