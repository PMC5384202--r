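# Shared fixtures and independent oracles, all built in code.

# tiny handmade reference: control 1-9, gene 10-21 (4 codons), rRNA 22-27,
# other 28-30
tiny_ref <- function() {
  seq <- paste0("ACGTACGTA", "ATGCTAGGATTC", "AACGGT", "TAG")
  ann <- data.frame(
    start = c(1L, 10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L, 21L, 22L),
    end   = c(9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L, 21L, 27L),
    partition = c("control", rep(c("codon1", "codon2", "codon3"), 4L), "rRNA_tRNA"),
    stringsAsFactors = FALSE
  )
  ref <- reference_system(seq, ann, name = "tiny")
  attr(ref, "control_interval") <- rbind(c(1L, 9L))
  ref
}

make_profile <- function(id, labels, L, covered = NULL) {
  haplotype_profile(id, labels, covered_range = covered, L = L)
}

# hand-build a haplogroup tree: `parent` (0 = root), `events` list,
# `sample` ids at leaves (NA for internal nodes)
manual_tree <- function(parent, events, sample, L = 1000L) {
  structure(
    list(parent = as.integer(parent), events = events,
         clade = rep(NA_character_, length(parent)),
         sample = sample, n_tips = sum(!is.na(sample)), L = L),
    class = "haplogroup_tree"
  )
}

# star clade: root node 1, one leaf per element of `counts`, each leaf edge
# carrying that many distinct private mutations
star_tree <- function(counts, start_pos = 100L) {
  n <- length(counts)
  parent <- c(0L, rep(1L, n))
  pos <- start_pos
  events <- vector("list", n + 1L)
  events[[1L]] <- character()
  for (i in seq_len(n)) {
    k <- counts[i]
    events[[i + 1L]] <- if (k > 0) paste0("A", pos + seq_len(k), "G") else character()
    pos <- pos + k
  }
  manual_tree(parent, events, c(NA, paste0("t", seq_len(n))))
}

# independent small-parsimony oracle: exhaustive enumeration of internal
# state assignments, per site, over the observed state alphabet
brute_parsimony <- function(phy, profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, "")
  varsets <- lapply(profiles, function(p) p$variants)
  names(varsets) <- ids
  all_v <- unique(unlist(varsets))
  if (!length(all_v)) return(0L)
  pos <- vapply(all_v, function(lb) parse_variant_label(lb)$position, 1L)
  n <- length(phy$tip.label)
  m <- phy$Nnode
  total <- 0L
  for (p in unique(pos)) {
    site_labels <- all_v[pos == p]
    states <- c("ref", site_labels)
    leaf_state <- vapply(phy$tip.label, function(id) {
      hit <- intersect(varsets[[id]], site_labels)
      if (length(hit)) match(hit[1], states) else 1L
    }, 1L)
    ns <- length(states)
    grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), m)))
    cost <- numeric(nrow(grid))
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      pa_states <- grid[, pa - n]
      ch_states <- if (ch <= n) rep(leaf_state[ch], nrow(grid)) else grid[, ch - n]
      cost <- cost + (pa_states != ch_states)
    }
    total <- total + min(cost)
  }
  as.integer(total)
}

# random profiles on random positions for parsimony instances
random_parsimony_instance <- function(n_leaves, n_sites, L = 500L) {
  phy <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("s", seq_len(n_leaves))
  pos <- sample(L, n_sites)
  varsets <- replicate(n_leaves, character(), simplify = FALSE)
  for (p in pos) {
    anc <- sample(c("A", "C", "G", "T"), 1L)
    der <- sample(setdiff(c("A", "C", "G", "T"), anc),
                  sample(1:2, 1L, prob = c(0.8, 0.2)))
    for (d in der) {
      carriers <- which(stats::runif(n_leaves) < 0.4)
      lb <- substitution_label(p, anc, d)
      for (i in carriers) {
        # at most one substitution per position per leaf
        existing <- vapply(varsets[[i]], function(x) parse_variant_label(x)$position, 1L)
        if (!length(existing) || !p %in% existing) {
          varsets[[i]] <- c(varsets[[i]], lb)
        }
      }
    }
  }
  profiles <- lapply(seq_len(n_leaves), function(i) {
    make_profile(paste0("s", i), varsets[[i]], L)
  })
  list(phy = phy, profiles = profiles)
}

# random conflict-free clade structure for perfect-phylogeny tests:
# recursively split the sample set, assigning unique characters per edge.
# Returns profiles plus the generating edge partition (tip-set -> labels).
random_perfect_instance <- function(n, L = 2000L) {
  next_pos <- new.env(parent = emptyenv()); next_pos$p <- 1L
  new_labels <- function(k) {
    pos <- next_pos$p + seq_len(k) - 1L
    next_pos$p <- next_pos$p + k
    paste0("A", pos, "G")
  }
  truth <- list()
  varsets <- replicate(n, character(), simplify = FALSE)
  recurse <- function(members) {
    if (length(members) < 2L) return(invisible())
    n_blocks <- sample(2:min(4L, length(members)), 1L)
    grp <- sample(rep(seq_len(n_blocks), length.out = length(members)))
    for (b in seq_len(n_blocks)) {
      blk <- members[grp == b]
      if (length(blk) == length(members)) next
      k <- sample(1:3, 1L)
      labs <- new_labels(k)
      truth[[length(truth) + 1L]] <<- list(tips = sort(blk), labels = labs)
      for (i in blk) varsets[[i]] <<- c(varsets[[i]], labs)
      if (length(blk) >= 2L && stats::runif(1L) < 0.7) recurse(blk)
    }
  }
  recurse(seq_len(n))
  root_labs <- new_labels(2L)
  truth[[length(truth) + 1L]] <- list(tips = seq_len(n), labels = root_labs)
  for (i in seq_len(n)) varsets[[i]] <- c(varsets[[i]], root_labs)
  profiles <- lapply(seq_len(n), function(i) {
    make_profile(paste0("s", i), varsets[[i]], L)
  })
  list(profiles = profiles, truth = truth)
}

# edge partition realised by a built haplogroup tree: named by sorted tip
# indices (sample ids s<i>), mapping to the edge's event labels
tree_edge_partition <- function(tree) {
  out <- list()
  for (v in seq_along(tree$parent)) {
    ev <- tree$events[[v]]
    if (!length(ev)) next
    tips <- sort(tree$sample[tips_below(tree, v)])
    key <- paste(tips, collapse = ",")
    out[[key]] <- sort(c(out[[key]], ev))
  }
  out
}
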