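#' Build a maximum-parsimony haplogroup tree
#'
#' Constructs a rooted haplotype tree whose edges carry mutation events.
#' When the character matrix (one binary character per distinct variant) is
#' conflict-free, the result is the unique perfect phylogeny: every
#' character maps to exactly one edge and polytomies are preserved.  Under
#' conflict (recurrent mutation), characters are resolved greedily in order
#' of descending site weight, then descending carrier count: the weaker
#' character is fragmented over the already-placed blocks and recurs as a
#' repeat event on several edges.  Hypermutable sites (e.g. 152 or 16309 in
#' the human control region) can be down-weighted through `weights` so they
#' lose conflicts against stable coding sites.
#'
#' Variants carried by every input profile form the root motif: the edge
#' subtending the tree's root clade.
#'
#' @param profiles list of `haplotype_profile`s (complete genomes; partial
#'   profiles are accepted but count as non-carriers at uncovered sites).
#' @param weights optional named numeric vector mapping site position to
#'   weight (default 1 per site).
#' @return object of class `haplogroup_tree`: parallel vectors `parent`
#'   (0 for the root), `events` (variant labels on the edge into each node),
#'   `clade` (clade names, `NA` until named), `sample` (sample ids at
#'   leaves), plus `n_tips` and `L`.
#' @export
build_mp_tree <- function(profiles, weights = NULL) {
  if (length(profiles) == 0L) stop("no input profiles")
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!any(!vapply(profiles, function(p) p$partial, TRUE))) {
    stop("need at least one complete profile")
  }
  n <- length(profiles)
  varsets <- lapply(profiles, function(p) p$variants)
  labels <- sort_variant_labels(unique(unlist(varsets)))
  carriers <- lapply(labels, function(lb) {
    which(vapply(varsets, function(v) lb %in% v, TRUE))
  })
  pos <- if (length(labels)) variant_positions(labels) else integer()
  wt <- rep(1, length(labels))
  if (!is.null(weights) && length(labels)) {
    hit <- match(as.character(pos), names(weights))
    wt[!is.na(hit)] <- as.numeric(weights[hit[!is.na(hit)]])
  }

  tr <- new.env(parent = emptyenv())
  tr$parent <- integer(); tr$events <- list(); tr$clade <- character()
  tr$sample <- character()
  add_node <- function(parent) {
    id <- length(tr$parent) + 1L
    tr$parent[id] <- parent
    tr$events[[id]] <- character()
    tr$clade[id] <- NA_character_
    tr$sample[id] <- NA_character_
    id
  }

  # pending characters are (label, weight, position, carrier set) rows
  recurse <- function(node, S, pend) {
    if (length(pend)) {
      shared <- vapply(pend, function(ch) length(ch$carriers) == length(S), TRUE)
      if (any(shared)) {
        lbs <- vapply(pend[shared], function(ch) ch$label, "")
        tr$events[[node]] <- c(tr$events[[node]], sort_variant_labels(unique(lbs)))
        pend <- pend[!shared]
      }
    }
    if (length(S) == 1L && tr$parent[node] != 0L) {
      tr$sample[node] <- ids[S]
      return(invisible())
    }
    ord <- order(-vapply(pend, function(ch) ch$weight, 1),
                 -vapply(pend, function(ch) length(ch$carriers), 1L),
                 vapply(pend, function(ch) ch$position, 1L),
                 vapply(pend, function(ch) ch$label, ""))
    pend <- pend[ord]
    blocks <- list()         # disjoint carrier subsets of S
    block_pend <- list()     # pending characters per block
    for (ch in pend) {
      K <- ch$carriers
      for (b in seq_along(blocks)) {
        I <- intersect(K, blocks[[b]])
        if (length(I)) {
          frag <- ch; frag$carriers <- I
          block_pend[[b]] <- c(block_pend[[b]], list(frag))
          K <- setdiff(K, I)
          if (!length(K)) break
        }
      }
      if (length(K)) {
        frag <- ch; frag$carriers <- K
        blocks[[length(blocks) + 1L]] <- K
        block_pend[[length(blocks)]] <- list(frag)
      }
    }
    placed <- if (length(blocks)) unlist(blocks) else integer()
    for (s in setdiff(S, placed)) {
      leaf <- add_node(node)
      tr$sample[leaf] <- ids[s]
    }
    for (b in seq_along(blocks)) {
      child <- add_node(node)
      recurse(child, blocks[[b]], block_pend[[b]])
    }
    invisible()
  }

  root <- add_node(0L)
  pend <- lapply(seq_along(labels), function(i) {
    list(label = labels[i], weight = wt[i], position = pos[i],
         carriers = carriers[[i]])
  })
  recurse(root, seq_len(n), pend)

  out <- structure(
    list(parent = tr$parent, events = tr$events, clade = tr$clade,
         sample = tr$sample, n_tips = n,
         L = profiles[[1]]$L),
    class = "haplogroup_tree"
  )
  stopifnot(sum(!is.na(out$sample)) == n)
  out
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("<haplogroup_tree>", x$n_tips, "tips,",
      length(x$parent) - x$n_tips, "internal nodes,",
      sum(lengths(x$events)), "mutation events\n")
  named <- which(!is.na(x$clade))
  if (length(named)) {
    cat("  clades:", paste(x$clade[named], collapse = " "), "\n")
  }
  invisible(x)
}

tree_children <- function(tree, node) which(tree$parent == node)

tree_root <- function(tree) which(tree$parent == 0L)

is_leaf <- function(tree, node) !is.na(tree$sample[node])

#' Tips below a node
#' @param tree a `haplogroup_tree`.
#' @param node node index.
#' @return integer vector of leaf node indices in the subtree rooted at
#'   `node` (including `node` itself when it is a leaf).
#' @export
tips_below <- function(tree, node) {
  acc <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (is_leaf(tree, v)) acc <- c(acc, v)
    stack <- c(stack, tree_children(tree, v))
  }
  acc
}

subtree_nodes <- function(tree, node) {
  acc <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    acc <- c(acc, v)
    stack <- c(stack, tree_children(tree, v))
  }
  acc
}

#' Find the node carrying a clade name
#' @param tree a named `haplogroup_tree`.
#' @param clade clade name (or a node index, returned unchanged).
#' @return node index.
#' @export
node_of_clade <- function(tree, clade) {
  if (is.numeric(clade)) return(as.integer(clade))
  hit <- which(!is.na(tree$clade) & tree$clade == clade)
  if (length(hit) != 1L) stop("clade not found (or ambiguous): ", clade)
  hit
}

#' Reconstruct a leaf's profile from the tree
#'
#' Concatenates the mutation events on the path from the root edge down to a
#' leaf; a label occurring twice on the path is a back mutation and toggles
#' the site back to its previous state.
#'
#' @param tree a `haplogroup_tree`.
#' @param sample_id leaf sample id.
#' @return character vector of variant labels.
#' @export
reconstruct_profile <- function(tree, sample_id) {
  leaf <- which(!is.na(tree$sample) & tree$sample == sample_id)
  if (length(leaf) != 1L) stop("unknown sample: ", sample_id)
  path <- character()
  v <- leaf
  while (v != 0L) {
    path <- c(tree$events[[v]], path)
    v <- tree$parent[v]
  }
  present <- character()
  for (lb in path) {
    if (lb %in% present) present <- setdiff(present, lb) else present <- c(present, lb)
  }
  sort_variant_labels(present)
}

#' Small-parsimony score of a topology
#'
#' Minimum number of state changes needed to explain the profiles on a given
#' rooted topology, computed per site (Hartigan's generalisation of the
#' Fitch two-pass, exact on multifurcating trees) and summed over sites.
#'
#' @param topology an `ape::phylo` object (rooted; polytomies allowed) whose
#'   tip labels are sample ids, or a `haplogroup_tree`.
#' @param profiles list of `haplotype_profile`s matching the tips.
#' @return integer parsimony length.
#' @export
parsimony_score <- function(topology, profiles) {
  if (inherits(topology, "haplogroup_tree")) topology <- as_phylo(topology)
  stopifnot(inherits(topology, "phylo"))
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (!setequal(topology$tip.label, ids) || length(topology$tip.label) != length(ids)) {
    stop("topology tips and profiles do not match")
  }
  varsets <- lapply(profiles, function(p) p$variants)
  names(varsets) <- ids
  all_v <- unique(unlist(varsets))
  if (!length(all_v)) return(0L)
  vt <- parse_variant_label(all_v)
  total <- 0L
  for (p in unique(vt$position)) {
    site_labels <- all_v[vt$position == p]
    # leaf state: the carried label at this site, or "ref"
    states <- c("ref", site_labels)
    leaf_state <- vapply(topology$tip.label, function(id) {
      hit <- intersect(varsets[[id]], site_labels)
      if (length(hit)) hit[1] else "ref"
    }, "")
    total <- total + hartigan_length(topology, factor(leaf_state, levels = states))
  }
  as.integer(total)
}

# minimum changes for one character on a rooted (possibly multifurcating)
# phylo; leaf_states is a factor over the state alphabet, ordered by tip
hartigan_length <- function(phy, leaf_states) {
  n <- length(phy$tip.label)
  m <- phy$Nnode
  nstate <- nlevels(leaf_states)
  upper <- matrix(FALSE, n + m, nstate)
  upper[cbind(seq_len(n), as.integer(leaf_states))] <- TRUE
  cost <- 0L
  child_of <- split(phy$edge[, 2L], phy$edge[, 1L])
  # process internal nodes in reverse breadth-first order from the root
  # so every child is resolved before its parent
  ord <- integer()
  stack <- n + 1L
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    ord <- c(ord, v)
    kids <- child_of[[as.character(v)]]
    stack <- c(stack, kids[kids > n])
  }
  for (v in rev(ord)) {
    kids <- child_of[[as.character(v)]]
    votes <- colSums(upper[kids, , drop = FALSE])
    kmax <- max(votes)
    upper[v, ] <- votes == kmax
    cost <- cost + (length(kids) - kmax)
  }
  cost
}

#' Assign clade names to tree nodes
#'
#' Auto-names internal nodes that carry defining mutations, following
#' haplogroup conventions: the root clade takes `root_name`; children are
#' suffixed with letters when the parent name ends in a digit and with
#' digits otherwise (so `U7` begets `U7a`, which begets `U7a1`).  Children
#' are ordered by descending subtree size, then by the lowest position among
#' their defining mutations.
#'
#' @param tree a `haplogroup_tree`.
#' @param root_name name for the root clade.
#' @return the tree with `clade` filled in.
#' @export
name_clades <- function(tree, root_name = "H") {
  root <- tree_root(tree)
  tree$clade[root] <- root_name
  walk <- function(node) {
    kids <- tree_children(tree, node)
    kids <- kids[!is_leaf(tree, kids)]
    if (!length(kids)) return(invisible())
    size <- vapply(kids, function(k) length(tips_below(tree, k)), 1L)
    minpos <- vapply(kids, function(k) {
      ev <- tree$events[[k]]
      if (length(ev)) min(variant_positions(ev)) else .Machine$integer.max
    }, 1L)
    kids <- kids[order(-size, minpos)]
    parent_name <- tree$clade[node]
    suffixes <- if (grepl("[0-9]$", parent_name)) {
      make_letter_suffixes(length(kids))
    } else {
      as.character(seq_along(kids))
    }
    for (i in seq_along(kids)) {
      tree$clade[kids[i]] <<- paste0(parent_name, suffixes[i])
      walk(kids[i])
    }
    invisible()
  }
  walk(root)
  tree
}

make_letter_suffixes <- function(k) {
  single <- letters
  if (k <= 26L) return(single[seq_len(k)])
  extra <- as.vector(outer(letters, letters, function(a, b) paste0(a, b)))
  c(single, extra)[seq_len(k)]
}

#' Extract clade-defining motifs
#'
#' One motif per named clade: exactly the mutation events on the edge
#' subtending that clade's node, ordered by position.  The root clade's
#' motif is the edge into the tree's root (the variants shared by all
#' samples).  An unnamed tree is auto-named first (with a warning).
#'
#' @param tree a `haplogroup_tree`.
#' @param root_name used if auto-naming is required.
#' @return named list mapping clade name to ordered variant labels.
#' @export
extract_motifs <- function(tree, root_name = "H") {
  if (all(is.na(tree$clade))) {
    warning("tree has no clade names; auto-naming applied")
    tree <- name_clades(tree, root_name)
  }
  named <- which(!is.na(tree$clade))
  out <- lapply(named, function(v) sort_variant_labels(tree$events[[v]]))
  names(out) <- tree$clade[named]
  out
}

#' Convert a haplogroup tree to ape's phylo
#'
#' Leaf labels are sample ids, internal node labels are clade names (empty
#' when unnamed) and branch lengths count the mutation events on each edge.
#'
#' @param tree a `haplogroup_tree`.
#' @return an `ape::phylo` object.
#' @export
as_phylo <- function(tree) {
  nn <- length(tree$parent)
  leaves <- which(!is.na(tree$sample))
  internal <- setdiff(seq_len(nn), leaves)
  root <- tree_root(tree)
  internal <- c(root, setdiff(internal, root))
  new_id <- integer(nn)
  new_id[leaves] <- seq_along(leaves)
  new_id[internal] <- length(leaves) + seq_along(internal)
  non_root <- setdiff(seq_len(nn), root)
  edge <- cbind(new_id[tree$parent[non_root]], new_id[non_root])
  phy <- list(
    edge = edge,
    edge.length = lengths(tree$events)[non_root],
    tip.label = tree$sample[leaves],
    node.label = ifelse(is.na(tree$clade[internal]), "", tree$clade[internal]),
    Nnode = length(internal)
  )
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a haplogroup tree as newick
#'
#' Plain newick (parseable by standard readers) with sample ids at tips,
#' clade names on internal nodes and event counts as branch lengths.  With
#' `comments = TRUE`, each branch additionally carries its variant labels in
#' a bracketed comment (readers that honour newick comments will skip it;
#' strict parsers should read the default form).
#'
#' @param tree a `haplogroup_tree`.
#' @param path output path.
#' @param comments emit `[&variants=...]` branch comments.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path, comments = FALSE) {
  emit <- function(v) {
    kids <- tree_children(tree, v)
    lab <- if (is_leaf(tree, v)) tree$sample[v]
           else if (!is.na(tree$clade[v])) tree$clade[v] else ""
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, emit, ""), collapse = ","), ")")
    } else ""
    com <- if (comments && length(tree$events[[v]])) {
      paste0("[&variants=", paste(tree$events[[v]], collapse = "|"), "]")
    } else ""
    paste0(inner, lab, ":", length(tree$events[[v]]), com)
  }
  writeLines(paste0("(", emit(tree_root(tree)), ");"), path)
  invisible(path)
}
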