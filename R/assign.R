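#' Assign a profile to a haplogroup
#'
#' Scores a (possibly partial) haplotype profile against the nested motif
#' system of a haplogroup tree.  For each named clade the expected variant
#' set is the concatenation of motifs from the root down to that clade;
#' only motif sites inside the profile's sequenced range are evaluated.
#' The assignment maximises `matched - missing` (motif variants observed
#' minus motif variants that should have been seen in the covered range but
#' were not); ties go to the shallower clade.  A profile covering none of
#' any motif site, or matching nothing, is reported `"unassigned"`.
#'
#' @param profile a `haplotype_profile`.
#' @param motifs named list of clade motifs (as from [extract_motifs()]).
#' @param tree the named `haplogroup_tree` the motifs came from (supplies
#'   the clade nesting).
#' @return list with `clade` (name or `"unassigned"`), `score`, `matched`,
#'   `missing`, `extra` (non-motif variants carried by the profile) and
#'   `table` (per-clade score report, a data frame).
#' @export
assign_haplogroup <- function(profile, motifs, tree) {
  named <- which(!is.na(tree$clade))
  if (!length(named)) stop("tree carries no clade names")
  if (!all(tree$clade[named] %in% names(motifs))) {
    stop("motif table missing clade(s): ",
         paste(setdiff(tree$clade[named], names(motifs)), collapse = ", "))
  }
  root <- tree_root(tree)
  depth_of <- function(v) {
    d <- 0L
    while (tree$parent[v] != 0L) { v <- tree$parent[v]; d <- d + 1L }
    d
  }
  chain_of <- function(v) {
    chain <- character()
    while (v != 0L) {
      if (!is.na(tree$clade[v]) && tree$clade[v] %in% names(motifs)) {
        chain <- c(motifs[[tree$clade[v]]], chain)
      }
      v <- tree$parent[v]
    }
    unique(chain)
  }
  rows <- lapply(named, function(v) {
    expected <- chain_of(v)
    pos <- if (length(expected)) variant_positions(expected) else integer()
    in_cov <- positions_in_intervals(pos, profile$covered_range)
    expected_cov <- expected[in_cov]
    matched <- intersect(expected_cov, profile$variants)
    missing <- setdiff(expected_cov, profile$variants)
    data.frame(clade = tree$clade[v], depth = depth_of(v),
               n_expected_covered = length(expected_cov),
               n_matched = length(matched), n_missing = length(missing),
               score = length(matched) - length(missing),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, tab$depth, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  if (max(tab$n_matched) == 0L) {
    return(list(clade = "unassigned", score = 0L, matched = character(),
                missing = character(), extra = profile$variants, table = tab))
  }
  best <- tab[1L, ]
  v <- node_of_clade(tree, best$clade)
  expected <- chain_of(v)
  pos <- variant_positions(expected)
  expected_cov <- expected[positions_in_intervals(pos, profile$covered_range)]
  list(
    clade = best$clade,
    score = best$score,
    matched = intersect(expected_cov, profile$variants),
    missing = setdiff(expected_cov, profile$variants),
    extra = setdiff(profile$variants, expected),
    table = tab
  )
}

#' Assign many profiles and tabulate the report
#'
#' @param profiles list of `haplotype_profile`s.
#' @param motifs named motif list.
#' @param tree named `haplogroup_tree`.
#' @return data frame with one row per profile: `sample_id`, `clade`,
#'   `score`, `n_matched`, `n_missing`, `n_extra`.
#' @export
assign_all <- function(profiles, motifs, tree) {
  rows <- lapply(profiles, function(p) {
    a <- assign_haplogroup(p, motifs, tree)
    data.frame(sample_id = p$sample_id, clade = a$clade, score = a$score,
               n_matched = length(a$matched), n_missing = length(a$missing),
               n_extra = length(a$extra), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a clade-nesting tree from a motif table
#'
#' Published motif tables (clade name plus defining mutations) carry the
#' clade nesting in their names: `U7a1` nests inside `U7a` inside `U7`.
#' This constructs the corresponding `haplogroup_tree` skeleton — named
#' internal nodes whose edges carry the motifs, no sample leaves — so
#' profiles can be assigned against a published table without rebuilding
#' the tree from sequences.
#'
#' @param motifs named list of variant-label vectors (as from
#'   [read_motif_table()]).
#' @param root_name the root clade; must be in `motifs` (added with an
#'   empty motif when absent).
#' @param L reference length.
#' @return a `haplogroup_tree` with zero tips.
#' @export
motif_tree <- function(motifs, root_name, L = 16569L) {
  if (!root_name %in% names(motifs)) {
    motifs <- c(stats::setNames(list(character()), root_name), motifs)
  }
  nms <- names(motifs)
  if (!all(startsWith(nms, root_name))) {
    stop("all clade names must nest under ", sQuote(root_name))
  }
  # parent = longest proper prefix among the clade names
  parent_name <- vapply(nms, function(nm) {
    cand <- nms[nms != nm & startsWith(nm, nms)]
    if (!length(cand)) NA_character_ else cand[which.max(nchar(cand))]
  }, "")
  if (sum(is.na(parent_name)) != 1L || !is.na(parent_name[nms == root_name])) {
    stop("motif names do not form a single rooted hierarchy")
  }
  ord <- order(nchar(nms))  # parents precede children
  idx <- stats::setNames(seq_along(nms), nms[ord])
  parent <- integer(length(nms))
  events <- vector("list", length(nms))
  clade <- character(length(nms))
  for (i in seq_along(ord)) {
    nm <- nms[ord[i]]
    parent[i] <- if (is.na(parent_name[ord[i]])) 0L else idx[[parent_name[ord[i]]]]
    events[[i]] <- sort_variant_labels(motifs[[nm]])
    clade[i] <- nm
  }
  structure(
    list(parent = parent, events = events, clade = clade,
         sample = rep(NA_character_, length(nms)), n_tips = 0L, L = L),
    class = "haplogroup_tree"
  )
}

#' Collapse an assignment to its major branch
#'
#' Maps a (possibly deep) clade name such as `U7a3b1` to the major branch
#' directly below the root clade (`U7a`), using name nesting.
#'
#' @param clade character vector of clade names.
#' @param root_name the root clade's name.
#' @return character vector of major-branch names (`root_name` itself for
#'   samples sitting on the root, `"unassigned"` passed through).
#' @export
major_branch <- function(clade, root_name) {
  vapply(clade, function(cl) {
    if (cl == "unassigned" || cl == root_name) return(cl)
    if (!startsWith(cl, root_name)) return("unassigned")
    rest <- substring(cl, nchar(root_name) + 1L)
    # first naming component after the root: a letter run or a digit run
    m <- regmatches(rest, regexpr("^([a-z]+|[0-9]+)", rest))
    if (!length(m)) cl else paste0(root_name, m)
  }, "", USE.NAMES = FALSE)
}
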