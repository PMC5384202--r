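test_that("a single profile yields one edge carrying all its events", {
  p <- make_profile("s1", c("T152C", "T980C", "C1741T"), 2000L)
  tree <- build_mp_tree(list(p))
  root <- which(tree$parent == 0L)
  expect_setequal(tree$events[[root]], p$variants)
  expect_equal(tree$n_tips, 1L)
  expect_equal(reconstruct_profile(tree, "s1"), p$variants)
})

test_that("conflict-free profiles recover the generating tree exactly", {
  # hand-built clade structure with a basal polytomy of three branches
  L <- 2000L
  root_m <- c("T152C", "T980C")
  a_m <- "C151T"; b_m <- "T1084C"; c_m <- "G1709A"
  profs <- list(
    make_profile("a1", c(root_m, a_m, "A300G"), L),
    make_profile("a2", c(root_m, a_m, "A301G"), L),
    make_profile("b1", c(root_m, b_m, "A302G"), L),
    make_profile("b2", c(root_m, b_m), L),
    make_profile("c1", c(root_m, c_m, "A303G"), L),
    make_profile("c2", c(root_m, c_m, "A304G"), L)
  )
  tree <- build_mp_tree(profs)
  root <- which(tree$parent == 0L)
  expect_setequal(tree$events[[root]], root_m)
  expect_length(tree_children <- which(tree$parent == root), 3L)  # polytomy
  for (p in profs) {
    expect_equal(reconstruct_profile(tree, p$sample_id), p$variants)
  }
  tree <- name_clades(tree, "U7")
  motifs <- extract_motifs(tree)
  expect_equal(motifs[["U7"]], sort(root_m))
  # children ordered by lowest defining position at equal subtree size
  expect_equal(motifs[["U7a"]], "C151T")
  expect_equal(motifs[["U7b"]], "T1084C")
  expect_equal(motifs[["U7c"]], "G1709A")
})

test_that("random conflict-free matrices reconstruct topology, edges and polytomies", {
  set.seed(19)
  for (rep in 1:20) {
    inst <- random_perfect_instance(sample(5:12, 1L))
    tree <- build_mp_tree(inst$profiles)
    expect_equal(tree$n_tips, length(inst$profiles))
    got <- tree_edge_partition(tree)
    want <- list()
    for (tr in inst$truth) {
      key <- paste(sort(paste0("s", tr$tips)), collapse = ",")
      want[[key]] <- sort(c(want[[key]], tr$labels))
    }
    expect_equal(got[order(names(got))], want[order(names(want))])
    for (p in inst$profiles) {
      expect_setequal(reconstruct_profile(tree, p$sample_id), p$variants)
    }
  }
})

test_that("parsimony score is zero for identical profiles and one for a clean split", {
  L <- 100L
  phy <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  same <- lapply(1:4, function(i) make_profile(paste0("s", i), "A5G", L))
  expect_equal(parsimony_score(phy, same), 0L)
  split <- list(
    make_profile("s1", "A5G", L), make_profile("s2", "A5G", L),
    make_profile("s3", character(), L), make_profile("s4", character(), L)
  )
  expect_equal(parsimony_score(phy, split), 1L)
})

test_that("parsimony score equals exhaustive enumeration on random instances", {
  set.seed(23)
  for (rep in 1:25) {
    inst <- random_parsimony_instance(sample(4:6, 1L), sample(3:8, 1L))
    expect_equal(parsimony_score(inst$phy, inst$profiles),
                 brute_parsimony(inst$phy, inst$profiles))
  }
})

test_that("parsimony score agrees with an independent phylogenetics library", {
  set.seed(29)
  for (rep in 1:10) {
    inst <- random_parsimony_instance(6L, 6L)
    # re-encode per site: reference state "a", derived alleles "c"/"g"
    # (keeps states distinct even when a derived allele is A)
    all_v <- unique(unlist(lapply(inst$profiles, `[[`, "variants")))
    vt <- parse_variant_label(all_v)
    state_of <- stats::setNames(rep("c", length(all_v)), all_v)
    for (p in unique(vt$position)) {
      labs <- all_v[vt$position == p]
      state_of[labs] <- c("c", "g", "t")[seq_along(labs)]
    }
    seqs <- lapply(inst$profiles, function(p) {
      chars <- rep("a", 500L)
      if (length(p$variants)) {
        v <- parse_variant_label(p$variants)
        chars[v$position] <- state_of[p$variants]
      }
      chars
    })
    names(seqs) <- vapply(inst$profiles, `[[`, "", "sample_id")
    pd <- phangorn::phyDat(do.call(rbind, seqs), type = "USER",
                           levels = c("a", "c", "g", "t"))
    expect_equal(parsimony_score(inst$phy, inst$profiles),
                 as.integer(phangorn::parsimony(inst$phy, pd)))
  }
})

test_that("a single incompatible character costs exactly one extra step", {
  L <- 100L
  # chars: X on {1,2,3}, Y on {3,4} -> overlap at 3, neither nested
  profs <- list(
    make_profile("s1", "A10G", L),
    make_profile("s2", "A10G", L),
    make_profile("s3", c("A10G", "A20G"), L),
    make_profile("s4", "A20G", L),
    make_profile("s5", character(), L)
  )
  tree <- build_mp_tree(profs)
  score <- parsimony_score(tree, profs)
  # exhaustive minimum over all rooted topologies
  all_top <- phangorn::allTrees(5L, rooted = TRUE,
                                tip.label = paste0("s", 1:5))
  best <- min(vapply(all_top, function(t) parsimony_score(t, profs), 1L))
  expect_equal(score, best)
  expect_equal(best, 3L)  # 2 characters + 1 recurrence
  # events are conserved: every leaf still reconstructs
  for (p in profs) {
    expect_setequal(reconstruct_profile(tree, p$sample_id), p$variants)
  }
})

test_that("site weights decide which conflicting character recurs", {
  L <- 17000L
  # hypermutable site 16309 conflicts with a stable coding site
  profs <- list(
    make_profile("s1", c("A16309G", "A5000G"), L),
    make_profile("s2", c("A16309G", "A5000G"), L),
    make_profile("s3", "A5000G", L),
    make_profile("s4", "A16309G", L),
    make_profile("s5", character(), L)
  )
  tree <- build_mp_tree(profs, weights = c("16309" = 0.5))
  part <- tree_edge_partition(tree)
  # the down-weighted hotspot recurs; the coding character stays single
  n_occurrences <- function(lab) {
    sum(vapply(part, function(ev) lab %in% ev, TRUE))
  }
  expect_equal(n_occurrences("A5000G"), 1L)
  expect_equal(n_occurrences("A16309G"), 2L)
})

test_that("clade naming alternates letters and digits by convention", {
  L <- 2000L
  profs <- list(
    make_profile("x1", c("T152C", "C151T"), L),
    make_profile("x2", c("T152C", "C151T", "A400G", "A500G"), L),
    make_profile("x3", c("T152C", "C151T", "A400G", "A501G"), L),
    make_profile("x4", c("T152C", "T1084C"), L),
    make_profile("x5", c("T152C", "T1084C", "A600G"), L)
  )
  tree <- name_clades(build_mp_tree(profs), "U7")
  motifs <- extract_motifs(tree)
  expect_setequal(names(motifs), c("U7", "U7a", "U7a1", "U7b"))
  expect_equal(major_branch(c("U7a1", "U7b", "U7", "unassigned"), "U7"),
               c("U7a", "U7b", "U7", "unassigned"))
})

test_that("degenerate inputs are rejected", {
  expect_error(build_mp_tree(list()), "no input")
  p <- make_profile("s1", "A5G", 100L)
  expect_error(build_mp_tree(list(p, p)), "duplicate")
  phy <- ape::read.tree(text = "((s1,s2),(s3,sX));")
  expect_error(parsimony_score(phy, list(p)), "match")
})
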