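tip_depths <- function(phy) {
  ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
}

test_that("star genealogies attach every tip to the root at tmrca", {
  phy <- simulate_genealogy(4L, 12000, model = "star")
  expect_equal(nrow(phy$edge), 4L)
  expect_equal(phy$edge.length, rep(12000, 4L))
})

test_that("genealogies are ultrametric with root height tmrca", {
  for (model in c("star", "kingman")) {
    phy <- simulate_genealogy(12L, 9000, model = model, seed = 4)
    expect_equal(unname(tip_depths(phy)), rep(9000, 12L), tolerance = 1e-9)
  }
})

test_that("same seed regenerates the identical genealogy and mutations", {
  g1 <- simulate_genealogy(10L, 5000, model = "kingman", seed = 42)
  g2 <- simulate_genealogy(10L, 5000, model = "kingman", seed = 42)
  expect_identical(g1, g2)
  ref <- synthetic_reference(seed = 2)
  s1 <- drop_mutations(g1, 1e-7, ref, seed = 9)
  s2 <- drop_mutations(g2, 1e-7, ref, seed = 9)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$events, s2$events)
})

test_that("two-lineage epoch length matches the coalescent expectation", {
  # observable: fraction of total tree length contributed by the 2-lineage
  # epoch; oracle simulates the closed-form exponential epoch durations
  # directly, without building trees
  set.seed(8)
  n <- 10L; reps <- 400L
  oracle <- replicate(reps, {
    tk <- stats::rexp(n - 1L, rate = choose(n:2, 2))
    2 * tk[n - 1L] / sum((n:2) * tk)
  })
  observed <- replicate(reps, {
    phy <- simulate_genealogy(n, 10000, model = "kingman")
    d <- ape::node.depth.edgelength(phy)
    heights <- max(d[1:n]) - d
    second <- sort(heights[(n + 1L):(2L * n - 1L)], decreasing = TRUE)[2L]
    2 * (10000 - second) / sum(phy$edge.length)
  })
  se <- sqrt(stats::var(oracle) / reps + stats::var(observed) / reps)
  expect_lt(abs(mean(oracle) - mean(observed)), 3 * se)
})

test_that("zero mutation rate leaves every profile empty", {
  ref <- synthetic_reference(seed = 2)
  gen <- simulate_genealogy(5L, 8000, model = "star")
  sim <- drop_mutations(gen, 0, ref, seed = 1)
  expect_true(all(lengths(lapply(sim$profiles, `[[`, "variants")) == 0L))
})

test_that("mutation counts per edge are Poisson with mean mu*L*t", {
  ref <- synthetic_reference(seed = 2)
  mu <- 1.4e-7; tmrca <- 18600
  lambda <- mu * ref$length * tmrca
  gen <- simulate_genealogy(400L, tmrca, model = "star")
  sim <- drop_mutations(gen, mu, ref, seed = 77)
  counts <- lengths(sim$events)
  expect_equal(mean(counts), lambda, tolerance = 4 / sqrt(400 * lambda))
  # chi-square goodness of fit against the Poisson pmf
  brk <- 0:8
  obs <- table(factor(pmin(counts, 8L), levels = brk))
  pr <- c(stats::dpois(0:7, lambda), 1 - stats::ppois(7, lambda))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("transitions dominate derived alleles at the configured ratio", {
  ref <- synthetic_reference(seed = 2)
  gen <- simulate_genealogy(300L, 18600, model = "star")
  sim <- drop_mutations(gen, 1.4e-7, ref, seed = 5, ts_tv = 20)
  v <- parse_variant_label(unlist(sim$events))
  ts_frac <- mean(v$kind == "transition")
  expect_gt(ts_frac, 0.90)  # expectation 20/21 ~ 0.952
})

test_that("simulated studies respect the configured bookkeeping", {
  pops <- data.frame(
    population = c("P1", "P2", "P3", "P4"),
    region = c("Near East", "South Asia", "Europe", "Central Asia"),
    latitude = c(32, 27, 41, 40), longitude = c(53, 68, 15, 65),
    n = rep(25L, 4L))
  freqs <- rbind(a = rep(0.2, 4L), b = rep(0.04, 4L))
  colnames(freqs) <- pops$population
  sim <- simulate_study(list(populations = pops, clade_frequencies = freqs,
                             clade_ages = c(a = 15000, b = 8000),
                             partial_fraction = 0.6), seed = 21)
  expect_equal(nrow(sim$metadata), 100L)
  expect_equal(sum(sim$truth$labels$partial), 60L)
  got <- sim$truth$frequencies
  expect_equal(got$frequency[got$clade == "Ua"], rep(20, 4L))
  expect_equal(got$frequency[got$clade == "Ub"], rep(4, 4L))
  # partial samples carry control-region coverage only
  part_id <- sim$truth$labels$sample_id[sim$truth$labels$partial][1]
  rec <- Filter(function(r) r$sample_id == part_id, sim$records)[[1]]
  expect_lt(mitophylo:::interval_width(rec$covered_range), sim$ref$length)
  # regenerating with the same seed is bit-identical
  sim2 <- simulate_study(list(populations = pops, clade_frequencies = freqs,
                              clade_ages = c(a = 15000, b = 8000),
                              partial_fraction = 0.6), seed = 21)
  expect_identical(sim$metadata, sim2$metadata)
  expect_identical(sim$truth, sim2$truth)
})

test_that("impossible clade frequencies are rejected", {
  freqs <- rbind(a = rep(0.8, 8L), b = rep(0.4, 8L))
  colnames(freqs) <- default_study_config()$populations$population
  expect_error(simulate_study(list(clade_frequencies = freqs), seed = 1),
               "sum")
})

test_that("written studies contain consistent pipeline inputs", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(seed = 33)
  paths <- write_simulated_study(sim, dir)
  expect_true(all(file.exists(paths)))
  md <- read_metadata(paths[["metadata"]])
  recs <- read_sample_fasta(paths[["fasta"]], metadata = md)
  expect_equal(length(recs), nrow(sim$metadata))
  ann <- read_annotation_bed(paths[["annotation"]])
  ref <- reference_system(recs_ref <- read_sample_fasta(paths[["reference"]])[[1]]$sequence,
                          ann)
  expect_identical(ref$partition, sim$ref$partition)
  motifs <- read_motif_table(paths[["motifs"]])
  expect_identical(motifs, sim$truth$motifs)
})
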