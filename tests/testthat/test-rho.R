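test_that("rho is the mean root-to-tip mutation count", {
  tree <- star_tree(c(1L, 2L, 3L))
  est <- compute_rho(tree, 1L)
  expect_equal(est$rho, 2.0)
  expect_equal(est$n, 3L)
  # single tip with 5 private mutations
  expect_equal(compute_rho(star_tree(5L), 1L)$rho, 5.0)
})

test_that("rho handles shared edges by tip weighting", {
  # shared edge: 1 event over 2 tips; private edges: 0 and 2 events
  tree <- manual_tree(
    parent = c(0L, 1L, 2L, 2L),
    events = list(character(), "A10G",
                  character(), c("A20G", "A21G")),
    sample = c(NA, NA, "t1", "t2")
  )
  est <- compute_rho(tree, 1L)
  expect_equal(est$rho, (1 + 3) / 2)
})

test_that("Saillard sigma follows the tip-weighted Poisson formula", {
  expect_equal(compute_sigma(star_tree(c(1L, 2L, 3L)), 1L), sqrt(6) / 3)
  expect_equal(compute_sigma(star_tree(c(0L, 0L)), 1L), 0)
  # shared edge m = 4 over 4 tips: rho = 4, sigma = sqrt(4 * 16)/4 = 2,
  # confirmed by Poisson resampling (rho ~ Poisson(4), sd = 2)
  tree <- manual_tree(
    parent = c(0L, 1L, 2L, 2L, 2L, 2L),
    events = list(character(), paste0("A", 10:13, "G"),
                  character(), character(), character(), character()),
    sample = c(NA, NA, paste0("t", 1:4))
  )
  expect_equal(compute_sigma(tree, 1L), 2.0)
})

test_that("sigma matches the empirical sd of rho under Poisson resampling", {
  set.seed(5)
  gen <- simulate_genealogy(20L, 15000, model = "kingman", seed = 6)
  sim <- drop_mutations(gen, 1.4e-7, synthetic_reference(seed = 6), seed = 7)
  tree <- as_haplogroup_tree(sim)
  root <- which(tree$parent == 0L)
  est <- compute_rho(tree, root)
  m <- lengths(tree$events)[-root]
  n_below <- vapply(seq_along(tree$parent)[-root],
                    function(v) length(tips_below(tree, v)), 1L)
  reps <- 2e4L
  draws <- matrix(stats::rpois(reps * length(m), rep(m, each = reps)),
                  nrow = reps)
  rho_reps <- as.vector(draws %*% n_below) / est$n
  expect_lt(abs(stats::sd(rho_reps) - est$sigma) / est$sigma, 0.05)
})

test_that("rho converts to years through the clock and correction", {
  est <- structure(list(clade = "x", rho = 1, sigma = 0.5, n = 10L,
                        mutation_filter = "all"), class = "rho_estimate")
  clock <- complete_clock()
  age <- rho_to_age(est, clock)
  expect_equal(age$years, 1 / (1.6865e-8 * 16569), tolerance = 1e-9)
  expect_equal(age$years, 3578.6, tolerance = 1e-4)
  expect_equal(age$sigma_years, 0.5 / (1.6865e-8 * 16569), tolerance = 1e-9)
  expect_lte(age$ci_low, age$years)
  expect_gte(age$ci_high, age$years)
  # zero rho gives a zero age floored at zero
  est0 <- structure(list(clade = "x", rho = 0, sigma = 0.1, n = 3L,
                         mutation_filter = "all"), class = "rho_estimate")
  age0 <- rho_to_age(est0, clock)
  expect_equal(age0$years, 0)
  expect_equal(age0$ci_low, 0)
})

test_that("monotone corrections preserve the ordering of ages", {
  curve <- correction_from_table(
    data.frame(raw = c(0, 5000, 20000, 50000),
               corrected = c(0, 6000, 26000, 70000)))
  mk <- function(rho) structure(
    list(clade = "x", rho = rho, sigma = 0.2, n = 5L, mutation_filter = "all"),
    class = "rho_estimate")
  clock <- clock_model("complete", mu = 1.6865e-8, L_effective = 16569L,
                       correction = curve)
  a <- rho_to_age(mk(2), clock); b <- rho_to_age(mk(5), clock)
  expect_lt(a$years, b$years)
  expect_gt(a$years, rho_to_age(mk(2), complete_clock())$years)  # inflating curve
})

test_that("clock/filter mismatches are rejected", {
  est <- structure(list(clade = "x", rho = 1, sigma = 0.5, n = 10L,
                        mutation_filter = "all"), class = "rho_estimate")
  syn_clock <- clock_model("synonymous", mu = 1e-8, L_effective = 5000L)
  expect_error(rho_to_age(est, syn_clock), "incompatible")
})

test_that("synonymous-filtered rho never exceeds the all-sites rho", {
  ref <- synthetic_reference(seed = 13)
  for (s in 1:5) {
    gen <- simulate_genealogy(8L, 20000, model = "kingman", seed = s)
    sim <- drop_mutations(gen, 2e-7, ref, seed = s + 100L)
    tree <- as_haplogroup_tree(sim)
    root <- which(tree$parent == 0L)
    expect_lte(compute_rho(tree, root, "synonymous", ref)$rho,
               compute_rho(tree, root, "all")$rho)
  }
})

test_that("rate averaging is the arithmetic mean within bounds", {
  expect_identical(average_rates(1.665e-8, 1.708e-8), 1.6865e-8)
  expect_identical(average_rates(3e-8, 3e-8), 3e-8)
  r <- average_rates(1e-8, 2e-8)
  expect_true(r >= 1e-8 && r <= 2e-8)
  expect_error(average_rates(-1e-8, 2e-8), "positive")
})

test_that("age comparison behaves like a normal z test", {
  mk <- function(years, sigma) structure(
    list(clade = "x", years = years, ci_low = years - 1.96 * sigma,
         ci_high = years + 1.96 * sigma, sigma_years = sigma,
         clock = "complete"), class = "age_estimate")
  expect_equal(compare_ages(mk(10000, 500), mk(10000, 500))$p_value, 1.0)
  joint <- sqrt(500^2 + 500^2)
  res <- compare_ages(mk(10000 + 1.96 * joint, 500), mk(10000, 500))
  expect_equal(res$p_value, 0.05, tolerance = 1e-3)
  expect_error(compare_ages(mk(1, 0), mk(2, 0)), "variance")
})

test_that("age tables render one row per clade with motifs", {
  clock <- complete_clock()
  est <- structure(list(clade = "U7", rho = 5.2, sigma = 0.7, n = 30L,
                        mutation_filter = "all"), class = "rho_estimate")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_age_table(list(U7 = list(rho_to_age(est, clock))), path,
                  motifs = list(U7 = c("T152C", "T980C")))
  tab <- utils::read.delim(path, check.names = FALSE)
  expect_equal(tab$clade, "U7")
  expect_match(tab$defining_mutations, "T152C")
  expect_match(tab$complete, "\\d+\\.\\d \\(")
})
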