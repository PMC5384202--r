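toy_assignments <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:10),
    clade = c("U7a", "U7a1", "U7b", "U7", "unassigned",
              "U7a", "U7b", "unassigned", "U7a2", "U7b1"),
    stringsAsFactors = FALSE
  )
}

toy_metadata <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:10),
    population = rep(c("P1", "P2"), each = 5L),
    latitude = rep(c(30, 40), each = 5L),
    longitude = rep(c(50, 20), each = 5L),
    stringsAsFactors = FALSE
  )
}

test_that("frequencies count carriers including subclades", {
  tab <- tabulate_frequencies(toy_assignments(), toy_metadata(), "U7a")
  expect_equal(tab$n_sampled, c(5L, 5L))
  expect_equal(tab$n_carrier, c(2L, 2L))     # U7a, U7a1 | U7a, U7a2
  expect_equal(tab$frequency, c(40, 40))
  expect_true(all(tab$low_sample == FALSE | tab$n_sampled < 5L))
  # whole-haplogroup tabulation includes every named clade
  all_tab <- tabulate_frequencies(toy_assignments(), toy_metadata(), "U7")
  expect_equal(all_tab$n_carrier, c(4L, 4L))
  # daughters never exceed the parent (counting oracle)
  b_tab <- tabulate_frequencies(toy_assignments(), toy_metadata(), "U7b")
  expect_true(all(tab$frequency + b_tab$frequency <= all_tab$frequency))
})

test_that("unknown samples and missing populations are rejected", {
  bad <- rbind(toy_assignments(),
               data.frame(sample_id = "ghost", clade = "U7"))
  expect_error(tabulate_frequencies(bad, toy_metadata(), "U7"), "ghost")
})

test_that("gene diversity follows the unbiased heterozygosity formula", {
  expect_equal(gene_diversity(rep(1L, 4L)), 1.0)
  expect_equal(gene_diversity(c(7L)), 0.0)
  expect_equal(gene_diversity(c(3L, 2L)), 1.25 * (1 - 0.52))
  expect_error(gene_diversity(c(1L)), "n < 2")
})

planar_table <- function(df) {
  class(df) <- c("frequency_table", "data.frame")
  df
}

test_that("a constant field kriges to the constant everywhere", {
  tab <- planar_table(data.frame(
    latitude = c(0, 0, 1, 1), longitude = c(0, 1, 0, 1),
    frequency = rep(42, 4L)))
  surf <- krige(tab, grid_spec = list(latitude = seq(0, 1, 0.5),
                                      longitude = seq(0, 1, 0.5)),
                variogram_spec = list(model = "linear", nugget = 0,
                                      sill = 1, range = 1),
                distance = "planar")
  expect_equal(surf$grid$value, rep(42, 9L), tolerance = 1e-10)
  expect_equal(surf$grid$weight_sum, rep(1, 9L), tolerance = 1e-10)
})

test_that("kriging is exact at observations when the nugget is zero", {
  set.seed(3)
  tab <- planar_table(data.frame(
    latitude = runif(6, 0, 10), longitude = runif(6, 0, 10),
    frequency = runif(6, 5, 60)))
  surf <- krige(tab, grid_spec = list(latitude = tab$latitude,
                                      longitude = tab$longitude),
                variogram_spec = list(model = "exponential", nugget = 0,
                                      sill = 20, range = 5),
                distance = "planar")
  at_obs <- merge(surf$grid, tab, by = c("latitude", "longitude"))
  expect_equal(at_obs$value, at_obs$frequency, tolerance = 1e-8)
  expect_equal(surf$grid$weight_sum, rep(1, nrow(surf$grid)),
               tolerance = 1e-10)
})

test_that("the midpoint of two observations averages them under a linear variogram", {
  tab <- planar_table(data.frame(latitude = c(0, 0), longitude = c(0, 10),
                                 frequency = c(20, 60)))
  surf <- krige(tab, grid_spec = list(latitude = 0, longitude = 5),
                variogram_spec = list(model = "linear", nugget = 0,
                                      sill = 1, range = 1),
                distance = "planar")
  # by symmetry of the 3x3 ordinary-kriging system the weights are 1/2, 1/2
  expect_equal(surf$grid$value, 40, tolerance = 1e-10)
})

test_that("surfaces are invariant under translation of all coordinates", {
  set.seed(9)
  base <- data.frame(latitude = runif(5, 0, 5), longitude = runif(5, 0, 5),
                     frequency = runif(5, 0, 50))
  spec <- list(model = "spherical", nugget = 0.5, sill = 30, range = 6)
  g1 <- krige(planar_table(base),
              grid_spec = list(latitude = 1:3, longitude = 1:3),
              variogram_spec = spec, distance = "planar")
  shifted <- base
  shifted$latitude <- shifted$latitude + 100
  g2 <- krige(planar_table(shifted),
              grid_spec = list(latitude = 1:3 + 100, longitude = 1:3),
              variogram_spec = spec, distance = "planar")
  expect_equal(g1$grid$value, g2$grid$value, tolerance = 1e-8)
})

test_that("predictions are clipped to the frequency scale", {
  tab <- planar_table(data.frame(latitude = c(0, 1, 2), longitude = c(0, 0, 0),
                                 frequency = c(0, 0, 100)))
  spec <- list(model = "spherical", nugget = 0, sill = 50, range = 1.5)
  grid <- list(latitude = seq(-2, 6, 0.25), longitude = 0)
  raw <- krige(tab, grid_spec = grid, variogram_spec = spec,
               distance = "planar", clip = FALSE)
  expect_lt(min(raw$grid$value), 0)  # screening produces negative weights
  expect_message(
    surf <- krige(tab, grid_spec = grid, variogram_spec = spec,
                  distance = "planar"),
    "clipped")
  expect_true(all(surf$grid$value >= 0 & surf$grid$value <= 100))
})

test_that("conflicting duplicate coordinates are rejected", {
  tab <- planar_table(data.frame(latitude = c(0, 0), longitude = c(0, 0),
                                 frequency = c(10, 20)))
  expect_error(krige(tab, grid_spec = list(latitude = 1, longitude = 1),
                     variogram_spec = list(model = "linear", nugget = 0,
                                           sill = 1, range = 1),
                     distance = "planar"),
               "conflicting")
})

test_that("variogram fitting recovers a clean linear trend", {
  set.seed(11)
  emp <- data.frame(dist = 1:10, gamma = 2 * (1:10), n_pairs = rep(20L, 10L))
  fit <- fit_variogram(emp, "linear")
  expect_equal(fit$sill / fit$range, 2, tolerance = 0.05)
  expect_lt(fit$nugget, 0.2)
})

test_that("haversine distances are used for degree coordinates", {
  # two points one degree of longitude apart at the equator: ~111 km
  d <- mitophylo:::pair_distances(c(0, 0), c(0, 1), "haversine")
  expect_equal(d[1, 2], 111.2, tolerance = 0.01)
})
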