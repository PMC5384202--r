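#' Tabulate haplogroup frequencies per population
#'
#' Counts carriers of a clade (including its subclades, recognised by name
#' nesting or, when a tree is given, by tree descent) in each population
#' and attaches coordinates.
#'
#' @param assignments data frame with `sample_id` and `clade` (as from
#'   [assign_all()]).
#' @param metadata data frame with `sample_id`, `population` and population
#'   coordinates (`latitude`, `longitude`).
#' @param clade clade whose carriers to count.
#' @param tree optional named `haplogroup_tree`; when supplied, descent is
#'   read off the tree instead of name prefixes.
#' @param min_n populations sampled below this floor are flagged.
#' @return data frame of class `frequency_table`: `population`, `latitude`,
#'   `longitude`, `n_sampled`, `n_carrier`, `frequency` (percent),
#'   `low_sample` flag.
#' @export
tabulate_frequencies <- function(assignments, metadata, clade, tree = NULL,
                                 min_n = 5L) {
  stopifnot(all(c("sample_id", "clade") %in% names(assignments)))
  hit <- match(assignments$sample_id, metadata$sample_id)
  if (anyNA(hit)) {
    stop("assignments reference unknown sample(s): ",
         paste(utils::head(assignments$sample_id[is.na(hit)], 5L), collapse = ", "))
  }
  pop <- metadata$population[hit]
  if (anyNA(pop)) stop("samples without population label")
  carrier_clades <- if (!is.null(tree)) {
    node <- node_of_clade(tree, clade)
    stats::na.omit(tree$clade[subtree_nodes(tree, node)])
  } else NULL
  is_carrier <- vapply(assignments$clade, function(cl) {
    if (cl == "unassigned") return(FALSE)
    if (!is.null(carrier_clades)) cl %in% carrier_clades
    else cl == clade || startsWith(cl, clade)
  }, TRUE, USE.NAMES = FALSE)
  pops <- sort(unique(metadata$population))
  rows <- lapply(pops, function(p) {
    idx <- pop == p
    md <- metadata[metadata$population == p, , drop = FALSE]
    n <- sum(idx); k <- sum(is_carrier & idx)
    data.frame(population = p,
               latitude = md$latitude[1], longitude = md$longitude[1],
               n_sampled = n, n_carrier = k, frequency = 100 * k / n,
               low_sample = n < min_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Gene (haplotype) diversity
#'
#' `H = n/(n-1) * (1 - sum p_i^2)`: the probability that two haplotypes
#' drawn at random from the sample differ, with the small-sample
#' correction.
#'
#' @param counts vector of haplotype counts (sum >= 2).
#' @return diversity in `[0, 1]`.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("gene diversity undefined for n < 2")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

variogram_models <- c("spherical", "exponential", "linear")

model_gamma <- function(h, model, nugget, sill, range) {
  base <- switch(model,
    spherical = ifelse(h >= range, sill,
                       sill * (1.5 * h / range - 0.5 * (h / range)^3)),
    exponential = sill * (1 - exp(-h / range)),
    linear = (sill / range) * h
  )
  ifelse(h == 0, 0, nugget + base)
}

#' Empirical semivariogram
#'
#' Bins squared half-differences of observed values by pairwise distance.
#'
#' @param table a `frequency_table` (or data frame with `latitude`,
#'   `longitude` and a value column).
#' @param value column name holding the observed values.
#' @param n_bins number of distance bins.
#' @param cutoff maximum pair distance (default: one third of the maximum).
#' @param distance `"haversine"` (great-circle km on degree input) or
#'   `"planar"` (Euclidean on raw coordinates, for synthetic tests).
#' @return data frame with `dist` (bin centre), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(table, value = "frequency", n_bins = 12L,
                                cutoff = NULL,
                                distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  D <- pair_distances(table$latitude, table$longitude, distance)
  z <- table[[value]]
  ij <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[ij]
  g <- 0.5 * (z[ij[, 1L]] - z[ij[, 2L]])^2
  if (is.null(cutoff)) cutoff <- max(h) / 3
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  if (!length(h)) stop("no point pairs within the cutoff")
  bins <- cut(h, breaks = seq(0, cutoff, length.out = n_bins + 1L),
              include.lowest = TRUE)
  data.frame(
    dist = tapply(h, bins, mean),
    gamma = tapply(g, bins, mean),
    n_pairs = as.integer(table(bins))
  )[stats::complete.cases(tapply(h, bins, mean)), ]
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises `sum N_h (gamma_hat - gamma_model)^2` over the model
#' parameters (nugget, partial sill, range — slope for the linear model).
#'
#' @param emp empirical variogram from [empirical_variogram()].
#' @param model `"spherical"`, `"exponential"` or `"linear"`.
#' @return list `(model, nugget, sill, range)` usable as `variogram_spec`
#'   in [krige()].
#' @export
fit_variogram <- function(emp, model = c("spherical", "exponential", "linear")) {
  model <- match.arg(model)
  obj <- function(par) {
    nug <- abs(par[1L]); sill <- abs(par[2L]); rng <- abs(par[3L])
    if (rng <= 0) return(1e12)
    gm <- model_gamma(emp$dist, model, nug, sill, rng)
    sum(emp$n_pairs * (emp$gamma - gm)^2)
  }
  start <- c(0, max(emp$gamma), max(emp$dist))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000L))
  list(model = model, nugget = abs(fit$par[1L]), sill = abs(fit$par[2L]),
       range = abs(fit$par[3L]))
}

pair_distances <- function(lat, lon, distance) {
  if (distance == "haversine") {
    geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  } else {
    as.matrix(stats::dist(cbind(lon, lat)))
  }
}

cross_distances <- function(lat1, lon1, lat2, lon2, distance) {
  if (distance == "haversine") {
    geosphere::distm(cbind(lon1, lat1), cbind(lon2, lat2),
                     fun = geosphere::distHaversine) / 1000
  } else {
    p1 <- cbind(lon1, lat1); p2 <- cbind(lon2, lat2)
    t(apply(p1, 1L, function(a) sqrt(colSums((t(p2) - a)^2))))
  }
}

#' Ordinary kriging of a frequency table
#'
#' Interpolates observed frequencies onto a geographic grid by ordinary
#' kriging: at each grid node the weights solve the semivariogram system
#' under the unbiasedness constraint (weights sum to 1).  With a zero
#' nugget the surface passes exactly through the observations.  Predictions
#' are clipped to `[0, 100]` (with a message when clipping occurs).
#'
#' @param table a `frequency_table`.
#' @param grid_spec list with `latitude` and `longitude` vectors defining
#'   the grid axes, or `NULL` for an automatic grid over the bounding box
#'   (`n` controls resolution, default 25 per axis).
#' @param variogram_spec list `(model, nugget, sill, range)` as from
#'   [fit_variogram()], or a model name to fit automatically.
#' @param value column of `table` to interpolate.
#' @param distance `"haversine"` or `"planar"` (see
#'   [empirical_variogram()]).
#' @param clip clip predictions to `[0, 100]`.
#' @return object of class `frequency_surface`: data frame `grid`
#'   (`latitude`, `longitude`, `value`), `variogram`, plus the observation
#'   table.
#' @export
krige <- function(table, grid_spec = NULL, variogram_spec = "spherical",
                  value = "frequency", distance = c("haversine", "planar"),
                  clip = TRUE) {
  distance <- match.arg(distance)
  lat <- table$latitude; lon <- table$longitude; z <- table[[value]]
  if (length(z) < 2L) stop("kriging needs at least two observations")
  D <- pair_distances(lat, lon, distance)
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup)) {
    if (any(z[dup[, 1L]] != z[dup[, 2L]])) {
      stop("duplicate coordinates with conflicting values")
    }
    keep <- !duplicated(cbind(lat, lon))
    lat <- lat[keep]; lon <- lon[keep]; z <- z[keep]
    D <- pair_distances(lat, lon, distance)
  }
  if (is.character(variogram_spec)) {
    if (!variogram_spec %in% variogram_models) {
      stop("unknown variogram model: ", variogram_spec)
    }
    emp <- empirical_variogram(data.frame(latitude = lat, longitude = lon,
                                          frequency = z),
                               value = "frequency", distance = distance)
    variogram_spec <- fit_variogram(emp, variogram_spec)
  }
  vs <- variogram_spec
  if (!vs$model %in% variogram_models) stop("unknown variogram model: ", vs$model)
  if (is.null(grid_spec)) {
    grid_spec <- list(latitude = seq(min(lat), max(lat), length.out = 25L),
                      longitude = seq(min(lon), max(lon), length.out = 25L))
  }
  grid <- expand.grid(latitude = grid_spec$latitude,
                      longitude = grid_spec$longitude,
                      KEEP.OUT.ATTRS = FALSE)
  n <- length(z)
  G <- model_gamma(D, vs$model, vs$nugget, vs$sill, vs$range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("singular kriging system (co-located or collinear points); ",
         "consider a positive nugget")
  })
  D0 <- cross_distances(grid$latitude, grid$longitude, lat, lon, distance)
  preds <- numeric(nrow(grid))
  wsums <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g0 <- model_gamma(D0[i, ], vs$model, vs$nugget, vs$sill, vs$range)
    # a grid node on top of an observation: exact interpolation when the
    # nugget is zero
    hit <- which(D0[i, ] == 0)
    sol <- Ainv %*% c(g0, 1)
    w <- sol[seq_len(n)]
    preds[i] <- sum(w * z)
    wsums[i] <- sum(w)
    if (length(hit) && vs$nugget == 0) preds[i] <- z[hit[1L]]
  }
  if (clip) {
    n_clip <- sum(preds < 0 | preds > 100)
    if (n_clip) message("clipped ", n_clip, " kriging prediction(s) to [0, 100]")
    preds <- pmin(pmax(preds, 0), 100)
  }
  structure(
    list(grid = cbind(grid, value = preds, weight_sum = wsums),
         variogram = vs,
         observations = data.frame(latitude = lat, longitude = lon, value = z),
         distance = distance),
    class = "frequency_surface"
  )
}

#' @export
print.frequency_surface <- function(x, ...) {
  cat("<frequency_surface>", nrow(x$grid), "grid nodes,",
      nrow(x$observations), "observations\n")
  cat(sprintf("  variogram: %s (nugget %.3g, sill %.3g, range %.3g)\n",
              x$variogram$model, x$variogram$nugget, x$variogram$sill,
              x$variogram$range))
  invisible(x)
}

#' Write a frequency table or surface as TSV
#' @param x a `frequency_table` or `frequency_surface`.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_frequency_tsv <- function(x, path) {
  tab <- if (inherits(x, "frequency_surface")) x$grid else x
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency table
#' @param path TSV with `population`, `latitude`, `longitude`, `n_sampled`,
#'   `n_carrier` and/or `frequency`.
#' @return a `frequency_table`.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"frequency" %in% names(tab)) {
    if (!all(c("n_sampled", "n_carrier") %in% names(tab))) {
      stop("frequency table needs `frequency` or counts")
    }
    tab$frequency <- 100 * tab$n_carrier / tab$n_sampled
  }
  if (all(c("n_sampled", "n_carrier") %in% names(tab)) &&
      any(tab$n_carrier > tab$n_sampled | tab$n_carrier < 0)) {
    stop("carrier counts out of range")
  }
  class(tab) <- c("frequency_table", "data.frame")
  tab
}
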