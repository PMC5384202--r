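#' Assemble a pipeline run configuration
#'
#' A run configuration names the inputs (reference FASTA, BED-like
#' annotation, sample FASTA, metadata TSV), the output directory, the clock
#' and kriging settings and the master seed.  It can be given as a list or
#' a YAML file; unknown keys are rejected so typos fail early.
#'
#' @param config list or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "mitophylo_out",
    reference_fasta = NULL, annotation_bed = NULL,
    sample_fasta = NULL, metadata_tsv = NULL,
    correction_table = NULL,
    root_name = "U",
    clock = list(mu = average_rates(1.665e-8, 1.708e-8), L_effective = NULL),
    control_region = NULL,
    site_weights = NULL,
    kriging = list(model = "spherical", distance = "haversine",
                   clade = NULL, min_n = 5L, grid_n = 25L),
    skyline_tsv = NULL,
    simulation = list(),
    seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (key in c("reference_fasta", "annotation_bed", "sample_fasta",
                "metadata_tsv", "correction_table", "skyline_tsv")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) stop("config file not found: ", key, " = ", p)
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- artifact(cfg, name)
  if (!file.exists(p)) {
    stop("missing prerequisite artifact ", sQuote(name),
         "; run stage ", sQuote(producer), " first")
  }
  p
}

load_reference <- function(cfg) {
  if (is.null(cfg$reference_fasta) || is.null(cfg$annotation_bed)) {
    stop("config must name reference_fasta and annotation_bed")
  }
  recs <- read_sample_fasta(cfg$reference_fasta)
  ann <- read_annotation_bed(cfg$annotation_bed)
  ref <- reference_system(recs[[1]]$sequence, ann, name = recs[[1]]$sample_id)
  ctrl <- ann[ann$partition == "control", c("start", "end")]
  if (nrow(ctrl)) attr(ref, "control_interval") <- as_intervals(ctrl)
  ref
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end with one master seed and a manifest
#' of every file written (path, md5, producing stage).  Stages:
#' `simulate` (synthetic survey), `score` (profiles from FASTA), `tree`
#' (maximum-parsimony haplogroup tree, motifs, newick), `assign`
#' (haplogroup assignment report), `date` (rho ages per named clade),
#' `skyline` (time-axis rescaling of a skyline export), `map` (frequency
#' table and kriged surface) and `all` (score through map).
#'
#' @param stage one of the stage names above.
#' @param config a `run_config`, list, or YAML path.
#' @param seed overrides the config seed when given.
#' @return invisibly, the manifest (data frame of written artifacts).
#' @export
run_pipeline <- function(stage = c("all", "simulate", "score", "tree",
                                   "assign", "date", "skyline", "map"),
                         config = list(), seed = NULL) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") c("score", "tree", "assign", "date", "map") else stage
  written <- character()
  for (st in stages) {
    written <- c(written, switch(st,
      simulate = stage_simulate(cfg),
      score = stage_score(cfg),
      tree = stage_tree(cfg),
      assign = stage_assign(cfg),
      date = stage_date(cfg),
      skyline = stage_skyline(cfg),
      map = stage_map(cfg)
    ))
  }
  manifest <- data.frame(
    path = written,
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE
  )
  info <- list(seed = cfg$seed, package = "mitophylo",
               version = as.character(utils::packageVersion("mitophylo")),
               stages = stages,
               artifacts = stats::setNames(as.list(manifest$md5), manifest$path))
  jsonlite::write_json(info, artifact(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(cfg) {
  sim <- simulate_study(cfg$simulation, seed = cfg$seed)
  paths <- write_simulated_study(sim, file.path(cfg$out_dir, "sim"))
  unname(paths)
}

stage_score <- function(cfg) {
  ref <- load_reference(cfg)
  md <- read_metadata(cfg$metadata_tsv)
  recs <- read_sample_fasta(cfg$sample_fasta, metadata = md, ref = ref)
  profiles <- lapply(recs, score_against_reference, ref = ref)
  out <- artifact(cfg, "profiles.tsv")
  write_profiles(profiles, out)
  out
}

stage_tree <- function(cfg) {
  ref <- load_reference(cfg)
  profs <- read_profiles(require_artifact(cfg, "profiles.tsv", "score"), ref$length)
  complete <- Filter(function(p) !p$partial, profs)
  tree <- build_mp_tree(complete, weights = cfg$site_weights)
  tree <- name_clades(tree, cfg$root_name)
  motifs <- extract_motifs(tree)
  saveRDS(tree, artifact(cfg, "tree.rds"))
  nwk <- artifact(cfg, "tree.nwk"); mot <- artifact(cfg, "motifs.tsv")
  write_newick(tree, nwk)
  write_motif_table(motifs, mot)
  c(artifact(cfg, "tree.rds"), nwk, mot)
}

stage_assign <- function(cfg) {
  ref <- load_reference(cfg)
  tree <- readRDS(require_artifact(cfg, "tree.rds", "tree"))
  motifs <- read_motif_table(require_artifact(cfg, "motifs.tsv", "tree"))
  profs <- read_profiles(require_artifact(cfg, "profiles.tsv", "score"), ref$length)
  report <- assign_all(profs, motifs, tree)
  out <- artifact(cfg, "assignments.tsv")
  utils::write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

stage_date <- function(cfg) {
  ref <- load_reference(cfg)
  tree <- readRDS(require_artifact(cfg, "tree.rds", "tree"))
  correction <- if (!is.null(cfg$correction_table)) {
    correction_from_table(cfg$correction_table)
  } else identity_correction()
  L_eff <- if (is.null(cfg$clock$L_effective)) ref$length else cfg$clock$L_effective
  clock <- clock_model("complete", mu = cfg$clock$mu, L_effective = L_eff,
                       correction = correction)
  motifs <- extract_motifs(tree)
  named <- names(motifs)
  ages <- list()
  for (cl in named) {
    node <- node_of_clade(tree, cl)
    if (length(tips_below(tree, node)) < 2L) next
    ages[[cl]] <- list(rho_to_age(compute_rho(tree, cl), clock))
  }
  out <- artifact(cfg, "ages.tsv")
  write_age_table(ages, out, motifs = motifs)
  out
}

stage_skyline <- function(cfg) {
  if (is.null(cfg$skyline_tsv)) stop("config must name skyline_tsv")
  track <- read_skyline(cfg$skyline_tsv)
  correction <- if (!is.null(cfg$correction_table)) {
    correction_from_table(cfg$correction_table)
  } else identity_correction()
  out <- artifact(cfg, "skyline_corrected.tsv")
  write_skyline(correct_timescale(track, correction), out)
  out
}

stage_map <- function(cfg) {
  assign_path <- require_artifact(cfg, "assignments.tsv", "assign")
  assignments <- utils::read.delim(assign_path, stringsAsFactors = FALSE)
  md <- read_metadata(cfg$metadata_tsv)
  clade <- if (is.null(cfg$kriging$clade)) cfg$root_name else cfg$kriging$clade
  tab <- tabulate_frequencies(assignments, md, clade, min_n = cfg$kriging$min_n)
  surf <- krige(tab, variogram_spec = cfg$kriging$model,
                distance = cfg$kriging$distance)
  f_out <- artifact(cfg, paste0("frequencies_", clade, ".tsv"))
  s_out <- artifact(cfg, paste0("surface_", clade, ".tsv"))
  write_frequency_tsv(tab, f_out)
  write_frequency_tsv(surf, s_out)
  c(f_out, s_out)
}
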