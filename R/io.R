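#' Read sample sequences from a FASTA file
#'
#' Sequences are assumed pre-aligned to reference coordinates (the standard
#' mitogenome convention: equal length, indels encoded in the alignment).
#' FASTA headers carry sample ids; optional metadata attaches population,
#' region, coordinates and the sequenced coverage.
#'
#' @param path FASTA file path.
#' @param metadata optional data frame from [read_metadata()].
#' @param ref optional `reference_system`; when given, complete sequences are
#'   checked against the reference length.
#' @return list of `sample_record` objects: `sample_id`, `sequence`
#'   (uppercase string), `covered_range` (interval matrix), `population`,
#'   `region`, `latitude`, `longitude`.
#' @export
read_sample_fasta <- function(path, metadata = NULL, ref = NULL) {
  dna <- ape::read.FASTA(path)
  ids <- names(dna)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(as.character(dna), function(x) toupper(paste(x, collapse = "")), "")
  records <- vector("list", length(ids))
  offenders <- character()
  for (i in seq_along(ids)) {
    md <- NULL
    if (!is.null(metadata) && ids[i] %in% metadata$sample_id) {
      md <- metadata[metadata$sample_id == ids[i], , drop = FALSE]
    }
    covered <- if (!is.null(md) && "covered_range" %in% names(md) &&
                   nzchar(md$covered_range[1]) && !is.na(md$covered_range[1])) {
      parse_intervals(md$covered_range[1])
    } else {
      full_interval(nchar(seqs[i]))
    }
    if (!is.null(ref) && interval_width(covered) == ref$length &&
        nchar(seqs[i]) != ref$length) {
      offenders <- c(offenders, ids[i])
    }
    records[[i]] <- sample_record(
      sample_id = ids[i], sequence = seqs[i], covered_range = covered,
      population = if (!is.null(md)) md$population[1] else NA_character_,
      region = if (!is.null(md)) md$region[1] else NA_character_,
      latitude = if (!is.null(md) && "latitude" %in% names(md)) md$latitude[1] else NA_real_,
      longitude = if (!is.null(md) && "longitude" %in% names(md)) md$longitude[1] else NA_real_
    )
  }
  if (length(offenders)) {
    stop("complete-genome sequences with length != reference length: ",
         paste(offenders, collapse = ", "))
  }
  records
}

#' Construct a sample record
#'
#' @param sample_id sample identifier.
#' @param sequence nucleotide string (or `NA` when only variant calls exist).
#' @param covered_range interval set actually sequenced (1-based closed).
#' @param population,region labels.
#' @param latitude,longitude decimal degrees.
#' @return object of class `sample_record`.
#' @export
sample_record <- function(sample_id, sequence = NA_character_,
                          covered_range = NULL, population = NA_character_,
                          region = NA_character_, latitude = NA_real_,
                          longitude = NA_real_) {
  covered <- as_intervals(covered_range)
  if (!is.na(latitude) && (latitude < -90 || latitude > 90)) {
    stop("latitude out of range for ", sample_id)
  }
  if (!is.na(longitude) && (longitude < -180 || longitude > 180)) {
    stop("longitude out of range for ", sample_id)
  }
  structure(
    list(sample_id = sample_id, sequence = sequence,
         covered_range = covered, population = population, region = region,
         latitude = latitude, longitude = longitude),
    class = "sample_record"
  )
}

#' Write sample records to FASTA
#'
#' @param records list of `sample_record`s (with sequences).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sample_fasta <- function(records, path) {
  seqs <- lapply(records, function(r) strsplit(tolower(r$sequence), "")[[1]])
  names(seqs) <- vapply(records, function(r) r$sample_id, "")
  ape::write.FASTA(ape::as.DNAbin(seqs), path)
  invisible(path)
}

#' Merge sample collections
#'
#' Combines newly sequenced records with literature records into one input
#' set for tree building, refusing duplicate sample ids.
#'
#' @param ... lists of `sample_record`s.
#' @return one combined list.
#' @export
merge_sample_sets <- function(...) {
  combined <- c(...)
  ids <- vapply(combined, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids across collections: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  combined
}

#' Read a sample metadata table
#'
#' Tab-separated with header; requires `sample_id` and `population`, and
#' uses `region`, `latitude`, `longitude` and `covered_range`
#' (`"start-end;start-end"`) when present.
#'
#' @param path TSV path.
#' @return data frame keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  if ("latitude" %in% names(tab) &&
      any(!is.na(tab$latitude) & abs(tab$latitude) > 90)) {
    stop("latitude out of [-90, 90]")
  }
  if ("longitude" %in% names(tab) &&
      any(!is.na(tab$longitude) & abs(tab$longitude) > 180)) {
    stop("longitude out of [-180, 180]")
  }
  tab
}

#' Write a sample metadata table
#' @param metadata data frame as returned by [read_metadata()].
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clade-motif table
#'
#' Two-column tab-separated table (clade, defining mutations separated by
#' commas or spaces), the shape of the usual "defining mutations" tables in
#' haplogroup surveys.
#'
#' @param path TSV path (no header, or header `clade<TAB>motif`).
#' @return named list mapping clade name to a character vector of canonical
#'   variant labels.
#' @export
read_motif_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^clade\t", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  out <- list()
  for (ln in lines) {
    if (!grepl("\t", ln)) stop("motif table row without motif column: ", sQuote(ln))
    f <- strsplit(ln, "\t")[[1]]
    # an empty motif is legal: a root clade identical to the reference
    labels <- if (length(f) < 2L) character() else {
      strsplit(trimws(f[2]), "[,[:space:]]+")[[1]]
    }
    labels <- labels[nzchar(labels)]
    out[[f[1]]] <- parse_variant_label(labels)$label
  }
  out
}

#' Write a clade-motif table
#' @param motifs named list of variant-label vectors.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_motif_table <- function(motifs, path) {
  lines <- c("clade\tmotif",
             vapply(names(motifs), function(nm) {
               paste0(nm, "\t", paste(motifs[[nm]], collapse = ", "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export a partitioned alignment as NEXUS
#'
#' Writes the alignment together with one `charset` per genome partition
#' (control region, rRNA+tRNA, codon positions 1-3, other), the input layout
#' expected by partitioned phylodynamic analyses.  Only partitions present in
#' the annotation are emitted; their site counts always sum to the reference
#' length.
#'
#' @param records list of `sample_record`s with full-length sequences.
#' @param ref a `reference_system`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_nexus_partitioned <- function(records, ref, path) {
  stopifnot(inherits(ref, "reference_system"))
  ids <- vapply(records, function(r) r$sample_id, "")
  seqs <- vapply(records, function(r) r$sequence, "")
  if (any(nchar(seqs) != ref$length)) {
    stop("all sequences must match the reference length for NEXUS export")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(ids), ref$length),
    "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
    "  MATRIX"
  ), con)
  writeLines(sprintf("    %s  %s", ids, seqs), con)
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  for (p in PARTITIONS) {
    pos <- which(ref$partition == p)
    if (!length(pos)) next
    runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
    spans <- vapply(runs, function(r) {
      if (length(r) == 1L) as.character(r[1]) else paste0(r[1], "-", r[length(r)])
    }, "")
    writeLines(sprintf("  CHARSET %s = %s;", p, paste(spans, collapse = " ")), con)
  }
  writeLines("END;", con)
  invisible(path)
}

#' Serialize haplotype profiles to TSV
#'
#' Columns: `sample_id`, comma-joined variant labels, covered intervals.
#'
#' @param profiles list of `haplotype_profile`s.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_profiles <- function(profiles, path) {
  lines <- c("sample_id\tvariants\tcovered_range",
             vapply(profiles, function(p) {
               paste(p$sample_id, paste(p$variants, collapse = ","),
                     format_intervals(p$covered_range), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read haplotype profiles from TSV
#' @param path TSV path written by [write_profiles()].
#' @param L reference length, used to flag partial coverage.
#' @return list of `haplotype_profile`s.
#' @export
read_profiles <- function(path, L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  lapply(seq_len(nrow(tab)), function(i) {
    labels <- strsplit(tab$variants[i], ",")[[1]]
    labels <- labels[nzchar(labels)]
    haplotype_profile(tab$sample_id[i], labels,
                      parse_intervals(tab$covered_range[i]), L = L)
  })
}
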