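#' Construct a haplotype profile
#'
#' A haplotype profile is a sample's set of variants relative to the
#' reference, together with the genomic intervals actually sequenced.
#'
#' @param sample_id sample identifier.
#' @param variants character vector of canonical variant labels.
#' @param covered_range interval set (1-based closed); defaults to `1..L`.
#' @param L reference length.
#' @return object of class `haplotype_profile` with fields `sample_id`,
#'   `variants` (position-sorted labels), `covered_range` and `partial`.
#' @export
haplotype_profile <- function(sample_id, variants = character(),
                              covered_range = NULL, L) {
  covered <- if (is.null(covered_range)) full_interval(L) else as_intervals(covered_range)
  if (nrow(covered) && (covered[1, 1] < 1L || covered[nrow(covered), 2] > L)) {
    stop("covered_range outside 1..", L)
  }
  variants <- sort_variant_labels(unique(variants))
  if (length(variants)) {
    v <- parse_variant_label(variants)
    sub <- v$kind %in% c("transition", "transversion", "deletion")
    if (anyDuplicated(v$position[sub])) {
      stop("more than one substitution at a position for ", sample_id)
    }
    if (!all(positions_in_intervals(v$position, covered))) {
      stop("variant positions outside covered_range for ", sample_id)
    }
  }
  structure(
    list(sample_id = sample_id, variants = variants, covered_range = covered,
         partial = interval_width(covered) < L, L = L),
    class = "haplotype_profile"
  )
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat("<haplotype_profile>", x$sample_id,
      if (x$partial) "(partial)" else "(complete)", "\n")
  cat("  variants:", if (length(x$variants)) paste(x$variants, collapse = " ") else "(none)", "\n")
  cat("  covered:", format_intervals(x$covered_range), "\n")
  invisible(x)
}

#' Score a sample sequence against the reference
#'
#' Position-by-position comparison over the sequenced range.  Sites holding
#' `N` in either sequence are skipped; an alignment gap (`-`) in the sample
#' is scored as a deletion; ambiguity codes other than `N` are rejected.
#' Input sequences must be pre-aligned to reference coordinates (equal
#' length), the standard convention for mitogenome data.
#'
#' @param record a `sample_record` with a sequence.
#' @param ref a `reference_system`.
#' @return a `haplotype_profile`.
#' @export
score_against_reference <- function(record, ref) {
  stopifnot(inherits(record, "sample_record"), inherits(ref, "reference_system"))
  if (is.na(record$sequence)) stop("record ", record$sample_id, " has no sequence")
  seq_chars <- strsplit(toupper(record$sequence), "")[[1]]
  covered <- record$covered_range
  if (nrow(covered) == 0L) covered <- full_interval(ref$length)
  if (length(seq_chars) != ref$length) {
    if (interval_width(covered) == ref$length) {
      stop("sequence length ", length(seq_chars), " != reference length ",
           ref$length, " for ", record$sample_id,
           " and no covered_range given")
    }
    if (length(seq_chars) != interval_width(covered)) {
      stop("sequence length does not match covered_range width for ",
           record$sample_id)
    }
    # expand a coverage-only sequence onto reference coordinates
    expanded <- rep("N", ref$length)
    pos <- unlist(apply(covered, 1L, function(r) r[1]:r[2], simplify = FALSE))
    expanded[pos] <- seq_chars
    seq_chars <- expanded
  }
  rc <- ref_chars(ref)
  idx <- which(positions_in_intervals(seq_len(ref$length), covered))
  smp <- seq_chars[idx]
  bad <- !smp %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad)) {
    stop("ambiguity codes other than N at positions ",
         paste(utils::head(idx[bad], 5L), collapse = ", "),
         " for ", record$sample_id)
  }
  usable <- smp != "N" & rc[idx] != "N"
  diff <- usable & smp != rc[idx]
  pos <- idx[diff]
  labels <- character(length(pos))
  if (length(pos)) {
    a <- rc[pos]; d <- smp[diff]
    is_del <- d == "-"
    labels[is_del] <- paste0(a[is_del], pos[is_del], "d")
    labels[!is_del] <- substitution_label(pos[!is_del], a[!is_del], d[!is_del])
  }
  haplotype_profile(record$sample_id, labels, covered, L = ref$length)
}

#' Reconstruct a sample sequence from a profile
#'
#' Applies a profile's substitutions and deletions to the reference over the
#' covered range; positions outside coverage are emitted as `N`.  The inverse
#' of [score_against_reference()] up to `N` sites.
#'
#' @param profile a `haplotype_profile`.
#' @param ref a `reference_system`.
#' @return nucleotide string of reference length.
#' @export
apply_profile <- function(profile, ref) {
  chars <- ref_chars(ref)
  if (length(profile$variants)) {
    v <- parse_variant_label(profile$variants)
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "insertion") next  # not representable in fixed coordinates
      chars[v$position[i]] <- if (v$kind[i] == "deletion") "-" else v$derived[i]
    }
  }
  outside <- !positions_in_intervals(seq_len(ref$length), profile$covered_range)
  chars[outside] <- "N"
  paste(chars, collapse = "")
}

#' Classify a variant by genome partition and coding effect
#'
#' Returns the partition label of the site and, for coding substitutions,
#' whether the change is synonymous under the vertebrate mitochondrial code
#' (the reference codon translated against the codon with the derived allele
#' substituted).
#'
#' @param v a single variant label or one-row `mito_variants` frame.
#' @param ref a `reference_system`.
#' @return list with `position`, `partition` and `synonymous` (`NA` outside
#'   coding partitions and for indels).
#' @export
classify_variant <- function(v, ref) {
  if (is.character(v)) v <- parse_variant_label(v)
  stopifnot(nrow(v) == 1L)
  pos <- v$position[1]
  if (pos < 1L || pos > ref$length) {
    stop("position ", pos, " outside reference 1..", ref$length)
  }
  part <- ref$partition[pos]
  syn <- NA
  if (part %in% c("codon1", "codon2", "codon3") &&
      v$kind[1] %in% c("transition", "transversion")) {
    idx <- codon_at(ref, pos)
    codon <- ref_chars(ref)[idx]
    if (!any(codon == "N")) {
      mutated <- codon
      mutated[match(pos, idx)] <- v$derived[1]
      aa_ref <- seqinr::translate(codon, numcode = 2)
      aa_alt <- seqinr::translate(mutated, numcode = 2)
      syn <- identical(aa_ref, aa_alt)
    }
  }
  list(position = pos, partition = part, synonymous = syn)
}

#' Restrict a profile to an interval set
#'
#' Drops variants outside the interval set and intersects the coverage,
#' yielding the profile that would have been observed had only those
#' intervals been sequenced (e.g. control-region-only data).
#'
#' @param profile a `haplotype_profile`.
#' @param interval_set intervals (matrix/data frame/length-2 vector).
#' @return restricted `haplotype_profile` (flagged partial unless the
#'   restriction covers the whole reference).
#' @export
restrict_profile <- function(profile, interval_set) {
  iv <- as_intervals(interval_set)
  if (nrow(iv) == 0L) stop("empty interval set")
  covered <- intersect_intervals(profile$covered_range, iv)
  keep <- if (length(profile$variants)) {
    positions_in_intervals(variant_positions(profile$variants), covered)
  } else logical(0)
  haplotype_profile(profile$sample_id, profile$variants[keep], covered,
                    L = profile$L)
}

#' Default control-region interval set
#'
#' The community-standard control-region bounds for the human mitogenome
#' (16024-16569 joined with 1-576 across the origin); for synthetic
#' references supply the generator's control interval instead.
#'
#' @param L reference length.
#' @return interval matrix.
#' @export
control_region_default <- function(L = 16569L) {
  if (L == 16569L) as_intervals(rbind(c(1L, 576L), c(16024L, 16569L)))
  else stop("no default control region for L = ", L,
            "; pass the annotation's control interval")
}
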