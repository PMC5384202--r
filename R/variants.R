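#' Parse PhyloTree-style variant labels
#'
#' Parses mutation labels written in the nomenclature used throughout the
#' mtDNA haplogroup literature: `T152C` is a transition (uppercase derived
#' allele), `A16318t` a transversion (lowercase derived allele), `573.1C`
#' an insertion (`.k` gives the ordinal of the inserted base) and `A249d`
#' a deletion (`d` suffix).  Heteroplasmy and ambiguity codes are rejected.
#'
#' The ancestral allele is mandatory for substitutions and deletions (the
#' label is otherwise ambiguous) and absent for insertions.
#'
#' @param label character vector of variant labels.
#' @return A data frame of class `mito_variants` with one row per label and
#'   columns `label` (canonical form), `position` (1-based site index),
#'   `ancestral`, `derived` (always uppercase; `"-"` for deletions), `kind`
#'   (one of `"transition"`, `"transversion"`, `"insertion"`, `"deletion"`)
#'   and `insertion_index` (0 unless an insertion).
#' @examples
#' parse_variant_label(c("T152C", "A16318t", "573.1C", "A249d"))
#' @seealso [format_variant()] for the inverse operation.
#' @export
parse_variant_label <- function(label) {
  stopifnot(is.character(label))
  if (length(label) == 0L) return(empty_variants())
  m <- regmatches(label, regexec("^([ACGT])?([0-9]+)(\\.([0-9]+))?([ACGTacgt]|d)$", label))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed variant label(s): ", paste(sQuote(label[bad]), collapse = ", "))
  }
  parts <- do.call(rbind, m)
  anc <- parts[, 2L]
  pos <- as.integer(parts[, 3L])
  idx <- ifelse(parts[, 5L] == "", 0L, suppressWarnings(as.integer(parts[, 5L])))
  tail <- parts[, 6L]
  if (any(pos < 1L)) stop("variant position must be >= 1: ", paste(label[pos < 1L], collapse = ", "))

  kind <- character(length(label))
  der <- character(length(label))
  is_ins <- idx > 0L
  is_del <- tail == "d"
  is_sub <- !is_ins & !is_del

  if (any(is_ins & is_del)) {
    stop("label cannot be both insertion and deletion: ",
         paste(sQuote(label[is_ins & is_del]), collapse = ", "))
  }
  if (any(is_del & anc == "")) {
    stop("deletion label missing ancestral allele: ",
         paste(sQuote(label[is_del & anc == ""]), collapse = ", "))
  }
  if (any(is_sub & anc == "")) {
    stop("substitution label missing ancestral allele: ",
         paste(sQuote(label[is_sub & anc == ""]), collapse = ", "))
  }
  if (any(is_ins & anc != "")) {
    stop("insertion label must not carry an ancestral allele: ",
         paste(sQuote(label[is_ins & anc != ""]), collapse = ", "))
  }

  kind[is_ins] <- "insertion"
  der[is_ins] <- toupper(tail[is_ins])
  kind[is_del] <- "deletion"
  der[is_del] <- "-"

  if (any(is_sub)) {
    a <- anc[is_sub]
    d_raw <- tail[is_sub]
    d <- toupper(d_raw)
    same <- a == d
    if (any(same)) {
      stop("ancestral and derived allele identical: ",
           paste(sQuote(label[is_sub][same]), collapse = ", "))
    }
    ts <- is_transition_pair(a, d)
    # case of the derived allele is notation for the substitution class and
    # must agree with the allele pair
    case_ok <- ifelse(ts, d_raw == d, d_raw == tolower(d_raw))
    if (any(!case_ok)) {
      stop("derived-allele case inconsistent with substitution class ",
           "(transitions uppercase, transversions lowercase): ",
           paste(sQuote(label[is_sub][!case_ok]), collapse = ", "))
    }
    kind[is_sub] <- ifelse(ts, "transition", "transversion")
    der[is_sub] <- d
  }

  anc[anc == ""] <- NA_character_
  out <- data.frame(
    label = label, position = pos, ancestral = anc, derived = der,
    kind = kind, insertion_index = idx, stringsAsFactors = FALSE
  )
  out$label <- format_variant(out)
  class(out) <- c("mito_variants", "data.frame")
  out
}

empty_variants <- function() {
  out <- data.frame(
    label = character(), position = integer(), ancestral = character(),
    derived = character(), kind = character(), insertion_index = integer(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mito_variants", "data.frame")
  out
}

is_transition_pair <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Format variants back into canonical labels
#'
#' Inverse of [parse_variant_label()]: transitions print an uppercase derived
#' allele, transversions a lowercase one, insertions `pos.kB`, deletions
#' `Aposd`.  `format_variant(parse_variant_label(x))` is the identity on
#' canonical labels.
#'
#' @param v a `mito_variants` data frame (or any data frame with the same
#'   columns).
#' @return character vector of canonical labels.
#' @export
format_variant <- function(v) {
  stopifnot(is.data.frame(v))
  if (nrow(v) == 0L) return(character())
  out <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    out[i] <- switch(v$kind[i],
      transition = paste0(v$ancestral[i], v$position[i], v$derived[i]),
      transversion = paste0(v$ancestral[i], v$position[i], tolower(v$derived[i])),
      insertion = paste0(v$position[i], ".", v$insertion_index[i], v$derived[i]),
      deletion = paste0(v$ancestral[i], v$position[i], "d"),
      stop("unknown variant kind: ", v$kind[i])
    )
  }
  out
}

#' Build a substitution label from alleles
#'
#' Convenience constructor used by the scoring engine: given position and
#' allele pair it derives the substitution class and emits the canonical
#' label.
#'
#' @param position 1-based site index.
#' @param ancestral,derived allele symbols (A/C/G/T).
#' @return character vector of canonical labels.
#' @export
substitution_label <- function(position, ancestral, derived) {
  ts <- is_transition_pair(ancestral, derived)
  ifelse(ts,
    paste0(ancestral, position, derived),
    paste0(ancestral, position, tolower(derived))
  )
}

variant_positions <- function(labels) {
  if (length(labels) == 0L) return(integer())
  parse_variant_label(labels)$position
}

# order labels by position, then insertion index, then label
sort_variant_labels <- function(labels) {
  if (length(labels) <= 1L) return(labels)
  v <- parse_variant_label(labels)
  labels[order(v$position, v$insertion_index, v$label)]
}
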