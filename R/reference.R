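PARTITIONS <- c("control", "rRNA_tRNA", "codon1", "codon2", "codon3", "other")

#' Construct a reference system
#'
#' A reference system bundles a (circular) reference mitogenome sequence with
#' a total partition annotation: every position carries exactly one label
#' among `control`, `rRNA_tRNA`, `codon1`, `codon2`, `codon3`, `other`.
#' Coding positions are labelled by codon position, so the codon containing
#' any coding site can be reconstructed from the annotation alone (forward
#' strand, contiguous codons).  Positions holding `N` in the sequence (such
#' as the placeholder at 3107 of the rCRS) are ignored during scoring.
#'
#' @param sequence single character string over A/C/G/T/N.
#' @param annotation data frame with columns `start`, `end` (1-based, closed)
#'   and `partition`; intervals must tile `1..L` without overlap (gaps are
#'   filled with `"other"`).
#' @param name identifier for the reference (e.g. `"rCRS"`, `"RSRS"`).
#' @return object of class `reference_system` with elements `sequence`
#'   (character string), `length`, `partition` (character vector of length L)
#'   and `name`.
#' @export
reference_system <- function(sequence, annotation, name = "reference") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("reference contains non-ACGTN symbols at positions: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  stopifnot(is.data.frame(annotation),
            all(c("start", "end", "partition") %in% names(annotation)))
  if (!all(annotation$partition %in% PARTITIONS)) {
    stop("unknown partition label(s): ",
         paste(setdiff(annotation$partition, PARTITIONS), collapse = ", "))
  }
  if (any(annotation$start < 1L | annotation$end > L | annotation$start > annotation$end)) {
    stop("annotation intervals must lie within 1..", L)
  }
  part <- rep(NA_character_, L)
  for (i in seq_len(nrow(annotation))) {
    idx <- annotation$start[i]:annotation$end[i]
    if (any(!is.na(part[idx]))) {
      stop("overlapping annotation intervals at interval ", i)
    }
    part[idx] <- annotation$partition[i]
  }
  part[is.na(part)] <- "other"
  structure(
    list(sequence = sequence, length = L, partition = part, name = name),
    class = "reference_system"
  )
}

#' @export
print.reference_system <- function(x, ...) {
  cat("<reference_system>", x$name, "-", x$length, "bp\n")
  print(table(x$partition))
  invisible(x)
}

#' Read a BED-like partition annotation
#'
#' Reads a 3+1 column BED-like file (`chrom`, `start`, `end`, `partition`;
#' 0-based half-open coordinates) and converts it to the 1-based closed
#' intervals used internally.
#'
#' @param path file path.
#' @return data frame with `start`, `end`, `partition` (1-based closed).
#' @export
read_annotation_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("annotation BED needs 4 columns (chrom, start, end, label)")
  data.frame(
    start = as.integer(tab[[2L]]) + 1L,
    end = as.integer(tab[[3L]]),
    partition = as.character(tab[[4L]]),
    stringsAsFactors = FALSE
  )
}

#' Write a BED-like partition annotation
#'
#' Emits maximal runs of equal partition labels as 0-based half-open
#' intervals; the inverse of [read_annotation_bed()] up to interval merging.
#'
#' @param ref a `reference_system`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_annotation_bed <- function(ref, path) {
  stopifnot(inherits(ref, "reference_system"))
  r <- rle(ref$partition)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tab <- data.frame(chrom = ref$name, start = starts - 1L, end = ends,
                    partition = r$values)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# positions (1-based) of the codon containing a coding site, using the
# codon-position labels; errors if the annotation is locally inconsistent
codon_at <- function(ref, position) {
  lab <- ref$partition[position]
  k <- match(lab, c("codon1", "codon2", "codon3"))
  if (is.na(k)) stop("position ", position, " is not a coding site")
  start <- position - (k - 1L)
  idx <- start:(start + 2L)
  if (idx[1L] < 1L || idx[3L] > ref$length ||
      !identical(ref$partition[idx], c("codon1", "codon2", "codon3"))) {
    stop("inconsistent codon annotation around position ", position)
  }
  idx
}

ref_chars <- function(ref) strsplit(ref$sequence, "")[[1]]
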