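# 1-based closed interval sets, stored as a 2-column integer matrix
# (start, end).  Used for sequenced coverage and region restrictions.

as_intervals <- function(x) {
  if (is.null(x)) return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.vector(x) && length(x) == 2L) x <- matrix(as.integer(x), ncol = 2L)
  x <- matrix(as.integer(x), ncol = 2L)
  colnames(x) <- c("start", "end")
  if (any(x[, 1L] > x[, 2L])) stop("interval start exceeds end")
  normalize_intervals(x)
}

normalize_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv[i, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

intersect_intervals <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  res <- matrix(integer(), ncol = 2L)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      s <- max(a[i, 1L], b[j, 1L]); e <- min(a[i, 2L], b[j, 2L])
      if (s <= e) res <- rbind(res, c(s, e))
    }
  }
  colnames(res) <- c("start", "end")
  if (nrow(res)) normalize_intervals(res) else res
}

positions_in_intervals <- function(pos, iv) {
  if (length(pos) == 0L) return(logical(0))
  iv <- as_intervals(iv)
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) out <- out | (pos >= iv[i, 1L] & pos <= iv[i, 2L])
  out
}

interval_width <- function(iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) == 0L) return(0L)
  sum(iv[, 2L] - iv[, 1L] + 1L)
}

format_intervals <- function(iv) {
  iv <- as_intervals(iv)
  paste(paste0(iv[, 1L], "-", iv[, 2L]), collapse = ";")
}

parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(as_intervals(NULL))
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  as_intervals(t(vapply(parts, function(p) as.integer(p[1:2]), integer(2L))))
}

full_interval <- function(L) as_intervals(c(1L, L))
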