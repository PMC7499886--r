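#' Per-base signal track
#'
#' A simple container for strand-summed per-base signal: one non-negative
#' finite numeric vector per chromosome.
#'
#' @param values named list of per-chromosome numeric vectors.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values) {
  stopifnot(is.list(values), length(names(values)) == length(values))
  for (v in values) stopifnot(is.numeric(v), all(is.finite(v)))
  structure(list(values = values,
                 chrom_lengths = vapply(values, length, integer(1))),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosome(s),",
      sum(x$chrom_lengths), "bp\n")
  invisible(x)
}

# render a normalized small RNA read table as a per-base point-mass track
# (mass at alignment start), optionally restricted to a read-length range
as_signal_track <- function(track, chrom_lengths, size_range = NULL) {
  stopifnot(inherits(track, "sirna_track"))
  reads <- track$reads
  if (!is.null(size_range))
    reads <- reads[reads$length >= size_range[1] & reads$length <= size_range[2], ]
  values <- lapply(names(chrom_lengths), function(ch) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    v <- numeric(max(chrom_lengths[[ch]],
                     if (nrow(r)) max(r$start) + 1L else 0L))
    if (nrow(r)) {
      m <- rowsum(r$rpm, r$start + 1L)
      v[as.integer(rownames(m))] <- m[, 1L]
    }
    v
  })
  names(values) <- names(chrom_lengths)
  signal_track(values)
}
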