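fmt_num <- function(x) formatC(x, format = "g", digits = 6)

#' Read a BED annotation
#'
#' Accepts BED3 or BED6 (0-based half-open). Malformed lines -- wrong column
#' count, non-numeric or inverted/empty coordinates -- are rejected with
#' their line numbers.
#'
#' @param path file path.
#' @return annotation data.frame: chrom, start, end, te_id, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L & nf != 6L))
    stop("malformed BED line(s) ",
         paste(lineno[nf != 3L & nf != 6L], collapse = ", "),
         ": expected 3 or 6 tab-separated fields")
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad))
    stop("invalid BED interval(s) at line(s) ",
         paste(lineno[bad], collapse = ", "),
         ": need numeric 0 <= start < end")
  has6 <- nf == 6L
  data.frame(chrom = chrom, start = start, end = end,
             te_id = ifelse(has6, vapply(parts, function(p) p[4L], ""),
                            paste0("region_", seq_along(parts))),
             score = ifelse(has6,
                            suppressWarnings(as.numeric(
                              vapply(parts, function(p) p[min(5L, length(p))], ""))),
                            0),
             strand = ifelse(has6, vapply(parts, function(p) p[min(6L, length(p))], ""),
                             "+"),
             stringsAsFactors = FALSE)
}

#' Write a BED6 annotation
#'
#' @param annotation data.frame with chrom, start, end, te_id and optionally
#'   score, strand.
#' @param path output path.
#' @export
write_bed <- function(annotation, path) {
  score <- if ("score" %in% names(annotation)) annotation$score else 0L
  strand <- if ("strand" %in% names(annotation)) annotation$strand else "+"
  ord <- order(annotation$chrom, annotation$start)
  writeLines(paste(annotation$chrom[ord], annotation$start[ord],
                   annotation$end[ord], annotation$te_id[ord],
                   score[ord], strand[ord], sep = "\t"), path)
  invisible(path)
}

#' Read an allc-style cytosine table
#'
#' Tab-separated columns: chrom, pos (1-based), strand, trinucleotide
#' context, mc, cov. Context and CHH subcontext are derived from the
#' trinucleotide. Lines with `mc > cov` are rejected with their position.
#'
#' @param path file path.
#' @return cytosine data.frame (chrom, pos, strand, context, subcontext,
#'   trinuc, mc, cov); empty file gives an empty table.
#' @export
read_allc <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      subcontext = character(), trinuc = character(),
                      mc = integer(), cov = integer(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty)
  d <- utils::read.table(text = lines, sep = "\t",
                         col.names = c("chrom", "pos", "strand", "trinuc",
                                       "mc", "cov"),
                         colClasses = c("character", "integer", "character",
                                       "character", "integer", "integer"))
  bad <- d$mc > d$cov | d$mc < 0 | d$cov < 0
  if (any(bad))
    stop("mc > cov at ", paste(paste0(d$chrom[bad], ":", d$pos[bad]),
                               collapse = ", "))
  ctx <- trinuc_context(d$trinuc)
  data.frame(chrom = d$chrom, pos = d$pos, strand = d$strand,
             context = ctx$context, subcontext = ctx$subcontext,
             trinuc = d$trinuc, mc = d$mc, cov = d$cov,
             stringsAsFactors = FALSE)
}

#' Write an allc-style cytosine table
#'
#' @param sites cytosine data.frame with chrom, pos, strand, trinuc, mc, cov.
#' @param path output path.
#' @export
write_allc <- function(sites, path) {
  ord <- order(sites$chrom, sites$pos, sites$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tcontext\tmc\tcov", con)
  if (nrow(sites))
    writeLines(paste(sites$chrom[ord], sites$pos[ord], sites$strand[ord],
                     sites$trinuc[ord], sites$mc[ord], sites$cov[ord],
                     sep = "\t"), con)
  invisible(path)
}

#' Write a small RNA alignment table
#'
#' One row per collapsed read: read_id, length, first_base, count, and the
#' candidate loci as a semicolon-joined `chrom:start:strand` list (start
#' 0-based).
#'
#' @param alignments long-format alignment table (as produced by
#'   [simulate_sirna_reads()]).
#' @param path output path.
#' @export
write_alignments <- function(alignments, path) {
  ord <- order(alignments$read_id, alignments$cand_idx)
  a <- alignments[ord, , drop = FALSE]
  cand <- paste(a$chrom, a$start, a$strand, sep = ":")
  joined <- tapply(cand, a$read_id, paste, collapse = ";")
  first <- a[a$cand_idx == 1L, , drop = FALSE]
  joined <- joined[first$read_id]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#read_id\tlength\tfirst_base\tcount\tcandidates", con)
  if (nrow(first))
    writeLines(paste(first$read_id, first$length, first$first_base,
                     first$count, unname(joined), sep = "\t"), con)
  invisible(path)
}

#' Read a small RNA alignment table
#'
#' @param path file written by [write_alignments()].
#' @return long-format alignment data.frame (read_id, length, first_base,
#'   count, chrom, start, strand, n_cand, cand_idx).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(read_id = character(), length = integer(),
                      first_base = character(), count = integer(),
                      chrom = character(), start = integer(),
                      strand = character(), n_cand = integer(),
                      cand_idx = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    stop("malformed alignment line(s) ",
         paste(which(lengths(parts) != 5L), collapse = ", "))
  cands <- strsplit(vapply(parts, `[`, "", 5L), ";", fixed = TRUE)
  n_cand <- lengths(cands)
  if (any(n_cand < 1L)) stop("alignment record with empty candidate list")
  fields <- strsplit(unlist(cands), ":", fixed = TRUE)
  if (any(lengths(fields) != 3L)) stop("malformed candidate locus entry")
  rep_i <- rep(seq_along(parts), n_cand)
  data.frame(read_id = vapply(parts, `[`, "", 1L)[rep_i],
             length = as.integer(vapply(parts, `[`, "", 2L))[rep_i],
             first_base = vapply(parts, `[`, "", 3L)[rep_i],
             count = as.integer(vapply(parts, `[`, "", 4L))[rep_i],
             chrom = vapply(fields, `[`, "", 1L),
             start = as.integer(vapply(fields, `[`, "", 2L)),
             strand = vapply(fields, `[`, "", 3L),
             n_cand = n_cand[rep_i],
             cand_idx = sequence(n_cand),
             stringsAsFactors = FALSE)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal value are condensed; zero-valued runs are omitted.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in sort(names(track$values))) {
    v <- track$values[[ch]]
    r <- rle(fmt_num(v))
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != "0"
    if (any(keep))
      writeLines(paste(ch, start[keep], end[keep], r$values[keep],
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph into a signal track
#'
#' @param path bedGraph path.
#' @param chrom_lengths optional named lengths; defaults to the maximum end
#'   seen per chromosome.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  d <- utils::read.table(path, sep = "\t",
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                       "numeric"))
  if (any(d$start < 0 | d$start >= d$end)) stop("invalid bedGraph interval")
  chroms <- sort(unique(d$chrom))
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch)
      max(d$end[d$chrom == ch]), numeric(1))
  values <- lapply(chroms, function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    r <- d[d$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(r)))
      v[(r$start[i] + 1L):r$end[i]] <- r$value[i]
    v
  })
  names(values) <- chroms
  signal_track(values)
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of a [generate_genome()] result.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$te_class <- as.list(truth$te_class)            # keep names as keys
  out$nucleosome_archetype <- as.list(truth$nucleosome_archetype)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read ground truth JSON
#'
#' @param path path written by [write_ground_truth()].
#' @return the truth list (te_class and nucleosome_archetype as named
#'   vectors, dmr_truth as a data.frame).
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$te_class <- unlist(x$te_class)
  x$nucleosome_archetype <- unlist(x$nucleosome_archetype)
  x$dmr_truth <- as.data.frame(x$dmr_truth, stringsAsFactors = FALSE)
  x
}

#' Write a TE quantification matrix
#'
#' @param mat TE x sample matrix.
#' @param path output path.
#' @export
write_quant_table <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#te_id", colnames(mat)), collapse = "\t"), con)
  writeLines(paste(rownames(mat),
                   apply(mat, 1L, function(r)
                     paste(fmt_num(r), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a TE quantification matrix
#'
#' @param path path written by [write_quant_table()].
#' @return numeric matrix with te_id rownames.
#' @export
read_quant_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  d <- utils::read.table(text = lines[-1L], sep = "\t",
                         colClasses = c("character",
                                        rep("numeric", length(header) - 1L)))
  m <- as.matrix(d[, -1L, drop = FALSE])
  dimnames(m) <- list(d[[1L]], header[-1L])
  m
}
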