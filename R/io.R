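## Plain-text genomics formats. bedGraph and BED are simple TSVs; the
## readers validate line by line so malformed input is reported with its
## line number, and the writers emit the canonical tab-separated form so
## canonical files round-trip byte-identically.

fmt_num <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  out[is.na(x)] <- "NA"
  out
}

#' Read a bedGraph track
#'
#' Four tab/space-separated columns: chrom, start, end, value; 0-based,
#' half-open. Comment (`#`) and `track` lines are skipped. Malformed lines
#' raise an error naming the line number.
#'
#' @param path file path.
#' @return a track data.frame (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[lineno]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1]
    stop_invalid("parse error at line ", lineno[i],
                 ": expected 4 columns, got ", nf[i])
  }
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  value <- suppressWarnings(as.numeric(mat[, 4]))
  bad <- is.na(start) | is.na(end) | is.na(value)
  if (any(bad)) {
    stop_invalid("parse error at line ", lineno[which(bad)[1]],
                 ": non-numeric field")
  }
  if (any(end <= start)) {
    stop_invalid("parse error at line ", lineno[which(end <= start)[1]],
                 ": end <= start")
  }
  data.frame(chrom = mat[, 1], start = start, end = end, value = value)
}

#' Write a bedGraph track
#' @param track a track data.frame (`chrom`, `start`, `end`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  check_track(track)
  writeLines(paste(track$chrom, fmt_num(track$start), fmt_num(track$end),
                   fmt_num(track$value), sep = "\t"), path)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3 through BED6+1 (an optional 7th numeric column, e.g. a raw read
#' count). Intervals are returned as read; overlapping intervals are
#' allowed — merging is always an explicit, separate step.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`, `extra`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  cols <- c("chrom", "start", "end", "name", "score", "strand", "extra")
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3L || length(f) > 7L) {
      stop_invalid("parse error at line ", i, ": expected 3-7 columns, got ",
                   length(f))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_invalid("parse error at line ", i, ": non-numeric coordinate")
    }
    if (end <= start) stop_invalid("parse error at line ", i, ": end <= start")
    rows[[length(rows) + 1L]] <- f
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  ncol_out <- max(vapply(rows, length, 1L))
  mat <- t(vapply(rows, function(f) c(f, rep(NA_character_, ncol_out - length(f))),
                  character(ncol_out)))
  out <- data.frame(chrom = mat[, 1], start = as.numeric(mat[, 2]),
                    end = as.numeric(mat[, 3]), stringsAsFactors = FALSE)
  if (ncol_out >= 4) out$name <- mat[, 4]
  if (ncol_out >= 5) out$score <- suppressWarnings(as.numeric(mat[, 5]))
  if (ncol_out >= 6) out$strand <- mat[, 6]
  if (ncol_out >= 7) out$extra <- suppressWarnings(as.numeric(mat[, 7]))
  names(out) <- cols[seq_len(ncol_out)]
  out
}

#' Write a BED interval file
#'
#' Intervals are sorted by (chrom, start) on write; unsorted input is
#' flagged with a message.
#'
#' @param intervals data.frame with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand`, `extra` columns are written in BED
#'   order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    stop_invalid("intervals must have chrom/start/end columns")
  }
  ord <- order(intervals$chrom, intervals$start)
  if (!identical(ord, seq_len(nrow(intervals)))) {
    message("unsorted intervals: sorting on write")
    intervals <- intervals[ord, , drop = FALSE]
  }
  cols <- list(intervals$chrom, fmt_num(intervals$start),
               fmt_num(intervals$end))
  for (nm in c("name", "score", "strand", "extra")) {
    if (!nm %in% names(intervals)) break
    v <- intervals[[nm]]
    cols[[length(cols) + 1L]] <- if (is.numeric(v)) fmt_num(v) else
      as.character(v)
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write a data.frame as a TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
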