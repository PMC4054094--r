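#' Read a BED3+ file
#'
#' Tab-separated BED with 0-based half-open coordinates, preserved exactly.
#' `browser`/`track` and `#` comment lines are skipped. Columns beyond the
#' third are retained as payload (`name`, `score`, `strand`, then `V7`...).
#'
#' @param path Path to a BED file.
#' @return Data.table with `chrom`, `start`, `end` and any payload columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(browser|track|#)", lines) | lines == ""
  body <- lines[!skip]
  if (!length(body)) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  }
  lineno <- which(!skip)
  parts <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3L)) {
    abort("%s line %d: fewer than 3 BED columns", path, lineno[which(ncol < 3L)[1]])
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort("%s line %d: non-integer coordinates", path, lineno[bad[1]])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort("%s line %d: start >= end", path, lineno[bad[1]])
  }
  dt <- data.table::data.table(chrom = vapply(parts, `[[`, "", 1L),
                               start = start, end = end)
  extras <- c("name", "score", "strand")
  for (j in seq_len(max(ncol) - 3L)) {
    nm <- if (j <= 3L) extras[j] else paste0("V", j + 3L)
    dt[[nm]] <- vapply(parts, function(p) if (length(p) >= j + 3L) p[[j + 3L]]
                       else NA_character_, "")
  }
  dt
}

#' Write intervals as BED
#'
#' @param x Data.frame with `chrom`, `start`, `end` and optional further
#'   columns (written in order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(x), c("chrom", "start", "end")))
  data.table::fwrite(data.table::as.data.table(x)[, cols, with = FALSE],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' Four-column bedGraph (`chrom`, `start`, `end`, `value`), 0-based
#' half-open, steps sorted on return. Overlapping steps are rejected.
#'
#' @param path Path to a bedGraph file.
#' @return Data.table with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(browser|track|#)", lines) | lines == ""
  body <- lines[!skip]
  lineno <- which(!skip)
  if (!length(body)) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0), value = numeric(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    abort("%s line %d: fewer than 4 bedGraph columns", path,
          lineno[which(lengths(parts) < 4L)[1]])
  }
  dt <- data.table::data.table(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    value = as.numeric(vapply(parts, `[[`, "", 4L)))
  if (anyNA(dt$start) || anyNA(dt$end) || anyNA(dt$value)) {
    abort("%s: non-numeric coordinates or values", path)
  }
  if (any(dt$start >= dt$end)) abort("%s: step with start >= end", path)
  ord <- order(dt$chrom, dt$start)
  dt <- dt[ord, ]
  for (ch in unique(dt$chrom)) {
    s <- dt[dt$chrom == ch, ]
    if (nrow(s) > 1L) {
      i <- which(s$start[-1] < s$end[-nrow(s)])
      if (length(i)) {
        abort("%s: overlapping steps on %s at [%d,%d) and [%d,%d)",
              path, ch, s$start[i[1]], s$end[i[1]],
              s$start[i[1] + 1L], s$end[i[1] + 1L])
      }
    }
  }
  dt
}

#' Read aligned reads from BED3 or two-column TSV
#'
#' BED3+ (`chrom`, `start`, `end`; strand ignored; the start position is
#' used) or a headerless two-column `chrom`, `pos` table. An optional `dup`
#' column (0/1, fourth column of the TSV dialect or a column named `dup`)
#' flags PCR duplicates.
#'
#' @param path Path to the reads file.
#' @param format `"bed"` or `"tsv"` (`"auto"` sniffs the column count).
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    format <- if (length(first) >= 3L &&
                  !is.na(suppressWarnings(as.integer(first[3]))) &&
                  as.integer(first[3]) > as.integer(first[2])) "bed" else "tsv"
  }
  if (format == "bed") {
    dt <- read_bed(path)
    dup <- if ("dup" %in% names(dt)) dt$dup == "1" else FALSE
    read_set(dt$chrom, dt$start, dup)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    dup <- if (ncol(dt) >= 3L) dt[[3]] == 1 else FALSE
    read_set(dt[[1]], dt[[2]], dup)
  }
}

# self-describing TSV: "#key value" comment header then a column header line
write_tsv_commented <- function(x, path, params = list()) {
  hdr <- c(sprintf("#covbias %s", as.character(packageVersion("covbias"))),
           vapply(names(params), function(nm) {
             sprintf("#%s %s", nm, paste(params[[nm]], collapse = ","))
           }, ""),
           paste(names(x), collapse = "\t"))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t",
                     col.names = FALSE, quote = FALSE, append = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & lines != ""]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                    header = TRUE)
}

#' Write a window set as TSV (and optionally BED4)
#'
#' @param windows A [window_set].
#' @param path Output TSV path.
#' @param bed Optional BED4 path (name column = window index).
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path, bed = NULL) {
  stopifnot(inherits(windows, "window_set"))
  df <- data.table::as.data.table(windows)[
    , c("chrom", "start", "end", "accessible_bp", "gc", "index"), with = FALSE]
  write_tsv_commented(df, path,
                      params = list(mode = attr(windows, "mode"),
                                    size = attr(windows, "size")))
  if (!is.null(bed)) {
    write_bed(df[, c("chrom", "start", "end", "index"), with = FALSE], bed)
  }
  invisible(path)
}

#' Write a count track as TSV
#'
#' @param track A [count_track()].
#' @param windows The matching [window_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(track, windows, path) {
  stopifnot(inherits(track, "count_track"), inherits(windows, "window_set"))
  df <- data.table::data.table(chrom = windows$chrom, start = windows$start,
                               end = windows$end, window = track$window_ids,
                               count = track$counts)
  if (!is.null(attr(track, "n_medgc"))) {
    df$n_medgc <- attr(track, "n_medgc")
    df$flag <- as.integer(is.na(track$counts))
  }
  write_tsv_commented(df, path,
                      params = list(sample = track$sample, state = track$state,
                                    library_size = track$library_size))
  invisible(path)
}
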