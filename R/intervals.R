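#' Genomic intervals as 0-based half-open data frames
#'
#' `dfprint` represents genomic intervals as plain data frames with the
#' columns `chrom` (character), `start` and `end` (0-based half-open, the BED
#' convention), and optionally `name`, `score` and `strand`. All internal
#' coordinates follow this convention so BED files round-trip bit-exactly.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, 0-based half-open (`end > start`)
#' @param name optional character labels
#' @param score optional numeric scores
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`
#' @return a `data.frame` with one row per interval
#' @examples
#' intervals("chr1", c(10, 50), c(20, 80))
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      strand = NULL) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Read intervals from a BED file
#'
#' Parses BED3+ (tab-separated, no header). Columns beyond the first three
#' are mapped to `name`, `score` and `strand` when present; record order is
#' preserved. Coordinates stay 0-based half-open, exactly as in the file.
#'
#' @param path path to a BED3/BED6 file
#' @return interval data frame (see [intervals()])
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = starts, end = ends, stringsAsFactors = FALSE)
  ncol_min <- min(nf)
  if (ncol_min >= 4) df$name <- vapply(fields, `[`, "", 4L)
  if (ncol_min >= 5)
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (ncol_min >= 6) df$strand <- vapply(fields, `[`, "", 6L)
  validate_intervals(df)
  df
}

#' Write intervals to a BED file
#'
#' Emits BED3/BED6 depending on which optional columns are present. Missing
#' `name`/`score` are filled with `"."`/`0` when a later column is present, so
#' the output is always a valid fixed-width BED.
#'
#' @param df interval data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  cols <- list(df$chrom, df$start, df$end)
  have <- c("name", "score", "strand") %in% names(df)
  upto <- if (any(have)) max(which(have)) else 0L
  if (upto >= 1) cols <- c(cols, list(if (have[1]) df$name else "."))
  if (upto >= 2) cols <- c(cols, list(if (have[2]) df$score else 0))
  if (upto >= 3) cols <- c(cols, list(if (have[3]) df$strand else "."))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# 0-based half-open data frame -> GRanges (1-based closed) for overlap work
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand == ".", "*", df$strand)
  } else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

#' Count intervals shared with a second set
#'
#' An interval of `a` is "shared" iff it overlaps at least 1 bp of some
#' interval of `b` (strand-agnostic). Used to summarise how many
#' hypersensitive sites, or differential footprints, fall in regions common
#' to two datasets.
#'
#' @param a,b interval data frames
#' @return list with `shared_count` (integer) and `membership` (logical
#'   vector along the rows of `a`)
#' @export
intersect_counts <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0)
    return(list(shared_count = 0L, membership = logical()))
  if (nrow(b) == 0)
    return(list(shared_count = 0L, membership = rep(FALSE, nrow(a))))
  hits <- GenomicRanges::countOverlaps(as_granges(a), as_granges(b),
                                       ignore.strand = TRUE)
  membership <- hits > 0
  list(shared_count = sum(membership), membership = membership)
}

#' Pad intervals on both sides
#'
#' Extends every interval by `pad` bp in each direction, flooring the start
#' at 0. Differential footprints are padded by 10 bp before motif occupancy
#' counting so that motif hits abutting the protected window still count.
#'
#' @param df interval data frame
#' @param pad non-negative integer, bp added to each side (default 10)
#' @return interval data frame with widened coordinates
#' @export
extend_intervals <- function(df, pad = 10L) {
  validate_intervals(df)
  stopifnot(pad >= 0)
  df$start <- pmax(0L, df$start - as.integer(pad))
  df$end <- df$end + as.integer(pad)
  df
}
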