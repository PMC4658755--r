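#' Library-normalised differential DHS score
#'
#' The read-count baseline the footprint-level test is compared against:
#' for a hypersensitive site with cut counts `c_A`, `c_B` and library totals
#' `T_A`, `T_B`,
#'
#'   `dDHS = 1e6 * (c_A / T_A - c_B / T_B)`
#'
#' i.e. a cuts-per-million difference. Antisymmetric under swapping the two
#' datasets. Counts are 5' cuts on both strands inside the interval,
#' consistent with the cut-level data model used everywhere else.
#'
#' @param c_a,c_b cut counts in the interval for datasets A and B
#' @param t_a,t_b library total read counts (must be positive)
#' @param normalize optional hook: a function `(c, t) -> normalised value`
#'   replacing the default `1e6 * c / t` per-dataset normalisation
#' @return numeric vector of scores
#' @export
delta_dhs_score <- function(c_a, c_b, t_a, t_b, normalize = NULL) {
  if (any(t_a <= 0) || any(t_b <= 0))
    stop("library totals must be > 0")
  stopifnot(all(c_a >= 0), all(c_b >= 0))
  if (is.null(normalize)) normalize <- function(c, t) 1e6 * c / t
  normalize(c_a, t_a) - normalize(c_b, t_b)
}

#' Score every DHS of a set against two read sources
#'
#' @param a,b [read_source()]s
#' @param dhs interval data frame of hypersensitive sites
#' @return `dhs` with added columns `c_a`, `c_b`, `delta_dhs`
#' @export
score_delta_dhs <- function(a, b, dhs) {
  validate_intervals(dhs)
  count_cuts <- function(src, r) {
    p <- extract_cuts(src, dhs$chrom[r], dhs$start[r], dhs$end[r])
    sum(p$fwd) + sum(p$rev)
  }
  dhs$c_a <- vapply(seq_len(nrow(dhs)), function(r) count_cuts(a, r), 0)
  dhs$c_b <- vapply(seq_len(nrow(dhs)), function(r) count_cuts(b, r), 0)
  dhs$delta_dhs <- delta_dhs_score(dhs$c_a, dhs$c_b, a$total, b$total)
  dhs
}

#' Select the top and bottom n intervals by score
#'
#' Deterministic tie-break: equal scores are ordered by chromosome, then
#' start coordinate.
#'
#' @param df interval data frame with a score column
#' @param n how many to take from each end
#' @param score_col name of the score column (default `"delta_dhs"`)
#' @return list with data frames `top` (n highest, descending) and `bottom`
#'   (n lowest, ascending)
#' @export
select_top_bottom <- function(df, n, score_col = "delta_dhs") {
  stopifnot(score_col %in% names(df))
  if (n > nrow(df))
    stop("cannot select ", n, " from each end of ", nrow(df), " intervals")
  s <- df[[score_col]]
  top <- df[order(-s, df$chrom, df$start), , drop = FALSE][seq_len(n), ,
                                                           drop = FALSE]
  bottom <- df[order(s, df$chrom, df$start), , drop = FALSE][seq_len(n), ,
                                                             drop = FALSE]
  list(top = top, bottom = bottom)
}

#' Keep intervals near exactly one transcription start site
#'
#' An interval passes iff its midpoint lies within `max_dist` bp of exactly
#' one TSS; it is then annotated with that gene. Intervals near zero TSSs or
#' equidistantly ambiguous between two or more are dropped, so each retained
#' site has an unambiguous target gene.
#'
#' @param df interval data frame
#' @param tss data frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate) and `gene`
#' @param max_dist maximum midpoint-to-TSS distance in bp (default 2000)
#' @return subset of `df` with an added `gene` column
#' @export
filter_near_single_tss <- function(df, tss, max_dist = 2000L) {
  validate_intervals(df)
  stopifnot(all(c("chrom", "pos", "gene") %in% names(tss)), nrow(tss) > 0)
  if (nrow(df) == 0) { df$gene <- character(); return(df) }
  mid <- df$start + (df$end - df$start) %/% 2L
  keep <- logical(nrow(df))
  gene <- character(nrow(df))
  for (r in seq_len(nrow(df))) {
    same <- tss$chrom == df$chrom[r]
    d <- abs(tss$pos[same] - mid[r])
    hit <- which(d <= max_dist)
    if (length(hit) == 1) {
      keep[r] <- TRUE
      gene[r] <- tss$gene[same][hit]
    }
  }
  out <- df[keep, , drop = FALSE]
  out$gene <- gene[keep]
  out
}
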