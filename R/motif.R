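#' Count differential footprints occupied by a motif
#'
#' A footprint counts as occupied iff at least one motif hit overlaps it by
#' at least 1 bp; multiple hits in the same footprint count once. Occupancy
#' is strand-agnostic (hits on either strand count). Footprints should
#' normally be padded by 10 bp on each side first (see [extend_intervals()]).
#'
#' @param dfps interval data frame of (extended) differential footprints
#' @param hits interval data frame of motif hit locations
#' @return integer: the number of occupied footprints
#' @export
count_motif_occupancy <- function(dfps, hits) {
  intersect_counts(dfps, hits)$shared_count
}

#' Relative motif-frequency matrix across comparisons
#'
#' For motif `i` and differential-footprint set `j`, with `n[i, j]` the
#' number of footprints in set `j` occupied by motif `i` and `M[j]` the size
#' of set `j`, the relative frequency is
#'
#'   `value[i, j] = (n[i, j] / M[j]) * (C * sum_j M[j] / sum_j n[i, j])`
#'
#' where `C` is a scaling constant (default 1). The per-motif rescaling
#' makes rows comparable across motifs of very different genome-wide
#' abundance; each row `i` satisfies the identity
#' `sum_j value[i, j] * M[j] = C * sum_j M[j]` exactly. Motifs with no
#' occupancy anywhere (`sum_j n[i, j] = 0`) are dropped with a warning.
#'
#' @param n I x J integer matrix of occupancy counts (rows = motifs,
#'   columns = comparisons); dimnames are carried through
#' @param M length-J vector of differential-footprint set sizes (all > 0)
#' @param C scaling constant (default 1)
#' @return list of class `motif_frequency_matrix` with `values`, `n`, `M`,
#'   `C`
#' @export
relative_frequency_matrix <- function(n, M, C = 1) {
  n <- as.matrix(n)
  stopifnot(length(M) == ncol(n), all(M > 0), all(n >= 0), C > 0)
  if (any(t(n) > M)) stop("occupancy counts exceed set sizes")
  row_tot <- rowSums(n)
  if (any(row_tot == 0)) {
    dropped <- rownames(n)[row_tot == 0]
    if (is.null(dropped)) dropped <- which(row_tot == 0)
    warning("dropping motif(s) with zero occupancy everywhere: ",
            paste(dropped, collapse = ", "))
    n <- n[row_tot > 0, , drop = FALSE]
    row_tot <- row_tot[row_tot > 0]
  }
  freq <- sweep(n, 2L, M, "/")
  values <- sweep(freq, 1L, C * sum(M) / row_tot, "*")
  structure(list(values = values, n = n, M = M, C = C),
            class = "motif_frequency_matrix")
}

#' Hierarchically cluster a motif-frequency matrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' applied independently to rows (motifs) and columns (comparisons). The
#' leaf orders are the canonical output used to arrange heatmaps; rendering
#' itself is left to the caller (e.g. `stats::heatmap` or pheatmap).
#'
#' @param m a `motif_frequency_matrix` (or a plain numeric matrix)
#' @return list with `row_order`, `col_order` (leaf index vectors),
#'   `row_hclust`, `col_hclust`
#' @export
cluster_matrix <- function(m) {
  v <- if (inherits(m, "motif_frequency_matrix")) m$values else as.matrix(m)
  stopifnot(nrow(v) >= 2, ncol(v) >= 2)
  hr <- stats::hclust(stats::dist(v, method = "euclidean"),
                      method = "complete")
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "complete")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}

#' Minimal position-weight-matrix scanner
#'
#' Plumbing for when motif hits are not supplied externally: scores every
#' window of the sequence on both strands with a log-odds PWM and reports
#' windows scoring at least `threshold` times the maximum achievable score.
#' Probability PWMs are converted to log-odds against a uniform background
#' with a small pseudocount.
#'
#' @param seq DNA string
#' @param pwm 4 x L numeric matrix with rownames `A`, `C`, `G`, `T`; either
#'   column-stochastic probabilities or already log-odds
#' @param threshold fraction of the maximum achievable score (default 0.8)
#' @param pseudocount added to probability PWMs before the log (default 0.01)
#' @return data frame with `start` (0-based), `end`, `strand`, `score`
#' @export
pwm_scan <- function(seq, pwm, threshold = 0.8, pseudocount = 0.01) {
  pwm <- as.matrix(pwm)
  stopifnot(nrow(pwm) == 4, ncol(pwm) >= 4,
            setequal(rownames(pwm), c("A", "C", "G", "T")))
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (all(pwm >= 0) && all(abs(colSums(pwm) - 1) < 1e-6))
    pwm <- log2((pwm + pseudocount) / (0.25 + pseudocount))
  L <- ncol(pwm)
  s <- toupper(seq)
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  max_score <- sum(apply(pwm, 2L, max))
  cutoff <- threshold * max_score
  base_idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  score_strand <- function(idx, mat) {
    vapply(seq_len(n - L + 1L), function(i) {
      b <- idx[i:(i + L - 1L)]
      if (anyNA(b)) return(-Inf)
      sum(mat[cbind(b, seq_len(L))])
    }, numeric(1))
  }
  fwd_scores <- score_strand(base_idx, pwm)
  # minus strand: reverse-complement the PWM, scan the forward sequence
  rc_pwm <- pwm[4:1, L:1, drop = FALSE]
  rev_scores <- score_strand(base_idx, rc_pwm)
  strand_hits <- function(scores, strand) {
    i <- which(scores >= cutoff)
    data.frame(start = i - 1L, strand = rep(strand, length(i)),
               score = scores[i], stringsAsFactors = FALSE)
  }
  res <- rbind(strand_hits(fwd_scores, "+"), strand_hits(rev_scores, "-"))
  res$end <- res$start + L
  res[order(res$start, res$strand), c("start", "end", "strand", "score")]
}

#' Rank-sum test for an expression shift in a gene set
#'
#' Two-sided Mann-Whitney U test comparing the expression values (e.g.
#' FPKM) of a set of genes between two conditions -- used to ask whether
#' genes near differential footprints shift expression. Exact for small
#' samples without ties (via `stats::wilcox.test`).
#'
#' @param fpkm_a,fpkm_b named numeric vectors of per-gene expression
#' @param gene_set character vector of gene names (must appear in both)
#' @return list with `U` (statistic for the first sample), `p_value`, `n`
#'   (genes used); with fewer than 3 usable genes `p_value` is `NA` with a
#'   warning
#' @export
expression_shift_test <- function(fpkm_a, fpkm_b, gene_set) {
  stopifnot(length(gene_set) > 0)
  genes <- intersect(gene_set, intersect(names(fpkm_a), names(fpkm_b)))
  if (length(genes) < 3) {
    warning("fewer than 3 genes usable; p-value not applicable")
    return(list(U = NA_real_, p_value = NA_real_, n = length(genes)))
  }
  wt <- stats::wilcox.test(fpkm_a[genes], fpkm_b[genes],
                           alternative = "two.sided")
  list(U = unname(wt$statistic), p_value = wt$p.value, n = length(genes))
}
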