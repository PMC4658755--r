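#' Bootstrap configuration for differential footprint scoring
#'
#' @param n_shuffles number of random shuffles of the comparator profile
#'   (default 1000, so scores are multiples of 0.1)
#' @param seed integer seed; every locus derives its own substream from
#'   `(seed, locus index)` so serial and per-locus runs agree
#' @param min_comparator_cuts loci whose comparator window holds fewer total
#'   cuts than this are still scored but flagged `low_coverage`: absence of
#'   reads is not evidence of absent binding
#' @return list of class `shuffle_config`
#' @export
shuffle_config <- function(n_shuffles = 1000L, seed = 1L,
                           min_comparator_cuts = 10L) {
  stopifnot(n_shuffles >= 1)
  structure(list(n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed),
                 min_comparator_cuts = as.integer(min_comparator_cuts)),
            class = "shuffle_config")
}

# Seed for the locus-specific RNG substream; kept below 2^31.
locus_seed <- function(seed, locus_index) {
  (as.numeric(seed) * 48271 + as.numeric(locus_index) * 69621) %% 2147483647
}

# Score components from explicit window segment sums.
# Window layout: [U shoulder | FP | D shoulder]; q = shoulder/(shoulder+fp).
score_from_sums <- function(X_f, N_f, X_r, N_r, q) {
  -(log10_binom_tail(X_f, N_f, q) + log10_binom_tail(X_r, N_r, q))
}

# Segment sums of one strand vector for window layout (sh, fp, sh).
segment_sums <- function(v, shoulder, fp_size) {
  u <- sum(v[seq_len(shoulder)])
  f <- sum(v[shoulder + seq_len(fp_size)])
  d <- sum(v[shoulder + fp_size + seq_len(shoulder)])
  c(u = u, f = f, d = d)
}

#' Bootstrap percentile score for differential footprint occupancy
#'
#' Tests whether the comparator dataset `b` contributes to the footprint
#' structure at a locus detected in the primary dataset `a`. The cut counts
#' of both datasets are restricted to the scored window (footprint plus both
#' shoulders), pooled, and the footprint score of the pooled data computed
#' (`S_real`). The comparator window is then shuffled `n_shuffles` times --
#' randomising per-base count positions independently on each strand --
#' pooled with `a` and re-scored, giving the bootstrap distribution `S_k`.
#' The differential footprint (DFP) score is the percentile
#'
#'   `100 * #\{k : S_k >= S_real\} / n_shuffles`.
#'
#' If `b` genuinely contributes footprint structure, the unshuffled pooled
#' score beats the shuffles and the DFP score is low (non-differential); if
#' `b`'s cuts carry no footprint arrangement, shuffling changes little and
#' the score is high (over-footprinted in `a`). Ties count as `>=`.
#'
#' The locus is re-scored at its detected width only; width/position
#' flexibility adds cost without benefit here.
#'
#' @param locus one row of a [scan_footprints()] result (absolute `start`,
#'   `end`, `best_size` columns)
#' @param a,b [cut_profile()]s covering the locus window plus shoulders
#' @param params [footprint_params()] (supplies the shoulder width)
#' @param cfg [shuffle_config()]
#' @param locus_index integer used to derive the per-locus RNG substream
#' @return list with `score` in [0, 100], `s_real`, `comparator_cuts`,
#'   `low_coverage`
#' @export
bootstrap_score <- function(locus, a, b, params = footprint_params(),
                            cfg = shuffle_config(), locus_index = 1L) {
  shoulder <- params$shoulder_size
  fp_size <- as.integer(locus$best_size)
  w_start <- as.integer(locus$start) - shoulder
  w_end <- as.integer(locus$end) + shoulder
  aw <- subset_profile(a, w_start, w_end)
  bw <- subset_profile(b, w_start, w_end)
  q <- shoulder / (shoulder + fp_size)

  sa_f <- segment_sums(aw$fwd, shoulder, fp_size)
  sa_r <- segment_sums(aw$rev, shoulder, fp_size)
  sb_f <- segment_sums(bw$fwd, shoulder, fp_size)
  sb_r <- segment_sums(bw$rev, shoulder, fp_size)
  s_real <- score_from_sums(
    sa_f["u"] + sb_f["u"], sa_f["u"] + sb_f["u"] + sa_f["f"] + sb_f["f"],
    sa_r["d"] + sb_r["d"], sa_r["d"] + sb_r["d"] + sa_r["f"] + sb_r["f"], q)

  L <- length(bw$fwd)
  n <- cfg$n_shuffles
  s_shuf <- withr::with_seed(locus_seed(cfg$seed, locus_index), {
    vapply(seq_len(n), function(k) {
      pf <- bw$fwd[sample.int(L)]
      pr <- bw$rev[sample.int(L)]
      pb_f <- segment_sums(pf, shoulder, fp_size)
      pb_r <- segment_sums(pr, shoulder, fp_size)
      score_from_sums(
        sa_f["u"] + pb_f["u"],
        sa_f["u"] + pb_f["u"] + sa_f["f"] + pb_f["f"],
        sa_r["d"] + pb_r["d"],
        sa_r["d"] + pb_r["d"] + sa_r["f"] + pb_r["f"], q)
    }, numeric(1))
  })
  cuts_b <- sum(bw$fwd) + sum(bw$rev)
  list(score = 100 * sum(s_shuf >= s_real) / n,
       s_real = unname(s_real),
       comparator_cuts = cuts_b,
       low_coverage = cuts_b < cfg$min_comparator_cuts)
}

#' Exhaustive-permutation differential footprint score
#'
#' Replaces the random shuffles of [bootstrap_score()] by the full
#' distribution over all permutations of the comparator window, computed
#' exactly: every permutation of the forward-strand counts is enumerated
#' (each of the `L!` orderings equally likely, so arrangements of duplicated
#' values carry their multinomial weight automatically), reduced to the
#' distribution of segment sums, and combined with the independent
#' reverse-strand distribution. Feasible for windows up to ~9 bp; used as
#' the oracle the Monte-Carlo score is validated against.
#'
#' @inheritParams bootstrap_score
#' @return list with `score` (exact percentile in [0, 100]) and `s_real`
#' @export
exhaustive_bootstrap_score <- function(locus, a, b,
                                       params = footprint_params()) {
  shoulder <- params$shoulder_size
  fp_size <- as.integer(locus$best_size)
  w_start <- as.integer(locus$start) - shoulder
  w_end <- as.integer(locus$end) + shoulder
  aw <- subset_profile(a, w_start, w_end)
  bw <- subset_profile(b, w_start, w_end)
  L <- length(bw$fwd)
  if (L > 9) stop("window too long for exhaustive enumeration (", L, " bp)")
  q <- shoulder / (shoulder + fp_size)

  sa_f <- segment_sums(aw$fwd, shoulder, fp_size)
  sa_r <- segment_sums(aw$rev, shoulder, fp_size)
  sb_f <- segment_sums(bw$fwd, shoulder, fp_size)
  sb_r <- segment_sums(bw$rev, shoulder, fp_size)
  s_real <- score_from_sums(
    sa_f["u"] + sb_f["u"], sa_f["u"] + sb_f["u"] + sa_f["f"] + sb_f["f"],
    sa_r["d"] + sb_r["d"], sa_r["d"] + sb_r["d"] + sa_r["f"] + sb_r["f"], q)

  perms <- all_permutations(L)
  # distribution of (upstream, footprint) sums per strand, uniform over L!
  sum_dist <- function(v) {
    m <- matrix(v[perms], nrow = nrow(perms))
    u <- rowSums(m[, seq_len(shoulder), drop = FALSE])
    f <- rowSums(m[, shoulder + seq_len(fp_size), drop = FALSE])
    d <- rowSums(m[, shoulder + fp_size + seq_len(shoulder), drop = FALSE])
    key <- paste(u, f, d)
    agg <- tapply(rep(1, length(key)), key, sum)
    parts <- do.call(rbind, lapply(strsplit(names(agg), " "), as.numeric))
    list(u = parts[, 1], f = parts[, 2], d = parts[, 3],
         p = as.numeric(agg) / nrow(perms))
  }
  df <- sum_dist(bw$fwd)
  dr <- sum_dist(bw$rev)
  prob_ge <- 0
  for (i in seq_along(df$p)) {
    X_f <- sa_f["u"] + df$u[i]
    N_f <- X_f + sa_f["f"] + df$f[i]
    for (j in seq_along(dr$p)) {
      X_r <- sa_r["d"] + dr$d[j]
      N_r <- X_r + sa_r["f"] + dr$f[j]
      s <- score_from_sums(X_f, N_f, X_r, N_r, q)
      if (s >= s_real) prob_ge <- prob_ge + df$p[i] * dr$p[j]
    }
  }
  list(score = 100 * prob_ge, s_real = unname(s_real))
}

# all L! permutations of 1..L as a matrix (rows = permutations)
all_permutations <- function(L) {
  if (L == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(L - 1L)
  do.call(rbind, lapply(seq_len(L), function(k) {
    rest <- seq_len(L)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Differential footprints between two DNase-seq datasets
#'
#' Runs the full pairwise analysis: footprints are detected in dataset `a`
#' within its hypersensitive sites, each detected locus is bootstrap-scored
#' against dataset `b`, and loci with DFP score at or above `threshold` are
#' reported as over-footprinted in `a`. The roles of the datasets are then
#' reversed to obtain the sites over-footprinted in `b`. Deterministic for a
#' given `cfg$seed`.
#'
#' @param a,b [read_source()]s for the two conditions
#' @param dhs_a,dhs_b interval data frames of hypersensitive sites for each
#'   condition (footprint search space)
#' @param params [footprint_params()]
#' @param cfg [shuffle_config()]
#' @param threshold minimum DFP score for a call (default 10)
#' @return list of class `dfp_call_set` with data frames `over_in_A` and
#'   `over_in_B` (columns `chrom`, `start`, `end`, `best_size`,
#'   `wellington_score`, `dfp_score`, `comparator_cuts`, `low_coverage`),
#'   plus `all_A`, `all_B` holding every scored locus, and `threshold`
#' @export
differential_footprints <- function(a, b, dhs_a, dhs_b,
                                    params = footprint_params(),
                                    cfg = shuffle_config(),
                                    threshold = 10) {
  one_direction <- function(src, comp, dhs, seed_offset) {
    pad <- params$shoulder_size + max(params$footprint_sizes)
    rows <- list()
    idx <- 0L
    for (r in seq_len(nrow(dhs))) {
      w_start <- max(0L, dhs$start[r] - pad)
      w_end <- dhs$end[r] + pad
      prof <- extract_cuts(src, dhs$chrom[r], w_start, w_end)
      fps <- suppressWarnings(scan_footprints(prof, params))
      # keep footprints whose window lies inside the DHS proper
      fps <- fps[fps$start >= dhs$start[r] & fps$end <= dhs$end[r], ,
                 drop = FALSE]
      if (nrow(fps) == 0) next
      comp_prof <- extract_cuts(comp, dhs$chrom[r], w_start, w_end)
      for (f in seq_len(nrow(fps))) {
        idx <- idx + 1L
        bs <- bootstrap_score(fps[f, ], prof, comp_prof, params,
                              shuffle_config(cfg$n_shuffles,
                                             cfg$seed + seed_offset,
                                             cfg$min_comparator_cuts),
                              locus_index = idx)
        rows[[idx]] <- data.frame(
          chrom = fps$chrom[f], start = fps$start[f], end = fps$end[f],
          best_size = fps$best_size[f], wellington_score = fps$score[f],
          dfp_score = bs$score, comparator_cuts = bs$comparator_cuts,
          low_coverage = bs$low_coverage, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      warning("no footprints detected in primary dataset")
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), best_size = integer(),
                        wellington_score = numeric(), dfp_score = numeric(),
                        comparator_cuts = integer(), low_coverage = logical(),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  }
  all_A <- one_direction(a, b, dhs_a, 0L)
  all_B <- one_direction(b, a, dhs_b, 1L)
  structure(list(
    over_in_A = all_A[all_A$dfp_score >= threshold, , drop = FALSE],
    over_in_B = all_B[all_B$dfp_score >= threshold, , drop = FALSE],
    all_A = all_A, all_B = all_B, threshold = threshold),
    class = "dfp_call_set")
}

#' @export
print.dfp_call_set <- function(x, ...) {
  cat("<dfp_call_set> threshold ", x$threshold,
      ": ", nrow(x$over_in_A), " over-footprinted in A, ",
      nrow(x$over_in_B), " in B (", nrow(x$all_A), "/", nrow(x$all_B),
      " loci scored)\n", sep = "")
  invisible(x)
}

#' Shared-DHS overlap summary for a pairwise comparison
#'
#' Summarises how differential footprints distribute over hypersensitive
#' sites common to the two conditions: counts of DHSs per condition, shared
#' DHSs, over-footprinted sites per direction, and how many of those fall in
#' shared DHSs (with the percentage, 1 decimal). Percentages with a zero
#' denominator are reported as `NA`, never a division by zero.
#'
#' @param dhs_a,dhs_b DHS interval data frames
#' @param calls a `dfp_call_set` from [differential_footprints()]
#' @return one-row data frame: `n_dhs_a`, `n_dhs_b`, `n_shared`,
#'   `over_a`, `over_a_shared`, `pct_a_shared`, `over_b`, `over_b_shared`,
#'   `pct_b_shared`
#' @export
shared_dhs_summary <- function(dhs_a, dhs_b, calls) {
  shared <- intersect_counts(dhs_a, dhs_b)
  shared_dhs <- dhs_a[shared$membership, , drop = FALSE]
  in_shared <- function(df) {
    if (nrow(df) == 0) return(0L)
    intersect_counts(df, shared_dhs)$shared_count
  }
  over_a <- nrow(calls$over_in_A)
  over_b <- nrow(calls$over_in_B)
  a_sh <- in_shared(calls$over_in_A)
  b_sh <- in_shared(calls$over_in_B)
  data.frame(n_dhs_a = nrow(dhs_a), n_dhs_b = nrow(dhs_b),
             n_shared = shared$shared_count,
             over_a = over_a, over_a_shared = a_sh,
             pct_a_shared = shared_pct(a_sh, over_a),
             over_b = over_b, over_b_shared = b_sh,
             pct_b_shared = shared_pct(b_sh, over_b))
}

#' Percentage of differential footprints in shared DHSs
#'
#' The percentage rule used throughout the overlap summaries:
#' `100 * in_shared / total`, rounded to one decimal; `NA` when `total` is 0.
#'
#' @param in_shared number of over-footprinted sites falling in shared DHSs
#' @param total number of over-footprinted sites
#' @return percentage rounded to 1 decimal, or `NA`
#' @export
shared_pct <- function(in_shared, total) {
  ifelse(total > 0, round(100 * in_shared / total, 1), NA_real_)
}
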