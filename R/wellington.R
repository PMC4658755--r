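#' Footprint scan parameters
#'
#' @param footprint_sizes candidate protected-window widths in bp; odd values
#'   11 to 25 by default, matching the sub-30 bp scale of transcription
#'   factor footprints
#' @param shoulder_size width in bp of the flanking high-cleavage windows
#'   used as the reference (default 35)
#' @param score_threshold minimum footprint score to report (default 10)
#' @return list of class `footprint_params`
#' @export
footprint_params <- function(footprint_sizes = seq(11L, 25L, by = 2L),
                             shoulder_size = 35L,
                             score_threshold = 10) {
  stopifnot(all(footprint_sizes >= 1), shoulder_size >= 1,
            score_threshold >= 0)
  structure(list(footprint_sizes = as.integer(footprint_sizes),
                 shoulder_size = as.integer(shoulder_size),
                 score_threshold = score_threshold),
            class = "footprint_params")
}

# log10 of the upper binomial tail P[Bin(n, q) >= x], exact
log10_binom_tail <- function(x, n, q) {
  stats::pbinom(x - 1, n, q, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Strand-imbalance footprint score at one window
#'
#' Scores the evidence that a window of width `fp_size` centred at offset
#' `center` of the profile is protected from DNaseI cleavage. The double-hit
#' DNase-seq protocol concentrates positive-strand 5' cuts immediately
#' upstream of a bound site and negative-strand cuts immediately downstream.
#' With `U`/`D` the shoulder windows immediately up/downstream of the
#' footprint window `FP`, let `X_f` be the positive-strand cuts in `U` and
#' `N_f` those in `U` and `FP` together (`X_r`, `N_r` mirrored on the
#' negative strand downstream). Under no protection each cut lands in the
#' shoulder with probability `q = shoulder / (shoulder + fp_size)`, so the
#' one-sided binomial tails `p_f = P[Bin(N_f, q) >= X_f]` and
#' `p_r = P[Bin(N_r, q) >= X_r]` measure the per-strand excess. The score is
#'
#'   `S = -(log10 p_f + log10 p_r)`
#'
#' computed exactly (no normal approximation).
#'
#' @param profile a [cut_profile()]
#' @param center 0-based offset within the profile; the footprint window is
#'   `[center - fp_size %/% 2, center - fp_size %/% 2 + fp_size)` (for odd
#'   sizes, symmetric about `center`)
#' @param fp_size footprint window width in bp
#' @param shoulder shoulder width in bp
#' @return non-negative score (0 when there is no evidence)
#' @export
wellington_score <- function(profile, center, fp_size, shoulder) {
  stopifnot(inherits(profile, "cut_profile"))
  L <- length(profile$fwd)
  fp_a <- center - fp_size %/% 2L      # 0-based offsets within profile
  fp_b <- fp_a + fp_size - 1L
  if (fp_a - shoulder < 0 || fp_b + shoulder > L - 1)
    stop("scoring window [", fp_a - shoulder, ", ", fp_b + shoulder,
         "] out of profile bounds [0, ", L - 1, "]")
  fwd <- profile$fwd; rev <- profile$rev
  u <- (fp_a - shoulder + 1L):fp_a            # 1-based: U = upstream shoulder
  fp <- (fp_a + 1L):(fp_b + 1L)
  d <- (fp_b + 2L):(fp_b + shoulder + 1L)
  X_f <- sum(fwd[u]);  N_f <- X_f + sum(fwd[fp])
  X_r <- sum(rev[d]);  N_r <- X_r + sum(rev[fp])
  q <- shoulder / (shoulder + fp_size)
  -(log10_binom_tail(X_f, N_f, q) + log10_binom_tail(X_r, N_r, q))
}

# Vectorised scores over all valid centers for a single footprint size.
# Returns a length-L vector, NA where the window does not fit.
wellington_score_track <- function(fwd, rev, fp_size, shoulder) {
  L <- length(fwd)
  out <- rep(NA_real_, L)
  half <- fp_size %/% 2L
  centers <- which(seq_len(L) - 1L - half - shoulder >= 0 &
                   seq_len(L) - 1L - half + fp_size - 1L + shoulder <= L - 1L) - 1L
  if (length(centers) == 0) return(out)
  csf <- cumsum(c(0L, fwd)); csr <- cumsum(c(0L, rev))
  wsum <- function(cs, a, b) cs[b + 2L] - cs[a + 1L]  # 0-based [a, b]
  fp_a <- centers - half
  fp_b <- fp_a + fp_size - 1L
  X_f <- wsum(csf, fp_a - shoulder, fp_a - 1L)
  N_f <- X_f + wsum(csf, fp_a, fp_b)
  X_r <- wsum(csr, fp_b + 1L, fp_b + shoulder)
  N_r <- X_r + wsum(csr, fp_a, fp_b)
  q <- shoulder / (shoulder + fp_size)
  out[centers + 1L] <- -(log10_binom_tail(X_f, N_f, q) +
                         log10_binom_tail(X_r, N_r, q))
  out
}

#' Scan a profile for footprints
#'
#' At every candidate center the score is maximised over the configured
#' footprint sizes; candidates at or above `score_threshold` are reduced to a
#' non-overlapping set greedily in decreasing score order (ties broken by
#' leftmost coordinate, then smallest size), and returned sorted by
#' coordinate.
#'
#' @param profile a [cut_profile()]
#' @param params a [footprint_params()]
#' @return data frame with columns `chrom`, `start`, `end` (absolute, 0-based
#'   half-open footprint window), `center`, `score`, `best_size`
#' @export
scan_footprints <- function(profile, params = footprint_params()) {
  stopifnot(inherits(profile, "cut_profile"))
  L <- length(profile$fwd)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer(),
                      score = numeric(), best_size = integer(),
                      stringsAsFactors = FALSE)
  if (L <= max(params$footprint_sizes) + 2L * params$shoulder_size) {
    warning("profile too short to scan (", L, " bp)")
    return(empty)
  }
  tracks <- vapply(params$footprint_sizes, function(sz)
    wellington_score_track(profile$fwd, profile$rev, sz,
                           params$shoulder_size),
    numeric(L))
  best <- apply(tracks, 1L, function(r)
    if (all(is.na(r))) c(NA_real_, NA_real_)
    else c(max(r, na.rm = TRUE), which.max(r)))
  score <- best[1L, ]; size_idx <- best[2L, ]
  cand <- which(!is.na(score) & score >= params$score_threshold)
  if (length(cand) == 0) return(empty)
  sizes <- params$footprint_sizes[size_idx[cand]]
  fp_a <- cand - 1L - sizes %/% 2L
  fp_b <- fp_a + sizes
  ord <- order(-score[cand], fp_a, sizes)
  taken <- rep(FALSE, L)
  keep <- logical(length(cand))
  for (k in ord) {
    span <- (fp_a[k] + 1L):fp_b[k]
    if (!any(taken[span])) {
      keep[k] <- TRUE
      taken[span] <- TRUE
    }
  }
  res <- data.frame(chrom = profile$chrom,
                    start = profile$start + fp_a[keep],
                    end = profile$start + fp_b[keep],
                    center = profile$start + cand[keep] - 1L,
                    score = score[cand][keep],
                    best_size = sizes[keep],
                    stringsAsFactors = FALSE)
  res[order(res$start), , drop = FALSE]
}
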