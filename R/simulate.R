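#' Specification of a simulated DNase-seq cut landscape
#'
#' Describes the observable signature of bound transcription factors in
#' double-hit DNase-seq data: a short protected window, a pile-up of
#' positive-strand 5' cuts in the shoulder immediately upstream and of
#' negative-strand cuts immediately downstream. The generator draws
#' independent per-base background counts and, for each planted footprint
#' that is realised (with probability `occupancy`), adds `depth` signal cuts
#' split between the two shoulders with the stated strand imbalance, while
#' depleting the footprint interior.
#'
#' @param region_length simulated region length in bp
#' @param depth expected signal cuts per realised footprint (default 100)
#' @param footprints data frame with columns `center` (0-based), `width`
#'   (>= 5 bp) and `occupancy` in [0, 1]
#' @param imbalance enrichment of the signature strand over the opposite
#'   strand within a shoulder (default 5)
#' @param background expected background cuts per bp per strand
#'   (default 0.25, a deeply sequenced hypersensitive site)
#' @param shoulder_width width of the simulated cut pile-ups (default 20 bp)
#' @param interior_depletion multiplier on background inside a realised
#'   footprint (default 0.1)
#' @param bias optional [bias_model()]: background rates are modulated by
#'   the hexamer propensity of `genome_seq`
#' @param genome_seq DNA string for the region plus 3 bp context each side
#'   (required with `bias`)
#' @param chrom chromosome name for emitted profiles (default "chrS")
#' @param region_start 0-based genomic start of the region (default 0)
#' @param seed RNG seed; the simulation is fully determined by it
#' @return list of class `sim_spec`
#' @export
sim_spec <- function(region_length, depth = 100, footprints = NULL,
                     imbalance = 5, background = 0.25, shoulder_width = 20L,
                     interior_depletion = 0.1, bias = NULL, genome_seq = NULL,
                     chrom = "chrS", region_start = 0L, seed = 1L) {
  if (is.null(footprints))
    footprints <- data.frame(center = integer(), width = integer(),
                             occupancy = numeric())
  stopifnot(all(footprints$occupancy >= 0 & footprints$occupancy <= 1),
            all(footprints$width >= 5),
            all(footprints$center >= 0 &
                footprints$center < region_length),
            depth >= 0, background >= 0, imbalance > 0)
  if (!is.null(bias) && is.null(genome_seq))
    stop("a bias model requires genome_seq for hexamer context")
  structure(list(region_length = as.integer(region_length), depth = depth,
                 footprints = footprints, imbalance = imbalance,
                 background = background,
                 shoulder_width = as.integer(shoulder_width),
                 interior_depletion = interior_depletion,
                 bias = bias, genome_seq = genome_seq,
                 chrom = chrom, region_start = as.integer(region_start),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a cut profile with planted footprints
#'
#' @param spec a [sim_spec()]
#' @return list with `profile` (a [cut_profile()]) and `truth` (data frame
#'   of planted footprints: `start`, `end` absolute coordinates, `center`,
#'   `width`, `occupancy`, `occupied` -- whether the plant was realised)
#' @export
simulate_profile <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_profile_impl(spec))
}

simulate_profile_impl <- function(spec) {
  L <- spec$region_length
  rate_f <- rep(spec$background, L)
  rate_r <- rep(spec$background, L)
  if (!is.null(spec$bias)) {
    wf <- unname(spec$bias$weights[cut_hexamers(spec$genome_seq, "+")])
    wr <- unname(spec$bias$weights[cut_hexamers(spec$genome_seq, "-")])
    stopifnot(length(wf) == L)
    rate_f <- rate_f * wf / mean(wf, na.rm = TRUE)
    rate_r <- rate_r * wr / mean(wr, na.rm = TRUE)
    rate_f[is.na(rate_f)] <- spec$background
    rate_r[is.na(rate_r)] <- spec$background
  }
  fps <- spec$footprints
  occupied <- logical(nrow(fps))
  sh <- spec$shoulder_width
  extra_f <- numeric(L); extra_r <- numeric(L)
  interior <- rep(1, L)
  for (k in seq_len(nrow(fps))) {
    occupied[k] <- stats::runif(1) < fps$occupancy[k]
    if (!occupied[k]) next
    half <- fps$width[k] %/% 2L
    a <- fps$center[k] - half               # footprint window [a, b) 0-based
    b <- a + fps$width[k]
    up <- if (a >= 1) seq(max(0L, a - sh), a - 1L) else integer(0)
    dn <- if (b <= L - 1) seq(b, min(L - 1L, b + sh - 1L)) else integer(0)
    n_cuts <- stats::rpois(1, spec$depth)
    # signature strands get `imbalance` times the cuts of the opposite ones
    w_sig <- spec$imbalance / (2 * (spec$imbalance + 1))
    alloc <- stats::rmultinom(1, n_cuts,
                              c(w_sig, 1 / (2 * (spec$imbalance + 1)),
                                w_sig, 1 / (2 * (spec$imbalance + 1))))
    place <- function(n, positions) {
      if (n == 0 || length(positions) == 0) return(integer(0))
      positions[sample.int(length(positions), n, replace = TRUE)]
    }
    add <- function(vec, pos) {
      t <- tabulate(pos + 1L, nbins = L); vec + t
    }
    extra_f <- add(extra_f, place(alloc[1], up))
    extra_r <- add(extra_r, place(alloc[2], up))
    extra_r <- add(extra_r, place(alloc[3], dn))
    extra_f <- add(extra_f, place(alloc[4], dn))
    span <- (a + 1L):b
    span <- span[span >= 1 & span <= L]
    interior[span] <- spec$interior_depletion
  }
  fwd <- stats::rpois(L, rate_f * interior) + extra_f
  rev <- stats::rpois(L, rate_r * interior) + extra_r
  profile <- cut_profile(spec$chrom, spec$region_start,
                         spec$region_start + L, fwd, rev)
  truth <- data.frame(
    chrom = rep(spec$chrom, nrow(fps)),
    start = spec$region_start + fps$center - fps$width %/% 2L,
    end = spec$region_start + fps$center - fps$width %/% 2L + fps$width,
    center = spec$region_start + fps$center,
    width = fps$width, occupancy = fps$occupancy, occupied = occupied,
    stringsAsFactors = FALSE)
  list(profile = profile, truth = truth)
}

#' Simulate a two-condition pair with shared and condition-specific plants
#'
#' Plants `shared` footprints in both conditions, `a_only` in condition A
#' and `b_only` in condition B, over a common region. Footprint windows must
#' be disjoint. The returned truth table labels every planted site
#' `shared`, `A_only` or `B_only`; swapping the two seed arguments swaps the
#' conditions, not the labels.
#'
#' @param region_length region length in bp
#' @param shared,a_only,b_only data frames of plants (`center`, `width`,
#'   `occupancy`; occupancy defaults to 1 if absent)
#' @param seed base seed; conditions use `seed` and `seed + 1`
#' @param ... further arguments passed to [sim_spec()] (depth, background,
#'   imbalance, ...)
#' @return list with `profile_a`, `profile_b` ([cut_profile()]s), `truth`
#'   (plants with a `label` column), and the two specs
#' @export
simulate_pair <- function(region_length, shared, a_only, b_only,
                          seed = 1L, ...) {
  fill <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(center = integer(), width = integer(),
                        occupancy = numeric()))
    if (!"occupancy" %in% names(df)) df$occupancy <- 1
    df[c("center", "width", "occupancy")]
  }
  shared <- fill(shared); a_only <- fill(a_only); b_only <- fill(b_only)
  all_fp <- rbind(shared, a_only, b_only)
  if (nrow(all_fp) > 1) {
    a <- all_fp$center - all_fp$width %/% 2L
    b <- a + all_fp$width
    ord <- order(a)
    if (any(a[ord][-1] < b[ord][-length(ord)]))
      stop("planted footprints overlap")
  }
  spec_a <- sim_spec(region_length,
                     footprints = rbind(shared, a_only), seed = seed, ...)
  spec_b <- sim_spec(region_length,
                     footprints = rbind(shared, b_only), seed = seed + 1L,
                     ...)
  out_a <- simulate_profile(spec_a)
  out_b <- simulate_profile(spec_b)
  label <- rep(c("shared", "A_only", "B_only"),
               c(nrow(shared), nrow(a_only), nrow(b_only)))
  truth <- rbind(out_a$truth[seq_len(nrow(shared) + nrow(a_only)), ,
                             drop = FALSE],
                 out_b$truth[nrow(shared) + seq_len(nrow(b_only)), ,
                             drop = FALSE])
  truth$label <- label
  truth <- truth[order(truth$start), , drop = FALSE]
  list(profile_a = out_a$profile, profile_b = out_b$profile,
       truth = truth, spec_a = spec_a, spec_b = spec_b)
}

#' Reproducible toy genome sequence
#'
#' A single pseudo-random chromosome (uniform ACGT) determined by the seed;
#' used for the hexamer-bias machinery in tests and simulations.
#'
#' @param length chromosome length in bp (default 50000)
#' @param seed RNG seed
#' @return character string of A/C/G/T
#' @export
toy_genome <- function(length = 50000L, seed = 1L) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""))
}

#' Write a cut profile as SAM alignments
#'
#' Emits one read per cut: positive-strand reads start at the cut position,
#' negative-strand reads end at it, so `extract_cuts(emit_sam(p)) == p` --
#' the generator's central round-trip contract. Reads near the chromosome
#' edges are shortened so every record stays within bounds.
#'
#' @param profile a [cut_profile()]
#' @param path output SAM path
#' @param read_length read length in bp (default 36)
#' @param chrom_length length of the reference chromosome for the `@SQ`
#'   header (default: profile end + read length)
#' @return `path`, invisibly
#' @export
emit_sam <- function(profile, path, read_length = 36L,
                     chrom_length = NULL) {
  stopifnot(inherits(profile, "cut_profile"))
  if (is.null(chrom_length))
    chrom_length <- profile$end + read_length
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", profile$chrom, "\tLN:", chrom_length))
  pos <- profile$start + seq_along(profile$fwd) - 1L  # 0-based cut positions
  recs <- character(0)
  mk <- function(cuts, counts, flag) {
    cuts <- rep(cuts, counts)
    if (length(cuts) == 0) return(character(0))
    if (flag == 0L) {
      p1 <- cuts + 1L                                  # 1-based leftmost
      len <- pmin(read_length, chrom_length - cuts)
    } else {
      len <- pmin(read_length, cuts + 1L)
      p1 <- cuts + 2L - len
    }
    paste(paste0("r", flag, "_", seq_along(cuts)), flag, profile$chrom,
          p1, 60L, paste0(len, "M"), "*", 0L, 0L,
          strrep("A", len), "*", sep = "\t")
  }
  recs <- c(mk(pos, profile$fwd, 0L), mk(pos, profile$rev, 16L))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Write a toy genome as FASTA
#'
#' @param seqs named character vector of chromosome sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
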