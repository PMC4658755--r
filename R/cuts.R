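#' Open a source of aligned DNase-seq reads
#'
#' Wraps a coordinate-sorted, indexed BAM file (or a SAM text file, which is
#' converted, sorted and indexed into a temporary BAM) together with its
#' library size. Random access by interval is required by everything
#' downstream, so a BAM without an index is an error rather than a silent
#' full scan.
#'
#' @param path path to a BAM (indexed) or SAM file
#' @return an object of class `read_source` with elements `bam` (a
#'   [Rsamtools::BamFile]) and `total` (total number of mapped reads)
#' @export
read_source <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    dest <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                 indexDestination = TRUE)
  } else {
    bam_path <- path
    idx <- paste0(path, ".bai")
    idx2 <- sub("\\.bam$", ".bai", path)
    if (!file.exists(idx) && !file.exists(idx2))
      stop("BAM file is not indexed (no .bai found): ", path,
           " -- sort and index it first")
  }
  bam <- Rsamtools::BamFile(bam_path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  total <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = flag))$records
  structure(list(bam = bam, total = total, path = bam_path),
            class = "read_source")
}

#' @export
print.read_source <- function(x, ...) {
  cat("<read_source> ", x$path, " (", x$total, " mapped reads)\n", sep = "")
  invisible(x)
}

#' Per-base strand-specific 5' cut counts over an interval
#'
#' Constructs a `cut_profile`: the universal currency of the package. `fwd`
#' and `rev` hold, for every base of the interval, the number of sequenced 5'
#' read ends (= DNaseI cleavage events) on the positive and negative strand.
#'
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @param fwd,rev non-negative integer count vectors of length `end - start`
#' @return an object of class `cut_profile`
#' @export
cut_profile <- function(chrom, start, end, fwd, rev) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end > start, length(fwd) == end - start,
            length(rev) == end - start, all(fwd >= 0), all(rev >= 0),
            all(is.finite(fwd)), all(is.finite(rev)))
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 fwd = as.integer(fwd), rev = as.integer(rev)),
            class = "cut_profile")
}

#' @export
print.cut_profile <- function(x, ...) {
  cat("<cut_profile> ", x$chrom, ":", x$start, "-", x$end,
      "  fwd cuts: ", sum(x$fwd), "  rev cuts: ", sum(x$rev), "\n", sep = "")
  invisible(x)
}

#' @export
length.cut_profile <- function(x) x$end - x$start

#' Extract strand-specific 5' DNase cut counts
#'
#' For every base of the interval, counts reads whose 5' end falls there:
#' the leftmost aligned base for positive-strand reads, the rightmost aligned
#' base for negative-strand reads (no +/-1 offset is applied; see the
#' package vignette). Unmapped, secondary and supplementary alignments are
#' excluded; duplicates are retained.
#'
#' @param source a [read_source()]
#' @param chrom chromosome name (must exist in the BAM header)
#' @param start,end 0-based half-open interval to profile
#' @return a [cut_profile()]
#' @export
extract_cuts <- function(source, chrom, start, end) {
  stopifnot(inherits(source, "read_source"))
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(end > start, start >= 0)
  known <- Rsamtools::seqinfo(source$bam)
  if (!chrom %in% GenomeInfoDb::seqnames(known))
    stop("chromosome not present in alignment file: ", chrom)
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, which = which)
  aln <- GenomicAlignments::readGAlignments(source$bam, param = param)
  L <- end - start
  fwd <- integer(L); rev <- integer(L)
  if (length(aln) > 0) {
    plus <- as.logical(BiocGenerics::strand(aln) == "+")
    # 5' cut, 0-based: alignment start-1 for +, alignment end-1 for -
    cut5 <- ifelse(plus, BiocGenerics::start(aln) - 1L,
                   BiocGenerics::end(aln) - 1L)
    off <- cut5 - start
    inside <- off >= 0 & off < L
    fwd <- tabulate(off[inside & plus] + 1L, nbins = L)
    rev <- tabulate(off[inside & !plus] + 1L, nbins = L)
  }
  cut_profile(chrom, start, end, fwd, rev)
}

#' Elementwise sum of two cut profiles over the same interval
#'
#' Pooling the comparator's cuts with the primary dataset's is the first step
#' of the bootstrap test: the statistic is then recomputed on the pooled
#' profile.
#'
#' @param a,b `cut_profile` objects over identical intervals
#' @return pooled `cut_profile`
#' @export
pool_profiles <- function(a, b) {
  stopifnot(inherits(a, "cut_profile"), inherits(b, "cut_profile"))
  if (a$chrom != b$chrom || a$start != b$start || a$end != b$end)
    stop("cannot pool profiles over different intervals: ",
         a$chrom, ":", a$start, "-", a$end, " vs ",
         b$chrom, ":", b$start, "-", b$end)
  cut_profile(a$chrom, a$start, a$end, a$fwd + b$fwd, a$rev + b$rev)
}

#' Shuffle a cut profile's per-base counts
#'
#' Randomises the positions of the per-base counts: the forward-strand vector
#' is permuted uniformly at random, and the reverse-strand vector gets an
#' independent permutation ("strand independent" shuffling). The per-strand
#' multiset of counts -- hence total cut numbers -- is preserved exactly.
#'
#' @param p a `cut_profile`
#' @return shuffled `cut_profile` over the same interval
#' @export
shuffle_profile <- function(p) {
  stopifnot(inherits(p, "cut_profile"))
  L <- length(p$fwd)
  cut_profile(p$chrom, p$start, p$end,
              p$fwd[sample.int(L)], p$rev[sample.int(L)])
}

# subset a profile to [start, end) (0-based absolute coordinates)
subset_profile <- function(p, start, end) {
  stopifnot(start >= p$start, end <= p$end, end > start)
  i <- (start - p$start + 1L):(end - p$start)
  cut_profile(p$chrom, start, end, p$fwd[i], p$rev[i])
}
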