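#' DNaseI hexamer cleavage-bias model
#'
#' DNaseI cleaves some sequence contexts far more readily than others; the
#' bias is well captured by the 6-mer surrounding the cut. A bias model maps
#' each DNA 6-mer to a positive relative cleavage propensity, typically
#' estimated from deproteinised ("naked") DNA. The model is used to compute
#' per-base expected cut counts against which observed cuts are normalised.
#'
#' @param weights named numeric vector: names are uppercase ACGT 6-mers,
#'   values are positive weights; 6-mers absent from the table are treated
#'   as missing
#' @param provenance free-text label recording where the table came from
#' @return object of class `bias_model`
#' @export
bias_model <- function(weights, provenance = "user") {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  if (any(weights <= 0)) stop("bias weights must be > 0")
  if (any(!grepl("^[ACGT]{6}$", names(weights))))
    stop("bias model keys must be uppercase ACGT 6-mers")
  structure(list(weights = weights, provenance = provenance),
            class = "bias_model")
}

#' Flat (uniform) bias model over all 4096 hexamers
#'
#' Useful as a null model: expected counts become uniform and bias
#' correction reduces to a rescaling of the observed counts.
#'
#' @return a [bias_model()] with every weight 1
#' @export
flat_bias_model <- function() {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
  bias_model(stats::setNames(rep(1, length(kmers)), kmers), "flat")
}

#' Read a bias table from a two-column text file
#'
#' Format: whitespace-separated, one `6-mer weight` pair per line, `#`
#' comments allowed.
#'
#' @param path file path
#' @param provenance label stored on the model (default: the file name)
#' @return a [bias_model()]
#' @export
read_bias_table <- function(path, provenance = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("kmer", "weight"),
                           colClasses = c("character", "numeric"))
  bias_model(stats::setNames(tab$weight, toupper(tab$kmer)), provenance)
}

# hexamer covering a cut at 0-based position i of `seq` (a character
# string): plus strand uses seq[i-3 .. i+2]; minus strand uses the reverse
# complement of seq[i-2 .. i+3] (the same window mirrored about the cut).
cut_hexamers <- function(seq, strand = "+") {
  n <- nchar(seq)
  stopifnot(n >= 7)
  s <- toupper(seq)
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  starts <- seq_len(n - 6L)
  hex <- substring(s, starts, starts + 5L)
  if (strand == "-") rev(hex) else hex
}

#' Per-base expected cut counts under a bias model
#'
#' Distributes `total_observed` cuts over the positions of a region
#' proportionally to the cleavage propensity of each position's hexamer
#' context: `expected_i = total_observed * w_i / sum_j w_j`, summing over
#' positions with a usable hexamer. The supplied sequence must extend the
#' region by 3 bp on each side so every position has full context. Positions
#' whose hexamer contains a non-ACGT base, or is absent from the model, are
#' returned as `NA` and excluded from the normalising sum.
#'
#' @param seq DNA string covering the region plus 3 bp of flanking context
#'   on each side (so the region length is `nchar(seq) - 6`)
#' @param total_observed total observed cut count to distribute
#' @param model a [bias_model()]
#' @param strand `"+"` or `"-"`: which strand the cuts are on (minus-strand
#'   hexamers are looked up reverse-complemented)
#' @return numeric vector of length `nchar(seq) - 6` with `NA` at excluded
#'   positions
#' @export
expected_cuts <- function(seq, total_observed, model, strand = "+") {
  stopifnot(inherits(model, "bias_model"), total_observed >= 0)
  hex <- cut_hexamers(seq, strand)
  w <- unname(model$weights[hex])
  valid <- grepl("^[ACGT]{6}$", hex)
  listed <- valid & !is.na(w)
  if (any(valid & is.na(w)))
    stop("bias model missing 6-mer(s): ",
         paste(unique(hex[valid & is.na(w)]), collapse = ", "))
  w[!listed] <- NA_real_
  tot_w <- sum(w, na.rm = TRUE)
  if (tot_w == 0) return(w)  # all missing
  total_observed * w / tot_w
}

#' Divide observed cuts by bias-expected cuts
#'
#' `corrected_i = observed_i / expected_i` where the expectation is positive;
#' positions with missing or zero expectation propagate as `NA`, never as a
#' silent zero.
#'
#' @param observed numeric vector of observed per-base counts
#' @param expected numeric vector from [expected_cuts()], same length
#' @return numeric vector of corrected values
#' @export
bias_correct <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  out <- rep(NA_real_, length(observed))
  ok <- !is.na(expected) & expected > 0
  out[ok] <- observed[ok] / expected[ok]
  out
}

#' Substitute sample SNVs into a reference sequence
#'
#' Applies single-nucleotide variants to the reference before hexamer
#' lookup, so the bias correction reflects the DNA actually present in the
#' sample. Records whose REF/ALT are not single bases (indels, multi-allelic
#' ALTs) are skipped with a warning.
#'
#' @param seq reference DNA string for the region
#' @param variants data frame with columns `pos` (0-based offset within the
#'   region), `ref`, `alt`
#' @return DNA string with substitutions applied
#' @export
apply_variants <- function(seq, variants) {
  if (is.null(variants) || nrow(variants) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (r in seq_len(nrow(variants))) {
    ref <- toupper(variants$ref[r]); alt <- toupper(variants$alt[r])
    pos <- variants$pos[r]
    if (nchar(ref) != 1 || nchar(alt) != 1 || !alt %in% c("A", "C", "G", "T")) {
      warning("skipping non-SNV variant at region position ", pos)
      next
    }
    if (pos < 0 || pos >= length(chars)) {
      warning("skipping variant outside region at position ", pos)
      next
    }
    if (toupper(chars[pos + 1L]) != ref)
      warning("variant REF mismatch at region position ", pos,
              " (reference has ", chars[pos + 1L], ", record says ", ref, ")")
    chars[pos + 1L] <- alt
  }
  paste(chars, collapse = "")
}

#' Read SNVs from a VCF file for a region
#'
#' Thin wrapper around `VariantAnnotation::readVcf` that returns the SNV
#' records overlapping a region in the form [apply_variants()] consumes.
#'
#' @param path VCF file path
#' @param chrom chromosome name
#' @param start,end 0-based half-open region
#' @return data frame with columns `pos` (0-based offset within the region),
#'   `ref`, `alt`
#' @export
read_vcf_snvs <- function(path, chrom, start, end) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("package 'VariantAnnotation' is required to read VCF files")
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(alt_l), function(i) {
    a <- as.character(alt_l[[i]])
    if (length(a) == 1) a else ""
  }, "")
  pos0 <- BiocGenerics::start(gr) - 1L
  sel <- as.character(GenomeInfoDb::seqnames(gr)) == chrom &
    pos0 >= start & pos0 < end
  data.frame(pos = pos0[sel] - start, ref = ref[sel], alt = alt[sel],
             stringsAsFactors = FALSE)
}

#' Average (optionally bias-corrected) cleavage profile over loci
#'
#' Centres a window of `2 * flank + 1` bp on each locus midpoint, extracts
#' per-base cut counts, optionally divides them by the bias model's expected
#' counts (per strand, using the genome sequence), orients minus-strand loci
#' (mirrored, with forward/reverse swapped), and averages per offset.
#' Correction is applied per locus before averaging.
#'
#' @param loci interval data frame (a `strand` column, if present, controls
#'   orientation)
#' @param source a [read_source()]
#' @param flank bp on each side of the locus midpoint
#' @param model optional [bias_model()]; requires `genome`
#' @param genome optional named character vector (or `DNAStringSet`) of
#'   chromosome sequences for hexamer context
#' @return list of class `average_profile` with `offsets`
#'   (`-flank .. flank`), `fwd_mean`, `rev_mean`, `n_loci`, `corrected`
#' @export
average_profile <- function(loci, source, flank = 100L, model = NULL,
                            genome = NULL) {
  validate_intervals(loci)
  if (nrow(loci) == 0) stop("no loci supplied")
  if (!is.null(model) && is.null(genome))
    stop("bias correction requires the genome sequence")
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- stats::setNames(as.character(genome), nm)
  }
  W <- 2L * flank + 1L
  fwd_mat <- matrix(NA_real_, nrow(loci), W)
  rev_mat <- matrix(NA_real_, nrow(loci), W)
  for (r in seq_len(nrow(loci))) {
    mid <- loci$start[r] + (loci$end[r] - loci$start[r]) %/% 2L
    w_start <- mid - flank; w_end <- mid + flank + 1L
    if (w_start < 0) stop("locus ", r, " cannot be expanded by flank ", flank)
    p <- extract_cuts(source, loci$chrom[r], w_start, w_end)
    fwd <- as.numeric(p$fwd); rev <- as.numeric(p$rev)
    if (!is.null(model)) {
      chrom_seq <- genome[[loci$chrom[r]]]
      if (is.null(chrom_seq)) stop("no sequence for ", loci$chrom[r])
      ctx <- substr(chrom_seq, w_start - 3L + 1L, w_end + 3L)
      fwd <- bias_correct(fwd, expected_cuts(ctx, sum(fwd), model, "+"))
      rev <- bias_correct(rev, expected_cuts(ctx, sum(rev), model, "-"))
    }
    minus <- "strand" %in% names(loci) && loci$strand[r] == "-"
    if (minus) {
      fwd_mat[r, ] <- rev(rev)
      rev_mat[r, ] <- rev(fwd)
    } else {
      fwd_mat[r, ] <- fwd
      rev_mat[r, ] <- rev
    }
  }
  structure(list(offsets = seq(-flank, flank),
                 fwd_mean = colMeans(fwd_mat, na.rm = TRUE),
                 rev_mean = colMeans(rev_mat, na.rm = TRUE),
                 n_loci = nrow(loci),
                 corrected = !is.null(model)),
            class = "average_profile")
}

#' Strand-imbalance matrix for a scored call set
#'
#' Builds the matrix behind score-sorted footprint heatmaps: one row per
#' locus (ascending DFP score), one column per position in a window of
#' `2 * flank + 1` bp around the locus midpoint, value = forward minus
#' reverse cuts per base. Two blocks are returned, one per dataset, sharing
#' the row order.
#'
#' @param calls data frame of scored loci (needs `chrom`, `start`, `end`,
#'   `dfp_score`)
#' @param a,b [read_source()]s
#' @param flank bp on each side of the locus midpoint
#' @return list with `imbalance_a`, `imbalance_b` (loci x positions
#'   matrices), `order` (row indices into `calls`), `scores` (ascending)
#' @export
strand_imbalance_matrix <- function(calls, a, b, flank = 100L) {
  stopifnot(nrow(calls) > 0, "dfp_score" %in% names(calls))
  ord <- order(calls$dfp_score, calls$chrom, calls$start)
  W <- 2L * flank + 1L
  block <- function(src) {
    m <- matrix(0, length(ord), W)
    for (k in seq_along(ord)) {
      r <- ord[k]
      mid <- calls$start[r] + (calls$end[r] - calls$start[r]) %/% 2L
      p <- extract_cuts(src, calls$chrom[r], mid - flank, mid + flank + 1L)
      m[k, ] <- p$fwd - p$rev
    }
    m
  }
  list(imbalance_a = block(a), imbalance_b = block(b),
       order = ord, scores = calls$dfp_score[ord])
}
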