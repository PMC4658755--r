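#' Bundled shared-DHS overlap counts for seven primary cell types
#'
#' Loads the example table of pairwise DNase-seq comparisons between seven
#' human primary cell types (CD4+, CD8+ T cells, CD14+ monocytes, CD19+
#' B cells, CD56+ NK cells, spinal cord, fibroblasts): DHS counts per cell
#' type, shared DHS counts, and over-footprinted site counts per direction
#' with their shared-DHS subset. One row per unordered pair; each row
#' carries both directed comparisons.
#'
#' @return data frame with columns `cell_a`, `cell_b`, `n_dhs_a`, `n_dhs_b`,
#'   `n_shared`, `over_a`, `over_a_shared`, `over_b`, `over_b_shared`
#' @export
shared_dhs_counts <- function() {
  utils::read.delim(system.file("extdata", "shared_dhs_counts.tsv",
                                package = "dfprint"),
                    stringsAsFactors = FALSE)
}

#' Shared-DHS percentages for a table of overlap counts
#'
#' Applies the [shared_pct()] rule to every directed comparison of a counts
#' table shaped like [shared_dhs_counts()], returning one row per direction.
#'
#' @param counts data frame with the columns of [shared_dhs_counts()]
#' @return data frame with `primary`, `comparator`, `over`, `over_shared`,
#'   `pct_shared`
#' @export
shared_dhs_percentages <- function(counts = shared_dhs_counts()) {
  rbind(
    data.frame(primary = counts$cell_a, comparator = counts$cell_b,
               over = counts$over_a, over_shared = counts$over_a_shared,
               pct_shared = shared_pct(counts$over_a_shared, counts$over_a),
               stringsAsFactors = FALSE),
    data.frame(primary = counts$cell_b, comparator = counts$cell_a,
               over = counts$over_b, over_shared = counts$over_b_shared,
               pct_shared = shared_pct(counts$over_b_shared, counts$over_b),
               stringsAsFactors = FALSE))
}
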