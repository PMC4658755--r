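test_that("occupancy counts footprints, not hits", {
  dfps <- intervals("chrT", c(100, 300, 500), c(130, 330, 530))
  expect_equal(count_motif_occupancy(dfps, dfps[0, ]), 0)
  # three hits inside the first footprint count once
  hits <- intervals("chrT", c(102, 110, 120), c(108, 116, 126))
  expect_equal(count_motif_occupancy(dfps, hits), 1)

  # all-pairs oracle on random sets
  withr::with_seed(103, {
    d <- random_intervals(30)
    h <- random_intervals(30, max_width = 12)
  })
  expect_equal(count_motif_occupancy(d, h), sum(overlap_oracle(d, h)))
})

test_that("relative_frequency_matrix implements the stated formula", {
  # single motif, single comparison: collapses to the scaling constant
  m1 <- relative_frequency_matrix(matrix(5, 1, 1), M = 10, C = 1)
  expect_equal(unname(m1$values[1, 1]), 1)
  m2 <- relative_frequency_matrix(matrix(5, 1, 1), M = 10, C = 2.5)
  expect_equal(unname(m2$values[1, 1]), 2.5)

  # hand-evaluated 2x2 example
  n <- matrix(c(2, 1, 0, 1), 2, 2)  # rows: motifs
  out <- relative_frequency_matrix(n, M = c(10, 10), C = 1)
  expect_equal(unname(out$values), matrix(c(2, 1, 0, 1), 2, 2))

  # zero cell with non-zero row stays zero
  expect_equal(unname(out$values[1, 2]), 0)

  # row identity sum_j value_ij * M_j = C * sum_j M_j on random matrices;
  # doubling C doubles every entry
  withr::with_seed(107, {
    for (rep in 1:20) {
      I <- sample(2:8, 1); J <- sample(2:6, 1)
      M <- sample(50:500, J)
      nm <- matrix(rbinom(I * J, 50, 0.3), I, J)
      nm[1, ] <- pmax(nm[1, ], 1)
      out <- suppressWarnings(relative_frequency_matrix(nm, M, C = 1))
      expect_equal(as.numeric(out$values %*% M),
                   rep(sum(M), nrow(out$values)), tolerance = 1e-9)
      out2 <- suppressWarnings(relative_frequency_matrix(nm, M, C = 2))
      expect_equal(out2$values, 2 * out$values, tolerance = 1e-12)
    }
  })

  # all-zero motif rows are dropped with a warning
  nz <- rbind(a = c(0, 0), b = c(3, 1))
  expect_warning(out3 <- relative_frequency_matrix(nz, M = c(5, 5)), "a")
  expect_equal(rownames(out3$values), "b")

  expect_error(relative_frequency_matrix(matrix(11, 1, 1), M = 10),
               "exceed")
})

test_that("cluster_matrix groups by structure, deterministically", {
  # two identical rows merge first (distance 0)
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(9, 9, 9, 9), c(0, 9, 0, 9))
  cl <- cluster_matrix(m)
  expect_equal(sort(cl$row_hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$row_hclust$height[1], 0)

  # block-diagonal: leaves group by block, rows and columns
  blk <- rbind(c(10, 10, 0, 0), c(11, 9, 0, 0),
               c(0, 0, 10, 10), c(0, 0, 9, 11))
  cl2 <- cluster_matrix(blk)
  ro <- cl2$row_order
  expect_setequal(ro[1:2], if (1 %in% ro[1:2]) c(1, 2) else c(3, 4))
  co <- cl2$col_order
  expect_setequal(co[1:2], if (1 %in% co[1:2]) c(1, 2) else c(3, 4))

  # hand-checked complete-linkage heights for the 4 block points:
  # within-block distances sqrt(2); between blocks the farthest pair rules
  d <- as.matrix(dist(blk))
  expect_equal(cl2$row_hclust$height,
               c(sqrt(2), sqrt(2), max(d)), tolerance = 1e-12)

  # permuting rows preserves dendrogram topology (heights and partition)
  perm <- c(3, 1, 4, 2)
  cl3 <- cluster_matrix(blk[perm, ])
  expect_equal(cl3$row_hclust$height, cl2$row_hclust$height)
  ct2 <- stats::cutree(cl2$row_hclust, 2)
  ct3 <- stats::cutree(cl3$row_hclust, 2)
  # membership of original row i under the permuted clustering
  ct3_orig <- ct3[match(seq_len(4), perm)]
  expect_true(all(outer(ct2, ct2, "==") == outer(ct3_orig, ct3_orig, "==")))

  # repeated runs are identical
  expect_identical(cluster_matrix(blk)$row_order, cl2$row_order)
})

test_that("pwm_scan agrees with brute-force window scoring", {
  consensus <- "ACGTAC"
  pwm <- matrix(0.04, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:6) pwm[substring(consensus, j, j), j] <- 0.88

  seq <- paste0("TT", consensus, "GGGG", consensus, "TT")
  hits <- pwm_scan(seq, pwm, threshold = 1.0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, c(2, 12))  # only exact consensus at threshold 1

  # brute-force oracle at a permissive threshold on a random sequence
  rseq <- toy_genome(60, seed = 11)
  lo <- log2((pwm + 0.01) / 0.26)
  maxs <- sum(apply(lo, 2, max))
  score_win <- function(w) sum(vapply(1:6, function(j) lo[substring(w, j, j), j],
                                      numeric(1)))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  starts <- 1:(60 - 6 + 1)
  wins <- substring(rseq, starts, starts + 5)
  brute <- data.frame(
    start = rep(starts - 1L, 2),
    strand = rep(c("+", "-"), each = length(starts)),
    score = c(vapply(wins, score_win, numeric(1)),
              vapply(wins, function(w) score_win(rc(w)), numeric(1))))
  brute <- brute[brute$score >= 0.5 * maxs, ]
  got <- pwm_scan(rseq, pwm, threshold = 0.5)
  expect_equal(nrow(got), nrow(brute))
  key <- function(d) sort(paste(d$start, d$strand, round(d$score, 9)))
  expect_equal(key(got), key(brute))

  # palindromic PWM hits both strands identically
  pal <- "ACGCGT"
  ppwm <- matrix(0.04, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:6) ppwm[substring(pal, j, j), j] <- 0.88
  ph <- pwm_scan(paste0("GG", pal, "GG"), ppwm, threshold = 1.0)
  expect_equal(sum(ph$strand == "+"), sum(ph$strand == "-"))
  expect_equal(ph$start[ph$strand == "+"], ph$start[ph$strand == "-"])

  # sequence shorter than the motif: no hits
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0)
})

test_that("expression_shift_test behaves like a two-sided rank-sum test", {
  genes <- paste0("g", 1:10)
  a <- stats::setNames(seq(11, 20), genes)
  b <- stats::setNames(seq(1, 10), genes)

  # complete separation: U = 100, minimal exact two-sided p
  res <- expression_shift_test(a, b, genes)
  expect_equal(res$U, 100)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-9)

  # swapping the conditions leaves p unchanged
  res2 <- expression_shift_test(b, a, genes)
  expect_equal(res2$p_value, res$p_value)

  # identical distributions: p ~ 1
  res3 <- suppressWarnings(expression_shift_test(a, a, genes))
  expect_gt(res3$p_value, 0.9)

  # fewer than 3 genes -> NA with a warning
  expect_warning(res4 <- expression_shift_test(a, b, genes[1:2]), "fewer")
  expect_true(is.na(res4$p_value))
})
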