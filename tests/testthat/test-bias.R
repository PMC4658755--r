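test_that("expected_cuts distributes the total by hexamer weight", {
  flat <- flat_bias_model()
  seq12 <- paste(rep("ACGT", 5), collapse = "")  # 20 bp -> 14 positions
  e <- expected_cuts(seq12, 70, flat)
  expect_equal(length(e), nchar(seq12) - 6)
  expect_equal(e, rep(70 / 14, 14))           # flat bias -> uniform
  expect_equal(sum(e), 70)                    # conservation
  expect_equal(expected_cuts(seq12, 0, flat), rep(0, 14))

  # two-entry toy model, hand-evaluated: region of 2 positions
  s <- "AACGTTCC"                             # positions: AACGTT, ACGTTC
  m <- bias_model(c(AACGTT = 3, ACGTTC = 1))
  expect_equal(expected_cuts(s, 8, m), c(6, 2))

  expect_error(expected_cuts("AAAAAAAA", 5, m), "missing 6-mer")
})

test_that("minus-strand hexamers are the mirrored reverse complement", {
  s <- "AACGTTCC"
  # cut at region position 0 (genome offset 3): minus hexamer is the
  # reverse complement of plus-strand [1..6] = ACGTTC -> GAACGT
  m <- bias_model(c(GAACGT = 4, GGAACG = 1))
  e <- expected_cuts(s, 10, m, strand = "-")
  expect_equal(e, c(8, 2))
})

test_that("bias_correct divides and propagates missing values", {
  obs <- c(2, 4, 6, 1)
  exp_ <- c(1, 2, 3, 0.5)
  expect_equal(bias_correct(obs, exp_), c(2, 2, 2, 2))  # proportional -> flat
  exp_[2] <- NA; exp_[3] <- 0
  out <- bias_correct(obs, exp_)
  expect_equal(out, c(2, NA, NA, 2))
})

test_that("correcting with the true generator bias flattens profiles", {
  # strong planted hexamer bias; corrected positional variance must drop
  ratios <- vapply(1:10, function(seed) {
    L <- 600L
    g <- toy_genome(L + 6L, seed = 1000 + seed)
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6)
    w <- withr::with_seed(77, exp(rnorm(length(kmers), sd = 1.2)))
    model <- bias_model(stats::setNames(w, kmers), "synthetic truth")
    spec <- sim_spec(L, depth = 0, background = 4, bias = model,
                     genome_seq = g, seed = seed)
    p <- simulate_profile(spec)$profile
    e <- expected_cuts(g, sum(p$fwd), model)
    corr <- bias_correct(as.numeric(p$fwd), e)
    var(corr / mean(corr, na.rm = TRUE), na.rm = TRUE) /
      var(p$fwd / mean(p$fwd))
  }, numeric(1))
  expect_lt(median(ratios), 0.5)
  expect_lt(mean(ratios), 0.75)
})

test_that("apply_variants substitutes SNVs only", {
  s <- "ACGTACGTAC"
  expect_equal(apply_variants(s, NULL), s)
  expect_equal(apply_variants(s, data.frame(pos = integer(),
                                            ref = character(),
                                            alt = character())), s)
  one <- apply_variants(s, data.frame(pos = 5, ref = "C", alt = "T"))
  expect_equal(one, "ACGTATGTAC")
  expect_warning(
    indel <- apply_variants(s, data.frame(pos = 2, ref = "GT", alt = "G")),
    "non-SNV")
  expect_equal(indel, s)

  # 10 random SNVs vs a naive substitution oracle
  withr::with_seed(91, {
    long <- toy_genome(200, seed = 8)
    pos <- sample(0:199, 10)
    alt <- sample(c("A", "C", "G", "T"), 10, replace = TRUE)
  })
  ref <- substring(long, pos + 1, pos + 1)
  naive <- strsplit(long, "")[[1]]
  naive[pos + 1] <- alt
  got <- apply_variants(long, data.frame(pos = pos, ref = ref, alt = alt))
  expect_equal(got, paste(naive, collapse = ""))
})

test_that("average_profile is order-invariant and shows the cut signature", {
  withr::with_seed(97, {
    centers <- seq(300L, by = 400L, length.out = 12L)
    sim <- simulate_profile(sim_spec(5200L, depth = 150,
      footprints = data.frame(center = centers, width = 15L, occupancy = 1),
      seed = 97))
  })
  sam <- tempfile(fileext = ".sam")
  emit_sam(sim$profile, sam)
  src <- read_source(sam)
  loci <- intervals("chrS", centers - 8L, centers + 8L)  # midpoint = center

  ap <- average_profile(loci, src, flank = 60L)
  ap_perm <- average_profile(loci[sample(nrow(loci)), ], src, flank = 60L)
  expect_equal(ap$fwd_mean, ap_perm$fwd_mean)
  expect_equal(ap$rev_mean, ap_perm$rev_mean)

  one <- average_profile(loci[1, ], src, flank = 60L)
  p1 <- extract_cuts(src, "chrS", centers[1] - 60L, centers[1] + 61L)
  expect_equal(one$fwd_mean, as.numeric(p1$fwd))

  # signature: fwd pile-up upstream and rev pile-up downstream of center,
  # both well above the protected interior
  off <- ap$offsets
  interior <- abs(off) <= 5
  up <- off < -5 & off >= -20
  dn <- off > 5 & off <= 20
  expect_gt(mean(ap$fwd_mean[up]), 2 * mean(ap$fwd_mean[interior]))
  expect_gt(mean(ap$rev_mean[dn]), 2 * mean(ap$rev_mean[interior]))

  expect_error(average_profile(loci[0, ], src), "no loci")
})

test_that("strand_imbalance_matrix rows follow ascending score", {
  sim <- simulated_experiment(n_each = 4L, seed = 7L)
  calls <- data.frame(chrom = "chrS",
                      start = sim$truth$start, end = sim$truth$end,
                      dfp_score = withr::with_seed(7, runif(nrow(sim$truth), 0, 100)))
  m <- strand_imbalance_matrix(calls, sim$a, sim$b, flank = 50L)
  expect_equal(dim(m$imbalance_a), c(nrow(calls), 101))
  expect_equal(m$scores, sort(calls$dfp_score))
  expect_equal(cor(seq_along(m$scores), m$scores, method = "spearman"), 1)

  # balanced profile -> zero rows
  flatsam <- tempfile(fileext = ".sam")
  emit_sam(cut_profile("chrS", 0, 2000, rep(1L, 2000), rep(1L, 2000)),
           flatsam)
  flat <- read_source(flatsam)
  calls1 <- data.frame(chrom = "chrS", start = 500L, end = 520L,
                       dfp_score = 50)
  m2 <- strand_imbalance_matrix(calls1, flat, flat, flank = 30L)
  expect_true(all(m2$imbalance_a == 0))
})
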