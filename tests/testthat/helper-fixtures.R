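# Shared fixture builders. Everything is generated in code at test time;
# no binary files are stored.

# Hand-written SAM with a known set of reads on a toy chromosome.
# Reads (0-based coordinates of the aligned span, half-open):
#   rp1  + strand  [100, 136)  -> 5' cut at 100
#   rp2  + strand  [100, 136)  -> 5' cut at 100 (duplicate, retained)
#   rm1  - strand  [100, 136)  -> 5' cut at 135
write_toy_sam <- function(path) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:1000",
    "rp1\t0\tchrT\t101\t60\t36M\t*\t0\t0\t*\t*",
    "rp2\t0\tchrT\t101\t60\t36M\t*\t0\t0\t*\t*",
    "rm1\t16\tchrT\t101\t60\t36M\t*\t0\t0\t*\t*")
  writeLines(lines, path)
  path
}

# random interval set on a toy chromosome
random_intervals <- function(n, chrom_len = 10000L, max_width = 200L) {
  start <- sample.int(chrom_len - max_width, n) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  intervals("chrT", start, start + width)
}

# quadratic all-pairs overlap oracle for intersect_counts
overlap_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & a$end[i] > b$start)
  }, logical(1))
}

# independent exact binomial upper tail via explicit enumeration
enum_binom_tail <- function(x, n, q) {
  if (x <= 0) return(1)
  k <- x:n
  sum(choose(n, k) * q^k * (1 - q)^(n - k))
}

# independent re-implementation of the strand-imbalance score from the
# definition, used as the oracle for wellington_score
oracle_wellington <- function(fwd, rev, center, fp_size, shoulder) {
  half <- fp_size %/% 2
  a <- center - half; b <- a + fp_size - 1
  U <- (a - shoulder):(a - 1) + 1
  FP <- a:b + 1
  D <- (b + 1):(b + shoulder) + 1
  X_f <- sum(fwd[U]); N_f <- X_f + sum(fwd[FP])
  X_r <- sum(rev[D]); N_r <- X_r + sum(rev[FP])
  q <- shoulder / (shoulder + fp_size)
  -(log10(enum_binom_tail(X_f, N_f, q)) + log10(enum_binom_tail(X_r, N_r, q)))
}

# a profile with one strong planted footprint, via the generator
planted_profile <- function(center = 200L, width = 15L, len = 400L,
                            seed = 1L, depth = 200, occupancy = 1) {
  simulate_profile(sim_spec(len, depth = depth,
                            footprints = data.frame(center = center,
                                                    width = width,
                                                    occupancy = occupancy),
                            seed = seed))$profile
}

# simulated two-condition experiment written to SAM and opened as sources
simulated_experiment <- function(n_each = 20L, seed = 42L, depth = 100,
                                 spacing = 800L) {
  centers <- seq(500L, by = spacing, length.out = 3L * n_each)
  grp <- rep(c("shared", "A_only", "B_only"), n_each)
  plants <- function(cs) data.frame(center = cs, width = 15L, occupancy = 1)
  region <- max(centers) + 500L
  sim <- simulate_pair(region,
                       shared = plants(centers[grp == "shared"]),
                       a_only = plants(centers[grp == "A_only"]),
                       b_only = plants(centers[grp == "B_only"]),
                       seed = seed, depth = depth)
  dir <- tempfile("simexp"); dir.create(dir)
  sam_a <- file.path(dir, "a.sam"); sam_b <- file.path(dir, "b.sam")
  emit_sam(sim$profile_a, sam_a)
  emit_sam(sim$profile_b, sam_b)
  dhs <- intervals("chrS", centers - 100L, centers + 100L)
  list(a = read_source(sam_a), b = read_source(sam_b),
       dhs = dhs, truth = sim$truth, sim = sim)
}

# label calls against a truth table by any overlap
label_calls <- function(calls, truth) {
  if (nrow(calls) == 0) return(character(0))
  vapply(seq_len(nrow(calls)), function(i) {
    ov <- truth$start < calls$end[i] & truth$end > calls$start[i] &
      truth$chrom == calls$chrom[i]
    if (any(ov)) truth$label[which(ov)[1]] else "none"
  }, "")
}
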