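test_that("Viterbi decoding equals exhaustive path enumeration on short instances", {
  model <- roh_model()
  for (seed in 1:6) {
    set.seed(seed)
    nv <- sample(3:12, 1)
    g <- sample(c(0L, 1L, 2L, NA), nv, replace = TRUE,
                prob = c(0.4, 0.2, 0.3, 0.1))
    p <- runif(nv, 0.05, 0.95)
    emis <- herdscan:::roh_emissions(g, p, model)
    dists <- sample(c(500, 5e4, 5e5), nv - 1, replace = TRUE)
    path <- herdscan:::roh_viterbi(emis, dists, model)
    expect_identical(path, oracle_viterbi(emis, dists, model)$path)
  }
})

test_that("a fully heterozygous sample yields no RoH segments", {
  g <- cbind(rep(1L, 50), matrix(sample(0:2, 50 * 9, replace = TRUE), 50, 9))
  co <- toy_cohort(g, pos = seq(1000, by = 1000, length.out = 50),
                   chrom_len = 6e4)
  segs <- roh_call(co, "s1")
  expect_equal(nrow(segs), 0)
})

test_that("a planted megabase segment is recovered to within one marker spacing", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 15, chrom_lengths = c(chr1 = 4e6),
                    site_density = 1 / 1000, fst = 0, seed = 41)
  co <- sim_balding_nichols(cfg)$cohort
  truth <- data.frame(chrom = "chr1", start = 15e5, end = 25e5)
  pl <- plant_autozygosity(co, "pop1_1", truth, error_rate = 0)
  segs <- roh_call(pl$cohort, "pop1_1")
  segs <- segs[segs$length >= 5e5, , drop = FALSE]
  expect_equal(nrow(segs), 1)
  # the called run must cover every marker inside the planted interval
  # (no undershoot at marker resolution); outward extension is bounded
  # separately as false-positive bases
  inside <- co$variants$pos[co$variants$pos >= truth$start &
                              co$variants$pos <= truth$end]
  expect_lte(segs$start, min(inside))
  expect_gte(segs$end, max(inside))
  expect_gt(segs$mean_posterior, 0.9)
  fp <- (max(0, truth$start - segs$start) + max(0, segs$end - truth$end))
  expect_lt(fp / (4e6 - 1e6), 0.02)
})

test_that("F_RoH arithmetic, monotonicity and scale invariance hold", {
  segs <- data.frame(sample_id = "s1", chrom = "chr1",
                     start = 1e6, end = 4e6 - 1, length = 3e6,
                     n_snps = 100L, mean_posterior = 1)
  fr <- f_roh(segs, l_genome = 1e8)
  expect_equal(fr$froh_50kb, 0.03)
  expect_equal(fr$froh_2mb, 0.03)
  expect_equal(fr$froh_4mb, 0)
  vals <- unlist(fr[1, c("froh_50kb", "froh_100kb", "froh_1mb",
                         "froh_2mb", "froh_4mb")])
  expect_true(all(diff(vals) <= 0))
  # doubling all coordinates and the genome length leaves F_RoH unchanged
  segs2 <- transform(segs, start = start * 2, end = end * 2,
                     length = length * 2)
  fr2 <- f_roh(segs2, classes = c(1e5, 2e5, 2e6, 4e6, 8e6), l_genome = 2e8)
  expect_equal(unname(unlist(fr2[1, 2:6])), unname(vals))
  expect_equal(nrow(f_roh(segs[0, ])), 0)
})

test_that("SNP-in-RoH frequencies match brute-force interval membership", {
  co <- random_cohort(3, nv = 60, ns = 10, chrom_len = 60000L)
  set.seed(3)
  segs <- do.call(rbind, lapply(1:10, function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    start <- sort(sample.int(50000L, k))
    data.frame(sample_id = paste0("s", i), chrom = "chr1",
               start = start, end = start + sample.int(15000L, k),
               length = 0, n_snps = 1L, mean_posterior = 1)
  }))
  fr <- roh_snp_freq(segs, co, "popA")
  for (v in sample(seq_len(60), 12)) {
    cnt <- 0
    for (s in paste0("s", 1:10)) {
      ss <- segs[segs$sample_id == s, , drop = FALSE]
      if (nrow(ss) && any(co$variants$pos[v] >= ss$start &
                            co$variants$pos[v] <= ss$end))
        cnt <- cnt + 1
    }
    expect_equal(fr$freq[v], cnt / 10)
  }
  # degenerate cases
  all_cov <- data.frame(sample_id = paste0("s", 1:10), chrom = "chr1",
                        start = 1, end = 60000, length = 60000,
                        n_snps = 60L, mean_posterior = 1)
  expect_true(all(roh_snp_freq(all_cov, co, "popA")$freq == 1))
  two_cov <- all_cov[1:2, ]
  expect_true(all(roh_snp_freq(two_cov, co, "popA")$freq == 0.2))
})

test_that("island selection follows the ceiling rule and the gap merge rule", {
  set.seed(6)
  fr <- data.frame(chrom = "chr1", pos = sort(sample.int(5e7, 10000)),
                   n_in_roh = 0L, freq = runif(10000))
  res <- roh_islands(fr, top_fraction = 5e-4, max_gap = 1e5)
  expect_equal(sum(res$islands$n_snps), ceiling(5e-4 * 10000))
  expect_equal(sum(res$islands$n_snps), 5)
  expect_gte(min(res$islands$peak_freq), res$threshold)

  fr2 <- data.frame(chrom = "chr1",
                    pos = c(1.00e6, 1.05e6, 1.30e6, seq(2e6, 9e6, by = 1e4)),
                    n_in_roh = 0L, freq = 0)
  fr2$freq <- c(0.9, 0.92, 0.95, runif(nrow(fr2) - 3, 0, 0.5))
  res2 <- roh_islands(fr2, top_fraction = 3 / nrow(fr2), max_gap = 1e5)
  expect_equal(nrow(res2$islands), 2)
  expect_equal(res2$islands$start, c(1.00e6, 1.30e6))
  expect_equal(res2$islands$end, c(1.05e6, 1.30e6))
  expect_equal(res2$islands$n_snps, c(2L, 1L))

  res3 <- roh_islands(fr2, top_fraction = 1 / nrow(fr2), max_gap = 1e5)
  expect_equal(res3$islands$start, res3$islands$end)
  expect_equal(res3$islands$n_snps, 1L)
  expect_warning(
    roh_islands(data.frame(chrom = "chr1", pos = 1:10, n_in_roh = 0L,
                           freq = 0.5)),
    "equal")
})

test_that("decoding is conservative for outbred samples", {
  # with a vanishing entry rate no autozygous state is decoded in HWE data
  co <- sim_balding_nichols(sim_config(
    n_pops = 1, n_per_pop = 10, chrom_lengths = c(chr1 = 2e6),
    site_density = 1 / 1000, fst = 0, seed = 55))$cohort
  segs <- roh_call(co, "pop1_1", model = roh_model(az_enter_rate = 1e-14,
                                                   error_rate = 1e-6))
  expect_equal(nrow(segs), 0)
})
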