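test_that("Hudson per-site terms follow the ratio-of-averages forms", {
  ac <- function(n_alt, n) data.frame(n_ref = n - n_alt, n_alt = n_alt,
                                      n = n, p = n_alt / n, q = 1 - n_alt / n)
  t1 <- hudson_site(ac(10, 10), ac(0, 10))  # fixed difference
  expect_equal(t1$N, 1)
  expect_equal(t1$D, 1)
  t2 <- hudson_site(ac(5, 10), ac(5, 10))
  expect_equal(t2$N, -2 * 0.25 / 9)
  expect_equal(round(t2$N, 5), -0.05556)
  expect_equal(t2$D, 0.5)
  t3 <- hudson_site(ac(0, 10), ac(0, 10))   # monomorphic same allele
  expect_equal(t3$N, 0)
  expect_equal(t3$D, 0)
  t4 <- hudson_site(ac(1, 1), ac(5, 10))    # n < 2 -> excluded
  expect_true(is.na(t4$N))
})

test_that("genome-wide F_ST has its fixed points and symmetries", {
  co <- random_cohort(23, nv = 400, ns = 20,
                      pops = rep(c("A", "B"), each = 10))
  # allele-label swap at every site leaves the estimate unchanged
  f0 <- fst_genomewide(co, "A", "B")
  co_sw <- co
  co_sw$genotypes <- 2L - co$genotypes
  expect_equal(fst_genomewide(co_sw, "A", "B"), f0, tolerance = 1e-12)
  expect_equal(fst_genomewide(co, "B", "A"), f0, tolerance = 1e-12)

  # identical samples in both roles: exactly -1/(n-1)
  co_self <- subset_samples(co, population = "A")
  co_self$samples$population <- "A"
  co2 <- co
  co2$samples$population <- rep("A", 20)
  dup <- new_cohort(co$variants,
                    data.frame(sample_id = c(paste0("x", 1:10), paste0("y", 1:10)),
                               population = rep(c("A", "B"), each = 10)),
                    cbind(co$genotypes[, 1:10], co$genotypes[, 1:10]))
  expect_equal(fst_genomewide(dup, "A", "B"), -1 / 19, tolerance = 1e-12)

  # split halves of one panmictic population: near zero
  co3 <- sim_balding_nichols(sim_config(
    n_pops = 1, n_per_pop = 60, chrom_lengths = c(chr1 = 5e6),
    site_density = 1 / 1000, fst = 0, seed = 71))$cohort
  co3$samples$population <- rep(c("h1", "h2"), each = 30)
  expect_lt(abs(fst_genomewide(co3, "h1", "h2")), 0.01)

  # opposite fixation at all sites
  g <- cbind(matrix(0L, 50, 5), matrix(2L, 50, 5))
  co4 <- toy_cohort(g, pops = rep(c("A", "B"), each = 5))
  expect_equal(fst_genomewide(co4, "A", "B"), 1)
})

test_that("the pairwise F_ST table ranks populations and ignores sample order", {
  co <- sim_balding_nichols(sim_config(
    n_pops = 3, n_per_pop = 25, chrom_lengths = c(chr1 = 3e6),
    site_density = 1 / 1000, fst = c(0, 0.04, 0.16), seed = 29))$cohort
  tab <- fst_matrix(co, "pop1")
  expect_equal(tab$population, c("pop2", "pop3"))
  expect_true(all(diff(tab$fst) > 0))
  perm <- sample(n_samples(co))
  co_p <- subset_samples(co, ids = co$samples$sample_id[perm])
  tab_p <- fst_matrix(co_p, "pop1")
  expect_equal(tab_p$fst, tab$fst, tolerance = 1e-12)
})

test_that("windowed F_ST honours the SNP minimum and the per-window ratio", {
  co <- random_cohort(31, nv = 200, ns = 16,
                      pops = rep(c("A", "B"), each = 8), chrom_len = 20000L)
  w <- fst_windows(co, "A", "B", window_bp = 1000, min_snps = 5)
  expect_true(all(w$n_snps >= 5))
  # brute-force per-window ratio
  sub <- segregating_subset(co, c("A", "B"))
  terms <- hudson_site(allele_counts(sub, population = "A"),
                       allele_counts(sub, population = "B"))
  for (r in seq_len(nrow(w))) {
    sel <- sub$variants$pos >= w$start[r] & sub$variants$pos <= w$end[r] &
      !is.na(terms$N)
    expect_equal(w$value[r], sum(terms$N[sel]) / sum(terms$D[sel]),
                 tolerance = 1e-12)
  }
  # a window with 4 usable SNPs must be absent
  w4 <- fst_windows(co, "A", "B", window_bp = 1000, min_snps = 200)
  expect_equal(nrow(w4), 0)
})

test_that("top-window selection uses the ceiling rule and merges adjacent windows", {
  w <- data.frame(chrom = "w", start = seq(1, by = 10, length.out = 10),
                  end = seq(10, by = 10, length.out = 10),
                  n_snps = 5L, value = c(1:9 / 10, 0.99))
  sel <- top_fraction_windows(w, top_fraction = 1e-4)
  expect_equal(nrow(sel$selected), 1)  # ceiling(0.001) = 1
  expect_equal(sel$selected$value, 0.99)

  w2 <- data.frame(chrom = "1",
                   start = c(29280001, 29290001, 29500001),
                   end = c(29290000, 29300000, 29510000),
                   n_snps = 10L, value = c(0.9, 0.85, 0.8))
  sel2 <- top_fraction_windows(w2, top_fraction = 2 / 3)
  expect_equal(nrow(sel2$regions), 1)
  expect_equal(sel2$regions$start, 29280001)
  expect_equal(sel2$regions$end, 29300000)
  expect_equal(sel2$regions$end - sel2$regions$start + 1, 20000)
})

test_that("Manhattan distances rescale missingness like complete data", {
  g <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  co <- toy_cohort(g)
  m <- manhattan_matrix(co)
  expect_equal(m["s1", "s2"], 4)
  expect_equal(diag(m), c(s1 = 0, s2 = 0))

  co2 <- random_cohort(41, nv = 500, ns = 6)
  full <- manhattan_matrix(co2)
  co3 <- co2
  set.seed(42)
  co3$genotypes[runif(length(co3$genotypes)) < 0.1] <- NA
  miss <- manhattan_matrix(co3)
  expect_true(all(abs(miss / full - 1)[upper.tri(full)] < 0.05))
})

test_that("UPGMA reproduces the O(n^3) reference including tie cases", {
  m <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(as.dist(m))
  expect_equal(node_heights(tr), 2)
  expect_equal(to_newick(tr), "(A:2,B:2);")

  for (seed in 1:20) {
    set.seed(seed)
    n <- 12
    d <- matrix(0, n, n)
    vals <- sample(seq(0.5, 6, by = 0.5), n * (n - 1) / 2, replace = TRUE)
    d[lower.tri(d)] <- vals  # coarse grid forces ties
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    hc <- upgma(as.dist(d))
    ref <- oracle_upgma(d)
    expect_equal(hclust_merge_trace(hc), ref$merges)
    expect_equal(hc$height, ref$heights, tolerance = 1e-12)
  }

  # ultrametric input: all leaf-to-root path lengths equal
  phy <- from_newick("((A:1,B:1):2,(C:2,D:2):1);")
  dm <- ape::cophenetic.phylo(phy)
  hc <- upgma(as.dist(dm))
  phy2 <- ape::as.phylo(hc)
  depths <- ape::node.depth.edgelength(phy2)[seq_len(4)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-12)
})

test_that("Newick serialization round trips and rejects malformed text", {
  for (seed in 1:20) {
    set.seed(seed)
    phy <- ape::rcoal(8)
    txt <- to_newick(phy)
    back <- from_newick(txt)
    expect_equal(sort(back$tip.label), sort(phy$tip.label))
    d1 <- ape::cophenetic.phylo(phy); d2 <- ape::cophenetic.phylo(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  }
  expect_error(from_newick("((A:1,B:1):2;"), "parse error")
})

test_that("outlier animals are pruned to the largest pure clade and breeds collapse", {
  # breed X split 8 + 2 across the tree; breed Y pure
  txt <- paste0("(((x1:1,x2:1):1,((x3:1,x4:1):0.5,(x5:1,(x6:0.5,(x7:0.2,",
                "x8:0.2):0.3):0.5):1):1):2,((y1:1,y2:1):1,(x9:1,x10:1):1):2);")
  phy <- from_newick(txt)
  breed_of <- stats::setNames(c(rep("X", 10), rep("Y", 2)),
                              c(paste0("x", 1:10), paste0("y", 1:2)))
  res <- prune_outlier_animals(phy, breed_of)
  expect_setequal(res$removed, c("x9", "x10"))
  expect_setequal(res$kept, c(paste0("x", 1:8), "y1", "y2"))
  expect_setequal(res$collapsed$tip.label, c("X", "Y"))
  expect_equal(ape::Ntip(res$collapsed), 2)

  # a fully pure breed loses nothing
  phy2 <- from_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  res2 <- prune_outlier_animals(
    phy2, stats::setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2")))
  expect_equal(length(res2$removed), 0)
})

test_that("the GRM behaves like VanRaden method 1", {
  co <- sim_balding_nichols(sim_config(
    n_pops = 1, n_per_pop = 30, chrom_lengths = c(chr1 = 3e6),
    site_density = 1 / 1000, fst = 0, seed = 61))$cohort
  G <- grm(co)
  expect_equal(G, t(G))
  # centering by sample frequencies constrains the off-diagonal mean of an
  # unrelated panel to about -1/(n-1) rather than exactly 0
  off <- G[upper.tri(G)]
  n <- nrow(G)
  expect_lt(abs(mean(off) + 1 / (n - 1)), 0.01)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)

  # duplicated sample: off-diagonal ~ diagonal
  dup <- new_cohort(co$variants,
                    data.frame(sample_id = c(co$samples$sample_id, "clone"),
                               population = "pop1"),
                    cbind(co$genotypes, co$genotypes[, 1]))
  G2 <- grm(dup)
  expect_equal(G2["pop1_1", "clone"], G2["pop1_1", "pop1_1"],
               tolerance = 1e-12)
})

test_that("greedy least-related selection avoids clones and is deterministic", {
  co <- sim_balding_nichols(sim_config(
    n_pops = 1, n_per_pop = 20, chrom_lengths = c(chr1 = 2e6),
    site_density = 1 / 1000, fst = 0, seed = 63))$cohort
  dup <- new_cohort(co$variants,
                    data.frame(sample_id = c(co$samples$sample_id, "clone"),
                               population = "pop1"),
                    cbind(co$genotypes, co$genotypes[, 1]))
  G <- grm(dup)
  sel <- least_related_subset(G, k = 15, seed = 3)
  expect_lte(sum(c("pop1_1", "clone") %in% sel), 1)
  expect_identical(least_related_subset(G, k = 15, seed = 3), sel)
  expect_setequal(least_related_subset(G, k = nrow(G), seed = 1),
                  rownames(G))
  expect_error(least_related_subset(G, k = nrow(G) + 1), "exceeds")
})

test_that("f3 is negative for admixed targets and positive for drifted ones", {
  sim <- sim_balding_nichols(sim_config(
    n_pops = 3, n_per_pop = 25, chrom_lengths = c(chr1 = 2e7),
    site_density = 1 / 1000, fst = c(0.2, 0.2, 0.1), seed = 83))
  co <- sim$cohort
  # target admixed at the frequency level between pop1 and pop2
  acA <- allele_counts(co, population = "pop1")
  acB <- allele_counts(co, population = "pop2")
  set.seed(84)
  nv <- n_variants(co)
  hC <- matrix(stats::rbinom(nv * 50, 1, (acA$p + acB$p) / 2), nv, 50)
  gC <- hC[, seq(1, 50, 2)] + hC[, seq(2, 50, 2)]
  colnames(gC) <- paste0("mix_", 1:25)
  co2 <- new_cohort(co$variants,
                    rbind(co$samples,
                          data.frame(sample_id = colnames(gC),
                                     population = "mix")),
                    cbind(co$genotypes, gC))
  adm <- f3(co2, "mix", "pop1", "pop2", block_variants = 4000)
  expect_lt(adm$f3, 0)
  expect_lt(adm$z, -3)
  # independently drifted target (its own Balding-Nichols draw)
  drift <- f3(co, "pop3", "pop1", "pop2", block_variants = 4000)
  expect_gt(drift$f3, 0)
  expect_gte(drift$n_blocks, 2)
  expect_error(f3(co, "pop3", "pop1", "pop2", block_variants = 1e6),
               "blocks")
})
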