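# Builders and independent oracles shared across the suite.

# Hand-built cohort from a genotype matrix (variants x samples).
toy_cohort <- function(geno, pops = NULL, pos = NULL, chrom = "chr1",
                       chrom_len = NULL) {
  geno <- as.matrix(geno)
  nv <- nrow(geno); ns <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(pops)) pops <- rep("popA", ns)
  ids <- paste0("s", seq_len(ns))
  new_cohort(
    data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "C"),
    data.frame(sample_id = ids, population = pops),
    geno,
    chrom_lengths = if (!is.null(chrom_len)) stats::setNames(chrom_len, chrom))
}

# Random unphased cohort for property tests.
random_cohort <- function(seed, nv = 50, ns = 10, miss = 0,
                          pops = NULL, chrom_len = nv * 200L) {
  set.seed(seed)
  g <- matrix(sample(0:2, nv * ns, replace = TRUE), nv, ns)
  if (miss > 0) g[runif(nv * ns) < miss] <- NA
  pos <- sort(sample.int(chrom_len, nv))
  toy_cohort(g, pops = pops, pos = pos, chrom_len = chrom_len)
}

# Brute-force per-site diversity: count differing pairs over all called
# allele pairs at a site.
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NaN)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / (n * (n - 1) / 2)
}

# Brute-force windowed pi from a cohort (percent scale).
oracle_windowed_pi <- function(cohort, population, window_bp) {
  keep <- cohort$samples$population == population
  g <- cohort$genotypes[, keep, drop = FALSE]
  win <- herdscan:::make_windows(
    herdscan:::effective_chrom_lengths(cohort), window_bp)
  win$value <- 0
  for (w in seq_len(nrow(win))) {
    sel <- which(cohort$variants$chrom == win$chrom[w] &
                   cohort$variants$pos >= win$start[w] &
                   cohort$variants$pos <= win$end[w])
    tot <- 0
    for (v in sel) {
      gv <- g[v, ]
      alleles <- unlist(lapply(gv[!is.na(gv)], function(x)
        switch(x + 1, c(0, 0), c(0, 1), c(1, 1))))
      pv <- oracle_site_pi(alleles)
      if (!is.nan(pv)) tot <- tot + pv
    }
    win$value[w] <- tot / window_bp * 100
  }
  win
}

# Exhaustive two-state HMM decoding by path enumeration (<= 15 sites).
oracle_viterbi <- function(emis, dists, model) {
  nv <- nrow(emis)
  stopifnot(nv <= 15)
  paths <- as.matrix(expand.grid(rep(list(1:2), nv)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(model$init[s[1]]) + log(emis[1, s[1]])
    if (nv > 1) for (i in 2:nv) {
      d <- dists[i - 1]
      p_ha <- 1 - exp(-model$az_enter_rate * d)
      p_ah <- 1 - exp(-model$az_exit_rate * d)
      tp <- matrix(c(1 - p_ha, p_ah, p_ha, 1 - p_ah), 2, 2)
      lp <- lp + log(tp[s[i - 1], s[i]]) + log(emis[i, s[i]])
    }
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(logp = best, path = unname(best_path))
}

# Independent UPGMA reference: at every step recompute all inter-cluster
# mean distances directly from the original leaf matrix (O(n^3) overall),
# with the same tie rule (lexicographically smallest sorted label pair).
oracle_upgma <- function(m) {
  labels <- rownames(m)
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- mean(m[clusters[[i]], clusters[[j]]])
      ki <- min(labels[clusters[[i]]]); kj <- min(labels[clusters[[j]]])
      key <- c(min(ki, kj), max(ki, kj))
      better <- dij < bestd ||
        (dij == bestd && (key[1] < bestkey[1] ||
                            (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (better) { best <- c(i, j); bestd <- dij; bestkey <- key }
    }
    merges[[length(merges) + 1]] <-
      sort(c(min(labels[clusters[[best[1]]]]),
             min(labels[clusters[[best[2]]]])))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Merge-label trace of an upgma()/hclust object, comparable with the oracle:
# for each step, the sorted pair of smallest-member labels of the two merged
# clusters.
hclust_merge_trace <- function(hc) {
  n <- length(hc$labels)
  key_of <- character(n - 1)
  trace <- vector("list", n - 1)
  key <- function(code) if (code < 0) hc$labels[-code] else key_of[code]
  for (s in seq_len(n - 1)) {
    k1 <- key(hc$merge[s, 1]); k2 <- key(hc$merge[s, 2])
    trace[[s]] <- sort(c(k1, k2))
    key_of[s] <- min(k1, k2)
  }
  trace
}

# Brute-force EHHS: partition haplotypes by their full allele string from
# the core to each extension, recompute homozygosity from scratch.
oracle_ehhs <- function(haps, positions, core, direction) {
  idx <- if (direction == "left") rev(seq_len(core)) else core:nrow(haps)
  n <- ncol(haps)
  strings <- rep("", n)
  out <- data.frame(pos = numeric(0), value = numeric(0))
  hh0 <- NULL
  for (i in idx) {
    strings <- paste(strings, haps[i, ], sep = ",")
    tab <- table(strings)
    hh <- sum(tab * (tab - 1)) / (n * (n - 1))
    if (is.null(hh0)) hh0 <- hh
    out <- rbind(out, data.frame(pos = positions[i], value = hh / hh0))
  }
  out
}

# Fraction of positions (1 bp grid would be slow: use the planted marker
# grid) of truth segments covered by called segments, and vice versa.
interval_cover <- function(points, segments) {
  cov <- rep(FALSE, length(points))
  for (i in seq_len(nrow(segments)))
    cov <- cov | (points >= segments$start[i] & points <= segments$end[i])
  cov
}
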