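#' Per-site terms of Hudson's F_ST estimator
#'
#' Ratio-of-averages forms: numerator
#' `N = (p1 - p2)^2 - p1 q1 / (n1 - 1) - p2 q2 / (n2 - 1)` and denominator
#' `D = p1 (1 - p2) + p2 (1 - p1)`, with `p` the alternate-allele frequency
#' and `n` the called allele count per population. Sites with `n < 2` in
#' either population are excluded (`NA` terms).
#'
#' @param ac1,ac2 allele-count data.frames (see [allele_counts()]) for the
#'   two populations, row-aligned
#' @return data.frame with columns `N` and `D`
#' @export
hudson_site <- function(ac1, ac2) {
  ok <- ac1$n >= 2 & ac2$n >= 2
  p1 <- ac1$p; p2 <- ac2$p
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (ac1$n - 1) - p2 * (1 - p2) / (ac2$n - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  N[!ok] <- NA_real_; D[!ok] <- NA_real_
  data.frame(N = N, D = D)
}

#' Genome-wide Hudson F_ST between two populations
#'
#' Restricts to variants segregating in the pooled pair (unless
#' `presubset = FALSE`), then returns `sum(N) / sum(D)` over usable sites
#' (ratio of averages, not average of ratios).
#'
#' @param cohort a `cohort`
#' @param popA,popB population labels
#' @param presubset apply [segregating_subset()] internally (default TRUE)
#' @return scalar F_ST estimate
#' @export
fst_genomewide <- function(cohort, popA, popB, presubset = TRUE) {
  if (presubset) cohort <- segregating_subset(cohort, c(popA, popB))
  terms <- hudson_site(allele_counts(cohort, population = popA),
                       allele_counts(cohort, population = popB))
  ok <- !is.na(terms$N) & !is.na(terms$D)
  if (!any(ok)) stop("no usable sites for F_ST")
  sum(terms$N[ok]) / sum(terms$D[ok])
}

#' Pairwise F_ST of a focal population against others
#'
#' One [fst_genomewide()] per pair, each on its own segregating subset,
#' sorted by increasing F_ST.
#'
#' @param cohort a `cohort`
#' @param focal focal population label
#' @param others other population labels (default: all non-focal
#'   populations)
#' @return data.frame `population`, `fst`, ascending
#' @export
fst_matrix <- function(cohort, focal, others = NULL) {
  if (is.null(others))
    others <- setdiff(unique(cohort$samples$population), focal)
  fst <- vapply(others, function(b) fst_genomewide(cohort, focal, b),
                numeric(1))
  out <- data.frame(population = others, fst = fst,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$fst), , drop = FALSE]
}

#' Windowed Hudson F_ST
#'
#' Per fixed-width window, the within-window ratio of averages
#' `sum(N) / sum(D)`; windows with fewer than `min_snps` usable variants are
#' omitted.
#'
#' @inheritParams fst_genomewide
#' @param window_bp window width in bp (default 10000)
#' @param min_snps minimum usable variants per window (default 5)
#' @return window table (`chrom`, `start`, `end`, `n_snps`, `value`), with
#'   attribute `statistic = "fst"`
#' @export
fst_windows <- function(cohort, popA, popB, window_bp = 10000, min_snps = 5,
                        presubset = TRUE) {
  if (presubset) cohort <- segregating_subset(cohort, c(popA, popB))
  terms <- hudson_site(allele_counts(cohort, population = popA),
                       allele_counts(cohort, population = popB))
  ok <- !is.na(terms$N)
  win <- make_windows(effective_chrom_lengths(cohort), window_bp)
  key_w <- paste(win$chrom, (win$start - 1) %/% window_bp)
  key_v <- paste(cohort$variants$chrom,
                 (cohort$variants$pos - 1) %/% window_bp)[ok]
  idx <- factor(match(key_v, key_w), levels = seq_len(nrow(win)))
  n <- as.integer(table(idx))
  sN <- tapply(terms$N[ok], idx, sum); sN[is.na(sN)] <- 0
  sD <- tapply(terms$D[ok], idx, sum); sD[is.na(sD)] <- 0
  win$n_snps <- n
  win$value <- ifelse(as.numeric(sD) != 0, as.numeric(sN) / as.numeric(sD),
                      NA_real_)
  win <- win[n >= min_snps & !is.na(win$value), , drop = FALSE]
  rownames(win) <- NULL
  structure(win, statistic = "fst", window_bp = window_bp)
}

#' Select the top fraction of windows and merge adjacent ones into regions
#'
#' Selects the `ceiling(top_fraction * N)` highest-value windows (ties
#' resolved deterministically by chromosome and start); the reported
#' threshold is the smallest selected value. Adjacent selected windows
#' (`end + 1 == start` on the same chromosome) merge into one region.
#'
#' @param windows a window table (e.g. [fst_windows()])
#' @param top_fraction fraction selected (default 1e-4, the top 0.01 %)
#' @return list with `threshold`, `selected` (the selected windows) and
#'   `regions` (data.frame `chrom`, `start`, `end`, `n_windows`, `max_value`)
#' @export
top_fraction_windows <- function(windows, top_fraction = 1e-4) {
  N <- nrow(windows)
  if (N == 0) stop("empty window table")
  k <- min(N, ceiling(top_fraction * N))
  ord <- order(-windows$value, windows$chrom, windows$start)
  sel <- windows[sort(ord[seq_len(k)]), , drop = FALSE]
  threshold <- min(sel$value)
  regions <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(s$start[-1] != s$end[-nrow(s)] + 1)))
    for (g in unique(grp)) {
      r <- s[grp == g, , drop = FALSE]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = r$start[1L], end = r$end[nrow(r)],
        n_windows = nrow(r), max_value = max(r$value),
        stringsAsFactors = FALSE)
    }
  }
  list(threshold = threshold, selected = sel,
       regions = do.call(rbind, regions))
}

#' Manhattan distance matrix between samples
#'
#' `d(i, j) = sum |g_i - g_j|` over pairwise-complete sites, rescaled by
#' (total sites / complete sites) so missingness does not shrink distances
#' (the rescaling of [stats::dist()]).
#'
#' @param cohort a `cohort`
#' @return symmetric matrix with sample ids as dimnames
#' @export
manhattan_matrix <- function(cohort) {
  if (n_samples(cohort) < 2) stop("need at least two samples")
  d <- stats::dist(t(cohort$genotypes), method = "manhattan")
  m <- as.matrix(d)
  dimnames(m) <- list(cohort$samples$sample_id, cohort$samples$sample_id)
  if (anyNA(m)) stop("a sample pair has zero pairwise-complete sites")
  m
}

#' UPGMA hierarchical clustering with deterministic ties
#'
#' Iteratively merges the closest pair of clusters; the distance of a new
#' cluster to the rest is the size-weighted arithmetic mean of its parts,
#' and the node height is half the merge distance. Ties on the minimum
#' distance are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member label), which makes
#' the merge order reproducible.
#'
#' @param d a `dist` or symmetric matrix with labels
#' @return an `hclust`-compatible object (classes `upgma`, `hclust`) whose
#'   `$height` holds merge distances; ultrametric node heights are
#'   `$height / 2` (see [to_newick()])
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  labels <- rownames(m)
  n <- nrow(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  stopifnot(n >= 2, isSymmetric(unname(m)))
  D <- m
  active <- seq_len(n)
  key <- labels               # smallest member label per cluster
  size <- rep(1L, n)
  code <- -seq_len(n)         # hclust merge codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    sub[upper.tri(sub, diag = TRUE)] <- Inf
    dmin <- min(sub)
    hits <- which(sub == dmin, arr.ind = TRUE)
    # tie-break: lexicographically smallest sorted label pair
    k1 <- pmin(key[active[hits[, 1]]], key[active[hits[, 2]]])
    k2 <- pmax(key[active[hits[, 1]]], key[active[hits[, 2]]])
    pick <- order(k1, k2)[1L]
    ia <- active[hits[pick, 2]]; ib <- active[hits[pick, 1]]  # col < row
    if (key[ib] < key[ia]) { tmp <- ia; ia <- ib; ib <- tmp }
    merge[step, ] <- c(code[ia], code[ib])  # smaller-label cluster first
    height[step] <- dmin
    # weighted-mean update onto slot ia
    rest <- setdiff(active, c(ia, ib))
    if (length(rest))
      D[ia, rest] <- D[rest, ia] <-
        (size[ia] * D[ia, rest] + size[ib] * D[ib, rest]) /
        (size[ia] + size[ib])
    size[ia] <- size[ia] + size[ib]
    key[ia] <- min(key[ia], key[ib])
    code[ia] <- step
    active <- setdiff(active, ib)
  }
  order_ <- upgma_order(merge, n)
  structure(list(merge = merge, height = height, order = order_,
                 labels = labels, method = "upgma",
                 call = match.call(), dist.method = "user"),
            class = c("upgma", "hclust"))
}

# Leaf ordering for plotting / hclust validity.
upgma_order <- function(merge, n) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  walk(n - 1L)
}

#' Node heights of an ultrametric clustering
#'
#' @param tree an [upgma()] / `hclust` object
#' @return numeric vector: half of each merge distance
#' @export
node_heights <- function(tree) tree$height / 2

#' Serialize / parse dendrograms as Newick
#'
#' `to_newick()` accepts an [upgma()] result (converted via
#' [ape::as.phylo()], branch lengths = height differences) or an existing
#' `phylo`; `from_newick()` parses Newick text to a `phylo`. The round trip
#' is lossless to well below 1e-9 on unit-scale branch lengths.
#'
#' @param tree `hclust`/`upgma` or `ape::phylo`
#' @return `to_newick`: a Newick string; `from_newick`: a `phylo`
#' @export
to_newick <- function(tree) {
  phy <- if (inherits(tree, "hclust")) ape::as.phylo(tree) else tree
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy, digits = 12)
}

#' @rdname to_newick
#' @param text Newick text
#' @export
from_newick <- function(text) {
  open <- lengths(regmatches(text, gregexpr("\\(", text)))
  close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (open != close)
    stop(sprintf("Newick parse error: %d '(' vs %d ')'", open, close))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error near character 1")
  phy
}

#' Remove animals clustering outside their breed's main clade
#'
#' For every breed, the largest monophyletic clade whose leaves are all of
#' that breed is kept; leaves of the breed outside it are removed. The
#' surviving clade of each breed is then collapsed to a single leaf labelled
#' with the breed name (the branch of a deterministic representative, the
#' lexicographically smallest member, is retained).
#'
#' @param tree `hclust`/`upgma` or `phylo` with sample-id tip labels
#' @param breed_of named character vector mapping sample id to breed
#' @return list with `kept` (sample ids), `removed` (sample ids) and
#'   `collapsed` (a `phylo` with one leaf per breed)
#' @export
prune_outlier_animals <- function(tree, breed_of) {
  phy <- if (inherits(tree, "hclust")) ape::as.phylo(tree) else tree
  tips <- phy$tip.label
  if (!all(tips %in% names(breed_of))) stop("every leaf must be labelled")
  breeds <- breed_of[tips]
  parts <- c(lapply(seq_along(tips), function(i) i),  # singleton "clades"
             ape::prop.part(phy))
  kept <- character(0); removed <- character(0)
  rep_tip <- character(0)
  for (b in unique(breeds)) {
    bt <- which(breeds == b)
    pure <- Filter(function(p) all(breeds[p] == b), parts)
    sizes <- lengths(pure)
    best <- pure[sizes == max(sizes)]
    mins <- vapply(best, function(p) min(tips[p]), "")
    chosen <- best[[order(mins)[1L]]]
    kept <- c(kept, tips[chosen])
    removed <- c(removed, tips[setdiff(bt, chosen)])
    rep_tip[b] <- min(tips[chosen])
  }
  pruned <- ape::drop.tip(phy, removed)
  drop_more <- setdiff(pruned$tip.label, rep_tip)
  collapsed <- if (length(drop_more)) ape::drop.tip(pruned, drop_more) else pruned
  collapsed$tip.label <-
    names(rep_tip)[match(collapsed$tip.label, rep_tip)]
  list(kept = kept, removed = removed, collapsed = collapsed)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' Dosages are centred by twice the cohort allele frequency and the
#' cross-product scaled by `2 * sum(p * (1 - p))` over the polymorphic sites
#' used; missing genotypes contribute zero after centring. Under
#' Hardy-Weinberg, unrelated pairs have expectation 0 and diagonals
#' approximately `1 + F`.
#'
#' @param cohort a `cohort`
#' @return symmetric matrix with sample ids as dimnames
#' @export
grm <- function(cohort) {
  ac <- allele_counts(cohort)
  poly <- ac$n_alt > 0 & ac$n_alt < ac$n
  if (!any(poly)) stop("all sites are monomorphic")
  g <- cohort$genotypes[poly, , drop = FALSE]
  p <- ac$p[poly]
  Z <- g - 2 * p
  Z[is.na(Z)] <- 0
  G <- crossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(cohort$samples$sample_id, cohort$samples$sample_id)
  G
}

#' Greedy selection of the k least-related samples
#'
#' Starts from a seeded random sample and repeatedly adds the sample with
#' the smallest mean genomic relationship to the current set (ties by
#' smallest sample id). Deterministic given the seed.
#'
#' @param grm matrix from [grm()]
#' @param k subset size (default 50)
#' @param seed integer seed for the random starting animal
#' @return character vector of selected sample ids (selection order)
#' @export
least_related_subset <- function(grm, k = 50L, seed = 1L) {
  n <- nrow(grm)
  ids <- rownames(grm)
  if (k > n) stop("k exceeds the number of samples")
  set.seed(seed)
  sel <- sample.int(n, 1L)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mrel <- rowMeans(grm[cand, sel, drop = FALSE])
    best <- cand[mrel == min(mrel)]
    sel <- c(sel, best[order(ids[best])[1L]])
  }
  ids[sel]
}

#' f3 admixture statistic with block-jackknife error
#'
#' Site term `(p_C - p_A)(p_C - p_B) - p_C (1 - p_C) / (n_C - 1)` (the
#' heterozygosity bias correction applies to the target only); f3 is the
#' mean over usable sites. Standard error comes from a leave-one-block-out
#' jackknife over consecutive blocks of `block_variants` sites (a trailing
#' block shorter than half the nominal size is merged into its neighbour).
#' Significantly negative `Z = f3 / SE` indicates the target is admixed
#' between the two sources.
#'
#' @param cohort a `cohort`
#' @param target target population C
#' @param source_a,source_b source populations A and B
#' @param block_variants variants per jackknife block (default 10000)
#' @return list with `f3`, `se`, `z`, `n_blocks`, `n_sites`,
#'   `block_variants`
#' @export
f3 <- function(cohort, target, source_a, source_b, block_variants = 10000L) {
  acC <- allele_counts(cohort, population = target)
  acA <- allele_counts(cohort, population = source_a)
  acB <- allele_counts(cohort, population = source_b)
  ok <- acC$n >= 2 & acA$n >= 1 & acB$n >= 1
  t <- ((acC$p - acA$p) * (acC$p - acB$p) -
          acC$p * acC$q / (acC$n - 1))[ok]
  ns <- length(t)
  if (ns < 2) stop("need at least two usable sites")
  blk <- (seq_len(ns) - 1L) %/% block_variants + 1L
  B <- max(blk)
  if (B >= 2 && sum(blk == B) < block_variants / 2) {
    blk[blk == B] <- B - 1L
    B <- B - 1L
  }
  if (B < 2) stop("need at least two jackknife blocks; lower block_variants")
  f3_all <- mean(t)
  S <- sum(t)
  loo <- vapply(seq_len(B), function(b) {
    inb <- blk == b
    (S - sum(t[inb])) / (ns - sum(inb))
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(f3 = f3_all, se = se, z = if (se > 0) f3_all / se else NaN,
       n_blocks = B, n_sites = ns, block_variants = block_variants)
}
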