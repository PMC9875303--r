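#' Two-state autozygosity HMM parameters
#'
#' Hidden states are HW (Hardy-Weinberg / non-autozygous) and AZ
#' (autozygous). Transitions between adjacent sites at distance `d` bp are
#' `P(HW -> AZ) = 1 - exp(-az_enter_rate * d)` and
#' `P(AZ -> HW) = 1 - exp(-az_exit_rate * d)`; the exit rate defaults to a
#' recombination rate of 1e-8 per bp (1 cM/Mb). Initial state probabilities
#' default to the stationary distribution of the two rates.
#'
#' @param az_enter_rate per-bp rate of entering autozygosity
#'   (default 6.6e-9)
#' @param az_exit_rate per-bp rate of leaving autozygosity (default 1e-8)
#' @param error_rate probability `eps` of observing a heterozygous call at
#'   a truly autozygous site (default 0.01); must be in `[0, 0.5)`
#' @param eps_hw symmetric het-miscall mass added to the homozygous
#'   Hardy-Weinberg emissions (`q^2 + p q eps_hw`, `p^2 + p q eps_hw`);
#'   default 0 gives pure Hardy-Weinberg emissions
#' @param init optional length-2 vector `c(hw, az)` of initial state
#'   probabilities
#' @return list of class `roh_model`
#' @export
roh_model <- function(az_enter_rate = 6.6e-9, az_exit_rate = 1e-8,
                      error_rate = 0.01, eps_hw = 0, init = NULL) {
  stopifnot(az_enter_rate > 0, az_exit_rate > 0,
            error_rate >= 0, error_rate < 0.5, eps_hw >= 0)
  if (is.null(init)) {
    tot <- az_enter_rate + az_exit_rate
    init <- c(hw = az_exit_rate / tot, az = az_enter_rate / tot)
  }
  structure(list(az_enter_rate = az_enter_rate, az_exit_rate = az_exit_rate,
                 error_rate = error_rate, eps_hw = eps_hw, init = init),
            class = "roh_model")
}

# Emission probabilities for one sample's genotypes given alt frequency p.
# Columns: hw, az. Missing genotypes emit 1 in both states.
roh_emissions <- function(g, p, model) {
  q <- 1 - p
  eps <- model$error_rate
  e_hw <- rep(1, length(g)); e_az <- rep(1, length(g))
  hom_ref <- !is.na(g) & g == 0L
  het <- !is.na(g) & g == 1L
  hom_alt <- !is.na(g) & g == 2L
  e_hw[hom_ref] <- q[hom_ref]^2 + p[hom_ref] * q[hom_ref] * model$eps_hw
  e_hw[het] <- 2 * p[het] * q[het]
  e_hw[hom_alt] <- p[hom_alt]^2 + p[hom_alt] * q[hom_alt] * model$eps_hw
  e_az[hom_ref] <- (1 - eps) * q[hom_ref]
  e_az[het] <- eps
  e_az[hom_alt] <- (1 - eps) * p[hom_alt]
  cbind(hw = e_hw, az = e_az)
}

# Viterbi decoding over one chromosome. Returns integer state path
# (1 = HW, 2 = AZ).
roh_viterbi <- function(emis, dists, model) {
  nv <- nrow(emis)
  le <- log(emis)
  delta <- matrix(-Inf, nv, 2)
  back <- matrix(1L, nv, 2)
  delta[1, ] <- log(model$init) + le[1, ]
  if (nv > 1) for (i in 2:nv) {
    d <- dists[i - 1]
    p_ha <- -expm1(-model$az_enter_rate * d)  # HW -> AZ
    p_ah <- -expm1(-model$az_exit_rate * d)   # AZ -> HW
    lt <- log(matrix(c(1 - p_ha, p_ah, p_ha, 1 - p_ah), 2, 2))
    for (s in 1:2) {
      cand <- delta[i - 1, ] + lt[, s]
      back[i, s] <- which.max(cand)
      delta[i, s] <- cand[back[i, s]] + le[i, s]
    }
  }
  path <- integer(nv)
  path[nv] <- which.max(delta[nv, ])
  if (nv > 1) for (i in (nv - 1):1) path[i] <- back[i + 1, path[i + 1]]
  path
}

# Scaled forward-backward; returns per-site posterior P(AZ).
roh_posterior <- function(emis, dists, model) {
  nv <- nrow(emis)
  al <- matrix(0, nv, 2); be <- matrix(0, nv, 2)
  sc <- numeric(nv)
  trans <- function(d) {
    p_ha <- -expm1(-model$az_enter_rate * d)
    p_ah <- -expm1(-model$az_exit_rate * d)
    matrix(c(1 - p_ha, p_ah, p_ha, 1 - p_ah), 2, 2)
  }
  a <- model$init * emis[1, ]
  sc[1] <- sum(a); al[1, ] <- a / sc[1]
  if (nv > 1) for (i in 2:nv) {
    a <- (al[i - 1, ] %*% trans(dists[i - 1]))[1, ] * emis[i, ]
    sc[i] <- sum(a); al[i, ] <- a / sc[i]
  }
  be[nv, ] <- 1
  if (nv > 1) for (i in (nv - 1):1) {
    b <- trans(dists[i]) %*% (emis[i + 1, ] * be[i + 1, ])
    be[i, ] <- b[, 1] / sc[i + 1]
  }
  g <- al * be
  g[, 2] / rowSums(g)
}

#' Call runs of homozygosity for one sample
#'
#' Viterbi-decodes the two-state HMM of [roh_model()] over each chromosome
#' using hard genotype calls and per-site allele frequencies; maximal runs
#' of the AZ state become segments spanning the first to last AZ site. Sites
#' with no called alleles in the frequency scope are skipped; missing
#' genotypes are uninformative (emit 1 in both states).
#'
#' @param cohort a `cohort`
#' @param sample sample id
#' @param model a [roh_model()]
#' @param freqs optional data.frame of per-site allele counts as returned by
#'   [allele_counts()] (rows aligned with the cohort's variants); by default
#'   computed at `freq_scope`
#' @param freq_scope `"population"` (the sample's own population, default)
#'   or `"cohort"`
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `length` (`end - start + 1`), `n_snps`, `mean_posterior` (mean per-site
#'   posterior probability of autozygosity inside the segment).
#'
#' @details Sites that are monomorphic in the frequency scope, or have no
#'   called allele there, are uninformative: a fixed site predicts the same
#'   homozygote under both states, so such sites emit 1 in both states
#'   (like missing genotypes) while still occupying their position in the
#'   transition chain. Decoded runs therefore begin and end at informative
#'   sites and inter-marker distances are not distorted by the filter.
#' @export
roh_call <- function(cohort, sample, model = roh_model(), freqs = NULL,
                     freq_scope = c("population", "cohort")) {
  freq_scope <- match.arg(freq_scope)
  j <- match(sample, cohort$samples$sample_id)
  if (is.na(j)) stop("unknown sample: ", sample)
  if (is.null(freqs)) {
    freqs <- if (freq_scope == "population")
      allele_counts(cohort, population = cohort$samples$population[j])
    else allele_counts(cohort)
  }
  segs <- list()
  for (ch in unique(cohort$variants$chrom)) {
    sel <- which(cohort$variants$chrom == ch)
    if (!length(sel)) next
    g <- cohort$genotypes[sel, j]
    pos <- cohort$variants$pos[sel]
    emis <- roh_emissions(g, freqs$p[sel], model)
    uninf <- freqs$n[sel] == 0 | freqs$p[sel] <= 0 | freqs$p[sel] >= 1
    emis[uninf, ] <- 1
    dists <- diff(pos)
    path <- roh_viterbi(emis, dists, model)
    if (!any(path == 2L)) next
    post <- roh_posterior(emis, dists, model)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    az <- which(r$values == 2L)
    for (k in az) {
      i0 <- starts[k]; i1 <- ends[k]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample, chrom = ch,
        start = pos[i0], end = pos[i1],
        length = pos[i1] - pos[i0] + 1,
        n_snps = i1 - i0 + 1L,
        mean_posterior = mean(post[i0:i1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      length = numeric(0), n_snps = integer(0),
                      mean_posterior = numeric(0)))
  do.call(rbind, segs)
}

#' Genomic inbreeding from RoH length classes
#'
#' `F_RoH = sum(L_RoH) / L_genome`, computed per minimum-length class:
#' for class `c`, only segments with `length >= c` contribute. Values are
#' monotone non-increasing across increasing classes.
#'
#' @param segments segment data.frame from [roh_call()] (may contain several
#'   samples)
#' @param classes minimum segment lengths in bp
#'   (default 50 kb, 100 kb, 1 Mb, 2 Mb, 4 Mb)
#' @param l_genome genome length covered by SNPs, bp (default the cattle
#'   autosome total 2,487,849,970 bp)
#' @return data.frame with one row per sample and one column per class
#'   (`froh_50kb`, ...), plus `l_genome`.
#' @export
f_roh <- function(segments, classes = c(5e4, 1e5, 1e6, 2e6, 4e6),
                  l_genome = 2487849970) {
  stopifnot(l_genome > 0)
  ids <- unique(segments$sample_id)
  if (!length(ids)) ids <- character(0)
  lab <- paste0("froh_", ifelse(classes >= 1e6,
                                paste0(classes / 1e6, "mb"),
                                paste0(classes / 1e3, "kb")))
  out <- lapply(ids, function(s) {
    len <- segments$length[segments$sample_id == s]
    vals <- vapply(classes, function(c0) sum(len[len >= c0]) / l_genome,
                   numeric(1))
    df <- as.data.frame(as.list(stats::setNames(vals, lab)))
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), df,
          l_genome = l_genome)
  })
  if (!length(out))
    return(cbind(data.frame(sample_id = character(0)),
                 stats::setNames(as.data.frame(
                   matrix(numeric(0), 0, length(classes))), lab),
                 data.frame(l_genome = numeric(0))))
  do.call(rbind, out)
}

#' Per-variant frequency of lying inside a RoH
#'
#' For each variant, the number of animals of a population with at least one
#' RoH segment covering the position, divided by the population size.
#'
#' @param segments segments of all animals of one population ([roh_call()]
#'   output, row-bound)
#' @param cohort the `cohort` the segments were called on
#' @param population population label (defines the denominator)
#' @return data.frame `chrom`, `pos`, `n_in_roh`, `freq`
#' @export
roh_snp_freq <- function(segments, cohort, population) {
  ids <- cohort$samples$sample_id[cohort$samples$population == population]
  if (!length(ids)) stop("unknown population: ", population)
  nv <- n_variants(cohort)
  count <- integer(nv)
  v <- cohort$variants
  for (s in intersect(ids, unique(segments$sample_id))) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    covered <- rep(FALSE, nv)
    for (i in seq_len(nrow(seg))) {
      covered <- covered | (v$chrom == seg$chrom[i] &
                              v$pos >= seg$start[i] & v$pos <= seg$end[i])
    }
    count <- count + covered
  }
  data.frame(chrom = v$chrom, pos = v$pos, n_in_roh = count,
             freq = count / length(ids), stringsAsFactors = FALSE)
}

#' RoH islands from SNP-in-RoH frequencies
#'
#' Selects the `ceiling(top_fraction * N)` variants with the highest
#' SNP-in-RoH frequency (the reported threshold is the smallest selected
#' value), then merges consecutive selected variants on a chromosome into
#' islands when separated by at most `max_gap` bp. Internal gaps larger than
#' `gap_report` are recorded.
#'
#' @param freqs data.frame from [roh_snp_freq()]
#' @param top_fraction fraction of variants forming islands (default 5e-4,
#'   i.e. the top 0.05 %)
#' @param max_gap maximum bp between consecutive member SNPs of one island
#'   (default 100 kb)
#' @param gap_report record internal gaps longer than this (default 10 kb)
#' @return list with `threshold` and `islands` (data.frame `chrom`, `start`,
#'   `end`, `n_snps`, `peak_freq`, `n_gaps`; attribute `"gaps"` holds the
#'   recorded gap intervals).
#' @export
roh_islands <- function(freqs, top_fraction = 5e-4, max_gap = 1e5,
                        gap_report = 1e4) {
  N <- nrow(freqs)
  if (N == 0) stop("empty frequency table")
  k <- min(N, ceiling(top_fraction * N))
  if (length(unique(freqs$freq)) == 1L)
    warning("all SNP-in-RoH frequencies are equal; the whole set is flagged")
  ord <- order(-freqs$freq, freqs$chrom, freqs$pos)
  members <- sort(ord[seq_len(k)])
  threshold <- min(freqs$freq[members])
  mem <- freqs[members, , drop = FALSE]
  islands <- list(); gaps <- list()
  for (ch in unique(mem$chrom)) {
    m <- mem[mem$chrom == ch, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    brk <- c(0L, which(diff(m$pos) > max_gap), nrow(m))
    for (b in seq_len(length(brk) - 1L)) {
      rows <- (brk[b] + 1L):brk[b + 1L]
      g <- m[rows, , drop = FALSE]
      dg <- diff(g$pos)
      big <- which(dg > gap_report)
      if (length(big))
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ch, island_start = g$pos[1L],
          gap_start = g$pos[big] + 1, gap_end = g$pos[big + 1L] - 1,
          stringsAsFactors = FALSE)
      islands[[length(islands) + 1L]] <- data.frame(
        chrom = ch, start = g$pos[1L], end = g$pos[nrow(g)],
        n_snps = nrow(g), peak_freq = max(g$freq),
        n_gaps = length(big), stringsAsFactors = FALSE)
    }
  }
  isl <- do.call(rbind, islands)
  attr(isl, "gaps") <- if (length(gaps)) do.call(rbind, gaps)
  list(threshold = threshold, islands = isl)
}
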