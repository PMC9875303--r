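#' Per-site pairwise nucleotide diversity
#'
#' Mean number of differences over all pairs of called alleles at one site:
#' `n_ref * n_alt / choose(n, 2) = 2 p q n / (n - 1)`. Undefined (`NaN`)
#' when fewer than two alleles are called; such sites are skipped by
#' [windowed_pi()].
#'
#' @param n_ref,n_alt called reference / alternate allele counts
#'   (vectorized)
#' @return per-site diversity values
#' @export
site_pairwise_diversity <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  ifelse(n >= 2, n_ref * n_alt / (n * (n - 1) / 2), NaN)
}

#' Windowed nucleotide diversity (percent)
#'
#' Tiles each chromosome with fixed windows and reports, per window, the sum
#' of per-site pairwise diversities divided by the window width in bp,
#' multiplied by 100 so values are percentages. Windows without SNPs get 0.
#'
#' @param cohort a `cohort`
#' @param population population whose samples enter the allele counts
#' @param window_bp window width in bp (default 10000)
#' @return a window table: data.frame `chrom`, `start`, `end`, `n_snps`,
#'   `value`, with attributes `statistic = "pi_percent"` and `window_bp`.
#' @export
windowed_pi <- function(cohort, population, window_bp = 10000) {
  ac <- allele_counts(cohort, population = population)
  pi_site <- site_pairwise_diversity(ac$n_ref, ac$n_alt)
  usable <- !is.nan(pi_site)
  win <- make_windows(effective_chrom_lengths(cohort), window_bp)
  win$n_snps <- 0L
  win$value <- 0
  key_w <- paste(win$chrom, (win$start - 1) %/% window_bp)
  key_v <- paste(cohort$variants$chrom,
                 (cohort$variants$pos - 1) %/% window_bp)[usable]
  idx <- match(key_v, key_w)
  if (length(idx)) {
    cnt <- table(factor(idx, levels = seq_len(nrow(win))))
    win$n_snps <- as.integer(cnt)
    sums <- tapply(pi_site[usable], factor(idx, levels = seq_len(nrow(win))),
                   sum)
    sums[is.na(sums)] <- 0
    win$value <- as.numeric(sums) / window_bp * 100
  }
  structure(win, statistic = "pi_percent", window_bp = window_bp)
}

#' Chromosome and genome summaries of windowed diversity
#'
#' Means and medians over all windows (zero-SNP windows included by
#' default, since the windows tile the genome).
#'
#' @param windows a window table from [windowed_pi()]
#' @param include_empty include windows with `n_snps == 0` (default TRUE)
#' @return list with `per_chromosome` (data.frame `chrom`, `mean`, `median`,
#'   `n_windows`) and `genome` (`mean`, `median`, `n_windows`), on the same
#'   (percent) scale as the input.
#' @export
pi_summaries <- function(windows, include_empty = TRUE) {
  if (nrow(windows) == 0) stop("empty window table")
  w <- if (include_empty) windows else windows[windows$n_snps > 0, , drop = FALSE]
  per <- do.call(rbind, lapply(split(w$value, w$chrom), function(v)
    data.frame(mean = mean(v), median = stats::median(v),
               n_windows = length(v))))
  per <- data.frame(chrom = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_chromosome = per,
       genome = data.frame(mean = mean(w$value),
                           median = stats::median(w$value),
                           n_windows = nrow(w)))
}

#' Per-individual observed and expected heterozygosity and F_Hom
#'
#' For each sample of a population: `o_het` is the count of heterozygous
#' calls, `o_hom = n_used - o_het` the homozygous count over the sample's
#' called sites, and `e_hom` the sum over those sites of
#' `1 - 2 p q n / (n - 1)` with unbiased allele frequencies. Rates `h_o` and
#' `h_e` are reported relative to a fixed external denominator (typically
#' the cohort-wide variant count) so breeds with different numbers of
#' segregating sites remain comparable; the same denominator is the "total
#' number of variants" in F_Hom.
#'
#' @param cohort a `cohort`
#' @param population population label
#' @param denominator fixed variant-count denominator; defaults to the
#'   number of variants in the cohort
#' @param freq_scope `"population"` (default: allele frequencies from the
#'   focal population) or `"cohort"` (all samples)
#' @return data.frame with one row per sample: `sample_id`, `population`,
#'   `n_used`, `o_het`, `o_hom`, `e_hom`, `h_o`, `h_e`, `f_hom`.
#' @export
individual_heterozygosity <- function(cohort, population,
                                      denominator = NULL,
                                      freq_scope = c("population", "cohort")) {
  freq_scope <- match.arg(freq_scope)
  if (is.null(denominator)) denominator <- n_variants(cohort)
  if (denominator <= 0) stop("denominator must be positive")
  ac <- if (freq_scope == "population")
    allele_counts(cohort, population = population) else allele_counts(cohort)
  hom_exp_site <- ifelse(ac$n >= 2,
                         1 - 2 * ac$p * ac$q * ac$n / (ac$n - 1), NA_real_)
  j <- which(cohort$samples$population == population)
  if (!length(j)) stop("unknown population: ", population)
  out <- lapply(j, function(s) {
    g <- cohort$genotypes[, s]
    called <- !is.na(g) & !is.na(hom_exp_site)
    n_used <- sum(called)
    o_het <- sum(g[called] == 1L)
    e_hom <- sum(hom_exp_site[called])
    data.frame(sample_id = cohort$samples$sample_id[s],
               population = population,
               n_used = n_used, o_het = o_het, o_hom = n_used - o_het,
               e_hom = e_hom,
               h_o = o_het / denominator,
               h_e = (n_used - e_hom) / denominator,
               f_hom = f_hom(n_used - o_het, e_hom, denominator),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Excess-of-homozygosity inbreeding coefficient
#'
#' Method-of-moments estimator
#' `F_Hom = (o_hom - e_hom) / (total_variants - e_hom)`.
#'
#' @param o_hom observed homozygous count
#' @param e_hom expected homozygous count under Hardy-Weinberg
#' @param total_variants the fixed variant-count denominator
#' @return F_Hom (vectorized); `NaN` when the denominator is degenerate
#' @export
f_hom <- function(o_hom, e_hom, total_variants) {
  d <- total_variants - e_hom
  ifelse(d > 0, (o_hom - e_hom) / d, NaN)
}

#' @rdname f_hom
#' @param stats a data.frame from [individual_heterozygosity()]
#' @return `breed_f_hom`: unweighted mean F_Hom over individuals
#' @export
breed_f_hom <- function(stats) mean(stats$f_hom)

#' Chi-squared goodness-of-fit test between observed and expected
#' heterozygosity counts
#'
#' One-degree-of-freedom test on breed-summed heterozygous / homozygous
#' counts: `X2 = (o_het - e_het)^2 / e_het + (o_hom - e_hom)^2 / e_hom`.
#'
#' @param o_het,o_hom observed counts
#' @param e_het,e_hom expected counts (must be positive)
#' @return list with `statistic` and `p.value` (upper chi-squared(1) tail)
#' @export
het_chisq <- function(o_het, e_het, o_hom, e_hom) {
  if (e_het <= 0 || e_hom <= 0) stop("expected counts must be positive")
  x2 <- (o_het - e_het)^2 / e_het + (o_hom - e_hom)^2 / e_hom
  list(statistic = x2, p.value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}
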