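#' Read a multi-sample VCF into a cohort
#'
#' Parsing is delegated to [vcfR::read.vcfR()]; only the GT field is used.
#' Genotypes are coded as alternate-allele dosage (0/1/2, `NA` missing); when
#' every called genotype in the file is phased (`|` separator) the haplotype
#' matrix is populated and the `phased` flag set. Multi-allelic records are
#' retained with a comma-separated `alt` (their haplotype codes are `NA` and
#' their dosage counts non-reference alleles); [filter_variants()] removes
#' them.
#'
#' @param path path to an uncompressed or bgzipped VCF
#' @param pop_map optional data.frame (`sample_id`, `population`) or path to a
#'   two-column TSV; samples absent from the map get population `"unknown"`.
#' @param region optional `"chrom"` or `"chrom:start-end"` string; variants
#'   outside it are dropped after parsing.
#' @param chrom_lengths optional named vector (or TSV path) of chromosome
#'   lengths.
#' @return a [new_cohort()] object
#' @export
read_vcf <- function(path, pop_map = NULL, region = NULL, chrom_lengths = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))  # single-record files come back as a bare vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    sample_ids <- colnames(v@gt)[-1]
    gt_raw <- matrix(character(0), 0, length(sample_ids))
  } else {
    fmt <- v@gt[, "FORMAT"]
    if (any(!grepl("(^|:)GT(:|$)", fmt)))
      stop("VCF format error: GT field missing from FORMAT")
    gt_raw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
    sample_ids <- colnames(gt_raw)
  }
  variants <- data.frame(chrom = as.character(fix$CHROM),
                         pos = as.integer(fix$POS),
                         ref = as.character(fix$REF),
                         alt = as.character(fix$ALT),
                         stringsAsFactors = FALSE)

  nv <- nrow(variants); ns <- length(sample_ids)
  gt_chr <- as.vector(gt_raw)
  gt_chr[gt_chr %in% c(".", "./.", ".|.")] <- NA
  has_call <- !is.na(gt_chr)
  ploidy <- lengths(regmatches(gt_chr[has_call],
                               gregexpr("[/|]", gt_chr[has_call]))) + 1L
  if (any(ploidy != 2L))
    stop("unsupported input: non-diploid GT encountered")
  phased <- length(gt_chr[has_call]) > 0 && all(grepl("\\|", gt_chr[has_call]))

  a1 <- a2 <- rep(NA_integer_, length(gt_chr))
  sp <- strsplit(gt_chr[has_call], "[/|]")
  a1[has_call] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
  a2[has_call] <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2L)))
  geno <- matrix(a1 + a2, nv, ns, dimnames = list(NULL, sample_ids))

  haplotypes <- NULL
  if (phased && ns > 0) {
    haplotypes <- matrix(NA_integer_, nv, 2L * ns)
    h1 <- matrix(a1, nv, ns); h2 <- matrix(a2, nv, ns)
    multi <- grepl(",", variants$alt)
    h1[multi, ] <- NA_integer_; h2[multi, ] <- NA_integer_
    haplotypes[, seq(1L, 2L * ns, 2L)] <- h1
    haplotypes[, seq(2L, 2L * ns, 2L)] <- h2
  }

  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  pops <- if (is.null(pop_map)) rep("unknown", ns) else {
    p <- pop_map$population[match(sample_ids, pop_map$sample_id)]
    ifelse(is.na(p), "unknown", p)
  }
  if (is.character(chrom_lengths)) chrom_lengths <- read_chrom_lengths(chrom_lengths)

  co <- new_cohort(variants,
                   data.frame(sample_id = sample_ids, population = pops,
                              stringsAsFactors = FALSE),
                   geno, haplotypes, phased = phased,
                   chrom_lengths = chrom_lengths,
                   validate = FALSE)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0) stop("malformed region: ", region)
    keep <- co$variants$chrom == m[2]
    if (nzchar(m[3]))
      keep <- keep & co$variants$pos >= as.integer(m[4]) &
        co$variants$pos <= as.integer(m[5])
    co <- subset_variants(co, keep)
  }
  validate_cohort(co)
  co
}

#' Write a cohort as a GT-only VCF
#'
#' Emits VCFv4.2 plain text: one FORMAT=GT column set, phased separators iff
#' the cohort is phased, `./.` for missing genotypes, 1-based positions.
#'
#' @param cohort a `cohort`
#' @param path output path (plain text)
#' @export
write_vcf <- function(cohort, path) {
  validate_cohort(cohort)
  if (!variants_sorted(cohort$variants))
    stop("variants must be sorted before writing")
  ns <- n_samples(cohort); nv <- n_variants(cohort)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=herdscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(cohort$chrom_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(cohort$chrom_lengths),
                                as.integer(cohort$chrom_lengths)))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT",
                              cohort$samples$sample_id), collapse = "\t"))
  sep <- if (cohort$phased) "|" else "/"
  if (nv > 0) {
    if (cohort$phased && !is.null(cohort$haplotypes)) {
      h1 <- cohort$haplotypes[, seq(1L, 2L * ns, 2L), drop = FALSE]
      h2 <- cohort$haplotypes[, seq(2L, 2L * ns, 2L), drop = FALSE]
      gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), sep,
                          ifelse(is.na(h2), ".", h2)), nv, ns)
      gt[is.na(h1) & is.na(h2)] <- "./."
    } else {
      g <- cohort$genotypes
      gt <- matrix("./.", nv, ns)
      gt[!is.na(g) & g == 0L] <- paste0("0", sep, "0")
      gt[!is.na(g) & g == 1L] <- paste0("0", sep, "1")
      gt[!is.na(g) & g == 2L] <- paste0("1", sep, "1")
    }
    body <- paste(cohort$variants$chrom, cohort$variants$pos, ".",
                  cohort$variants$ref, cohort$variants$alt, ".", "PASS", ".",
                  "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    if (ns == 0)
      body <- paste(cohort$variants$chrom, cohort$variants$pos, ".",
                    cohort$variants$ref, cohort$variants$alt, ".", "PASS", ".",
                    "GT", sep = "\t")
  } else body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter variants on call rate, biallelic status and chromosome set
#'
#' @param cohort a `cohort`
#' @param min_call_rate keep variants with call rate `>=` this threshold
#'   (inclusive, default 0.95)
#' @param biallelic_only drop records with more than one ALT allele
#' @param autosomes optional character vector of chromosome labels to keep
#' @return filtered `cohort` (order preserved; may be empty)
#' @export
filter_variants <- function(cohort, min_call_rate = 0.95,
                            biallelic_only = TRUE, autosomes = NULL) {
  keep <- rep(TRUE, n_variants(cohort))
  if (n_variants(cohort) == 0) return(cohort)
  cr <- call_rate(cohort)
  keep <- keep & (!is.na(cr) & cr >= min_call_rate)
  if (biallelic_only)
    keep <- keep & !grepl(",", cohort$variants$alt) &
      nzchar(cohort$variants$alt) & cohort$variants$alt != "."
  if (!is.null(autosomes))
    keep <- keep & cohort$variants$chrom %in% autosomes
  subset_variants(cohort, keep)
}

#' Keep variants segregating in the pooled samples of given populations
#'
#' A variant is kept when the genotype calls pooled over the named
#' populations contain both the reference and the alternate allele
#' (`0 < pooled n_alt < pooled n`). A site fixed for opposite alleles in two
#' populations is pooled-polymorphic and kept.
#'
#' @param cohort a `cohort`
#' @param populations population labels to pool
#' @return filtered `cohort`
#' @export
segregating_subset <- function(cohort, populations) {
  ac <- allele_counts(cohort, population = populations)
  subset_variants(cohort, ac$n_alt > 0L & ac$n_alt < ac$n)
}

#' Squared dosage correlation between two variants
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples; the linkage-disequilibrium measure used for pruning.
#'
#' @param g_i,g_j genotype dosage vectors of equal length (`NA` = missing)
#' @return r-squared in `[0, 1]`, or `NA` when fewer than two
#'   pairwise-complete entries exist or either vector is constant over them
#'   ("not estimable"; treated as 0 by [ld_prune()]).
#' @export
genotype_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- g_i[ok]; y <- g_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' PLINK-style `--indep-pairwise` pass per chromosome: a window of
#' `window_snps` variants slides by `step_snps`; within each window, while any
#' retained pair exceeds `r2_max`, the pair with the largest r-squared is
#' resolved by removing its lower minor-allele-frequency member (ties by
#' later position). The retained set contains no pair above `r2_max` within
#' any window placement.
#'
#' @param cohort a `cohort`
#' @param window_snps window size in SNPs (default 50)
#' @param step_snps step size in SNPs (default 5)
#' @param r2_max prune pairs with r-squared above this (default 0.6)
#' @return integer vector of retained variant indices (ascending)
#' @export
ld_prune <- function(cohort, window_snps = 50L, step_snps = 5L, r2_max = 0.6) {
  stopifnot(window_snps > step_snps, step_snps > 0)
  g <- cohort$genotypes
  p <- allele_counts(cohort)$p
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, n_variants(cohort))
  for (ch in unique(cohort$variants$chrom)) {
    idx <- which(cohort$variants$chrom == ch)
    starts <- seq(1L, max(1L, length(idx)), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      repeat {
        r2 <- suppressWarnings(
          stats::cor(t(g[win, , drop = FALSE]),
                     use = "pairwise.complete.obs")^2)
        r2[is.na(r2)] <- 0  # non-estimable: conservative, no pruning
        diag(r2) <- 0
        worst <- max(r2)
        if (worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1L, ]
        i <- win[hit[1L]]; j <- win[hit[2L]]
        drop <- if (maf[i] < maf[j]) i
        else if (maf[j] < maf[i]) j
        else max(i, j)  # MAF tie: later position
        keep[drop] <- FALSE
        win <- win[win != drop]
        if (length(win) < 2) break
      }
    }
  }
  which(keep)
}
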