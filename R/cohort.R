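#' Construct a cohort of genotyped (optionally phased) samples
#'
#' A `cohort` is the substrate of every statistic in herdscan: a variant table,
#' a sample table with population (breed) labels, a genotype matrix coded as
#' alternate-allele dosage, and, when the source calls are phased, a haplotype
#' matrix with two columns per sample.
#'
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based bp, integer), `ref`, `alt` (non-empty allele strings; a
#'   comma-separated `alt` marks a multi-allelic record, which
#'   [filter_variants()] removes). Must be sorted by chromosome block and
#'   strictly increasing position within each chromosome.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `population` (non-empty breed label).
#' @param genotypes integer matrix `[n_variants x n_samples]` with codes
#'   0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing. Never imputed.
#' @param haplotypes optional integer matrix `[n_variants x 2*n_samples]`
#'   with codes 0/1/`NA`; columns `2s-1, 2s` belong to sample `s`.
#' @param phased logical; `TRUE` iff `haplotypes` carry phase.
#' @param chrom_lengths optional named numeric vector of chromosome lengths
#'   (bp), used to tile windows; defaults to the last variant position per
#'   chromosome when absent.
#' @param validate check invariants (genotype = sum of the two haplotype
#'   codes wherever both are present; sorted variants; unique sample ids).
#'
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(variants, samples, genotypes, haplotypes = NULL,
                       phased = FALSE, chrom_lengths = NULL, validate = TRUE) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
  }
  obj <- structure(
    list(variants = variants, samples = samples, genotypes = genotypes,
         haplotypes = haplotypes, phased = isTRUE(phased),
         chrom_lengths = chrom_lengths),
    class = "cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @param x a `cohort`
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  v <- x$variants
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(v)))
    stop("variant table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(x$samples$sample_id))
    stop("sample identifiers must be unique")
  if (any(!nzchar(x$samples$population)))
    stop("population labels must be non-empty")
  if (nrow(v) > 0) {
    if (any(v$pos < 1)) stop("positions must be >= 1")
    ord <- variants_sorted(v)
    if (!ord) stop("variants must be sorted by (chromosome, position)")
  }
  nv <- nrow(v); ns <- nrow(x$samples)
  if (!all(dim(x$genotypes) == c(nv, ns)))
    stop("genotype matrix must be n_variants x n_samples")
  if (any(x$genotypes < 0L | x$genotypes > 2L, na.rm = TRUE))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(x$haplotypes)) {
    if (!all(dim(x$haplotypes) == c(nv, 2L * ns)))
      stop("haplotype matrix must be n_variants x 2*n_samples")
    g2 <- x$haplotypes[, seq(1L, 2L * ns, by = 2L), drop = FALSE] +
      x$haplotypes[, seq(2L, 2L * ns, by = 2L), drop = FALSE]
    both <- !is.na(g2) & !is.na(x$genotypes)
    if (any(g2[both] != x$genotypes[both]))
      stop("genotype codes disagree with haplotype sums")
  }
  invisible(x)
}

# TRUE iff chromosomes form contiguous blocks with strictly increasing pos.
variants_sorted <- function(v) {
  if (nrow(v) < 2) return(TRUE)
  ch <- v$chrom
  blocks <- rle(ch)$values
  if (anyDuplicated(blocks)) return(FALSE)
  same <- ch[-1] == ch[-length(ch)]
  all(diff(v$pos)[same] > 0)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d variants x %d samples, %d population(s)%s\n",
              nrow(x$variants), nrow(x$samples),
              length(unique(x$samples$population)),
              if (x$phased) ", phased" else ""))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of variants / samples in a cohort
#' @param cohort a `cohort`
#' @export
n_variants <- function(cohort) nrow(cohort$variants)

#' @rdname n_variants
#' @export
n_samples <- function(cohort) nrow(cohort$samples)

#' Per-variant call rate
#'
#' Fraction of samples with a called (non-missing) genotype at each variant.
#' @param cohort a `cohort`
#' @return numeric vector in `[0, 1]`.
#' @export
call_rate <- function(cohort) {
  if (n_samples(cohort) == 0) return(rep(NA_real_, n_variants(cohort)))
  rowMeans(!is.na(cohort$genotypes))
}

#' Subset a cohort by variant index or by sample
#'
#' @param cohort a `cohort`
#' @param idx integer or logical index over variants (order preserved)
#' @return a `cohort`
#' @export
subset_variants <- function(cohort, idx) {
  new_cohort(cohort$variants[idx, , drop = FALSE],
             cohort$samples,
             cohort$genotypes[idx, , drop = FALSE],
             if (!is.null(cohort$haplotypes)) cohort$haplotypes[idx, , drop = FALSE],
             phased = cohort$phased, chrom_lengths = cohort$chrom_lengths,
             validate = FALSE)
}

#' @rdname subset_variants
#' @param ids sample identifiers (or a population label via `population`)
#' @param population keep all samples of these populations instead of `ids`
#' @export
subset_samples <- function(cohort, ids = NULL, population = NULL) {
  if (is.null(ids)) {
    unknown <- setdiff(population, cohort$samples$population)
    if (length(unknown))
      stop("unknown population(s): ", paste(unknown, collapse = ", "))
    ids <- cohort$samples$sample_id[cohort$samples$population %in% population]
  }
  j <- match(ids, cohort$samples$sample_id)
  if (anyNA(j)) stop("unknown sample id(s): ", paste(ids[is.na(j)], collapse = ", "))
  hj <- as.vector(rbind(2L * j - 1L, 2L * j))
  new_cohort(cohort$variants,
             cohort$samples[j, , drop = FALSE],
             cohort$genotypes[, j, drop = FALSE],
             if (!is.null(cohort$haplotypes)) cohort$haplotypes[, hj, drop = FALSE],
             phased = cohort$phased, chrom_lengths = cohort$chrom_lengths,
             validate = FALSE)
}

#' Per-site allele counts for a set of samples
#'
#' Houses the `p`, `q`, `n` that drive Hudson's F_ST, expected heterozygosity
#' and the RoH HMM emissions.
#'
#' @param cohort a `cohort`
#' @param population restrict to one or more populations (default: all samples)
#' @param ids restrict to explicit sample ids (overrides `population`)
#' @return data.frame with one row per variant: `n_ref`, `n_alt`, `n`
#'   (called alleles), `p` (alternate-allele frequency, `NaN` when `n = 0`)
#'   and `q = 1 - p`.
#' @export
allele_counts <- function(cohort, population = NULL, ids = NULL) {
  g <- cohort$genotypes
  if (!is.null(ids)) {
    j <- match(ids, cohort$samples$sample_id)
    if (anyNA(j)) stop("unknown sample id(s)")
    g <- g[, j, drop = FALSE]
  } else if (!is.null(population)) {
    unknown <- setdiff(population, cohort$samples$population)
    if (length(unknown))
      stop("unknown population(s): ", paste(unknown, collapse = ", "))
    g <- g[, cohort$samples$population %in% population, drop = FALSE]
  }
  called <- rowSums(!is.na(g))
  n <- 2L * called
  n_alt <- as.integer(rowSums(g, na.rm = TRUE))
  p <- ifelse(n > 0, n_alt / n, NaN)
  data.frame(n_ref = n - n_alt, n_alt = n_alt, n = n, p = p, q = 1 - p)
}

#' Read a two-column sample-to-population map
#'
#' @param path TSV with columns `sample_id` and `population` (header optional;
#'   detected from the first line).
#' @return data.frame with `sample_id`, `population`.
#' @export
read_pop_map <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", tolower(first))
  m <- if (header)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("sample_id", "population"))
  names(m)[1:2] <- c("sample_id", "population")
  m[, c("sample_id", "population")]
}

#' Read a chromosome-length table
#'
#' @param path TSV with columns chromosome and length (bp); header optional.
#' @return named numeric vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom|length", tolower(first))
  m <- utils::read.table(path, header = header, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(m[[2]]), as.character(m[[1]]))
}

# Effective chromosome lengths: declared lengths if present, else the last
# variant position per chromosome.
effective_chrom_lengths <- function(cohort, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(cohort$variants$chrom)
  out <- vapply(chroms, function(ch) {
    if (!is.null(cohort$chrom_lengths) && ch %in% names(cohort$chrom_lengths))
      return(as.numeric(cohort$chrom_lengths[[ch]]))
    max(cohort$variants$pos[cohort$variants$chrom == ch])
  }, numeric(1))
  stats::setNames(out, chroms)
}

# Tile [1, L] with fixed-width windows, 1-based inclusive bounds.
make_windows <- function(chrom_lengths, window_bp) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    start <- seq(1, L, by = window_bp)
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_bp - 1, L))
  })
  do.call(rbind, out)
}
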