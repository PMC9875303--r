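#' Configuration for the Balding-Nichols cohort simulator
#'
#' @param n_pops number of populations
#' @param n_per_pop diploid samples per population (recycled)
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param site_density expected variant sites per bp (default 1/1000)
#' @param maf_min ancestral frequencies are drawn uniformly on
#'   `[maf_min, 1 - maf_min]` (default 0.05, avoids monomorphic draws)
#' @param fst per-population Balding-Nichols `F` parameter in `[0, 1)`
#'   (recycled); the expected Hudson F_ST between populations `i` and `j` is
#'   `(F_i + F_j) / 2`
#' @param error_rate per-allele genotyping error rate: each haplotype allele
#'   is flipped independently with this probability (default 0)
#' @param seed integer RNG seed; all draws flow from it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_pops = 2L, n_per_pop = 50L,
                       chrom_lengths = c(chr1 = 5e6),
                       site_density = 1 / 1000, maf_min = 0.05,
                       fst = 0, error_rate = 0, seed = 1L) {
  stopifnot(site_density > 0, maf_min >= 0, maf_min < 0.5,
            all(fst >= 0), error_rate >= 0, error_rate <= 1)
  if (any(fst >= 1)) stop("F = 1 is rejected (fixed populations)")
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = rep_len(as.integer(n_per_pop), n_pops),
                 chrom_lengths = chrom_lengths,
                 site_density = site_density, maf_min = maf_min,
                 fst = rep_len(fst, n_pops), error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-population cohort under the Balding-Nichols model
#'
#' Per site an ancestral frequency `p0` is drawn uniformly on
#' `[maf_min, 1 - maf_min]`; population `k` with drift parameter `F_k` draws
#' its frequency from `Beta(p0 (1 - F_k) / F_k, (1 - p0)(1 - F_k) / F_k)`
#' (`p_k = p0` when `F_k = 0`); haplotype alleles are i.i.d. Bernoulli of
#' that frequency and paired into diploid genotypes. Sites are independent
#' (no background LD), placed uniformly at the configured density and
#' sorted, so downstream estimators have exact expectations under the
#' generating model.
#'
#' @param config a [sim_config()]
#' @return `list(cohort = <cohort>, truth = <sim_truth>)`; `truth$pop_fst`
#'   records the expected pairwise Hudson F_ST `(F_i + F_j)/2`.
#' @export
sim_balding_nichols <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns_tot <- sum(config$n_per_pop)
  pops <- rep(paste0("pop", seq_len(config$n_pops)), config$n_per_pop)
  sample_ids <- paste0(pops, "_", unlist(lapply(config$n_per_pop, seq_len)))

  vlist <- list(); hlist <- list()
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    nv <- max(1L, round(L * config$site_density))
    pos <- sort(sample.int(L, nv))
    p0 <- stats::runif(nv, config$maf_min, 1 - config$maf_min)
    hap <- matrix(NA_integer_, nv, 2L * ns_tot)
    col0 <- 0L
    for (k in seq_len(config$n_pops)) {
      Fk <- config$fst[k]
      pk <- if (Fk == 0) p0 else
        stats::rbeta(nv, p0 * (1 - Fk) / Fk, (1 - p0) * (1 - Fk) / Fk)
      nh <- 2L * config$n_per_pop[k]
      hap[, col0 + seq_len(nh)] <-
        matrix(stats::rbinom(nv * nh, 1L, pk), nv, nh)
      col0 <- col0 + nh
    }
    if (config$error_rate > 0) {
      flip <- matrix(stats::runif(length(hap)) < config$error_rate,
                     nrow(hap), ncol(hap))
      hap[flip] <- 1L - hap[flip]
    }
    vlist[[ch]] <- data.frame(chrom = ch, pos = pos, ref = "A", alt = "C",
                              stringsAsFactors = FALSE)
    hlist[[ch]] <- hap
  }
  variants <- do.call(rbind, vlist)
  hap <- do.call(rbind, hlist)
  geno <- hap[, seq(1L, 2L * ns_tot, 2L), drop = FALSE] +
    hap[, seq(2L, 2L * ns_tot, 2L), drop = FALSE]
  colnames(geno) <- sample_ids
  cohort <- new_cohort(variants,
                       data.frame(sample_id = sample_ids, population = pops,
                                  stringsAsFactors = FALSE),
                       geno, hap, phased = TRUE,
                       chrom_lengths = config$chrom_lengths, validate = FALSE)
  pop_names <- paste0("pop", seq_len(config$n_pops))
  pairs <- if (config$n_pops >= 2) utils::combn(config$n_pops, 2) else
    matrix(integer(0), 2, 0)
  pop_fst <- data.frame(
    pop_a = pop_names[pairs[1, ]], pop_b = pop_names[pairs[2, ]],
    fst = (config$fst[pairs[1, ]] + config$fst[pairs[2, ]]) / 2,
    stringsAsFactors = FALSE)
  truth <- structure(list(pop_fst = pop_fst, autozygous_segments = NULL,
                          sweep = NULL, seed = config$seed,
                          config = config),
                     class = "sim_truth")
  list(cohort = cohort, truth = truth)
}

#' Plant known autozygous segments into one sample
#'
#' Inside each segment the sample's second haplotype is overwritten by its
#' first (every covered site becomes homozygous); each covered site is then
#' flipped to heterozygous independently with probability `error_rate`,
#' emulating genotyping error inside a true run of homozygosity. Ground
#' truth for the RoH caller and for F_Hom / F_RoH recovery.
#'
#' @param cohort a phased `cohort`
#' @param sample sample id to modify
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive, non-overlapping, within chromosome bounds)
#' @param error_rate per-site heterozygous-error probability inside segments
#' @param truth optional existing `sim_truth` to append to
#' @return `list(cohort, truth)`; `truth$autozygous_segments` lists the
#'   planted intervals.
#' @export
plant_autozygosity <- function(cohort, sample, segments, error_rate = 0,
                               truth = NULL) {
  if (!cohort$phased || is.null(cohort$haplotypes))
    stop("plant_autozygosity requires a phased cohort")
  segments <- as.data.frame(segments)
  cl <- effective_chrom_lengths(cohort)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (any(s$start > s$end) || any(s$start < 1) ||
        any(s$end > cl[[ch]]))
      stop("segments must lie within chromosome bounds")
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments for sample ", sample)
  }
  j <- match(sample, cohort$samples$sample_id)
  if (is.na(j)) stop("unknown sample: ", sample)
  h <- cohort$haplotypes
  c1 <- 2L * j - 1L; c2 <- 2L * j
  for (i in seq_len(nrow(segments))) {
    sel <- which(cohort$variants$chrom == segments$chrom[i] &
                   cohort$variants$pos >= segments$start[i] &
                   cohort$variants$pos <= segments$end[i])
    if (!length(sel)) next
    h[sel, c2] <- h[sel, c1]
    if (error_rate > 0) {
      err <- sel[stats::runif(length(sel)) < error_rate]
      h[err, c2] <- 1L - h[err, c1]
    }
  }
  g <- cohort$genotypes
  g[, j] <- h[, c1] + h[, c2]
  out <- new_cohort(cohort$variants, cohort$samples, g, h, phased = TRUE,
                    chrom_lengths = cohort$chrom_lengths, validate = FALSE)
  seg_rec <- cbind(sample_id = sample, segments[, c("chrom", "start", "end")])
  if (is.null(truth))
    truth <- structure(list(pop_fst = NULL, autozygous_segments = NULL,
                            sweep = NULL, seed = NA_integer_),
                       class = "sim_truth")
  truth$autozygous_segments <- rbind(truth$autozygous_segments, seg_rec)
  list(cohort = out, truth = truth)
}

#' Plant an extended-haplotype sweep in one population
#'
#' A fraction of the population's haplotypes (rounded down, drawn with the
#' session RNG) is replaced over `[core - extent, core + extent]` by one
#' template haplotype, creating the long shared haplotype around a selected
#' core that XP-EHH detects.
#'
#' @param cohort a phased `cohort`
#' @param population carrier population label
#' @param chrom chromosome of the core
#' @param core_position core position in bp (a variant must lie within
#'   `extent` of it)
#' @param carrier_fraction fraction of haplotypes carrying the sweep, in
#'   `(0, 1]`
#' @param extent half-width of the swept interval in bp
#' @param truth optional existing `sim_truth` to append to
#' @return `list(cohort, truth)`
#' @export
plant_sweep <- function(cohort, population, chrom, core_position,
                        carrier_fraction, extent, truth = NULL) {
  if (!cohort$phased || is.null(cohort$haplotypes))
    stop("plant_sweep requires a phased cohort")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  sel <- which(cohort$variants$chrom == chrom &
                 abs(cohort$variants$pos - core_position) <= extent)
  if (!length(sel)) stop("no variant within `extent` of the core position")
  j <- which(cohort$samples$population == population)
  if (!length(j)) stop("unknown population: ", population)
  hcols <- as.vector(rbind(2L * j - 1L, 2L * j))
  n_car <- floor(carrier_fraction * length(hcols))
  if (n_car < 1) stop("carrier_fraction too small for population size")
  carriers <- sample(hcols, n_car)
  h <- cohort$haplotypes
  template <- h[sel, carriers[1L]]
  h[sel, carriers] <- template
  g <- cohort$genotypes
  g[sel, j] <- h[sel, 2L * j - 1L, drop = FALSE] +
    h[sel, 2L * j, drop = FALSE]
  out <- new_cohort(cohort$variants, cohort$samples, g, h, phased = TRUE,
                    chrom_lengths = cohort$chrom_lengths, validate = FALSE)
  if (is.null(truth))
    truth <- structure(list(pop_fst = NULL, autozygous_segments = NULL,
                            sweep = NULL, seed = NA_integer_),
                       class = "sim_truth")
  truth$sweep <- rbind(truth$sweep, data.frame(
    population = population, chrom = chrom, core_position = core_position,
    carrier_fraction = carrier_fraction, extent = extent,
    stringsAsFactors = FALSE))
  list(cohort = out, truth = truth)
}

#' Write / read a simulated fixture (VCF + population map + truth JSON)
#'
#' @param cohort a `cohort`
#' @param truth a `sim_truth`
#' @param directory output directory (created if needed); files written are
#'   `cohort.vcf`, `samples.tsv`, `chrom_lengths.tsv`, `truth.json`.
#' @return the directory, invisibly
#' @export
write_fixture <- function(cohort, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort, file.path(directory, "cohort.vcf"))
  utils::write.table(cohort$samples, file.path(directory, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$chrom_lengths))
    utils::write.table(
      data.frame(chrom = names(cohort$chrom_lengths),
                 length = as.numeric(cohort$chrom_lengths)),
      file.path(directory, "chrom_lengths.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- truth[c("pop_fst", "autozygous_segments", "sweep", "seed")]
  jsonlite::write_json(tr, file.path(directory, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(directory)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(directory) {
  clp <- file.path(directory, "chrom_lengths.tsv")
  cohort <- read_vcf(file.path(directory, "cohort.vcf"),
                     pop_map = file.path(directory, "samples.tsv"),
                     chrom_lengths = if (file.exists(clp)) clp)
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  class(truth) <- "sim_truth"
  list(cohort = cohort, truth = truth)
}
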