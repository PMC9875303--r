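#' Convert between 1-based inclusive regions and 0-based half-open BED
#'
#' Internal and reported coordinates are 1-based inclusive (VCF style);
#' BED files are 0-based half-open. Conversion is centralized here so the
#' off-by-one is testable in both directions.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional extra columns
#' @param path output / input BED path
#' @return `write_bed`: the path, invisibly; `read_bed`: a data.frame with
#'   1-based inclusive `start`, `end`
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = b[[1]], start = b[[2]] + 1, end = b[[3]],
             stringsAsFactors = FALSE)
}

#' Extend regions by flanking sequence, clamped to the chromosome
#'
#' `start' = max(1, start - flank)`, `end' = min(L, end + flank)`. The
#' original bounds are kept (`core_start`, `core_end`) so annotation can
#' classify hits as inside versus flank.
#'
#' @param regions data.frame `chrom`, `start`, `end` (1-based inclusive)
#' @param flank flank width in bp (default 250 kb)
#' @param chrom_sizes named vector of chromosome lengths covering all
#'   regions
#' @return data.frame with flanked `start`, `end` plus `core_start`,
#'   `core_end`
#' @export
flank_regions <- function(regions, flank = 250000, chrom_sizes) {
  if (!all(regions$chrom %in% names(chrom_sizes)))
    stop("chrom_sizes must cover all regions")
  L <- chrom_sizes[regions$chrom]
  if (any(regions$start < 1) || any(regions$end > L))
    stop("region beyond chromosome bounds")
  out <- regions
  out$core_start <- regions$start
  out$core_end <- regions$end
  out$start <- pmax(1, regions$start - flank)
  out$end <- pmin(as.numeric(L), regions$end + flank)
  out
}

# Interval files via rtracklayer; genes: GFF3 (type == "gene") or BED.
read_gene_intervals <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  gr <- if (fmt %in% c("gff", "gff3", "gtf")) {
    g <- rtracklayer::import(path)
    g[!is.na(S4Vectors::mcols(g)$type) & S4Vectors::mcols(g)$type == "gene"]
  } else rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)
  name <- if ("Name" %in% names(nm)) nm$Name
  else if ("name" %in% names(nm)) nm$name
  else if ("ID" %in% names(nm)) nm$ID
  else paste0("feature_", seq_along(gr))
  S4Vectors::mcols(gr)$feature <- as.character(name)
  gr
}

# QTL BED 6+1: chrom start end name score strand trait_class.
read_qtl_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(trait_class = "character"))
  S4Vectors::mcols(gr)$feature <- as.character(S4Vectors::mcols(gr)$name)
  gr
}

#' Annotate regions with genes and QTLs
#'
#' Regions are flanked with [flank_regions()], then intersected with gene
#' intervals (GFF3 `type == "gene"` records or BED) and with QTL intervals
#' (BED 6+1 with a trait-class column). Gene hits are classified `inside`
#' when they overlap the unflanked region and `flank` otherwise. QTLs are
#' kept only when shorter than `qtl_max_len` (strictly) and of a listed
#' trait class; hits with an unknown trait class are dropped with a
#' warning.
#'
#' @param regions data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   optionally a `source` column naming the originating statistic
#' @param genes path to a GFF3/BED gene file (or `NULL`)
#' @param qtls path to a QTL BED 6+1 file (or `NULL`)
#' @param chrom_sizes named chromosome-length vector
#' @param flank flank width in bp (default 250 kb)
#' @param qtl_max_len strict upper bound on QTL length in bp
#'   (default 10 kb)
#' @param trait_classes admissible QTL trait classes
#' @return data.frame of hits: region coordinates, `feature`, `type`
#'   (`gene`/`qtl`), `overlap_class` (`inside`/`flank`), `trait_class`
#' @export
annotate_regions <- function(regions, genes = NULL, qtls = NULL, chrom_sizes,
                             flank = 250000, qtl_max_len = 10000,
                             trait_classes = c("production", "exterior",
                                               "meat", "milk", "health",
                                               "reproduction")) {
  fl <- flank_regions(regions, flank, chrom_sizes)
  reg_gr <- GenomicRanges::GRanges(fl$chrom,
                                   IRanges::IRanges(fl$start, fl$end))
  core_gr <- GenomicRanges::GRanges(fl$chrom,
                                    IRanges::IRanges(fl$core_start, fl$core_end))
  hits <- list()
  collect <- function(feat_gr, type) {
    ov <- GenomicRanges::findOverlaps(reg_gr, feat_gr)
    if (!length(ov)) return(NULL)
    ri <- S4Vectors::queryHits(ov); fi <- S4Vectors::subjectHits(ov)
    inside <- GenomicRanges::start(feat_gr)[fi] <= fl$core_end[ri] &
      GenomicRanges::end(feat_gr)[fi] >= fl$core_start[ri]
    df <- data.frame(
      chrom = fl$chrom[ri], start = fl$core_start[ri], end = fl$core_end[ri],
      feature = S4Vectors::mcols(feat_gr)$feature[fi], type = type,
      overlap_class = ifelse(inside, "inside", "flank"),
      trait_class = if (type == "qtl")
        S4Vectors::mcols(feat_gr)$trait_class[fi] else NA_character_,
      stringsAsFactors = FALSE)
    if ("source" %in% names(fl)) df$source <- fl$source[ri]
    df
  }
  if (!is.null(genes))
    hits[["gene"]] <- collect(read_gene_intervals(genes), "gene")
  if (!is.null(qtls)) {
    q <- read_qtl_intervals(qtls)
    q <- q[GenomicRanges::width(q) < qtl_max_len]
    bad <- !(S4Vectors::mcols(q)$trait_class %in% trait_classes)
    if (any(bad)) {
      warning(sum(bad), " QTL hit(s) with unknown trait class dropped: ",
              paste(unique(S4Vectors::mcols(q)$trait_class[bad]),
                    collapse = ", "))
      q <- q[!bad]
    }
    hits[["qtl"]] <- collect(q, "qtl")
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), feature = character(0),
                      type = character(0), overlap_class = character(0),
                      trait_class = character(0))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from a configuration file
#'
#' Executes the stages in dependency order -- variant filtering, optional
#' LD pruning, per-breed diversity, RoH calling with F_RoH and islands,
#' pairwise F_ST with windowed top regions, UPGMA tree, XP-EHH scan, and
#' region annotation -- and writes versioned TSV/Newick/JSON outputs plus a
#' log of the seed and parameters. Rerunning with the same configuration
#' and seed reproduces every numeric table byte for byte.
#'
#' Configuration is YAML with keys: `vcf`, `pop_map`, `out_dir`, `seed`,
#' optional `chrom_lengths`, `stages` (subset of `filter`, `prune`,
#' `diversity`, `roh`, `islands`, `fst`, `tree`, `xpehh`, `annotate`),
#' `focal`, and per-stage parameter blocks (`filter.min_call_rate`,
#' `diversity.window_bp`, `diversity.denominator`, `roh.*`,
#' `fst.window_bp`, `fst.min_snps`, `fst.top_fraction`, `islands.*`,
#' `xpehh.pop_a`, `xpehh.pop_b`, `annotate.genes`, `annotate.qtls`,
#' `annotate.flank`).
#'
#' @param config path to a YAML file or an equivalent named list
#' @param out_dir overrides the configured output directory
#' @return the output directory, invisibly
#' @export
run_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config missing required key: ", key)
    cfg[[key]]
  }
  out <- out_dir %||% need("out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  set.seed(seed)
  stages <- cfg$stages %||%
    c("filter", "diversity", "roh", "islands", "fst", "tree", "xpehh")
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("herdscan run, seed = %d", seed)
  logline("stages: %s", paste(stages, collapse = ", "))

  for (key in c("vcf", "pop_map"))
    if (!file.exists(need(key)))
      stop("stage input: missing file for '", key, "': ", cfg[[key]])
  co <- read_vcf(cfg$vcf, pop_map = cfg$pop_map,
                 chrom_lengths = cfg$chrom_lengths)
  logline("input: %d variants x %d samples", n_variants(co), n_samples(co))

  if ("filter" %in% stages) {
    fcfg <- cfg$filter %||% list()
    co <- filter_variants(co,
                          min_call_rate = fcfg$min_call_rate %||% 0.95,
                          biallelic_only = fcfg$biallelic_only %||% TRUE,
                          autosomes = fcfg$autosomes)
    logline("filter: %d variants retained", n_variants(co))
  }
  pops <- unique(co$samples$population)

  if ("prune" %in% stages) {
    pcfg <- cfg$prune %||% list()
    kept <- ld_prune(co, window_snps = pcfg$window_snps %||% 50L,
                     step_snps = pcfg$step_snps %||% 5L,
                     r2_max = pcfg$r2_max %||% 0.6)
    co_pruned <- subset_variants(co, kept)
    logline("prune: %d variants retained", length(kept))
  } else co_pruned <- co

  tsv <- function(x, name) {
    utils::write.table(x, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("diversity" %in% stages) {
    dcfg <- cfg$diversity %||% list()
    wbp <- dcfg$window_bp %||% 10000
    denom <- dcfg$denominator %||% n_variants(co)
    div <- list(); het <- list()
    for (p in pops) {
      pw <- windowed_pi(co, p, window_bp = wbp)
      ps <- pi_summaries(pw)
      div[[p]] <- data.frame(population = p,
                             pi_tot_mean = ps$genome$mean,
                             pi_tot_median = ps$genome$median,
                             stringsAsFactors = FALSE)
      het[[p]] <- individual_heterozygosity(co, p, denominator = denom)
    }
    div_tab <- do.call(rbind, div)
    het_all <- do.call(rbind, het)
    breed_het <- do.call(rbind, lapply(split(het_all, het_all$population),
      function(h) data.frame(population = h$population[1],
                             h_o = mean(h$h_o), h_e = mean(h$h_e),
                             f_hom = mean(h$f_hom))))
    div_tab <- merge(div_tab, breed_het, by = "population")
    tsv(div_tab[order(div_tab$population), ], "diversity_per_breed.tsv")
    tsv(het_all, "heterozygosity_per_individual.tsv")
    logline("diversity: window %d bp, denominator %d", wbp, denom)
  }

  roh_all <- NULL
  if ("roh" %in% stages) {
    rcfg <- cfg$roh %||% list()
    model <- roh_model(az_enter_rate = rcfg$az_enter_rate %||% 6.6e-9,
                       az_exit_rate = rcfg$az_exit_rate %||% 1e-8,
                       error_rate = rcfg$error_rate %||% 0.01)
    l_genome <- rcfg$l_genome %||%
      sum(effective_chrom_lengths(co))
    segs <- lapply(co$samples$sample_id, function(s)
      roh_call(co, s, model = model))
    roh_all <- do.call(rbind, segs)
    tsv(roh_all, "roh_segments.tsv")
    froh <- f_roh(roh_all, l_genome = l_genome)
    froh$population <- co$samples$population[
      match(froh$sample_id, co$samples$sample_id)]
    tsv(froh, "froh_per_individual.tsv")
    logline("roh: %d segments, l_genome = %.0f", nrow(roh_all), l_genome)
  }

  if ("islands" %in% stages) {
    if (is.null(roh_all)) stop("stage 'islands' requires stage 'roh'")
    icfg <- cfg$islands %||% list()
    isl_all <- list()
    for (p in pops) {
      segs_p <- roh_all[roh_all$sample_id %in%
                          co$samples$sample_id[co$samples$population == p], ,
                        drop = FALSE]
      fr <- roh_snp_freq(segs_p, co, p)
      res <- suppressWarnings(
        roh_islands(fr, top_fraction = icfg$top_fraction %||% 5e-4,
                    max_gap = icfg$max_gap %||% 1e5))
      if (!is.null(res$islands) && nrow(res$islands))
        isl_all[[p]] <- cbind(population = p, res$islands,
                              threshold = res$threshold)
    }
    isl <- if (length(isl_all)) do.call(rbind, isl_all) else
      data.frame(population = character(0))
    tsv(isl, "roh_islands.tsv")
    logline("islands: %d", if (nrow(isl)) nrow(isl) else 0L)
  }

  top <- NULL
  if ("fst" %in% stages) {
    fcfg <- cfg$fst %||% list()
    focal <- cfg$focal %||% pops[1]
    rank <- fst_matrix(co, focal)
    tsv(rank, "fst_ranking.tsv")
    other <- fcfg$versus %||% rank$population[1]
    wins <- fst_windows(co, focal, other,
                        window_bp = fcfg$window_bp %||% 10000,
                        min_snps = fcfg$min_snps %||% 5)
    tsv(wins, "fst_windows.tsv")
    if (nrow(wins)) {
      top <- top_fraction_windows(wins,
                                  top_fraction = fcfg$top_fraction %||% 1e-4)
      tsv(top$regions, "fst_top_regions.tsv")
      write_bed(top$regions, file.path(out, "fst_top_regions.bed"))
      logline("fst: focal %s vs %s, threshold %.6g, %d region(s)",
              focal, other, top$threshold, nrow(top$regions))
    }
  }

  if ("tree" %in% stages) {
    dm <- manhattan_matrix(co_pruned)
    tr <- upgma(stats::as.dist(dm))
    writeLines(to_newick(tr), file.path(out, "tree.nwk"))
    breed_of <- stats::setNames(co$samples$population, co$samples$sample_id)
    pr <- prune_outlier_animals(tr, breed_of)
    writeLines(to_newick(pr$collapsed), file.path(out, "tree_breeds.nwk"))
    logline("tree: %d kept, %d removed", length(pr$kept), length(pr$removed))
  }

  scan <- NULL
  if ("xpehh" %in% stages) {
    xcfg <- cfg$xpehh %||% list()
    if (!co$phased)
      stop("stage 'xpehh' requires phased input genotypes ",
           "(haplotypes with '|' separators in the VCF)")
    pa <- xcfg$pop_a %||% pops[1]; pb <- xcfg$pop_b %||% pops[2]
    scan <- suppressMessages(
      xpehh_scan(co, pa, pb, cutoff = xcfg$cutoff %||% 0.05,
                 alpha = xcfg$alpha %||% 0.05))
    tsv(as.data.frame(scan), "xpehh_scan.tsv")
    regs <- significant_regions(scan)
    tsv(regs, "xpehh_regions.tsv")
    if (nrow(regs)) write_bed(regs, file.path(out, "xpehh_regions.bed"))
    logline("xpehh: %s vs %s, %d significant of %d",
            pa, pb, sum(scan$significant), nrow(scan))
  }

  if ("annotate" %in% stages) {
    acfg <- cfg$annotate %||% list()
    regions <- list()
    if (!is.null(top) && nrow(top$regions))
      regions[["fst_top"]] <- cbind(top$regions[c("chrom", "start", "end")],
                                    source = "fst_top")
    if (!is.null(scan)) {
      regs <- significant_regions(scan)
      if (nrow(regs))
        regions[["xpehh"]] <- cbind(regs[c("chrom", "start", "end")],
                                    source = "xpehh")
    }
    if (length(regions)) {
      allreg <- do.call(rbind, regions)
      ann <- annotate_regions(allreg, genes = acfg$genes, qtls = acfg$qtls,
                              chrom_sizes = effective_chrom_lengths(co),
                              flank = acfg$flank %||% 250000,
                              qtl_max_len = acfg$qtl_max_len %||% 10000)
      tsv(ann, "region_annotation.tsv")
      logline("annotate: %d hit(s)", nrow(ann))
    }
  }
  jsonlite::write_json(list(seed = seed, stages = stages),
                       file.path(out, "run_meta.json"), auto_unbox = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
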