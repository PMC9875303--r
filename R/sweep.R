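#' Site-specific extended haplotype homozygosity (EHHS) curve half
#'
#' Starting from the partition of a population's haplotypes by their allele
#' at the core variant, haplotypes are progressively partitioned by their
#' allele string from the core out to each flanking variant. At extension
#' `x` the haplotype homozygosity is `hh(x) = sum n_k (n_k - 1) / (n (n - 1))`
#' over partition classes, and the curve value is `hh(x) / hh(core)`, so it
#' is 1 at the core and non-increasing outwards. Haplotypes with a missing
#' allele in the span are dropped from that extension onward; the curve is
#' truncated when fewer than two haplotypes remain.
#'
#' @param haps 0/1 haplotype matrix `[n_variants x n_haplotypes]` of one
#'   population on one chromosome
#' @param positions bp positions aligned with the rows of `haps`
#' @param core core variant row index
#' @param direction `"left"` or `"right"`
#' @param cutoff stop extending once the curve drops below this value (the
#'   first sub-cutoff point is retained for interpolation); default 0
#'   returns the full curve
#' @return data.frame `pos`, `dist` (bp from the core), `value`; the first
#'   row is the core itself (`dist = 0`, `value = 1`)
#' @export
ehhs <- function(haps, positions, core, direction = c("left", "right"),
                 cutoff = 0) {
  direction <- match.arg(direction)
  r <- ehhs_core(haps, positions, core, direction == "right", cutoff)
  data.frame(pos = r$pos, dist = abs(r$pos - positions[core]),
             value = r$value)
}

# Hot path shared with xpehh_scan(): returns plain vectors.
ehhs_core <- function(haps, positions, core, right, cutoff) {
  nv <- nrow(haps)
  stopifnot(core >= 1, core <= nv, length(positions) == nv)
  alive <- which(!is.na(haps[core, ]))
  if (length(alive) < 2) stop("need at least two haplotypes at the core")
  g <- match(haps[core, alive], unique(haps[core, alive]))
  hh0 <- hh_from_groups(g)
  idx <- if (!right) rev(seq_len(core - 1L)) else
    if (core < nv) (core + 1L):nv else integer(0)
  out_pos <- numeric(length(idx) + 1L); out_val <- numeric(length(idx) + 1L)
  out_pos[1L] <- positions[core]; out_val[1L] <- 1
  m <- 1L
  for (i in idx) {
    a <- haps[i, alive]
    drop <- is.na(a)
    if (any(drop)) { alive <- alive[!drop]; g <- g[!drop]; a <- a[!drop] }
    if (length(alive) < 2) break
    keycode <- g * 2L + a
    g <- match(keycode, keycode[!duplicated(keycode)])
    val <- hh_from_groups(g) / hh0
    m <- m + 1L
    out_pos[m] <- positions[i]; out_val[m] <- val
    if (val < cutoff || (cutoff > 0 && val == 0)) break
  }
  list(pos = out_pos[seq_len(m)], value = out_val[seq_len(m)])
}

# Haplotype homozygosity of a partition given integer group ids.
hh_from_groups <- function(g) {
  n <- length(g)
  tab <- tabulate(g)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' Integrated EHHS (iES) over physical distance
#'
#' Trapezoidal integral of the EHHS curve over bp, each side truncated at
#' the first point where the value drops below `cutoff`, with the crossing
#' interpolated linearly; the two sides are summed. When the curve never
#' drops below the cutoff the integral simply stops at the last variant
#' (chromosome edge, no penalty).
#'
#' @param curve_left,curve_right curve halves from [ehhs()] sharing a core
#' @param cutoff truncation level (default 0.05)
#' @return integral in bp units
#' @export
ies <- function(curve_left, curve_right, cutoff = 0.05) {
  stopifnot(curve_left$pos[1] == curve_right$pos[1])
  ies_half(curve_left, cutoff) + ies_half(curve_right, cutoff)
}

ies_half <- function(curve, cutoff) ies_vec(curve$dist, curve$value, cutoff)

ies_vec <- function(d, v, cutoff) {
  below <- which(v < cutoff)
  if (length(below)) {
    j <- below[1L]
    if (j == 1L) return(0)
    # interpolated crossing between j-1 and j
    d_star <- d[j - 1L] + (v[j - 1L] - cutoff) / (v[j - 1L] - v[j]) *
      (d[j] - d[j - 1L])
    d <- c(d[seq_len(j - 1L)], d_star)
    v <- c(v[seq_len(j - 1L)], cutoff)
  }
  if (length(d) < 2) return(0)
  sum(diff(d) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Cross-population extended haplotype homozygosity scan (XP-EHH)
#'
#' For every variant segregating in the pooled pair of populations, the raw
#' score is `ln(iES_A / iES_B)`; scores are standardized genome-wide
#' (`z = (raw - mean) / sd` over all scanned cores, no frequency binning),
#' two-sided normal p-values are Bonferroni-corrected over the number of
#' scanned cores, and positive scores indicate selection in `popA`. Cores
#' where either integral is zero are skipped and recorded.
#'
#' @param cohort a phased `cohort`
#' @param popA,popB population labels
#' @param cutoff EHHS truncation level passed to [ies()] (default 0.05)
#' @param alpha family-wise significance level (default 0.05)
#' @return data.frame of class `xpehh_scan`: `chrom`, `pos`, `ies_a`,
#'   `ies_b`, `raw`, `z`, `p`, `p_bonf`, `significant`; skipped cores in
#'   attribute `"skipped"`.
#' @export
xpehh_scan <- function(cohort, popA, popB, cutoff = 0.05, alpha = 0.05) {
  if (!cohort$phased || is.null(cohort$haplotypes))
    stop("xpehh_scan requires a phased cohort (haplotypes present)")
  sub <- segregating_subset(cohort, c(popA, popB))
  ja <- which(sub$samples$population == popA)
  jb <- which(sub$samples$population == popB)
  if (length(ja) < 1 || length(jb) < 1) stop("both populations required")
  ca <- as.vector(rbind(2L * ja - 1L, 2L * ja))
  cb <- as.vector(rbind(2L * jb - 1L, 2L * jb))
  rows <- list()
  for (ch in unique(sub$variants$chrom)) {
    sel <- which(sub$variants$chrom == ch)
    ha <- sub$haplotypes[sel, ca, drop = FALSE]
    hb <- sub$haplotypes[sel, cb, drop = FALSE]
    pos <- sub$variants$pos[sel]
    n <- length(sel)
    ies_a <- ies_b <- numeric(n)
    ies_one <- function(h, i) {
      l <- ehhs_core(h, pos, i, FALSE, cutoff)
      r <- ehhs_core(h, pos, i, TRUE, cutoff)
      ies_vec(abs(l$pos - pos[i]), l$value, cutoff) +
        ies_vec(abs(r$pos - pos[i]), r$value, cutoff)
    }
    for (i in seq_len(n)) {
      ies_a[i] <- ies_one(ha, i)
      ies_b[i] <- ies_one(hb, i)
    }
    rows[[ch]] <- data.frame(chrom = ch, pos = pos,
                             ies_a = ies_a, ies_b = ies_b,
                             stringsAsFactors = FALSE)
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  usable <- scan$ies_a > 0 & scan$ies_b > 0
  skipped <- scan[!usable, c("chrom", "pos"), drop = FALSE]
  if (nrow(skipped))
    message(nrow(skipped), " core(s) skipped (zero iES on one side)")
  scan <- scan[usable, , drop = FALSE]
  if (nrow(scan) < 2) stop("fewer than two scannable cores")
  scan$raw <- log(scan$ies_a / scan$ies_b)
  mu <- mean(scan$raw); sdv <- stats::sd(scan$raw)
  scan$z <- (scan$raw - mu) / sdv
  scan$p <- 2 * stats::pnorm(-abs(scan$z))
  scan$p_bonf <- pmin(1, scan$p * nrow(scan))
  scan$significant <- scan$p_bonf < alpha
  attr(scan, "skipped") <- skipped
  attr(scan, "alpha") <- alpha
  class(scan) <- c("xpehh_scan", "data.frame")
  scan
}

#' Merge neighbouring significant XP-EHH variants into regions
#'
#' Consecutive scanned variants on one chromosome that are all significant
#' with the same sign form one region (start = first, end = last position);
#' singletons are allowed. `direction` is `"A"` for positive scores
#' (selection in the first population) and `"B"` otherwise.
#'
#' @param scan an [xpehh_scan()] result
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `direction`,
#'   `max_abs_z`
#' @export
significant_regions <- function(scan) {
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    state <- ifelse(!s$significant, 0L, ifelse(s$z > 0, 1L, -1L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0L)) {
      rows <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$pos[starts[k]], end = s$pos[ends[k]],
        n_snps = length(rows),
        direction = if (r$values[k] > 0) "A" else "B",
        max_abs_z = max(abs(s$z[rows])), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      direction = character(0), max_abs_z = numeric(0)))
  do.call(rbind, out)
}
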