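# Region detection from meta-analysis p-values, in the comb-p style:
# (1) estimate the autocorrelation of z-scores as a function of inter-probe
# distance; (2) smooth each probe's p-value by a Stouffer-Liptak-Kechris
# combination of its neighbors within a window, correcting the combined
# variance for the estimated correlations; (3) grow candidate regions from
# nominally significant smoothed probes with a 200-bp extension rule;
# (4) score each region by combining its members' original meta p-values
# (again correlation-aware) and apply a Sidak multiplicity correction.

#' Estimate the distance autocorrelation of probe z-scores
#'
#' For each distance bin (0, bin], (bin, 2*bin], ... up to `max_lag`, the
#' Pearson correlation of all z-score pairs whose inter-probe distance falls
#' in the bin, pooled across chromosomes. Bins with fewer than 10 pairs are
#' set to 0 with a warning.
#'
#' @param stats `MetaStats` (needs chrom, pos, z), position-sorted per
#'   chromosome (sorted internally).
#' @param max_lag maximum distance in bp (default 200).
#' @param bin bin width in bp (default 50).
#' @return data.frame of class `AcfEstimate`: `lag_lo`, `lag_hi`, `rho`,
#'   `n_pairs`.
#' @export
estimate_acf <- function(stats, max_lag = 200L, bin = 50L) {
  stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  breaks <- seq(0L, max_lag, by = bin)
  nb <- length(breaks) - 1L
  pairs_x <- vector("list", nb)
  pairs_y <- vector("list", nb)
  for (ch in unique(stats$chrom)) {
    idx <- which(stats$chrom == ch)
    if (length(idx) < 2) next
    pos <- stats$pos[idx]
    z <- stats$z[idx]
    # neighbor pairs within max_lag: walk forward from each probe
    for (off in seq_len(length(idx) - 1L)) {
      d <- pos[(1L + off):length(pos)] - pos[seq_len(length(pos) - off)]
      keep <- which(d <= max_lag)
      if (length(keep) == 0) {
        if (min(d) > max_lag) break else next
      }
      b <- findInterval(d[keep], breaks, left.open = TRUE)
      for (bb in unique(b)) {
        sel <- keep[b == bb]
        pairs_x[[bb]] <- c(pairs_x[[bb]], z[sel])
        pairs_y[[bb]] <- c(pairs_y[[bb]], z[sel + off])
      }
    }
  }
  rho <- numeric(nb)
  n_pairs <- integer(nb)
  for (bb in seq_len(nb)) {
    n_pairs[bb] <- length(pairs_x[[bb]])
    if (n_pairs[bb] < 10) {
      if (n_pairs[bb] > 0)
        warning("fewer than 10 pairs in ACF bin ", bb, "; correlation set to 0")
      rho[bb] <- 0
    } else {
      r <- stats::cor(pairs_x[[bb]], pairs_y[[bb]])
      rho[bb] <- if (is.finite(r)) max(min(r, 1), -1) else 0
    }
  }
  structure(data.frame(lag_lo = breaks[-length(breaks)], lag_hi = breaks[-1L],
                       rho = rho, n_pairs = n_pairs),
            class = c("AcfEstimate", "data.frame"))
}

# correlation for a vector of distances under a binned ACF (0 beyond max lag;
# 1 at distance 0 by definition)
acf_rho_at <- function(acf, d) {
  out <- numeric(length(d))
  out[d == 0] <- 1
  b <- findInterval(d, c(acf$lag_lo, acf$lag_hi[nrow(acf)]), left.open = TRUE)
  inside <- d > 0 & b >= 1 & b <= nrow(acf)
  out[inside] <- acf$rho[b[inside]]
  out
}

# signed one-sided z-transform: two-sided p + sign of the meta z ->
# one-sided z testing "effect > 0", so opposite-direction neighbors cancel
signed_z <- function(p, z_sign) {
  p <- pmin(pmax(p, 1e-300), 1)
  one_sided <- ifelse(z_sign >= 0, p / 2, 1 - p / 2)
  stats::qnorm(one_sided, lower.tail = FALSE)
}

# Stouffer-Liptak-Kechris combination of a set of (p, sign) with pairwise
# correlations rho_ij: Z = sum(z_i)/sqrt(k + 2*sum_{i<j} rho_ij),
# returned as a two-sided p-value
slk_p_value <- function(p, z_sign, pos, acf) {
  k <- length(p)
  z <- signed_z(p, z_sign)
  if (k == 1) return(min(2 * stats::pnorm(-abs(z)), 1))
  dmat <- abs(outer(pos, pos, "-"))
  rho_sum <- sum(acf_rho_at(acf, dmat[upper.tri(dmat)]))
  v <- k + 2 * rho_sum
  if (v <= 0) {
    warning("nonpositive combined variance; flooring")
    v <- k * 1e-6
  }
  Z <- sum(z) / sqrt(v)
  p_one <- stats::pnorm(Z, lower.tail = FALSE)
  min(2 * min(p_one, 1 - p_one), 1)
}

#' Smooth per-probe p-values by Stouffer-Liptak combination of neighbors
#'
#' For each probe, the two-sided meta p-values of all probes within `window`
#' bp (itself included) are converted to signed one-sided z-scores (the sign
#' of the meta z, so opposite-direction neighbors cancel), summed, and
#' variance-corrected with the binned ACF; the result is returned as a
#' two-sided p-value per probe. An isolated probe keeps its input p.
#'
#' @param stats `MetaStats` with chrom, pos, z, p.
#' @param acf an [estimate_acf()] result.
#' @param window neighborhood radius in bp: probes within `window` bp of the
#'   index probe are combined (default 200).
#' @return `stats` with an extra column `p_slk`, sorted by chrom, pos.
#' @export
slk_combine <- function(stats, acf, window = 200L) {
  stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  p_slk <- rep(NA_real_, nrow(stats))
  for (ch in unique(stats$chrom)) {
    idx <- which(stats$chrom == ch)
    pos <- stats$pos[idx]
    p <- stats$p[idx]
    zs <- sign(stats$z[idx])
    for (i in seq_along(idx)) {
      nb <- which(abs(pos - pos[i]) <= window)
      p_slk[idx[i]] <- slk_p_value(p[nb], zs[nb], pos[nb], acf)
    }
  }
  stats$p_slk <- p_slk
  rownames(stats) <- NULL
  stats
}

#' Grow candidate regions from smoothed p-values
#'
#' A region is seeded at a probe with smoothed p < `seed_p` and extended
#' while the next such probe lies within `extend` bp of the current region
#' end; member probes are the sub-threshold probes of the run. Regions with
#' at least 2 probes are retained. Each region is scored by a
#' Stouffer-Liptak combination of its members' original meta p-values
#' (`slk_p`) and Sidak-corrected for the number of independent
#' region-sized windows among the covered bases (`sidak_p`).
#'
#' @param stats output of [slk_combine()] (needs chrom, pos, z, p, p_slk,
#'   cpg).
#' @param acf an [estimate_acf()] result.
#' @param seed_p nominal significance threshold that seeds/extends regions
#'   (default 0.05).
#' @param extend extension cutoff in bp (default 200).
#' @return data.frame of class `DmrRegion`: chrom, start, end (1-based
#'   inclusive), n_probes, cpgs (comma-joined), slk_p, sidak_p.
#' @export
call_regions <- function(stats, acf, seed_p = 0.05, extend = 200L) {
  stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  total_coverage <- nrow(stats)  # point probes cover 1 bp each
  regions <- list()
  for (ch in unique(stats$chrom)) {
    idx <- which(stats$chrom == ch)
    sig <- idx[stats$p_slk[idx] < seed_p]
    if (length(sig) == 0) next
    pos <- stats$pos[sig]
    run_start <- 1L
    flush <- function(a, b) {
      members <- sig[a:b]
      if (length(members) < 2) return(NULL)
      data.frame(chrom = ch, start = stats$pos[members[1L]],
                 end = stats$pos[members[length(members)]],
                 n_probes = length(members),
                 cpgs = paste(stats$cpg[members], collapse = ","),
                 slk_p = slk_p_value(stats$p[members],
                                     sign(stats$z[members]),
                                     stats$pos[members], acf),
                 stringsAsFactors = FALSE)
    }
    if (length(sig) > 1) {
      for (i in 2:length(sig)) {
        if (pos[i] - pos[i - 1L] > extend) {
          regions <- c(regions, list(flush(run_start, i - 1L)))
          run_start <- i
        }
      }
    }
    regions <- c(regions, list(flush(run_start, length(sig))))
  }
  regions <- regions[!vapply(regions, is.null, logical(1))]
  if (length(regions) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      cpgs = character(0), slk_p = numeric(0),
                      sidak_p = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, regions)
    width <- pmax(out$end - out$start + 1, 1)
    n_tests <- pmax(total_coverage / width, 1)
    out$sidak_p <- 1 - (1 - out$slk_p)^n_tests
    # numerical underflow guard for very small slk_p
    tiny <- out$slk_p < 1e-12
    out$sidak_p[tiny] <- pmin(1, out$slk_p[tiny] * n_tests[tiny])
  }
  rownames(out) <- NULL
  class(out) <- c("DmrRegion", "data.frame")
  out
}

#' Filter regions at epigenome-wide significance
#'
#' @param regions a [call_regions()] result.
#' @param threshold region-level significance threshold (default 9e-8).
#' @param filter_on `"sidak"` (multiplicity-corrected, the default) or
#'   `"slk"` (uncorrected combined p).
#' @return the retained rows.
#' @export
filter_regions <- function(regions, threshold = EPIGENOME_WIDE_P,
                           filter_on = c("sidak", "slk")) {
  filter_on <- match.arg(filter_on)
  pcol <- if (filter_on == "sidak") regions$sidak_p else regions$slk_p
  out <- regions[pcol < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full DMR calling pipeline on meta-analysis statistics
#'
#' Convenience wrapper: ACF estimation, Stouffer-Liptak smoothing, region
#' growth, and significance filtering.
#'
#' @param meta `MetaStats` data.frame.
#' @inheritParams call_regions
#' @inheritParams filter_regions
#' @param window smoothing window in bp passed to [slk_combine()].
#' @return list with `acf`, `smoothed`, `candidates`, `regions` (filtered).
#' @export
run_dmr <- function(meta, seed_p = 0.05, extend = 200L, window = 200L,
                    threshold = EPIGENOME_WIDE_P,
                    filter_on = c("sidak", "slk")) {
  acf <- estimate_acf(meta)
  sm <- slk_combine(meta, acf, window = window)
  cand <- call_regions(sm, acf, seed_p = seed_p, extend = extend)
  list(acf = acf, smoothed = sm, candidates = cand,
       regions = filter_regions(cand, threshold, match.arg(filter_on)))
}
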