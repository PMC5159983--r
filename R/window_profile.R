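# Fixed-width genome windows and window-level methylation summaries.

#' Tile a genome into fixed non-overlapping windows
#'
#' Each chromosome is tiled with half-open windows `[0,w), [w,2w), ...`; a
#' final partial window covering the chromosome tail is retained and flagged.
#'
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param width window width in bp (default 20 kb).
#' @return data.frame (chrom, start, end, partial) tiling the genome without
#'   gaps or overlaps.
#' @export
tile_windows <- function(genome, width = 20000) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a positive scalar")
  if (length(genome) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), partial = logical()))
  if (is.null(names(genome))) stop("genome must be a named length vector")
  res <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    n_win <- ceiling(L / width)
    if (n_win < 1) return(NULL)
    starts <- width * (seq_len(n_win) - 1)
    ends <- pmin(starts + width, L)
    data.frame(chrom = ch, start = starts, end = ends,
               partial = (ends - starts) < width)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "width") <- width
  out
}

#' Per-window pooled methylation of one CpG track
#'
#' For every window, methylated and total calls of the CpGs falling inside it
#' are summed and the window fraction is the count pool `sum(meth)/sum(total)`
#' (not a mean of per-CpG fractions, which would be near-binary at x1-2
#' coverage). Windows supported by fewer than `min_support` total calls get a
#' missing fraction.
#'
#' @param track a [cpg_track()].
#' @param windows output of [tile_windows()].
#' @param min_support minimum total calls for a defined window fraction.
#' @return A `window_track`: `windows` plus columns n_cpgs, meth_sum,
#'   total_sum, fraction (NA below `min_support`).
#' @export
window_methylation <- function(track, windows, min_support = 10) {
  wt <- windows
  wt$n_cpgs <- 0L
  wt$meth_sum <- 0
  wt$total_sum <- 0
  if (nrow(track)) {
    dt <- as.data.table(as.data.frame(track))
    for (ch in unique(wt$chrom)) {
      wi <- which(wt$chrom == ch)
      sub <- dt[dt$chrom == ch]
      if (!nrow(sub)) next
      idx <- findInterval(sub$pos, wt$start[wi])
      keep <- idx >= 1 & sub$pos < wt$end[wi][pmax(idx, 1)]
      sub <- sub[keep]; idx <- idx[keep]
      if (!nrow(sub)) next
      agg <- sub[, list(n = .N, m = sum(meth), t = sum(total)), by = list(g = idx)]
      gi <- wi[agg$g]
      wt$n_cpgs[gi] <- agg$n
      wt$meth_sum[gi] <- agg$m
      wt$total_sum[gi] <- agg$t
    }
  }
  wt$fraction <- ifelse(wt$total_sum >= max(min_support, 1),
                        wt$meth_sum / wt$total_sum, NA_real_)
  attr(wt, "min_support") <- min_support
  attr(wt, "sample_id") <- attr(track, "sample_id")
  class(wt) <- c("window_track", "data.frame")
  wt
}

#' Pool CpG tracks from several samples into one consensus track
#'
#' Counts are summed per CpG position across samples; a position observed in
#' any sample appears in the pool. Used to build the high-coverage consensus
#' map on which PMD/HMD boundaries are trained and decoded.
#'
#' @param tracks list of [cpg_track()] objects on the same genome.
#' @param sample_id identifier for the pooled track.
#' @return A pooled [cpg_track()].
#' @export
pool_samples <- function(tracks, sample_id = "pooled") {
  stopifnot(length(tracks) >= 1)
  genomes <- lapply(tracks, track_genome)
  g0 <- genomes[[1]]
  for (g in genomes[-1]) {
    if (!identical(g, g0)) stop("pool_samples: tracks have conflicting genomes")
  }
  all <- rbindlist(lapply(tracks, function(t)
    as.data.table(as.data.frame(t)[c("chrom", "pos", "meth", "total")])))
  pooled <- all[, list(meth = sum(meth), total = sum(total)),
                by = c("chrom", "pos")]
  cpg_track(setDF(pooled), sample_id = sample_id, genome = g0)
}

#' Proportion of windows below a methylation threshold
#'
#' The study-level summary "percent of 20 kb windows with methylation below
#' 60%": the proportion of non-missing windows whose fraction is strictly
#' less than `threshold`.
#'
#' @param wt a `window_track` from [window_methylation()].
#' @param threshold methylation fraction cutoff (default 0.60); a window at
#'   exactly the threshold counts as not below.
#' @return Proportion in \[0, 1\].
#' @export
fraction_windows_below <- function(wt, threshold = 0.60) {
  f <- wt$fraction[!is.na(wt$fraction)]
  if (!length(f)) stop("fraction_windows_below: all windows are missing")
  mean(f < threshold)
}

#' Per-sample window-methylation histograms at 1% increments
#'
#' Each sample's non-missing window fractions are binned into 100 bins of 1
#' percentage point, normalized to unit mass, and the minimum, mean, maximum
#' and (population) standard deviation of the per-bin masses across samples
#' are reported — the summary used to compare distribution shapes when curves
#' overlap too much to plot directly.
#'
#' @param window_tracks list of `window_track`s, one per sample.
#' @return A `bin_summary` data.frame with 100 rows: bin_lo, bin_mid, bin_hi,
#'   min, mean, max, sd, and attribute `masses` (samples x 100 matrix).
#' @export
binned_distribution <- function(window_tracks) {
  stopifnot(length(window_tracks) >= 1)
  breaks <- seq(0, 1, by = 0.01)
  masses <- t(vapply(window_tracks, function(wt) {
    f <- wt$fraction[!is.na(wt$fraction)]
    if (!length(f)) return(rep(NA_real_, 100))
    # bins [0,0.01), ..., [0.98,0.99), [0.99,1]: fraction 1 folds into bin 100
    bin <- pmin(floor(f * 100) + 1L, 100L)
    tabulate(bin, nbins = 100) / length(f)
  }, numeric(100)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- data.frame(bin_lo = breaks[-101], bin_mid = breaks[-101] + 0.005,
                    bin_hi = breaks[-1],
                    min = apply(masses, 2, min),
                    mean = colMeans(masses),
                    max = apply(masses, 2, max),
                    sd = apply(masses, 2, pop_sd))
  attr(out, "masses") <- masses
  class(out) <- c("bin_summary", "data.frame")
  out
}

#' Local-linear (degree-1 local polynomial) smoothing of a window profile
#'
#' Fits a weighted straight line around each window midpoint using a tricube
#' kernel over a fixed bandwidth in bp, the smoothing used for browser-style
#' methylation profiles. Missing values are excluded from every local fit and
#' stay missing in the output.
#'
#' @param x window midpoint coordinates (bp), increasing.
#' @param y window methylation fractions (may contain NA).
#' @param bandwidth kernel half-width in bp (> 0).
#' @return Numeric vector of smoothed values, NA where `y` is NA.
#' @export
smooth_profile <- function(x, y, bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0)
    stop("bandwidth must be a positive scalar")
  stopifnot(length(x) == length(y))
  ok <- which(!is.na(y))
  if (length(ok) < 2) stop("smooth_profile: need at least 2 non-missing points")
  xo <- x[ok]; yo <- y[ok]
  out <- rep(NA_real_, length(y))
  for (i in ok) {
    d <- abs(xo - x[i])
    w <- (1 - pmin(d / bandwidth, 1)^3)^3
    use <- w > 0
    if (sum(use) < 2) { out[i] <- yo[which.min(d)]; next }
    xw <- xo[use]; yw <- yo[use]; ww <- w[use]
    # weighted least squares line through the local points, evaluated at x[i]
    sw <- sum(ww); mx <- sum(ww * xw) / sw; my <- sum(ww * yw) / sw
    sxx <- sum(ww * (xw - mx)^2)
    if (sxx < .Machine$double.eps * sw * max(1, mean(xw)^2)) {
      out[i] <- my
    } else {
      b <- sum(ww * (xw - mx) * (yw - my)) / sxx
      out[i] <- my + b * (x[i] - mx)
    }
  }
  out
}

#' Kernel-smoothed density of window methylation
#'
#' Display-only companion to [binned_distribution()]: a Gaussian kernel
#' density (Silverman's rule bandwidth) over a sample's non-missing window
#' fractions. Never feeds any statistic.
#'
#' @param wt a `window_track`.
#' @param n grid size.
#' @return data.frame (x, density).
#' @export
window_density <- function(wt, n = 512) {
  f <- wt$fraction[!is.na(wt$fraction)]
  if (length(f) < 2) stop("window_density: need at least 2 non-missing windows")
  d <- stats::density(f, bw = "nrd0", n = n, from = 0, to = 1)
  data.frame(x = d$x, density = d$y)
}

#' Autosome filter for chromosome names
#'
#' Default chromosome filter used when a summary is restricted to autosomes:
#' anything not named like a sex or mitochondrial chromosome.
#'
#' @param chroms character vector of chromosome names.
#' @return Logical vector, TRUE for autosomes.
#' @export
is_autosome <- function(chroms) {
  !grepl("^(chr)?(X|Y|M|MT)$", chroms, ignore.case = TRUE)
}
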