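# Maternal-blood contamination QC from X-chromosome CpG-island methylation.
# In male placentas the single active X leaves CpG-island promoters
# unmethylated; admixed female (maternal) cells carry one inactive X whose
# CGIs are ~half methylated, so CGI methylation in chrX HMDs scales linearly
# with the fraction of female cells.

#' Select X-chromosome CpG islands lying inside HMDs
#'
#' Keeps CpG islands fully contained (subset-or-equal on half-open
#' coordinates) in an HMD of the decoded domain set; islands inside PMDs or
#' straddling a domain boundary are excluded.
#'
#' @param cgi data.frame (chrom, start, end) of CpG islands on the X
#'   chromosome.
#' @param domains a [domain_set()] restricted to (or containing) the X
#'   chromosome; only its HMD intervals are used.
#' @param x_chrom name of the X chromosome (default matches "X"/"chrX").
#' @return The selected CGI intervals (sorted data.frame).
#' @export
x_cgi_hmd_regions <- function(cgi, domains, x_chrom = NULL) {
  cgi <- as.data.frame(cgi)
  dom <- as.data.frame(domains)
  if (is.null(x_chrom)) {
    xs <- unique(c(cgi$chrom, dom$chrom))
    x_chrom <- xs[grepl("^(chr)?X$", xs)]
    if (!length(x_chrom)) stop("x_cgi_hmd_regions: no X chromosome found")
  }
  cgi <- cgi[cgi$chrom %in% x_chrom, , drop = FALSE]
  hmd <- dom[dom$chrom %in% x_chrom & dom$state == "HMD", , drop = FALSE]
  keep <- logical(nrow(cgi))
  for (i in seq_len(nrow(hmd))) {
    keep <- keep | (cgi$start >= hmd$start[i] & cgi$end <= hmd$end[i] &
                      cgi$chrom == hmd$chrom[i])
  }
  sel <- cgi[keep, , drop = FALSE]
  if (!nrow(sel))
    stop("x_cgi_hmd_regions: no CpG island fully contained in an X HMD; ",
         "the contamination estimator is undefined for this input")
  validate_intervals(sel, what = "selected X CGIs")
}

#' Estimate the female-cell fraction of a sample
#'
#' Pools counts over all CpGs inside the selected X CGI regions and maps the
#' pooled methylation linearly between two declared anchors: `male_baseline`,
#' the CGI methylation expected with no female cells, and `female_baseline`,
#' the methylation of a pure female cell population (one inactive X, so about
#' half methylated). The estimate is clipped to \[0, 1\].
#'
#' @param track a [cpg_track()] for one sample.
#' @param regions selected intervals from [x_cgi_hmd_regions()].
#' @param male_baseline,female_baseline methylation anchors (defaults 0.10
#'   and 0.50); `female_baseline` must exceed `male_baseline`.
#' @return list (class `contamination_estimate`): sample_id, x_cgi_meth,
#'   female_fraction, n_regions, n_cpgs.
#' @export
estimate_female_fraction <- function(track, regions, male_baseline = 0.10,
                                     female_baseline = 0.50) {
  if (female_baseline <= male_baseline)
    stop("female_baseline must exceed male_baseline")
  regions <- validate_intervals(as.data.frame(regions), "regions")
  idx <- assign_to_intervals(track, regions)
  ok <- !is.na(idx)
  if (!any(ok) || sum(track$total[ok]) == 0)
    stop("estimate_female_fraction: no covered CpG in any region")
  x <- sum(track$meth[ok]) / sum(track$total[ok])
  f <- (x - male_baseline) / (female_baseline - male_baseline)
  structure(list(sample_id = attr(track, "sample_id"),
                 x_cgi_meth = x,
                 female_fraction = min(max(f, 0), 1),
                 n_regions = length(unique(idx[ok])),
                 n_cpgs = sum(ok)),
            class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "<contamination_estimate> %s: X CGI methylation %.3f -> female fraction %.3f (%d regions, %d CpGs)\n",
    x$sample_id, x$x_cgi_meth, x$female_fraction, x$n_regions, x$n_cpgs))
  invisible(x)
}

#' Relate contamination estimates to autosomal PMD methylation
#'
#' Pearson correlation between X CGI methylation and global autosomal PMD
#' methylation, computed over male samples only (the estimator's logic
#' requires a single active X); female samples are summarized separately,
#' where elevated X CGI methylation is expected from the female genome
#' itself rather than from contamination.
#'
#' @param estimates list of `contamination_estimate`s.
#' @param pmd_means named numeric vector of per-sample global autosomal PMD
#'   methylation.
#' @param sexes named character vector ("M"/"F") per sample.
#' @return list with `male` (r, p, n, data) and `female` (n, mean_x_cgi_meth,
#'   data).
#' @export
contamination_correlation <- function(estimates, pmd_means, sexes) {
  d <- do.call(rbind, lapply(estimates, function(e)
    data.frame(sample_id = e$sample_id, x_cgi_meth = e$x_cgi_meth,
               female_fraction = e$female_fraction)))
  d$pmd_mean <- pmd_means[d$sample_id]
  d$sex <- sexes[d$sample_id]
  males <- d[d$sex == "M" & !is.na(d$pmd_mean), , drop = FALSE]
  females <- d[d$sex == "F", , drop = FALSE]
  if (nrow(males) < 3)
    stop("contamination_correlation: need >= 3 male samples")
  if (sd(males$x_cgi_meth) == 0 || sd(males$pmd_mean) == 0)
    stop("contamination_correlation: zero variance among male samples")
  ct <- stats::cor.test(males$x_cgi_meth, males$pmd_mean)
  list(male = list(r = unname(ct$estimate), p = ct$p.value, n = nrow(males),
                   data = males),
       female = list(n = nrow(females),
                     mean_x_cgi_meth = if (nrow(females))
                       mean(females$x_cgi_meth) else NA_real_,
                     data = females))
}
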