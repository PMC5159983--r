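# Synthetic methylome cohort generator. Emulates the data structure of a
# low-coverage placental WGBS study: alternating PMD/HMD genome architecture,
# per-sample global methylation offsets with a shared genome-wide component
# and a larger PMD-specific spread, Poisson read depth with binomial
# methylation calls, X-chromosome CpG islands whose methylation reflects sex
# and female-cell admixture, and a planted group-differential HMD. Every
# planted quantity is recorded in a truth ledger so each pipeline stage can
# be tested against known ground truth.

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Architecture configuration for the synthetic genome
#'
#' Defaults describe a compact desk-scale genome with the study's
#' architecture: PMD segments averaging 300 kb and HMDs 150 kb (PMDs are
#' usually over 100 kb), PMD methylation ~0.55 vs HMD ~0.85 (the two modes
#' of the window-methylation distribution), CpGs every ~100 bp, and an X
#' chromosome carrying dense CpG islands inside HMDs whose methylation is
#' low (~0.10) on the single active male X and ~0.50 in female cells.
#'
#' @param seed RNG seed.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length autosome length (bp).
#' @param cpg_spacing mean bp between CpGs.
#' @param pmd_mean_length,hmd_mean_length mean segment lengths (bp); must be
#'   at least `window_width`.
#' @param pmd_meth,hmd_meth state methylation means; PMD must be below HMD.
#' @param include_x add an X chromosome with CGI regions.
#' @param x_length X chromosome length (bp).
#' @param n_x_cgi number of CpG islands placed inside X HMDs.
#' @param cgi_length CGI length (bp).
#' @param cgi_cpg_spacing mean bp between CpGs inside CGIs.
#' @param x_cgi_male_meth,x_cgi_female_meth X CGI methylation of male
#'   placenta and of female cells.
#' @param locus_noise_sd per-CpG Gaussian noise on the logit scale, fixed
#'   across samples.
#' @param window_width window width the domain boundaries align to.
#' @param length_model `"geometric"` run lengths (matching the HMM's
#'   implicit run-length law) or `"heavy"` (lognormal) for robustness tests.
#' @param training_fraction fraction of true domains exported as the
#'   "visually annotated" training subset.
#' @return An `architecture_config` list.
#' @export
architecture_config <- function(seed = 1,
                                n_chromosomes = 2,
                                chrom_length = 5e6,
                                cpg_spacing = 100,
                                pmd_mean_length = 300e3,
                                hmd_mean_length = 150e3,
                                pmd_meth = 0.55,
                                hmd_meth = 0.85,
                                include_x = TRUE,
                                x_length = chrom_length,
                                n_x_cgi = 60,
                                cgi_length = 1000,
                                cgi_cpg_spacing = 20,
                                x_cgi_male_meth = 0.10,
                                x_cgi_female_meth = 0.50,
                                locus_noise_sd = 0.1,
                                window_width = 20000,
                                length_model = c("geometric", "heavy"),
                                training_fraction = 0.3) {
  length_model <- match.arg(length_model)
  cfg <- as.list(environment())
  if (cfg$pmd_meth >= cfg$hmd_meth)
    stop("architecture_config: PMD methylation mean must be below HMD mean")
  if (cfg$pmd_mean_length < cfg$window_width ||
      cfg$hmd_mean_length < cfg$window_width)
    stop("architecture_config: segment length means must be >= window width")
  if (cfg$n_chromosomes < 1 || cfg$chrom_length < cfg$window_width)
    stop("architecture_config: invalid genome dimensions")
  class(cfg) <- "architecture_config"
  cfg
}

#' Cohort configuration for the synthetic study
#'
#' Defaults mirror the study conditions: 24 ASD and 23 TD samples at ~x1.5
#' coverage. Per-sample methylation offsets act on the logit scale and
#' decompose into a shared genome-wide component (`global_sd`) plus
#' state-specific components with the PMD spread larger than the HMD spread
#' (`pmd_sd` > `hmd_sd`); the defaults are calibrated so realized
#' cross-sample ranges approximate the reported maxima (11.17 percentage
#' points over PMDs, 4.76 over HMDs) and the shared component reproduces the
#' reported positive PMD-HMD correlation (~0.64). One HMD carries a planted
#' differential region: ASD samples are shifted by `dmr_delta_pp` percentage
#' points inside it.
#'
#' @param seed RNG seed.
#' @param n_asd,n_td,n_odc diagnostic group sizes.
#' @param coverage mean per-sample fold coverage.
#' @param global_sd,pmd_sd,hmd_sd logit-scale offset standard deviations.
#' @param dmr_target_hmd index of the autosomal HMD carrying the planted
#'   DMR (NULL disables planting).
#' @param dmr_delta_pp planted ASD-TD group mean difference in percentage
#'   points.
#' @param contamination per-sample female-cell fractions: scalar recycled or
#'   vector of length n_samples.
#' @param n_female_per_group females per diagnostic group (the study had 2
#'   in each of ASD and TD).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1,
                          n_asd = 24, n_td = 23, n_odc = 0,
                          coverage = 1.5,
                          global_sd = 0.074,
                          pmd_sd = 0.069,
                          hmd_sd = 0.042,
                          dmr_target_hmd = 2,
                          dmr_delta_pp = 5,
                          contamination = 0,
                          n_female_per_group = 2) {
  cfg <- as.list(environment())
  if (cfg$n_asd < 0 || cfg$n_td < 0 || cfg$n_odc < 0)
    stop("cohort_config: group sizes must be non-negative")
  if (any(cfg$contamination < 0 | cfg$contamination > 1))
    stop("cohort_config: contamination fractions must lie in [0, 1]")
  if (cfg$coverage < 0) stop("cohort_config: coverage must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

# alternating-state segment lengths (in windows) for one chromosome
draw_domain_states <- function(n_windows, cfg) {
  mean_w <- c(PMD = cfg$pmd_mean_length, HMD = cfg$hmd_mean_length) /
    cfg$window_width
  states <- character(0); lens <- integer(0)
  s <- sample(STATES, 1)
  total <- 0
  while (total < n_windows) {
    L <- if (cfg$length_model == "geometric") {
      1L + stats::rgeom(1, prob = 1 / mean_w[[s]])
    } else {
      max(1L, round(stats::rlnorm(1, meanlog = log(mean_w[[s]]) - 0.5,
                                  sdlog = 1)))
    }
    L <- min(L, n_windows - total)
    states <- c(states, s); lens <- c(lens, L)
    total <- total + L
    s <- setdiff(STATES, s)
  }
  list(states = states, lens = lens)
}

#' Generate the synthetic genome architecture
#'
#' Builds the genome (autosomes plus optional X), the true alternating
#' PMD/HMD domain set (boundaries aligned to window width, geometric segment
#' lengths), CpG positions from the spacing model with per-CpG locus noise
#' on the logit scale, and the annotation interval sets: X CpG islands
#' placed inside HMDs, promoters and gene bodies, ChromHMM-like state
#' elements, and a random ~30% subset of true domains standing in for
#' visual annotation used to train the HMM. Deterministic under the config
#' seed.
#'
#' @param cfg an [architecture_config()].
#' @return An `architecture` list: genome, domains (truth [domain_set()]),
#'   cpg (data.frame chrom/pos/state/is_x_cgi/logit_male/logit_female),
#'   annotations (list of BED-style data.frames: cgi, promoters,
#'   gene_bodies, chromhmm, training), config.
#' @export
generate_architecture <- function(cfg) {
  stopifnot(inherits(cfg, "architecture_config"))
  set.seed(cfg$seed)
  genome <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                            sprintf("auto%d", seq_len(cfg$n_chromosomes)))
  if (cfg$include_x) genome <- c(genome, chrX = cfg$x_length)

  dom_list <- list(); cpg_list <- list()
  for (ch in names(genome)) {
    L <- genome[[ch]]
    nw <- floor(L / cfg$window_width)
    ds <- draw_domain_states(nw, cfg)
    hi <- cumsum(ds$lens); lo <- hi - ds$lens + 1
    dom_list[[ch]] <- data.frame(
      chrom = ch,
      start = (lo - 1) * cfg$window_width,
      end = ifelse(hi == nw, L, hi * cfg$window_width),  # tail absorbed
      state = ds$states, n_windows = ds$lens)
    gaps <- 1L + stats::rgeom(ceiling(1.2 * L / cfg$cpg_spacing) + 50,
                              prob = 1 / cfg$cpg_spacing)
    pos <- cumsum(gaps)
    pos <- pos[pos < L]
    cpg_list[[ch]] <- data.frame(chrom = ch, pos = pos)
  }
  domains <- do.call(rbind, dom_list)
  domains <- domain_set(domains$chrom, domains$start, domains$end,
                        domains$state, domains$n_windows)

  # X CpG islands: fully contained in X HMDs, dense CpGs
  cgi <- NULL
  if (cfg$include_x) {
    xh <- as.data.frame(domains)
    xh <- xh[xh$chrom == "chrX" & xh$state == "HMD" &
               (xh$end - xh$start) >= cfg$cgi_length + 2000, , drop = FALSE]
    if (!nrow(xh)) stop("generate_architecture: no X HMD can host a CGI; ",
                        "increase x_length or hmd_mean_length")
    host <- sample(seq_len(nrow(xh)), cfg$n_x_cgi, replace = TRUE)
    offs <- vapply(host, function(i)
      floor(stats::runif(1, xh$start[i] + 1000,
                         xh$end[i] - 1000 - cfg$cgi_length)), numeric(1))
    cgi <- data.frame(chrom = "chrX", start = offs,
                      end = offs + cfg$cgi_length,
                      name = sprintf("xCGI_%d", seq_along(offs)))
    cgi <- cgi[order(cgi$start), , drop = FALSE]
    # drop overlapping islands (keep first of each overlapping pair)
    keep <- c(TRUE, cgi$start[-1] >= cgi$end[-nrow(cgi)])
    cgi <- cgi[keep, , drop = FALSE]
    rownames(cgi) <- NULL
    cgi_pos <- unlist(lapply(seq_len(nrow(cgi)), function(i) {
      gaps <- 1L + stats::rgeom(ceiling(2 * cfg$cgi_length /
                                          cfg$cgi_cpg_spacing),
                                prob = 1 / cfg$cgi_cpg_spacing)
      p <- cgi$start[i] + cumsum(gaps)
      p[p < cgi$end[i]]
    }))
    cpg_list[["chrX"]] <- data.frame(
      chrom = "chrX", pos = sort(unique(c(cpg_list[["chrX"]]$pos, cgi_pos))))
  }
  cpg <- do.call(rbind, cpg_list)
  rownames(cpg) <- NULL

  # per-CpG domain state and base methylation on the logit scale
  cpg$state <- domains$state[assign_to_intervals(
    data.frame(chrom = cpg$chrom, pos = cpg$pos), domains)]
  cpg$is_x_cgi <- FALSE
  if (!is.null(cgi)) {
    in_cgi <- assign_to_intervals(data.frame(chrom = cpg$chrom, pos = cpg$pos),
                                  cgi)
    cpg$is_x_cgi <- !is.na(in_cgi)
  }
  eta <- stats::rnorm(nrow(cpg), 0, cfg$locus_noise_sd)
  base <- ifelse(cpg$state == "PMD", cfg$pmd_meth, cfg$hmd_meth)
  cpg$logit_male <- ifelse(cpg$is_x_cgi, logit(cfg$x_cgi_male_meth),
                           logit(base)) + eta
  cpg$logit_female <- ifelse(cpg$is_x_cgi, logit(cfg$x_cgi_female_meth),
                             logit(base)) + eta

  autos <- names(genome)[is_autosome(names(genome))]
  rand_intervals <- function(n, width, prefix) {
    ch <- sample(autos, n, replace = TRUE)
    st <- floor(stats::runif(n, 0, genome[ch] - width))
    data.frame(chrom = ch, start = st, end = st + width,
               name = sprintf("%s_%d", prefix, seq_len(n)))
  }
  promoters <- rand_intervals(50, 2000, "prom")
  gene_bodies <- rand_intervals(50, 20000, "gene")
  chrom_states <- c("TssA", "TssP", "Enh", "Tx", "Het", "ReprPC", "Quies")
  chromhmm <- rand_intervals(140, 5000, "el")
  chromhmm$name <- sample(chrom_states, nrow(chromhmm), replace = TRUE)
  # "visual annotation": random subset of true domains, trimmed one window
  # on each side so annotations look hand-drawn but stay within the domain
  dd <- as.data.frame(domains)
  cand <- which(dd$n_windows >= 3)
  pick <- sort(sample(cand, max(2, round(cfg$training_fraction * length(cand)))))
  training <- data.frame(chrom = dd$chrom[pick],
                         start = dd$start[pick],
                         end = dd$end[pick],
                         state = dd$state[pick])
  if (!all(STATES %in% training$state)) {  # ensure both states represented
    for (s in setdiff(STATES, training$state)) {
      extra <- which(dd$state == s & dd$n_windows >= 3)[1]
      training <- rbind(training, dd[extra, c("chrom", "start", "end", "state")])
    }
  }

  structure(list(genome = genome, domains = domains, cpg = cpg,
                 annotations = list(cgi = cgi, promoters = promoters,
                                    gene_bodies = gene_bodies,
                                    chromhmm = chromhmm, training = training),
                 config = cfg),
            class = "architecture")
}

#' Simulate one sample's CpG count track
#'
#' Per CpG, read depth is Poisson with mean `coverage` and the methylated
#' count is binomial with success probability
#' `logistic(locus logit + state offset)`; zero-depth CpGs are omitted. X
#' CGI CpGs use the male or female baseline according to `sex` and receive
#' no state offset. An optional DMR shift (logit scale) applies to CpGs
#' inside one interval.
#'
#' @param arch an `architecture` from [generate_architecture()].
#' @param offsets named numeric c(pmd=, hmd=) logit-scale sample offsets.
#' @param coverage mean fold coverage (>= 0).
#' @param sex "M" or "F".
#' @param sample_id identifier for the track.
#' @param dmr optional list(chrom, start, end, delta_logit).
#' @param seed optional RNG seed for this sample.
#' @return A [cpg_track()] with attributes `p` (per-record success
#'   probability) and `arch_idx` (row index into `arch$cpg`).
#' @export
simulate_sample <- function(arch, offsets = c(pmd = 0, hmd = 0),
                            coverage = 1.5, sex = "M",
                            sample_id = "sample", dmr = NULL, seed = NULL) {
  stopifnot(inherits(arch, "architecture"))
  if (!all(is.finite(offsets))) stop("simulate_sample: offsets must be finite")
  if (coverage < 0) stop("simulate_sample: coverage must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  cpg <- arch$cpg
  lg <- if (identical(sex, "F")) cpg$logit_female else cpg$logit_male
  off <- ifelse(cpg$is_x_cgi, 0,
                ifelse(cpg$state == "PMD", offsets[["pmd"]], offsets[["hmd"]]))
  lg <- lg + off
  if (!is.null(dmr)) {
    hit <- cpg$chrom == dmr$chrom & cpg$pos >= dmr$start & cpg$pos < dmr$end
    lg[hit] <- lg[hit] + dmr$delta_logit
  }
  p <- inv_logit(lg)
  depth <- stats::rpois(nrow(cpg), coverage)
  keep <- depth > 0
  meth <- stats::rbinom(sum(keep), depth[keep], p[keep])
  tr <- cpg_track(data.frame(chrom = cpg$chrom[keep], pos = cpg$pos[keep],
                             meth = meth, total = depth[keep]),
                  sample_id = sample_id, genome = arch$genome)
  ord <- order(cpg$chrom[keep], cpg$pos[keep])
  attr(tr, "p") <- p[keep][ord]
  attr(tr, "arch_idx") <- which(keep)[ord]
  tr
}

#' Admix contaminating blood into a simulated track
#'
#' Models maternal-blood contamination: each CpG's success probability
#' becomes `(1-f) * p_placenta + f * p_blood`, where blood is highly
#' methylated over autosomes (raising observed PMD methylation
#' proportionally to `f`) and half-methylated over X CpG islands (female
#' blood carries an inactive X). Methylated counts are re-drawn under the
#' mixed probability at the track's existing depths. `f = 0` returns the
#' track unchanged.
#'
#' @param track a track from [simulate_sample()] (carries per-CpG
#'   probabilities).
#' @param arch the `architecture` the track was simulated from.
#' @param f female-cell (blood) fraction in \[0, 1\].
#' @param blood blood methylation profile: list(autosome, x_cgi, x_other).
#' @param seed optional RNG seed.
#' @return A [cpg_track()] with updated counts and `p` attribute.
#' @export
simulate_contamination <- function(track, arch, f,
                                   blood = list(autosome = 0.85,
                                                x_cgi = 0.50,
                                                x_other = 0.85),
                                   seed = NULL) {
  if (f < 0 || f > 1) stop("simulate_contamination: f must lie in [0, 1]")
  if (f == 0) return(track)
  p_plac <- attr(track, "p")
  idx <- attr(track, "arch_idx")
  if (is.null(p_plac) || is.null(idx))
    stop("simulate_contamination: track lacks simulation attributes; ",
         "use a track from simulate_sample()")
  if (!is.null(seed)) set.seed(seed)
  cpg <- arch$cpg[idx, ]
  p_blood <- ifelse(cpg$is_x_cgi, blood$x_cgi,
                    ifelse(is_autosome(cpg$chrom), blood$autosome,
                           blood$x_other))
  p_mix <- (1 - f) * p_plac + f * p_blood
  new_meth <- stats::rbinom(nrow(track), track$total, p_mix)
  out <- cpg_track(data.frame(chrom = track$chrom, pos = track$pos,
                              meth = new_meth, total = track$total),
                   sample_id = attr(track, "sample_id"),
                   genome = attr(track, "genome"))
  attr(out, "p") <- p_mix
  attr(out, "arch_idx") <- idx
  out
}

#' Generate a full synthetic study cohort with recorded truth
#'
#' Produces per-sample CpG tracks, a sample sheet, annotation sets and a
#' truth ledger. Per-sample logit offsets are a shared genome-wide draw plus
#' state-specific draws; the planted DMR shifts ASD samples inside one
#' designated autosomal HMD; per-sample contamination is applied when
#' nonzero. Fully deterministic under the two config seeds.
#'
#' @param arch_cfg an [architecture_config()].
#' @param cohort_cfg a [cohort_config()].
#' @return A `synthetic_cohort` list: tracks (named list of
#'   [cpg_track()]s), sheet (sample sheet), arch (the `architecture`), truth
#'   (list: domains, training, offsets, dmr, contamination).
#' @export
generate_cohort <- function(arch_cfg = architecture_config(),
                            cohort_cfg = cohort_config()) {
  stopifnot(inherits(cohort_cfg, "cohort_config"))
  arch <- generate_architecture(arch_cfg)
  set.seed(cohort_cfg$seed)
  n <- cohort_cfg$n_asd + cohort_cfg$n_td + cohort_cfg$n_odc
  diagnosis <- rep(c("ASD", "TD", "ODC"),
                   c(cohort_cfg$n_asd, cohort_cfg$n_td, cohort_cfg$n_odc))
  ids <- sprintf("%s_%02d", diagnosis, stats::ave(seq_len(n), diagnosis,
                                                  FUN = seq_along))
  sex <- unlist(lapply(split(seq_len(n), diagnosis)[unique(diagnosis)],
                       function(ii) {
    s <- rep("M", length(ii))
    nf <- min(cohort_cfg$n_female_per_group, length(ii))
    if (nf > 0) s[sample(length(ii), nf)] <- "F"
    s
  }))
  sex <- sex[order(unlist(split(seq_len(n), diagnosis)[unique(diagnosis)]))]

  g <- stats::rnorm(n, 0, cohort_cfg$global_sd)
  off_pmd <- g + stats::rnorm(n, 0, cohort_cfg$pmd_sd)
  off_hmd <- g + stats::rnorm(n, 0, cohort_cfg$hmd_sd)
  contam <- rep(cohort_cfg$contamination, length.out = n)
  sample_cov <- cohort_cfg$coverage * stats::runif(n, 0.85, 1.15)

  dmr <- NULL
  if (!is.null(cohort_cfg$dmr_target_hmd)) {
    dd <- as.data.frame(arch$domains)
    hmds <- dd[dd$state == "HMD" & is_autosome(dd$chrom), , drop = FALSE]
    k <- cohort_cfg$dmr_target_hmd
    if (k < 1 || k > nrow(hmds))
      stop("generate_cohort: dmr_target_hmd out of range (1..", nrow(hmds), ")")
    p0 <- arch$config$hmd_meth
    dmr <- list(chrom = hmds$chrom[k], start = hmds$start[k],
                end = hmds$end[k],
                delta_pp = cohort_cfg$dmr_delta_pp,
                delta_logit = (cohort_cfg$dmr_delta_pp / 100) /
                  (p0 * (1 - p0)))
  }

  seeds <- sample.int(.Machine$integer.max - 1, 2 * n)
  tracks <- vector("list", n)
  names(tracks) <- ids
  for (i in seq_len(n)) {
    this_dmr <- if (!is.null(dmr) && diagnosis[i] == "ASD" &&
                    dmr$delta_pp != 0) dmr else NULL
    tr <- simulate_sample(arch,
                          offsets = c(pmd = off_pmd[i], hmd = off_hmd[i]),
                          coverage = sample_cov[i], sex = sex[i],
                          sample_id = ids[i], dmr = this_dmr,
                          seed = seeds[i])
    if (contam[i] > 0)
      tr <- simulate_contamination(tr, arch, contam[i], seed = seeds[n + i])
    tracks[[i]] <- tr
  }
  races <- c("white non-Hispanic", "Asian", "multi-racial", "white Hispanic",
             "non-white Hispanic")
  sheet <- data.frame(
    sample_id = ids, diagnosis = diagnosis, sex = sex,
    run = sample(sprintf("run%d", 1:4), n, replace = TRUE),
    order = seq_len(n), coverage = sample_cov,
    race_ethnicity = sample(races, n, replace = TRUE,
                            prob = c(0.5, 0.15, 0.15, 0.1, 0.1)))
  truth <- list(domains = arch$domains,
                training = arch$annotations$training,
                offsets = data.frame(sample_id = ids, global = g,
                                     pmd = off_pmd, hmd = off_hmd),
                dmr = dmr,
                contamination = stats::setNames(contam, ids))
  structure(list(tracks = tracks, sheet = validate_sample_sheet(sheet),
                 arch = arch, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%s), %d CpGs, %d true domains\n",
              length(x$tracks),
              paste(sprintf("%d %s", table(x$sheet$diagnosis),
                            names(table(x$sheet$diagnosis))), collapse = ", "),
              nrow(x$arch$cpg), nrow(x$truth$domains)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits exactly what the IO module reads: one cpg_report TSV per sample, a
#' CSV sample sheet, BED annotation files (true domains, training subset,
#' CGIs, promoters, gene bodies, ChromHMM-like elements), a chromosome-size
#' table and a flat JSON truth ledger.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$tracks))
    write_cpg_counts(cohort$tracks[[s]], file.path(dir, paste0(s, ".cpg.tsv")))
  utils::write.csv(cohort$sheet, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  write_bed(cohort$truth$domains, file.path(dir, "true_domains.bed"))
  ann <- cohort$arch$annotations
  write_bed(ann$training, file.path(dir, "training.bed"))
  if (!is.null(ann$cgi)) write_bed(ann$cgi, file.path(dir, "cgi.bed"))
  write_bed(ann$promoters, file.path(dir, "promoters.bed"))
  write_bed(ann$gene_bodies, file.path(dir, "gene_bodies.bed"))
  write_bed(ann$chromhmm, file.path(dir, "chromhmm.bed"))
  write_tsv_plain(data.frame(chrom = names(cohort$arch$genome),
                             length = unname(cohort$arch$genome)),
                  file.path(dir, "genome.tsv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(offsets = truth$offsets,
         dmr = truth$dmr[c("chrom", "start", "end", "delta_pp")],
         contamination = as.list(truth$contamination)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a domain-level methylation matrix for group testing
#'
#' Feature-scale generator for differential-testing studies: per-sample
#' percent methylation of `n_features` domains, Gaussian with within-group
#' standard deviation `sd_pp` around `base_pp`, with one optional planted
#' feature shifted by `delta_pp` in group A. This is the scale at which the
#' domain t-test family operates.
#'
#' @param n_features number of features (rows).
#' @param n_a,n_b group sizes (columns; group A first).
#' @param sd_pp within-group standard deviation (percentage points).
#' @param delta_pp planted group A - group B difference at `target`.
#' @param target planted feature row (NULL = null cohort).
#' @param base_pp baseline percent methylation.
#' @return list: values (matrix), groups (per-column labels), target.
#' @export
simulate_domain_matrix <- function(n_features, n_a = 24, n_b = 23,
                                   sd_pp = 2.5, delta_pp = 0, target = NULL,
                                   base_pp = 85) {
  vals <- matrix(stats::rnorm(n_features * (n_a + n_b), base_pp, sd_pp),
                 nrow = n_features,
                 dimnames = list(sprintf("HMD_%d", seq_len(n_features)), NULL))
  groups <- rep(c("ASD", "TD"), c(n_a, n_b))
  if (!is.null(target)) {
    if (target < 1 || target > n_features)
      stop("simulate_domain_matrix: target out of range")
    vals[target, groups == "ASD"] <- vals[target, groups == "ASD"] + delta_pp
  }
  list(values = vals, groups = groups, target = target)
}
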