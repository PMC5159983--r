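# Two-state PMD/HMD hidden Markov model: supervised training on visually
# annotated segments of a pooled consensus track, Viterbi decoding of domain
# boundaries, and per-sample domain methylation summaries.

STATES <- c("PMD", "HMD")

#' Construct a two-state PMD/HMD HMM
#'
#' Gaussian emissions on window methylation fractions, one state per domain
#' type. The PMD emission mean must lie below the HMD mean.
#'
#' @param means named numeric c(PMD=, HMD=): emission means.
#' @param sds named numeric: emission standard deviations (> 0).
#' @param trans 2x2 row-stochastic transition matrix, rows/cols PMD, HMD.
#' @param init initial state probabilities (default: stationary distribution
#'   of `trans`).
#' @return An `hmm_model` object.
#' @export
hmm_model <- function(means, sds, trans, init = NULL) {
  means <- means[STATES]; sds <- sds[STATES]
  if (any(is.na(means)) || any(is.na(sds)))
    stop("hmm_model: means and sds must be named for PMD and HMD")
  if (any(sds <= 0)) stop("hmm_model: emission sd must be positive")
  if (means["PMD"] >= means["HMD"])
    stop("hmm_model: PMD emission mean must be below HMD emission mean")
  trans <- as.matrix(trans)
  if (!all(dim(trans) == c(2, 2)) || any(trans < 0) ||
      any(abs(rowSums(trans) - 1) > 1e-12))
    stop("hmm_model: transition matrix must be 2x2 row-stochastic")
  dimnames(trans) <- list(STATES, STATES)
  if (is.null(init)) init <- stationary_dist(trans)
  init <- as.numeric(init)
  if (length(init) != 2 || any(init < 0) || abs(sum(init) - 1) > 1e-9)
    stop("hmm_model: init must be a 2-vector of probabilities")
  names(init) <- STATES
  structure(list(states = STATES, means = means, sds = sds,
                 trans = trans, init = init),
            class = "hmm_model")
}

stationary_dist <- function(trans) {
  a <- trans["PMD", "HMD"]; b <- trans["HMD", "PMD"]
  if (a + b == 0) return(c(PMD = 0.5, HMD = 0.5))
  c(PMD = b / (a + b), HMD = a / (a + b))
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> two-state PMD/HMD, Gaussian emissions\n")
  for (s in x$states)
    cat(sprintf("  %s: mean %.4f sd %.4f, self-transition %.4f\n",
                s, x$means[s], x$sds[s], x$trans[s, s]))
  cat(sprintf("  initial: PMD %.3f / HMD %.3f\n", x$init[1], x$init[2]))
  invisible(x)
}

#' Write / read an HMM model as a key-value text file
#' @param model an [hmm_model()]; `path` a file path.
#' @return `path` invisibly, or the model for `read_hmm_model`.
#' @rdname hmm_model_io
#' @export
write_hmm_model <- function(model, path) {
  lines <- c(
    sprintf("state\t%s\tmean\t%.17g\tsd\t%.17g\ttrans\t%.17g\t%.17g",
            model$states[1], model$means[1], model$sds[1],
            model$trans[1, 1], model$trans[1, 2]),
    sprintf("state\t%s\tmean\t%.17g\tsd\t%.17g\ttrans\t%.17g\t%.17g",
            model$states[2], model$means[2], model$sds[2],
            model$trans[2, 1], model$trans[2, 2]),
    sprintf("init\t%.17g\t%.17g", model$init[1], model$init[2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname hmm_model_io
#' @export
read_hmm_model <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  st <- lines[[1]]; st2 <- lines[[2]]; ini <- lines[[3]]
  means <- c(as.numeric(st[4]), as.numeric(st2[4]))
  sds <- c(as.numeric(st[6]), as.numeric(st2[6]))
  names(means) <- names(sds) <- c(st[2], st2[2])
  trans <- rbind(as.numeric(st[8:9]), as.numeric(st2[8:9]))
  hmm_model(means, sds, trans, init = as.numeric(ini[2:3]))
}

# ---------------------------------------------------------------------------
# Domain set container
# ---------------------------------------------------------------------------

#' Construct an ordered PMD/HMD domain set
#'
#' Domains are 0-based half-open intervals labelled PMD or HMD; within a
#' chromosome they must be sorted, non-overlapping, and alternate in state
#' (two adjacent same-state intervals would be one domain).
#'
#' @param chrom,start,end,state parallel vectors; `state` in PMD/HMD.
#' @param n_windows optional per-domain window count.
#' @return A `domain_set` data.frame.
#' @export
domain_set <- function(chrom, start, end, state, n_windows = NA_integer_) {
  if (length(n_windows) == 1L) n_windows <- rep(n_windows, length(chrom))
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  state = as.character(state), n_windows = n_windows)
  if (nrow(x)) {
    if (!all(x$state %in% STATES))
      stop("domain_set: state labels must be PMD or HMD")
    x <- x[order(x$chrom, x$start), , drop = FALSE]
    rownames(x) <- NULL
    if (any(x$start >= x$end)) stop("domain_set: start >= end")
    if (nrow(x) > 1) {
      same <- x$chrom[-1] == x$chrom[-nrow(x)]
      if (any(same & x$start[-1] < x$end[-nrow(x)]))
        stop("domain_set: overlapping domains")
      if (any(same & x$state[-1] == x$state[-nrow(x)]))
        stop("domain_set: adjacent domains share a state (must alternate)")
    }
  }
  class(x) <- c("domain_set", "data.frame")
  x
}

# collapse a per-window state path into a domain_set (helper)
windows_to_domains <- function(chrom, start, end, states) {
  if (!length(states)) {
    return(domain_set(character(), numeric(), numeric(), character()))
  }
  r <- rle(states)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  domain_set(chrom = chrom[lo], start = start[lo], end = end[hi],
             state = r$values, n_windows = r$lengths)
}

# ---------------------------------------------------------------------------
# Supervised training
# ---------------------------------------------------------------------------

#' Train the PMD/HMD HMM on annotated segments of a pooled track
#'
#' Supervised closed-form estimation: emission mean/sd per state are the
#' sample mean/sd of pooled-window fractions inside that state's training
#' intervals; the self-transition probability of each state is
#' `1 - 1/L` where `L` is the mean training run length in windows (a
#' geometric run-length fit); the initial distribution is the stationary
#' distribution of the transition matrix. A floor of `sd_floor` guards
#' degenerate (constant) training data.
#'
#' @param pooled a `window_track` of the pooled consensus map.
#' @param training data.frame (chrom, start, end, state) of annotated
#'   PMD/HMD segments; windows fully contained in a segment are training
#'   observations for its state.
#' @param sd_floor lower bound for emission sd (default 0.01).
#' @return An [hmm_model()].
#' @export
train_supervised <- function(pooled, training, sd_floor = 0.01) {
  tr <- as.data.frame(training)
  if ("name" %in% names(tr) && !"state" %in% names(tr)) tr$state <- tr$name
  if (!all(c("chrom", "start", "end", "state") %in% names(tr)))
    stop("training intervals need chrom, start, end, state")
  if (!all(tr$state %in% STATES))
    stop("training labels must be PMD or HMD, got: ",
         paste(setdiff(unique(tr$state), STATES), collapse = ", "))
  # assign each window the label of the training interval that contains it
  lab <- rep(NA_character_, nrow(pooled))
  run_id <- rep(NA_integer_, nrow(pooled))
  for (i in seq_len(nrow(tr))) {
    hit <- pooled$chrom == tr$chrom[i] &
      pooled$start >= tr$start[i] & pooled$end <= tr$end[i]
    lab[hit] <- tr$state[i]
    run_id[hit] <- i
  }
  means <- sds <- numeric(0)
  for (s in STATES) {
    f <- pooled$fraction[!is.na(lab) & lab == s]
    f <- f[!is.na(f)]
    if (length(f) < 2)
      stop("train_supervised: fewer than 2 usable training windows for ", s)
    means[s] <- mean(f)
    sds[s] <- max(sd(f), sd_floor)
  }
  # mean run length in windows per state, one run per training segment
  runs <- table(factor(tr$state[unique(run_id[!is.na(run_id)])],
                       levels = STATES))
  nwin <- table(factor(lab[!is.na(lab)], levels = STATES))
  trans <- matrix(0, 2, 2, dimnames = list(STATES, STATES))
  for (s in STATES) {
    L <- as.numeric(nwin[s]) / max(as.numeric(runs[s]), 1)
    self <- 1 - 1 / max(L, 1)
    trans[s, s] <- self
    trans[s, setdiff(STATES, s)] <- 1 - self
  }
  hmm_model(means, sds, trans)
}

# ---------------------------------------------------------------------------
# Viterbi decoding
# ---------------------------------------------------------------------------

# log-space Viterbi over one chromosome's window fractions; NA observations
# contribute no emission term (transition-only bridging). Ties resolve toward
# PMD (state 1).
viterbi_path <- function(model, obs) {
  n <- length(obs)
  lt <- log(model$trans)
  li <- log(model$init)
  emis <- function(o) {
    if (is.na(o)) return(c(0, 0))
    stats::dnorm(o, mean = model$means, sd = model$sds, log = TRUE)
  }
  delta <- matrix(-Inf, n, 2)
  psi <- matrix(1L, n, 2)
  delta[1, ] <- li + emis(obs[1])
  if (n > 1) {
    for (t in 2:n) {
      e <- emis(obs[t])
      for (j in 1:2) {
        cand <- delta[t - 1, ] + lt[, j]
        best <- which.max(cand)      # ties -> lowest index = PMD
        psi[t, j] <- best
        delta[t, j] <- cand[best] + e[j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])   # ties -> PMD
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path, loglik = max(delta[n, ]))
}

#' Decode genome-wide PMD/HMD boundaries by Viterbi
#'
#' Runs the most-probable-path decoding of the two-state model over each
#' chromosome's ordered window fractions and merges consecutive same-state
#' windows into domains. Missing windows carry no emission term and are
#' absorbed into the decoded path of their flanks. A chromosome whose windows
#' are all missing is skipped with a warning.
#'
#' @param model an [hmm_model()].
#' @param pooled a `window_track` (typically of the pooled consensus track).
#' @return A [domain_set()] covering every windowed chromosome with at least
#'   one non-missing window.
#' @export
viterbi_segment <- function(model, pooled) {
  stopifnot(inherits(model, "hmm_model"))
  pieces <- list()
  for (ch in unique(pooled$chrom)) {
    wi <- which(pooled$chrom == ch)
    obs <- pooled$fraction[wi]
    if (all(is.na(obs))) {
      warning("viterbi_segment: all windows missing on ", ch, "; skipped")
      next
    }
    vp <- viterbi_path(model, obs)
    pieces[[ch]] <- windows_to_domains(pooled$chrom[wi], pooled$start[wi],
                                       pooled$end[wi], STATES[vp$path])
  }
  if (!length(pieces))
    return(domain_set(character(), numeric(), numeric(), character()))
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  domain_set(out$chrom, out$start, out$end, out$state, out$n_windows)
}

#' Merge short decoded domains into their flanks
#'
#' With `policy = "merge"`, any domain shorter than `min_length` is absorbed
#' into the longer flanking neighbour (ties go to the preceding neighbour),
#' shortest first, and same-state neighbours are re-merged until every domain
#' meets the length floor. `policy = "keep"` (the default elsewhere in the
#' pipeline) returns the decoded set untouched; PMDs are usually over 100 kb,
#' which motivates the default floor when merging is requested.
#'
#' @param raw a [domain_set()].
#' @param min_length minimum domain length in bp (default 100 kb).
#' @param policy `"keep"` or `"merge"`.
#' @return A [domain_set()].
#' @export
postprocess_domains <- function(raw, min_length = 100000,
                                policy = c("keep", "merge")) {
  policy <- match.arg(policy)
  if (policy == "keep" || !nrow(raw)) return(raw)
  pieces <- lapply(split(as.data.frame(raw), raw$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    repeat {
      len <- d$end - d$start
      if (nrow(d) <= 1 || all(len >= min_length)) break
      i <- which.min(ifelse(len < min_length, len, Inf))
      prev_len <- if (i > 1) len[i - 1] else -Inf
      next_len <- if (i < nrow(d)) len[i + 1] else -Inf
      into <- if (prev_len >= next_len) i - 1 else i + 1
      # absorb: the neighbour's interval extends over the short domain
      if (into < i) d$end[into] <- d$end[i] else d$start[into] <- d$start[i]
      d$n_windows[into] <- d$n_windows[into] + d$n_windows[i]
      d <- d[-i, , drop = FALSE]
      # re-merge same-state neighbours
      j <- 1
      while (j < nrow(d)) {
        if (d$state[j] == d$state[j + 1]) {
          d$end[j] <- d$end[j + 1]
          d$n_windows[j] <- d$n_windows[j] + d$n_windows[j + 1]
          d <- d[-(j + 1), , drop = FALSE]
        } else j <- j + 1
      }
    }
    d
  })
  out <- do.call(rbind, pieces)
  domain_set(out$chrom, out$start, out$end, out$state, out$n_windows)
}

# ---------------------------------------------------------------------------
# Per-sample domain methylation
# ---------------------------------------------------------------------------

# assign each CpG of `track` to a domain row index (NA if in no domain)
assign_to_intervals <- function(track, intervals) {
  idx <- rep(NA_integer_, nrow(track))
  for (ch in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    ord <- ii[order(intervals$start[ii])]
    k <- findInterval(track$pos[ti], intervals$start[ord])
    ok <- k >= 1 & track$pos[ti] < intervals$end[ord][pmax(k, 1)]
    idx[ti[ok]] <- ord[k[ok]]
  }
  idx
}

#' Per-sample, per-domain methylation table
#'
#' Count-pooled methylation of every sample over every decoded domain, plus
#' per-sample global PMD/HMD means (the count pool over all of a sample's
#' CpGs lying in domains of that state) and per-chromosome state means.
#' Domains with no covered CpG in a sample are missing for that sample.
#'
#' @param tracks named list of [cpg_track()]s (names = sample ids).
#' @param domains a [domain_set()].
#' @return A `domain_meth_table`: list with `domains` (the input set with a
#'   `domain_id`), `fractions` (domains x samples matrix), `global`
#'   (sample/state/fraction data.frame) and `per_chrom`
#'   (sample/chrom/state/fraction data.frame).
#' @export
sample_domain_methylation <- function(tracks, domains) {
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, function(t)
      as.character(attr(t, "sample_id")), character(1))
  nd <- nrow(domains)
  domain_ids <- sprintf("%s:%.0f-%.0f_%s", domains$chrom, domains$start,
                        domains$end, domains$state)
  frac <- matrix(NA_real_, nd, length(tracks),
                 dimnames = list(domain_ids, names(tracks)))
  glob <- list(); perchrom <- list()
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    idx <- assign_to_intervals(tr, domains)
    ok <- !is.na(idx)
    if (any(ok)) {
      dm <- rowsum(tr$meth[ok], idx[ok])
      dt <- rowsum(tr$total[ok], idx[ok])
      rows <- as.integer(rownames(dm))
      frac[rows, s] <- ifelse(dt[, 1] > 0, dm[, 1] / dt[, 1], NA_real_)
      st <- domains$state[idx[ok]]
      chs <- domains$chrom[idx[ok]]
      for (state in STATES) {
        sel <- st == state
        glob[[length(glob) + 1]] <- data.frame(
          sample_id = s, state = state,
          fraction = if (any(sel)) sum(tr$meth[ok][sel]) / sum(tr$total[ok][sel])
                     else NA_real_)
        if (any(sel)) {
          pm <- rowsum(tr$meth[ok][sel], chs[sel])
          pt <- rowsum(tr$total[ok][sel], chs[sel])
          perchrom[[length(perchrom) + 1]] <- data.frame(
            sample_id = s, chrom = rownames(pm), state = state,
            fraction = pm[, 1] / pt[, 1])
        }
      }
    } else {
      for (state in STATES)
        glob[[length(glob) + 1]] <- data.frame(sample_id = s, state = state,
                                               fraction = NA_real_)
    }
  }
  dom <- as.data.frame(domains)
  dom$domain_id <- domain_ids
  structure(list(domains = dom, fractions = frac,
                 global = do.call(rbind, glob),
                 per_chrom = do.call(rbind, perchrom)),
            class = "domain_meth_table")
}

#' @export
print.domain_meth_table <- function(x, ...) {
  cat(sprintf("<domain_meth_table> %d domains x %d samples\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Correlation between per-sample global PMD and HMD methylation
#'
#' Pearson correlation of each sample's global PMD mean against its global
#' HMD mean, overall and per diagnostic group, with per-group least-squares
#' regression lines. A shared genome-wide methylation component across
#' domains shows up as a positive correlation here.
#'
#' @param table a `domain_meth_table` from [sample_domain_methylation()].
#' @param groups optional named vector of group labels per sample.
#' @return list with `overall` (r, n, p), `per_group` data.frame
#'   (group, r, n, intercept, slope) and `samples` (the paired means).
#' @export
pmd_hmd_correlation <- function(table, groups = NULL) {
  g <- table$global
  wide <- data.frame(
    sample_id = unique(g$sample_id),
    pmd = g$fraction[match(paste(unique(g$sample_id), "PMD"),
                           paste(g$sample_id, g$state))],
    hmd = g$fraction[match(paste(unique(g$sample_id), "HMD"),
                           paste(g$sample_id, g$state))])
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3)
    stop("pmd_hmd_correlation: need >= 3 samples with both global means")
  if (sd(wide$pmd) == 0 || sd(wide$hmd) == 0)
    stop("pmd_hmd_correlation: zero variance in PMD or HMD means")
  ct <- stats::cor.test(wide$pmd, wide$hmd)
  per_group <- NULL
  if (!is.null(groups)) {
    wide$group <- groups[wide$sample_id]
    per_group <- do.call(rbind, lapply(split(wide, wide$group), function(d) {
      if (nrow(d) < 3 || sd(d$pmd) == 0 || sd(d$hmd) == 0)
        return(data.frame(group = d$group[1], r = NA_real_, n = nrow(d),
                          intercept = NA_real_, slope = NA_real_))
      fit <- stats::lm(hmd ~ pmd, data = d)
      data.frame(group = d$group[1], r = stats::cor(d$pmd, d$hmd), n = nrow(d),
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]))
    }))
    rownames(per_group) <- NULL
  }
  list(overall = list(r = unname(ct$estimate), n = nrow(wide),
                      p = ct$p.value),
       per_group = per_group, samples = wide)
}

#' Compare a decoded domain set against a reference at window resolution
#'
#' Labels every window by the state of the domain containing its midpoint in
#' each set and reports the fraction of windows with matching states, plus
#' the median absolute displacement (in windows) between each internal
#' reference boundary and the nearest decoded boundary on the same
#' chromosome.
#'
#' @param reference,decoded [domain_set()] objects.
#' @param windows window intervals from [tile_windows()].
#' @return list(window_accuracy, median_boundary_displacement_windows,
#'   n_windows, n_boundaries).
#' @export
compare_domain_sets <- function(reference, decoded, windows) {
  width <- attr(windows, "width")
  if (is.null(width)) width <- stats::median(windows$end - windows$start)
  mid <- data.frame(chrom = windows$chrom,
                    pos = (windows$start + windows$end) / 2)
  lab_ref <- reference$state[assign_to_intervals(mid, reference)]
  lab_dec <- decoded$state[assign_to_intervals(mid, decoded)]
  ok <- !is.na(lab_ref) & !is.na(lab_dec)
  acc <- mean(lab_ref[ok] == lab_dec[ok])
  internal_bounds <- function(ds) {
    d <- as.data.frame(ds)
    do.call(rbind, lapply(split(d, d$chrom), function(x)
      if (nrow(x) > 1) data.frame(chrom = x$chrom[-1], pos = x$start[-1])
      else NULL))
  }
  br <- internal_bounds(reference); bd <- internal_bounds(decoded)
  disp <- NA_real_
  if (!is.null(br) && nrow(br)) {
    disp <- vapply(seq_len(nrow(br)), function(i) {
      cand <- bd$pos[bd$chrom == br$chrom[i]]
      if (!length(cand)) return(Inf)
      min(abs(cand - br$pos[i])) / width
    }, numeric(1))
  }
  list(window_accuracy = acc,
       median_boundary_displacement_windows = stats::median(disp),
       n_windows = sum(ok),
       n_boundaries = if (all(is.na(disp))) 0L else length(disp))
}
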