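# Shared fixture builders and independent oracles used across test files.

# small random CpG track on a toy genome
random_track <- function(n = 50, genome = c(auto1 = 1e5, auto2 = 1e5),
                         sample_id = "s1") {
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- floor(runif(n, 0, genome[chrom]))
  key <- paste(chrom, pos)
  keep <- !duplicated(key)
  total <- rpois(sum(keep), 4) + 1
  meth <- rbinom(sum(keep), total, 0.6)
  cpg_track(data.frame(chrom = chrom[keep], pos = pos[keep],
                       meth = meth, total = total),
            sample_id = sample_id, genome = genome)
}

# exhaustive-enumeration Viterbi oracle: scores all 2^n state paths
enumerate_viterbi <- function(model, obs) {
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))[, n:1, drop = FALSE]
  emis <- sapply(1:2, function(s)
    ifelse(is.na(obs), 0, dnorm(obs, model$means[s], model$sds[s], log = TRUE)))
  emis <- matrix(emis, ncol = 2)
  lt <- log(model$trans); li <- log(model$init)
  score <- li[paths[, 1]]
  for (t in 1:n) score <- score + emis[cbind(t, paths[, t])]
  if (n > 1) {
    for (t in 2:n) score <- score + lt[cbind(paths[, t - 1], paths[, t])]
  }
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  # among ties, the lexicographically smallest path with PMD (1) first
  pick <- cand[do.call(order, as.data.frame(paths[cand, , drop = FALSE]))[1]]
  list(path = paths[pick, ], loglik = best,
       n_ties = length(cand))
}

# random two-state model with well-defined ordering
random_model <- function() {
  m_pmd <- runif(1, 0.3, 0.6)
  m_hmd <- runif(1, m_pmd + 0.05, 0.95)
  sds <- runif(2, 0.02, 0.15)
  a <- runif(1, 0.05, 0.5); b <- runif(1, 0.05, 0.5)
  hmm_model(c(PMD = m_pmd, HMD = m_hmd), c(PMD = sds[1], HMD = sds[2]),
            rbind(c(1 - a, a), c(b, 1 - b)))
}

# textbook BH step-up oracle: largest i with p_(i) <= i*alpha/m is rejected
bh_stepup_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * alpha / m
  k <- which(ps <= thresh)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  # step-up q-values with monotone adjustment
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  qq <- numeric(m); qq[o] <- q
  list(q = qq, rejected = rej)
}

# hand-computed HC1 sandwich covariance for an lm fit
hc1_oracle <- function(X, y) {
  n <- nrow(X); k <- ncol(X)
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  e <- as.numeric(y - X %*% beta)
  meat <- crossprod(X * e)
  (n / (n - k)) * XtXi %*% meat %*% XtXi
}
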