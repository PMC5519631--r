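# Independent oracles, kept deliberately naive: they re-derive expected
# values by enumeration/brute force and must not share code with the
# implementation paths they check.

# exhaustive-path forward-backward posterior (<= 6 sites x 4 haplotypes)
brute_posterior <- function(target, panel, params) {
  H <- panel$haps
  S <- nrow(H); K <- ncol(H)
  eps <- params$eps
  rho <- if (S > 1)
    1 - exp(-4 * params$ne * (diff(panel$sites$cm) / 100) / K) else numeric(0)
  emis <- function(s, h) {
    if (is.na(target[s])) 1
    else if (H[s, h] == target[s]) 1 - eps else eps
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  post <- matrix(0, S, K)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- 1 / K * emis(1, paths[r, 1])
    if (S > 1) for (s in 2:S) {
      tr <- if (paths[r, s] == paths[r, s - 1])
        1 - rho[s - 1] + rho[s - 1] / K else rho[s - 1] / K
      pr <- pr * tr * emis(s, paths[r, s])
    }
    tot <- tot + pr
    for (s in seq_len(S)) post[s, paths[r, s]] <- post[s, paths[r, s]] + pr
  }
  post / tot
}

# direct-formula exact HWE p-value (log-factorials, no recurrence)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  m <- min(nA, 2 * n - nA)
  h <- seq(m %% 2, m, by = 2)
  na_ <- (m - h) / 2
  nb <- n - h - na_
  lp <- lfactorial(n) - lfactorial(na_) - lfactorial(h) - lfactorial(nb) +
    h * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, h)] * (1 + 1e-9)])
}

# exhaustive 3x3x3 trio and 3x3 duo Mendelian consistency tables
trio_consistency_oracle <- function() {
  ok <- function(f, m, c) {
    from_f <- unique(c(floor(f / 2), ceiling(f / 2)))
    from_m <- unique(c(floor(m / 2), ceiling(m / 2)))
    c %in% outer(from_f, from_m, `+`)
  }
  grid <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  grid$consistent <- mapply(ok, grid$f, grid$m, grid$c)
  grid
}

# pooled-Pearson aggregate r2 on plain vectors
pooled_r2_oracle <- function(imp, tru) stats::cor(imp, tru)^2

# per-sample switch-error rate of an inferred panel vs truth haplotypes
switch_error <- function(phased, truth_panel, gm) {
  d <- gt_dosage(gm)
  key_q <- paste(gm$sites$chrom, gm$sites$pos)
  idx <- match(key_q, paste(truth_panel$sites$chrom, truth_panel$sites$pos))
  out <- c()
  for (i in seq_along(gm$samples)) {
    sm <- gm$samples[i]
    cp <- which(phased$hap_samples == sm)
    ct <- which(truth_panel$hap_samples == sm)
    het <- which(!is.na(d[, i]) & d[, i] == 1L)
    if (length(het) < 2) next
    o <- phased$haps[het, cp[1]] == truth_panel$haps[idx[het], ct[1]]
    out <- c(out, mean(o[-1] != o[-length(o)]))
  }
  out
}
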