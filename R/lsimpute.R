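# ---- haploid Li-Stephens haplotype-copying HMM -----------------------------
#
# Hidden state: which of the K panel haplotypes is being copied at each panel
# site. Between adjacent sites at genetic distance d cM the chain switches to
# a uniformly-drawn haplotype with probability rho = 1 - exp(-4*Ne*(d/100)/K)
# (so the stay probability is 1 - rho + rho/K). Emissions at typed sites are
# 1 - eps on allele match, eps otherwise; untyped sites emit uniformly, i.e.
# they sit in the chain but carry no evidence.

#' Li-Stephens model parameters
#'
#' @param ne effective population size controlling switch rate (default 100,
#'   a founder-cohort scale)
#' @param eps allele miscopy probability in (0, 0.5)
#' @param min_typed_sites refuse targets with fewer typed sites than this
#' @return an `ls_params` list
#' @export
ls_params <- function(ne = 100, eps = 1e-3, min_typed_sites = 3) {
  if (ne <= 0) stop("ls_params: ne must be > 0")
  if (eps <= 0 || eps >= 0.5) stop("ls_params: eps must be in (0, 0.5)")
  structure(list(ne = ne, eps = eps,
                 min_typed_sites = as.integer(min_typed_sites)),
            class = "ls_params")
}

#' Forward-backward posterior copy probabilities
#'
#' @param target integer vector over the panel's sites: 0/1 at typed sites,
#'   NA at untyped sites
#' @param panel a [hap_panel()]
#' @param params an [ls_params()]
#' @return numeric matrix (sites x haplotypes) of posterior copying
#'   probabilities; rows sum to 1
#' @export
ls_forward_backward <- function(target, panel, params = ls_params()) {
  H <- panel$haps
  S <- nrow(H); K <- ncol(H)
  stopifnot(length(target) == S)
  typed <- which(!is.na(target))
  if (length(typed) < params$min_typed_sites)
    stop("ls_forward_backward: fewer than ", params$min_typed_sites,
         " typed sites")
  eps <- params$eps
  E <- matrix(1, S, K)
  E[typed, ] <- ifelse(H[typed, , drop = FALSE] == target[typed], 1 - eps, eps)
  rho <- if (S > 1)
    1 - exp(-4 * params$ne * (diff(panel$sites$cm) / 100) / K) else numeric(0)

  f <- matrix(0, S, K)
  scal <- numeric(S)
  a <- E[1, ] / K
  scal[1] <- sum(a); f[1, ] <- a / scal[1]
  if (S > 1) for (s in 2:S) {
    a <- ((1 - rho[s - 1]) * f[s - 1, ] + rho[s - 1] / K) * E[s, ]
    scal[s] <- sum(a)
    if (scal[s] <= 0) stop("ls_forward_backward: zero forward probability")
    f[s, ] <- a / scal[s]
  }
  b <- matrix(0, S, K)
  b[S, ] <- 1
  if (S > 1) for (s in (S - 1):1) {
    v <- b[s + 1, ] * E[s + 1, ]
    b[s, ] <- ((1 - rho[s]) * v + rho[s] / K * sum(v)) / scal[s + 1]
  }
  post <- f * b
  post / rowSums(post)
}

# posterior alt-allele probability per site for one target haplotype
impute_haploid <- function(target, panel, params = ls_params()) {
  post <- ls_forward_backward(target, panel, params)
  eps <- params$eps
  p_alt <- rowSums(post * (panel$haps * (1 - eps) + (1 - panel$haps) * eps))
  typed <- !is.na(target)
  p_alt[typed] <- target[typed]
  p_alt
}

#' Impute diploid dosages for one phased sample
#'
#' Each haplotype is imputed independently against the panel; the diploid
#' alternate-allele dosage is the sum of the two haploid posterior allele
#' probabilities. Typed sites pass through the observed alleles.
#'
#' @param hap1,hap2 integer vectors over the panel's sites (0/1 typed,
#'   NA untyped)
#' @param panel a [hap_panel()]
#' @param params an [ls_params()]
#' @return list(dosage, p_alt1, p_alt2)
#' @export
impute_dosage <- function(hap1, hap2, panel, params = ls_params()) {
  p1 <- impute_haploid(hap1, panel, params)
  p2 <- impute_haploid(hap2, panel, params)
  list(dosage = p1 + p2, p_alt1 = p1, p_alt2 = p2)
}

#' Impute a set of phased target samples against a reference panel
#'
#' Typed sites are the intersection of the target panel's sites with the
#' reference panel's; dosages are produced on the reference panel's site
#' grid.
#'
#' @param targets a [hap_panel()] of phased target haplotypes (typically
#'   masked to array sites)
#' @param panel the reference [hap_panel()]
#' @param params an [ls_params()]
#' @return a `dosage_matrix`: list(sites, samples, dosage [samples x sites],
#'   info) where info is a per-site imputation-quality summary (ratio of
#'   imputed-dosage variance to the binomial expectation, as in INFO-style
#'   diagnostics)
#' @export
impute_dosages <- function(targets, panel, params = ls_params()) {
  key_t <- paste(targets$sites$chrom, targets$sites$pos)
  key_p <- paste(panel$sites$chrom, panel$sites$pos)
  typed_p <- match(key_t, key_p)
  if (all(is.na(typed_p)))
    stop("impute_dosages: target and panel share no sites")
  samples <- panel_samples(targets)
  S <- nrow(panel$sites)
  D <- matrix(NA_real_, length(samples), S,
              dimnames = list(samples, NULL))
  for (i in seq_along(samples)) {
    cols <- which(targets$hap_samples == samples[i])
    t1 <- rep(NA_integer_, S); t2 <- rep(NA_integer_, S)
    ok <- !is.na(typed_p)
    t1[typed_p[ok]] <- targets$haps[ok, cols[1]]
    t2[typed_p[ok]] <- targets$haps[ok, cols[2]]
    D[i, ] <- impute_dosage(t1, t2, panel, params)$dosage
  }
  p_hat <- colMeans(D) / 2
  info <- ifelse(p_hat > 0 & p_hat < 1,
                 pmin(1, apply(D, 2L, stats::var) / (2 * p_hat * (1 - p_hat))),
                 NA_real_)
  structure(list(sites = panel$sites, samples = samples, dosage = D,
                 info = info), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d sites\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
write_vcf.dosage_matrix <- function(x, path, provenance = character(0)) {
  ds <- t(x$dosage)                       # sites x samples
  cells <- matrix(paste0(".|.:", format(round(ds, 4), trim = TRUE,
                                        scientific = FALSE)),
                  nrow = nrow(x$sites))
  body <- paste(vcf_fixed_cols(x$sites, "GT:DS"),
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(
    x$samples,
    c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed dosage\">"),
    provenance), body), path)
  invisible(path)
}
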