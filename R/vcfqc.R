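# ---- quality-control cascade ----------------------------------------------
#
# Fixed filter order: record normalization -> genotype filters -> Mendelian
# masking -> site filters. QC is monotone: a genotype only ever becomes
# missing, a site is only ever removed, so re-running QC on its own output
# is a no-op.

#' Default site-filter thresholds
#'
#' @param max_missing maximum per-site missing-call rate (strict `>` drops)
#' @param max_mendel maximum per-site trio Mendelian error rate
#' @param hwe_p Hardy-Weinberg exact-test floor (strict `<` drops)
#' @return named list of thresholds
#' @export
qc_thresholds <- function(max_missing = 0.25, max_mendel = 0.10,
                          hwe_p = 1e-6) {
  list(max_missing = max_missing, max_mendel = max_mendel, hwe_p = hwe_p)
}

autosome_chrom <- function(chrom) {
  x <- sub("^chr", "", chrom)
  suppressWarnings(n <- as.integer(x))
  !is.na(n) & n >= 1L & n <= 22L & grepl("^[0-9]+$", x)
}

# parsimonious representation: strip shared suffix then shared prefix,
# keeping at least one base of each allele; pos advances over the prefix
trim_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize records and restrict to biallelic autosomal variants
#'
#' Drops multi-allelic and non-autosomal records, trims indel alleles to a
#' parsimonious left-shifted representation, and collapses duplicate
#' (pos, ref, alt) records (first record wins). Counts of removed records
#' are attached as attribute `"norm_counts"`.
#'
#' @param vcf a `raw_vcf` from [read_vcf()] or a path to a VCF file
#' @return a [geno_matrix()]
#' @export
normalize_and_restrict <- function(vcf) {
  if (is.character(vcf)) vcf <- read_vcf(vcf)
  stopifnot(inherits(vcf, "raw_vcf"))
  fx <- vcf$fixed
  multi <- grepl(",", fx$alt, fixed = TRUE)
  nonauto <- !autosome_chrom(fx$chrom)
  keep <- !multi & !nonauto
  fx <- fx[keep, , drop = FALSE]
  calls <- vcf$calls[keep, , drop = FALSE]
  if (nrow(fx)) {
    for (r in which(nchar(fx$ref) > 1L | nchar(fx$alt) > 1L)) {
      t <- trim_alleles(fx$pos[r], fx$ref[r], fx$alt[r])
      fx$pos[r] <- t$pos; fx$ref[r] <- t$ref; fx$alt[r] <- t$alt
    }
  }
  key <- paste(fx$chrom, fx$pos, fx$ref, fx$alt)
  dup <- duplicated(key)
  ord <- order(fx$chrom[!dup], fx$pos[!dup])
  fx2 <- fx[!dup, , drop = FALSE][ord, , drop = FALSE]
  calls2 <- calls[!dup, , drop = FALSE][ord, , drop = FALSE]
  gm <- parse_vcf_calls(fx2, calls2, vcf$samples)
  attr(gm, "norm_counts") <- c(multi_allelic = sum(multi),
                               non_autosomal = sum(nonauto & !multi),
                               duplicate = sum(dup))
  gm
}

#' Genotype-level filters
#'
#' Sets to missing: half-calls, calls with GQ below `gq_min`, calls with DP
#' below `dp_min`, and heterozygous calls whose allele balance
#' `alt_reads / (ref_reads + alt_reads)` falls outside `ab_range`
#' (heterozygotes only). Calls lacking a quality field pass that specific
#' rule. Per-rule counts are attached as attribute `"genotype_filter_counts"`.
#'
#' @param gm a [geno_matrix()]
#' @param gq_min,dp_min,ab_range filter thresholds (strict inequalities)
#' @return the filtered [geno_matrix()]
#' @export
filter_genotypes <- function(gm, gq_min = 20, dp_min = 8,
                             ab_range = c(0.25, 0.75)) {
  present <- !is.na(gm$a1) | !is.na(gm$a2)
  half <- gt_half(gm) & present
  low_gq <- present & !is.na(gm$gq) & gm$gq < gq_min
  low_dp <- present & !is.na(gm$dp) & gm$dp < dp_min
  d <- gt_dosage(gm)
  ab <- gm$ad_alt / (gm$ad_ref + gm$ad_alt)
  ab_fail <- present & !is.na(d) & d == 1L & is.finite(ab) &
    (ab < ab_range[1] | ab > ab_range[2])
  mask <- half | low_gq | low_dp | ab_fail
  out <- set_missing(gm, mask)
  attr(out, "genotype_filter_counts") <- c(
    half_call = sum(half), low_gq = sum(low_gq), low_dp = sum(low_dp),
    allele_balance = sum(ab_fail), total_masked = sum(mask),
    missing_quality_fields = sum(present & is.na(gm$gq) & is.na(gm$dp)))
  out
}

# genotype configurations impossible under Mendelian transmission
trio_inconsistent <- function(f, m, c) {
  (c == 0L & (f == 2L | m == 2L)) |
    (c == 2L & (f == 0L | m == 0L)) |
    (c == 1L & ((f == 0L & m == 0L) | (f == 2L & m == 2L)))
}

duo_inconsistent <- function(p, c) (p == 2L & c == 0L) | (p == 0L & c == 2L)

#' Mendelian-inconsistency masking
#'
#' For every trio (and, optionally, parent-child duo with the other parent
#' ungenotyped) whose genotype configuration is impossible under Mendelian
#' transmission, all implicated calls are set to missing (the error cannot be
#' attributed to one member). Per-site error rates are computed over trios
#' with complete calls.
#'
#' @param gm a [geno_matrix()]
#' @param ped a [pedigree()]; members absent from the cohort are treated as
#'   ungenotyped unless `strict = TRUE`
#' @param use_duos also check parent-child duos (default TRUE)
#' @param strict error if the pedigree references samples absent from `gm`
#' @return list(gm, site_error_rate, site_n_trios, n_trios, n_masked_calls)
#' @export
mendel_mask <- function(gm, ped, use_duos = TRUE, strict = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  if (strict) {
    unknown <- setdiff(ped$df$id, gm$samples)
    if (length(unknown))
      stop("pedigree error: unknown sample(s) ", paste(unknown, collapse = ", "))
  }
  d <- gt_dosage(gm)
  S <- nrow(gm$sites)
  mask <- matrix(FALSE, S, length(gm$samples))
  tr <- ped_trios(ped)
  tr <- tr[tr$child %in% gm$samples & tr$father %in% gm$samples &
             tr$mother %in% gm$samples, , drop = FALSE]
  err_count <- integer(S); complete_count <- integer(S)
  if (nrow(tr)) {
    ci <- match(tr$child, gm$samples)
    fi <- match(tr$father, gm$samples)
    mi <- match(tr$mother, gm$samples)
    for (t in seq_len(nrow(tr))) {
      f <- d[, fi[t]]; m <- d[, mi[t]]; c <- d[, ci[t]]
      complete <- !is.na(f) & !is.na(m) & !is.na(c)
      err <- complete & trio_inconsistent(f, m, c)
      err_count <- err_count + err
      complete_count <- complete_count + complete
      mask[err, c(fi[t], mi[t], ci[t])] <- TRUE
    }
  }
  if (use_duos) {
    duos <- ped_duos(ped)
    other <- ifelse(duos$parent == ped$df$father[match(duos$child, ped$df$id)],
                    ped$df$mother[match(duos$child, ped$df$id)],
                    ped$df$father[match(duos$child, ped$df$id)])
    solo <- duos[duos$child %in% gm$samples & duos$parent %in% gm$samples &
                   (is.na(other) | !(other %in% gm$samples)), , drop = FALSE]
    if (nrow(solo)) {
      ci <- match(solo$child, gm$samples)
      pi <- match(solo$parent, gm$samples)
      for (t in seq_len(nrow(solo))) {
        p <- d[, pi[t]]; c <- d[, ci[t]]
        err <- !is.na(p) & !is.na(c) & duo_inconsistent(p, c)
        mask[err, c(pi[t], ci[t])] <- TRUE
      }
    }
  }
  rate <- ifelse(complete_count > 0, err_count / complete_count, 0)
  list(gm = set_missing(gm, mask),
       site_error_rate = rate, site_n_trios = complete_count,
       n_trios = nrow(tr), n_masked_calls = sum(mask))
}

#' Site-level filters
#'
#' Drops sites with missing rate above `max_missing`, trio Mendelian error
#' rate above `max_mendel`, exact HWE p-value below `hwe_p`, or no remaining
#' non-reference alleles. Thresholds are strict, as printed (e.g. missing
#' rate must *exceed* 25% to drop).
#'
#' @param gm a [geno_matrix()] with genotype-level masks already applied
#' @param ped optional [pedigree()] used to compute Mendelian error rates
#'   when `mendel_rates` is not supplied (note: rates computed *after*
#'   Mendelian masking are zero; pass the rates from [mendel_mask()])
#' @param thresholds a [qc_thresholds()] list
#' @param mendel_rates per-site error rates from [mendel_mask()]
#' @return list(gm, report) where report is a `qc_report`
#' @export
filter_sites <- function(gm, ped = NULL, thresholds = qc_thresholds(),
                         mendel_rates = NULL) {
  S <- nrow(gm$sites)
  if (is.null(mendel_rates)) {
    mendel_rates <- if (!is.null(ped)) mendel_mask(gm, ped)$site_error_rate
    else numeric(S)
  }
  d <- gt_dosage(gm)
  miss <- rowMeans(is.na(d))
  n0 <- rowSums(d == 0L, na.rm = TRUE)
  n1 <- rowSums(d == 1L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  informative <- (n0 + n1 + n2) > 0
  hwe_p <- rep(1, S)
  hwe_p[informative] <- hwe_exact(n0[informative], n1[informative], n2[informative])
  mono <- (n1 + n2) == 0
  fail_miss <- miss > thresholds$max_missing
  fail_mendel <- mendel_rates > thresholds$max_mendel
  fail_hwe <- hwe_p < thresholds$hwe_p
  drop <- fail_miss | fail_mendel | fail_hwe | mono
  report <- structure(list(
    n_input_sites = S, n_surviving = sum(!drop),
    site_counts = c(missingness = sum(fail_miss), mendel = sum(fail_mendel),
                    hwe = sum(fail_hwe), monomorphic = sum(mono),
                    dropped = sum(drop)),
    thresholds = thresholds), class = "qc_report")
  list(gm = subset_gm(gm, site_idx = which(!drop)), report = report)
}

#' Run the full QC cascade
#'
#' Genotype filters, then Mendelian masking, then site filters, collecting
#' all per-stage counts into one `qc_report`.
#'
#' @param gm a [geno_matrix()] (already normalized/biallelic)
#' @param ped a [pedigree()] (NULL skips Mendelian masking)
#' @param thresholds a [qc_thresholds()] list
#' @param use_duos check parent-child duos in the Mendelian step
#' @return list(gm, report)
#' @export
run_qc <- function(gm, ped = NULL, thresholds = qc_thresholds(),
                   use_duos = TRUE) {
  gm1 <- filter_genotypes(gm)
  gcounts <- attr(gm1, "genotype_filter_counts")
  if (!is.null(ped)) {
    mm <- mendel_mask(gm1, ped, use_duos = use_duos)
    gm2 <- mm$gm
    rates <- mm$site_error_rate
  } else {
    gm2 <- gm1
    rates <- numeric(nrow(gm$sites))
    mm <- list(n_trios = 0L, n_masked_calls = 0L)
  }
  fs <- filter_sites(gm2, thresholds = thresholds, mendel_rates = rates)
  rep <- fs$report
  rep$genotype_counts <- gcounts
  rep$mendel <- c(n_trios = mm$n_trios, n_masked_calls = mm$n_masked_calls)
  rep$norm_counts <- attr(gm, "norm_counts")
  list(gm = fs$gm, report = rep)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_input_sites, "sites in,", x$n_surviving, "surviving\n")
  cat("  site drops:", paste(names(x$site_counts), x$site_counts,
                             sep = "=", collapse = " "), "\n")
  if (!is.null(x$genotype_counts))
    cat("  genotype masks:", paste(names(x$genotype_counts), x$genotype_counts,
                                   sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Duplicate-sample genotype concordance
#'
#' Fraction of sites where both calls are non-missing and agree, reported
#' separately for SNVs and indels.
#'
#' @param gm a [geno_matrix()]
#' @param pairs list of length-2 character vectors of sample ids
#' @return data.frame(class, n_compared, n_agree, concordance)
#' @export
concordance <- function(gm, pairs) {
  d <- gt_dosage(gm)
  snv <- is_snv(gm$sites)
  acc <- list(SNV = c(0L, 0L), indel = c(0L, 0L))
  for (p in pairs) {
    i <- match(p[1], gm$samples); j <- match(p[2], gm$samples)
    if (is.na(i) || is.na(j))
      stop("concordance: unknown sample in pair ", paste(p, collapse = "/"))
    both <- !is.na(d[, i]) & !is.na(d[, j])
    agree <- both & d[, i] == d[, j]
    acc$SNV <- acc$SNV + c(sum(both & snv), sum(agree & snv))
    acc$indel <- acc$indel + c(sum(both & !snv), sum(agree & !snv))
  }
  data.frame(class = names(acc),
             n_compared = vapply(acc, `[`, integer(1), 1L),
             n_agree = vapply(acc, `[`, integer(1), 2L),
             concordance = vapply(acc, function(v)
               if (v[1] > 0) v[2] / v[1] else NA_real_, numeric(1)),
             row.names = NULL)
}

#' Variant-detection sensitivity by array MAF bin
#'
#' Array sites passing the high-quality rules (minor allele count > 0,
#' missing rate < 5%, HWE p > 1e-4) are binned by array MAF; per bin, the
#' fraction of sites also present and segregating in the sequencing call set
#' is reported.
#'
#' @param wgs sequencing [geno_matrix()]
#' @param array array [geno_matrix()]
#' @param bins increasing vector of right-closed upper MAF bin edges
#' @return data.frame(bin, bin_hi, n_array_sites, n_found, sensitivity)
#' @export
sensitivity_by_maf <- function(wgs, array, bins = c(0.01, 0.05, 0.1, 0.2,
                                                    0.3, 0.4, 0.5)) {
  if (!length(intersect(wgs$samples, array$samples)))
    stop("sensitivity_by_maf: no overlapping samples")
  d <- gt_dosage(array)
  mac <- pmin(rowSums(d, na.rm = TRUE),
              2 * rowSums(!is.na(d)) - rowSums(d, na.rm = TRUE))
  miss <- rowMeans(is.na(d))
  n0 <- rowSums(d == 0L, na.rm = TRUE); n1 <- rowSums(d == 1L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  ok <- (n0 + n1 + n2) > 0
  hwe_p <- rep(1, nrow(array$sites))
  hwe_p[ok] <- hwe_exact(n0[ok], n1[ok], n2[ok])
  hq <- mac > 0 & miss < 0.05 & hwe_p > 1e-4
  maf <- gm_maf(array)
  dw <- gt_dosage(wgs)
  seg <- rowSums(dw, na.rm = TRUE) > 0
  wgs_key <- paste(wgs$sites$chrom, wgs$sites$pos)[seg]
  found <- paste(array$sites$chrom, array$sites$pos) %in% wgs_key
  bin <- cut(maf, breaks = c(0, bins), include.lowest = FALSE)
  out <- data.frame(bin = levels(bin), bin_hi = bins)
  out$n_array_sites <- as.vector(table(bin[hq]))
  out$n_found <- as.vector(table(bin[hq & found]))
  out$sensitivity <- ifelse(out$n_array_sites > 0,
                            out$n_found / out$n_array_sites, NA_real_)
  out
}
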