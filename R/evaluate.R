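# ---- masking / imputation evaluation harness -------------------------------

#' Default MAF bin edges for imputation evaluation
#'
#' Fourteen right-closed upper edges, log-dense at rare frequencies; sites
#' absent from the bin-source population fall in the lowest bin.
#'
#' @return numeric vector of upper bin edges
#' @export
default_maf_bins <- function() {
  c(0.0005, 0.001, 0.002, 0.005, 0.01, 0.02, 0.03, 0.05,
    0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
}

# right-closed bin index; maf <= lowest edge (including 0 / absent) -> bin 1
maf_bin_index <- function(maf, edges) {
  pmin(findInterval(maf, edges, left.open = TRUE) + 1L, length(edges))
}

#' Mask a test set down to array sites
#'
#' @param test a phased [hap_panel()] (or [geno_matrix()]) of test samples
#' @param manifest data.frame(chrom, pos) of array sites; must intersect the
#'   test site set
#' @return list(typed, truth_dosage [samples x masked sites], masked_sites,
#'   typed_sites)
#' @export
mask_to_array <- function(test, manifest) {
  if (!nrow(manifest)) stop("mask_to_array: empty manifest")
  sites <- test$sites
  key <- paste(sites$chrom, sites$pos)
  typed_idx <- which(key %in% paste(manifest$chrom, manifest$pos))
  if (!length(typed_idx))
    stop("mask_to_array: manifest disjoint from test site set")
  masked_idx <- setdiff(seq_len(nrow(sites)), typed_idx)
  if (inherits(test, "hap_panel")) {
    typed <- subset_panel(test, site_idx = typed_idx)
    n <- ncol(test$haps) %/% 2L
    odd <- seq(1L, by = 2L, length.out = n)
    truth <- t(test$haps[masked_idx, odd, drop = FALSE] +
                 test$haps[masked_idx, odd + 1L, drop = FALSE])
    rownames(truth) <- test$hap_samples[odd]
  } else {
    typed <- subset_gm(test, site_idx = typed_idx)
    truth <- t(gt_dosage(test)[masked_idx, , drop = FALSE])
    rownames(truth) <- test$samples
  }
  list(typed = typed, truth_dosage = truth,
       masked_sites = sites[masked_idx, , drop = FALSE],
       typed_sites = sites[typed_idx, , drop = FALSE])
}

#' Aggregate r-squared by MAF bin
#'
#' Pools all (imputed, true) dosage pairs of each bin's sites into two
#' vectors and reports the squared Pearson correlation. Bins where either
#' pooled vector has zero variance are undefined (NA, `defined = FALSE`),
#' not zero.
#'
#' @param imputed,truth numeric matrices (samples x sites), same shape
#' @param bins right-closed upper MAF bin edges
#' @param bin_maf per-site MAF used for binning (0 / absent -> lowest bin)
#' @return data.frame(bin, bin_lo, bin_hi, n_variants, r2, defined)
#' @export
aggregate_r2 <- function(imputed, truth, bins = default_maf_bins(), bin_maf) {
  if (!all(dim(imputed) == dim(truth)))
    stop("aggregate_r2: imputed/truth shape mismatch")
  stopifnot(length(bin_maf) == ncol(truth))
  idx <- maf_bin_index(bin_maf, bins)
  lo <- c(0, utils::head(bins, -1))
  out <- data.frame(bin = seq_along(bins), bin_lo = lo, bin_hi = bins,
                    n_variants = 0L, r2 = NA_real_, defined = FALSE)
  for (b in seq_along(bins)) {
    cols <- which(idx == b)
    out$n_variants[b] <- length(cols)
    if (!length(cols)) next
    x <- as.vector(imputed[, cols, drop = FALSE])
    y <- as.vector(truth[, cols, drop = FALSE])
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      out$r2[b] <- stats::cor(x, y)^2
      out$defined[b] <- TRUE
    }
  }
  out
}

#' Run the masking / imputation comparison across panel configurations
#'
#' Masks the test set to array sites, imputes the masked sites against each
#' named panel, and scores per-bin aggregate r-squared over the variants
#' present in *all* panels (so configurations are compared on a common site
#' set). When `cohort` and `merged` configurations are present, additionally
#' reports the sharing accounting of masked cohort variants across the other
#' panels and the imputation accuracy of cohort-specific variants under the
#' merged panel.
#'
#' @param test phased [hap_panel()] of held-out test samples
#' @param panels named list of [hap_panel()] configurations
#' @param manifest data.frame(chrom, pos) of typed array sites
#' @param bins right-closed MAF bin edges
#' @param params an [ls_params()]
#' @param bin_source name of the panel whose MAF defines the bins
#'   (default: first panel that is neither `cohort` nor `merged`, else the
#'   first panel)
#' @param cohort,merged names of the cohort-only and merged configurations
#' @return an `eval_report`: list(r2, sharing, specific, n_scored, bins)
#' @export
compare_configs <- function(test, panels, manifest, bins = default_maf_bins(),
                            params = ls_params(), bin_source = NULL,
                            cohort = "cohort", merged = "merged") {
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    stop("compare_configs: panels must be a named list")
  if (is.null(bin_source)) {
    cand <- setdiff(names(panels), c(cohort, merged))
    bin_source <- if (length(cand)) cand[1] else names(panels)[1]
  }
  ma <- mask_to_array(test, manifest)
  masked_key <- paste(ma$masked_sites$chrom, ma$masked_sites$pos)
  panel_keys <- lapply(panels, function(p) paste(p$sites$chrom, p$sites$pos))
  in_all <- Reduce(`&`, lapply(panel_keys, function(k) masked_key %in% k))
  scored_key <- masked_key[in_all]
  bmaf <- panel_maf(panels[[bin_source]])[match(scored_key,
                                                panel_keys[[bin_source]])]
  dosages <- lapply(panels, function(p) impute_dosages(ma$typed, p, params))
  r2 <- do.call(rbind, lapply(names(panels), function(nm) {
    dm <- dosages[[nm]]
    cols <- match(scored_key, paste(dm$sites$chrom, dm$sites$pos))
    imp <- dm$dosage[, cols, drop = FALSE]
    tru <- ma$truth_dosage[, match(scored_key, masked_key), drop = FALSE]
    cbind(config = nm, aggregate_r2(imp, tru, bins, bmaf))
  }))

  sharing <- NULL; specific <- NULL
  refs <- setdiff(names(panels), c(cohort, merged))
  if (cohort %in% names(panels) && length(refs)) {
    ck <- panel_keys[[cohort]]
    cohort_masked <- masked_key[masked_key %in% ck]
    cmaf <- panel_maf(panels[[cohort]])[match(cohort_masked, ck)]
    sharing <- specific_variant_report(
      sites_key = cohort_masked, cohort_maf = cmaf,
      reference_keys = panel_keys[refs], bins = bins)
    if (merged %in% names(panels)) {
      spec_key <- cohort_masked[!Reduce(`|`, lapply(
        panel_keys[refs], function(k) cohort_masked %in% k))]
      if (length(spec_key)) {
        dm <- dosages[[merged]]
        cols <- match(spec_key, paste(dm$sites$chrom, dm$sites$pos))
        imp <- dm$dosage[, cols, drop = FALSE]
        tru <- ma$truth_dosage[, match(spec_key, masked_key), drop = FALSE]
        r2s <- if (stats::sd(as.vector(imp)) > 0 &&
                   stats::sd(as.vector(tru)) > 0)
          stats::cor(as.vector(imp), as.vector(tru))^2 else NA_real_
        specific <- list(n = length(spec_key), r2 = r2s)
      } else specific <- list(n = 0L, r2 = NA_real_)
    }
  }
  structure(list(r2 = r2, sharing = sharing, specific = specific,
                 n_scored = length(scored_key), bins = bins,
                 bin_source = bin_source),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", x$n_scored, "scored variants,",
      length(unique(x$r2$config)), "configurations\n")
  print(x$r2[x$r2$defined, c("config", "bin_lo", "bin_hi", "n_variants", "r2")],
        row.names = FALSE)
  invisible(x)
}

#' Sharing accounting of cohort variants across reference panels
#'
#' Each cohort variant is assigned to exactly one category: the first
#' reference panel (in the given order) that contains it, or "none"
#' (cohort-specific). Per cohort-MAF bin, category proportions sum to 1.
#'
#' @param sites_key character keys ("chrom pos") of cohort variants
#' @param cohort_maf per-variant cohort MAF (for binning)
#' @param reference_keys named list of reference-panel site-key vectors
#' @param bins right-closed MAF bin edges
#' @return data.frame(bin, bin_hi, category, n, proportion)
#' @export
specific_variant_report <- function(sites_key, cohort_maf, reference_keys,
                                    bins = default_maf_bins()) {
  cat_order <- c(names(reference_keys), "none")
  category <- rep("none", length(sites_key))
  for (nm in rev(names(reference_keys)))
    category[sites_key %in% reference_keys[[nm]]] <- nm
  bin <- maf_bin_index(cohort_maf, bins)
  tab <- table(factor(bin, levels = seq_along(bins)),
               factor(category, levels = cat_order))
  tot <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("bin", "category", "n")
  out$bin <- as.integer(out$bin)
  out$bin_hi <- bins[out$bin]
  out$proportion <- ifelse(tot[out$bin] > 0, out$n / tot[out$bin], NA_real_)
  out[order(out$bin, match(out$category, cat_order)),
      c("bin", "bin_hi", "category", "n", "proportion")]
}
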