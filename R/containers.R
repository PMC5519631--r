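#' @keywords internal
"_PACKAGE"

# ---- core containers -------------------------------------------------------
#
# All matrices are sites x columns (samples or haplotypes). Sites are carried
# as a data.frame (chrom, pos, ref, alt[, cm]); pos is 1-based, cM intervals
# are half-open [start, end).

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Phased haplotype panel
#'
#' A reference-panel object: ordered biallelic sites with genetic-map (cM)
#' positions and a 0/1 haplotype matrix, two haplotypes per diploid sample.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt, cm; pos strictly
#'   increasing within the (single) chromosome.
#' @param haps integer matrix, `nrow(sites)` x n_haplotypes, values 0/1.
#' @param hap_samples character vector naming the sample of origin of each
#'   haplotype column (each diploid sample appears twice).
#' @param map_length_cm total genetic map length in cM (used as the segment
#'   and sharing denominator); defaults to the cM span of `sites`.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(sites, haps, hap_samples, map_length_cm = NULL) {
  stopifnot(is.data.frame(sites), nrow(sites) == nrow(haps),
            length(hap_samples) == ncol(haps))
  if (is.null(sites$cm)) stop("panel sites need a 'cm' column")
  if (nrow(sites) > 1 && any(diff(sites$pos) <= 0))
    stop("panel sites must be strictly increasing in pos")
  if (!all(haps %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  storage.mode(haps) <- "integer"
  if (is.null(map_length_cm))
    map_length_cm <- max(sites$cm) - min(0, min(sites$cm))
  colnames(haps) <- make_hap_names(hap_samples)
  structure(list(sites = sites, haps = haps,
                 hap_samples = as.character(hap_samples),
                 map_length_cm = map_length_cm),
            class = "hap_panel")
}

make_hap_names <- function(hap_samples) {
  idx <- stats::ave(seq_along(hap_samples), hap_samples, FUN = seq_along)
  paste0(hap_samples, ".", idx)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d sites x %d haplotypes (%d samples), %.1f cM\n",
              nrow(x$sites), ncol(x$haps), length(unique(x$hap_samples)),
              x$map_length_cm))
  invisible(x)
}

n_hap_sites <- function(p) nrow(p$sites)

panel_samples <- function(p) unique(p$hap_samples)

#' Alternate-allele frequency of each panel site
#' @param p a [hap_panel()]
#' @return numeric vector of alt-allele frequencies
#' @export
panel_freq <- function(p) rowMeans(p$haps)

#' Minor-allele frequency of each panel site
#' @param p a [hap_panel()]
#' @return numeric vector of MAF values in `[0, 0.5]`
#' @export
panel_maf <- function(p) pmin(panel_freq(p), 1 - panel_freq(p))

subset_panel <- function(p, site_idx = NULL, hap_idx = NULL) {
  s <- if (is.null(site_idx)) p$sites else p$sites[site_idx, , drop = FALSE]
  h <- p$haps
  if (!is.null(site_idx)) h <- h[site_idx, , drop = FALSE]
  if (!is.null(hap_idx)) h <- h[, hap_idx, drop = FALSE]
  hs <- if (is.null(hap_idx)) p$hap_samples else p$hap_samples[hap_idx]
  hap_panel(s, h, hs, map_length_cm = p$map_length_cm)
}

#' Diploid genotype matrix with per-call quality metadata
#'
#' Per-call storage is two allele matrices (`a1`, `a2`; NA for an undetermined
#' allele, so a half-call has exactly one NA) plus a phased flag and GQ, DP and
#' allele-depth matrices. Dosages are derived, never stored.
#'
#' @param sites data.frame(chrom, pos, ref, alt); biallelic records only.
#' @param samples character vector of sample identifiers.
#' @param a1,a2 integer matrices (sites x samples) of first/second alleles,
#'   values 0/1/NA.
#' @param phased logical matrix; TRUE where the call was written with "|".
#' @param gq,dp,ad_ref,ad_alt numeric matrices; NA where the field was absent.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, samples, a1, a2, phased = NULL, gq = NULL,
                        dp = NULL, ad_ref = NULL, ad_alt = NULL) {
  S <- nrow(sites); N <- length(samples)
  blank <- function(x, fill) {
    if (is.null(x)) matrix(fill, S, N) else x
  }
  a1 <- as_int_mat(a1); a2 <- as_int_mat(a2)
  stopifnot(all(dim(a1) == c(S, N)), all(dim(a2) == c(S, N)))
  obj <- structure(list(
    sites = sites, samples = as.character(samples),
    a1 = a1, a2 = a2,
    phased = blank(phased, FALSE),
    gq = blank(gq, NA_real_), dp = blank(dp, NA_real_),
    ad_ref = blank(ad_ref, NA_real_), ad_alt = blank(ad_alt, NA_real_)),
    class = "geno_matrix")
  obj
}

as_int_mat <- function(m) { storage.mode(m) <- "integer"; m }

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(gt_dosage(x)))))
  invisible(x)
}

#' Alternate-allele dosage matrix (0/1/2, NA when either allele is unknown)
#' @param gm a [geno_matrix()]
#' @return integer matrix sites x samples
#' @export
gt_dosage <- function(gm) gm$a1 + gm$a2

#' Half-call indicator (exactly one undetermined allele)
#' @param gm a [geno_matrix()]
#' @return logical matrix sites x samples
#' @export
gt_half <- function(gm) xor(is.na(gm$a1), is.na(gm$a2))

#' Cohort minor-allele frequency per site (missing calls dropped)
#' @param gm a [geno_matrix()]
#' @return numeric vector
#' @export
gm_maf <- function(gm) {
  p <- rowMeans(gt_dosage(gm), na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

gm_alt_freq <- function(gm) rowMeans(gt_dosage(gm), na.rm = TRUE) / 2

subset_gm <- function(gm, site_idx = NULL, sample_idx = NULL) {
  pick <- function(m) {
    if (!is.null(site_idx)) m <- m[site_idx, , drop = FALSE]
    if (!is.null(sample_idx)) m <- m[, sample_idx, drop = FALSE]
    m
  }
  geno_matrix(
    sites = if (is.null(site_idx)) gm$sites else gm$sites[site_idx, , drop = FALSE],
    samples = if (is.null(sample_idx)) gm$samples else gm$samples[sample_idx],
    a1 = pick(gm$a1), a2 = pick(gm$a2), phased = pick(gm$phased),
    gq = pick(gm$gq), dp = pick(gm$dp),
    ad_ref = pick(gm$ad_ref), ad_alt = pick(gm$ad_alt))
}

set_missing <- function(gm, mask) {
  gm$a1[mask] <- NA_integer_
  gm$a2[mask] <- NA_integer_
  gm
}

is_snv <- function(sites) nchar(sites$ref) == 1L & nchar(sites$alt) == 1L

#' Pedigree
#'
#' @param df data.frame with columns id, father, mother, sex (1 = male,
#'   2 = female) and optionally fid and generation; unknown parents are NA
#'   (the PED code "0" is mapped to NA on read).
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(df) {
  need <- c("id", "father", "mother", "sex")
  stopifnot(all(need %in% names(df)))
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  if (anyDuplicated(df$id)) stop("duplicate individual id in pedigree")
  bad <- setdiff(stats::na.omit(c(df$father, df$mother)), df$id)
  if (length(bad))
    stop("pedigree parent id(s) not present as individuals: ",
         paste(bad, collapse = ", "))
  if (is.null(df$fid)) df$fid <- "FAM"
  structure(list(df = df), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, %d founders, %d trios\n",
              nrow(x$df), length(ped_founders(x)), nrow(ped_trios(x))))
  invisible(x)
}

#' Founders (both parents unknown)
#' @param ped a [pedigree()]
#' @return character vector of ids
#' @export
ped_founders <- function(ped) {
  with(ped$df, id[is.na(father) & is.na(mother)])
}

#' Trio list (child with both parents known)
#' @param ped a [pedigree()]
#' @return data.frame(child, father, mother)
#' @export
ped_trios <- function(ped) {
  d <- ped$df[!is.na(ped$df$father) & !is.na(ped$df$mother), ]
  data.frame(child = d$id, father = d$father, mother = d$mother,
             stringsAsFactors = FALSE)
}

# parent-child duos (at least one parent known); one row per known parent link
ped_duos <- function(ped) {
  d <- ped$df
  rbind(
    data.frame(child = d$id[!is.na(d$father)], parent = d$father[!is.na(d$father)]),
    data.frame(child = d$id[!is.na(d$mother)], parent = d$mother[!is.na(d$mother)]))
}

# topological order: parents before children; errors on cycles
ped_topo_order <- function(ped) {
  d <- ped$df
  n <- nrow(d)
  idx <- stats::setNames(seq_len(n), d$id)
  fa <- idx[d$father]; mo <- idx[d$mother]
  depth <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(fa[i]) || !is.na(depth[fa[i]])) &&
        (is.na(mo[i]) || !is.na(depth[mo[i]]))
    }, logical(1))]
    if (!length(ready)) stop("pedigree contains a cycle")
    depth[ready] <- level
    remaining <- setdiff(remaining, ready)
    level <- level + 1L
  }
  order(depth, seq_len(n))
}
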