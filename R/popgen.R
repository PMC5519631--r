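# ---- population-genetic characterizations ----------------------------------

#' BLUE allele-frequency estimate for one site
#'
#' Best linear unbiased estimator on a pedigree: with the kinship matrix
#' `Phi*` (diagonal `(1 + F_i)/2`, off-diagonal pairwise kinship) and
#' per-individual allele fractions g in {0, 1/2, 1},
#' `p_hat = (1' Phi*^-1 g) / (1' Phi*^-1 1)` with
#' `se^2 = p_hat (1 - p_hat) / (1' Phi*^-1 1)`. Missing individuals are
#' dropped per site.
#'
#' @param g numeric vector of allele fractions (dosage / 2), NA = missing
#' @param kin kinship matrix (as from [pedigree_kinship()]) with dimnames
#'   matching `g`'s names, or positionally matching
#' @return list(p, se, n)
#' @export
blue_frequency <- function(g, kin) {
  keep <- which(!is.na(g))
  if (!length(keep)) return(list(p = NA_real_, se = NA_real_, n = 0L))
  K <- kin[keep, keep, drop = FALSE]
  w <- tryCatch(solve(K, rep(1, length(keep))),
                error = function(e)
                  stop("blue_frequency: singular kinship matrix (duplicate ",
                       "individuals?); deduplicate the cohort"))
  denom <- sum(w)
  p <- sum(w * g[keep]) / denom
  p <- min(max(p, 0), 1)
  list(p = p, se = sqrt(p * (1 - p) / denom), n = length(keep))
}

#' BLUE allele frequencies for every site of a cohort
#'
#' Vectorizes [blue_frequency()] over sites, caching the inverse-kinship
#' weights per missingness pattern. Individuals absent from the pedigree are
#' an error.
#'
#' @param gm a [geno_matrix()]
#' @param ped a [pedigree()] (or a precomputed kinship matrix via `kin`)
#' @param kin optional kinship matrix
#' @return a `freq_table` data.frame: chrom, pos, n, naive_freq, blue_freq,
#'   blue_se, maf (BLUE minor-allele frequency) and maf_class
#' @export
blue_frequencies <- function(gm, ped = NULL, kin = NULL) {
  if (is.null(kin)) kin <- pedigree_kinship(ped)
  if (!all(gm$samples %in% rownames(kin)))
    stop("blue_frequencies: cohort samples missing from kinship/pedigree")
  K <- kin[gm$samples, gm$samples, drop = FALSE]
  G <- gt_dosage(gm) / 2
  pat <- apply(!is.na(G), 1L, function(z) paste(which(z), collapse = ","))
  p_hat <- rep(NA_real_, nrow(G)); se <- rep(NA_real_, nrow(G))
  nn <- integer(nrow(G))
  for (pt in unique(pat)) {
    keep <- as.integer(strsplit(pt, ",", fixed = TRUE)[[1]])
    rows <- which(pat == pt)
    if (!length(keep)) next
    w <- tryCatch(solve(K[keep, keep, drop = FALSE], rep(1, length(keep))),
                  error = function(e)
                    stop("blue_frequencies: singular kinship matrix ",
                         "(duplicate individuals?)"))
    denom <- sum(w)
    p <- as.vector(G[rows, keep, drop = FALSE] %*% w) / denom
    p <- pmin(pmax(p, 0), 1)
    p_hat[rows] <- p
    se[rows] <- sqrt(p * (1 - p) / denom)
    nn[rows] <- length(keep)
  }
  maf <- pmin(p_hat, 1 - p_hat)
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos, n = nn,
             naive_freq = rowMeans(G, na.rm = TRUE), blue_freq = p_hat,
             blue_se = se, maf = maf, maf_class = maf_class(maf),
             stringsAsFactors = FALSE)
}

#' Three-way MAF classification
#'
#' Strict boundary convention: rare `< edges[1]`, low-frequency
#' `[edges[1], edges[2]]`, common `> edges[2]`; monomorphic (MAF 0) sites
#' are "absent".
#'
#' @param maf numeric MAF vector
#' @param edges two interior edges (default 0.005 and 0.05)
#' @return factor with levels absent, rare, low, common
#' @export
maf_class <- function(maf, edges = c(0.005, 0.05)) {
  out <- rep(NA_character_, length(maf))
  out[!is.na(maf) & maf == 0] <- "absent"
  out[!is.na(maf) & maf > 0 & maf < edges[1]] <- "rare"
  out[!is.na(maf) & maf >= edges[1] & maf <= edges[2]] <- "low"
  out[!is.na(maf) & maf > edges[2]] <- "common"
  factor(out, levels = c("absent", "rare", "low", "common"))
}

#' Rare-variant depletion by reference resampling
#'
#' Counts segregating SNVs per MAF class among a fixed subset of
#' pedigree-unrelated cohort individuals (unrelated up to the 3rd degree,
#' first `n_sub` in sorted order), and compares with `n_reps` subsamples of
#' `n_sub` reference individuals drawn with replacement. MAF is recomputed
#' within each counting subsample.
#'
#' @param cohort,reference [geno_matrix()] objects
#' @param ped cohort [pedigree()]
#' @param n_sub subsample size
#' @param n_reps reference resampling replicates (default 10)
#' @param edges interior MAF-class edges (see [maf_class()])
#' @param seed integer seed
#' @return data.frame(class, cohort_count, ref_mean, ref_sd) with the
#'   per-replicate reference counts as attribute `"ref_counts"`
#' @export
depletion_resample <- function(cohort, reference, ped, n_sub, n_reps = 10,
                               edges = c(0.005, 0.05), seed = 1) {
  unrel <- select_unrelated(ped, max_degree = 3, ids = cohort$samples)
  if (length(unrel) < n_sub)
    stop("depletion_resample: insufficient unrelated individuals ",
         "(achievable n = ", length(unrel), ")")
  if (length(reference$samples) < n_sub)
    stop("depletion_resample: reference smaller than n_sub")
  use <- sort(unrel)[seq_len(n_sub)]
  classes <- c("rare", "low", "common")
  count_classes <- function(d, snv) {
    p <- rowMeans(d, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    cl <- maf_class(maf, edges)
    tab <- table(cl[snv & !is.na(maf) & maf > 0])
    as.integer(tab[classes])
  }
  d_c <- gt_dosage(cohort)[, match(use, cohort$samples), drop = FALSE]
  cohort_counts <- count_classes(d_c, is_snv(cohort$sites))
  d_r <- gt_dosage(reference)
  snv_r <- is_snv(reference$sites)
  reps <- with_seed(substream_seed(seed, "depletion"), {
    vapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(d_r), n_sub, replace = TRUE)
      count_classes(d_r[, cols, drop = FALSE], snv_r)
    }, integer(length(classes)))
  })
  out <- data.frame(class = classes, cohort_count = cohort_counts,
                    ref_mean = rowMeans(reps), ref_sd = apply(reps, 1L, stats::sd),
                    stringsAsFactors = FALSE)
  attr(out, "ref_counts") <- reps
  out
}

#' Drifted variants: rare or absent in the reference, common in the cohort
#'
#' @param cohort_freqs data.frame(chrom, pos, maf) — BLUE cohort MAF
#' @param reference_freqs data.frame(chrom, pos, maf); cohort sites absent
#'   here are treated as reference MAF 0
#' @param ref_max strict reference-MAF upper bound (default 0.005)
#' @param cohort_min strict cohort-MAF lower bound (default 0.05)
#' @return list(variants, n, crosstab) where crosstab cross-tabulates the
#'   reference and cohort MAF classes
#' @export
drift_enrichment <- function(cohort_freqs, reference_freqs,
                             ref_max = 0.005, cohort_min = 0.05) {
  key_c <- paste(cohort_freqs$chrom, cohort_freqs$pos)
  key_r <- paste(reference_freqs$chrom, reference_freqs$pos)
  ref_maf <- reference_freqs$maf[match(key_c, key_r)]
  ref_maf[is.na(ref_maf)] <- 0
  sel <- ref_maf < ref_max & cohort_freqs$maf > cohort_min
  variants <- cbind(cohort_freqs[sel, , drop = FALSE],
                    reference_maf = ref_maf[sel])
  list(variants = variants, n = sum(sel),
       crosstab = table(reference = maf_class(ref_maf),
                        cohort = maf_class(cohort_freqs$maf)))
}

# haplotype-pair helpers --------------------------------------------------

#' Haplotype pairs for IBD / HBD segment detection
#'
#' `ibd_hap_pairs` returns the 4 haplotype pairings for every pair of
#' individuals (within one id set, or between two sets); `hbd_hap_pairs`
#' returns each individual's own two haplotypes.
#'
#' @param ids1,ids2 individual id vectors; `ids2 = NULL` means all pairs
#'   within `ids1`
#' @return data.frame(hap1, hap2, id1, id2)
#' @export
ibd_hap_pairs <- function(ids1, ids2 = NULL) {
  pairs <- if (is.null(ids2)) {
    if (length(ids1) < 2) return(NULL)
    t(utils::combn(ids1, 2))
  } else as.matrix(expand.grid(ids1, ids2, stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expand.grid(hap1 = paste0(i, ".", 1:2), hap2 = paste0(j, ".", 1:2),
                stringsAsFactors = FALSE)
  }))
  out$id1 <- sub("\\.[12]$", "", out$hap1)
  out$id2 <- sub("\\.[12]$", "", out$hap2)
  out
}

#' @rdname ibd_hap_pairs
#' @param ids individual ids
#' @export
hbd_hap_pairs <- function(ids) {
  data.frame(hap1 = paste0(ids, ".1"), hap2 = paste0(ids, ".2"),
             id1 = ids, id2 = ids, stringsAsFactors = FALSE)
}

# site boundaries in cM: midpoints between sites, map ends at 0 and L
site_boundaries <- function(cm, map_length_cm) {
  S <- length(cm)
  if (S == 1L) return(c(0, map_length_cm))
  c(0, (cm[-1] + cm[-S]) / 2, map_length_cm)
}

# maximal runs of TRUE in `eq`, allowing up to max_mismatch FALSE sites per
# segment (greedy left-to-right extension); returns site-index intervals
identity_runs <- function(eq, max_mismatch) {
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  true_runs <- which(r$values)
  if (!length(true_runs)) return(NULL)
  segs <- list()
  k <- 1L
  while (k <= length(true_runs)) {
    i <- true_runs[k]
    seg_start <- starts[i]
    seg_end <- ends[i]
    budget <- max_mismatch
    k2 <- k
    while (k2 < length(true_runs)) {
      gap_run <- true_runs[k2] + 1L      # the FALSE run between
      gap <- r$lengths[gap_run]
      if (gap <= budget && true_runs[k2 + 1L] == gap_run + 1L) {
        budget <- budget - gap
        k2 <- k2 + 1L
        seg_end <- ends[true_runs[k2]]
      } else break
    }
    segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
    k <- k2 + 1L
  }
  do.call(rbind, segs)
}

#' Detect IBD / HBD segments
#'
#' In `truth` mode, segments are maximal intervals where two haplotypes
#' carry the same founder label (exact, from gene-dropping truth tracks).
#' In `haplotype` mode, segments are maximal intervals of allele identity
#' between two phased haplotypes, allowing up to `max_mismatch` mismatching
#' sites per segment. Segment coordinates are half-open cM intervals built
#' from inter-site midpoints; segments shorter than `min_cm` are discarded.
#'
#' @param x a `truth_tracks` (truth mode) or [hap_panel()] (haplotype mode)
#' @param mode "truth" or "haplotype"
#' @param pairs data.frame(hap1, hap2, id1, id2) from [ibd_hap_pairs()] /
#'   [hbd_hap_pairs()]
#' @param min_cm minimum reported segment length (default 3 cM)
#' @param max_mismatch mismatch tolerance for haplotype mode (default 2)
#' @return a `segment_set` data.frame: hap1, hap2, id1, id2, start_cm,
#'   end_cm, length_cm
#' @export
detect_segments <- function(x, mode = c("truth", "haplotype"), pairs,
                            min_cm = 3, max_mismatch = 2) {
  mode <- match.arg(mode)
  if (mode == "truth") {
    stopifnot(inherits(x, "truth_tracks"))
    M <- x$label_matrix
    cm <- x$sites$cm
    L <- x$map_length_cm
    mm <- 0L
  } else {
    stopifnot(inherits(x, "hap_panel"))
    M <- x$haps
    cm <- x$sites$cm
    L <- x$map_length_cm
    mm <- max_mismatch
  }
  if (anyNA(cm)) stop("detect_segments: unmapped sites (missing cM)")
  bnd <- site_boundaries(cm, L)
  empty <- data.frame(hap1 = character(0), hap2 = character(0),
                      id1 = character(0), id2 = character(0),
                      start_cm = numeric(0), end_cm = numeric(0),
                      length_cm = numeric(0), stringsAsFactors = FALSE)
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    h1 <- pairs$hap1[r]; h2 <- pairs$hap2[r]
    if (!(h1 %in% colnames(M)) || !(h2 %in% colnames(M)))
      stop("detect_segments: unknown haplotype ", h1, " or ", h2)
    runs <- identity_runs(M[, h1] == M[, h2], mm)
    if (is.null(runs)) next
    start_cm <- bnd[runs[, 1]]
    end_cm <- bnd[runs[, 2] + 1L]
    len <- end_cm - start_cm
    keep <- len >= min_cm
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      hap1 = h1, hap2 = h2, id1 = pairs$id1[r], id2 = pairs$id2[r],
      start_cm = start_cm[keep], end_cm = end_cm[keep],
      length_cm = len[keep], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  structure(do.call(rbind, out), class = c("segment_set", "data.frame"))
}

#' Summarize IBD / HBD sharing
#'
#' Pair IBD sharing is reported on the kinship scale: the summed matched cM
#' over the four haplotype pairings divided by twice the map length, so the
#' gene-dropping expectation equals `2 * phi`. HBD is the total cM of
#' own-haplotype segments per individual.
#'
#' @param segments a `segment_set` from [detect_segments()]
#' @param map_length_cm map length (denominator)
#' @param pairs optional data.frame(id1, id2) universe of individual pairs,
#'   so pairs without segments report fraction 0
#' @param ids optional id universe for the HBD table
#' @return list(ibd = data.frame(id1, id2, total_cm, fraction),
#'   hbd = data.frame(id, total_cm))
#' @export
sharing_summaries <- function(segments, map_length_cm, pairs = NULL,
                              ids = NULL) {
  seg <- as.data.frame(segments)
  is_hbd <- seg$id1 == seg$id2
  ib <- seg[!is_hbd, , drop = FALSE]
  key <- paste(pmin(ib$id1, ib$id2), pmax(ib$id1, ib$id2), sep = "|")
  tot <- tapply(ib$length_cm, key, sum)
  if (is.null(pairs)) {
    ukey <- sort(unique(key))
  } else {
    ukey <- unique(paste(pmin(pairs$id1, pairs$id2),
                         pmax(pairs$id1, pairs$id2), sep = "|"))
  }
  tt <- ifelse(ukey %in% names(tot), tot[ukey], 0)
  ibd <- data.frame(
    id1 = sub("\\|.*", "", ukey), id2 = sub(".*\\|", "", ukey),
    total_cm = as.numeric(tt),
    fraction = as.numeric(tt) / (2 * map_length_cm),
    stringsAsFactors = FALSE)
  hb <- seg[is_hbd, , drop = FALSE]
  htot <- tapply(hb$length_cm, hb$id1, sum)
  hids <- if (is.null(ids)) sort(unique(hb$id1)) else ids
  hbd <- data.frame(id = hids,
                    total_cm = as.numeric(ifelse(hids %in% names(htot),
                                                 htot[hids], 0)),
                    stringsAsFactors = FALSE)
  list(ibd = ibd, hbd = hbd)
}

#' Deleteriousness comparison by sharing status
#'
#' Within each stratum (cohort MAF class, optionally crossed with a
#' coding/non-coding label carried in a `class` column of the score table),
#' compares scores of shared versus cohort-specific variants with a
#' two-sided Wilcoxon rank-sum test (tie-corrected normal approximation
#' with continuity correction; exact when both groups have <= 20
#' observations and no ties). Strata with an empty group are reported as
#' not testable rather than erroring.
#'
#' @param scores data.frame(chrom, pos, score, status) from
#'   [assign_scores()], optionally with a `class` column
#' @param freqs data.frame(chrom, pos, maf) — cohort (BLUE) frequencies
#' @param edges interior MAF-class edges (see [maf_class()])
#' @return data.frame with one row per stratum: maf_class, class (if any),
#'   n_shared, n_specific, mean_shared, mean_specific, p_value, testable
#' @export
deleteriousness_compare <- function(scores, freqs, edges = c(0.005, 0.05)) {
  key_s <- paste(scores$chrom, scores$pos)
  key_f <- paste(freqs$chrom, freqs$pos)
  maf <- freqs$maf[match(key_s, key_f)]
  if (anyNA(maf))
    stop("deleteriousness_compare: scored variant(s) missing a frequency")
  cl <- maf_class(maf, edges)
  strata <- if (!is.null(scores$class))
    split(seq_along(key_s), list(cl, scores$class), drop = FALSE)
  else split(seq_along(key_s), cl, drop = FALSE)
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    sh <- scores$score[idx][scores$status[idx] == "shared"]
    sp <- scores$score[idx][scores$status[idx] == "cohort_specific"]
    testable <- length(sh) > 0 && length(sp) > 0
    p <- NA_real_
    if (testable) {
      exact <- length(sh) <= 20 && length(sp) <= 20 &&
        !anyDuplicated(c(sh, sp))
      p <- suppressWarnings(stats::wilcox.test(
        sp, sh, alternative = "two.sided", exact = exact,
        correct = TRUE)$p.value)
    }
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(maf_class = parts[1],
               class = if (length(parts) > 1) parts[2] else NA_character_,
               n_shared = length(sh), n_specific = length(sp),
               mean_shared = if (length(sh)) mean(sh) else NA_real_,
               mean_specific = if (length(sp)) mean(sp) else NA_real_,
               p_value = p, testable = testable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
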