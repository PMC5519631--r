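mk_raw_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
               lines), path)
  path
}

test_that("normalization drops multi-allelic/non-autosomal and trims indels", {
  path <- mk_raw_vcf(c(
    "1\t50\t.\tA\tC,T\t.\t.\t.\tGT\t0/1\t0/0",
    "X\t60\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0",
    "chrM\t61\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t100\t.\tCA\tCT\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t200\t.\tA\tG\t.\t.\t.\tGT\t0/1\t1/1",
    "1\t200\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/0"))
  gm <- normalize_and_restrict(path)
  counts <- attr(gm, "norm_counts")
  expect_equal(unname(counts["multi_allelic"]), 1L)
  expect_equal(unname(counts["non_autosomal"]), 2L)
  expect_equal(unname(counts["duplicate"]), 1L)
  # "pos 100 REF CA ALT CT" -> pos 101 REF A ALT T
  expect_equal(gm$sites$pos, c(101L, 200L))
  expect_equal(gm$sites$ref[1], "A")
  expect_equal(gm$sites$alt[1], "T")
  # duplicate collapse keeps the first record
  expect_equal(gt_dosage(gm)[2, ], c(S1 = 1L, S2 = 2L), ignore_attr = TRUE)
})

test_that("allele trimming matches an exhaustive small-string oracle", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(r1 = bases, r2 = c(bases, ""), a1 = bases,
                        a2 = c(bases, ""), stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos), 120), ]
  for (k in seq_len(nrow(combos))) {
    ref <- paste0(combos$r1[k], combos$r2[k])
    alt <- paste0(combos$a1[k], combos$a2[k])
    got <- founderpanel:::trim_alleles(100L, ref, alt)
    # oracle: strip common suffix then common prefix, keeping >= 1 base
    r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    pos <- 100L
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1L
    }
    expect_identical(got,
                     list(pos = pos, ref = paste(r, collapse = ""),
                          alt = paste(a, collapse = "")))
  }
})

test_that("genotype filters apply the printed thresholds strictly", {
  mk <- function(a1, a2, gq, dp, adr, ada) {
    geno_matrix(data.frame(chrom = "1", pos = 1L, ref = "A", alt = "C"),
                "S1", matrix(a1), matrix(a2), gq = matrix(gq),
                dp = matrix(dp), ad_ref = matrix(adr), ad_alt = matrix(ada))
  }
  masked <- function(gm) is.na(gt_dosage(filter_genotypes(gm))[1, 1])
  expect_true(masked(mk(0L, 1L, 19, 30, 15, 15)))   # GQ < 20
  expect_false(masked(mk(0L, 1L, 20, 30, 15, 15)))  # GQ exactly 20 kept
  expect_true(masked(mk(0L, 1L, 40, 7, 4, 3)))      # DP < 8
  expect_false(masked(mk(0L, 1L, 40, 8, 4, 4)))     # DP exactly 8 kept
  expect_true(masked(mk(0L, 1L, 60, 30, 25, 5)))    # het AB 1/6 < 0.25
  expect_false(masked(mk(0L, 1L, 60, 30, 22, 8)))   # AB ~0.27 kept
  expect_false(masked(mk(1L, 1L, 60, 30, 0, 30)))   # AB rule het-only
  expect_false(masked(mk(1L, 1L, 60, 30, 30, 0)))   # hom-alt AB 0 kept
  expect_true(masked(mk(0L, NA, 60, 30, 15, 15)))   # half-call
  expect_false(masked(mk(0L, 1L, NA, NA, NA, NA)))  # absent fields pass
})

test_that("Mendelian masking agrees with the enumerated consistency table", {
  tab <- trio_consistency_oracle()
  samples <- c("F", "M", "C")
  ped <- pedigree(data.frame(id = samples, father = c(NA, NA, "F"),
                             mother = c(NA, NA, "M"), sex = c(1, 2, 1)))
  S <- nrow(tab)
  g2a <- function(g) list(a1 = as.integer(g > 0), a2 = as.integer(g > 1))
  a1 <- sapply(list(tab$f, tab$m, tab$c), function(g) g2a(g)$a1)
  a2 <- sapply(list(tab$f, tab$m, tab$c), function(g) g2a(g)$a2)
  gm <- geno_matrix(data.frame(chrom = "1", pos = seq_len(S) * 10L,
                               ref = "A", alt = "C"),
                    samples, a1, a2)
  mm <- mendel_mask(gm, ped)
  masked_rows <- is.na(gt_dosage(mm$gm)[, match("C", samples)])
  expect_identical(unname(masked_rows), !tab$consistent)
  # all three members masked at inconsistent sites
  expect_true(all(is.na(gt_dosage(mm$gm)[!tab$consistent, ])))
  expect_equal(mm$site_error_rate, as.numeric(!tab$consistent))
  # duo: parent/child opposite homozygotes are impossible
  ped2 <- pedigree(data.frame(id = c("P", "C"), father = c(NA, "P"),
                              mother = c(NA, NA), sex = c(1, 1)))
  duo_tab <- expand.grid(p = 0:2, c = 0:2)
  gm2 <- geno_matrix(data.frame(chrom = "1", pos = seq_len(9) * 10L,
                                ref = "A", alt = "C"),
                     c("P", "C"),
                     sapply(list(duo_tab$p, duo_tab$c), function(g) g2a(g)$a1),
                     sapply(list(duo_tab$p, duo_tab$c), function(g) g2a(g)$a2))
  mm2 <- mendel_mask(gm2, ped2)
  expect_identical(unname(is.na(gt_dosage(mm2$gm)[, 2])),
                   (duo_tab$p == 2 & duo_tab$c == 0) |
                     (duo_tab$p == 0 & duo_tab$c == 2))
  expect_error(mendel_mask(gm2, ped, strict = TRUE), "pedigree error")
})

test_that("exact HWE test matches enumeration and simple cases", {
  expect_equal(hwe_exact(50, 0, 0), 1.0)
  expect_error(hwe_exact(0, 0, 0), "all-zero")
  expect_error(hwe_exact(-1, 2, 0), "nonnegative")
  # direct-enumeration oracle on assorted configurations
  set.seed(31)
  for (k in 1:60) {
    n <- sample(1:120, 1)
    nAA <- sample(0:n, 1); nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
  # uniform-ish p-values under true HWE: rejection at 0.05 stays near level
  set.seed(77)
  p <- replicate(400, {
    g <- rbinom(100, 2, 0.3)
    hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("site filters drop by missingness, Mendel rate, HWE and monomorphism", {
  toy <- qc_toy_matrix()
  qc <- run_qc(toy$gm, toy$ped)
  expect_equal(qc$report$n_surviving, 3L)
  expect_equal(qc$gm$sites$pos, c(800L, 900L, 1000L))
  # strictness: 26/100 missing drops, 25/100 does not
  mk_missing <- function(n_miss) {
    a1 <- matrix(0L, 1, 100); a2 <- matrix(0L, 1, 100)
    a1[1, 1:5] <- 1L                      # keep polymorphic
    a1[1, 6:(5 + n_miss)] <- NA; a2[1, 6:(5 + n_miss)] <- NA
    geno_matrix(data.frame(chrom = "1", pos = 1L, ref = "A", alt = "C"),
                sprintf("S%03d", 1:100), a1, a2)
  }
  expect_equal(filter_sites(mk_missing(26))$report$n_surviving, 0L)
  expect_equal(filter_sites(mk_missing(25))$report$n_surviving, 1L)
})

test_that("QC is monotone and idempotent", {
  w <- tiny_world(19)
  noisy <- inject_noise(w$fe$genotypes, noise_config(), seed = 2,
                        ped = w$fe$ped)
  qc1 <- run_qc(noisy, w$fe$ped)
  # monotone: never un-missing, never a new value
  d0 <- gt_dosage(noisy)[match(paste(qc1$gm$sites$chrom, qc1$gm$sites$pos),
                               paste(noisy$sites$chrom, noisy$sites$pos)), ]
  d1 <- gt_dosage(qc1$gm)
  changed <- !is.na(d1) & !is.na(d0) & d1 != d0
  expect_false(any(changed))
  expect_true(all(is.na(d1[is.na(d0)])))
  # idempotent: re-running QC is a no-op
  qc2 <- run_qc(qc1$gm, w$fe$ped)
  expect_equal(qc2$report$n_surviving, qc1$report$n_surviving)
  expect_identical(gt_dosage(qc2$gm), gt_dosage(qc1$gm))
})

test_that("clean HWE-consistent cohorts survive QC nearly intact", {
  w <- tiny_world(23)
  clean <- inject_noise(w$fe$genotypes, noise_config(0, 0, 0, 0, 0),
                        seed = 1, ped = w$fe$ped)
  qc <- run_qc(clean, w$fe$ped)
  seg <- sum(gm_alt_freq(w$fe$genotypes) > 0)
  expect_gte(qc$report$n_surviving / seg, 0.99)
})

test_that("duplicate concordance counts co-called sites per class", {
  sites <- data.frame(chrom = "1", pos = c(10L, 20L, 30L, 40L),
                      ref = c("A", "C", "AT", "G"),
                      alt = c("C", "G", "A", "GT"))
  a1 <- matrix(c(0L, 1L, 1L, 0L,
                 0L, 1L, 0L, 0L,
                 NA, 1L, 1L, 0L), 4, 3)
  a2 <- matrix(c(1L, 1L, 1L, 0L,
                 1L, 1L, 1L, 0L,
                 NA, 1L, 1L, 1L), 4, 3)
  gm <- geno_matrix(sites, c("A", "Adup", "B"), a1, a2)
  cc <- concordance(gm, list(c("A", "Adup")))
  # SNVs: sites 1,2 both called; one dosage disagreement at site 1? no:
  # A = 1, Adup = 1 at site 1; site 3 is an indel with a mismatch
  expect_equal(cc$concordance[cc$class == "SNV"], 1.0)
  expect_equal(cc$n_compared[cc$class == "indel"], 2L)
  expect_equal(cc$concordance[cc$class == "indel"], 0.5)
  # missing calls excluded from the denominator
  cc2 <- concordance(gm, list(c("A", "B")))
  expect_equal(cc2$n_compared[cc2$class == "SNV"], 1L)
  expect_error(concordance(gm, list(c("A", "nope"))), "unknown sample")
})

test_that("sensitivity by MAF applies the high-quality site rules", {
  w <- tiny_world(29)
  gm <- w$fe$genotypes
  maf <- gm_maf(gm)
  common <- which(!is.na(maf) & maf >= 0.05)
  array <- subset_gm(gm, site_idx = common)
  # WGS superset: sensitivity 1 in every populated bin
  sens <- sensitivity_by_maf(gm, array)
  expect_true(all(sens$sensitivity[sens$n_array_sites > 0] == 1))
  # an array site with 6% missing calls is excluded from the denominator
  array2 <- array
  nmiss <- ceiling(0.06 * length(array2$samples))
  array2$a1[1, 1:nmiss] <- NA; array2$a2[1, 1:nmiss] <- NA
  sens2 <- sensitivity_by_maf(gm, array2)
  expect_equal(sum(sens2$n_array_sites), sum(sens$n_array_sites) - 1L)
  # 2% random drop-out in WGS: flat profile near 0.98
  drop <- founderpanel:::with_seed(5, sample(common, round(0.02 * length(common))))
  wgs2 <- subset_gm(gm, site_idx = setdiff(seq_len(nrow(gm$sites)), drop))
  sens3 <- sensitivity_by_maf(wgs2, array)
  pooled <- sum(sens3$n_found) / sum(sens3$n_array_sites)
  expect_gt(pooled, 0.95)
  expect_lt(pooled, 1)
})
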