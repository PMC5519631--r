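test_that("BLUE reduces to the sample mean for unrelated individuals", {
  ped <- pedigree(data.frame(id = paste0("S", 1:6), father = NA, mother = NA,
                             sex = 1))
  kin <- pedigree_kinship(ped)
  g <- c(0, 0.5, 1, 0.5, 0, 0)
  names(g) <- paste0("S", 1:6)
  r <- blue_frequency(g, kin)
  expect_equal(r$p, mean(g))
  expect_equal(r$se, sqrt(r$p * (1 - r$p) / (2 * 6)))
})

test_that("trio BLUE matches the explicit 3x3 inversion", {
  ped <- pedigree(data.frame(id = c("P1", "P2", "C"),
                             father = c(NA, NA, "P1"),
                             mother = c(NA, NA, "P2"), sex = c(1, 2, 1)))
  kin <- pedigree_kinship(ped)
  g <- c(P1 = 0, P2 = 1, C = 0.5)
  r <- blue_frequency(g, kin)
  Phi <- matrix(c(0.5, 0, 0.25, 0, 0.5, 0.25, 0.25, 0.25, 0.5), 3, 3)
  w <- solve(Phi, rep(1, 3))
  expect_equal(r$p, sum(w * g) / sum(w))
  expect_equal(r$p, 0.5)
  # the child adds no information beyond its parents: weights concentrate
  # on the two parents
  expect_equal(unname(w[3]), 0)
})

test_that("BLUE is unbiased and no less efficient than the naive mean", {
  cfg <- sim_config(ancestral_pop_size = 100, burn_in_generations = 400,
                    mutation_rate_per_site_per_gen = 5e-4, n_sites = 200,
                    n_founders = 20, pedigree_generations = 3,
                    mean_offspring = 3, seed = 5)
  anc <- simulate_ancestral(cfg)
  fe <- found_and_expand(anc, cfg)
  ft <- blue_frequencies(fe$genotypes, fe$ped)
  truth <- fe$truth$true_frequencies$founder_freq
  seg <- truth > 0 & truth < 1
  err_b <- ft$blue_freq[seg] - truth[seg]
  err_n <- ft$naive_freq[seg] - truth[seg]
  expect_lt(abs(mean(err_b)), 3 * sd(err_b) / sqrt(sum(seg)))
  expect_lte(var(err_b), var(err_n))
})

test_that("BLUE errors on a singular kinship matrix", {
  kin <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(blue_frequency(c(a = 0, b = 1), kin), "singular")
})

test_that("MAF classes use strict boundary conventions", {
  cl <- maf_class(c(0, 0.004999, 0.005, 0.03, 0.05, 0.0501, NA))
  expect_equal(as.character(cl),
               c("absent", "rare", "low", "low", "low", "common", NA))
})

test_that("depletion resampling is exchangeable when cohort == reference", {
  w <- tiny_world(59)
  coh <- w$fe$genotypes
  unrel <- select_unrelated(w$fe$ped, 3, ids = coh$samples)
  n_sub <- min(6, length(unrel))
  ref <- subset_gm(coh, sample_idx = match(sort(unrel), coh$samples))
  dep <- depletion_resample(coh, ref, w$fe$ped, n_sub = n_sub, n_reps = 10,
                            edges = c(0.1, 0.2), seed = 2)
  ok <- abs(dep$cohort_count - dep$ref_mean) <= 3 * pmax(dep$ref_sd, 1)
  expect_true(all(ok))
  expect_equal(ncol(attr(dep, "ref_counts")), 10)   # default 10 replicates
  expect_error(depletion_resample(coh, ref, w$fe$ped,
                                  n_sub = length(unrel) + 50, seed = 1),
               "achievable n")
})

test_that("drift enrichment applies strict thresholds and absent-site rule", {
  cf <- data.frame(chrom = "1", pos = 1:5 * 10,
                   maf = c(0.10, 0.05, 0.40, 0.004, 0.2))
  rf <- data.frame(chrom = "1", pos = c(10, 20, 30, 40),
                   maf = c(0.004, 0.001, 0.3, 0.004))
  dr <- drift_enrichment(cf, rf)
  # pos 10: ref rare, cohort 0.10 -> in; pos 20: cohort exactly 0.05 -> out;
  # pos 30: ref common -> out; pos 40: cohort rare -> out;
  # pos 50: absent in reference (maf 0), cohort 0.2 -> in
  expect_equal(sort(dr$variants$pos), c(10, 50))
  expect_equal(dr$n, 2L)
  # identical tables: empty
  expect_equal(drift_enrichment(rf, rf)$n, 0L)
})

test_that("segment detection: trivial cases and mismatch tolerance", {
  S <- 200
  sites <- data.frame(chrom = "1", pos = 1:S * 10L, ref = "A", alt = "C",
                      cm = (1:S - 0.5) / S * 100)
  h <- matrix(0L, S, 4)
  h[, 3] <- 1L; h[, 4] <- 1L
  h[100, 4] <- 0L                          # single mismatch in the Y pair
  pan <- hap_panel(sites, h, c("X", "X", "Y", "Y"), 100)
  # identical own haplotypes: one full-length HBD segment
  seg <- detect_segments(pan, "haplotype", pairs = hbd_hap_pairs("X"),
                         min_cm = 3, max_mismatch = 0)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$length_cm, 100)
  # a single mismatch splits without tolerance, merges with tolerance
  seg0 <- detect_segments(pan, "haplotype", pairs = hbd_hap_pairs("Y"),
                          min_cm = 3, max_mismatch = 0)
  expect_equal(nrow(seg0), 2L)
  seg1 <- detect_segments(pan, "haplotype", pairs = hbd_hap_pairs("Y"),
                          min_cm = 3, max_mismatch = 1)
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$length_cm, 100)
  # order invariance: permuting site storage after sorting changes nothing
  expect_error(detect_segments(pan, "haplotype", pairs = hbd_hap_pairs("Z")),
               "unknown haplotype")
})

test_that("truth-mode segments: unrelated founders share nothing", {
  ped <- pedigree(data.frame(id = c("A", "B"), father = NA, mother = NA,
                             sex = c(1, 2)))
  tt <- gene_drop(ped, n_sites = 100, seed = 1)
  seg <- detect_segments(tt, "truth", pairs = ibd_hap_pairs("A", "B"),
                         min_cm = 0)
  expect_equal(nrow(seg), 0L)
  shr <- sharing_summaries(seg, 100, pairs = data.frame(id1 = "A", id2 = "B"))
  expect_equal(shr$ibd$fraction, 0)
})

test_that("haplotype-mode detector recovers truth IBD at high density", {
  # dense-marker world so allele identity can resolve founder-label
  # identity at 3 cM scale (the naive detector needs ~2 segregating
  # mismatches per cM between non-IBD haplotypes)
  cfg <- sim_config(ancestral_pop_size = 60, burn_in_generations = 240,
                    mutation_rate_per_site_per_gen = 1e-3, n_sites = 5000,
                    n_founders = 12, pedigree_generations = 2,
                    mean_offspring = 3, max_mate_kinship = 1 / 32, seed = 3)
  anc <- simulate_ancestral(cfg)
  fe <- found_and_expand(anc, cfg)
  kin <- pedigree_kinship(fe$ped)
  ids <- fe$genotypes$samples
  K <- kin[ids, ids]; diag(K) <- 0
  rel <- which(K >= 1 / 8, arr.ind = TRUE)
  rel <- rel[rel[, 1] < rel[, 2], , drop = FALSE][1:8, ]
  pairs <- ibd_hap_pairs(ids[1])[0, ]
  for (r in seq_len(nrow(rel)))
    pairs <- rbind(pairs, ibd_hap_pairs(ids[rel[r, 1]], ids[rel[r, 2]]))
  tseg <- detect_segments(fe$truth, "truth", pairs = pairs, min_cm = 3)
  hseg <- detect_segments(fe$truth$true_haps, "haplotype", pairs = pairs,
                          min_cm = 3, max_mismatch = 0)
  cover <- function(seg) {
    if (!nrow(seg)) return(numeric(0))
    tapply(seg$length_cm, paste(seg$hap1, seg$hap2), sum)
  }
  tc <- cover(tseg); hc <- cover(hseg)
  shared <- intersect(names(tc), names(hc))
  recovered <- sum(pmin(tc[shared], hc[shared])) / sum(tc)
  false_cm <- (sum(hc) - sum(pmin(tc[shared], hc[shared]))) / sum(hc)
  expect_gte(recovered, 0.9)
  expect_lte(false_cm, 0.10)
})

test_that("rank-sum comparison is calibrated and powered", {
  cs <- data.frame(chrom = "1", pos = 1:200 * 10)
  rs <- cs[1:120, , drop = FALSE]
  freqs <- data.frame(chrom = "1", pos = cs$pos, maf = 0.2)
  # calibration: null rejection near nominal level
  rej <- mean(sapply(1:120, function(s) {
    sc <- assign_scores(cs, rs, shift = 0, seed = s)
    p <- deleteriousness_compare(sc, freqs)$p_value
    min(p, na.rm = TRUE) < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.07)
  # power at 2 SD shift
  sc <- assign_scores(cs, rs, shift = 2, seed = 9)
  res <- deleteriousness_compare(sc, freqs)
  expect_lt(res$p_value[res$testable], 1e-4)
  # empty-group strata are reported, not an error
  sc2 <- sc; sc2$status <- "shared"
  res2 <- deleteriousness_compare(sc2, freqs)
  expect_false(any(res2$testable))
  # exact vs normal approximation agree for small untied groups
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15) + 0.8
  p_exact <- wilcox.test(y, x, exact = TRUE)$p.value
  p_norm <- wilcox.test(y, x, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_norm) / p_exact, 0.35)
})

test_that("coding/non-coding strata are compared separately when present", {
  cs <- data.frame(chrom = "1", pos = 1:200 * 10)
  rs <- cs[1:120, , drop = FALSE]
  freqs <- data.frame(chrom = "1", pos = cs$pos, maf = 0.2)
  sc <- assign_scores(cs, rs, shift = 2, seed = 12)
  sc$class <- rep(c("coding", "noncoding"), 100)
  res <- deleteriousness_compare(sc, freqs)
  expect_setequal(unique(res$class[res$testable]), c("coding", "noncoding"))
  expect_true(all(res$p_value[res$testable] < 0.01))
})
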