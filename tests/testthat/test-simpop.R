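test_that("configuration validation rejects bad values", {
  expect_error(sim_config(ancestral_pop_size = 0), "positive")
  expect_error(sim_config(region_length_cm = -1), "region_length_cm")
  expect_error(sim_config(mean_offspring = 0), "mean_offspring")
  expect_error(noise_config(frac_low_gq = 1.2), "proportion")
  expect_error(noise_config(frac_half_calls = -0.1), "proportion")
})

test_that("no mutation from a monomorphic start leaves no variation", {
  cfg <- sim_config(ancestral_pop_size = 20, burn_in_generations = 30,
                    mutation_rate_per_site_per_gen = 0, n_sites = 200,
                    n_founders = 4, seed = 1)
  anc <- simulate_ancestral(cfg)
  expect_equal(sum(panel_freq(anc) > 0), 0)
  expect_equal(dim(anc$haps), c(200L, 40L))
})

test_that("fixed seed gives identical ancestral output", {
  cfg <- sim_config(ancestral_pop_size = 20, burn_in_generations = 40,
                    n_sites = 300, seed = 5)
  a <- simulate_ancestral(cfg)
  b <- simulate_ancestral(cfg)
  expect_identical(a$haps, b$haps)
  expect_identical(a$sites, b$sites)
})

test_that("burn-in heterozygosity approaches the diffusion prediction", {
  # E[het] ~ theta/(1+theta) for the 2-allele recurrent-mutation model;
  # 8N generations of burn-in from a monomorphic start
  N <- 100; mu <- 2e-4
  theta <- 4 * N * mu
  cfg <- sim_config(ancestral_pop_size = N, burn_in_generations = 8 * N,
                    mutation_rate_per_site_per_gen = mu, n_sites = 600,
                    seed = 11)
  anc <- simulate_ancestral(cfg)
  f <- panel_freq(anc)
  het <- 2 * f * (1 - f)
  se <- stats::sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - theta / (1 + theta)), 3 * se)
})

test_that("sample site-frequency spectrum is dominated by rare classes", {
  counts <- matrix(0, 3, 5)
  for (s in 1:3) {
    cfg <- sim_config(ancestral_pop_size = 60, burn_in_generations = 300,
                      mutation_rate_per_site_per_gen = 2e-4, n_sites = 800,
                      seed = s)
    anc <- simulate_ancestral(cfg)
    dac <- rowSums(anc$haps[, 1:40, drop = FALSE])  # 20-individual sample
    counts[s, ] <- tabulate(dac[dac >= 1 & dac <= 5], nbins = 5)
  }
  # monotone decreasing over derived-allele-count classes 1..5 in the
  # majority of replicates (neutral SFS ~ 1/i)
  mono <- apply(counts, 1, function(x) all(diff(x) <= 0))
  expect_gte(sum(mono), 2)
})

test_that("gene dropping transmits founder material exactly", {
  w <- tiny_world(3)
  fe <- w$fe
  segs <- truth_segments(fe$truth)
  # segments of one haplotype partition the site range without overlap
  for (h in unique(segs$hap)[1:8]) {
    ss <- segs[segs$hap == h, ]
    expect_equal(ss$start_site[1], 1L)
    expect_equal(ss$end_site[nrow(ss)], nrow(fe$truth$label_matrix))
    if (nrow(ss) > 1)
      expect_equal(ss$start_site[-1], utils::head(ss$end_site, -1) + 1L)
  }
  expect_true(all(segs$founder_hap %in% fe$truth$founder_hap_names))
  # alleles conserved: every child allele equals the founder-haplotype
  # allele at the segment covering that site (no mutation in the drop)
  fhap <- fe$truth$founder_haps$haps
  colnames(fhap) <- colnames(fe$truth$founder_haps$haps)
  lab <- fe$truth$label_matrix
  for (h in sample(colnames(lab), 6)) {
    expect_identical(fe$truth$true_haps$haps[, h],
                     fhap[cbind(seq_len(nrow(lab)),
                                lab[, h])])
  }
})

test_that("two-founder child carries one maternal and one paternal track", {
  ped <- pedigree(data.frame(id = c("F", "M", "C"),
                             father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
                             sex = c(1, 2, 1)))
  tt <- gene_drop(ped, n_sites = 300, seed = 4)
  lab <- tt$label_matrix
  expect_true(all(tt$founder_hap_names[lab[, "C.1"]] %in% c("F.1", "F.2")))
  expect_true(all(tt$founder_hap_names[lab[, "C.2"]] %in% c("M.1", "M.2")))
})

test_that("founder cohort loses diversity relative to the ancestral pool", {
  hets <- sapply(1:4, function(s) {
    w <- tiny_world(s)
    f_anc <- panel_freq(w$anc)
    f_coh <- panel_freq(w$fe$truth$true_haps)
    c(anc = mean(2 * f_anc * (1 - f_anc)), coh = mean(2 * f_coh * (1 - f_coh)))
  })
  expect_gte(sum(hets["coh", ] <= hets["anc", ]), 3)
})

test_that("bottleneck depletes cohort-rare sites but not common ones", {
  res <- sapply(1:4, function(s) {
    cfg <- sim_config(ancestral_pop_size = 80, burn_in_generations = 320,
                      mutation_rate_per_site_per_gen = 1e-4, n_sites = 2000,
                      n_founders = 20, pedigree_generations = 3,
                      mean_offspring = 3, max_mate_kinship = 1 / 32, seed = s)
    anc <- simulate_ancestral(cfg)
    fe <- found_and_expand(anc, cfg)
    m <- min(length(fe$genotypes$samples), 60)
    match_ref <- ancestral_cohort(anc, n = m, exclude = fe$founder_source,
                                  seed = s)
    maf_c <- gm_maf(subset_gm(fe$genotypes, sample_idx = seq_len(m)))
    maf_r <- gm_maf(match_ref$genotypes)
    # scaled rare boundary: 0.5% is below the MAF granularity of a
    # 120-haplotype sample, so "rare" here means at most 2 copies
    c(rare_c = sum(maf_c > 0 & maf_c < 0.02),
      rare_r = sum(maf_r > 0 & maf_r < 0.02),
      common_c = sum(maf_c > 0.05, na.rm = TRUE),
      common_r = sum(maf_r > 0.05, na.rm = TRUE))
  })
  expect_gte(sum(res["rare_c", ] < res["rare_r", ]), 3)
})

test_that("noise injection honours its configuration", {
  w <- tiny_world(9)
  gm <- w$fe$genotypes
  # all fractions zero: identity
  clean <- inject_noise(gm, noise_config(0, 0, 0, 0, 0), seed = 1,
                        ped = w$fe$ped)
  expect_identical(clean$a1, gm$a1)
  expect_identical(clean$gq, gm$gq)
  expect_equal(nrow(attr(clean, "noise_mask")), 0)
  # saturation: every call half-called
  half <- inject_noise(gm, noise_config(0, 0, 1, 0, 0), seed = 1,
                       ped = w$fe$ped)
  expect_true(all(gt_half(half)))
  # determinism
  n1 <- inject_noise(gm, noise_config(), seed = 42, ped = w$fe$ped)
  n2 <- inject_noise(gm, noise_config(), seed = 42, ped = w$fe$ped)
  expect_identical(n1$a1, n2$a1)
  expect_identical(attr(n1, "noise_mask"), attr(n2, "noise_mask"))
})

test_that("Mendelian flips are recorded and flagged downstream", {
  w <- tiny_world(13)
  nz <- noise_config(0, 0, 0, frac_mendel_errors = 0.05, 0)
  noisy <- inject_noise(w$fe$genotypes, nz, seed = 8, ped = w$fe$ped)
  mask <- attr(noisy, "noise_mask")
  expect_true(all(mask$type == "mendel_flip"))
  expect_gt(nrow(mask), 0)
  # flipped calls are trio-child calls
  tr <- ped_trios(w$fe$ped)
  kids <- tr$child[tr$father %in% noisy$samples & tr$mother %in% noisy$samples]
  expect_true(all(noisy$samples[mask$sample] %in% kids))
  # the QC Mendel check flags every *detectable* flip (those creating an
  # impossible configuration per the enumeration oracle)
  mm <- mendel_mask(noisy, w$fe$ped, use_duos = FALSE)
  d <- gt_dosage(noisy)
  tab <- trio_consistency_oracle()
  tr <- tr[tr$child %in% noisy$samples & tr$father %in% noisy$samples &
             tr$mother %in% noisy$samples, ]
  fi <- match(tr$father, noisy$samples); mi <- match(tr$mother, noisy$samples)
  ci <- match(tr$child, noisy$samples)
  detectable <- 0L; flagged <- 0L
  for (r in seq_len(nrow(mask))) {
    s <- mask$site[r]
    t <- which(ci == mask$sample[r])
    if (!length(t)) next
    f <- d[s, fi[t]]; m <- d[s, mi[t]]; c <- d[s, ci[t]]
    if (anyNA(c(f, m, c))) next
    cons <- tab$consistent[tab$f == f & tab$m == m & tab$c == c]
    if (!cons) {
      detectable <- detectable + 1L
      if (is.na(gt_dosage(mm$gm)[s, ci[t]])) flagged <- flagged + 1L
    }
  }
  expect_gt(detectable, 0)
  expect_gte(flagged / detectable, 0.95)
})

test_that("array manifest selection is a deterministic common-site subset", {
  w <- tiny_world(21)
  gm <- w$fe$genotypes
  maf <- gm_maf(gm)
  qualifying <- sum(!is.na(maf) & maf >= 0.05)
  m1 <- make_array_manifest(gm, 20, min_maf = 0.05, seed = 3)
  m2 <- make_array_manifest(gm, 20, min_maf = 0.05, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(maf[match(m1$pos, gm$sites$pos)] >= 0.05))
  expect_true(!is.unsorted(m1$pos))
  # requesting every qualifying site returns the full qualifying set
  mall <- make_array_manifest(gm, qualifying, min_maf = 0.05, seed = 1)
  expect_equal(nrow(mall), qualifying)
  expect_error(make_array_manifest(gm, qualifying + 1, 0.05, 1), "manifest")
})

test_that("score assignment labels and shifts cohort-specific variants", {
  cs <- data.frame(chrom = "1", pos = 1:300 * 10)
  rs <- data.frame(chrom = "1", pos = 1:150 * 10)
  sc <- assign_scores(cs, rs, shift = 3, seed = 2)
  expect_equal(nrow(sc), 300)
  expect_equal(sum(sc$status == "shared"), 150)
  expect_gt(mean(sc$score[sc$status == "cohort_specific"]),
            mean(sc$score[sc$status == "shared"]) + 1)
  expect_error(assign_scores(cs, rs, shift = -1, seed = 1), "shift")
})
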