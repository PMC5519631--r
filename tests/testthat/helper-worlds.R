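# Stated simulation worlds used by the tests. Parameters were chosen up
# front for scientific plausibility at desk scale (see the methods
# vignette) and are shared between unit and acceptance tests.

# small world for fast unit tests
tiny_world <- function(seed = 7, ...) {
  cfg <- sim_config(ancestral_pop_size = 60, burn_in_generations = 240,
                    mutation_rate_per_site_per_gen = 1e-4, n_sites = 1000,
                    n_founders = 12, pedigree_generations = 3,
                    mean_offspring = 3, max_mate_kinship = 1 / 32,
                    seed = seed, ...)
  anc <- simulate_ancestral(cfg)
  fe <- found_and_expand(anc, cfg)
  list(cfg = cfg, anc = anc, fe = fe)
}

# bottlenecked-cohort imputation world (acceptance criterion: panel
# configuration ordering); truth-phased panels isolate imputation accuracy
# from phasing error
imputation_world <- function(seed) {
  cfg <- sim_config(ancestral_pop_size = 100, burn_in_generations = 400,
                    mutation_rate_per_site_per_gen = 1e-4, n_sites = 4000,
                    n_founders = 22, pedigree_generations = 3,
                    mean_offspring = 3, max_mate_kinship = 1 / 16,
                    seed = seed)
  anc <- simulate_ancestral(cfg)
  fe <- found_and_expand(anc, cfg)
  ref <- ancestral_cohort(anc, n = 70, exclude = fe$founder_source,
                          seed = seed)
  noisy <- inject_noise(fe$genotypes, cfg$noise, seed = seed, ped = fe$ped)
  qc <- run_qc(noisy, fe$ped)
  test_ids <- founderpanel:::with_seed(seed, sort(sample(qc$gm$samples, 8)))
  tp <- fe$truth$true_haps
  idx <- match(paste(qc$gm$sites$chrom, qc$gm$sites$pos),
               paste(tp$sites$chrom, tp$sites$pos))
  phased <- subset_panel(tp, site_idx = idx)
  rest <- subset_panel(phased,
                       hap_idx = which(!(phased$hap_samples %in% test_ids)))
  cp <- build_panel(rest, fe$ped, degree = 1)
  cp <- subset_panel(cp, site_idx = which(panel_freq(cp) > 0))
  rp <- subset_panel(ref$panel, site_idx = which(panel_freq(ref$panel) > 0))
  mg <- merge_panels(cp, rp)
  test_panel <- subset_panel(
    subset_panel(tp, hap_idx = which(tp$hap_samples %in% test_ids)),
    site_idx = idx)
  manifest <- make_array_manifest(
    qc$gm, round(0.7 * sum(gm_maf(qc$gm) >= 0.05, na.rm = TRUE)), 0.05, seed)
  ev <- compare_configs(test_panel,
                        list(cohort = cp, reference = rp, merged = mg),
                        manifest, bins = c(0.01, 0.05, 0.1, 0.2, 0.5),
                        bin_source = "reference")
  list(cfg = cfg, fe = fe, ref = ref, qc = qc, eval = ev)
}

# deep isolate world (depletion / IBD contrasts): a wide six-generation
# pedigree with a strict mate-kinship ceiling, cohort = last two generations
deep_isolate_world <- function(seed, n_sites = 4000, region_length_cm = 100,
                               cousin_mating_frac = 0,
                               ancestral_pop_size = 100) {
  cfg <- sim_config(ancestral_pop_size = ancestral_pop_size,
                    burn_in_generations = 4 * ancestral_pop_size,
                    mutation_rate_per_site_per_gen = 1e-4,
                    n_sites = n_sites, region_length_cm = region_length_cm,
                    n_founders = 40, pedigree_generations = 6,
                    mean_offspring = 2.85, max_mate_kinship = 1 / 32,
                    cousin_mating_frac = cousin_mating_frac, seed = seed)
  anc <- simulate_ancestral(cfg)
  fe <- found_and_expand(anc, cfg)
  gen <- fe$ped$df$generation[match(fe$genotypes$samples, fe$ped$df$id)]
  recent <- which(gen >= cfg$pedigree_generations - 1L)
  list(cfg = cfg, anc = anc, fe = fe,
       recent = subset_gm(fe$genotypes, sample_idx = recent))
}

# deterministic engineered 10-site QC fixture: 3 sites fail missingness,
# 2 fail the Mendelian rate, 1 fails HWE, 1 goes monomorphic after genotype
# masking, 3 survive. 30 samples = 10 father/mother/child trios.
qc_toy_matrix <- function() {
  n_trio <- 10L
  samples <- c(sprintf("F%02d", 1:n_trio), sprintf("M%02d", 1:n_trio),
               sprintf("C%02d", 1:n_trio))
  N <- length(samples)
  S <- 10L
  a1 <- matrix(0L, S, N); a2 <- matrix(0L, S, N)
  gq <- matrix(60, S, N); dp <- matrix(30, S, N)
  set_g <- function(s, who, g) {
    i <- match(who, samples)
    a1[s, i] <<- as.integer(g > 0L)
    a2[s, i] <<- as.integer(g > 1L)
  }
  # baseline polymorphism so no site is accidentally monomorphic: fathers
  # F01..F03 het, child inherits consistently
  for (s in 1:10) {
    for (k in 1:3) {
      set_g(s, sprintf("F%02d", k), 1L)
      set_g(s, sprintf("C%02d", k), 1L)   # het child of het x hom-ref: fine
    }
  }
  # sites 1-3: >25% missing (10 of 30 calls); keep missing individuals
  # outside the baseline carriers so the site stays polymorphic
  miss_ids <- c(sprintf("F%02d", 5:10), sprintf("M%02d", 5:8))
  for (s in 1:3) {
    i <- match(miss_ids, samples)
    a1[s, i] <- NA_integer_; a2[s, i] <- NA_integer_
  }
  # sites 4-5: two impossible trios each (error rate 2/10 > 10%)
  for (s in 4:5) for (k in 4:5) {
    set_g(s, sprintf("F%02d", k), 0L)
    set_g(s, sprintf("M%02d", k), 0L)
    set_g(s, sprintf("C%02d", k), 2L)
  }
  # site 6: all 30 samples heterozygous (gross HWE violation, Mendel-clean)
  a1[6, ] <- 0L; a2[6, ] <- 1L
  # site 7: single alt carrier whose call fails the GQ filter -> site
  # monomorphic after genotype masking
  a1[7, ] <- 0L; a2[7, ] <- 0L
  set_g(7, "M09", 1L)
  gq[7, match("M09", samples)] <- 10
  # sites 8-10 stay as the clean baseline
  ad_alt <- (a1 + a2) / 2 * dp
  gm <- geno_matrix(
    data.frame(chrom = "1", pos = seq_len(S) * 100L, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    samples, a1, a2, gq = gq, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt)
  ped <- pedigree(data.frame(
    id = samples,
    father = c(rep(NA, 2 * n_trio), sprintf("F%02d", 1:n_trio)),
    mother = c(rep(NA, 2 * n_trio), sprintf("M%02d", 1:n_trio)),
    sex = c(rep(1L, n_trio), rep(2L, n_trio), rep(1L, n_trio))))
  list(gm = gm, ped = ped)
}
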