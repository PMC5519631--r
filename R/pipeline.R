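# ---- pipeline driver -------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks and stage toggles. `sim` takes
#' [sim_config()] arguments (minus `seed`, which is governed globally);
#' unknown fields are an error so config typos fail fast.
#'
#' @param seed global integer seed; every stage derives a named substream
#' @param sim list of [sim_config()] arguments
#' @param reference_n reference (outbred) cohort size; default: all
#'   ancestral individuals not used as founders
#' @param n_test held-out test individuals for the imputation evaluation
#' @param array_frac fraction of qualifying common sites put on the
#'   pseudo-array manifest
#' @param array_min_maf MAF floor for manifest sites
#' @param score_shift location shift of cohort-specific deleteriousness
#'   scores, in SD units
#' @param bins MAF bin edges for the imputation evaluation
#' @param ls list of [ls_params()] arguments
#' @param qc list of [qc_thresholds()] arguments
#' @param depletion_n_sub,depletion_reps rare-variant depletion parameters
#' @param ibd_group_size individuals per group for IBD/HBD summaries
#' @param stages character subset of c("simulate", "qc", "panel",
#'   "evaluate", "popgen")
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1, sim = list(), reference_n = NULL,
                            n_test = 10, array_frac = 0.5,
                            array_min_maf = 0.05, score_shift = 2,
                            bins = default_maf_bins(), ls = list(),
                            qc = list(), depletion_n_sub = 8,
                            depletion_reps = 10, ibd_group_size = 10,
                            stages = c("simulate", "qc", "panel",
                                       "evaluate", "popgen")) {
  cfg <- list(seed = as.integer(seed), sim = sim, reference_n = reference_n,
              n_test = n_test, array_frac = array_frac,
              array_min_maf = array_min_maf, score_shift = score_shift,
              bins = bins, ls = ls, qc = qc,
              depletion_n_sub = depletion_n_sub,
              depletion_reps = depletion_reps,
              ibd_group_size = ibd_group_size, stages = stages)
  bad <- setdiff(stages, c("simulate", "qc", "panel", "evaluate", "popgen"))
  if (length(bad)) stop("pipeline_config: unknown stage(s) ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' A small demonstration configuration
#'
#' Desk-scale parameters (60 ancestral diploids, 1,500 sites, 12 founders)
#' so the full pipeline runs in well under a minute.
#'
#' @param seed integer seed
#' @return a `pipeline_config`
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(
    seed = seed,
    sim = list(ancestral_pop_size = 60, burn_in_generations = 240,
               n_sites = 1500, n_founders = 12, pedigree_generations = 3,
               mean_offspring = 3, mutation_rate_per_site_per_gen = 1e-4,
               max_mate_kinship = 1 / 32),
    reference_n = 30, n_test = 5, depletion_n_sub = 5, ibd_group_size = 6)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields override [pipeline_config()] defaults
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", substream_seed(0, as.character(json)))
}

#' Run the full pipeline
#'
#' simulate -> qc -> build-panel -> impute/evaluate -> popgen, as toggled;
#' every artifact carries a provenance header (package version, seed, config
#' hash) and outputs are byte-deterministic for a fixed seed.
#'
#' @param config a `pipeline_config`
#' @param out_dir artifact directory (created if needed)
#' @return invisibly, a list of in-memory stage results
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  hash <- config_hash(config)
  prov <- provenance_line(seed, hash)
  prov_vcf <- provenance_line(seed, hash, prefix = "##")
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  log_lines <- c(prov)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # simulate ----------------------------------------------------------------
  res <- stage("simulate", {
    scfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
    anc <- simulate_ancestral(scfg)
    fe <- found_and_expand(anc, scfg)
    ref_n <- config$reference_n
    if (is.null(ref_n))
      ref_n <- length(panel_samples(anc)) - scfg$n_founders
    ref <- ancestral_cohort(anc, n = ref_n, exclude = fe$founder_source,
                            seed = substream_seed(seed, "reference"))
    noisy <- inject_noise(fe$genotypes, scfg$noise,
                          seed = substream_seed(seed, "noise_stage"),
                          ped = fe$ped)
    qual <- sum(gm_maf(noisy) >= config$array_min_maf, na.rm = TRUE)
    manifest <- make_array_manifest(
      noisy, max(1L, round(config$array_frac * qual)),
      min_maf = config$array_min_maf,
      seed = substream_seed(seed, "manifest_stage"))
    seg_c <- gm_alt_freq(fe$genotypes) > 0
    seg_r <- gm_alt_freq(ref$genotypes) > 0
    scores <- assign_scores(noisy$sites[seg_c, , drop = FALSE],
                            ref$genotypes$sites[seg_r, , drop = FALSE],
                            shift = config$score_shift,
                            seed = substream_seed(seed, "score_stage"))
    write_vcf(noisy, file.path(out_dir, "cohort.vcf"), provenance = prov_vcf)
    write_vcf(ref$genotypes, file.path(out_dir, "reference.vcf"),
              provenance = prov_vcf)
    write_ped(fe$ped, file.path(out_dir, "cohort.ped"))
    write_map(noisy$sites[, c("chrom", "pos", "cm")],
              file.path(out_dir, "map.txt"))
    write_manifest(manifest, file.path(out_dir, "manifest.txt"))
    write_scores(scores, file.path(out_dir, "scores.tsv"))
    write_table_prov(truth_segments(fe$truth),
                     file.path(out_dir, "truth_segments.tsv"), prov)
    note("simulate: cohort n=", length(noisy$samples), " sites=",
         nrow(noisy$sites), " reference n=", ref_n)
    list(config = scfg, ancestral = anc, fe = fe, reference = ref,
         noisy = noisy, manifest = manifest, scores = scores)
  })
  if (!("qc" %in% config$stages))
    return(finish_pipeline(res, log_lines, out_dir))

  # qc ----------------------------------------------------------------------
  res <- stage("qc", {
    thr <- do.call(qc_thresholds, config$qc)
    qc <- run_qc(res$noisy, res$fe$ped, thresholds = thr)
    write_vcf(qc$gm, file.path(out_dir, "cohort_qc.vcf"),
              provenance = prov_vcf)
    jsonlite::write_json(
      list(provenance = prov,
           n_input_sites = qc$report$n_input_sites,
           n_surviving = qc$report$n_surviving,
           site_counts = as.list(qc$report$site_counts),
           genotype_counts = as.list(qc$report$genotype_counts),
           mendel = as.list(qc$report$mendel)),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
    note("qc: ", qc$report$n_surviving, "/", qc$report$n_input_sites,
         " sites survive")
    c(res, list(qc = qc))
  })
  if (!("panel" %in% config$stages))
    return(finish_pipeline(res, log_lines, out_dir))

  # panel -------------------------------------------------------------------
  res <- stage("panel", {
    phased <- transmission_phase(res$qc$gm, res$fe$ped)
    n_test <- min(config$n_test, length(res$qc$gm$samples) %/% 3L)
    test_ids <- with_seed(substream_seed(seed, "test_set"),
                          sort(sample(res$qc$gm$samples, n_test)))
    rest <- subset_panel(phased,
                         hap_idx = which(!(phased$hap_samples %in% test_ids)))
    cohort_panel <- build_panel(rest, res$fe$ped, degree = 1)
    # a panel lists only sites where some member carries the alternate allele
    cohort_panel <- subset_panel(cohort_panel,
                                 site_idx = which(panel_freq(cohort_panel) > 0))
    ref_panel <- res$reference$panel
    ref_panel <- subset_panel(ref_panel,
                              site_idx = which(panel_freq(ref_panel) > 0))
    lsp <- do.call(ls_params, config$ls)
    merged <- merge_panels(cohort_panel, ref_panel, lsp)
    write_vcf(cohort_panel, file.path(out_dir, "panel_cohort.vcf"),
              provenance = prov_vcf)
    write_vcf(ref_panel, file.path(out_dir, "panel_reference.vcf"),
              provenance = prov_vcf)
    write_vcf(merged, file.path(out_dir, "panel_merged.vcf"),
              provenance = prov_vcf)
    note("panel: cohort=", ncol(cohort_panel$haps), " reference=",
         ncol(ref_panel$haps), " merged=", ncol(merged$haps), " haplotypes")
    c(res, list(phased = phased, test_ids = test_ids, lsp = lsp,
                panels = list(cohort = cohort_panel, reference = ref_panel,
                              merged = merged)))
  })
  if (!("evaluate" %in% config$stages))
    return(finish_pipeline(res, log_lines, out_dir))

  # evaluate ----------------------------------------------------------------
  res <- stage("evaluate", {
    tp <- res$fe$truth$true_haps
    test_panel <- subset_panel(
      tp, hap_idx = which(tp$hap_samples %in% res$test_ids))
    site_idx <- match(paste(res$qc$gm$sites$chrom, res$qc$gm$sites$pos),
                      paste(tp$sites$chrom, tp$sites$pos))
    test_panel <- subset_panel(test_panel, site_idx = sort(site_idx))
    ev <- compare_configs(test_panel, res$panels, res$manifest,
                          bins = config$bins, params = res$lsp,
                          bin_source = "reference")
    write_table_prov(ev$r2, file.path(out_dir, "eval_r2.tsv"), prov)
    if (!is.null(ev$sharing))
      write_table_prov(ev$sharing, file.path(out_dir, "eval_sharing.tsv"),
                       prov)
    jsonlite::write_json(
      list(provenance = prov, n_scored = ev$n_scored,
           specific = ev$specific,
           r2 = ev$r2),
      file.path(out_dir, "eval_report.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    note("evaluate: ", ev$n_scored, " scored variants")
    c(res, list(eval = ev))
  })
  if (!("popgen" %in% config$stages))
    return(finish_pipeline(res, log_lines, out_dir))

  # popgen ------------------------------------------------------------------
  res <- stage("popgen", {
    kin <- pedigree_kinship(res$fe$ped)
    freqs <- blue_frequencies(res$qc$gm, kin = kin)
    ref_gm <- res$reference$genotypes
    ref_freqs <- data.frame(chrom = ref_gm$sites$chrom,
                            pos = ref_gm$sites$pos, maf = gm_maf(ref_gm))
    drift <- drift_enrichment(freqs[freqs$maf > 0, c("chrom", "pos", "maf")],
                              ref_freqs)
    n_unrel <- length(select_unrelated(res$fe$ped, 3,
                                       ids = res$qc$gm$samples))
    n_sub <- min(config$depletion_n_sub, n_unrel,
                 length(ref_gm$samples))
    if (n_sub < config$depletion_n_sub)
      note("popgen: depletion n_sub reduced to ", n_sub,
           " (achievable unrelated set)")
    depl <- depletion_resample(res$qc$gm, ref_gm, res$fe$ped,
                               n_sub = n_sub,
                               n_reps = config$depletion_reps,
                               seed = substream_seed(seed, "depletion_stage"))
    k <- config$ibd_group_size
    coh_ids <- utils::head(select_unrelated(res$fe$ped, max_degree = 1,
                                            ids = res$qc$gm$samples), k)
    ref_ids <- utils::head(panel_samples(res$reference$panel), k)
    # merge cohort and reference haplotypes on their overlapping variants
    ref_pan <- res$reference$panel
    key_ph <- paste(res$phased$sites$chrom, res$phased$sites$pos)
    key_rf <- paste(ref_pan$sites$chrom, ref_pan$sites$pos)
    common <- intersect(key_ph, key_rf)
    haps_all <- hap_panel(
      res$phased$sites[match(common, key_ph), , drop = FALSE],
      cbind(res$phased$haps[match(common, key_ph), , drop = FALSE],
            ref_pan$haps[match(common, key_rf), , drop = FALSE]),
      c(res$phased$hap_samples, ref_pan$hap_samples),
      map_length_cm = res$phased$map_length_cm)
    seg <- detect_segments(haps_all, mode = "haplotype",
                           pairs = rbind(ibd_hap_pairs(coh_ids),
                                         ibd_hap_pairs(ref_ids),
                                         ibd_hap_pairs(coh_ids, ref_ids),
                                         hbd_hap_pairs(c(coh_ids, ref_ids))))
    pair_univ <- rbind(
      expand.grid(id1 = coh_ids, id2 = coh_ids, stringsAsFactors = FALSE),
      expand.grid(id1 = ref_ids, id2 = ref_ids, stringsAsFactors = FALSE),
      expand.grid(id1 = coh_ids, id2 = ref_ids, stringsAsFactors = FALSE))
    pair_univ <- pair_univ[pair_univ$id1 != pair_univ$id2, ]
    shr <- sharing_summaries(seg, haps_all$map_length_cm, pairs = pair_univ,
                             ids = c(coh_ids, ref_ids))
    # scores annotate the called variant set; restrict to QC survivors
    sc <- res$scores[paste(res$scores$chrom, res$scores$pos) %in%
                       paste(freqs$chrom, freqs$pos), , drop = FALSE]
    scores_cmp <- deleteriousness_compare(sc,
                                          freqs[, c("chrom", "pos", "maf")])
    write_table_prov(freqs, file.path(out_dir, "freq_table.tsv"), prov)
    write_table_prov(depl, file.path(out_dir, "depletion.tsv"), prov)
    write_table_prov(as.data.frame(seg),
                     file.path(out_dir, "segments.tsv"), prov)
    write_table_prov(shr$ibd, file.path(out_dir, "ibd_fractions.tsv"), prov)
    write_table_prov(shr$hbd, file.path(out_dir, "hbd_totals.tsv"), prov)
    write_table_prov(scores_cmp, file.path(out_dir, "score_compare.tsv"),
                     prov)
    jsonlite::write_json(
      list(provenance = prov, n_drifted = drift$n,
           crosstab = as.data.frame(drift$crosstab)),
      file.path(out_dir, "drift.json"), auto_unbox = TRUE, pretty = TRUE)
    note("popgen: ", drift$n, " drifted variants")
    c(res, list(freqs = freqs, drift = drift, depletion = depl,
                segments = seg, sharing = shr, score_compare = scores_cmp))
  })
  finish_pipeline(res, log_lines, out_dir)
}

finish_pipeline <- function(res, log_lines, out_dir) {
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(res)
}
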