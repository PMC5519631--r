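# ---- synthetic founder-population generator --------------------------------
#
# Forward Wright-Fisher on a finite-sites grid for the outbred ancestral
# population, then a bottleneck: n_founders individuals sampled as pedigree
# founders and expanded through monogamous non-overlapping generations by
# gene dropping (Poisson crossovers in cM space, per-site recurrent
# mutation during burn-in only). Truth tracks record, for every cohort
# haplotype, which founder haplotype each segment was copied from.

#' Noise model for synthetic genotype calls
#'
#' Fractions of calls to corrupt so that the QC cascade has something to
#' remove. Thresholds mirror the QC rules (GQ < 20, DP < 8, het allele
#' balance outside `[0.25, 0.75]`, half-calls, Mendelian flips).
#'
#' @param frac_low_gq proportion of calls assigned GQ drawn below 20
#' @param frac_low_dp proportion of calls assigned DP below 8
#' @param frac_half_calls proportion of calls half-called
#' @param frac_mendel_errors proportion of trio-child calls flipped to a
#'   different genotype
#' @param het_ab_distortion proportion of heterozygous calls whose allele
#'   balance is pushed outside `[0.25, 0.75]`
#' @return A `noise_config` list.
#' @export
noise_config <- function(frac_low_gq = 0.02, frac_low_dp = 0.02,
                         frac_half_calls = 0.01, frac_mendel_errors = 0.01,
                         het_ab_distortion = 0.02) {
  x <- list(frac_low_gq = frac_low_gq, frac_low_dp = frac_low_dp,
            frac_half_calls = frac_half_calls,
            frac_mendel_errors = frac_mendel_errors,
            het_ab_distortion = het_ab_distortion)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("noise_config: ", nm, " must be a proportion in [0, 1]")
  }
  structure(x, class = "noise_config")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale world: an ancestral population of 100
#' diploids at mutation-drift balance over 5,000 sites spanning 100 cM, a
#' 20-founder bottleneck, and three generations of monogamous expansion with
#' Poisson(3) offspring per couple.
#'
#' @param ancestral_pop_size diploid ancestral population size N
#' @param burn_in_generations forward generations before sampling (default 4N)
#' @param mutation_rate_per_site_per_gen per-site per-generation flip rate
#' @param n_sites number of sites on the finite-sites grid
#' @param region_length_cm genetic map length in cM (uniform map)
#' @param n_founders diploid founders sampled from the ancestral population
#' @param pedigree_generations offspring generations below the founders
#' @param mean_offspring Poisson mean number of children per couple
#' @param max_mate_kinship maximum pedigree kinship allowed between mates;
#'   the default 0 forbids inbreeding loops entirely (deep pedigrees need a
#'   small positive value or couples become impossible to form)
#' @param cousin_mating_frac fraction of couples (generation >= 2) forced to
#'   be first cousins, to create homozygosity by descent
#' @param seed master integer seed
#' @param noise a [noise_config()]
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(ancestral_pop_size = 100, burn_in_generations = 400,
                       mutation_rate_per_site_per_gen = 1e-4, n_sites = 5000,
                       region_length_cm = 100, n_founders = 20,
                       pedigree_generations = 3, mean_offspring = 3,
                       max_mate_kinship = 0, cousin_mating_frac = 0,
                       mate_choice = c("random", "closest_permitted"),
                       seed = 1, noise = noise_config()) {
  mate_choice <- match.arg(mate_choice)
  cfg <- list(ancestral_pop_size = ancestral_pop_size,
              burn_in_generations = burn_in_generations,
              mutation_rate_per_site_per_gen = mutation_rate_per_site_per_gen,
              n_sites = n_sites, region_length_cm = region_length_cm,
              n_founders = n_founders,
              pedigree_generations = pedigree_generations,
              mean_offspring = mean_offspring,
              max_mate_kinship = max_mate_kinship,
              cousin_mating_frac = cousin_mating_frac,
              mate_choice = mate_choice,
              seed = as.integer(seed), noise = noise)
  sizes <- c("ancestral_pop_size", "burn_in_generations", "n_sites",
             "n_founders", "pedigree_generations")
  for (nm in sizes)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1)
      stop("sim_config: ", nm, " must be a positive integer")
  if (cfg$region_length_cm <= 0) stop("sim_config: region_length_cm must be > 0")
  if (cfg$mean_offspring <= 0) stop("sim_config: mean_offspring must be > 0")
  mu <- cfg$mutation_rate_per_site_per_gen
  if (mu < 0 || mu > 1) stop("sim_config: mutation rate must be in [0, 1]")
  if (!inherits(noise, "noise_config")) stop("sim_config: noise must be a noise_config")
  structure(cfg, class = "sim_config")
}

# one gamete: per-site source haplotype (1 or 2) under Poisson crossovers,
# breakpoints uniform in cM
meiosis_src <- function(cm, length_cm) {
  k <- stats::rpois(1L, length_cm / 100)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(rep.int(start, length(cm)))
  bp <- sort(stats::runif(k, 0, length_cm))
  1L + (start - 1L + findInterval(cm, bp)) %% 2L
}

# assemble a gamete from two parental columns given a source vector
splice <- function(h1, h2, src) {
  out <- h1
  w <- src == 2L
  out[w] <- h2[w]
  out
}

# Wright-Fisher burn-in on an active-site representation: only currently
# polymorphic sites are stored and recombined (monomorphic sites are a
# constant, copying them is a no-op); mutation activates sites, fixation
# deactivates them. An exact optimization of the naive per-generation
# matrix rebuild, not an approximation.
wf_evolve <- function(S, n2, cm, length_cm, mu, generations) {
  N <- n2 %/% 2L
  base <- integer(S)                    # allele carried at inactive sites
  act <- integer(0)                     # active (polymorphic) site indices
  H <- matrix(0L, 0L, n2)               # active rows x haplotypes
  for (g in seq_len(generations)) {
    if (length(act)) {
      cma <- cm[act]
      Hn <- matrix(0L, length(act), n2)
      for (i in seq_len(N)) {
        for (gam in 1:2) {
          p <- sample.int(N, 1L)
          k <- stats::rpois(1L, length_cm / 100)
          start <- sample.int(2L, 1L)
          child <- if (k == 0L) H[, 2L * p - 2L + start] else {
            bp <- sort(stats::runif(k, 0, length_cm))
            src <- 1L + (start - 1L + findInterval(cma, bp)) %% 2L
            splice(H[, 2L * p - 1L], H[, 2L * p], src)
          }
          Hn[, 2L * i - 2L + gam] <- child
        }
      }
      H <- Hn
    }
    if (mu > 0) {
      nm <- stats::rbinom(1L, S * n2, mu)
      if (nm > 0L) {
        pos <- sample.int(S * n2, nm)
        site <- (pos - 1L) %% S + 1L
        hap <- (pos - 1L) %/% S + 1L
        newsite <- setdiff(unique(site), act)
        if (length(newsite)) {
          H <- rbind(H, matrix(rep(base[newsite], n2), length(newsite), n2))
          act <- c(act, newsite)
        }
        row <- match(site, act)
        idx <- cbind(row, hap)
        H[idx] <- 1L - H[idx]
      }
    }
    if (length(act) && g %% 10L == 0L) {
      cnt <- rowSums(H)
      fixed1 <- cnt == n2; fixed0 <- cnt == 0L
      if (any(fixed1)) base[act[fixed1]] <- 1L
      keep <- !(fixed0 | fixed1)
      H <- H[keep, , drop = FALSE]
      act <- act[keep]
    }
  }
  full <- matrix(rep(base, n2), S, n2)
  if (length(act)) full[act, ] <- H
  full
}

sim_sites <- function(config) {
  S <- config$n_sites
  pairs <- cbind(c("A", "A", "C", "G", "T", "C"),
                 c("C", "G", "T", "A", "G", "T"))
  pick <- sample.int(nrow(pairs), S, replace = TRUE)
  data.frame(chrom = "1", pos = seq_len(S) * 100L,
             ref = pairs[pick, 1], alt = pairs[pick, 2],
             cm = (seq_len(S) - 0.5) / S * config$region_length_cm,
             stringsAsFactors = FALSE)
}

#' Simulate the outbred ancestral population
#'
#' Forward Wright-Fisher reproduction from a monomorphic start: each diploid
#' child draws two random parents; each gamete is a recombinant of the
#' parent's two haplotypes (crossover count Poisson with mean map length in
#' Morgans, breakpoints uniform in cM); recurrent per-site mutation flips
#' alleles. Monomorphic sites are retained with frequency 0 so later
#' site-union logic is well defined.
#'
#' @param config a [sim_config()]
#' @return A [hap_panel()] of `2 * ancestral_pop_size` phased haplotypes.
#' @export
simulate_ancestral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "ancestral"), {
    sites <- sim_sites(config)
    N <- config$ancestral_pop_size
    H <- wf_evolve(config$n_sites, 2L * N, sites$cm, config$region_length_cm,
                   config$mutation_rate_per_site_per_gen,
                   config$burn_in_generations)
    ids <- sprintf("A%04d", seq_len(N))
    hap_panel(sites, H, rep(ids, each = 2L),
              map_length_cm = config$region_length_cm)
  })
}

# clean per-call quality metadata for a dosage matrix; allele balance of
# clean het calls is kept inside [0.3, 0.7] (distortion is the noise model's
# job, not the clean sequencer's)
synth_call_metadata <- function(dosage) {
  S <- nrow(dosage); N <- ncol(dosage)
  n <- S * N
  dp <- matrix(8 + stats::rpois(n, 27), S, N)
  gq <- matrix(pmin(99, 20 + stats::rpois(n, 40)), S, N)
  ad_alt <- matrix(0, S, N)
  het <- which(dosage == 1L)
  if (length(het)) {
    draw <- stats::rbinom(length(het), dp[het], 0.5)
    ad_alt[het] <- pmin(pmax(draw, ceiling(0.3 * dp[het])), floor(0.7 * dp[het]))
  }
  hom_alt <- which(dosage == 2L)
  ad_alt[hom_alt] <- dp[hom_alt]
  list(gq = gq, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt)
}

# unphased geno_matrix from truth haplotype columns (allele order randomized)
haps_to_genotypes <- function(sites, hap1, hap2, samples) {
  swap <- matrix(stats::runif(nrow(hap1) * ncol(hap1)) < 0.5,
                 nrow(hap1), ncol(hap1))
  a1 <- hap1; a2 <- hap2
  a1[swap] <- hap2[swap]; a2[swap] <- hap1[swap]
  meta <- synth_call_metadata(a1 + a2)
  geno_matrix(sites, samples, a1, a2, phased = NULL, gq = meta$gq,
              dp = meta$dp, ad_ref = meta$ad_ref, ad_alt = meta$ad_alt)
}

shuffle <- function(x) x[sample.int(length(x))]

# greedy sex-respecting pairing under a kinship ceiling; optionally force a
# fraction of first-cousin couples (phi exactly 1/16 in an outbred pedigree).
# mate_choice "closest_permitted" marries the most-related partner under the
# ceiling (consanguinity-tolerant isolate demography): the population keeps
# re-using the same founder pool instead of fanning out into disjoint
# lineages, which is what sustains deep pedigrees at desk scale.
pair_couples <- function(ids, sex, kin, max_mate_kinship, cousin_frac,
                         mate_choice = "random") {
  males <- ids[sex == 1L]; females <- ids[sex == 2L]
  couples <- list()
  take_one <- function(x) x[sample.int(length(x), 1L)]
  if (cousin_frac > 0 && length(males) && length(females)) {
    target <- round(cousin_frac * min(length(males), length(females)))
    for (k in seq_len(target)) {
      found <- FALSE
      for (m in shuffle(males)) {
        cand <- females[abs(kin[m, females] - 1 / 16) < 1e-9]
        if (length(cand)) {
          f <- take_one(cand)
          couples[[length(couples) + 1L]] <- c(m, f)
          males <- setdiff(males, m); females <- setdiff(females, f)
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
  }
  # greedy matching can miss a feasible pairing; keep the best of a few
  # random restarts
  best <- list()
  for (try in seq_len(30L)) {
    cpl <- list()
    fem <- females
    for (m in shuffle(males)) {
      if (!length(fem)) break
      cand <- fem[kin[m, fem] <= max_mate_kinship + 1e-12]
      if (!length(cand)) next
      f <- if (mate_choice == "closest_permitted") {
        best_k <- max(kin[m, cand])
        take_one(cand[kin[m, cand] >= best_k - 1e-12])
      } else take_one(cand)
      cpl[[length(cpl) + 1L]] <- c(m, f)
      fem <- setdiff(fem, f)
    }
    if (length(cpl) > length(best)) best <- cpl
    if (length(best) == min(length(males), length(females))) break
  }
  c(couples, best)
}

#' Found a bottlenecked cohort and expand it through a pedigree
#'
#' Samples `n_founders` ancestral individuals as pedigree founders, forms
#' monogamous couples generation by generation, draws Poisson(mean_offspring)
#' children per couple, and transmits haplotypes by gene dropping with the
#' same recombination model as the ancestral simulation, recording
#' founder-segment labels. The genotyped cohort comprises all generations
#' below the founders ("final plus intermediate"); founders appear in the
#' pedigree only.
#'
#' @param ancestral a [hap_panel()] from [simulate_ancestral()]
#' @param config the same [sim_config()]
#' @return list with elements `genotypes` ([geno_matrix()]), `ped`
#'   ([pedigree()]), `truth` (`truth_tracks`), and `founder_ids`.
#' @export
found_and_expand <- function(ancestral, config) {
  stopifnot(inherits(ancestral, "hap_panel"), inherits(config, "sim_config"))
  N_anc <- length(panel_samples(ancestral))
  if (config$n_founders > N_anc)
    stop("n_founders exceeds ancestral population size")
  with_seed(substream_seed(config$seed, "pedigree"), {
    cm <- ancestral$sites$cm
    L <- config$region_length_cm
    F <- config$n_founders
    anc_ids <- panel_samples(ancestral)
    founder_src <- sample(anc_ids, F)
    founder_ids <- sprintf("F%03d", seq_len(F))
    founder_hap_names <- paste0(rep(founder_ids, each = 2L), ".", 1:2)

    # haplotype and label storage for every pedigree member
    hapA <- list(); hapB <- list(); labA <- list(); labB <- list()
    for (i in seq_len(F)) {
      cols <- which(ancestral$hap_samples == founder_src[i])
      hapA[[founder_ids[i]]] <- ancestral$haps[, cols[1]]
      hapB[[founder_ids[i]]] <- ancestral$haps[, cols[2]]
      labA[[founder_ids[i]]] <- rep.int(2L * i - 1L, length(cm))
      labB[[founder_ids[i]]] <- rep.int(2L * i, length(cm))
    }

    ped_df <- data.frame(id = founder_ids, father = NA_character_,
                         mother = NA_character_,
                         sex = rep(1:2, length.out = F),
                         generation = 0L, stringsAsFactors = FALSE)
    current <- founder_ids
    for (g in seq_len(config$pedigree_generations)) {
      kin <- pedigree_kinship(pedigree(ped_df))
      couples <- pair_couples(current,
                              ped_df$sex[match(current, ped_df$id)], kin,
                              config$max_mate_kinship,
                              if (g >= 2L) config$cousin_mating_frac else 0,
                              mate_choice = config$mate_choice)
      if (!length(couples))
        stop("simulation error: zero couples formed at generation ", g)
      children <- character(0)
      for (ci in seq_along(couples)) {
        fa <- couples[[ci]][1]; mo <- couples[[ci]][2]
        nk <- stats::rpois(1L, config$mean_offspring)
        for (k in seq_len(nk)) {
          id <- sprintf("G%d_%03d", g, length(children) + 1L)
          src_p <- meiosis_src(cm, L); src_m <- meiosis_src(cm, L)
          hapA[[id]] <- splice(hapA[[fa]], hapB[[fa]], src_p)
          labA[[id]] <- splice(labA[[fa]], labB[[fa]], src_p)
          hapB[[id]] <- splice(hapA[[mo]], hapB[[mo]], src_m)
          labB[[id]] <- splice(labA[[mo]], labB[[mo]], src_m)
          ped_df <- rbind(ped_df, data.frame(
            id = id, father = fa, mother = mo,
            sex = 0L, generation = g,
            stringsAsFactors = FALSE))
          children <- c(children, id)
        }
      }
      if (!length(children))
        stop("simulation error: pedigree went extinct at generation ", g)
      # balanced randomized sex ratio: desk-scale generations are small
      # enough that a fair coin regularly starves one sex of mates
      ped_df$sex[match(children, ped_df$id)] <-
        shuffle(rep_len(1:2, length(children)))
      current <- children
    }

    cohort <- ped_df$id[ped_df$generation > 0L]
    h1 <- do.call(cbind, hapA[cohort]); h2 <- do.call(cbind, hapB[cohort])
    l1 <- do.call(cbind, labA[cohort]); l2 <- do.call(cbind, labB[cohort])
    S <- length(cm)
    label_matrix <- matrix(0L, S, 2L * length(cohort))
    truth_haps <- matrix(0L, S, 2L * length(cohort))
    label_matrix[, seq(1L, by = 2L, length.out = length(cohort))] <- l1
    label_matrix[, seq(2L, by = 2L, length.out = length(cohort))] <- l2
    truth_haps[, seq(1L, by = 2L, length.out = length(cohort))] <- h1
    truth_haps[, seq(2L, by = 2L, length.out = length(cohort))] <- h2

    true_panel <- hap_panel(ancestral$sites, truth_haps,
                            rep(cohort, each = 2L), map_length_cm = L)
    colnames(label_matrix) <- colnames(true_panel$haps)
    founder_panel <- hap_panel(
      ancestral$sites,
      do.call(cbind, lapply(founder_ids, function(i) cbind(hapA[[i]], hapB[[i]]))),
      rep(founder_ids, each = 2L), map_length_cm = L)

    truth <- structure(list(
      label_matrix = label_matrix,
      founder_hap_names = founder_hap_names,
      sites = ancestral$sites,
      true_haps = true_panel,
      founder_haps = founder_panel,
      true_frequencies = data.frame(
        chrom = ancestral$sites$chrom, pos = ancestral$sites$pos,
        anc_freq = panel_freq(ancestral),
        founder_freq = panel_freq(founder_panel),
        cohort_freq = panel_freq(true_panel)),
      map_length_cm = L), class = "truth_tracks")

    genotypes <- haps_to_genotypes(ancestral$sites, h1, h2, cohort)
    list(genotypes = genotypes, ped = pedigree(ped_df), truth = truth,
         founder_ids = founder_ids, founder_source = founder_src)
  })
}

#' Founder-segment labels as interval lists
#'
#' Collapses each cohort haplotype's per-site founder labels into maximal
#' segments; segments of one haplotype partition the site range.
#'
#' @param truth a `truth_tracks` object
#' @return data.frame(hap, start_site, end_site, founder_hap)
#' @export
truth_segments <- function(truth) {
  out <- lapply(colnames(truth$label_matrix), function(h) {
    r <- rle(truth$label_matrix[, h])
    e <- cumsum(r$lengths)
    data.frame(hap = h, start_site = c(1L, utils::head(e, -1) + 1L),
               end_site = e,
               founder_hap = truth$founder_hap_names[r$values],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.truth_tracks <- function(x, ...) {
  cat(sprintf("truth_tracks: %d haplotypes x %d sites, %d founder haplotypes\n",
              ncol(x$label_matrix), nrow(x$label_matrix),
              length(x$founder_hap_names)))
  invisible(x)
}

#' Gene-drop founder labels down a fixed pedigree
#'
#' Transmits labelled founder haplotypes through an arbitrary (acyclic)
#' pedigree with the standard recombination model, recording which founder
#' haplotype every segment was copied from. Used for Mendelian-expectation
#' checks (mean truth-IBD sharing equals twice the pedigree kinship).
#'
#' @param ped a [pedigree()]
#' @param n_sites number of uniformly spaced sites
#' @param map_length_cm map length in cM
#' @param seed integer seed
#' @return a `truth_tracks` with label tracks for *all* pedigree members
#'   (founders included)
#' @export
gene_drop <- function(ped, n_sites = 500, map_length_cm = 100, seed = 1) {
  d <- ped$df
  ord <- ped_topo_order(ped)
  sites <- data.frame(chrom = "1", pos = seq_len(n_sites) * 100L,
                      ref = "A", alt = "C",
                      cm = (seq_len(n_sites) - 0.5) / n_sites * map_length_cm)
  founders <- ped_founders(ped)
  founder_hap_names <- paste0(rep(founders, each = 2L), ".", 1:2)
  with_seed(substream_seed(seed, "gene_drop"), {
    lab <- list()
    for (i in ord) {
      id <- d$id[i]
      if (is.na(d$father[i]) || is.na(d$mother[i])) {
        fi <- match(id, founders)
        lab[[id]] <- cbind(rep.int(2L * fi - 1L, n_sites),
                           rep.int(2L * fi, n_sites))
      } else {
        lab[[id]] <- cbind(
          splice(lab[[d$father[i]]][, 1], lab[[d$father[i]]][, 2],
                 meiosis_src(sites$cm, map_length_cm)),
          splice(lab[[d$mother[i]]][, 1], lab[[d$mother[i]]][, 2],
                 meiosis_src(sites$cm, map_length_cm)))
      }
    }
    label_matrix <- do.call(cbind, lab[d$id])
    colnames(label_matrix) <- paste0(rep(d$id, each = 2L), ".", 1:2)
    structure(list(label_matrix = label_matrix,
                   founder_hap_names = founder_hap_names,
                   sites = sites, map_length_cm = map_length_cm),
              class = "truth_tracks")
  })
}

#' Pair ancestral haplotypes into a diploid reference cohort
#'
#' Stand-in for an outbred sequenced reference sample (clean genotype
#' metadata, no pedigree). Individuals used as cohort founders can be
#' excluded so the reference sample is disjoint from the founder set.
#'
#' @param ancestral a [hap_panel()]
#' @param n number of individuals (default all available)
#' @param exclude sample ids to leave out
#' @param seed integer seed for the sampling and metadata draws
#' @return list(genotypes = [geno_matrix()], panel = [hap_panel()])
#' @export
ancestral_cohort <- function(ancestral, n = NULL, exclude = character(0),
                             seed = 1) {
  ids <- setdiff(panel_samples(ancestral), exclude)
  if (is.null(n)) n <- length(ids)
  if (n > length(ids)) stop("not enough ancestral individuals after exclusion")
  with_seed(substream_seed(seed, "ancestral_cohort"), {
    keep <- sort(sample(ids, n))
    cols <- which(ancestral$hap_samples %in% keep)
    panel <- subset_panel(ancestral, hap_idx = cols)
    odd <- seq(1L, by = 2L, length.out = n)
    gm <- haps_to_genotypes(panel$sites, panel$haps[, odd, drop = FALSE],
                            panel$haps[, odd + 1L, drop = FALSE],
                            panel_samples(panel))
    list(genotypes = gm, panel = panel)
  })
}

#' Corrupt genotype calls according to a noise model
#'
#' Applies, in order: low-GQ, low-DP (allele depths rescaled), half-calls,
#' het allele-balance distortion, and Mendelian flips of trio-child calls
#' (children whose two parents are both genotyped). A truth mask of corrupted
#' calls is attached as attribute `"noise_mask"`
#' (data.frame site, sample, type).
#'
#' @param genotypes a [geno_matrix()]
#' @param noise a [noise_config()]
#' @param seed integer seed
#' @param ped optional [pedigree()]; required for Mendelian flips
#' @return The corrupted [geno_matrix()].
#' @export
inject_noise <- function(genotypes, noise, seed, ped = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(noise, "noise_config"))
  gm <- genotypes
  S <- nrow(gm$sites); N <- length(gm$samples)
  mask <- list()
  note <- function(idx, type) {
    if (!length(idx)) return()
    mask[[length(mask) + 1L]] <<- data.frame(
      site = (idx - 1L) %% S + 1L, sample = (idx - 1L) %/% S + 1L,
      type = type, stringsAsFactors = FALSE)
  }
  with_seed(substream_seed(seed, "noise"), {
    n <- S * N
    draw <- function(frac, eligible = seq_len(n)) {
      k <- round(frac * length(eligible))
      if (k <= 0L) integer(0) else eligible[sample.int(length(eligible), k)]
    }
    idx <- draw(noise$frac_low_gq)
    gm$gq[idx] <- sample(0:19, length(idx), replace = TRUE)
    note(idx, "low_gq")

    idx <- draw(noise$frac_low_dp)
    newdp <- sample(0:7, length(idx), replace = TRUE)
    ab <- gm$ad_alt[idx] / pmax(gm$ad_ref[idx] + gm$ad_alt[idx], 1)
    gm$dp[idx] <- newdp
    gm$ad_alt[idx] <- round(newdp * ab)
    gm$ad_ref[idx] <- newdp - gm$ad_alt[idx]
    note(idx, "low_dp")

    idx <- draw(noise$frac_half_calls)
    if (length(idx)) {
      drop_first <- stats::runif(length(idx)) < 0.5
      gm$a1[idx[drop_first]] <- NA_integer_
      gm$a2[idx[!drop_first]] <- NA_integer_
    }
    note(idx, "half_call")

    het <- which(gt_dosage(gm) == 1L & gm$dp >= 4)
    idx <- draw(noise$het_ab_distortion, het)
    if (length(idx)) {
      low <- stats::runif(length(idx)) < 0.5
      dp <- gm$dp[idx]
      gm$ad_alt[idx] <- ifelse(low, pmin(floor(0.249 * dp),
                                         floor(dp * stats::runif(length(idx), 0, 0.22))),
                               pmax(ceiling(0.751 * dp),
                                    ceiling(dp * stats::runif(length(idx), 0.78, 1))))
      gm$ad_alt[idx] <- pmin(pmax(gm$ad_alt[idx], 0), dp)
      gm$ad_ref[idx] <- dp - gm$ad_alt[idx]
    }
    note(idx, "ab_distortion")

    if (noise$frac_mendel_errors > 0) {
      if (is.null(ped))
        stop("inject_noise: a pedigree is required for Mendelian flips")
      tr <- ped_trios(ped)
      tr <- tr[tr$child %in% gm$samples & tr$father %in% gm$samples &
                 tr$mother %in% gm$samples, ]
      kids <- match(unique(tr$child), gm$samples)
      if (length(kids)) {
        elig <- as.vector(outer(seq_len(S), (kids - 1L) * S, `+`))
        idx <- draw(noise$frac_mendel_errors, elig)
        if (length(idx)) {
          g <- gt_dosage(gm)[idx]
          shift <- sample.int(2L, length(idx), replace = TRUE)
          newg <- (g + shift) %% 3L
          gm$a1[idx] <- as.integer(newg > 0L)
          gm$a2[idx] <- as.integer(newg > 1L)
        }
        note(idx, "mendel_flip")
      }
    }
  })
  attr(gm, "noise_mask") <- if (length(mask)) do.call(rbind, mask) else
    data.frame(site = integer(0), sample = integer(0), type = character(0))
  gm
}

#' Draw a pseudo-array site manifest
#'
#' A sorted random subset of common sites stands in for the content of a
#' genotyping array.
#'
#' @param genotypes a [geno_matrix()]
#' @param n_array_sites number of sites to select
#' @param min_maf minimum cohort MAF for a site to qualify (default 0.05)
#' @param seed integer seed
#' @return data.frame(chrom, pos) sorted by position
#' @export
make_array_manifest <- function(genotypes, n_array_sites, min_maf = 0.05,
                                seed = 1) {
  maf <- gm_maf(genotypes)
  qual <- which(!is.na(maf) & maf >= min_maf)
  if (length(qual) < n_array_sites)
    stop("manifest error: only ", length(qual), " sites with MAF >= ", min_maf)
  with_seed(substream_seed(seed, "manifest"), {
    pick <- sort(qual[sample.int(length(qual), n_array_sites)])
    genotypes$sites[pick, c("chrom", "pos")]
  })
}

#' Assign synthetic deleteriousness scores
#'
#' Cohort-specific variants (absent from the reference site list) draw
#' normal scores location-shifted by `+shift` relative to shared variants;
#' only the shift matters to the downstream rank-sum comparison.
#'
#' @param cohort_sites data.frame(chrom, pos, ...) of cohort variants
#' @param reference_sites data.frame(chrom, pos, ...) of reference variants
#' @param shift nonnegative location shift, in score standard deviations
#' @param seed integer seed
#' @param sd score standard deviation (default 1)
#' @return data.frame(chrom, pos, score, status) — the score table
#' @export
assign_scores <- function(cohort_sites, reference_sites, shift, seed, sd = 1) {
  if (shift < 0) stop("assign_scores: shift must be >= 0")
  key_c <- paste(cohort_sites$chrom, cohort_sites$pos)
  key_r <- paste(reference_sites$chrom, reference_sites$pos)
  specific <- !(key_c %in% key_r)
  with_seed(substream_seed(seed, "scores"), {
    score <- stats::rnorm(nrow(cohort_sites), mean = ifelse(specific, shift, 0),
                          sd = sd)
    data.frame(chrom = cohort_sites$chrom, pos = cohort_sites$pos,
               score = score,
               status = ifelse(specific, "cohort_specific", "shared"),
               stringsAsFactors = FALSE)
  })
}
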