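# ---- reference-panel construction ------------------------------------------

#' Pedigree kinship matrix
#'
#' Standard recursion with founders pairwise unrelated:
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2` and
#' `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2` (unknown parents
#' contribute 0). The diagonal therefore already equals `(1 + F_i) / 2`, the
#' self-kinship needed by the BLUE frequency estimator.
#'
#' @param ped a [pedigree()] (acyclic; a cycle is an error)
#' @return symmetric numeric matrix with id dimnames
#' @export
pedigree_kinship <- function(ped) {
  d <- ped$df
  n <- nrow(d)
  if (!n) stop("empty pedigree")
  ord <- ped_topo_order(ped)
  fa <- match(d$father, d$id); mo <- match(d$mother, d$id)
  K <- matrix(0, n, n, dimnames = list(d$id, d$id))
  done <- integer(0)
  for (i in ord) {
    fi <- fa[i]; mi <- mo[i]
    kf <- if (!is.na(fi)) K[fi, done] else rep(0, length(done))
    km <- if (!is.na(mi)) K[mi, done] else rep(0, length(done))
    if (length(done)) {
      K[i, done] <- (kf + km) / 2
      K[done, i] <- K[i, done]
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(fi) && !is.na(mi)) K[fi, mi] else 0)
    done <- c(done, i)
  }
  K
}

# KING-style geometric degree boundary: individuals are considered related
# at degree <= d when phi >= 2^-(d+2) * (1 + sqrt(2)) / 2
kinship_degree_threshold <- function(max_degree) {
  2^-(max_degree + 2) * (1 + sqrt(2)) / 2
}

#' Greedy selection of pedigree-unrelated individuals
#'
#' Returns a maximal subset with pairwise kinship below the degree
#' threshold, removing individuals in descending order of number of
#' relatives (ties broken by sample id) until no related pair remains.
#'
#' @param ped a [pedigree()]
#' @param max_degree relationship degree to exclude (1 = first degree,
#'   3 = up to third degree)
#' @param ids restrict the selection to these individuals (default all)
#' @param kin optional precomputed kinship matrix
#' @return character vector of selected ids, sorted
#' @export
select_unrelated <- function(ped, max_degree = 3, ids = NULL, kin = NULL) {
  if (is.null(kin)) kin <- pedigree_kinship(ped)
  if (is.null(ids)) ids <- ped$df$id
  if (!length(ids)) stop("select_unrelated: empty pedigree / id set")
  thr <- kinship_degree_threshold(max_degree)
  K <- kin[ids, ids, drop = FALSE]
  adj <- K >= thr - 1e-12
  diag(adj) <- FALSE
  keep <- ids
  while (TRUE) {
    deg <- rowSums(adj)
    if (!any(deg > 0)) break
    drop_i <- order(-deg, keep)[1]
    keep <- keep[-drop_i]
    adj <- adj[-drop_i, -drop_i, drop = FALSE]
  }
  sort(keep)
}

#' Pedigree-transmission phasing
#'
#' Three complementary mechanisms, in decreasing order of reliability:
#'
#' 1. *Transmission skeleton*: paternal/maternal alleles assigned wherever
#'    Mendelian transmission is unambiguous (homozygous individual, or
#'    heterozygote with a homozygous parent).
#' 2. *Gamete chain phasing* for individuals with genotyped children: each
#'    child's determined gamete links consecutive heterozygous sites of the
#'    parent (no-recombination vote between neighbouring informative sites);
#'    majority voting resolves the parent's haplotypes, anchored to the
#'    paternal/maternal labelling by the skeleton.
#' 3. *Duo Viterbi* for remaining ambiguous heterozygotes of individuals
#'    with a phased genotyped parent: a 2-state copying HMM along that
#'    parent's haplotypes (switch probability = genetic distance in
#'    Morgans) fills each ambiguous site from the copied parental haplotype.
#'
#' Anything still unresolved (e.g. childless individuals with ungenotyped
#' parents) is phased by best-matching haplotype context in a sliding
#' window against the already-phased cohort. Missing genotypes are filled
#' with the major allele. Flags are kept as attribute `"phase_flags"`
#' ("ok", "chain", "duo", "pool", "arbitrary", "filled").
#'
#' @param gm QC-passed [geno_matrix()]; sites must carry a `cm` column or a
#'   `map` must be given
#' @param ped a [pedigree()]
#' @param map optional genetic map data.frame(chrom, pos, cm)
#' @param window half-width, in sites, of the fallback context window
#' @param err assumed per-site error rate of the duo-Viterbi emissions
#' @param map_length_cm optional map length for the resulting panel
#' @return a [hap_panel()] with two haplotypes per sample
#' @export
transmission_phase <- function(gm, ped, map = NULL, window = 50, err = 0.02,
                               map_length_cm = NULL) {
  sites <- gm$sites
  if (is.null(sites$cm)) {
    if (is.null(map)) stop("transmission_phase: sites lack cm and no map given")
    sites$cm <- map_interpolate(map, sites$pos)
  }
  d <- gt_dosage(gm)
  S <- nrow(sites); N <- length(gm$samples)
  pat <- matrix(NA_integer_, S, N); mat <- matrix(NA_integer_, S, N)
  flags <- matrix("ok", S, N)
  major <- as.integer(rowMeans(d, na.rm = TRUE) / 2 >= 0.5)
  major[is.na(major)] <- 0L
  fi <- match(ped$df$father[match(gm$samples, ped$df$id)], gm$samples)
  mi <- match(ped$df$mother[match(gm$samples, ped$df$id)], gm$samples)

  # --- 1. transmission skeleton -------------------------------------------
  for (i in seq_len(N)) {
    g <- d[, i]
    gf <- if (!is.na(fi[i])) d[, fi[i]] else rep(NA_integer_, S)
    gmo <- if (!is.na(mi[i])) d[, mi[i]] else rep(NA_integer_, S)
    hom0 <- !is.na(g) & g == 0L; hom2 <- !is.na(g) & g == 2L
    pat[hom0, i] <- 0L; mat[hom0, i] <- 0L
    pat[hom2, i] <- 1L; mat[hom2, i] <- 1L
    het <- !is.na(g) & g == 1L
    f0 <- het & !is.na(gf) & gf == 0L; f2 <- het & !is.na(gf) & gf == 2L
    pat[f0, i] <- 0L; mat[f0, i] <- 1L
    pat[f2, i] <- 1L; mat[f2, i] <- 0L
    rest <- het & is.na(pat[, i])
    m0 <- rest & !is.na(gmo) & gmo == 0L; m2 <- rest & !is.na(gmo) & gmo == 2L
    pat[m0, i] <- 1L; mat[m0, i] <- 0L
    pat[m2, i] <- 0L; mat[m2, i] <- 1L
    flags[het & is.na(pat[, i]), i] <- "ambiguous"
  }

  children_of <- lapply(seq_len(N), function(i)
    which(fi == i | mi == i))

  # --- 2. gamete chain phasing of parents ---------------------------------
  for (i in seq_len(N)) {
    kids <- children_of[[i]]
    amb <- which(flags[, i] == "ambiguous")
    if (!length(kids) || !length(amb)) next
    hets <- which(!is.na(d[, i]) & d[, i] == 1L)
    # determined gamete-from-i allele per child: the child's pat (if i is
    # the father) or mat (if mother) skeleton track
    gam <- vapply(kids, function(k) {
      side <- if (!is.na(fi[k]) && fi[k] == i) pat[, k] else mat[, k]
      side[flags[, k] %in% c("ambiguous", "filled")] <- NA_integer_
      side
    }, integer(S))
    z <- rep(NA_integer_, S)        # allele on "haplotype 1" at het sites
    comp <- rep(NA_integer_, S); comp_id <- 0L
    last_inf <- rep(NA_integer_, length(kids))  # last informative het/child
    for (s in hets) {
      votes <- integer(0)
      for (ci in seq_along(kids)) {
        if (is.na(gam[s, ci])) next
        pmind <- last_inf[ci]
        if (!is.na(pmind) && !is.na(z[pmind]))
          votes <- c(votes, xor(z[pmind],
                                xor(gam[pmind, ci], gam[s, ci])))
        last_inf[ci] <- s
      }
      if (length(votes)) {
        z[s] <- as.integer(mean(votes) >= 0.5)
      } else {
        z[s] <- 1L                  # new chain component
        comp_id <- comp_id + 1L
      }
      comp[s] <- comp_id
    }
    # anchor each component to the pat/mat labelling via the skeleton
    for (cid in seq_len(comp_id)) {
      ss <- hets[!is.na(comp[hets]) & comp[hets] == cid]
      det <- ss[flags[ss, i] == "ok" & !is.na(pat[ss, i])]
      flip <- if (length(det)) mean(pat[det, i] == z[det]) < 0.5 else FALSE
      fill <- ss[flags[ss, i] == "ambiguous"]
      if (!length(fill)) next
      zz <- if (flip) 1L - z[fill] else z[fill]
      pat[fill, i] <- zz
      mat[fill, i] <- 1L - zz
      flags[fill, i] <- if (length(det)) "chain" else "arbitrary"
    }
  }

  # --- 3. duo Viterbi against a phased parent -----------------------------
  duo_viterbi <- function(side_hap, par_h1, par_h2, cm) {
    known <- which(!is.na(side_hap) & !is.na(par_h1) & !is.na(par_h2))
    if (length(known) < 2) return(NULL)
    e1 <- ifelse(par_h1[known] == side_hap[known], log(1 - err), log(err))
    e2 <- ifelse(par_h2[known] == side_hap[known], log(1 - err), log(err))
    r <- pmin(pmax(diff(cm[known]) / 100, 1e-6), 0.49)
    n <- length(known)
    v1 <- numeric(n); v2 <- numeric(n); bk1 <- integer(n); bk2 <- integer(n)
    v1[1] <- e1[1]; v2[1] <- e2[1]
    for (k in 2:n) {
      stay <- log(1 - r[k - 1]); sw <- log(r[k - 1])
      a11 <- v1[k - 1] + stay; a21 <- v2[k - 1] + sw
      a12 <- v1[k - 1] + sw;  a22 <- v2[k - 1] + stay
      bk1[k] <- if (a11 >= a21) 1L else 2L
      v1[k] <- max(a11, a21) + e1[k]
      bk2[k] <- if (a22 >= a12) 2L else 1L
      v2[k] <- max(a22, a12) + e2[k]
    }
    state <- integer(n)
    state[n] <- if (v1[n] >= v2[n]) 1L else 2L
    for (k in n:2) state[k - 1] <- if (state[k] == 1L) bk1[k] else bk2[k]
    # per-site copied state by nearest known site
    idx <- findInterval(seq_along(side_hap), known)
    idx[idx == 0] <- 1L
    state[idx]
  }
  for (i in seq_len(N)) {
    amb <- which(flags[, i] == "ambiguous")
    if (!length(amb)) next
    for (side in c("pat", "mat")) {
      p <- if (side == "pat") fi[i] else mi[i]
      if (is.na(p)) next
      par_ready <- !any(flags[, p] == "ambiguous")
      if (!par_ready) next
      sh <- if (side == "pat") pat[, i] else mat[, i]
      st <- duo_viterbi(sh, pat[, p], mat[, p], sites$cm)
      if (is.null(st)) next
      src <- ifelse(st == 1L, pat[, p], mat[, p])
      fill <- amb[!is.na(src[amb])]
      if (side == "pat") {
        pat[fill, i] <- src[fill]; mat[fill, i] <- 1L - src[fill]
      } else {
        mat[fill, i] <- src[fill]; pat[fill, i] <- 1L - src[fill]
      }
      flags[fill, i] <- "duo"
      amb <- which(flags[, i] == "ambiguous")
      if (!length(amb)) break
    }
  }

  # --- 4. sliding-window pool fallback ------------------------------------
  fill_missing <- function() {
    for (i in seq_len(N)) {
      miss <- is.na(d[, i])
      pat[miss, i] <<- major[miss]; mat[miss, i] <<- major[miss]
      flags[miss, i] <<- "filled"
    }
  }
  fill_missing()
  ord <- order(colSums(flags == "ambiguous"))
  for (pass in 1:2) {
    refs <- cbind(pat, mat)
    refs[is.na(refs)] <- -1L
    for (i in ord) {
      s_amb <- which(flags[, i] == "ambiguous")
      if (!length(s_amb) || N < 2L) next
      hits <- refs == pat[, i]
      hits[is.na(hits)] <- FALSE
      hits[s_amb, ] <- FALSE
      hits[, c(i, N + i)] <- FALSE
      C <- apply(hits, 2L, cumsum)
      lo <- pmax(s_amb - window, 1L); hi <- pmin(s_amb + window, S)
      W <- C[hi, , drop = FALSE] - C[lo, , drop = FALSE] +
        hits[lo, , drop = FALSE]
      best <- max.col(W, ties.method = "first")
      new_pat <- refs[cbind(s_amb, best)]
      new_pat[new_pat < 0L] <- 1L
      pat[s_amb, i] <- new_pat
      mat[s_amb, i] <- 1L - new_pat
      if (pass == 2L) flags[s_amb, i] <- "pool"
    }
  }

  haps <- matrix(0L, S, 2L * N)
  haps[, seq(1L, by = 2L, length.out = N)] <- pat
  haps[, seq(2L, by = 2L, length.out = N)] <- mat
  out <- hap_panel(sites, haps, rep(gm$samples, each = 2L),
                   map_length_cm = map_length_cm)
  attr(out, "phase_flags") <- flags
  out
}

#' Assemble a reference panel from phased haplotypes
#'
#' Restricts the phased cohort to individuals unrelated at the given degree
#' (default first degree, keeping as many haplotypes as possible while
#' removing the duplicated haplotypes close relatives carry).
#'
#' @param haps a phased [hap_panel()]
#' @param ped a [pedigree()]
#' @param degree relatedness degree to exclude (default 1)
#' @return a [hap_panel()]
#' @export
build_panel <- function(haps, ped, degree = 1) {
  ids <- select_unrelated(ped, max_degree = degree,
                          ids = intersect(panel_samples(haps), ped$df$id))
  subset_panel(haps, hap_idx = which(haps$hap_samples %in% ids))
}

#' Merge two haplotype panels by reciprocal imputation
#'
#' The merged site set is the union; sites private to one panel are filled
#' on the other panel's haplotypes with the posterior-mode allele from a
#' haploid Li-Stephens pass against the opposite panel (typed sites = the
#' shared site set). The merged haplotype count is the sum of the inputs'.
#'
#' @param a,b [hap_panel()] objects on the same chromosome/coordinates
#' @param params an [ls_params()]
#' @return a [hap_panel()]
#' @export
merge_panels <- function(a, b, params = ls_params()) {
  key_a <- paste(a$sites$chrom, a$sites$pos)
  key_b <- paste(b$sites$chrom, b$sites$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  if (any(a$sites$ref[ia] != b$sites$ref[ib] |
          a$sites$alt[ia] != b$sites$alt[ib]))
    stop("merge error: conflicting ref/alt at shared position(s)")
  only_a <- setdiff(key_a, key_b); only_b <- setdiff(key_b, key_a)
  union_sites <- rbind(a$sites,
                       b$sites[match(only_b, key_b), , drop = FALSE])
  union_sites <- union_sites[order(union_sites$pos), , drop = FALSE]
  key_u <- paste(union_sites$chrom, union_sites$pos)
  ua <- match(key_a, key_u); ub <- match(key_b, key_u)
  S <- nrow(union_sites)

  fill <- function(src, other, src_in_union, shared_keys) {
    # rows: union sites; known rows copied, missing rows imputed against
    # `other` (posterior-mode allele)
    H <- matrix(NA_integer_, S, ncol(src$haps))
    H[src_in_union, ] <- src$haps
    missing_rows <- which(is.na(H[, 1]))
    if (length(missing_rows)) {
      typed_in_other <- match(shared_keys, paste(other$sites$chrom,
                                                 other$sites$pos))
      out_rows <- match(paste(other$sites$chrom, other$sites$pos), key_u)
      for (j in seq_len(ncol(src$haps))) {
        target <- rep(NA_integer_, nrow(other$sites))
        target[typed_in_other] <-
          src$haps[match(shared_keys, paste(src$sites$chrom, src$sites$pos)), j]
        dose <- impute_haploid(target, other, params)
        H[out_rows, j] <- ifelse(is.na(H[out_rows, j]),
                                 as.integer(dose >= 0.5), H[out_rows, j])
      }
    }
    H
  }
  Ha <- fill(a, b, ua, shared)
  Hb <- fill(b, a, ub, shared)
  if (anyNA(Ha) || anyNA(Hb))
    stop("merge error: union sites unreachable from either panel")
  hap_panel(union_sites, cbind(Ha, Hb), c(a$hap_samples, b$hap_samples),
            map_length_cm = max(a$map_length_cm, b$map_length_cm))
}
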