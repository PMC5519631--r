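# ---- readers / writers -----------------------------------------------------
#
# Minimal VCF 4.2 dialect (single pseudo-chromosome studies, GT[:GQ:DP:AD]),
# PLINK 6-column PED, tab-delimited genetic map / manifest / score / segment
# tables. 1-based closed coordinates (VCF convention); cM intervals are
# half-open [start, end). The writers are byte-deterministic so fixture
# round trips and same-seed pipeline reruns compare equal.

fp_version <- function() as.character(utils::packageVersion("founderpanel"))

provenance_line <- function(seed = NULL, config_hash = NULL, prefix = "#") {
  paste0(prefix, " founderpanel ", fp_version(),
         if (!is.null(seed)) paste0(" seed=", seed),
         if (!is.null(config_hash)) paste0(" config=", config_hash))
}

#' Read a VCF file
#'
#' Parses header, fixed fields and raw call strings without interpreting
#' genotypes; use [normalize_and_restrict()] to obtain a [geno_matrix()].
#'
#' @param path VCF 4.x text file
#' @return A `raw_vcf` list (header, fixed, calls, samples).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty VCF file: ", path)
  hdr <- lines[startsWith(lines, "##")]
  cn_i <- which(startsWith(lines, "#CHROM"))
  if (length(cn_i) != 1L) stop("VCF missing #CHROM header line: ", path)
  cols <- strsplit(lines[cn_i], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns: ", path)
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(cn_i)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop("malformed VCF record at line ",
         cn_i + which(nf != length(cols))[1], " of ", path)
  m <- matrix(unlist(parts), nrow = length(parts), byrow = TRUE)
  fixed <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), id = m[, 3],
                      ref = m[, 4], alt = m[, 5], qual = m[, 6],
                      filter = m[, 7], info = m[, 8], format = m[, 9],
                      stringsAsFactors = FALSE)
  calls <- m[, -(1:9), drop = FALSE]
  colnames(calls) <- samples
  structure(list(header = hdr, fixed = fixed, calls = calls,
                 samples = samples), class = "raw_vcf")
}

# interpret GT[:GQ:DP:AD] call strings for biallelic records
parse_vcf_calls <- function(fixed, calls, samples) {
  S <- nrow(fixed); N <- length(samples)
  a1 <- matrix(NA_integer_, S, N); a2 <- matrix(NA_integer_, S, N)
  phased <- matrix(FALSE, S, N)
  gq <- matrix(NA_real_, S, N); dp <- matrix(NA_real_, S, N)
  ad_ref <- matrix(NA_real_, S, N); ad_alt <- matrix(NA_real_, S, N)
  if (S == 0L)
    return(geno_matrix(fixed[, c("chrom", "pos", "ref", "alt")], samples,
                       a1, a2, phased, gq, dp, ad_ref, ad_alt))
  fmt_fields <- strsplit(fixed$format, ":", fixed = TRUE)
  for (r in seq_len(S)) {
    ff <- fmt_fields[[r]]
    gt_i <- match("GT", ff)
    if (is.na(gt_i)) stop("format error: record ", r, " lacks GT")
    cs <- strsplit(calls[r, ], ":", fixed = TRUE)
    gt <- vapply(cs, `[`, character(1), gt_i)
    sep <- regexpr("[/|]", gt)
    one <- sep < 0L
    if (any(!one & grepl("[/|]", substr(gt, sep + 1L, nchar(gt)))))
      stop("ploidy != 2 on autosomal record ", r)
    if (any(one & gt != "."))
      stop("ploidy != 2 on autosomal record ", r)
    s1 <- ifelse(one, ".", substr(gt, 1L, sep - 1L))
    s2 <- ifelse(one, ".", substr(gt, sep + 1L, nchar(gt)))
    bad <- !(s1 %in% c(".", "0", "1")) | !(s2 %in% c(".", "0", "1"))
    if (any(bad)) stop("unexpected allele code in biallelic record ", r)
    a1[r, s1 != "."] <- as.integer(s1[s1 != "."])
    a2[r, s2 != "."] <- as.integer(s2[s2 != "."])
    phased[r, ] <- substr(gt, sep, sep) == "|"
    grab <- function(name) {
      i <- match(name, ff)
      if (is.na(i)) rep(NA_character_, N)
      else vapply(cs, function(x) if (length(x) >= i) x[i] else ".", character(1))
    }
    gq_s <- grab("GQ"); dp_s <- grab("DP"); ad_s <- grab("AD")
    gq[r, ] <- suppressWarnings(as.numeric(ifelse(gq_s == ".", NA, gq_s)))
    dp[r, ] <- suppressWarnings(as.numeric(ifelse(dp_s == ".", NA, dp_s)))
    has_ad <- !is.na(ad_s) & ad_s != "." & grepl(",", ad_s, fixed = TRUE)
    ad_ref[r, has_ad] <- as.numeric(sub(",.*", "", ad_s[has_ad]))
    ad_alt[r, has_ad] <- as.numeric(sub(".*,", "", ad_s[has_ad]))
  }
  geno_matrix(fixed[, c("chrom", "pos", "ref", "alt")], samples,
              a1, a2, phased, gq, dp, ad_ref, ad_alt)
}

fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                    scientific = FALSE))

#' Write genotypes, a haplotype panel or dosages as VCF
#'
#' `geno_matrix` objects are written with FORMAT `GT:GQ:DP:AD` (per-call
#' phase separators preserved); `hap_panel` objects with phased `GT`;
#' `dosage_matrix` objects with `GT:DS` (posterior-mean dosage).
#'
#' @param x object to write
#' @param path output path
#' @param provenance extra `##` header lines (e.g. seed/config provenance)
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, provenance = character(0)) {
  UseMethod("write_vcf")
}

vcf_header <- function(samples, format_lines, provenance) {
  c("##fileformat=VCFv4.2",
    provenance,
    format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_fixed_cols <- function(sites, format) {
  paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", ".", ".",
        format, sep = "\t")
}

#' @export
write_vcf.geno_matrix <- function(x, path, provenance = character(0)) {
  al <- function(a) ifelse(is.na(a), ".", as.character(a))
  sep <- ifelse(x$phased, "|", "/")
  gt <- matrix(paste0(al(x$a1), sep, al(x$a2)), nrow = nrow(x$sites))
  ad <- matrix(ifelse(is.na(x$ad_ref) | is.na(x$ad_alt), ".",
                      paste0(fmt_num(x$ad_ref), ",", fmt_num(x$ad_alt))),
               nrow = nrow(x$sites))
  call <- matrix(paste(gt, fmt_num(x$gq), fmt_num(x$dp), ad, sep = ":"),
                 nrow = nrow(x$sites))
  body <- paste(vcf_fixed_cols(x$sites, "GT:GQ:DP:AD"),
                apply(call, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(
    x$samples,
    c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"),
    provenance), body), path)
  invisible(path)
}

#' @export
write_vcf.hap_panel <- function(x, path, provenance = character(0)) {
  n <- ncol(x$haps) %/% 2L
  odd <- seq(1L, by = 2L, length.out = n)
  gt <- matrix(paste0(x$haps[, odd], "|", x$haps[, odd + 1L]),
               nrow = nrow(x$sites))
  body <- paste(vcf_fixed_cols(x$sites, "GT"),
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(
    x$hap_samples[odd],
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    provenance), body), path)
  invisible(path)
}

#' Read a phased haplotype panel from VCF
#'
#' All calls must be phased and complete; cM positions come from a genetic
#' map (file path or data.frame chrom/pos/cm) by linear interpolation.
#'
#' @param path phased VCF
#' @param map genetic map path or data.frame
#' @param map_length_cm optional total map length
#' @return a [hap_panel()]
#' @export
read_panel <- function(path, map, map_length_cm = NULL) {
  gm <- normalize_and_restrict(read_vcf(path))
  if (anyNA(gm$a1) || anyNA(gm$a2))
    stop("panel VCF contains missing alleles: ", path)
  if (!all(gm$phased)) stop("panel VCF contains unphased calls: ", path)
  if (is.character(map)) map <- read_map(map)
  sites <- gm$sites
  sites$cm <- map_interpolate(map, sites$pos)
  S <- nrow(sites); N <- length(gm$samples)
  haps <- matrix(0L, S, 2L * N)
  haps[, seq(1L, by = 2L, length.out = N)] <- gm$a1
  haps[, seq(2L, by = 2L, length.out = N)] <- gm$a2
  hap_panel(sites, haps, rep(gm$samples, each = 2L),
            map_length_cm = map_length_cm)
}

#' Read a PLINK 6-column pedigree file
#'
#' Columns FID IID PAT MAT SEX PHENO; parent code "0" becomes NA.
#'
#' @param path PED file
#' @return a [pedigree()]
#' @export
read_ped <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#",
                         col.names = c("fid", "id", "father", "mother",
                                       "sex", "pheno"))
  if (!nrow(d)) stop("empty pedigree file: ", path)
  d$father[d$father == "0"] <- NA
  d$mother[d$mother == "0"] <- NA
  pedigree(d[, c("id", "father", "mother", "sex", "fid")])
}

#' @rdname read_ped
#' @param ped a [pedigree()]
#' @param path output path
#' @export
write_ped <- function(ped, path) {
  d <- ped$df
  out <- data.frame(fid = d$fid, id = d$id,
                    father = ifelse(is.na(d$father), "0", d$father),
                    mother = ifelse(is.na(d$mother), "0", d$mother),
                    sex = d$sex, pheno = -9)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genetic map (chrom, pos, cM)
#' @param path tab-delimited file with a header line
#' @return data.frame(chrom, pos, cm)
#' @export
read_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  names(d) <- c("chrom", "pos", "cm")
  if (!nrow(d)) stop("empty map file: ", path)
  d$chrom <- as.character(d$chrom)
  d
}

#' @rdname read_map
#' @param map data.frame(chrom, pos, cm)
#' @export
write_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "pos", "cm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate cM positions from a genetic map
#'
#' Linear between listed anchors, flat extrapolation beyond the ends.
#'
#' @param map data.frame(chrom, pos, cm)
#' @param pos positions to interpolate
#' @return numeric cM positions
#' @export
map_interpolate <- function(map, pos) {
  if (nrow(map) == 1L) return(rep(map$cm, length(pos)))
  stats::approx(map$pos, map$cm, xout = pos, rule = 2, ties = "ordered")$y
}

#' Read / write an array-site manifest (chrom, pos)
#' @param path tab-delimited file with a header line
#' @return data.frame(chrom, pos)
#' @export
read_manifest <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  names(d) <- c("chrom", "pos")
  if (!nrow(d)) stop("empty manifest file: ", path)
  d$chrom <- as.character(d$chrom)
  d
}

#' @rdname read_manifest
#' @param manifest data.frame(chrom, pos)
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a deleteriousness score table (chrom, pos, score, status)
#' @param path tab-delimited file with a header line
#' @return data.frame(chrom, pos, score, status)
#' @export
read_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  d$chrom <- as.character(d$chrom)
  d
}

#' @rdname read_scores
#' @param scores data.frame(chrom, pos, score, status)
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# generic tab-table writer with provenance comment lines
write_table_prov <- function(d, path, provenance = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(provenance, con)
  utils::write.table(format(d, trim = TRUE, scientific = FALSE,
                            digits = 10), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
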