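#' Read a VCF and a population map into a genotype matrix
#'
#' Parses a VCF v4.2 (via vcfR) together with a Stacks-style two-column
#' tab-separated population map (sample, population; no header). Only
#' biallelic SNP records are accepted; multi-allelic records raise an error
#' naming the offending record. `./.` genotypes become missing calls. If the
#' VCF carries a `DP` FORMAT field, per-cell depths are attached.
#'
#' @param vcf_path Path to an uncompressed VCF.
#' @param popmap_path Path to the population map TSV.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  popmap <- read_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | !grepl("^[ACGT]$", fix$ALT) | !grepl("^[ACGT]$", fix$REF)
  if (any(multi)) {
    bad <- which(multi)[1]
    stop(sprintf(
      "non-biallelic-SNP record at %s:%s (REF=%s, ALT=%s)",
      fix$CHROM[bad], fix$POS[bad], fix$REF[bad], fix$ALT[bad]
    ), call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)
  missing_in_map <- setdiff(vcf_samples, names(popmap))
  if (length(missing_in_map) > 0)
    stop("sample(s) missing from popmap: ", paste(missing_in_map, collapse = ", "),
         call. = FALSE)
  clean <- gsub("|", "/", gt, fixed = TRUE)
  if (any(!is.na(clean) & clean %in% c("0", "1")))
    stop("haploid genotype call found; all samples must be diploid", call. = FALSE)
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- lut[clean]                    # anything else (./., ./1, NA) -> NA
  dim(calls) <- dim(gt)                  # loci x samples
  calls <- t(calls)                      # samples x loci
  rownames(calls) <- vcf_samples
  depth <- NULL
  fmt <- unique(unlist(strsplit(as.character(v@gt[, "FORMAT"]), ":")))
  if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }
  loci <- tibble::tibble(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  ord <- order(loci$chrom, loci$pos)
  genotype_matrix(
    calls = calls[, ord, drop = FALSE],
    samples = tibble::tibble(sample_id = vcf_samples, pop = unname(popmap[vcf_samples])),
    loci = loci[ord, ],
    depth = if (is.null(depth)) NULL else depth[, ord, drop = FALSE]
  )
}

#' Read a Stacks-style population map
#'
#' @param path Two-column tab-separated file (sample id, population id), no
#'   header.
#' @return Named character vector mapping sample id to population id.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("popmap not found: ", path, call. = FALSE)
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("sample", "pop"))
  if (any(!nzchar(pm$pop))) stop("popmap has empty population ids", call. = FALSE)
  if (anyDuplicated(pm$sample)) stop("popmap has duplicated sample ids", call. = FALSE)
  stats::setNames(pm$pop, pm$sample)
}

#' Write a genotype matrix as VCF + population map
#'
#' Emits an uncompressed VCF v4.2 (GT and, when depths are present, DP fields)
#' plus the matching two-column popmap, such that
#' `read_genotypes(write_genotypes(g))` round-trips calls, coordinates and
#' labels exactly. Missing calls are written as `./.`.
#'
#' @param g A [genotype_matrix()].
#' @param vcf_path,popmap_path Output paths.
#' @return Invisibly, the VCF path.
#' @export
write_genotypes <- function(g, vcf_path, popmap_path) {
  validate_genotype_matrix(g)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$calls + 1L],
                   nrow = nrow(g$calls))
  gt_str[is.na(g$calls)] <- "./."
  has_dp <- !is.null(g$depth)
  if (has_dp) {
    dp <- g$depth
    dp[is.na(dp)] <- 0L
    gt_str <- matrix(paste(gt_str, dp, sep = ":"), nrow = nrow(gt_str))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fireantdemog",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g$calls)), function(j) {
    paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$locus_id[j], g$loci$ref[j],
            g$loci$alt[j], ".", "PASS", ".",
            if (has_dp) "GT:DP" else "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  utils::write.table(
    data.frame(g$samples$sample_id, g$samples$pop),
    popmap_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(vcf_path)
}
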