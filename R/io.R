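#' Write / read the phenotype table
#'
#' Native exchange format: tab-separated, UTF-8, headered. Columns `cow`,
#' `herd`, `parity`, `season` (or `date`, mapped to season by the
#' recording-year calendar rule), `dim`, optional `fat_pct`/`protein_pct`,
#' then one `wvn_<cm-1>` column per wavenumber.
#'
#' @param dataset A `spectra_dataset`.
#' @param path Output file.
#' @return `write_phenotypes`: the path, invisibly.
#' @export
write_phenotypes <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  tr <- as.data.frame(dataset$transmittance)
  names(tr) <- paste0("wvn_", format_wvn(dataset$grid))
  data.table::fwrite(cbind(dataset$records, tr), path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes`: a validated `spectra_dataset`. Rows failing
#'   validation (dim outside 1..400, non-numeric transmittance, bad parity
#'   or season) are rejected with a collected per-row report, attached as
#'   attribute `"rejected"` and logged.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("cow", "herd", "parity", "dim")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"season" %in% names(dt)) {
    if (!"date" %in% names(dt)) stop("missing required column: season or date")
    dt$season <- season_from_date(dt$date)
  }
  wcols <- grep("^wvn_", names(dt), value = TRUE)
  if (!length(wcols)) stop("no wavenumber (wvn_*) columns found")
  grid <- as.numeric(sub("^wvn_", "", wcols))
  ord <- order(grid)
  grid <- grid[ord]; wcols <- wcols[ord]

  Y <- suppressWarnings(
    vapply(dt[wcols], function(x) as.numeric(as.character(x)),
           numeric(nrow(dt))))
  if (nrow(dt) == 1) Y <- matrix(Y, nrow = 1)
  bad_dim <- !is.finite(dt$dim) | dt$dim < 1 | dt$dim > 400
  bad_tr <- rowSums(!is.finite(Y)) > 0
  bad_par <- !dt$parity %in% c(1, 2)
  bad_sea <- !dt$season %in% c("summer", "winter")
  bad <- bad_dim | bad_tr | bad_par | bad_sea
  if (any(bad)) {
    why <- paste0("row ", which(bad), ": ",
                  ifelse(bad_dim[bad], "dim outside [1,400]; ", ""),
                  ifelse(bad_tr[bad], "non-numeric transmittance; ", ""),
                  ifelse(bad_par[bad], "parity not 1/2; ", ""),
                  ifelse(bad_sea[bad], "season not summer/winter; ", ""))
    message(sum(bad), " row(s) rejected:\n", paste(why, collapse = "\n"))
  }
  keep <- !bad
  rec <- dt[keep, setdiff(names(dt), wcols), drop = FALSE]
  out <- spectra_dataset(rec, Y[keep, , drop = FALSE], grid)
  attr(out, "rejected") <- dt[bad, , drop = FALSE]
  out
}

#' Write / read genotypes as dosage matrix plus SNP map
#'
#' Matrix file: tab-separated with a `cow` id column then one 0/1/2/NA
#' column per SNP. Map file: `snp_id`, `chrom`, `bp`.
#'
#' @param genotypes A `genotype_data` object.
#' @param matrix_path,map_path Output / input files.
#' @export
write_genotypes <- function(genotypes, matrix_path, map_path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  d <- as.data.frame(genotypes$dosages)
  data.table::fwrite(cbind(cow = genotypes$cow_ids, d), matrix_path,
                     sep = "\t")
  data.table::fwrite(genotypes$map, map_path, sep = "\t")
  invisible(matrix_path)
}

#' @rdname write_genotypes
#' @param max_missing Drop SNPs with missing-genotype rate strictly above
#'   this (default 0.40).
#' @param min_maf Drop SNPs with minor allele frequency strictly below this
#'   (default 0.01).
#' @param autosomes Optional vector of chromosome labels to keep (e.g.
#'   `1:29` for cattle); `NULL` keeps chromosomes that parse as numbers.
#' @param phenotype_cows Optional cow ids that must all be present; a
#'   mismatch is an error listing the offenders.
#' @return `read_genotypes`: a QC'd `genotype_data`; dropped-SNP counts are
#'   logged.
#' @export
read_genotypes <- function(matrix_path, map_path, max_missing = 0.40,
                           min_maf = 0.01, autosomes = NULL,
                           phenotype_cows = NULL) {
  d <- data.table::fread(matrix_path, sep = "\t", data.table = FALSE)
  stopifnot("cow" %in% names(d))
  cow_ids <- as.character(d$cow)
  dos <- as.matrix(d[setdiff(names(d), "cow")])
  map <- data.table::fread(map_path, sep = "\t", data.table = FALSE)
  g <- genotype_data(dos, map, cow_ids)
  if (!is.null(phenotype_cows)) {
    missing_cows <- setdiff(phenotype_cows, g$cow_ids)
    if (length(missing_cows)) {
      stop("cow id mismatch with phenotypes: ",
           paste(utils::head(missing_cows, 10), collapse = ", "))
    }
  }
  apply_genotype_qc(g, max_missing, min_maf, autosomes)
}

#' Genotype quality control
#'
#' Drops SNPs with more than `max_missing` missing genotypes or MAF below
#' `min_maf`, keeps autosomes only, and logs the dropped counts. Never
#' mutates its input.
#'
#' @inheritParams read_genotypes
#' @param genotypes A `genotype_data` object.
#' @return A filtered `genotype_data`.
#' @export
apply_genotype_qc <- function(genotypes, max_missing = 0.40, min_maf = 0.01,
                              autosomes = NULL) {
  chrom <- genotypes$map$chrom
  on_auto <- if (is.null(autosomes)) {
    !is.na(suppressWarnings(as.numeric(as.character(chrom))))
  } else chrom %in% autosomes
  mr <- snp_missing_rate(genotypes)
  maf <- snp_maf(genotypes)
  drop <- !on_auto | mr > max_missing | maf < min_maf
  message("genotype QC: ", sum(!on_auto), " non-autosomal, ",
          sum(mr > max_missing), " high-missing, ",
          sum(maf < min_maf, na.rm = TRUE), " low-MAF; ",
          sum(drop), " SNP(s) dropped, ", sum(!drop), " kept")
  genotype_data(genotypes$dosages[, !drop, drop = FALSE],
                genotypes$map[!drop, , drop = FALSE],
                genotypes$cow_ids)
}

#' Import genotypes from a VCF file
#'
#' Convenience path; the native exchange format is the dosage matrix plus
#' map. GT fields are converted to alternate-allele dosages (`./.` to
#' missing), then the standard QC is applied. Requires the
#' `VariantAnnotation` package.
#'
#' @param vcf_path Path to a VCF file.
#' @inheritParams read_genotypes
#' @return A QC'd `genotype_data`.
#' @export
read_genotypes_vcf <- function(vcf_path, max_missing = 0.40, min_maf = 0.01,
                               autosomes = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF import requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT  # variants x samples
  dose <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(x %in% c("./.", ".", ""), NA_real_,
           vapply(strsplit(x, "/"),
                  function(al) sum(al != "0" & al != "."), numeric(1)))
  }
  dos <- t(apply(gt, 1, dose))  # variants x samples, then transpose below
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(snp_id = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    bp = GenomicRanges::start(rr))
  map$chrom <- suppressWarnings(as.numeric(map$chrom))
  keep <- !is.na(map$chrom)
  g <- genotype_data(t(dos[keep, , drop = FALSE]),
                     map[keep, , drop = FALSE],
                     colnames(gt))
  apply_genotype_qc(g, max_missing, min_maf, autosomes)
}

#' Write the simulation truth sidecar
#'
#' @param truth A `truth_record`.
#' @param path Output TSV (SNP effects, variance components, true
#'   heritability and planted QTL rows in long "key-value" form).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  rows <- data.frame(key = c(paste0("snp_effect_", seq_along(truth$snp_effects)),
                             names(truth$variance_components), "h2"),
                     value = c(truth$snp_effects,
                               unname(truth$variance_components), truth$h2))
  if (!is.null(truth$planted_qtl) && nrow(truth$planted_qtl)) {
    rows <- rbind(rows, data.frame(
      key = paste0("planted_qtl_", truth$planted_qtl$chrom, "_",
                   truth$planted_qtl$snp_id),
      value = truth$planted_qtl$bp_start))
  }
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
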