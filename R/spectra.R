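#' Repeated-record spectral phenotype container
#'
#' Holds milk-recording records (cow, herd, parity, season, days in milk,
#' optional fat/protein percentages) together with the transmittance matrix
#' aligned to a strictly monotone wavenumber grid.
#'
#' @param records Data frame with at least `cow`, `herd`, `parity` (1 or 2),
#'   `season` ("summer"/"winter"), `dim` (days in milk, 1..400). Optional
#'   `fat_pct`, `protein_pct`, `date`.
#' @param transmittance Numeric matrix, one row per record, one column per
#'   grid wavenumber.
#' @param grid Strictly increasing wavenumbers in cm^-1.
#' @return Object of class `"spectra_dataset"`.
#' @export
spectra_dataset <- function(records, transmittance, grid) {
  records <- as.data.frame(records)
  transmittance <- as.matrix(transmittance)
  need <- c("cow", "herd", "parity", "season", "dim")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(records) != nrow(transmittance)) {
    stop("records and transmittance row counts differ")
  }
  if (ncol(transmittance) != length(grid)) {
    stop("transmittance columns must match grid length")
  }
  if (length(grid) && is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  if (any(records$dim < 1 | records$dim > 400)) {
    stop("dim must lie in [1, 400]")
  }
  if (!all(records$parity %in% c(1L, 2L))) stop("parity must be 1 or 2")
  if (!all(records$season %in% c("summer", "winter"))) {
    stop('season must be "summer" or "winter"')
  }
  structure(list(records = records, transmittance = transmittance,
                 grid = as.numeric(grid)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("spectra_dataset:", nrow(x$records), "records on",
      length(unique(x$records$cow)), "cows,", length(x$grid),
      "wavenumbers (", min(x$grid), "-", max(x$grid), "cm^-1 )\n")
  invisible(x)
}

#' Exclude water-interacting wavenumber regions
#'
#' Infrared regions that interact with water molecules are removed before
#' analysis: everything strictly above 3008 cm^-1 (the upper water region;
#' 3008 itself is retained) and the closed band \[1623, 1669\] cm^-1. On
#' the instrument's uniform 1060-point grid spanning 925-5008 cm^-1 this
#' leaves exactly 530 wavenumbers.
#'
#' @param grid Numeric vector of wavenumbers (strictly monotone).
#' @param upper_bound Retain wavenumbers `<= upper_bound` (default 3008).
#' @param water_band Closed interval excluded in full (default
#'   `c(1623, 1669)`).
#' @return Integer indices into `grid` of retained wavenumbers, in original
#'   order. Idempotent: re-filtering the retained values keeps all of them.
#' @export
filter_water_regions <- function(grid, upper_bound = 3008,
                                 water_band = c(1623, 1669)) {
  if (!length(grid)) return(integer(0))
  keep <- grid <= upper_bound & !(grid >= water_band[1] & grid <= water_band[2])
  which(keep)
}

#' Record-level quality-control rules
#'
#' @param max_fat Drop records with fat percentage strictly above this.
#' @param min_protein,max_protein Drop records with protein percentage
#'   strictly below / above these.
#' @return Object of class `"qc_rules"`. `NA` disables a bound. Presets:
#'   `qc_rules_holstein()` (fat% > 8.0, protein% < 2.5 or > 5.0) and
#'   `qc_rules_jersey()` (protein% > 5.5).
#' @export
qc_rules <- function(max_fat = NA, min_protein = NA, max_protein = NA) {
  structure(list(max_fat = max_fat, min_protein = min_protein,
                 max_protein = max_protein), class = "qc_rules")
}

#' @rdname qc_rules
#' @export
qc_rules_holstein <- function() qc_rules(max_fat = 8.0, min_protein = 2.5,
                                         max_protein = 5.0)

#' @rdname qc_rules
#' @export
qc_rules_jersey <- function() qc_rules(max_protein = 5.5)

#' Drop outlying milk records
#'
#' Applies the configured fat/protein bounds; a record violating any bound
#' is removed. Comparisons are strict, matching the printed thresholds
#' (fat% > 8.0, protein% < 2.5, protein% > 5.0/5.5).
#'
#' @param dataset A `spectra_dataset`.
#' @param rules A [qc_rules()] object.
#' @return The filtered dataset, with attribute `"removed"` holding the
#'   removed record rows (a removal log).
#' @export
apply_record_qc <- function(dataset, rules) {
  stopifnot(inherits(dataset, "spectra_dataset"), inherits(rules, "qc_rules"))
  rec <- dataset$records
  uses_fat <- !is.na(rules$max_fat)
  uses_prot <- !is.na(rules$min_protein) || !is.na(rules$max_protein)
  if (uses_fat && is.null(rec$fat_pct)) {
    stop("configuration error: QC rule references missing field 'fat_pct'")
  }
  if (uses_prot && is.null(rec$protein_pct)) {
    stop("configuration error: QC rule references missing field 'protein_pct'")
  }
  bad <- rep(FALSE, nrow(rec))
  if (uses_fat) bad <- bad | rec$fat_pct > rules$max_fat
  if (!is.na(rules$min_protein)) bad <- bad | rec$protein_pct < rules$min_protein
  if (!is.na(rules$max_protein)) bad <- bad | rec$protein_pct > rules$max_protein
  bad[is.na(bad)] <- FALSE
  out <- spectra_dataset(rec[!bad, , drop = FALSE],
                         dataset$transmittance[!bad, , drop = FALSE],
                         dataset$grid)
  attr(out, "removed") <- rec[bad, , drop = FALSE]
  out
}

# Model matrix of the correction covariates: parity and season as categorical
# terms, the two Wilmink days-in-milk terms, herd as a fixed categorical term.
# Single-level factors are dropped (intercept absorbs them).
.correction_matrix <- function(records) {
  DIM <- records$dim / 365
  terms <- list(DIM = DIM, wilmink = exp(-0.05 * DIM))
  for (v in c("parity", "season", "herd")) {
    f <- factor(records[[v]])
    if (nlevels(f) > 1) {
      if (any(table(f) < 1)) stop("covariate level with no records: ", v)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1])
      terms[[v]] <- mm
    }
  }
  cbind(`(Intercept)` = 1, do.call(cbind, terms))
}

#' Covariate-corrected correlation matrix of wavenumbers
#'
#' For every retained wavenumber, transmittance is corrected for season,
#' parity, days in milk (the two Wilmink terms) and herd by ordinary least
#' squares, and the Pearson correlation matrix of the residuals is
#' returned. This is the matrix whose heatmap exhibits the blocks of
#' strongly correlated neighbouring wavenumbers.
#'
#' @param dataset A `spectra_dataset`.
#' @param retained Integer indices into the grid (e.g. from
#'   [filter_water_regions()]); defaults to the full grid.
#' @return Symmetric correlation matrix with unit diagonal, dimnames the
#'   retained wavenumbers, and attribute `"retained"` (the indices).
#' @export
residualized_correlation <- function(dataset,
                                     retained = seq_along(dataset$grid)) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (nrow(dataset$records) < 3) stop("need at least 3 records")
  if (length(retained) < 2) stop("need at least 2 retained wavenumbers")
  X <- .correction_matrix(dataset$records)
  Y <- dataset$transmittance[, retained, drop = FALSE]
  qrX <- qr(X)
  R <- qr.resid(qrX, Y)
  C <- stats::cor(R)
  dimnames(C) <- list(format_wvn(dataset$grid[retained]),
                      format_wvn(dataset$grid[retained]))
  attr(C, "retained") <- retained
  C
}

#' Detect contiguous blocks of strongly correlated wavenumbers
#'
#' Deterministic stand-in for visual heatmap inspection: scanning the
#' retained grid left to right, a block grows while *every* pairwise
#' correlation within the extended block exceeds the threshold; otherwise
#' the block is closed and a new one starts at the current wavenumber.
#' Singleton blocks are allowed.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @param threshold Pairwise correlation that must be exceeded (strict),
#'   default 0.95.
#' @return Data frame with one row per block: `block`, `start`, `end`
#'   (inclusive indices into the matrix), `n`.
#' @export
detect_blocks <- function(corr, threshold = 0.95) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      !isTRUE(all.equal(corr, t(corr), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("correlation matrix must be symmetric")
  }
  n <- nrow(corr)
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  for (j in seq_len(n)[-1]) {
    # extend current block [s, j-1] with j only if j correlates > threshold
    # with every current member
    if (all(corr[s:(j - 1L), j] > threshold)) next
    starts <- c(starts, s); ends <- c(ends, j - 1L)
    s <- j
  }
  starts <- c(starts, s); ends <- c(ends, n)
  data.frame(block = seq_along(starts), start = starts, end = ends,
             n = ends - starts + 1L)
}

#' Pick each block's representative wavenumber by correlation sum
#'
#' Within a block, every member's correlations to all block members
#' (diagonal included) are summed; the member with the highest sum is the
#' representative. Exact ties go to the lower index and are flagged.
#'
#' @param block One row of the [detect_blocks()] output (or any list with
#'   `start` and `end`).
#' @param corr The correlation matrix the blocks were detected on.
#' @return List: `index` (into the matrix), `corr_sum`, `tie` (logical).
#' @export
select_representative <- function(block, corr) {
  idx <- block$start:block$end
  sums <- rowSums(corr[idx, idx, drop = FALSE])
  best <- which.max(sums)  # which.max returns the first (lowest) maximiser
  tie <- sum(abs(sums - sums[best]) < 1e-12) > 1L
  list(index = idx[best], corr_sum = unname(sums[best]), tie = tie)
}

#' Run the full wavenumber-selection stage
#'
#' Chains water-region exclusion, optional record QC, residualised
#' correlation, block detection and representative selection.
#'
#' @param dataset A `spectra_dataset`.
#' @param rules Optional [qc_rules()]; `NULL` skips record QC.
#' @param threshold Block correlation threshold (default 0.95).
#' @return List with `retained` (grid indices), `corr`, `blocks`, and
#'   `selection`: a data frame (block, wavenumber, grid index, correlation
#'   sum, tie flag) with one row per block.
#' @export
select_wavenumbers <- function(dataset, rules = NULL, threshold = 0.95) {
  if (!is.null(rules)) dataset <- apply_record_qc(dataset, rules)
  retained <- filter_water_regions(dataset$grid)
  corr <- residualized_correlation(dataset, retained)
  blocks <- detect_blocks(corr, threshold)
  sel <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    r <- select_representative(blocks[i, ], corr)
    data.frame(block = blocks$block[i],
               wavenumber = dataset$grid[retained[r$index]],
               grid_index = retained[r$index],
               corr_sum = r$corr_sum, tie = r$tie)
  }))
  list(retained = retained, corr = corr, blocks = blocks, selection = sel)
}
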