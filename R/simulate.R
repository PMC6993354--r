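#' Simulation configuration for the synthetic herd
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()] and [simulate_spectra()]. The defaults describe a
#' desk-scale version of a national milk-recording study: a few hundred cows
#' spread over herds, one to twelve morning-milk records per cow collected
#' over a single recording year, two parities, two seasons, days in milk
#' (DIM) between 1 and 400, and transmittance phenotypes on a small
#' wavenumber grid organised in strongly correlated blocks.
#'
#' The default variance components `(sigma2_A, sigma2_Herd, sigma2_PE,
#' sigma2_E) = (0.3, 0.1, 0.2, 0.4)` give a true heritability of
#' `0.3 / (0.3 + 0.1 + 0.2 + 0.4) = 0.30`, a typical value for a heritable
#' mid-infrared wavenumber.
#'
#' @param n_cows Number of cows (>= 2).
#' @param n_herds Number of herds cows are assigned to (uniformly).
#' @param records_per_cow_range Integer range `c(min, max)` within `[1, 20]`;
#'   each cow's record count is drawn uniformly from it.
#' @param n_chromosomes,snps_per_chromosome Genome layout; SNP positions are
#'   strictly increasing within chromosome with ~40 kb median spacing.
#' @param maf_range Allele-frequency range `(low, high]` within `(0, 0.5]`
#'   from which per-SNP frequencies are drawn uniformly.
#' @param planted_qtl List of `list(chrom =, snp =, fraction =)` entries; each
#'   plants a causal SNP (1-based index within its chromosome) carrying the
#'   given fraction of the additive genetic variance. Fractions must lie in
#'   (0, 1] and sum to at most 1.
#' @param variance_components Named numeric: `sigma2_A`, `sigma2_Herd`,
#'   `sigma2_PE`, `sigma2_E`, all >= 0, in squared transmittance units.
#' @param fixed_effects Named numeric: `mu`, `parity2`, `season_summer`,
#'   `wilmink_beta1`, `wilmink_beta2`. The Wilmink terms use `DIM = dim/365`
#'   and `exp(-0.05 * DIM)` exactly as in the fitted model.
#' @param wavenumber_grid Strictly increasing wavenumbers in cm^-1.
#' @param wavenumber_blocks List of `c(lo, hi, rho)`: wavenumbers in
#'   `[lo, hi]` share a common noise component so that their pairwise
#'   phenotypic correlation exceeds `rho`.
#' @param missing_rate Genotype missingness rate in `[0, 0.5]`.
#' @param prob_parity2 Probability a cow is in second parity (most cows in
#'   such studies are first-parity).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cows = 500,
                       n_herds = 20,
                       records_per_cow_range = c(1L, 12L),
                       n_chromosomes = 5,
                       snps_per_chromosome = 200,
                       maf_range = c(0.05, 0.5),
                       planted_qtl = list(),
                       variance_components = c(sigma2_A = 0.3,
                                               sigma2_Herd = 0.1,
                                               sigma2_PE = 0.2,
                                               sigma2_E = 0.4),
                       fixed_effects = c(mu = 85, parity2 = 0.5,
                                         season_summer = -0.3,
                                         wilmink_beta1 = 1.0,
                                         wilmink_beta2 = 0.5),
                       wavenumber_grid = NULL,
                       wavenumber_blocks = NULL,
                       missing_rate = 0,
                       prob_parity2 = 0.09,
                       seed = 1L) {
  if (is.null(wavenumber_grid)) {
    wavenumber_grid <- c(975,
                         seq(1050, 1120, length.out = 5),
                         1500,
                         seq(1690, 1740, length.out = 5),
                         1966,
                         seq(2870, 2980, length.out = 5))
  }
  if (is.null(wavenumber_blocks)) {
    wavenumber_blocks <- list(c(1050, 1120, 0.98),
                              c(1690, 1740, 0.98),
                              c(2870, 2980, 0.98))
  }
  vc <- variance_components
  need_vc <- c("sigma2_A", "sigma2_Herd", "sigma2_PE", "sigma2_E")
  if (!all(need_vc %in% names(vc))) {
    stop("variance_components must name ", paste(need_vc, collapse = ", "))
  }
  if (any(vc < 0)) stop("variance components must be >= 0")
  need_fe <- c("mu", "parity2", "season_summer", "wilmink_beta1", "wilmink_beta2")
  if (!all(need_fe %in% names(fixed_effects))) {
    stop("fixed_effects must name ", paste(need_fe, collapse = ", "))
  }
  if (n_cows < 2 || snps_per_chromosome < 2) {
    stop("invalid config: n_cows and snps_per_chromosome must be >= 2")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  rr <- as.integer(records_per_cow_range)
  if (length(rr) != 2 || rr[1] < 1 || rr[2] > 20 || rr[1] > rr[2]) {
    stop("records_per_cow_range must be within [1, 20]")
  }
  fr <- vapply(planted_qtl, function(q) q$fraction, numeric(1))
  if (length(fr) && (any(fr <= 0) || any(fr > 1) || sum(fr) > 1)) {
    stop("invalid config: planted fractions must be in (0, 1] and sum <= 1")
  }
  if (is.unsorted(wavenumber_grid, strictly = TRUE)) {
    stop("wavenumber_grid must be strictly increasing")
  }
  if (missing_rate < 0 || missing_rate > 0.5) stop("missing_rate must be in [0, 0.5]")
  structure(list(n_cows = as.integer(n_cows),
                 n_herds = as.integer(n_herds),
                 records_per_cow_range = rr,
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 maf_range = maf_range,
                 planted_qtl = planted_qtl,
                 variance_components = vc[need_vc],
                 fixed_effects = fixed_effects[need_fe],
                 wavenumber_grid = wavenumber_grid,
                 wavenumber_blocks = wavenumber_blocks,
                 missing_rate = missing_rate,
                 prob_parity2 = prob_parity2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Genotype container: dosage matrix plus SNP map
#'
#' @param dosages Numeric matrix, cows x SNPs, values 0/1/2 or `NA`.
#' @param map Data frame with columns `snp_id`, `chrom`, `bp`, sorted by
#'   `(chrom, bp)` with strictly increasing `bp` per chromosome.
#' @param cow_ids Character vector of row identifiers.
#' @return Object of class `"genotype_data"`.
#' @export
genotype_data <- function(dosages, map, cow_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(cow_ids)) cow_ids <- paste0("cow", seq_len(nrow(dosages)))
  stopifnot(ncol(dosages) == nrow(map),
            all(c("snp_id", "chrom", "bp") %in% names(map)))
  ord <- order(map$chrom, map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
  }
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE)) {
      stop("bp must be strictly increasing within chromosome ", ch)
    }
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0/1/2 or NA")
  rownames(dosages) <- cow_ids
  colnames(dosages) <- map$snp_id
  structure(list(dosages = dosages, map = as.data.frame(map),
                 cow_ids = as.character(cow_ids)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", nrow(x$dosages), "cows x", ncol(x$dosages), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Per-SNP minor allele frequency
#'
#' @param genotypes A `genotype_data` object.
#' @return Numeric vector of MAF per SNP, missing dosages excluded.
#' @export
snp_maf <- function(genotypes) {
  p <- colMeans(genotypes$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-SNP missing-genotype rate
#' @param genotypes A `genotype_data` object.
#' @export
snp_missing_rate <- function(genotypes) {
  colMeans(is.na(genotypes$dosages))
}

#' Simulate biallelic SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Draws per-SNP allele frequencies uniformly from `config$maf_range` and
#' samples dosages 0/1/2 as Binomial(2, p), independently across SNPs
#' (linkage equilibrium). SNPs whose realised minor allele frequency falls
#' below 0.01 (including monomorphic SNPs) are resampled so downstream MAF
#' QC never drops simulated loci. Base-pair positions are strictly
#' increasing within chromosome.
#'
#' @param config A [sim_config()] object.
#' @return A [genotype_data()] object.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cows
  p_chr <- config$snps_per_chromosome
  p <- config$n_chromosomes * p_chr
  freq <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), nrow = n)
  # resample SNPs whose realised MAF drops below the 0.01 QC floor
  for (tries in 1:50) {
    pm <- colMeans(dos) / 2
    bad <- which(pmin(pm, 1 - pm) < 0.01)
    if (!length(bad)) break
    dos[, bad] <- stats::rbinom(n * length(bad), 2L, rep(freq[bad], each = n))
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < config$missing_rate, nrow = n)
    dos[miss] <- NA_real_
  }
  chrom <- rep(seq_len(config$n_chromosomes), each = p_chr)
  bp <- unlist(lapply(seq_len(config$n_chromosomes), function(ch) {
    cumsum(sample(20000:60000, p_chr, replace = TRUE))
  }), use.names = FALSE)
  map <- data.frame(snp_id = paste0("snp", chrom, "_", sequence(rep(p_chr, config$n_chromosomes))),
                    chrom = chrom, bp = bp)
  genotype_data(dos, map, cow_ids = sprintf("cow%04d", seq_len(n)))
}

#' Mean-impute missing dosages and centre columns
#'
#' Missing dosages are replaced by the per-SNP mean before columnwise
#' centring, keeping the design dense as the SNP-effect model requires.
#'
#' @param genotypes A `genotype_data` object.
#' @return Numeric matrix with column means 0 (to within 1e-8).
#' @export
center_dosages <- function(genotypes) {
  G <- genotypes$dosages
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  scale(G, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

# True SNP effect sizes: planted QTL sized to their variance fractions on the
# realised (centred) dosage variance; background effects i.i.d. normal scaled
# so the expected total additive variance equals sigma2_A.
.true_snp_effects <- function(config, Gc, map) {
  p <- ncol(Gc)
  a <- numeric(p)
  s2A <- config$variance_components[["sigma2_A"]]
  if (s2A == 0) return(a)
  vg <- apply(Gc, 2, stats::var)
  vg[vg == 0] <- NA_real_
  planted <- integer(0)
  for (q in config$planted_qtl) {
    j <- which(map$chrom == q$chrom)[q$snp]
    if (is.na(j) || length(j) != 1) stop("planted QTL index out of range")
    if (is.na(vg[j])) stop("planted QTL SNP is monomorphic")
    a[j] <- sample(c(-1, 1), 1) * sqrt(q$fraction * s2A / vg[j])
    planted <- c(planted, j)
  }
  frac_bg <- 1 - sum(vapply(config$planted_qtl, `[[`, numeric(1), "fraction"))
  bg <- setdiff(which(!is.na(vg)), planted)
  if (frac_bg > 0 && length(bg)) {
    tau <- sqrt(frac_bg * s2A / sum(vg[bg]))
    a[bg] <- stats::rnorm(length(bg), 0, tau)
    # rescale so the background carries its share exactly (up to sampling LD),
    # keeping planted variance fractions sharp
    a[bg] <- a[bg] * sqrt(frac_bg * s2A / sum(a[bg]^2 * vg[bg]))
  }
  a
}

#' Simulate repeated-record milk spectra with known genetic truth
#'
#' Phenotypes follow the repeatability model: for record `r` of cow `l`,
#' `y = mu + parity + season + b1*DIM + b2*exp(-0.05*DIM) + herd + CowA +
#' CowPE + E`, where `CowA = sum_m g_lm a_m` over centred dosages, planted
#' QTL carry their configured fractions of `sigma2_A`, and the remaining
#' additive variance is spread over background SNPs with i.i.d. normal
#' effects. Records are assigned a collection date uniform over a
#' one-year recording window (2015-10-01 to 2016-09-30); season is
#' "summer" from 2016-04-01 onwards, "winter" before. DIM is uniform on
#' 1..400. All wavenumbers share the systematic part; wavenumbers inside a
#' configured block additionally share a common noise component with weight
#' `sqrt(rho)` so their pairwise correlation exceeds `rho`.
#'
#' Fat and protein percentages are simulated (normal around 4.2 and 3.5) so
#' record-level QC can be exercised; they carry no genetic signal.
#'
#' @param config A [sim_config()] object.
#' @param genotypes Output of [simulate_genotypes()] for the same config.
#' @return List with `spectra` (a [spectra_dataset()]) and `truth` (class
#'   `"truth_record"`): per-SNP true effects, true variance components, true
#'   heritability, planted QTL positions, and the realised random components
#'   (cow genetic values, herd effects, permanent-environment effects, and
#'   the first wavenumber's residuals) for method-of-moments checking.
#' @export
simulate_spectra <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_data"))
  fr <- vapply(config$planted_qtl, `[[`, numeric(1), "fraction")
  if (length(fr) && sum(fr) > 1) stop("invalid config: planted fractions sum > 1")
  set.seed(config$seed + 1L)
  n <- config$n_cows
  vc <- config$variance_components
  fe <- config$fixed_effects

  Gc <- center_dosages(genotypes)
  a <- .true_snp_effects(config, Gc, genotypes$map)
  u <- as.numeric(Gc %*% a)

  herd_of <- sample(config$n_herds, n, replace = TRUE)
  parity <- 1L + stats::rbinom(n, 1L, config$prob_parity2)
  herd_eff <- stats::rnorm(config$n_herds, 0, sqrt(vc[["sigma2_Herd"]]))
  pe_eff <- stats::rnorm(n, 0, sqrt(vc[["sigma2_PE"]]))

  nrec <- sample(seq(config$records_per_cow_range[1],
                     config$records_per_cow_range[2]),
                 n, replace = TRUE)
  cow_idx <- rep(seq_len(n), nrec)
  m <- length(cow_idx)
  date <- as.Date("2015-10-01") + sample(0:365, m, replace = TRUE)
  season <- season_from_date(date)
  dim_days <- sample(1:400, m, replace = TRUE)
  DIM <- dim_days / 365

  core <- fe[["mu"]] +
    fe[["parity2"]] * (parity[cow_idx] == 2L) +
    fe[["season_summer"]] * (season == "summer") +
    fe[["wilmink_beta1"]] * DIM +
    fe[["wilmink_beta2"]] * exp(-0.05 * DIM) +
    herd_eff[herd_of[cow_idx]] + u[cow_idx] + pe_eff[cow_idx]

  grid <- config$wavenumber_grid
  nw <- length(grid)
  sdE <- sqrt(vc[["sigma2_E"]])
  block_of <- rep(NA_integer_, nw)
  rho_of <- rep(0, nw)
  for (b in seq_along(config$wavenumber_blocks)) {
    bl <- config$wavenumber_blocks[[b]]
    inb <- grid >= bl[1] & grid <= bl[2]
    block_of[inb] <- b
    rho_of[inb] <- bl[3]
  }
  Z <- matrix(stats::rnorm(m * nw, 0, sdE), nrow = m)
  Y <- matrix(core, nrow = m, ncol = nw)
  zb <- lapply(seq_along(config$wavenumber_blocks), function(b)
    stats::rnorm(m, 0, sdE))
  for (w in seq_len(nw)) {
    if (is.na(block_of[w])) {
      Y[, w] <- Y[, w] + Z[, w]
    } else {
      rho <- rho_of[w]
      Y[, w] <- Y[, w] + sqrt(rho) * zb[[block_of[w]]] + sqrt(1 - rho) * Z[, w]
    }
  }
  colnames(Y) <- format_wvn(grid)

  records <- data.frame(cow = genotypes$cow_ids[cow_idx],
                        herd = sprintf("herd%03d", herd_of[cow_idx]),
                        parity = parity[cow_idx],
                        season = season,
                        dim = dim_days,
                        date = date,
                        fat_pct = round(stats::rnorm(m, 4.2, 0.8), 2),
                        protein_pct = round(stats::rnorm(m, 3.5, 0.35), 2),
                        stringsAsFactors = FALSE)
  spectra <- spectra_dataset(records, Y, grid)

  qtl_pos <- do.call(rbind, lapply(config$planted_qtl, function(q) {
    j <- which(genotypes$map$chrom == q$chrom)[q$snp]
    data.frame(chrom = q$chrom, bp_start = genotypes$map$bp[j],
               bp_end = genotypes$map$bp[j], snp_id = genotypes$map$snp_id[j],
               fraction = q$fraction)
  }))
  truth <- structure(list(
    snp_effects = a,
    variance_components = vc,
    h2 = unname(vc[["sigma2_A"]] /
                  (vc[["sigma2_Herd"]] + vc[["sigma2_A"]] +
                     vc[["sigma2_PE"]] + vc[["sigma2_E"]])),
    planted_qtl = qtl_pos,
    realized = list(cow_genetic = u, herd = herd_eff, pe = pe_eff,
                    residual_w1 = Y[, 1] - core)
  ), class = "truth_record")
  list(spectra = spectra, truth = truth)
}

#' Map a calendar date to the recording-year season
#'
#' The recording year runs 2015-10-01 to 2016-09-30: dates from 2016-04-01
#' through 2016-09-30 are "summer", dates from 2015-10-01 through 2016-03-31
#' are "winter". Dates outside the window are classified by month
#' (April-September = summer) so simulated multi-year inputs still work.
#'
#' @param date A `Date` vector (or something coercible).
#' @return Character vector, `"summer"` or `"winter"`.
#' @export
season_from_date <- function(date) {
  date <- as.Date(date)
  mth <- as.integer(format(date, "%m"))
  ifelse(mth >= 4 & mth <= 9, "summer", "winter")
}

format_wvn <- function(x) sub("\\.?0+$", "", formatC(x, format = "f", digits = 2))
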