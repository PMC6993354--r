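#' MCMC settings for the repeatability model
#'
#' Defaults are the desk-scale chain (7,000 iterations with 3,000 burn-in,
#' a tenth of the full-scale 70,000/30,000 analysis chain) thinned by 10.
#' The improper UNI(0, +Inf) variance priors are realised as uniform on
#' `(0, bound]` with `bound = variance_bound_factor` times the phenotypic
#' variance.
#'
#' @param n_iterations Total Gibbs iterations.
#' @param n_burn_in Burn-in iterations discarded (< `n_iterations`).
#' @param thinning Keep every `thinning`-th post-burn-in draw (>= 1). Saved
#'   draws = `floor((n_iterations - n_burn_in) / thinning)`.
#' @param seed Integer RNG seed; chains are bit-reproducible under it.
#' @param variance_bound_factor Finite surrogate for the improper uniform
#'   variance prior's upper bound, as a multiple of phenotypic variance.
#' @return Object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iterations = 7000, n_burn_in = 3000, thinning = 10,
                        seed = 1L, variance_bound_factor = 1e6) {
  stopifnot(n_burn_in < n_iterations, thinning >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed),
                 variance_bound_factor = variance_bound_factor),
            class = "mcmc_config")
}

#' Build the model design for one selected wavenumber
#'
#' Assembles, exactly as the model is written: response `y` (transmittance
#' at the wavenumber), fixed-effect covariates (intercept, parity and
#' season indicators, the Wilmink lactation-stage terms `DIM = dim/365`
#' and `exp(-0.05 * DIM)`), herd and cow index vectors, and the columnwise
#' mean-centred dosage matrix. Records from cows without genotypes are
#' dropped with a logged count; missing dosages are mean-imputed before
#' centring. If every record shares one parity (or season) level, that
#' term is dropped with a warning since its contrast is not estimable.
#'
#' @param dataset A `spectra_dataset`.
#' @param genotypes A `genotype_data` object.
#' @param wavenumber One wavenumber present in the dataset grid.
#' @param wilmink `"as_printed"` uses `exp(-0.05 * DIM)` with `DIM =
#'   dim/365` (nearly linear over a lactation); `"per_day"` uses the
#'   conventional `exp(-0.05 * dim)` in days.
#' @return Object of class `"model_design"`: `y`, `X` (with column names),
#'   `herd`/`cow` (1-based integer indices), `herd_ids`/`cow_ids`, `G`
#'   (centred dosages for the cows present), `map`, `n_dropped`.
#' @export
build_design <- function(dataset, genotypes, wavenumber,
                         wilmink = c("as_printed", "per_day")) {
  stopifnot(inherits(dataset, "spectra_dataset"),
            inherits(genotypes, "genotype_data"))
  wilmink <- match.arg(wilmink)
  w <- match(TRUE, abs(dataset$grid - wavenumber) < 1e-6)
  if (is.na(w)) stop("wavenumber ", wavenumber, " not in dataset grid")
  rec <- dataset$records
  keep <- rec$cow %in% genotypes$cow_ids
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped: cow lacks genotypes")
  }
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no records with genotyped cows")
  y <- dataset$transmittance[keep, w]

  DIM <- rec$dim / 365
  wil <- if (wilmink == "as_printed") exp(-0.05 * DIM) else exp(-0.05 * rec$dim)
  X <- cbind(mu = 1, DIM = DIM, wilmink = wil)
  for (v in c("parity", "season")) {
    f <- factor(rec[[v]])
    if (nlevels(f) < 2) {
      warning("all records share one ", v, " level; term dropped")
    } else {
      X <- cbind(X, as.integer(f == levels(f)[2]))
      colnames(X)[ncol(X)] <- paste0(v, levels(f)[2])
    }
  }

  cow_ids <- sort(unique(rec$cow))
  herd_ids <- sort(unique(rec$herd))
  Gall <- center_dosages(genotypes)
  G <- Gall[match(cow_ids, genotypes$cow_ids), , drop = FALSE]
  G <- scale(G, center = TRUE, scale = FALSE)[, , drop = FALSE]  # recentre on fitted cows
  structure(list(y = y, X = X,
                 herd = match(rec$herd, herd_ids),
                 cow = match(rec$cow, cow_ids),
                 herd_ids = herd_ids, cow_ids = cow_ids,
                 G = G, map = genotypes$map,
                 wavenumber = dataset$grid[w],
                 n_dropped = n_dropped),
            class = "model_design")
}

#' Fit the hierarchical repeatability model by Gibbs sampling
#'
#' Samples all location parameters (fixed effects, herd, permanent
#' environment, SNP effects) and the four variance components from the
#' joint posterior by single-site Gibbs updates — the Metropolis-Hastings
#' special case in which every proposal is accepted. Location parameters
#' have conditionally conjugate normal draws; variances have
#' scaled-inverse-chi-square conditionals under the flat prior, truncated
#' at the configured bound. Each saved draw records the per-cow additive
#' genetic value `CowA = G a`.
#'
#' @param design A [build_design()] object.
#' @param config An [mcmc_config()] object.
#' @param fix_variances Optional named numeric `c(sigma2_Herd =, sigma2_PE =,
#'   sigma2_E =, sigma2_a =)`; when supplied the variance components are held
#'   fixed (conditional mode, used e.g. to check SNP-effect draws against the
#'   closed-form ridge/BLUP solution). `sigma2_a` is the per-SNP effect
#'   variance.
#' @param store_effects Keep per-draw herd and PE effect vectors (default
#'   TRUE; turn off to save memory on large designs).
#' @return Object of class `"posterior_samples"`: matrices `fixed`
#'   (draws x coefficients), `snp` (draws x SNPs), `cow_a` (draws x cows),
#'   `var` (draws x 4: sigma2_Herd, sigma2_PE, sigma2_E, sigma2_a), optional
#'   `herd`/`pe`, plus bookkeeping (`config`, `wavenumber`, `map`,
#'   `bound_hit_frac`, `at_bound_warning`).
#' @export
fit_mcmc <- function(design, config = mcmc_config(), fix_variances = NULL,
                     store_effects = TRUE) {
  stopifnot(inherits(design, "model_design"), inherits(config, "mcmc_config"))
  y <- design$y
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) stop("zero-variance response")
  bound <- config$variance_bound_factor * vy

  init_b <- stats::lm.fit(design$X, y)$coefficients
  init_b[is.na(init_b)] <- 0
  if (is.null(fix_variances)) {
    init_var <- rep(vy / 4, 4)  # sigma2_Herd, sigma2_PE, sigma2_E, sigma2_a-total
    init_var[4] <- init_var[4] / max(ncol(design$G), 1)  # per-SNP share
    update_vars <- TRUE
  } else {
    nm <- c("sigma2_Herd", "sigma2_PE", "sigma2_E", "sigma2_a")
    stopifnot(all(nm %in% names(fix_variances)))
    init_var <- unname(fix_variances[nm])
    update_vars <- FALSE
  }

  set.seed(config$seed)
  res <- .gibbs_repeatability(y, design$X,
                              as.integer(design$herd - 1L),
                              as.integer(design$cow - 1L),
                              design$G,
                              config$n_iterations, config$n_burn_in,
                              config$thinning, bound,
                              as.numeric(init_b), as.numeric(init_var),
                              update_vars, store_effects)
  colnames(res$fixed) <- colnames(design$X)
  colnames(res$var) <- c("sigma2_Herd", "sigma2_PE", "sigma2_E", "sigma2_a")
  colnames(res$snp) <- colnames(design$G)
  colnames(res$cow_a) <- design$cow_ids
  at_bound <- res$bound_frac > 0.5
  if (at_bound) {
    warning("variance draws hit the prior bound in >50% of draws")
  }
  structure(list(fixed = res$fixed, snp = res$snp, cow_a = res$cow_a,
                 var = res$var,
                 herd = res$herd, pe = res$pe,
                 config = config, wavenumber = design$wavenumber,
                 map = design$map,
                 bound_hit_frac = res$bound_frac,
                 at_bound_warning = at_bound),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", nrow(x$var), "saved draws,", ncol(x$snp),
      "SNP effects,", ncol(x$cow_a), "cows",
      if (!is.null(x$wavenumber)) paste0("(wavenumber ", x$wavenumber, ")"),
      "\n")
  invisible(x)
}

#' Posterior heritability of a wavenumber
#'
#' Per saved draw, heritability is
#' `sigma2_A / (sigma2_Herd + sigma2_A + sigma2_PE + sigma2_E)`, where
#' `sigma2_A` is the variance across cows of that draw's additive genetic
#' values (the genomic variance implied by the SNP effects) and the other
#' three components are the sampled variance parameters. Draws with an
#' all-zero denominator are skipped with a log message.
#'
#' @param samples A `posterior_samples` object.
#' @param threshold Pass/fail gate on the posterior mean (default 0.05).
#' @return Object of class `"heritability_estimate"`: `wavenumber`, `mean`,
#'   `sd`, `pass`, and the per-draw values `h2_draws`.
#' @export
heritability <- function(samples, threshold = 0.05) {
  stopifnot(inherits(samples, "posterior_samples"), nrow(samples$var) >= 1)
  s2A <- apply(samples$cow_a, 1, stats::var)
  den <- samples$var[, "sigma2_Herd"] + s2A + samples$var[, "sigma2_PE"] +
    samples$var[, "sigma2_E"]
  ok <- den > 0
  if (any(!ok)) message(sum(!ok), " draw(s) skipped: zero denominator")
  h2 <- s2A[ok] / den[ok]
  structure(list(wavenumber = samples$wavenumber,
                 mean = mean(h2), sd = stats::sd(h2),
                 pass = mean(h2) >= threshold,
                 h2_draws = h2),
            class = "heritability_estimate")
}

#' Gate wavenumbers on heritability
#'
#' Keeps wavenumbers whose posterior mean heritability is at least the
#' threshold (wavenumbers with h2 below 0.05 are excluded from the GWAS),
#' preserving input order.
#'
#' @param estimates List of `heritability_estimate` objects.
#' @param threshold Exclusive lower bound (default 0.05).
#' @return Numeric vector of retained wavenumbers.
#' @export
gate_heritable <- function(estimates, threshold = 0.05) {
  if (!length(estimates)) return(numeric(0))
  keep <- vapply(estimates, function(e) e$mean >= threshold, logical(1))
  vapply(estimates[keep], function(e) e$wavenumber, numeric(1))
}
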