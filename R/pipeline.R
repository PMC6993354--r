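#' Pipeline configuration
#'
#' One configuration object drives the whole chain: simulate (or load) ->
#' select wavenumbers -> fit -> window GWAS -> report. Populations are
#' processed fully independently (separate seeds, separate QC), mirroring
#' per-breed analysis; the overlap table is produced when two or more
#' populations are configured.
#'
#' @param populations List of population blocks. Each block is a list with
#'   `name`, and either `sim` (a [sim_config()]) or the input paths
#'   `phenotypes`, `genotypes`, `map` (or `vcf`). Optional `qc`:
#'   `"holstein"`, `"jersey"` or `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param water_upper,water_band Water-region exclusion bounds passed to
#'   [filter_water_regions()].
#' @param block_threshold Correlation-block threshold (default 0.95).
#' @param h2_gate Heritability gate (default 0.05).
#' @param mcmc An [mcmc_config()].
#' @param group_size,offsets,min_group_size SNP-window layout (100 /
#'   1,21,41,61,81 / 80).
#' @param qtl_threshold Percent-variance QTL cut-off (default 0.35).
#' @param max_wavenumbers Optional cap on how many gated wavenumbers are
#'   carried into the GWAS stage (keeps desk-scale runs bounded); `Inf`
#'   analyses all.
#' @param seed Master seed; per-population and per-wavenumber chain seeds
#'   are derived from it deterministically.
#' @param plots Write Manhattan PNGs (default FALSE; the plot *data* table
#'   is always written).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(populations, out_dir,
                            water_upper = 3008, water_band = c(1623, 1669),
                            block_threshold = 0.95, h2_gate = 0.05,
                            mcmc = mcmc_config(),
                            group_size = 100, offsets = c(1, 21, 41, 61, 81),
                            min_group_size = 80, qtl_threshold = 0.35,
                            max_wavenumbers = Inf, seed = 1L, plots = FALSE) {
  stopifnot(length(populations) >= 1, block_threshold > 0, h2_gate > 0,
            qtl_threshold > 0, group_size > 0, min_group_size > 0)
  for (p in populations) {
    if (is.null(p$sim)) {
      paths <- c(p$phenotypes, p$genotypes, p$map, p$vcf)
      if (!length(paths) || !all(file.exists(paths))) {
        stop("population '", p$name, "': input path(s) missing")
      }
    }
  }
  structure(list(populations = populations, out_dir = out_dir,
                 water_upper = water_upper, water_band = water_band,
                 block_threshold = block_threshold, h2_gate = h2_gate,
                 mcmc = mcmc, group_size = group_size, offsets = offsets,
                 min_group_size = min_group_size,
                 qtl_threshold = qtl_threshold,
                 max_wavenumbers = max_wavenumbers,
                 seed = as.integer(seed), plots = plots),
            class = "pipeline_config")
}

.pop_inputs <- function(pop, cfg, pop_seed) {
  if (!is.null(pop$sim)) {
    sc <- pop$sim
    sc$seed <- pop_seed
    geno <- simulate_genotypes(sc)
    sim <- simulate_spectra(sc, geno)
    list(spectra = sim$spectra, genotypes = geno, truth = sim$truth)
  } else {
    spectra <- read_phenotypes(pop$phenotypes)
    geno <- if (!is.null(pop$vcf)) {
      read_genotypes_vcf(pop$vcf)
    } else {
      read_genotypes(pop$genotypes, pop$map,
                     phenotype_cows = unique(spectra$records$cow))
    }
    list(spectra = spectra, genotypes = geno, truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, per population: input loading or simulation, record QC,
#' water-region exclusion, residualised-correlation block detection and
#' representative selection, per-wavenumber Gibbs fits, heritability
#' gating, 100-SNP-window variance partitioning, QTL and peak-region
#' calling; then cross-population QTL overlap when two or more populations
#' are configured. All tables are written tab-separated under
#' `config$out_dir`, together with a machine-readable JSON manifest that
#' fully determines the run (package version, seed, config echo, outputs).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-population results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  wr <- function(x, name) {
    path <- file.path(config$out_dir, name)
    data.table::fwrite(x, path, sep = "\t")
    outputs <<- c(outputs, name)
    path
  }
  message("pipeline: ", length(config$populations), " population(s); ",
          "block threshold ", config$block_threshold,
          ", h2 gate ", config$h2_gate,
          ", QTL threshold ", config$qtl_threshold, "%")

  results <- list()
  for (ip in seq_along(config$populations)) {
    pop <- config$populations[[ip]]
    nm <- if (!is.null(pop$name)) pop$name else paste0("pop", ip)
    pop_seed <- config$seed + 1000L * ip
    message("[", nm, "] loading inputs")
    inp <- .pop_inputs(pop, config, pop_seed)
    spectra <- inp$spectra
    rules <- switch(if (is.null(pop$qc)) "none" else pop$qc,
                    holstein = qc_rules_holstein(),
                    jersey = qc_rules_jersey(),
                    none = NULL)
    sel <- select_wavenumbers(spectra, rules, config$block_threshold)
    wr(sel$selection, paste0(nm, "_selection.tsv"))
    wr(sel$blocks, paste0(nm, "_blocks.tsv"))

    groups <- make_snp_groups(inp$genotypes$map, config$group_size,
                              config$offsets, config$min_group_size)
    ests <- list(); fits <- list()
    for (iw in seq_len(nrow(sel$selection))) {
      w <- sel$selection$wavenumber[iw]
      des <- build_design(spectra, inp$genotypes, w)
      mc <- config$mcmc
      mc$seed <- pop_seed + iw
      fits[[as.character(w)]] <- fit_mcmc(des, mc, store_effects = FALSE)
      ests[[as.character(w)]] <- heritability(fits[[as.character(w)]],
                                              config$h2_gate)
    }
    h2tab <- data.frame(
      wavenumber = vapply(ests, `[[`, numeric(1), "wavenumber"),
      h2_mean = vapply(ests, `[[`, numeric(1), "mean"),
      h2_sd = vapply(ests, `[[`, numeric(1), "sd"),
      pass = vapply(ests, `[[`, logical(1), "pass"))
    wr(h2tab, paste0(nm, "_heritability.tsv"))
    gated <- gate_heritable(ests, config$h2_gate)
    if (is.finite(config$max_wavenumbers)) {
      gated <- utils::head(gated, config$max_wavenumbers)
    }
    message("[", nm, "] ", length(gated), "/", nrow(h2tab),
            " wavenumber(s) pass the heritability gate")

    qtls <- list(); vars <- list()
    for (w in gated) {
      key <- as.character(w)
      gv <- group_variances(fits[[key]], inp$genotypes, groups)
      vars[[key]] <- gv
      wr(gv, paste0(nm, "_group_variance_", format_wvn(w), ".tsv"))
      md <- data.frame(chrom = gv$chrom, bp = gv$bp_mid,
                       percent_varA = gv$percent_varA)
      wr(md, paste0(nm, "_manhattan_", format_wvn(w), ".tsv"))
      if (isTRUE(config$plots)) {
        plot_manhattan(gv, file.path(config$out_dir,
                                     paste0(nm, "_manhattan_",
                                            format_wvn(w), ".png")),
                       config$qtl_threshold)
      }
      qtls[[key]] <- call_qtl(gv, config$qtl_threshold)
    }
    qtab <- do.call(rbind, qtls)
    if (is.null(qtab)) qtab <- call_qtl(cbind(groups[0, ], percent_varA = numeric(0)),
                                        config$qtl_threshold)
    wr(qtab, paste0(nm, "_qtl.tsv"))
    if (length(qtls)) {
      wr(peak_regions(qtls, vars, threshold = config$qtl_threshold),
         paste0(nm, "_peak_regions.tsv"))
    }
    results[[nm]] <- list(selection = sel, heritability = h2tab,
                          gated = gated, variances = vars, qtl = qtls,
                          qtl_table = qtab, truth = inp$truth)
  }

  if (length(results) >= 2) {
    nms <- names(results)
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      ol <- overlap_qtl(results[[nms[i]]]$qtl_table,
                        results[[nms[j]]]$qtl_table)
      ol$total <- attr(ol, "total")
      wr(ol, paste0("overlap_", nms[i], "_", nms[j], ".tsv"))
    }
  }

  manifest <- list(package = "spectraQTL",
                   version = as.character(utils::packageVersion("spectraQTL")),
                   seed = config$seed,
                   config = .config_echo(config),
                   outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline complete: ", length(outputs), " table(s) in ",
          config$out_dir)
  invisible(list(results = results, manifest = manifest))
}

# JSON-serialisable echo of the configuration (drops classes, keeps values;
# an unlimited wavenumber cap is stored as -1 since JSON has no Inf)
.config_echo <- function(config) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x <- unclass(x)
    # named atomic vectors must become objects, or JSON drops the names
    if (!is.null(names(x))) as.list(x) else x
  }
  out <- strip(config)
  out$max_wavenumbers <- if (is.finite(config$max_wavenumbers))
    config$max_wavenumbers else -1
  out
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir Where to write the reproduced outputs (defaults to the
#'   manifest's directory).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  cfg <- man$config
  pops <- lapply(cfg$populations, function(p) {
    if (!is.null(p$sim)) {
      s <- p$sim
      s$records_per_cow_range <- unlist(s$records_per_cow_range)
      s$maf_range <- unlist(s$maf_range)
      s$variance_components <- unlist(s$variance_components)
      s$fixed_effects <- unlist(s$fixed_effects)
      s$wavenumber_grid <- unlist(s$wavenumber_grid)
      s$wavenumber_blocks <- lapply(s$wavenumber_blocks, unlist)
      s$planted_qtl <- lapply(s$planted_qtl, function(q) q)
      p$sim <- do.call(sim_config, s)
    }
    p$phenotypes <- unlist(p$phenotypes); p$genotypes <- unlist(p$genotypes)
    p$map <- unlist(p$map); p$vcf <- unlist(p$vcf); p$qc <- unlist(p$qc)
    p$name <- unlist(p$name)
    p
  })
  mc <- do.call(mcmc_config, lapply(cfg$mcmc, unlist))
  mw <- unlist(cfg$max_wavenumbers)
  config <- pipeline_config(pops, out_dir,
                            water_upper = unlist(cfg$water_upper),
                            water_band = unlist(cfg$water_band),
                            block_threshold = unlist(cfg$block_threshold),
                            h2_gate = unlist(cfg$h2_gate), mcmc = mc,
                            group_size = unlist(cfg$group_size),
                            offsets = unlist(cfg$offsets),
                            min_group_size = unlist(cfg$min_group_size),
                            qtl_threshold = unlist(cfg$qtl_threshold),
                            max_wavenumbers = if (is.null(mw) || mw < 0) Inf else mw,
                            seed = unlist(cfg$seed),
                            plots = isTRUE(unlist(cfg$plots)))
  run_pipeline(config)
}
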