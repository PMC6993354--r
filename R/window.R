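#' Partition chromosomes into overlapping 100-SNP groups
#'
#' Within each chromosome, SNPs (ordered by position) are divided into
#' groups of `group_size` consecutive SNPs; the tiling is repeated once per
#' offset (counting from SNP 1, 21, 41, 61 and 81), so groups from
#' different offsets overlap but are never identical. The last group of a
#' tiling is truncated at the chromosome end; truncated groups with fewer
#' than `min_size` SNPs are excluded.
#'
#' @param snp_map Data frame with `chrom` and `bp`, sorted by chromosome
#'   then position (strictly increasing bp within chromosome).
#' @param group_size Number of SNPs per group (default 100).
#' @param offsets Starting ordinals of the repeated tilings.
#' @param min_size Minimum SNPs a (truncated) group must keep (default 80).
#' @return Data frame, one row per group: `group_id`, `chrom`, `offset`,
#'   `first`/`last` (1-based SNP ordinals within chromosome), `n_snps`,
#'   `bp_lower`/`bp_upper` (positions of the first/last member SNP, closed
#'   interval), `bp_mid` (position of the middle SNP, ordinal
#'   `ceiling(n/2)` within the group — the Manhattan-plot orientation
#'   point), and `col_first`/`col_last` (columns in the genome-wide dosage
#'   matrix).
#' @export
make_snp_groups <- function(snp_map, group_size = 100,
                            offsets = c(1, 21, 41, 61, 81),
                            min_size = 80) {
  stopifnot(all(c("chrom", "bp") %in% names(snp_map)))
  if (is.unsorted(order(snp_map$chrom, snp_map$bp)) ||
      !identical(order(snp_map$chrom, snp_map$bp), seq_len(nrow(snp_map)))) {
    stop("snp_map must be sorted by chromosome then bp")
  }
  out <- list()
  for (ch in unique(snp_map$chrom)) {
    cols <- which(snp_map$chrom == ch)
    n <- length(cols)
    bp <- snp_map$bp[cols]
    for (o in offsets) {
      if (o > n) next
      starts <- seq(o, n, by = group_size)
      for (s in starts) {
        e <- min(s + group_size - 1L, n)
        ns <- e - s + 1L
        if (ns < min_size) next
        mid <- s + ceiling(ns / 2) - 1L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, offset = o, first = s, last = e, n_snps = ns,
          bp_lower = bp[s], bp_upper = bp[e], bp_mid = bp[mid],
          col_first = cols[s], col_last = cols[e])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(group_id = character(0), chrom = integer(0),
                      offset = integer(0), first = integer(0),
                      last = integer(0), n_snps = integer(0),
                      bp_lower = numeric(0), bp_upper = numeric(0),
                      bp_mid = numeric(0), col_first = integer(0),
                      col_last = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$first, res$offset), , drop = FALSE]
  res <- cbind(group_id = paste0(res$chrom, "_", res$first, "_", res$last),
               res)
  rownames(res) <- NULL
  res
}

# centred dosage matrix aligned with the cows of a posterior_samples object
.aligned_dosages <- function(samples, genotypes) {
  if (is.matrix(genotypes)) return(genotypes)
  stopifnot(inherits(genotypes, "genotype_data"))
  G <- center_dosages(genotypes)
  G <- G[match(colnames(samples$cow_a), genotypes$cow_ids), , drop = FALSE]
  scale(G, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Additive genetic variance explained by SNP groups
#'
#' For each saved posterior draw `s` and group `j`, the per-cow group
#' breeding value is `sum_{m in j} g_lm a_m^(s)`; its variance across cows
#' is the group genomic variance for that draw. The percentage of total
#' additive genetic variance is `100 * mean_s(var_l gEBV) /
#' mean_s(var_l CowA)` — a ratio of draw-averaged variances, which is
#' stable when individual additive-variance draws are small (set
#' `per_draw_ratio = TRUE` for the mean of per-draw ratios instead).
#'
#' @param samples A `posterior_samples` object.
#' @param genotypes The `genotype_data` the model was fitted with (or a
#'   pre-aligned centred dosage matrix, cows in the order of
#'   `samples$cow_a`).
#' @param groups Output of [make_snp_groups()] (or a subset of its rows).
#' @param per_draw_ratio Average per-draw ratios instead of the
#'   ratio of averages.
#' @return `groups` with a `percent_varA` column appended.
#' @export
group_variances <- function(samples, genotypes, groups,
                            per_draw_ratio = FALSE) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!nrow(groups)) return(cbind(groups, percent_varA = numeric(0)))
  Gc <- .aligned_dosages(samples, genotypes)
  if (any(groups$col_last > ncol(Gc))) {
    stop("group refers to SNPs outside the fitted design")
  }
  A <- samples$snp
  den_draws <- apply(samples$cow_a, 1, stats::var)
  pct <- numeric(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    J <- groups$col_first[i]:groups$col_last[i]
    Ug <- Gc[, J, drop = FALSE] %*% t(A[, J, drop = FALSE])  # cows x draws
    num_draws <- apply(Ug, 2, stats::var)
    pct[i] <- if (per_draw_ratio) {
      100 * mean(ifelse(den_draws > 0, num_draws / den_draws, 0))
    } else {
      100 * mean(num_draws) / mean(den_draws)
    }
  }
  out <- cbind(groups, percent_varA = pct)
  attr(out, "wavenumber") <- samples$wavenumber
  out
}

#' @rdname group_variances
#' @param group A single group (one row of [make_snp_groups()] output).
#' @export
group_variance <- function(samples, genotypes, group,
                           per_draw_ratio = FALSE) {
  group_variances(samples, genotypes, group[1, , drop = FALSE],
                  per_draw_ratio)$percent_varA
}

#' Call QTL from significant SNP groups
#'
#' A QTL is one, or several overlapping, SNP groups each explaining more
#' than `threshold` percent of the total additive genetic variance.
#' Groups whose closed bp intervals overlap are merged transitively
#' (connected components per chromosome); the peak is the member group
#' explaining the most variance.
#'
#' @param variances Output of [group_variances()] for one wavenumber.
#' @param threshold Strict percent threshold (default 0.35).
#' @return Data frame, one row per QTL: `chrom`, `wavenumber`, `bp_lower`,
#'   `bp_upper` (union of member intervals), `n_groups`, `peak_group_id`,
#'   `peak_bp_lower`, `peak_bp_upper`, `peak_percent`; attribute
#'   `"members"` is a list of the member-group rows per QTL.
#' @export
call_qtl <- function(variances, threshold = 0.35) {
  wvn <- attr(variances, "wavenumber")
  if (is.null(wvn)) wvn <- NA_real_
  sig <- variances[variances$percent_varA > threshold, , drop = FALSE]
  empty <- data.frame(chrom = integer(0), wavenumber = numeric(0),
                      bp_lower = numeric(0), bp_upper = numeric(0),
                      n_groups = integer(0), peak_group_id = character(0),
                      peak_bp_lower = numeric(0), peak_bp_upper = numeric(0),
                      peak_percent = numeric(0))
  if (!nrow(sig)) { attr(empty, "members") <- list(); return(empty) }
  out <- list(); members <- list()
  for (ch in sort(unique(sig$chrom))) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$bp_lower, s$bp_upper), , drop = FALSE]
    comp <- integer(nrow(s)); comp[1] <- 1L; hi <- s$bp_upper[1]
    for (i in seq_len(nrow(s))[-1]) {
      # sorted by bp_lower: overlaps the running component iff it starts
      # at or before the component's right edge (closed intervals)
      if (s$bp_lower[i] <= hi) comp[i] <- comp[i - 1L]
      else comp[i] <- comp[i - 1L] + 1L
      hi <- max(hi, s$bp_upper[i])
      if (comp[i] != comp[i - 1L]) hi <- s$bp_upper[i]
    }
    for (k in unique(comp)) {
      m <- s[comp == k, , drop = FALSE]
      pk <- m[which.max(m$percent_varA), ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, wavenumber = wvn,
        bp_lower = min(m$bp_lower), bp_upper = max(m$bp_upper),
        n_groups = nrow(m), peak_group_id = pk$group_id,
        peak_bp_lower = pk$bp_lower, peak_bp_upper = pk$bp_upper,
        peak_percent = pk$percent_varA)
      members[[length(members) + 1L]] <- m
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "members") <- members
  res
}

#' Summarise the top peak region per chromosome
#'
#' Across a set of wavenumbers (optionally grouped by the chemical bond
#' they interact with), reports for each chromosome the single highest
#' peak SNP group, every wavenumber whose variance at that group exceeds
#' the threshold, and the top wavenumber.
#'
#' @param qtls_by_wvn Named list (name = wavenumber) of [call_qtl()]
#'   outputs.
#' @param variances_by_wvn Named list (same names) of [group_variances()]
#'   outputs.
#' @param bonds Optional named character vector mapping wavenumber name to
#'   a chemical-bond label; by default all wavenumbers form one group.
#' @param threshold Strict percent threshold (default 0.35).
#' @return Data frame: `bond`, `chrom`, `bp_lower`, `bp_upper` (the peak
#'   group's closed interval), `wavenumbers` and `percents`
#'   (comma-separated, ordered by decreasing percent), `top_wavenumber`,
#'   `top_percent`.
#' @export
peak_regions <- function(qtls_by_wvn, variances_by_wvn, bonds = NULL,
                         threshold = 0.35) {
  wvns <- names(qtls_by_wvn)
  stopifnot(length(wvns) >= 1, setequal(wvns, names(variances_by_wvn)))
  if (is.null(bonds)) bonds <- stats::setNames(rep("all", length(wvns)), wvns)
  out <- list()
  for (bd in unique(bonds)) {
    in_bd <- wvns[bonds[wvns] == bd]
    calls <- do.call(rbind, qtls_by_wvn[in_bd])
    if (is.null(calls) || !nrow(calls)) next
    for (ch in sort(unique(calls$chrom))) {
      cc <- calls[calls$chrom == ch, , drop = FALSE]
      top <- cc[which.max(cc$peak_percent), ]
      # percent of this exact peak group for every wavenumber in the bond
      pw <- vapply(in_bd, function(w) {
        v <- variances_by_wvn[[w]]
        j <- which(v$group_id == top$peak_group_id)
        if (length(j)) v$percent_varA[j[1]] else NA_real_
      }, numeric(1))
      sel <- which(!is.na(pw) & pw > threshold)
      sel <- sel[order(pw[sel], decreasing = TRUE)]
      out[[length(out) + 1L]] <- data.frame(
        bond = bd, chrom = ch,
        bp_lower = top$peak_bp_lower, bp_upper = top$peak_bp_upper,
        wavenumbers = paste(in_bd[sel], collapse = ","),
        percents = paste(formatC(pw[sel], format = "f", digits = 2),
                         collapse = ","),
        top_wavenumber = if (length(sel)) in_bd[sel[1]] else NA_character_,
        top_percent = if (length(sel)) pw[sel[1]] else NA_real_)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(bond = character(0), chrom = integer(0),
               bp_lower = numeric(0), bp_upper = numeric(0),
               wavenumbers = character(0), percents = character(0),
               top_wavenumber = character(0), top_percent = numeric(0))
  rownames(res) <- NULL
  res
}

#' Count overlapping QTL between two call sets
#'
#' Two QTL overlap when their merged closed bp intervals intersect on the
#' same chromosome. Counting is by connected components of the bipartite
#' intersection graph that contain calls from both sets, so the measure is
#' symmetric and a QTL matched by several partners is counted once.
#'
#' @param calls_a,calls_b [call_qtl()] outputs (same genome build /
#'   SNP-map convention).
#' @return Data frame per chromosome: `chrom`, `n_a`, `n_b`, `n_overlap`;
#'   attribute `"total"` holds the genome-wide overlap count.
#' @export
overlap_qtl <- function(calls_a, calls_b) {
  chroms <- sort(unique(c(calls_a$chrom, calls_b$chrom)))
  out <- lapply(chroms, function(ch) {
    A <- calls_a[calls_a$chrom == ch, , drop = FALSE]
    B <- calls_b[calls_b$chrom == ch, , drop = FALSE]
    n_ol <- 0L
    if (nrow(A) && nrow(B)) {
      # union-find over the bipartite intersection graph
      parent <- seq_len(nrow(A) + nrow(B))
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
        if (A$bp_lower[i] <= B$bp_upper[j] && B$bp_lower[j] <= A$bp_upper[i]) {
          parent[find(i)] <- find(nrow(A) + j)
        }
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      ra <- unique(roots[seq_len(nrow(A))])
      rb <- unique(roots[nrow(A) + seq_len(nrow(B))])
      n_ol <- length(intersect(ra, rb))
    }
    data.frame(chrom = ch, n_a = nrow(A), n_b = nrow(B), n_overlap = n_ol)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = integer(0), n_a = integer(0),
                                      n_b = integer(0), n_overlap = integer(0))
  attr(res, "total") <- sum(res$n_overlap)
  res
}

#' Manhattan-plot data and plot for window variances
#'
#' Each group's percent of additive genetic variance is plotted at its
#' middle SNP's position, with a horizontal reference line at the QTL
#' cut-off.
#'
#' @param variances [group_variances()] output.
#' @param file Optional PNG path; `NULL` plots to the active device.
#' @param threshold Reference-line percent (default 0.35).
#' @return Invisibly, the plotted data frame (`chrom`, `bp`,
#'   `percent_varA`).
#' @export
plot_manhattan <- function(variances, file = NULL, threshold = 0.35) {
  md <- data.frame(chrom = variances$chrom, bp = variances$bp_mid,
                   percent_varA = variances$percent_varA)
  md <- md[order(md$chrom, md$bp), ]
  offs <- c(0, cumsum(tapply(md$bp, md$chrom, max)))
  x <- md$bp + offs[match(md$chrom, sort(unique(md$chrom)))]
  if (!is.null(file)) grDevices::png(file, width = 900, height = 400)
  graphics::plot(x, md$percent_varA, pch = 20,
                 col = 1 + md$chrom %% 2,
                 xlab = "position", ylab = "% additive genetic variance",
                 main = attr(variances, "wavenumber"))
  graphics::abline(h = threshold, lty = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(md)
}
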