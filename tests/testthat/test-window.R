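mk_map <- function(n, chrom = 1, spacing = 1000) {
  data.frame(snp_id = paste0("s", chrom, "_", seq_len(n)), chrom = chrom,
             bp = seq_len(n) * spacing)
}

test_that("SNP grouping matches brute-force enumeration", {
  for (n in c(79, 100, 250, 1000)) {
    got <- make_snp_groups(mk_map(n))
    oracle <- brute_groups(n)
    if (is.null(oracle)) {
      expect_identical(nrow(got), 0L)
    } else {
      oracle <- oracle[order(oracle[, "first"], oracle[, "last"]), ,
                       drop = FALSE]
      ord <- order(got$first, got$last)
      expect_equal(got$first[ord], unname(oracle[, "first"]))
      expect_equal(got$last[ord], unname(oracle[, "last"]))
    }
  }
  # printed cases: 100 SNPs -> [1,100] and [21,100]; 250 SNPs -> 9 groups
  g100 <- make_snp_groups(mk_map(100))
  expect_identical(nrow(g100), 2L)
  expect_setequal(paste(g100$first, g100$last), c("1 100", "21 100"))
  expect_identical(nrow(make_snp_groups(mk_map(250))), 9L)
  expect_identical(nrow(make_snp_groups(mk_map(79))), 0L)
  # size bounds and bp intervals span member SNPs exactly
  g <- make_snp_groups(mk_map(250))
  expect_true(all(g$n_snps >= 80 & g$n_snps <= 100))
  expect_identical(g$last - g$first + 1L, g$n_snps)
  expect_identical(g$bp_lower, g$first * 1000)
  expect_identical(g$bp_upper, g$last * 1000)
  expect_false(any(duplicated(g[c("first", "last")])))
  expect_error(make_snp_groups(data.frame(chrom = c(1, 1), bp = c(5, 2),
                                          snp_id = c("a", "b"))), "sorted")
})

test_that("middle-SNP orientation point uses ordinal ceiling(n/2)", {
  g <- make_snp_groups(mk_map(100))
  # [1,100]: middle ordinal 50 -> bp 50000; [21,100]: 80 SNPs, middle is
  # the 40th member, ordinal 60 -> bp 60000
  expect_identical(g$bp_mid[g$first == 1], 50000)
  expect_identical(g$bp_mid[g$first == 21], 60000)
})

test_that("window variance matches the hand-computed brute-force oracle", {
  # printed-in-fixture instance: 5 cows x 4 SNPs, 3 posterior draws
  Graw <- matrix(c(0, 1, 2, 1, 0,
                   2, 2, 0, 1, 1,
                   1, 0, 1, 2, 0,
                   0, 0, 1, 1, 2), 5, 4)
  Gc <- scale(Graw, center = TRUE, scale = FALSE)
  A <- matrix(c(0.5, -0.2, 0.1, 0.3,
                0.4, -0.1, 0.0, 0.2,
                0.6, -0.3, 0.2, 0.4), 3, 4, byrow = TRUE)
  cow_a <- Gc %*% t(A)  # cows x draws
  samples <- fake_samples(snp = A, cow_a = t(cow_a),
                          var = matrix(1, 3, 4))
  groups <- data.frame(group_id = "1_1_2", chrom = 1, offset = 1,
                       first = 1, last = 2, n_snps = 2,
                       bp_lower = 100, bp_upper = 200, bp_mid = 100,
                       col_first = 1, col_last = 2)
  got <- group_variance(samples, Gc, groups)
  expect_equal(got, brute_percent_varA(Gc, A, 1:2), tolerance = 1e-12)
  # zero effects for the group give exactly zero
  A0 <- A; A0[, 3:4] <- 0
  s0 <- fake_samples(snp = A0, cow_a = t(Gc %*% t(A0)),
                     var = matrix(1, 3, 4))
  g34 <- transform(groups, first = 3, last = 4, col_first = 3, col_last = 4)
  expect_identical(group_variance(s0, Gc, g34), 0)
  # invariant to cow relabelling and to zero-effect SNP padding
  perm <- c(3, 1, 5, 2, 4)
  sp <- fake_samples(snp = A, cow_a = t(cow_a[perm, ]),
                     var = matrix(1, 3, 4))
  expect_equal(group_variance(sp, Gc[perm, ], groups), got)
  sz <- fake_samples(snp = cbind(A, 0, 0),
                     cow_a = t(cow_a), var = matrix(1, 3, 4))
  expect_equal(group_variance(sz, cbind(Gc, 1, -1), groups), got)
  expect_error(group_variances(samples, Gc,
                               transform(groups, col_last = 99)),
               "outside")
})

test_that("a group holding all genetic variance explains nearly all of it", {
  # needs n_cows >> n_snps: with p comparable to n, the null SNPs jointly
  # reconstruct ~p/n of the causal dosage in-sample (sampling LD), so the
  # window attribution leaks out of the group no matter how long the chain
  cfg <- sim_config(n_cows = 1000, n_herds = 15,
                    records_per_cow_range = c(3, 4),
                    n_chromosomes = 1, snps_per_chromosome = 150,
                    planted_qtl = list(list(chrom = 1, snp = 50,
                                            fraction = 1)),
                    seed = 55)
  g <- simulate_genotypes(cfg)
  ds <- simulate_spectra(cfg, g)$spectra
  fit <- fit_mcmc(build_design(ds, g, ds$grid[1]),
                  mcmc_config(2000, 800, 5, seed = 7), store_effects = FALSE)
  groups <- make_snp_groups(g$map)
  gv <- group_variances(fit, g, groups)
  with_qtl <- gv$first <= 50 & gv$last >= 50
  expect_gte(max(gv$percent_varA[with_qtl]), 90)
})

test_that("QTL calling merges transitively and respects member bounds", {
  base <- data.frame(group_id = paste0("g", 1:3), chrom = 1,
                     offset = 1, first = c(1, 21, 41),
                     last = c(100, 120, 140), n_snps = 100,
                     bp_lower = c(100, 250, 420), bp_upper = c(300, 450, 600),
                     bp_mid = 0, col_first = 1, col_last = 2)
  v <- cbind(base, percent_varA = c(0.5, 0.4, 0.6))
  attr(v, "wavenumber") <- 1449
  # A overlaps B, B overlaps C, A and C disjoint -> one QTL of three groups
  q <- call_qtl(v)
  expect_identical(nrow(q), 1L)
  expect_identical(q$n_groups, 3L)
  expect_identical(q$bp_lower, 100)
  expect_identical(q$bp_upper, 600)
  expect_identical(q$peak_group_id, "g3")
  expect_identical(q$wavenumber, 1449)
  # nothing significant -> empty call set
  v2 <- v; v2$percent_varA <- c(0.1, 0.35, 0.2)  # 0.35 is NOT > 0.35
  expect_identical(nrow(call_qtl(v2)), 0L)
})

test_that("QTL components agree with a brute-force interval oracle", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    lo <- sort(sample(1:500, n)) * 10
    hi <- lo + sample(20:200, n, replace = TRUE)
    v <- data.frame(group_id = paste0("g", 1:n), chrom = 1, offset = 1,
                    first = 1, last = 2, n_snps = 100,
                    bp_lower = lo, bp_upper = hi, bp_mid = 0,
                    col_first = 1, col_last = 2,
                    percent_varA = runif(n, 0.4, 3))
    attr(v, "wavenumber") <- 1000
    q <- call_qtl(v)
    comp <- brute_components(lo, hi)
    expect_identical(nrow(q), length(unique(comp)))
    for (k in unique(comp)) {
      m <- comp == k
      row <- which(q$bp_lower == min(lo[m]))
      expect_identical(q$bp_upper[row], max(hi[m]))
      expect_identical(q$n_groups[row], sum(m))
      expect_equal(q$peak_percent[row], max(v$percent_varA[m]))
      # merged interval never extends beyond member min/max
      expect_gte(min(lo[m]), q$bp_lower[row])
      expect_lte(max(hi[m]), q$bp_upper[row])
    }
  }
})

test_that("peak regions pick the chromosome-wise argmax across wavenumbers", {
  mkv <- function(pcts) {
    v <- data.frame(group_id = paste0(rep(1:3, each = 2), "_g",
                                      rep(1:2, 3)),
                    chrom = rep(1:3, each = 2), offset = 1,
                    first = rep(c(1, 101), 3), last = rep(c(100, 200), 3),
                    n_snps = 100,
                    bp_lower = rep(c(1e5, 2e5), 3),
                    bp_upper = rep(c(1.9e5, 3e5), 3), bp_mid = 0,
                    col_first = 1, col_last = 2, percent_varA = pcts)
    v
  }
  va <- mkv(c(0.5, 0.1, 0.1, 0.8, 0.4, 0.1)); attr(va, "wavenumber") <- 1226
  vb <- mkv(c(0.4, 0.1, 0.1, 0.6, 0.1, 0.1)); attr(vb, "wavenumber") <- 1114
  qa <- call_qtl(va); qb <- call_qtl(vb)
  pr <- peak_regions(list(`1226` = qa, `1114` = qb),
                     list(`1226` = va, `1114` = vb))
  expect_identical(nrow(pr), 3L)
  # chromosome 1: both wavenumbers exceed 0.35 at the shared peak; 1226 tops
  r1 <- pr[pr$chrom == 1, ]
  expect_identical(r1$top_wavenumber, "1226")
  expect_identical(r1$wavenumbers, "1226,1114")
  expect_equal(r1$top_percent, 0.5)
  # chromosome 3: only 1226 passes at the peak
  r3 <- pr[pr$chrom == 3, ]
  expect_identical(r3$wavenumbers, "1226")
  # brute-force argmax check on chromosome 2
  r2 <- pr[pr$chrom == 2, ]
  expect_equal(r2$top_percent, 0.8)
  expect_identical(r2$bp_lower, 2e5)
  # one wavenumber, one QTL: region equals that QTL's peak interval
  pr1 <- peak_regions(list(`1226` = qa[qa$chrom == 2, ]),
                      list(`1226` = va))
  expect_identical(pr1$bp_lower, qa$peak_bp_lower[qa$chrom == 2])
})

test_that("overlap counting is symmetric and matches a pairwise scan", {
  mkq <- function(chrom, lo, hi) {
    data.frame(chrom = chrom, wavenumber = 1, bp_lower = lo, bp_upper = hi,
               n_groups = 1, peak_group_id = "g", peak_bp_lower = lo,
               peak_bp_upper = hi, peak_percent = 1)
  }
  a <- mkq(c(1, 1, 2), c(100, 500, 100), c(200, 600, 300))
  # identical call sets: every QTL overlaps
  ol <- overlap_qtl(a, a)
  expect_identical(attr(ol, "total"), 3L)
  # disjoint chromosomes: zero overlap
  b <- mkq(3, 100, 200)
  expect_identical(attr(overlap_qtl(a, b), "total"), 0L)
  # staggered intervals: two b-intervals chained through one a-interval
  # form one component; symmetric
  a2 <- mkq(1, c(100, 400), c(300, 450))
  b2 <- mkq(1, c(150, 250, 500), c(180, 350, 600))
  expect_identical(attr(overlap_qtl(a2, b2), "total"), 1L)
  expect_identical(attr(overlap_qtl(b2, a2), "total"), 1L)
  # touching closed intervals count as overlapping
  expect_identical(attr(overlap_qtl(mkq(1, 100, 200), mkq(1, 200, 300)),
                        "total"), 1L)
})

test_that("Manhattan export places groups at their middle SNP", {
  v <- data.frame(group_id = c("1_1_100", "1_101_200"), chrom = 1,
                  offset = 1, first = c(1, 101), last = c(100, 200),
                  n_snps = 100, bp_lower = c(1, 101) * 1e3,
                  bp_upper = c(100, 200) * 1e3, bp_mid = c(50, 150) * 1e3,
                  col_first = 1, col_last = 2,
                  percent_varA = c(0.2, 0.9))
  f <- tempfile(fileext = ".png")
  md <- plot_manhattan(v, file = f)
  expect_true(file.exists(f))
  expect_identical(md$bp, c(50000, 150000))
  unlink(f)
})
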