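design <- pulse_design()

test_that("pair matching is set intersection with protein-data flags", {
  pm <- match_pairs(c("A", "B", "C"), c("B", "C", "D"),
                    protein_universe = c("B", "C", "D", "E"))
  expect_setequal(pm$pairs, c("B", "C"))
  expect_equal(pm$transcript_flags$has_protein_data, c(FALSE, TRUE, TRUE))
  expect_equal(pm$transcript_flags$is_pair, c(FALSE, TRUE, TRUE))
  expect_length(match_pairs(c("A", "B"), c("C", "D"), c("C", "D"))$pairs, 0)
  expect_error(match_pairs(c("A", "A"), "B", "B"), "duplicate")
})

test_that("category partition reproduces the published worked example", {
  # 9514 evaluated mRNAs, 3852 evaluated proteins, genome 9974;
  # 1128 regulated mRNAs of which 381 have protein data and 34 are pairs;
  # 57 regulated proteins
  mrna_universe <- sprintf("g%04d", 1:9514)
  pairs <- mrna_universe[1:34]
  buffered <- mrna_universe[35:381]
  no_pdata <- mrna_universe[382:1128]
  protein_universe <- c(mrna_universe[1:381],
                        sprintf("p%04d", 1:(3852 - 381)))
  t_reg <- c(pairs, buffered, no_pdata)
  p_reg <- c(pairs, sprintf("p%04d", 1:23))
  part <- partition_categories(t_reg, p_reg, mrna_universe, protein_universe,
                               n_genome = 9974)
  expect_equal(part$n_protein_only, 23)
  expect_equal(part$n_mrna_only_with_protein_data, 347)
  expect_equal(part$n_mrna_only_no_protein_data, 747)
  expect_equal(part$n_pairs, 34)
  empty <- partition_categories(character(), character(), mrna_universe,
                                protein_universe, n_genome = 9974)
  expect_equal(empty$n_pairs + empty$n_protein_only +
                 empty$n_mrna_only_with_protein_data, 0)
  expect_error(partition_categories("zz", character(), mrna_universe,
                                    protein_universe, 9974), "universe")
})

test_that("partition identities hold on random call sets", {
  set.seed(21)
  for (i in 1:20) {
    uni_t <- sprintf("f%03d", 1:300)
    uni_p <- sample(uni_t, 150)
    t_reg <- sample(uni_t, rpois(1, 40))
    p_reg <- sample(uni_p, rpois(1, 15))
    part <- partition_categories(t_reg, p_reg, uni_t, uni_p, n_genome = 400)
    expect_equal(part$n_pairs + part$n_mrna_only_with_protein_data +
                   part$n_mrna_only_no_protein_data, part$n_mrna_regulated)
    expect_equal(part$n_pairs + part$n_protein_only, part$n_protein_regulated)
    expect_true(all(unlist(part) >= 0))
  }
})

make_pair_profiles <- function(X, Y) {
  conds_t <- design_conditions(design, "transcript")$condition
  conds_p <- design_conditions(design, "protein")$condition
  lt <- cbind(0, X); dimnames(lt) <- list(rownames(X), conds_t)
  lp <- cbind(0, Y); dimnames(lp) <- list(rownames(Y), conds_p)
  list(t = make_profiles(lt, NULL, design),
       p = make_profiles(lp, NULL, design, layer = "protein"))
}

test_that("lag grid: shifted copy, brute-force oracle, sign and degenerate cases", {
  set.seed(31)
  n <- 10
  X <- matrix(rnorm(n * 5), n, dimnames = list(sprintf("q%02d", 1:n), NULL))
  Y <- cbind(rnorm(n), X[, 1:4])         # protein = transcript shifted one index
  rownames(Y) <- rownames(X)
  pp <- make_pair_profiles(X, Y)
  g <- lag_correlation(rownames(X), pp$t, pp$p)
  for (i in 1:4) expect_equal(g$r[i, i + 1], 1, tolerance = 1e-9)
  # independent brute-force Pearson recomputation
  for (cell in list(c(1, 1), c(3, 4), c(5, 2)))
    expect_equal(g$r[cell[1], cell[2]],
                 pearson_brute(X[, cell[1]], Y[, cell[2]]), tolerance = 1e-12)
  # anti-correlated pairs
  Y2 <- -X
  rownames(Y2) <- rownames(X)
  g2 <- lag_correlation(rownames(X), pp$t, make_pair_profiles(X, Y2)$p)
  expect_equal(g2$r[2, 2], -1, tolerance = 1e-12)
  # constant coordinate -> undefined cell
  Y3 <- Y; Y3[, 3] <- 5
  g3 <- lag_correlation(rownames(X), pp$t, make_pair_profiles(X, Y3)$p)
  expect_true(all(is.na(g3$r[, 3])))
  expect_error(lag_correlation(rownames(X)[1:2], pp$t, pp$p), ">= 3")
  # order invariance under pair permutation
  g4 <- lag_correlation(rev(rownames(X)), pp$t, pp$p)
  expect_equal(g$r, g4$r)
})

test_that("peak-lag estimate: arithmetic, tie to smallest lag, error on empty grid", {
  set.seed(32)
  X <- matrix(rnorm(8 * 5), 8, dimnames = list(sprintf("q%d", 1:8), NULL))
  Y <- matrix(rnorm(8 * 5), 8, dimnames = list(sprintf("q%d", 1:8), NULL))
  Y[, 4] <- X[, 3]                       # unique maximum at (25 min, 115 min)
  pp <- make_pair_profiles(X, Y)
  est <- estimate_peak_lag(lag_correlation(rownames(X), pp$t, pp$p))
  expect_equal(est$lag_minutes, 90)
  expect_equal(est$transcript_condition, "5L25D")
  expect_equal(est$protein_condition, "5L115D")
  # symmetric tie: both perfect, lag 30 (25->55) vs lag 90 (25->115)
  Y2 <- Y; Y2[, 3] <- X[, 3]
  est2 <- estimate_peak_lag(lag_correlation(rownames(X), pp$t,
                                            make_pair_profiles(X, Y2)$p))
  expect_equal(est2$lag_minutes, 30)
  g <- lag_correlation(rownames(X), pp$t, pp$p)
  g$r2[] <- NA
  expect_error(estimate_peak_lag(g), "undefined")
})

test_that("paired profile export is long, ordered, round-trips, and shows positive delay", {
  set.seed(33)
  X <- matrix(rnorm(3 * 5), 3, dimnames = list(c("a", "b", "c"), NULL))
  Y <- matrix(rnorm(3 * 5), 3, dimnames = list(c("a", "b", "c"), NULL))
  pp <- make_pair_profiles(X, Y)
  tab <- paired_profile_export("a", pp$t, pp$p)
  expect_equal(nrow(tab), 10)            # 5 + 5 conditions
  expect_equal(unique(tab$layer), c("transcript", "protein"))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(f)
  expect_equal(back$log2fc, tab$log2fc)
  # a noise-free concordant gene's exported protein series peaks later than its mRNA series
  sim <- simulate_light_pulse(c(concordant = 1, null = 30), noise = no_noise(),
                              seed = 5)
  tp <- fold_changes(normalize_library(sim$transcript), sim$design)
  pv <- remove_batch(vst_transform(sim$protein))
  ppr <- protein_profiles(pv, sim$design)
  gid <- sim$truth$gene_id[sim$truth$reg_class == "concordant"]
  ex <- paired_profile_export(gid, tp, ppr)
  tr <- ex[ex$layer == "transcript", ]; pr <- ex[ex$layer == "protein", ]
  expect_gt(pr$minutes[which.max(pr$log2fc)], tr$minutes[which.max(tr$log2fc)])
})
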