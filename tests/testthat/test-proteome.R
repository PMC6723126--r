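design <- pulse_design()
stp <- sample_table(design, "protein")

test_that("glog transform: scale-pair calibration, monotonicity, log2 limit", {
  set.seed(1)
  x1 <- rlnorm(300, 8, 1)
  mat <- cbind(s1 = x1, s2 = 3 * x1)          # exact scale factor
  v <- vst_transform(mat)
  expect_equal(median(v[, 1]), median(v[, 2]), tolerance = 1e-6)
  expect_equal(v[, 1], v[, 2], tolerance = 1e-9)   # identical after calibration
  ord <- order(x1)
  expect_true(all(diff(v[ord, 1]) > 0))            # strictly monotone
  # large-intensity differences approach log2 ratios
  big <- cbind(a = c(x1, 1e7, 2e7))
  vb <- vst_transform(big)
  expect_equal(unname(vb[302, 1] - vb[301, 1]), 1, tolerance = 1e-3)
  # zero-MAD sample falls back with a warning
  expect_warning(vst_transform(cbind(k = rep(5, 10))), "zero MAD")
})

test_that("batch removal: injected offsets, idempotence, limma cross-check", {
  ids <- sprintf("p%02d", 1:20)
  const <- matrix(5, 20, 18, dimnames = list(ids, stp$sample))
  off <- c(1, -1, 0)[stp$replicate]
  corrected <- remove_batch(sweep(const, 2, off, "+"))
  expect_equal(unname(corrected), unname(const), tolerance = 1e-9)
  # single batch: unchanged
  one <- const[, stp$replicate == 1]
  expect_equal(remove_batch(one, batch = rep("R1", ncol(one))), one)
  # idempotence: re-estimated batch effects are zero
  set.seed(2)
  noisy <- const + matrix(rnorm(20 * 18), 20, 18) + sweep(const * 0, 2, off, "+")
  once <- remove_batch(noisy); twice <- remove_batch(once)
  expect_equal(once, twice, tolerance = 1e-9)
  # cross-check against limma on complete data
  lm_corr <- limma::removeBatchEffect(noisy, batch = stp$batch)
  expect_equal(unname(once), unname(lm_corr), tolerance = 1e-8)
})

test_that("presence filter implements the two-of-three rule with correct overlap counts", {
  ids <- c("all3", "r1r2", "r2r3", "only1", "only3")
  mat <- matrix(1, 5, 18, dimnames = list(ids, stp$sample))
  mat["r1r2", stp$replicate == 3] <- NA
  mat["r2r3", stp$replicate == 1] <- NA
  mat["only1", stp$replicate != 1] <- NA
  mat["only3", stp$replicate != 3] <- NA
  f <- filter_presence(mat)
  expect_setequal(rownames(f$matrix), c("all3", "r1r2", "r2r3"))
  expect_false(anyNA(f$matrix["all3", ]))
  expect_equal(f$presence$n_detected[f$presence$protein_id == "only1"], 1L)
  expect_equal(f$overlap[["R1+R2+R3"]], 1L)
  expect_equal(f$overlap[["R1+R2"]], 1L)
  expect_equal(f$overlap[["R2+R3"]], 1L)
  expect_equal(f$overlap[["R1"]], 1L)
  expect_equal(f$overlap[["R3"]], 1L)
})

test_that("kNN imputation: identity, hand-computed toy, beats column means", {
  set.seed(4)
  full <- matrix(rnorm(40 * 18, 10), 40, 18, dimnames = list(sprintf("p%02d", 1:40), stp$sample))
  expect_identical(knn_impute(full), full)
  # 4-point toy with hand-computable weighted mean, k = 2
  toy <- rbind(target = c(1, 2, NA),
               n1 = c(1, 2, 10),       # distance 0 on observed columns
               n2 = c(1, 3, 20),       # distance 1
               n3 = c(5, 9, 30))       # distance sqrt(16+49)
  colnames(toy) <- c("c1", "c2", "c3")
  imp <- knn_impute(toy, k = 2)
  expect_equal(imp["target", "c3"], 10)   # zero-distance neighbour wins alone
  toy2 <- toy; toy2["n1", 1:2] <- c(1, 2.5)    # distances 0.5 and 1
  imp2 <- knn_impute(toy2, k = 2)
  w <- c(1 / 0.5, 1 / 1); w <- w / sum(w)
  expect_equal(imp2["target", "c3"], sum(w * c(10, 20)), tolerance = 1e-12)
  expect_equal(imp2["target", c("c1", "c2")], toy2["target", c("c1", "c2")])
  # masking experiment: kNN imputation error below column-mean imputation
  for (s in 1:5) {
    sim <- simulate_light_pulse(c(concordant = 40, null = 160), seed = s)
    v <- remove_batch(vst_transform(sim$protein))
    v <- v[rowSums(is.na(v)) == 0, ]
    set.seed(s)
    hidden <- v
    hidden[matrix(runif(length(v)) < 0.05, nrow(v))] <- NA
    hidden[rowSums(!is.na(hidden)) == 0, 1] <- v[rowSums(!is.na(hidden)) == 0, 1]
    idx <- is.na(hidden)
    imp <- knn_impute(hidden, k = 10)
    cm <- matrix(colMeans(hidden, na.rm = TRUE), nrow(v), ncol(v), byrow = TRUE)
    expect_lt(sqrt(mean((imp[idx] - v[idx])^2)),
              sqrt(mean((cm[idx] - v[idx])^2)))
  }
  expect_error(knn_impute(rbind(a = c(NA, 1), b = c(NA, 2))), "no fully observed")
})

test_that("moderated protein test: null convention, BH oracle, weight-zero equivalence", {
  ids <- sprintf("p%02d", 1:10)
  const <- matrix(7, 10, 18, dimnames = list(ids, stp$sample))
  prof0 <- protein_profiles(const, design)
  expect_true(all(prof0$raw_p == 1))
  expect_true(all(prof0$adj_p == 1))
  expect_true(all(prof0$log2fc == 0))
  # Benjamini-Hochberg: hand-applied step-up on {0.01..0.04}
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(11)
  pr <- runif(200)
  expect_equal(stats::p.adjust(pr, "BH"), bh_brute(pr), tolerance = 1e-12)
  # weight 0 recovers the plain paired one-sample t-test
  set.seed(12)
  mat <- matrix(rnorm(15 * 18, 10), 15, 18, dimnames = list(sprintf("p%02d", 1:15), stp$sample))
  prof <- protein_profiles(mat, design, moderation_weight = 0)
  for (i in 1:15) {
    d <- mat[i, stp$sample[stp$condition == "5L55D"][order(stp$replicate[stp$condition == "5L55D"])]] -
      mat[i, stp$sample[stp$is_control][order(stp$replicate[stp$is_control])]]
    expect_equal(unname(prof$raw_p[i, "5L55D"]), stats::t.test(d)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("protein regulation rule and final-peak summary", {
  conds <- design_conditions(design, "protein")$condition
  nc <- conds[-1]
  lfc <- matrix(0, 2, 6, dimnames = list(c("a", "b"), conds))
  adj <- matrix(1, 2, 5, dimnames = list(c("a", "b"), nc))
  lfc["a", "5L235D"] <- 1.3; adj["a", "5L235D"] <- 0.2   # fold ok, FDR fails
  lfc["b", "5L235D"] <- 1.3; adj["b", "5L235D"] <- 0.01
  prof <- make_profiles(lfc, adj, design, layer = "protein", adj_p = adj)
  calls <- call_regulated_proteins(prof)
  expect_false(calls$regulated[1])
  expect_true(calls$regulated[2])
  expect_true(calls$peak_is_final[2])
  # 57 regulated, 6 peaking earlier -> 89.5% at the final time point
  fake <- data.frame(regulated = rep(TRUE, 57),
                     peak_is_final = rep(c(FALSE, TRUE), c(6, 51)))
  s <- peak_time_summary(fake)
  expect_equal(s$final_pct, 89.5)
  expect_equal(s$n_earlier, 6)
})

test_that("observed values survive the pipeline unchanged; run offsets do not flip calls", {
  sim <- simulate_light_pulse(c(concordant = 30, null = 120), seed = 6)
  v <- remove_batch(vst_transform(sim$protein))
  f <- filter_presence(v)
  imp <- knn_impute(f$matrix)
  obs <- !is.na(f$matrix)
  expect_identical(imp[obs], f$matrix[obs])
  # additive per-run constants on complete transformed data: identical calls
  full <- imp
  prof_a <- protein_profiles(remove_batch(full), design)
  shifted <- full + c(0.7, -0.4, 0.2)[stp$replicate[match(colnames(full), stp$sample)]]
  prof_b <- protein_profiles(remove_batch(shifted), design)
  expect_equal(prof_a$log2fc, prof_b$log2fc, tolerance = 1e-9)
  expect_equal(call_regulated_proteins(prof_a)$regulated,
               call_regulated_proteins(prof_b)$regulated)
})
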