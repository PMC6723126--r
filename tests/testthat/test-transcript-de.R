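design <- pulse_design()
st <- sample_table(design, "transcript")

test_that("library normalization: identity, doubled sample, simulated recovery", {
  set.seed(1)
  v <- rpois(50, 100) + 1
  base <- matrix(v, 50, 18, dimnames = list(sprintf("g%02d", 1:50), st$sample))
  norm <- normalize_library(base)
  expect_equal(unname(attr(norm, "size_factors")), rep(1, 18))
  expect_equal(unname(norm), unname(base), ignore_attr = TRUE)
  doubled <- base
  doubled[, 4] <- 2 * doubled[, 4]
  f <- attr(normalize_library(doubled), "size_factors")
  expect_equal(unname(f[4]), 2, tolerance = 1e-9)
  expect_equal(unname(f[-4]), rep(1, 17), tolerance = 1e-9)
  # factors recover simulated library sizes up to a common constant
  libs <- exp(seq(-0.4, 0.4, length.out = 18))
  nm <- no_noise(); nm$library_sizes <- libs
  sim <- simulate_light_pulse(c(null = 60), noise = nm, seed = 1)
  f2 <- attr(normalize_library(sim$transcript), "size_factors")
  expect_equal(unname(f2 / f2[1]), libs / libs[1], tolerance = 1e-6)
})

test_that("fold-changes: control zero, exact arithmetic, brute-force oracle", {
  vals <- list(g1 = c(10, 40, 10, 10, 10, 10),   # DD then 5 pulse conditions
               g2 = c(8, 8, 8, 8, 8, 8))
  mat <- cond_matrix(vals, design, "transcript")
  prof <- fold_changes(mat, design, pseudocount = 0)
  expect_equal(unname(prof$log2fc[, "DD"]), c(0, 0))
  expect_equal(unname(prof$log2fc["g1", "5L0D"]), 2)      # 40 vs 10
  expect_equal(unname(prof$log2fc["g2", ]), rep(0, 6))
  set.seed(42)
  rmat <- matrix(rpois(20 * 18, 80), 20, 18,
                 dimnames = list(sprintf("g%02d", 1:20), st$sample))
  prof <- fold_changes(rmat, design, pseudocount = 1)
  for (cc in c("5L10D", "5L115D")) {
    a <- log2(rmat[, st$sample[st$condition == cc]] + 1)
    b <- log2(rmat[, st$sample[st$condition == "DD"]] + 1)
    expect_equal(prof$log2fc[, cc], rowMeans(a) - rowMeans(b), tolerance = 1e-9)
    pv <- vapply(1:20, function(i)
      stats::t.test(a[i, ], b[i, ])$p.value, numeric(1))
    expect_equal(unname(prof$raw_p[, cc]), pv, tolerance = 1e-9)
  }
})

test_that("Welch test conventions: identical groups give p = 1", {
  vals <- list(gA = c(5, 5, 5, 5, 5, 5))
  mat <- cond_matrix(vals, design, "transcript")
  expect_equal(test_condition(mat, design, "5L10D"), 1)
  # {1,2,3} vs {1,2,3} on the raw scale
  mat2 <- mat
  mat2[1, st$sample[st$condition == "DD"]] <- c(1, 2, 3)
  mat2[1, st$sample[st$condition == "5L10D"]] <- c(1, 2, 3)
  expect_equal(test_condition(mat2, design, "5L10D"), 1, tolerance = 1e-12)
})

test_that("regulation rule: fold and significance cutoffs are both required", {
  conds <- design_conditions(design, "transcript")$condition
  nc <- conds[-1]
  mk <- function(lfc_row, p_row) {
    lfc <- matrix(0, 2, 6, dimnames = list(c("a", "b"), conds))
    p <- matrix(1, 2, 5, dimnames = list(c("a", "b"), nc))
    lfc["a", nc] <- lfc_row$a; p["a", ] <- p_row$a
    lfc["b", nc] <- lfc_row$b; p["b", ] <- p_row$b
    make_profiles(lfc, p, design)
  }
  prof <- mk(lfc_row = list(a = c(0.9, 0.5, 0, 0, 0),      # significant but < twofold
                            b = c(0, 1.2, 0, 0, 0)),       # regulated at 10 min
             p_row = list(a = c(1e-6, 1e-6, 1, 1, 1),
                          b = c(0.5, 0.003, 1, 1, 1)))
  calls <- call_regulated_transcripts(prof)
  expect_false(calls$regulated[calls$feature_id == "a"])
  b <- calls[calls$feature_id == "b", ]
  expect_true(b$regulated)
  expect_equal(b$direction, "up")
  expect_equal(b$peak_condition, "5L10D")
  expect_equal(b$timing, "early")
})

test_that("calling is monotone in both thresholds", {
  set.seed(5)
  conds <- design_conditions(design, "transcript")$condition
  nc <- conds[-1]
  n <- 200
  lfc <- cbind(0, matrix(rnorm(n * 5, 0, 1.2), n))
  dimnames(lfc) <- list(sprintf("g%03d", 1:n), conds)
  p <- matrix(runif(n * 5), n, dimnames = list(rownames(lfc), nc))
  prof <- make_profiles(lfc, p, design)
  base <- call_regulated_transcripts(prof, p_threshold = 0.01, fc_threshold = 2)
  looser_fc <- call_regulated_transcripts(prof, p_threshold = 0.01, fc_threshold = 1.5)
  looser_p <- call_regulated_transcripts(prof, p_threshold = 0.05, fc_threshold = 2)
  expect_true(all(looser_fc$regulated[base$regulated]))
  expect_true(all(looser_p$regulated[base$regulated]))
})

test_that("permuting replicate labels within a condition changes nothing", {
  set.seed(9)
  mat <- matrix(rpois(30 * 18, 60), 30, 18,
                dimnames = list(sprintf("g%02d", 1:30), st$sample))
  perm <- mat
  sw <- st$sample[st$condition == "5L25D"]
  perm[, sw] <- perm[, sw[c(3, 1, 2)]]
  a <- fold_changes(mat, design); b <- fold_changes(perm, design)
  expect_equal(a$log2fc, b$log2fc)
  expect_equal(a$raw_p, b$raw_p)
})

test_that("timing classification respects the inclusive 25-min boundary", {
  expect_equal(classify_timing(c(0, 25, 55, 115)), c("early", "early", "late", "late"))
  calls <- data.frame(regulated = c(TRUE, FALSE), peak_minutes = c(10, NA))
  expect_error(classify_timing(calls), "unregulated")
})

test_that("PCA summary: duplicates, rank-1 variance, exact reconstruction", {
  conds <- design_conditions(design, "transcript")$condition
  set.seed(3)
  lfc <- cbind(0, matrix(rnorm(50 * 5), 50))
  dimnames(lfc) <- list(sprintf("g%02d", 1:50), conds)
  lfc[, "5L10D"] <- lfc[, "5L0D"]        # two identical conditions
  prof <- make_profiles(lfc, NULL, design)
  pc <- pca_summary(prof)
  expect_equal(pc$scores["5L0D", ], pc$scores["5L10D", ])
  expect_true(all(pc$rotation[1, ] >= 0))
  # rank-1: condition profiles proportional to one pattern
  v <- rnorm(50)
  lfc1 <- t(outer(c(0, 3, 2, 1, 0.5, 0.1), v))
  dimnames(lfc1) <- dimnames(t(matrix(0, 6, 50, dimnames = list(conds, rownames(lfc)))))
  prof1 <- make_profiles(lfc1, NULL, design)
  pc1 <- pca_summary(prof1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-9)
  # full reconstruction
  X <- t(prof$log2fc)
  rec <- pc$scores %*% t(pc$rotation) + rep(pc$center, each = nrow(X))
  expect_equal(unname(rec), unname(X), tolerance = 1e-9)
  # constant matrix errors
  lfc0 <- matrix(1, 6, 50, dimnames = list(conds, rownames(lfc)))
  expect_error(pca_summary(make_profiles(t(lfc0), NULL, design)), "constant")
})
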