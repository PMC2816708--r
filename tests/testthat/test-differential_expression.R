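test_that("per-gene t-test matches the hand-computed pooled statistic", {
  mat <- rbind(g1 = c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9),
               g2 = c(5, 5, 5, 5, 5, 5))
  cond <- rep(c("control", "treated"), each = 3)
  tt <- ttest_per_gene(mat, cond)
  expect_equal(tt$t[1], 12.24745, tolerance = 1e-5)
  expect_lt(tt$p_raw[1], 0.001)
  expect_equal(tt$df[1], 4)
  # identical groups -> p = 1
  expect_equal(tt$p_raw[2], 1)
  # label swap flips t, keeps p
  sw <- ttest_per_gene(mat, rep(c("treated", "control"), each = 3))
  expect_equal(sw$t[1], -tt$t[1])
  expect_equal(sw$p_raw, tt$p_raw)
  # matches the generic t-test implementation on random data
  set.seed(7)
  rmat <- matrix(rnorm(60), 10)
  rt <- ttest_per_gene(rmat, cond)
  for (i in c(1, 5, 10)) {
    ref <- stats::t.test(rmat[i, 4:6], rmat[i, 1:3], var.equal = TRUE)
    expect_equal(rt$t[i], unname(ref$statistic))
    expect_equal(rt$p_raw[i], ref$p.value)
  }
  expect_error(ttest_per_gene(mat[, c(1, 4)], c("a", "b")), "2 replicates")
})

test_that("BH adjustment equals the closed-form step-up recursion", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle on random p-vectors
  step_up <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(13)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  # permutation invariance (matched by position)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("the DE filter cascade applies fold-change, raw-p and q gates", {
  genes <- sprintf("g%03d", 1:40)
  sim <- sim_expression(genes, n_reps = 3, de_fraction = 1 / 40,
                        lfc_magnitude = 1, noise_sd = 0, seed = 3)
  de <- call_de(sim$mat, sim$condition)
  planted <- names(sim$truth)
  expect_equal(abs(de$fc_signed[de$gene_id == planted]), 2)
  expect_equal(de$direction[de$gene_id == planted],
               if (sim$truth[[1]] > 0) "up" else "down")
  expect_true(all(de$direction[de$gene_id != planted] == "ns"))

  # a strong p-value cannot rescue a sub-threshold fold change
  mat <- rbind(g1 = c(rep(0, 50), rep(log2(1.1), 50)))
  mat <- mat + matrix(rnorm(100, 0, 1e-4), 1)
  rownames(mat) <- "g1"
  de2 <- call_de(mat, rep(c("control", "treated"), each = 50))
  expect_lt(de2$p_raw, 1e-9)
  expect_equal(de2$direction, "ns")

  expect_error(call_de(mat, rep(c("c", "t"), each = 50), fc_min = 0.9),
               ">= 1")
})

test_that("median centering is exact, idempotent and a per-gene shift", {
  mat <- rbind(a = 1:6, b = c(2, 4, 8, 16, 32, 64))
  cen <- median_center(mat)
  expect_equal(apply(cen, 1, stats::median), c(a = 0, b = 0))
  expect_equal(median_center(cen), cen)
  expect_equal(unique(round(mat - cen, 12)[1, ]), 3.5)
  expect_warning(median_center(rbind(mat, z = rep(NA_real_, 6))), "dropped")
})

test_that("cross-comparison decomposes shared genes disjointly", {
  mk <- function(ids, dirs) {
    out <- data.frame(gene_id = ids, direction = dirs,
                      stringsAsFactors = FALSE)
    class(out) <- c("de_result", "data.frame")
    out
  }
  a <- mk(c("g1", "g2", "g6", "g9"), c("up", "up", "down", "ns"))
  b <- mk(c("g1", "g6", "g7", "g2"), c("up", "up", "down", "ns"))
  cc <- cross_compare(a, b)
  expect_equal(cc$shared, c("g1", "g6"))
  expect_equal(cc$co_up, "g1")
  expect_equal(cc$opposite, "g6")
  expect_equal(cc$exclusive_a, "g2")
  expect_equal(cc$exclusive_b, "g7")
  # partition identity
  expect_equal(cc$counts[["shared"]],
               cc$counts[["co_up"]] + cc$counts[["co_down"]] +
                 cc$counts[["opposite"]])

  # disjoint responsive sets
  d <- cross_compare(mk("g1", "up"), mk("g2", "down"))
  expect_length(d$shared, 0)
})

test_that("cross-comparison recovers planted shared and opposite genes exactly", {
  genes <- sprintf("g%03d", 1:200)
  # plant: 10 co-up, 8 co-down, 6 opposite, 5 exclusive to each line
  sets <- list(co_up = genes[1:10], co_down = genes[11:18],
               opposite = genes[19:24], ex_a = genes[25:29],
               ex_b = genes[30:34])
  shift <- function(ids, sign) stats::setNames(rep(sign, length(ids)), ids)
  mk_mat <- function(truth, seed) {
    sim <- sim_expression(genes, n_reps = 3, de_fraction = 0,
                          noise_sd = 0.05, seed = seed)
    mat <- sim$mat
    mat[names(truth), 4:6] <- mat[names(truth), 4:6] + 2 * truth
    mat
  }
  truth_a <- c(shift(sets$co_up, 1), shift(sets$co_down, -1),
               shift(sets$opposite, 1), shift(sets$ex_a, 1))
  truth_b <- c(shift(sets$co_up, 1), shift(sets$co_down, -1),
               shift(sets$opposite, -1), shift(sets$ex_b, -1))
  cond <- rep(c("control", "treated"), each = 3)
  cc <- cross_compare(call_de(mk_mat(truth_a, 21), cond),
                      call_de(mk_mat(truth_b, 22), cond))
  expect_setequal(cc$co_up, sets$co_up)
  expect_setequal(cc$co_down, sets$co_down)
  expect_setequal(cc$opposite, sets$opposite)
  expect_setequal(cc$exclusive_a, sets$ex_a)
  expect_setequal(cc$exclusive_b, sets$ex_b)
})

test_that("the F-test screen flags between-group structure", {
  set.seed(31)
  mat <- matrix(rnorm(50 * 12), 50)
  rownames(mat) <- sprintf("g%02d", 1:50)
  groups <- rep(letters[1:4], each = 3)
  mat[1:5, groups == "d"] <- mat[1:5, groups == "d"] + 6
  fs <- ftest_screen(mat, groups)
  expect_true(all(fs$significant[1:5]))
  expect_lt(mean(fs$significant[-(1:5)]), 0.2)
  ref <- stats::anova(stats::lm(mat[1, ] ~ groups))
  expect_equal(fs$f[1], ref$`F value`[1])
  expect_equal(fs$p_raw[1], ref$`Pr(>F)`[1])
})
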