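test_that("percent PPI follows 100*(1 - PP/P) and is scale invariant", {
  expect_equal(percent_ppi(10, 5), 50)
  expect_equal(percent_ppi(10, 10), 0)
  expect_equal(percent_ppi(10, 12), -20)
  expect_true(is.na(percent_ppi(0, 5)))
  expect_true(is.na(percent_ppi(-1, 5)))
  set.seed(51)
  for (i in 1:20) {
    p <- runif(1, 1, 50); pp <- runif(1, 0, 60); k <- runif(1, 0.1, 10)
    expect_equal(percent_ppi(k * p, k * pp), percent_ppi(p, pp))
  }
  expect_equal(ppi_from_amplitudes(c(P = 10, P30 = 6.5, P60 = 4.5,
                                     P120 = 6.5)),
               c(PPI30 = 35, PPI60 = 55, PPI120 = 35))
})

test_that("omnibus test gates on normality and matches Friedman by hand", {
  # every subject flat across conditions (and clearly non-Gaussian, so the
  # gate routes to Friedman): statistic 0, p = 1
  m <- matrix(rep(c(1, 1.1, 1.2, 1.3, 1.4, 100), times = 3), nrow = 6)
  colnames(m) <- c("PPI30", "PPI60", "PPI120")
  r <- omnibus_condition_test(m)
  expect_equal(r$test, "friedman")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # small integer table against the rank-formula oracle
  m2 <- matrix(c(1, 2, 3,
                 2, 4, 6,
                 3, 1, 5,
                 7, 6, 9), nrow = 4, byrow = TRUE)
  colnames(m2) <- c("a", "b", "c")
  m2j <- m2 + matrix(seq(0, 0.011, by = 0.001), 4, 3)  # break exact ties
  r2 <- omnibus_condition_test(m2j)
  if (r2$test == "friedman") {
    expect_equal(r2$statistic, friedman_oracle(m2j))
  }
  expect_equal(unname(stats::friedman.test(m2j)$statistic),
               friedman_oracle(m2j))

  # Gaussian table passes the gate and yields the RM-ANOVA F
  set.seed(52)
  m3 <- matrix(rnorm(24, mean = rep(c(0, 1, 0.5), each = 8)), nrow = 8)
  colnames(m3) <- c("a", "b", "c")
  r3 <- omnibus_condition_test(m3)
  expect_equal(r3$test, "rm_anova")
  expect_equal(r3$df, c(2, 14))
  expect_error(omnibus_condition_test(m3[1:2, ]), "3 complete")
})

test_that("Wilcoxon post hocs match exact enumeration, Bonferroni multiplies", {
  set.seed(53)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    p_r <- stats::wilcox.test(x, y, paired = TRUE)$p.value
    expect_equal(p_r, wilcoxon_exact_oracle(x, y))
  }

  m <- cbind(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  ph <- posthoc_pairwise(m, parametric = FALSE, pairs = "all")
  expect_equal(nrow(ph), 3)
  raw <- sapply(1:3, function(i) {
    wilcoxon_exact_oracle(m[, ph$a[i]], m[, ph$b[i]])
  })
  expect_equal(ph$p_value, pmin(3 * raw, 1))

  # all-ties pair yields p = 1 with a warning
  tied <- cbind(a = 1:6, b = 1:6)
  expect_warning(ph_t <- posthoc_pairwise(tied, parametric = FALSE),
                 "tied")
  expect_equal(ph_t$p_value, 1)

  # six positive, distinct differences: smallest exact two-sided p is 2/2^6
  # (a two-column table has a single pair, so Bonferroni leaves it unchanged)
  m6 <- cbind(a = (1:6) + c(10, 11, 12, 13, 14, 15), b = as.numeric(1:6))
  ph6 <- posthoc_pairwise(m6, parametric = FALSE, pairs = "all")
  expect_equal(ph6$p_value, 2 / 64)
  expect_equal(wilcoxon_exact_oracle(m6[, 1], m6[, 2]), 2 / 64)
})

test_that("Tukey post hocs come from the blocked fit and detect a planted gap", {
  set.seed(54)
  subj <- rnorm(10, sd = 2)
  m <- cbind(a = subj + rnorm(10, 0, 0.3),
             b = subj + rnorm(10, 3, 0.3),
             c = subj + rnorm(10, 0, 0.3))
  ph <- posthoc_pairwise(m, parametric = TRUE, pairs = "vs_first")
  expect_equal(ph$a, c("a", "a"))
  expect_lt(ph$p_value[ph$b == "b"], 0.01)
  expect_gt(ph$p_value[ph$b == "c"], 0.2)
})

# tau between two vectors through the module's correlation surface
cross_tau <- function(x, y) {
  n <- length(x)
  long <- rbind(
    data.frame(subject = seq_len(n), modality = "ASR", interval = "PPI60",
               ppi = x),
    data.frame(subject = seq_len(n), modality = "Fz", interval = "PPI60",
               ppi = y))
  ct <- cross_modality_correlation(long, electrodes = "Fz")
  ct$tau[ct$interval == "PPI60"]
}

test_that("Kendall tau-b matches pair-counting enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(cross_tau(x, x), 1)
  expect_equal(cross_tau(x, rev(x)), -1)
  y <- c(1, 2, 3, 4, 6, 5)                    # one swap
  expect_equal(cross_tau(x, y), kendall_oracle(x, y))
  set.seed(55)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(cross_tau(a, b), kendall_oracle(a, b))
  }
})

test_that("cross-modality correlation reports nine electrode-interval taus", {
  set.seed(56)
  subj <- sprintf("s%02d", 1:8)
  rows <- list()
  for (mod in c("ASR", "Fz", "Cz", "Pz")) {
    for (iv in c("PPI30", "PPI60", "PPI120")) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj, modality = mod, interval = iv, ppi = rnorm(8))
    }
  }
  long <- do.call(rbind, rows)
  ct <- cross_modality_correlation(long)
  expect_equal(nrow(ct), 9)
  expect_true(all(ct$n == 8))
  expect_true(all(abs(ct$tau) <= 1, na.rm = TRUE))
  one <- ct[ct$electrode == "Fz" & ct$interval == "PPI60", ]
  a <- long[long$modality == "ASR" & long$interval == "PPI60", "ppi"]
  b <- long[long$modality == "Fz" & long$interval == "PPI60", "ppi"]
  expect_equal(one$tau, kendall_oracle(a, b))

  # constant vector: tau undefined, reported missing
  long2 <- long
  long2$ppi[long2$modality == "Cz"] <- 1
  ct2 <- cross_modality_correlation(long2)
  expect_true(all(is.na(ct2$tau[ct2$electrode == "Cz"])))
})

test_that("the full battery produces the report structure with post hocs", {
  set.seed(57)
  subj <- sprintf("s%02d", 1:10)
  base <- rnorm(10, 20, 2)
  scale_by <- c(P = 1, P30 = 0.65, P60 = 0.45, P120 = 0.65)
  rows <- list()
  for (mod in c("ASR", "Fz")) {
    for (cond in names(scale_by)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj, modality = mod, condition = cond,
        amplitude = base * scale_by[[cond]] + rnorm(10, 0, 0.4))
    }
  }
  tab <- do.call(rbind, rows)
  rep <- ppi_statistics(tab)
  expect_true(all(c("ASR", "Fz", "kendall") %in% names(rep)))
  expect_lt(rep$ASR$amplitude_test$p_value, 0.05)
  expect_equal(nrow(rep$ASR$amplitude_posthoc), 3)   # P vs each prepulse
  expect_true(all(rep$ASR$amplitude_posthoc$a == "P"))
  expect_equal(unname(rep$ASR$amplitude_mean["P"]), mean(base),
               tolerance = 0.5)
  expect_equal(nrow(rep$kendall), 3)          # one electrode, three intervals
})
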