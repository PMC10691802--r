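test_that("partial eta squared from t matches the reported worked examples", {
  expect_equal(round(eta_p_from_t(4.12, 27), 2), 0.39)
  expect_equal(round(eta_p_from_t(4.33, 27), 2), 0.41)
  expect_equal(round(eta_p_from_t(2.77, 27), 2), 0.22)
  expect_equal(eta_p_from_t(0, 12), 0)
  # monotone in |t|, decreasing in df
  expect_true(all(diff(eta_p_from_t(seq(0, 5, 0.5), 20)) >= 0))
  expect_true(all(diff(eta_p_from_t(2, c(5, 10, 50, 200))) < 0))
  expect_error(eta_p_from_t(2, 0), "positive")
})

test_that("a two-condition rmANOVA equals the squared paired t-test", {
  set.seed(2)
  d <- tidyr::expand_grid(subject = 1:12, cond = c("a", "b"))
  d$value <- rnorm(nrow(d)) + 0.4 * (d$cond == "a")
  res <- rm_anova(d, "cond")
  wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "value")
  tt <- t.test(wide$a, wide$b, paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$eta_p2, eta_p_from_t(unname(tt$statistic), 11),
               tolerance = 1e-10)
})

test_that("a hand-worked 3-subject table matches the sums-of-squares oracle", {
  d <- tibble::tibble(
    subject = rep(1:3, each = 2),
    cond = rep(c("a", "b"), 3),
    value = c(4, 6, 5, 9, 3, 4)
  )
  # manual within-subject SS: effect and subject-by-effect interaction
  m <- matrix(d$value, nrow = 3, byrow = TRUE)
  cm <- colMeans(m)
  gm <- mean(m)
  ss_eff <- 3 * sum((cm - gm)^2)
  cent <- m - rowMeans(m) # remove subject means
  ss_err <- sum(sweep(cent, 2, colMeans(cent))^2)
  f_manual <- (ss_eff / 1) / (ss_err / 2)
  res <- rm_anova(d, "cond")
  expect_equal(res$F, f_manual, tolerance = 1e-10)
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 2)
})

test_that("factorial rmANOVA agrees with aov across all effects", {
  set.seed(7)
  d <- tidyr::expand_grid(subject = factor(1:9), drug = c("A", "B", "C"),
                          validity = c("i", "v"))
  d$value <- rnorm(nrow(d))
  mine <- rm_anova(d, c("drug", "validity"))
  a <- summary(aov(value ~ drug * validity +
                     Error(subject / (drug * validity)), data = d))
  f_aov <- c(
    a[["Error: subject:drug"]][[1]]["drug", "F value"],
    a[["Error: subject:validity"]][[1]]["validity", "F value"],
    a[["Error: subject:drug:validity"]][[1]]["drug:validity", "F value"]
  )
  expect_equal(mine$F, unname(f_aov), tolerance = 1e-8)
})

test_that("rmANOVA p-values are calibrated under the null", {
  set.seed(11)
  p <- replicate(400, {
    d <- tidyr::expand_grid(subject = 1:8, cond = c("a", "b", "c"))
    d$value <- rnorm(nrow(d))
    rm_anova(d, "cond")$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("missing cells are reported by name", {
  d <- tidyr::expand_grid(subject = 1:4, cond = c("a", "b"))
  d$value <- rnorm(nrow(d))
  expect_error(rm_anova(d[-1, ], "cond"), "incomplete")
})

test_that("the two-proportion z-test matches the pooled-variance formula", {
  res <- proportion_z_test(20, 28, 10, 28)
  pp <- 30 / 56
  z_manual <- (20 / 28 - 10 / 28) / sqrt(pp * (1 - pp) * (2 / 28))
  expect_equal(res$z, z_manual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  eq <- proportion_z_test(14, 28, 14, 28)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  extreme <- proportion_z_test(28, 28, 0, 28)
  expect_gt(abs(extreme$z), 7)
  expect_error(proportion_z_test(2, 0, 1, 5), "positive")
  expect_error(proportion_z_test(6, 5, 1, 5), "0 <= k <= n")
})

test_that("BIC Bayes factors satisfy the closed-form identities", {
  expect_equal(bf01_from_bic(100, 100), 1)
  expect_equal(bf01_from_bic(100, 100 + 2 * log(3)), 3)
  set.seed(3)
  d <- tidyr::expand_grid(subject = 1:10, cond = c("a", "b"))
  d$value <- rnorm(nrow(d))
  out <- bf01_approx(d, "cond", "cond")
  expect_true(out$approximation)
  expect_equal(out$bf01, bf01_from_bic(out$bic_null, out$bic_alt))
  expect_error(bf01_approx(d, "cond", "other"), "nest")
})

test_that("true-null data favors the null by BIC in the median", {
  set.seed(9)
  bfs <- replicate(100, {
    d <- tidyr::expand_grid(subject = 1:10, cond = c("a", "b"))
    d$value <- rnorm(nrow(d))
    bf01_approx(d, "cond", "cond")$bf01
  })
  expect_gt(median(bfs), 1)
})

test_that("cluster tests recover an injected window and match enumeration", {
  # power: strong effect in samples 30-60
  d <- make_rm_long(12, c("a", "b"), 80, seed = 21, effect = 1.5,
                    effect_samples = 30:60)
  res <- cluster_perm_rm_anova(d, "cond", n_perm = 500, seed = 2)
  sig <- res[res$p_perm < 0.05, ]
  expect_gte(nrow(sig), 1)
  hit <- unlist(sig$samples)
  expect_gte(length(intersect(hit, 30:60)) / 31, 0.8)

  # exactness: exhaustive enumeration against a brute-force oracle
  d3 <- make_rm_long(3, c("a", "b"), 4, seed = 5, effect = 6,
                     effect_samples = 1:4)
  res3 <- cluster_perm_rm_anova(d3, "cond", exhaustive = TRUE, seed = 1)
  expect_gte(nrow(res3), 1)
  # oracle: enumerate all 2^3 within-subject swaps by hand
  f_of <- function(swap) {
    dd <- d3
    for (s in which(swap)) {
      a_ix <- dd$subject == s & dd$cond == "a"
      b_ix <- dd$subject == s & dd$cond == "b"
      tmp <- dd$value[a_ix]
      dd$value[a_ix] <- dd$value[b_ix]
      dd$value[b_ix] <- tmp
    }
    sapply(1:4, function(sm) {
      rm_anova(dd[dd$sample == sm, ], "cond")$F
    })
  }
  crit <- qf(0.95, 1, 2)
  mass <- function(fv) {
    r <- rle(fv > crit)
    if (!any(r$values)) return(0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    max(sapply(which(r$values), function(k) sum(fv[starts[k]:ends[k]])))
  }
  null_masses <- sapply(0:7, function(code) {
    mass(f_of(as.logical(bitwAnd(bitwShiftR(code, 0:2), 1))))
  })
  obs_mass <- res3$mass[1]
  p_oracle <- max(mean(null_masses >= obs_mass - 1e-12), 1 / 8)
  expect_equal(res3$p_perm[1], p_oracle, tolerance = 1e-12)
})

test_that("one-sample cluster test matches exhaustive sign-flip enumeration", {
  set.seed(13)
  dat <- matrix(rnorm(4 * 6, mean = 1.2), nrow = 4)
  res <- cluster_perm_ttest_vs_zero(dat, exhaustive = TRUE)
  tstat <- function(m) colMeans(m) / (apply(m, 2, sd) / sqrt(nrow(m)))
  crit <- qt(0.975, 3)
  mass_abs <- function(tv) {
    sup <- tv > crit; sdn <- tv < -crit
    out <- 0
    for (mask in list(sup, sdn)) {
      r <- rle(mask)
      if (!any(r$values)) next
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      out <- max(out, max(sapply(which(r$values),
                                 function(k) abs(sum(tv[starts[k]:ends[k]])))))
    }
    out
  }
  null16 <- sapply(0:15, function(code) {
    flips <- ifelse(bitwAnd(bitwShiftR(code, 0:3), 1) == 1, -1, 1)
    mass_abs(tstat(dat * flips))
  })
  for (i in seq_len(nrow(res))) {
    p_oracle <- max(mean(null16 >= abs(res$mass[i]) - 1e-12), 1 / 16)
    expect_equal(res$p_perm[i], p_oracle, tolerance = 1e-12)
  }
})

test_that("an overwhelming constant offset spans nearly all samples", {
  set.seed(17)
  dat <- matrix(1 + 0.1 * rnorm(20 * 50), nrow = 20)
  res <- cluster_perm_ttest_vs_zero(dat, n_perm = 300, seed = 3)
  big <- res[which.max(res$end - res$start), ]
  expect_gte((big$end - big$start + 1) / 50, 0.95)
  expect_lt(big$p_perm, 0.05)
})

test_that("cluster p-values are invariant to monotone rescaling", {
  d <- make_rm_long(10, c("a", "b"), 40, seed = 31, effect = 1,
                    effect_samples = 10:25)
  r1 <- cluster_perm_rm_anova(d, "cond", n_perm = 300, seed = 4)
  d2 <- d
  d2$value <- d$value * 3.7 + 11
  r2 <- cluster_perm_rm_anova(d2, "cond", n_perm = 300, seed = 4)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$end, r2$end)
})

test_that("permutation tests are bit-reproducible under the seed", {
  d <- make_rm_long(8, c("a", "b"), 30, seed = 41, effect = 0.8,
                    effect_samples = 5:15)
  r1 <- cluster_perm_rm_anova(d, "cond", n_perm = 200, seed = 9)
  r2 <- cluster_perm_rm_anova(d, "cond", n_perm = 200, seed = 9)
  expect_identical(r1$p_perm, r2$p_perm)
  dat <- matrix(rnorm(6 * 20, 0.5), nrow = 6)
  t1 <- cluster_perm_ttest_vs_zero(dat, n_perm = 200, seed = 9)
  t2 <- cluster_perm_ttest_vs_zero(dat, n_perm = 200, seed = 9)
  expect_identical(t1$p_perm, t2$p_perm)
})

test_that("2D clustering uses 4-connectivity on the grid", {
  # two diagonal blobs must form separate clusters
  supra <- matrix(FALSE, 4, 4)
  supra[1:2, 1:2] <- TRUE
  supra[3:4, 3:4] <- TRUE
  cl <- cuedecide:::.find_clusters(as.vector(supra), grid = c(4, 4))
  expect_equal(length(cl), 2)
  supra[2, 3] <- TRUE # the bridge cell is 4-adjacent to both blobs
  cl2 <- cuedecide:::.find_clusters(as.vector(supra), grid = c(4, 4))
  expect_equal(length(cl2), 1)
})
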