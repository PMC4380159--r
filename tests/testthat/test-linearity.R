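q4 <- c(0, 0.05, 0.10, 0.20)

test_that("the reference-library filter is inclusive at the threshold", {
  refs <- c(3, 20, 21, 400, 19)
  counts <- cbind(0, round(outer(refs, q4[2:4] / 0.2)))
  counts[, 4] <- refs
  rownames(counts) <- paste0("Dvir\\g", 1:5)
  colnames(counts) <- paste0("lib", 1:4)
  tab <- count_table(counts,
                     libraries = data.frame(library_id = colnames(counts),
                                            protocol = "p",
                                            spike_fraction = q4))
  kept <- filter_spike_genes(tab, min_count = 20)
  expect_setequal(kept, c("Dvir\\g2", "Dvir\\g3", "Dvir\\g4"))
})

test_that("filtering degenerate tables warns or errors as appropriate", {
  tab <- toy_table()
  bg_only <- count_table(tab$counts[4:5, ], libraries = tab$libraries)
  expect_warning(kept <- filter_spike_genes(bg_only), "no spike")
  expect_length(kept, 0)
  no_spikein <- count_table(tab$counts,
                            libraries = data.frame(
                              library_id = colnames(tab$counts),
                              protocol = "p", spike_fraction = rep(0, 4)))
  expect_error(filter_spike_genes(no_spikein), "positive spike fraction")
})

test_that("fit_gene recovers the identity line and flags flat responses", {
  f <- fit_gene(q4, q4)
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)
  flat <- fit_gene(q4, rep(2.5, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(flat$r))
  expect_error(fit_gene(q4[1:2], c(1, 2)), "3 points")
  expect_error(fit_gene(rep(0.1, 4), c(1, 2, 3, 4)), "constant")
})

test_that("fit_gene matches lm() and cor() on fixed and random instances", {
  a <- c(0.01, 0.04, 0.12, 0.19)
  f <- fit_gene(q4, a)
  ref <- lm(a ~ q4)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-9)
  expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-9)
  expect_equal(f$r, cor(q4, a), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    q <- sort(runif(n))
    if (var(q) == 0) next
    y <- runif(n, 0, 10)
    f <- fit_gene(q, y)
    ref <- lm(y ~ q)
    expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-9)
    expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-9)
    expect_equal(f$r, cor(q, y), tolerance = 1e-9)
  }
})

test_that("protocol summaries match hand arithmetic", {
  fits <- data.frame(gene = c("a", "b"), slope = c(0.9, 1.1),
                     intercept = c(0.1, -0.1), r = c(0.9, 0.8))
  s <- summarize_protocol(fits, protocol = "p")
  expect_equal(s$mean_slope, 1)
  expect_equal(s$sd_slope, sqrt(0.02), tolerance = 1e-12)  # 0.14142...
  expect_equal(s$t_slope_vs_1, 0, tolerance = 1e-12)
  expect_equal(s$mean_intercept, 0)
  expect_equal(s$iqr_slope, 0.1, tolerance = 1e-12)
  expect_error(summarize_protocol(fits[1, ]), "at least 2")
})

test_that("zero-spread summaries flag the t statistics as undefined", {
  fits <- data.frame(gene = letters[1:3], slope = rep(1, 3),
                     intercept = rep(0, 3), r = rep(1, 3))
  s <- summarize_protocol(fits, "p")
  expect_equal(s$mean_slope, 1)
  expect_equal(s$sd_slope, 0)
  expect_true(is.na(s$t_slope_vs_1))
  expect_true(is.na(s$t_intercept_vs_0))
})

test_that("exact data Ahat = Q yields slope summaries (1, 0) with zero spread", {
  counts <- round(outer(c(100, 500, 2000, 40), q4 / 0.2))
  rownames(counts) <- paste0("Dvir\\g", 1:4)
  colnames(counts) <- paste0("l", 1:4)
  tab <- count_table(counts,
                     libraries = data.frame(library_id = colnames(counts),
                                            protocol = "exact",
                                            spike_fraction = q4))
  s <- summary(spikelin(tab, min_count = 20))
  expect_equal(s$mean_slope, 1, tolerance = 1e-12)
  expect_equal(s$sd_slope, 0, tolerance = 1e-12)
  expect_equal(s$mean_intercept, 0, tolerance = 1e-12)
  expect_equal(s$sd_intercept, 0, tolerance = 1e-12)
})

test_that("undefined correlations are excluded from mean_r but counted", {
  fits <- data.frame(gene = letters[1:4], slope = c(1, 1.2, 0.8, 1),
                     intercept = 0, r = c(0.9, NA, 0.7, NA))
  s <- summarize_protocol(fits, "p")
  expect_equal(s$mean_r, 0.8)
  expect_equal(s$n_r_undefined, 2L)
  expect_equal(s$n_genes, 4L)
})

test_that("protocol comparison handles identical and degenerate inputs", {
  f <- data.frame(gene = letters[1:5], r = c(0.9, 0.92, 0.95, 0.85, 0.99))
  same <- compare_protocols(f, f)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  g1 <- data.frame(gene = letters[1:10], r = rep(1, 10))
  g2 <- data.frame(gene = letters[1:10], r = rep(0.5, 10))
  deg <- compare_protocols(g1, g2)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(compare_protocols(f[0, ], f), "at least one")
})

test_that("protocol comparison p-values are uniform under the null", {
  set.seed(314)
  p <- vapply(1:500, function(i) {
    r1 <- rnorm(12, 0.9, 0.05)
    r2 <- rnorm(15, 0.9, 0.05)
    compare_protocols(data.frame(gene = 1:12, r = r1),
                      data.frame(gene = 1:15, r = r2))$p
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 1e-3)
})

test_that("deeper sequencing gives (non-strictly) higher mean correlation", {
  depths <- c(1e4, 1e5, 1e6, 1e7)
  mean_r <- sapply(depths, function(d) {
    mean(vapply(1:20, function(s) {
      cfg <- small_config(depth = d, seed = 100 + s)
      tab <- generate_experiment(cfg, run_seed = 200 + s)
      fit <- spikelin(tab, min_count = 20)
      mean(fit$fits$r, na.rm = TRUE)
    }, numeric(1)))
  })
  expect_true(all(diff(mean_r) > -0.002))
})
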