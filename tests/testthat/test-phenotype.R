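test_that("the egg color value is the mean of the three position readings", {
  expect_equal(egg_color_value(c(50, 52, 54)), 52)
  expect_equal(egg_color_value(c(55.5, 55.5, 55.5)), 55.5)
  expect_equal(round(egg_color_value(c(53.1, 54.2, 55.9)), 1), 54.4)
  expect_error(egg_color_value(c(50, 52)), "three")
})

test_that("weekly summaries reproduce the published variable coefficients", {
  tab <- read.delim(system.file("extdata", "eggshell_color_weekly.tsv",
                                package = "bspmeth"))
  cv <- round(tab$sd / tab$mean, 4)
  # exact at the printed precision for these weeks
  for (w in c(25, 30, 40, 45, 50, 60)) {
    i <- which(tab$week == w)
    expect_equal(cv[i], tab$cv[i])
  }
  # the remaining weeks differ only through rounding of the printed SD
  expect_true(all(abs(cv - tab$cv) <= 1e-4 + 1e-12))
  expect_equal(min(cv), 0.0479)
  expect_equal(max(cv), 0.0716)
  expect_equal(max(tab$sd), 4.07)
  expect_equal(range(c(tab$min, tab$max)), c(48.24, 65.55))
})

test_that("summarize_weeks computes sample statistics and rejects n < 2", {
  v <- c(5, 5, 5, 7, 9)
  wk <- c(1, 1, 1, 2, 2)
  s <- summarize_weeks(v, wk)
  expect_equal(s$sd[1], 0)
  expect_equal(s$cv[1], 0)
  expect_equal(s$mean[2], 8)
  expect_equal(s$sd[2], sd(c(7, 9)))
  expect_equal(s$min, c(5, 7))
  expect_equal(s$max, c(5, 9))
  expect_error(summarize_weeks(c(1, 2), c(1, 2)), "n >= 2")
  # recomputation from raw synthetic measurements matches to 1e-9
  cfg <- synth_config(seed = 31, color_n = rep(40L, 9))
  co <- generate_color(cfg)
  vals <- egg_color_values(co$color)
  s2 <- summarize_weeks(vals$value, vals$week)
  for (i in seq_len(nrow(s2))) {
    v <- vals$value[vals$week == s2$week[i]]
    expect_equal(s2$mean[i], mean(v), tolerance = 1e-9)
    expect_equal(s2$sd[i], sd(v), tolerance = 1e-9)
    expect_equal(s2$cv[i], sd(v) / mean(v), tolerance = 1e-9)
  }
})

test_that("one-way ANOVA behaves classically and degenerates gracefully", {
  expect_warning(res <- one_way_anova(rep(3, 10), rep(c("a", "b"), 5)),
                 "zero total variance")
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  set.seed(61)
  v <- c(rnorm(50, 0), rnorm(50, 5), rnorm(50, 10))
  g <- rep(c("a", "b", "c"), each = 50)
  res2 <- one_way_anova(v, g)
  expect_lt(res2$p, 1e-6)
  res3 <- one_way_anova(v + 100, g)
  expect_equal(res3$F, res2$F, tolerance = 1e-9)
  expect_error(one_way_anova(1:5, rep("a", 5)), "two groups")
})

test_that("compact letters satisfy the sharing invariant", {
  none <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(compact_letters(none)), c("a", "a", "a"))
  all_sig <- matrix(0.001, 3, 3, dimnames = list(1:3, 1:3))
  diag(all_sig) <- 1
  expect_equal(unname(compact_letters(all_sig)), c("a", "b", "c"))
  chain <- matrix(1, 3, 3, dimnames = list(1:3, 1:3))
  chain[1, 3] <- chain[3, 1] <- 0.01
  expect_equal(unname(compact_letters(chain)), c("a", "ab", "b"))
  # property: share a letter <=> not significant
  set.seed(71)
  for (k in 1:20) {
    g <- sample(3:6, 1)
    p <- matrix(1, g, g)
    p[upper.tri(p)] <- runif(g * (g - 1) / 2)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    lab <- as.character(seq_len(g))
    dimnames(p) <- list(lab, lab)
    let <- compact_letters(p, alpha = 0.3)
    sets <- strsplit(let, "")
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      expect_equal(share, p[i, j] >= 0.3,
                   label = sprintf("pair %d-%d (p=%.3f)", i, j, p[i, j]))
    }
  }
})

test_that("stage segmentation groups consecutive letter-sharing weeks", {
  one <- assign_stages(1:4, c("a", "a", "a", "a"), c(5, 5, 5, 5))
  expect_equal(nrow(one), 1L)
  st <- assign_stages(1:6, c("a", "a", "b", "b", "b", "c"),
                      c(53, 53, 56, 56, 56, 58))
  expect_equal(st$start_week, c(1, 3, 6))
  expect_equal(st$end_week, c(2, 5, 6))
  expect_equal(st$rank, c(1, 2, 3))
  # overlap chains split where the running intersection empties
  st2 <- assign_stages(1:3, c("a", "ab", "b"), c(1, 2, 3))
  expect_equal(nrow(st2), 2L)
})

test_that("planted three-level color means are recovered as three stages", {
  set.seed(81)
  means <- c(53.5, 53.5, 56.5, 56.5, 56.5, 56.5, 58.6, 58.6, 58.6)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    vals <- unlist(lapply(means, function(m) rnorm(150, m, 3)))
    wks <- rep(1:9, each = 150)
    pm <- tukey_pmatrix(vals, wks)
    lets <- compact_letters(pm)
    st <- assign_stages(1:9, lets[as.character(1:9)],
                        tapply(vals, wks, mean))
    if (nrow(st) == 3 && all(st$end_week == c(2, 6, 9))) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("2^-ddCt has its closed-form behavior", {
  mk <- function(weeks, dct) {
    do.call(rbind, lapply(seq_along(weeks), function(i)
      data.frame(sample_id = paste0("s", i), week = weeks[i],
                 gene_role = c("target", "reference"),
                 ct = c(20 + dct[i], 20), replicate = 1L)))
  }
  r <- ddct(mk(c(1, 2, 3), c(5, 6, 3)), calibrator_group = 1)
  expect_equal(r$rq, c(1, 0.5, 4))        # ddCt 0, 1, -2
  # equivariance under a global Ct shift
  tab <- mk(c(1, 2, 3), c(5, 6, 3))
  tab$ct <- tab$ct + 3.7
  expect_equal(ddct(tab, 1)$rq, r$rq)
  # planted folds at zero noise are recovered exactly
  cfg <- synth_config(seed = 91, weeks_meth = c(25L, 30L, 35L),
                      overall_rates = c(0.8, 0.85, 0.9),
                      folds = c(4, 2, 1), ct_noise_sd = 0,
                      samples_per_week = 2L)
  ctab <- generate_ct(cfg)$ct
  rr <- ddct(ctab, calibrator_group = 35)
  expect_equal(c(tapply(rr$rq, rr$week, mean)), c(`25` = 4, `30` = 2, `35` = 1))
  # missing reference Ct drops the sample with a warning
  bad <- mk(c(1, 2), c(5, 6))
  bad <- bad[!(bad$sample_id == "s2" & bad$gene_role == "reference"), ]
  expect_warning(out <- ddct(bad, 1), "no reference")
  expect_equal(nrow(out), 1L)
})
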