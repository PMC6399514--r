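test_that("the generator is deterministic given config and seed", {
  cfg <- synth_config(seed = 12, clones_per_week = 5L,
                      color_n = rep(10L, 9))
  a <- generate_reference(cfg); b <- generate_reference(cfg)
  expect_identical(a$ref$sequence, b$ref$sequence)
  expect_identical(generate_clones(a, cfg)$reads,
                   generate_clones(b, cfg)$reads)
  expect_identical(generate_color(cfg)$color, generate_color(cfg)$color)
  expect_identical(generate_ct(cfg)$ct, generate_ct(cfg)$ct)
  cfg2 <- synth_config(seed = 13, clones_per_week = 5L,
                       color_n = rep(10L, 9))
  expect_false(identical(generate_reference(cfg2)$ref$sequence,
                         a$ref$sequence))
})

test_that("infeasible reference constraints are rejected", {
  expect_error(generate_reference(synth_config(n_sites = 0L)), "n_sites")
  expect_error(generate_reference(synth_config(n_sites = 49L)), "too many")
})

test_that("planted sites are the only CpGs and the island covers them", {
  for (s in c(2, 9)) {
    rg <- generate_reference(synth_config(seed = s))
    sites <- enumerate_cpg_sites(rg$ref)
    expect_equal(sites$c_position, as.integer(rg$truth$site_positions))
    isl <- detect_cpg_islands(rg$ref)
    expect_equal(nrow(isl), 1L)
    expect_lte(isl$start, min(sites$c_position))
    expect_gte(isl$end, max(sites$c_position) + 2L)
  }
})

test_that("zero-error clones reproduce their planted states end to end", {
  cfg <- synth_config(seed = 23, clones_per_week = 8L,
                      conversion_failure = 0, seq_error = 0)
  rg <- generate_reference(cfg)
  cl <- generate_clones(rg, cfg)
  amp <- rg$truth$amplicon
  fit <- bsp_fit(cl$reads, substr(rg$ref$sequence, amp[1] + 1, amp[2]),
                 groups = cl$manifest$group)
  expect_equal(fit$n_excluded, 0L)
  for (w in names(fit$matrices)) {
    m <- fit$matrices[[w]]
    expect_equal(unname(m), unname(cl$truth$states[rownames(m), ]))
  }
})

test_that("fully methylated probabilities give integral rate 1 at zero error", {
  cfg <- synth_config(seed = 24, clones_per_week = 4L,
                      conversion_failure = 0, seq_error = 0,
                      per_week_site_prob = matrix(1, 8, 14))
  rg <- generate_reference(cfg)
  cl <- generate_clones(rg, cfg)
  amp <- rg$truth$amplicon
  fit <- bsp_fit(cl$reads, substr(rg$ref$sequence, amp[1] + 1, amp[2]),
                 groups = cl$manifest$group)
  expect_equal(unname(fit$integral), rep(1, 8))
})

test_that("realized conversion matches the configured failure rate", {
  cfg <- synth_config(seed = 25, clones_per_week = 125L,
                      conversion_failure = 0.10, seq_error = 0)
  rg <- generate_reference(cfg)
  cl <- generate_clones(rg, cfg)    # 1000 clones
  expect_equal(length(cl$truth$realized_conversion), 1000L)
  expect_lt(abs(mean(cl$truth$realized_conversion) - 0.90), 0.02)
})

test_that("color generation recovers its planted weekly means", {
  cfg <- synth_config(seed = 26)
  co <- generate_color(cfg)
  vals <- egg_color_values(co$color)
  s <- summarize_weeks(vals$value, vals$week)
  for (i in seq_along(cfg$weeks_color)) {
    tol <- 3 * cfg$color_sds[i] / sqrt(cfg$color_n[i])
    expect_lt(abs(s$mean[i] - cfg$color_means[i]), tol + 3 * cfg$position_sd /
                sqrt(3 * cfg$color_n[i]))
  }
  # zero colorimeter noise: the egg value is exactly the latent value
  cfg0 <- synth_config(seed = 27, position_sd = 0, color_n = rep(50L, 9))
  co0 <- generate_color(cfg0)
  expect_equal(co0$color$r1, co0$color$r2)
  expect_equal(co0$color$r1, co0$color$r3)
})

test_that("noisy Ct tables recover planted folds within delta-method tolerance", {
  # with replicate noise 0.2 over 3 replicates and 5 samples/week, the weekly
  # mean rq has ~7% relative error (sample noise plus the shared calibrator
  # term), so each week lands within 15% of its planted fold ~96% of the time
  n_seed <- 100
  hits <- matrix(FALSE, n_seed, 3)
  for (s in seq_len(n_seed)) {
    cfg <- synth_config(seed = 500 + s, weeks_meth = c(25L, 30L, 35L),
                        overall_rates = c(0.8, 0.85, 0.9),
                        folds = c(4, 2, 1), ct_noise_sd = 0.2,
                        samples_per_week = 5L)
    rr <- ddct(generate_ct(cfg)$ct, calibrator_group = 35)
    mw <- c(tapply(rr$rq, rr$week, mean))
    hits[s, ] <- abs(mw / c(4, 2, 1) - 1) < 0.15
  }
  expect_true(all(colMeans(hits) >= 0.90))
})

test_that("bundles are complete, deterministic and atomic", {
  dir1 <- file.path(tempdir(), "bundle_t1")
  dir2 <- file.path(tempdir(), "bundle_t2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  cfg <- synth_config(seed = 28, clones_per_week = 4L,
                      color_n = rep(8L, 9))
  b1 <- generate_bundle(cfg, dir1)
  expect_true(all(file.exists(unlist(b1$paths))))
  reads <- read_fasta(b1$paths$clones)
  expect_equal(length(reads), 4L * 8L)
  ref <- read_fasta(b1$paths$reference)
  expect_equal(nchar(ref[[1]]), 1000L)
  truth <- jsonlite::read_json(b1$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$site_positions,
               enumerate_cpg_sites(ref[[1]])$c_position)
  # identical seed gives byte-identical files
  b2 <- generate_bundle(cfg, dir2)
  for (f in c("reference", "clones", "manifest", "color", "ct"))
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]))
  # refusing to overwrite keeps the existing bundle intact
  expect_error(generate_bundle(cfg, dir1), "already exists")
  expect_true(file.exists(b1$paths$truth))
})

test_that("indel mode produces alignable clones with gaps handled", {
  cfg <- synth_config(seed = 29, clones_per_week = 2L,
                      weeks_meth = c(25L, 30L),
                      overall_rates = c(0.85, 0.9), folds = c(1, 0.5),
                      conversion_failure = 0, seq_error = 0,
                      indel_rate = 0.01, reverse_frac = 0)
  rg <- generate_reference(cfg)
  cl <- generate_clones(rg, cfg)
  amp <- rg$truth$amplicon
  fit <- bsp_fit(cl$reads, substr(rg$ref$sequence, amp[1] + 1, amp[2]),
                 groups = cl$manifest$group)
  expect_true(all(fit$qc$identity > 0.9))
  # calls at sites untouched by indels still match planted states
  for (w in names(fit$matrices)) {
    m <- fit$matrices[[w]]
    truth <- cl$truth$states[rownames(m), , drop = FALSE]
    ok <- !is.na(m)
    expect_gt(mean(m[ok] == truth[ok]), 0.95)
  }
})
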