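# build a refmap vector directly: reference, read bases at each ref position
refmap_from <- function(ref, read) strsplit(read, "")[[1]]

test_that("conversion efficiency is the fraction of non-CpG C read as T", {
  # reference with 10 non-CpG C and one CpG site
  ref <- paste0(strrep("AC", 10), "CG", "TT")
  sites <- enumerate_cpg_sites(ref)
  full <- bisulfite_convert(ref, "full")
  qc <- clone_qc(refmap_from(ref, full), ref, sites, identity = 1)
  expect_equal(qc$conversion_rate, 1.0)
  expect_true(qc$pass)
  # retain 2 of the 10 non-CpG C
  partial <- strsplit(full, "")[[1]]
  partial[c(2, 4)] <- "C"
  qc2 <- clone_qc(partial, ref, sites, identity = 1)
  expect_equal(qc2$conversion_rate, 0.8)
  expect_false(qc2$pass)
  expect_match(qc2$reason, "conversion")
  # low identity fails even with perfect conversion
  qc3 <- clone_qc(refmap_from(ref, full), ref, sites, identity = 0.85)
  expect_false(qc3$pass)
  expect_match(qc3$reason, "identity")
  # no informative positions is an explicit failure, not a zero
  ref2 <- "ATCGATTA"
  qc4 <- clone_qc(strsplit("ATCGATTA", "")[[1]], ref2,
                  enumerate_cpg_sites(ref2), identity = 1)
  expect_false(qc4$pass)
  expect_match(qc4$reason, "no informative")
  expect_true(is.na(qc4$conversion_rate))
})

test_that("calls follow the C/T/other rule at site columns", {
  ref <- paste0("AT", strrep("CGAT", 7))   # 7 sites
  sites <- enumerate_cpg_sites(ref)
  meth <- bisulfite_convert(ref, "cpg_protected")
  expect_equal(call_clone(refmap_from(ref, meth), sites), rep(1L, 7))
  un <- bisulfite_convert(ref, "full")
  expect_equal(call_clone(refmap_from(ref, un), sites), rep(0L, 7))
  odd <- strsplit(meth, "")[[1]]
  odd[sites$c_position[4] + 1] <- "A"
  got <- call_clone(odd, sites)
  expect_true(is.na(got[4]))
  expect_equal(got[-4], rep(1L, 6))
})

test_that("per-site and integral rates are the defining fractions", {
  m <- rbind(matrix(1L, 41, 1), matrix(0L, 16, 1))
  expect_equal(round(per_site_rates(m), 4), 0.7193)   # 41 of 57
  expect_equal(per_site_rates(matrix(1L, 5, 3)), rep(1, 3))
  m2 <- cbind(rbind(matrix(1L, 94, 1), matrix(0L, 18, 1)))
  expect_equal(round(integral_rate(m2), 4), 0.8393)   # 94 of 112
  expect_equal(integral_rate(matrix(1L, 4, 5)), 1)
  expect_error(integral_rate(matrix(NA_integer_, 2, 2)), "non-missing")
  # all-missing site is NA with warning, never 0
  m3 <- cbind(c(1L, 0L), c(NA_integer_, NA_integer_))
  expect_warning(r3 <- per_site_rates(m3), "no valid calls")
  expect_true(is.na(r3[2]))
  expect_equal(r3[1], 0.5)
})

test_that("integral rate is the valid-call-weighted mean of site rates and is permutation invariant", {
  set.seed(42)
  for (k in 1:10) {
    m <- matrix(sample(c(0L, 1L, NA), 30 * 8, replace = TRUE,
                       prob = c(0.2, 0.7, 0.1)), 30, 8)
    if (sum(!is.na(m)) == 0) next
    r <- suppressWarnings(per_site_rates(m))
    v <- colSums(!is.na(m))
    expect_equal(integral_rate(m),
                 sum(r * v, na.rm = TRUE) / sum(v))
    expect_equal(integral_rate(m[sample(nrow(m)), sample(ncol(m))]),
                 integral_rate(m))
    expect_gte(integral_rate(m), min(r, na.rm = TRUE))
    expect_lte(integral_rate(m), max(r, na.rm = TRUE))
  }
})

test_that("planted per-site probabilities are recovered within 3 binomial SDs", {
  set.seed(77)
  p <- c(0.2, 0.5, 0.9)
  m <- sapply(p, function(pp) rbinom(500, 1, pp))
  r <- per_site_rates(m)
  expect_true(all(abs(r - p) <= 3 * sqrt(p * (1 - p) / 500)))
})

test_that("expected integral rate is monotone in the planted probability", {
  set.seed(88)
  u <- matrix(runif(1000 * 14), 1000, 14)   # common random numbers
  ps <- seq(0.1, 0.95, by = 0.05)
  rates <- vapply(ps, function(p) integral_rate((u < p) * 1L), 1)
  expect_true(all(diff(rates) >= 0))
})

test_that("lollipop renderings are faithful and invertible", {
  m <- matrix(1L, 2, 5, dimnames = list(c("c1", "c2"), NULL))
  txt <- format_lollipop(m)
  expect_true(all(grepl("\\*{5}$", txt)))
  set.seed(9)
  m2 <- matrix(sample(c(0L, 1L, NA), 12 * 14, replace = TRUE), 12, 14,
               dimnames = list(sprintf("cl%02d", 1:12), NULL))
  back <- parse_lollipop(format_lollipop(m2))
  expect_equal(unname(back), unname(m2))
  expect_equal(rownames(back), rownames(m2))
  lp <- lollipop_matrix(m2)
  expect_equal(colSums(lp == "filled"), colSums(m2 == 1L, na.rm = TRUE))
  expect_equal(colSums(lp == "open"), colSums(m2 == 0L, na.rm = TRUE))
  # per-site fill fraction equals the per-site rate over called positions
  r <- suppressWarnings(per_site_rates(m2))
  fills <- colSums(lp == "filled") / (colSums(lp != "absent"))
  expect_equal(unname(fills), unname(r))
  svg <- tempfile(fileext = ".svg")
  write_lollipop_svg(m2, svg)
  lines <- readLines(svg)
  expect_equal(sum(grepl('fill="black"', lines)), sum(m2 == 1L, na.rm = TRUE))
  expect_equal(sum(grepl('fill="white"', lines)), sum(m2 == 0L, na.rm = TRUE))
})

test_that("simulate() draws matrices of the fitted shape and rates", {
  cfg <- synth_config(seed = 21, clones_per_week = 20,
                      conversion_failure = 0, seq_error = 0)
  rg <- generate_reference(cfg)
  cl <- generate_clones(rg, cfg)
  amp <- rg$truth$amplicon
  fit <- bsp_fit(cl$reads, substr(rg$ref$sequence, amp[1] + 1, amp[2]),
                 groups = cl$manifest$group)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]][["25"]]), dim(fit$matrices[["25"]]))
  expect_true(all(unlist(sims[[1]]) %in% c(0L, 1L, NA)))
  expect_equal(dim(coef(fit)), c(8L, 14L))
})
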