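test_that("Z-factor matches direct substitution and respects its bounds", {
  expect_equal(z_factor(c(100, 100), c(200, 200)), 1.0)
  # sd({95,105}) = sd({195,205}) = 7.0711...; 1 - 3*14.1421/100
  expect_equal(z_factor(c(95, 105), c(195, 205)),
               1 - 3 * (sqrt(50) + sqrt(50)) / 100)
  expect_error(z_factor(c(100, 100), c(100, 100)),
               class = "fpscreen_degenerate_error")

  # always <= 1; strictly increases as control noise shrinks, means fixed
  set.seed(1)
  for (i in 1:20) {
    pos <- stats::rnorm(20, 100, stats::runif(1, 1, 15))
    neg <- stats::rnorm(20, 200, stats::runif(1, 1, 15))
    z1 <- z_factor(pos, neg)
    expect_lte(z1, 1)
    shrink <- function(v) mean(v) + (v - mean(v)) * 0.5
    expect_gt(z_factor(shrink(pos), neg), z1)
    expect_gt(z_factor(pos, shrink(neg)), z1)
  }
})

test_that("NPI anchors at the control means and is affine-invariant", {
  s <- list(mean_pos = 100, mean_neg = 200)
  expect_equal(normalized_percent_inhibition(100, s), 0)
  expect_equal(normalized_percent_inhibition(200, s), 100)
  expect_equal(normalized_percent_inhibition(150, s), 50)
  expect_error(normalized_percent_inhibition(1, list(mean_pos = 5, mean_neg = 5)),
               class = "fpscreen_degenerate_error")

  # common affine rescaling of all mP values on the plate leaves NPI fixed
  set.seed(2)
  x <- stats::rnorm(50, 150, 20)
  for (i in 1:10) {
    a <- stats::runif(1, 0.2, 5); b <- stats::runif(1, -50, 50)
    s2 <- list(mean_pos = a * s$mean_pos + b, mean_neg = a * s$mean_neg + b)
    expect_equal(normalized_percent_inhibition(a * x + b, s2),
                 normalized_percent_inhibition(x, s))
  }
})

test_that("Z-score standardizes against the compound population", {
  expect_equal(z_score(100, c(90, 100, 110)), 0)
  expect_equal(z_score(110, c(90, 100, 110)), 1)  # sd = 10 by hand
  expect_error(z_score(7, c(5, 5, 5)), class = "fpscreen_degenerate_error")

  set.seed(3)
  v <- stats::rnorm(200, 150, 12)
  zz <- z_score(v, v)
  expect_equal(mean(zz), 0)
  expect_equal(stats::sd(zz), 1)
})

test_that("three-ranking selection returns the constructed hit and honors ties", {
  # one compound is best in all rankings; the runner-up slot of each
  # ranking is a different inert compound, so none reaches 2 rankings
  tab <- data.frame(
    compound_id = c("HIT", paste0("I", 1:9)),
    mean_fp = c(50, 100, 101, 102, 103, 104, 105, 106, 107, 108),
    npi     = c(95, 40, 39, 38, 37, 36, 35, 34, 33, 32),
    z_score = c(-6, 0.3, 0.2, 0.1, 0.0, -0.1, -0.2, -0.3, -0.4, -0.5),
    stringsAsFactors = FALSE)
  tab$npi[which(tab$compound_id == "I9")] <- 41    # NPI runner-up: I9
  tab$z_score[which(tab$compound_id == "I5")] <- -1  # Z runner-up: I5
  # FP runner-up is I1 (mean_fp 100)
  expect_identical(select_hits(tab, top_fraction = 0.2, min_rankings = 2), "HIT")
  expect_identical(oracle_select_hits(tab, 0.2, 2), "HIT")

  # identical values everywhere: the deterministic tie-break by compound_id
  # selects the same leading ids in every ranking
  flat <- data.frame(compound_id = sprintf("C%02d", 1:10),
                     mean_fp = 5, npi = 5, z_score = 5)
  expect_identical(select_hits(flat, top_fraction = 0.2, min_rankings = 2),
                   c("C01", "C02"))
  expect_identical(oracle_select_hits(flat, 0.2, 2), c("C01", "C02"))
})

test_that("selection agrees with the brute-force oracle on random tables", {
  set.seed(17)
  for (i in 1:200) {
    tab <- random_score_table(sample(3:20, 1))
    tf <- stats::runif(1, 0.05, 0.5)
    mr <- sample(1:3, 1)
    expect_identical(select_hits(tab, tf, mr), oracle_select_hits(tab, tf, mr))
  }
})

test_that("rankings form permutations and selection is order-invariant", {
  set.seed(23)
  tab <- random_score_table(15)
  r <- rank_compound_scores(tab, 0.2, 2)
  for (col in c("rank_fp", "rank_npi", "rank_z")) {
    expect_setequal(r[[col]], seq_len(nrow(tab)))
  }
  shuffled <- tab[sample(nrow(tab)), ]
  expect_identical(select_hits(tab, 0.2, 2), select_hits(shuffled, 0.2, 2))
})

test_that("confirmation requires both significance and a -3 sigma effect", {
  dmso <- c(100, 101, 99, 100)
  same <- confirm_hits(list(A = dmso), dmso)
  expect_equal(same$p_value, 1)
  expect_false(same$confirmed)

  strong <- confirm_hits(list(A = c(10, 11, 10, 11)), dmso)
  expect_true(strong$confirmed)
  expect_lt(strong$sigma_delta, -3)
  expect_lt(strong$p_value, 1e-6)

  weak <- confirm_hits(list(A = c(97, 99, 101, 98)), dmso)
  expect_false(weak$confirmed)
  expect_gt(weak$sigma_delta, -3)

  expect_error(confirm_hits(list(A = 5), dmso),
               class = "fpscreen_insufficient_replicates_error")
})

test_that("counter-screen flags only probe-signal reducers", {
  dmso <- data.frame(fp = c(45, 44, 46, 45, 44.5, 45.5, 45, 45),
                     intensity = c(1000, 990, 1010, 1005, 995, 1000, 998, 1002))
  sd_fp <- stats::sd(dmso$fp)
  null_cmp <- data.frame(compound_id = "A", fp = dmso$fp[1:4],
                         intensity = dmso$intensity[1:4])
  expect_false(counter_screen(null_cmp, dmso)$quencher_flagged)

  quench <- data.frame(compound_id = "Q",
                       fp = mean(dmso$fp) - 10 * sd_fp + c(0, 0.1, -0.1, 0),
                       intensity = dmso$intensity[1:4])
  res <- counter_screen(quench, dmso)
  expect_true(res$fp_flag)
  expect_true(res$quencher_flagged)

  expect_error(counter_screen(null_cmp[1, ], dmso),
               class = "fpscreen_insufficient_replicates_error")
})
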