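# Viability comparison, transmission statistics, mirror-pair ratio tests
# and the driver decision rules.

test_that("viability comparison pools spores and matches the Fisher oracle", {
  cross <- filter_octads(make_het(rep(c("RRRSSSS", "RRRRSSSS"), 13)[1:25]))
  ctrl <- filter_octads(make_control(25, n_dead = 2))
  vc <- viability_comparison(cross, ctrl)
  nv <- sum(cross$spores$viable); nd <- nrow(cross$spores)
  cv <- sum(ctrl$spores$viable); cd <- nrow(ctrl$spores)
  expect_equal(vc$viability$fraction, nv / nd)
  expect_equal(vc$reduction_pp, 100 * (cv / cd - nv / nd))
  expect_equal(vc$p_viability, oracle_fisher(nv, nd - nv, cv, cd - cv),
               tolerance = 1e-10)
})

test_that("identical viability gives zero reduction and p = 1", {
  a <- filter_octads(make_het(rep("RRRRSSSS", 5)))
  b <- filter_octads(make_control(5))
  vc <- viability_comparison(a, b)
  expect_equal(vc$reduction_pp, 0)
  expect_equal(vc$p_viability, 1.0)
})

test_that("a control worse than the cross gives a negative reduction", {
  cross <- filter_octads(make_het(rep("RRRRSSSS", 10)))
  ctrl <- filter_octads(make_control(10, n_dead = 5))
  expect_lt(viability_comparison(cross, ctrl)$reduction_pp, 0)
})

test_that("transmission test and TDR count viable genotyped spores", {
  # 60 S vs 40 R over 20 octads
  ds <- filter_octads(make_het(rep(c("RRSSSS", "RRSS"), 10)))
  tt <- transmission_test(ds)
  expect_equal(tt$n_S, 60)
  expect_equal(tt$n_R, 40)
  expect_equal(tt$p, oracle_binom(60, 100, 0.5), tolerance = 1e-10)
  expect_equal(transmission_distortion_ratio(ds), 0.6)
  # balanced single octad: modal outcome, p = 1
  one <- filter_octads(make_het("RRRRSSSS"))
  expect_equal(transmission_test(one)$p, 1.0)
  expect_equal(transmission_distortion_ratio(one), 0.5)
})

test_that("TDR hits its boundary cases", {
  all_R_dead <- filter_octads(make_het(rep("SSSS", 4)))
  expect_equal(transmission_distortion_ratio(all_R_dead), 1.0)
  expect_error(transmission_distortion_ratio(filter_octads(make_het(""))),
               "no viable genotyped")
})

test_that("mirror-pair ratio tests gate pairs with five or fewer octads", {
  counts <- octad_type_counts(
    r = c(rep(4, 3), rep(3, 2), rep(4, 6), rep(0, 2)),
    s = c(rep(3, 3), rep(4, 2), rep(0, 6), rep(4, 2)))
  rt <- octad_ratio_tests(counts)
  r43 <- rt[rt$pair == "4R3S:3R4S", ]
  expect_true(r43$gated)        # 3 + 2 = 5 octads: gated, no p
  expect_true(is.na(r43$p))
  r40 <- rt[rt$pair == "4R0S:0R4S", ]
  expect_false(r40$gated)       # 6 + 2 = 8 octads: tested
  expect_equal(r40$p, oracle_binom(6, 8, 0.5), tolerance = 1e-12)
  # a 6:0 pair: both tails collapse to the extremes, p = 2/64
  counts2 <- octad_type_counts(r = rep(4, 6), s = rep(1, 6))
  rt2 <- octad_ratio_tests(counts2)
  expect_equal(rt2[rt2$pair == "4R1S:1R4S", "p"], 0.03125)
  # balanced pair: p = 1
  counts3 <- octad_type_counts(r = c(rep(4, 10), rep(3, 10)),
                               s = c(rep(3, 10), rep(4, 10)))
  rt3 <- octad_ratio_tests(counts3)
  expect_equal(rt3[rt3$pair == "4R3S:3R4S", "p"], 1.0)
})

# minimal report constructor for table-driven decision-rule tests
mk_report <- function(reduction, p_viab, p_trans, tdr,
                      ratio_p = NA, ratio_first = 0, ratio_second = 0) {
  gated <- is.na(ratio_p)
  structure(list(
    cross_id = "x", gene = "g",
    viability = list(viable = 0L, dissected = 0L, fraction = NA_real_),
    control_viability = list(viable = 0L, dissected = 0L, fraction = NA_real_),
    reduction_pp = reduction, p_viability = p_viab,
    n_viable_R = 0L, n_viable_S = 0L, tdr = tdr, p_transmission = p_trans,
    ratio_tests = data.frame(
      pair = "4R3S:3R4S", n_first = ratio_first, n_second = ratio_second,
      total = ratio_first + ratio_second, gated = gated,
      p = ratio_p, stringsAsFactors = FALSE),
    status = NA_character_), class = "drive_report")
}

test_that("driver classification implements the decision gates", {
  cases <- list(
    # reduction, p_viab, p_trans, tdr, ratio_p, first, second -> expected
    list(mk_report(12, 0.001, 2e-4, 0.71), "active_driver"),
    list(mk_report(2, 0.001, 2e-4, 0.71), "no_drive"),       # reduction gate
    list(mk_report(12, 0.2, 2e-4, 0.71), "no_drive"),        # Fisher gate
    list(mk_report(12, 0.001, 0.2, 0.71), "no_drive"),       # binomial gate
    list(mk_report(12, 0.001, 2e-4, 0.4), "no_drive"),       # direction gate
    # weak driver: one significant mirror pair biased toward S
    list(mk_report(2, 0.5, 0.5, 0.55, ratio_p = 0.02,
                   ratio_first = 1, ratio_second = 8), "weak_driver"),
    # same p but biased toward R: not a wtf driver
    list(mk_report(2, 0.5, 0.5, 0.45, ratio_p = 0.02,
                   ratio_first = 8, ratio_second = 1), "no_drive"),
    list(mk_report(2, 0.5, 0.5, 0.5), "no_drive")
  )
  for (cs in cases)
    expect_identical(classify_driver(cs[[1]]), cs[[2]])
})

test_that("classification is monotone: raising p-values never promotes to active", {
  set.seed(10)
  for (i in 1:50) {
    r <- mk_report(runif(1, -5, 20), runif(1), runif(1), runif(1))
    s1 <- classify_driver(r)
    r2 <- r
    r2$p_viability <- min(1, r$p_viability + runif(1))
    r2$p_transmission <- min(1, r$p_transmission + runif(1))
    s2 <- classify_driver(r2)
    if (s1 == "no_drive") expect_identical(s2, "no_drive")
  }
})

test_that("null transmission tests reject at most at the nominal rate", {
  reps <- 2000
  rej <- withr::with_seed(2024, {
    vapply(seq_len(reps), function(i) {
      ds <- filter_octads(simulate_octads(octad_sim_spec(
        v = 0.95, k = 0, n_octads = 20,
        seed = sample.int(.Machine$integer.max, 1))))
      transmission_test(ds)$p < 0.05
    }, logical(1))
  })
  tol <- 3 * sqrt(0.05 * 0.95 / reps)
  # the exact test is conservative on discrete data, so only the upper
  # bound is asserted
  expect_lte(mean(rej), 0.05 + tol)
})

test_that("TDR/expression correlation recovers monotone association", {
  tdr <- c(a = 0.5, b = 0.6, c = 0.7, d = 0.85, e = 0.95)
  expr <- c(a = 1, b = 5, c = 20, d = 80, e = 300)
  ct <- tdr_expression_correlation(tdr, expr)
  expect_equal(ct$rho, 1)
  ct2 <- tdr_expression_correlation(tdr, -expr)
  expect_equal(ct2$rho, -1)
  expect_error(tdr_expression_correlation(tdr[1:2], expr), "at least 3")
  # under random pairing the mean correlation is near zero
  set.seed(33)
  rhos <- replicate(300, tdr_expression_correlation(
    tdr, setNames(sample(unname(expr)), names(expr)))$rho)
  expect_lt(abs(mean(rhos)), 0.1)
})
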