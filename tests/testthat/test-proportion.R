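cfg <- be_config("ABE")

test_that("odds-ratio inversion reproduces margins and odds ratio", {
  J <- joint_from_margins_or(0.5, 0.5, 9)
  expect_equal(unname(J), c(0.375, 0.125, 0.125, 0.375))
  expect_equal(unname(J["p11"] * J["p00"] / (J["p01"] * J["p10"])), 9)

  expect_equal(unname(joint_from_margins_or(0.3, 0.6, 1)["p11"]), 0.18)

  # comonotone limit: p11 -> min(p, q)
  Jinf <- joint_from_margins_or(0.4, 0.7, 1e8)
  expect_lt(abs(Jinf[["p11"]] - 0.4), 1e-4)

  # property over random draws: margins to 1e-9, odds ratio to 1e-6
  set.seed(123)
  for (i in 1:1000) {
    p <- stats::runif(1, 0.02, 0.98)
    q <- stats::runif(1, 0.02, 0.98)
    c0 <- exp(stats::runif(1, -3, 3))
    J <- joint_from_margins_or(p, q, c0)
    expect_lt(abs(sum(J) - 1), 1e-12)
    expect_lt(abs(J[["p11"]] + J[["p10"]] - p), 1e-9)
    expect_lt(abs(J[["p11"]] + J[["p01"]] - q), 1e-9)
    if (all(J > 1e-8)) { # away from the Frechet clipping boundary
      expect_lt(abs(J[["p11"]] * J[["p00"]] / (J[["p01"]] * J[["p10"]]) - c0),
                1e-6 * c0)
    }
  }

  expect_error(joint_from_margins_or(0, 0.5, 2), "margins")
  expect_error(joint_from_margins_or(0.5, 0.5, -1), "positive")
})

test_that("chain joint equals the brute-force Markov chain and sums to 1", {
  # independence: product of Bernoulli masses
  cm1 <- chain_model(c(5, 6, 7), c(0.3, 0.5, 0.7), 1)
  for (b in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_equal(chain_joint(cm1, b),
                 prod(ifelse(b == 1, c(.3, .5, .7), 1 - c(.3, .5, .7))))
  }

  set.seed(7)
  for (rep in 1:20) {
    m <- stats::runif(3, 0.05, 0.95)
    ors <- exp(stats::runif(2, -2, 2))
    cm <- chain_model(c(4, 6, 8), m, ors)
    oracle <- oracle_chain3(m, ors)
    tot <- 0
    for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
      p <- chain_joint(cm, c(b1, b2, b3))
      expect_equal(p, unname(oracle[paste0(b1, b2, b3)]), tolerance = 1e-9)
      tot <- tot + p
    }
    expect_lt(abs(tot - 1), 1e-9)
  }
})

test_that("chain sums to 1 for longer chains and matches the c=4, c=2 oracle", {
  cm <- chain_model(1:8, seq(0.1, 0.8, 0.1), rep(c(4, 2), length.out = 7))
  pats <- getFromNamespace("all_patterns", "bequant")(8)
  tot <- sum(apply(pats, 1, function(b) chain_joint(cm, b)))
  expect_lt(abs(tot - 1), 1e-9)
})

test_that("predicted proportions enumerate, renormalize and guard n > 12", {
  site <- fixture_site() # A at 5 and 6 in window
  cm <- chain_model(5, 0.3, numeric(0))
  d <- predict_proportions(cm, site, cfg)
  expect_equal(sum(d$proportion), 1)
  expect_equal(d$proportion[substr(d$edit_pattern, 5, 5) == "1"], 0.3)
  expect_equal(sort(d$proportion), c(0.3, 0.7))

  cm2 <- chain_model(5:6, c(0.4, 0.5), 3)
  d2 <- predict_proportions(cm2, site, cfg, mimic_observed = TRUE)
  expect_equal(sum(d2$proportion), 1)
  expect_false(any(substr(d2$edit_pattern, 5, 6) == "00"))

  big <- chain_model(1:13, rep(0.5, 13), 1)
  expect_error(predict_proportions(big, site, cfg), "12 editable")

  # every c = 1 reduces to the independent product distribution exactly
  cm3 <- chain_model(5:6, c(0.4, 0.5), 1)
  d3 <- predict_proportions(cm3, site, cfg)
  probs <- stats::setNames(d3$proportion, substr(d3$edit_pattern, 5, 6))
  expect_equal(unname(probs[c("00", "10", "01", "11")]),
               c(0.6 * 0.5, 0.4 * 0.5, 0.6 * 0.5, 0.4 * 0.5))
})

test_that("adjacent odds ratio is recovered from sampled outcomes", {
  # two-position chain with known c, sampled at depth 1e5 and re-estimated
  site <- fixture_site("GTCGAATCGTTTCGGTTCTG") # As at 5 and 6
  truth <- be_truth("ABE", intercept = 0.3, adjacent_or = 4,
                    bystander_rate = 0, insertion_rate_p18 = 0,
                    deletion_rate_window = 0, depth = 1e5, replicates = 1)
  m <- true_marginals(site, truth, NULL, cfg)
  expect_equal(m$positions, c(5, 6))
  tabs <- sample_allele_tables(site, truth, m, seed = 31)
  oc <- collapse_outcomes(tabs, site, cfg, keep_wildtype = TRUE)
  est <- estimate_adjacent_or(list(oc))
  expect_gt(est$c, 3.6)
  expect_lt(est$c, 4.4)

  # independence: c-hat close to 1
  truth1 <- truth; truth1$adjacent_or <- 1
  tabs1 <- sample_allele_tables(site, truth1, m, seed = 32)
  oc1 <- collapse_outcomes(tabs1, site, cfg, keep_wildtype = TRUE)
  est1 <- estimate_adjacent_or(list(oc1))
  expect_lt(abs(log(est1$c)), 0.1)

  # perfectly co-edited pairs: finite but large via the pseudocount
  pats <- c("....11..............", "....00..............")
  oc2 <- getFromNamespace("be_outcomes", "bequant")(
    data.frame(allele = pats, edit_pattern = pats, other_edits = "",
               proportion = c(0.5, 0.5), stringsAsFactors = FALSE),
    "s", "observed", total_reads = 1e4)
  est2 <- estimate_adjacent_or(list(oc2))
  expect_gt(est2$c, 1e4)
  expect_true(is.finite(est2$c))

  # unobserved pairs fall back to c = 1 with a warning
  expect_warning(none <- estimate_adjacent_or(list()), "no adjacent pair")
  expect_equal(none$c, 1)
})

test_that("form labels and deterministic Max-form tie-breaking", {
  mk <- function(patterns, props, other = "") {
    getFromNamespace("be_outcomes", "bequant")(
      data.frame(allele = patterns, edit_pattern = patterns,
                 other_edits = other, proportion = props,
                 stringsAsFactors = FALSE), "s", "predicted")
  }
  d <- mk(c("....10..............", "....01.............."), c(0.6, 0.4))
  fl <- classify_forms(d, "ABE")
  expect_equal(fl$max_form, "....10..............")
  expect_equal(fl$forms$form, c("Edited-form", "Edited-form"))

  # tie: fewer edits wins, then leftmost edited position
  d2 <- mk(c("....11..............", "....01..............",
             "....10.............."), c(1 / 3, 1 / 3, 1 / 3))
  fl2 <- classify_forms(d2, "ABE")
  expect_equal(fl2$max_form, "....10..............")

  # no edited allele: flagged, no Max-form
  d3 <- mk("....00..............", 1, other = "5A>C")
  fl3 <- classify_forms(d3, "ABE")
  expect_true(is.na(fl3$max_form))
  expect_equal(fl3$forms$form, "other")
})

test_that("mutual information: independence, coupling and chain residual", {
  mk <- function(patterns, props) {
    getFromNamespace("be_outcomes", "bequant")(
      data.frame(allele = patterns, edit_pattern = patterns, other_edits = "",
                 proportion = props, stringsAsFactors = FALSE), "s", "observed")
  }
  # independent pair, p = 0.5 each
  pats <- c("....00..............", "....01..............",
            "....10..............", "....11..............")
  ind <- mk(pats, rep(0.25, 4))
  expect_equal(mutual_information_audit(ind)$pairwise$mi_bits, 0)

  # perfect coupling at m = 0.5: exactly 1 bit
  cpl <- mk(pats[c(1, 4)], c(0.5, 0.5))
  expect_equal(mutual_information_audit(cpl)$pairwise$mi_bits, 1)

  # first-order chain: conditional MI of the outer pair given the middle ~ 0
  m <- c(0.4, 0.5, 0.6)
  cm <- chain_model(c(5, 6, 7), m, c(4, 3))
  site3 <- fixture_site("GTCGAAATGTTTCGGTTCTG") # As at 5,6,7
  pred <- predict_proportions(cm, site3, cfg)
  aud <- mutual_information_audit(pred)
  expect_equal(nrow(aud$conditional), 1)
  expect_lt(aud$conditional$cmi_bits, 1e-10)
  adj <- aud$pairwise$mi_bits[aud$pairwise$adjacent]
  dist <- aud$pairwise$mi_bits[!aud$pairwise$adjacent]
  expect_true(all(dist <= max(adj))) # distant MI carried through the chain
})
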