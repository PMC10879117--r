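cfg <- be_config("ABE")

test_that("replicate concordance filter removes low-edited and discordant replicates", {
  site <- fixture_site()
  edited <- list(list(n = 50), list(n = 950, sub = c(`5` = "A>G")))
  half <- list(list(n = 500), list(n = 500, sub = c(`5` = "A>G")))
  t1 <- fixture_table(site, edited, "r1")
  t2 <- fixture_table(site, edited, "r2")
  t3 <- fixture_table(site, half, "r3")
  res <- filter_outcome_replicates(list(t1, t2, t3), site, cfg)
  expect_setequal(vapply(res$retained, `[[`, character(1), "replicate_id"),
                  c("r1", "r2"))
  expect_equal(unname(res$edited_fraction["r3"]), 0.5)
  # identical replicates have zero KL and are all retained
  expect_equal(unname(res$mean_kl[c("r1", "r2")]), c(0, 0))

  res3 <- filter_outcome_replicates(list(t1, t2, fixture_table(site, edited, "r4")),
                                    site, cfg)
  expect_length(res3$retained, 3)

  expect_message(
    none <- filter_outcome_replicates(list(t3), site, cfg),
    "dropped")
  expect_length(none$retained, 0)
})

test_that("KL outlier fence removes a discordant replicate", {
  site <- fixture_site()
  mk <- function(p5, p6, id) {
    fixture_table(site, list(
      list(n = round(1000 * p5), sub = c(`5` = "A>G")),
      list(n = round(1000 * p6), sub = c(`6` = "A>G")),
      list(n = 1000 - round(1000 * p5) - round(1000 * p6),
           sub = c(`5` = "A>G", `6` = "A>G"))), id)
  }
  concordant <- list(mk(0.5, 0.3, "r1"), mk(0.49, 0.31, "r2"),
                     mk(0.5, 0.31, "r3"), mk(0.51, 0.29, "r4"))
  rogue <- mk(0.05, 0.9, "r5")
  res <- filter_outcome_replicates(c(concordant, list(rogue)), site, cfg)
  expect_false("r5" %in% vapply(res$retained, `[[`, character(1),
                                "replicate_id"))
  expect_length(res$retained, 4)
})

test_that("collapse removes wild type, thresholds at 5% and renormalizes", {
  site <- fixture_site()
  tb <- fixture_table(site, list(
    list(n = 900),
    list(n = 60, sub = c(`5` = "A>G")),
    list(n = 40, sub = c(`6` = "A>G"))
  ))
  oc <- collapse_outcomes(list(tb), site, cfg)
  expect_equal(sort(oc$proportion), c(0.4, 0.6))
  expect_equal(sum(oc$proportion), 1)

  # a 4%-of-edited allele is dropped and the rest renormalized
  tb2 <- fixture_table(site, list(
    list(n = 900),
    list(n = 96, sub = c(`5` = "A>G")),
    list(n = 4, sub = c(`6` = "A>G"))
  ))
  oc2 <- collapse_outcomes(list(tb2), site, cfg)
  expect_equal(nrow(oc2), 1)
  expect_equal(oc2$proportion, 1)

  # single edited allele
  tb3 <- fixture_table(site, list(list(n = 10), list(n = 90, sub = c(`5` = "A>G"))))
  oc3 <- collapse_outcomes(list(tb3), site, cfg)
  expect_equal(oc3$proportion, 1)

  # no edited alleles at all
  oc4 <- collapse_outcomes(list(fixture_table(site, list(list(n = 100)))),
                           site, cfg)
  expect_equal(nrow(oc4), 0)
  expect_true(attr(oc4, "empty"))
})

test_that("collapse is idempotent on its own output", {
  site <- fixture_site()
  tb <- fixture_table(site, list(
    list(n = 500),
    list(n = 300, sub = c(`5` = "A>G")),
    list(n = 150, sub = c(`6` = "A>G")),
    list(n = 50, sub = c(`5` = "A>G", `6` = "A>G"))
  ))
  oc <- collapse_outcomes(list(tb), site, cfg)
  # rebuild an allele table from the output with proportions scaled to reads
  rebuilt <- fixture_table(site, lapply(seq_len(nrow(oc)), function(i) {
    pos <- which(strsplit(oc$edit_pattern[i], "")[[1]] == "1")
    list(n = round(oc$proportion[i] * 1e6),
         sub = stats::setNames(rep("A>G", length(pos)), pos))
  }))
  oc2 <- collapse_outcomes(list(rebuilt), site, cfg)
  m <- match(oc$allele, oc2$allele)
  expect_false(anyNA(m))
  expect_equal(oc2$proportion[m], oc$proportion, tolerance = 1e-9)
})

test_that("outcome consistency classification follows set containment", {
  mk <- function(patterns, props) {
    be_outcomes <- getFromNamespace("be_outcomes", "bequant")
    be_outcomes(data.frame(allele = patterns, edit_pattern = patterns,
                           other_edits = "", proportion = props,
                           stringsAsFactors = FALSE), "s", "observed")
  }
  a <- "....1..............."
  b <- ".....1.............."
  c3 <- "....11.............."
  expect_equal(classify_outcome_consistency(mk(c(a, b), c(.5, .5)),
                                            mk(c(a, b), c(.9, .1))),
               "Consistent")
  expect_equal(classify_outcome_consistency(mk(c(a, b), c(.5, .5)),
                                            mk(a, 1)), "Endo-bias")
  expect_equal(classify_outcome_consistency(mk(c(a, b), c(.5, .5)),
                                            mk(c(a, c3), c(.5, .5))),
               "Discordant")
  # label symmetry under swapping inputs
  sets <- list(mk(c(a, b), c(.5, .5)), mk(a, 1), mk(c(a, c3), c(.4, .6)))
  swap <- c(Consistent = "Consistent", `Endo-bias` = "Inte-bias",
            `Inte-bias` = "Endo-bias", Discordant = "Discordant")
  for (x in sets) for (y in sets) {
    expect_equal(unname(swap[classify_outcome_consistency(x, y)]),
                 classify_outcome_consistency(y, x))
  }
  expect_error(classify_outcome_consistency(mk(a, 1)[0, ], mk(a, 1)), "empty")
})

test_that("efficiency bias groups use the mu +/- sigma residual band", {
  # construct data whose OLS residuals are {1,-2,0,2,-1}: population sd
  # sqrt(2), so only the +/-2 residuals leave the band
  inte <- c(1, 2, 3, 4, 5)
  d <- c(1, -2, 0, 2, -1)
  endo <- 0.1 + 0.5 * inte + d
  bg <- classify_efficiency_bias(endo, inte, paste0("s", 1:5))
  expect_equal(unname(sort(bg$residuals)), sort(d))
  expect_equal(bg$sigma, sqrt(2))
  expect_equal(unname(bg$assignment[d == 2]), "Endo-bias")
  expect_equal(unname(bg$assignment[d == -2]), "Inte-bias")
  expect_equal(unname(bg$assignment[abs(d) < 2]),
               rep("Consistent", 3))

  # perfectly linear pairs: sigma 0, everyone Consistent
  bg0 <- classify_efficiency_bias(0.2 + 0.7 * inte, inte)
  expect_equal(unique(unname(bg0$assignment)), "Consistent")
  expect_equal(bg0$sigma, 0)

  expect_error(classify_efficiency_bias(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(classify_efficiency_bias(c(1, 2), c(1, 2)), "3 paired")
})

test_that("co-occurrence matrix and edited-base histogram", {
  mkoc <- function(patterns, props) {
    getFromNamespace("be_outcomes", "bequant")(
      data.frame(allele = patterns, edit_pattern = patterns,
                 other_edits = "", proportion = props, stringsAsFactors = FALSE),
      "s", "observed")
  }
  # target bases at 5 and 6 (others '.')
  both <- "....11.............."
  oc <- mkoc(both, 1)
  M <- cooccurrence_matrix(oc)
  expect_equal(M["5", "6"], 1)
  expect_equal(M["5", "5"], 1)

  disjoint <- mkoc(c("....10..............", "....01.............."), c(.5, .5))
  M2 <- cooccurrence_matrix(disjoint)
  expect_equal(M2["5", "6"], 0)
  expect_equal(M2["5", "5"], 0.5)

  set.seed(9)
  pats <- replicate(6, paste0("....", paste(sample(0:1, 2, TRUE), collapse = ""),
                              strrep(".", 14)))
  props <- as.numeric(stats::rmultinom(1, 100, rep(1, 6))) / 100
  M3 <- cooccurrence_matrix(mkoc(pats, props))
  expect_equal(M3, t(M3))

  h <- edited_base_count_distribution(
    mkoc(c("....10..............", "....11.............."), c(.7, .3)))
  expect_equal(h, c(`1` = 0.7, `2` = 0.3))
  expect_equal(sum(h), 1)
  expect_length(edited_base_count_distribution(mkoc(both, 1)[0, ]), 0)
})
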