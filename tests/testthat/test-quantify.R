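cfg_abe <- be_config("ABE")

test_that("efficiency formulas: intended-in-window over total reads", {
  site <- fixture_site() # As at protospacer 2,4,5,6,10,16,19
  tb <- fixture_table(site, list(
    list(n = 850),
    list(n = 150, sub = c(`5` = "A>G"))
  ))
  s <- summarize_site(tb, site, cfg_abe)
  expect_equal(s$overall_efficiency, 0.15)
  expect_equal(s$per_position_efficiency[5], 0.15)
  expect_equal(s$modified_efficiency, 0.15)
  expect_true(is.na(s$per_position_efficiency[1])) # G, not a target base
  expect_equal(s$per_position_efficiency[2], 0)

  # edits outside the window do not count as overall efficiency
  tb2 <- fixture_table(site, list(
    list(n = 900),
    list(n = 100, sub = c(`16` = "A>G"))
  ))
  s2 <- summarize_site(tb2, site, cfg_abe)
  expect_equal(s2$overall_efficiency, 0)
  expect_equal(s2$per_position_efficiency[16], 0.1)
})

test_that("all-wild-type input yields zeros and NA purity", {
  site <- fixture_site()
  s <- summarize_site(fixture_table(site, list(list(n = 500))), site, cfg_abe)
  expect_equal(s$overall_efficiency, 0)
  expect_equal(s$modified_efficiency, 0)
  expect_true(all(is.na(s$transition_proportions)))
})

test_that("unintended transitions count in purity but not efficiency", {
  site <- fixture_site()
  tb <- fixture_table(site, list(
    list(n = 800),
    list(n = 200, sub = c(`13` = "C>T")) # CBE-style edit in an ABE run
  ))
  s <- summarize_site(tb, site, cfg_abe)
  expect_equal(s$overall_efficiency, 0)
  expect_equal(s$transition_proportions["overall", "C>T"], 1)
  expect_equal(s$transition_proportions["outside_window", "C>T"], 1)
  expect_true(all(is.na(s$transition_proportions["in_window", ])))
})

test_that("summarize_site matches an independent read-by-read recount", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (case in 1:8) {
    editor <- if (case %% 2 == 0) "ABE" else "CBE"
    cfg <- be_config(editor)
    repeat {
      proto <- paste(sample(bases, 20, replace = TRUE), collapse = "")
      if (grepl(editor_target_base(editor), substr(proto, cfg$window[1],
                                                   cfg$window[2]))) break
    }
    site <- fixture_site(proto, editor = editor)
    alleles <- lapply(seq_len(sample(3:10, 1)), function(i) {
      al <- list(n = sample(1:500, 1))
      nsub <- sample(0:3, 1)
      if (nsub > 0) {
        pos <- sample(1:20, nsub)
        ref <- strsplit(proto, "")[[1]][pos]
        al$sub <- stats::setNames(paste0(ref, ">", vapply(ref, function(r)
          sample(setdiff(bases, r), 1), character(1))), pos)
      }
      if (stats::runif(1) < 0.3) al$del <- list(sample(1:18, 1), sample(1:2, 1))
      al
    })
    tb <- fixture_table(site, alleles)
    s <- summarize_site(tb, site, cfg)
    oracle <- oracle_recount(tb, site, cfg)
    expect_equal(s$overall_efficiency, oracle$overall)
    expect_equal(s$modified_efficiency, oracle$modified)
    expect_equal(ifelse(is.na(s$per_position_efficiency), 0,
                        s$per_position_efficiency), oracle$per_position)
    expect_equal(unname(s$transition_proportions),
                 unname(oracle$transition_proportions))
    # invariants
    expect_lte(s$overall_efficiency, s$modified_efficiency)
    for (sc in rownames(s$transition_proportions)) {
      row <- s$transition_proportions[sc, ]
      if (!all(is.na(row))) expect_equal(sum(row), 1)
    }
  }
})

test_that("replicate averaging applies the coverage filter", {
  site <- fixture_site()
  lo <- summarize_site(fixture_table(site, list(
    list(n = 49), list(n = 50, sub = c(`5` = "A>G"))), "r1"), site, cfg_abe)
  hi <- summarize_site(fixture_table(site, list(
    list(n = 400), list(n = 100, sub = c(`5` = "A>G"))), "r2"), site, cfg_abe)
  expect_equal(lo$total_reads, 99)
  avg <- average_replicates(list(lo, hi), cfg_abe)
  expect_equal(avg$overall_efficiency, 0.2) # only the 500-read replicate
  expect_equal(avg$n_replicates, 1L)

  a <- hi; a$overall_efficiency <- 0.2
  b <- hi; b$overall_efficiency <- 0.4
  expect_equal(average_replicates(list(a, b), cfg_abe)$overall_efficiency, 0.3)

  expect_message(
    dropped <- average_replicates(list(lo, lo), cfg_abe),
    "dropped")
  expect_null(dropped)
})

test_that("indel positional profile applies the quartile band filter", {
  site <- fixture_site()
  mk <- function(freq, id) {
    s <- summarize_site(fixture_table(site, list(list(n = 1000))), site, cfg_abe)
    s$site_id <- id
    s$indel_by_position_length <- data.frame(position = 18L, length = 1L,
                                             frequency = freq)
    s
  }
  sums <- lapply(1:8, function(i) mk(i / 100, paste0("t", i)))
  prof <- indel_position_profile(sums, cfg_abe)
  # linear-interpolation quartiles of 1..8 are 2.75 and 6.25: sites 3,4,5,6
  expect_equal(prof$n_sites, 4L)
  expect_equal(prof$mean_frequency, mean(c(3, 4, 5, 6) / 100))
  expect_equal(prof$position, 18L)

  same <- lapply(1:6, function(i) mk(0.02, paste0("u", i)))
  prof2 <- indel_position_profile(same, cfg_abe)
  expect_equal(prof2$n_sites, 6L)
  expect_equal(prof2$mean_frequency, 0.02)

  expect_error(indel_position_profile(sums[1:3], cfg_abe), "insufficient sites")

  # +1 insertions at position 18 dominate the profile when generated there
  ins_site <- fixture_table(site, list(
    list(n = 950), list(n = 50, ins = list(18, "A"))))
  s <- summarize_site(ins_site, site, cfg_abe)
  expect_equal(s$indel_by_position_length$position, 18L)
  expect_equal(s$indel_by_position_length$length, 1L)
  expect_equal(s$indel_by_position_length$frequency, 0.05)
  expect_equal(s$ncas9_indel_freq, 0.05)
  expect_equal(s$deaminase_indel_freq, 0)
})

test_that("length normalization divides event frequency by |length|", {
  site <- fixture_site()
  mk2 <- function(freq, id) {
    s <- summarize_site(fixture_table(site, list(list(n = 1000))), site, cfg_abe)
    s$site_id <- id
    s$indel_by_position_length <- data.frame(position = 6L, length = -2L,
                                             frequency = freq)
    s
  }
  sums <- lapply(1:4, function(i) mk2(0.04, paste0("v", i)))
  prof <- indel_position_profile(sums, cfg_abe)
  expect_equal(prof$mean_frequency, 0.02)
  cfg_raw <- be_config("ABE", indel_length_normalize = FALSE)
  expect_equal(indel_position_profile(sums, cfg_raw)$mean_frequency, 0.04)
})

test_that("editing:indel ratio is summarized by the geometric mean", {
  site <- fixture_site()
  mk <- function(eff, indel, id) {
    s <- summarize_site(fixture_table(site, list(list(n = 100))), site, cfg_abe)
    s$site_id <- id
    s$overall_efficiency <- eff
    s$deaminase_indel_freq <- indel
    s
  }
  res <- be_indel_ratio(list(mk(0.5, 0.05, "a"), mk(0.5, 0.0005, "b")),
                        "deaminase")
  expect_equal(unname(res$ratios), c(10, 1000))
  expect_equal(res$geometric_mean, 100)
  expect_equal(res$n_excluded, 0)

  res2 <- be_indel_ratio(list(mk(0.5, 0.05, "a"), mk(0.5, 0, "z")), "deaminase")
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$geometric_mean, 10)

  expect_error(be_indel_ratio(list(mk(0.5, 0, "z")), "deaminase"), "no site")
})
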