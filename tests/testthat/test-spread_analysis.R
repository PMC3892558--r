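test_that("f-values hit the closed-form endpoints and report precision", {
  meta <- make_meta(2, 652, 2)
  m <- matrix(0L, 2, nrow(meta), dimnames = list(c("rare", "wide"), meta$organism_id))
  m["rare", "B1"] <- 1L                      # 1 of 652 bacteria
  m["rare", c("E1", "E2")] <- 3L
  m["wide", ] <- 1L
  tm <- trait_matrix(m)
  expect_equal(report_precision(f_value("rare", "Bacteria", tm, meta), 3), 0.001)
  expect_equal(f_value("wide", "B", tm, meta), 1.0)
  expect_equal(f_value("rare", "A", tm, meta), 0.0)
  expect_error(f_value("rare", "B", tm, meta[meta$superkingdom != "B", ]), "B1")
})

test_that("profiles define f exactly for the superkingdoms in the group label", {
  meta <- make_meta(0, 100, 100)
  meta <- rbind(meta, organism_metadata("A1", "A"))
  m <- matrix(0L, 1, nrow(meta), dimnames = list("be", meta$organism_id))
  m[1, paste0("B", 1:10)] <- 1L
  m[1, paste0("E", 1:90)] <- 2L
  p <- spread_profiles(trait_matrix(m), meta)
  expect_equal(p$venn_group, "BE")
  expect_equal(p$f_B, 0.100)
  expect_equal(p$f_E, 0.900)
  expect_true(is.na(p$f_A))
})

test_that("profiles equal the brute-force per-organism recount oracle", {
  set.seed(33)
  for (i in 1:12) {
    d <- random_dataset(20, 4, 5, 3)
    p <- spread_profiles(d$matrix, d$meta)
    for (j in seq_len(nrow(p))) {
      for (sk in c("A", "B", "E")) {
        got <- p[[paste0("f_", sk)]][j]
        want <- f_oracle(p$trait_id[j], sk, d$matrix, d$meta)
        if (grepl(sk, p$venn_group[j], fixed = TRUE)) {
          expect_equal(got, want)
          expect_gt(got, 0)
        } else {
          # letter absent from the group label <=> raw f is exactly 0
          expect_true(is.na(got))
          expect_equal(want, 0)
        }
      }
    }
  }
})

test_that("spread summaries report medians, quartiles and strict tail counts", {
  p <- data.frame(trait_id = paste0("t", 1:3), venn_group = "A",
                  f_A = c(0.1, 0.2, 0.3), f_B = NA_real_, f_E = NA_real_,
                  stringsAsFactors = FALSE)
  s <- summarize_spread(p, "A", "A")
  expect_equal(s$median_f, 0.2)
  expect_equal(s$n_tail, 0L)

  p2 <- data.frame(trait_id = paste0("t", 1:4), venn_group = "E",
                   f_A = NA_real_, f_B = NA_real_,
                   f_E = c(0.85, 0.9, 0.95, 0.5), stringsAsFactors = FALSE)
  s2 <- summarize_spread(p2, "E", "E", tail_threshold = 0.8)
  expect_equal(s2$n_tail, 3L)
  expect_true(s2$q1 <= s2$median_f && s2$median_f <= s2$q3)

  empty <- summarize_spread(p2, "AE", "E")
  expect_equal(empty$n_traits, 0L)
  expect_true(is.na(empty$median_f))

  expect_error(summarize_spread(p2, "AB", "E"), "not part of group")
})

test_that("the summary table covers each group's member superkingdoms once", {
  d <- random_dataset(30, 3, 4, 3)
  tab <- spread_summary_table(spread_profiles(d$matrix, d$meta))
  expect_equal(nrow(tab), 12)  # 3*1 + 3*2 + 1*3 panels
  expect_true(all(mapply(grepl, tab$superkingdom, tab$group, fixed = TRUE)))
})

test_that("universal core is strict and nests inside near-universal", {
  meta <- make_meta(2, 3, 2)
  m <- make_matrix(list(all7 = rep(1L, 7), miss1 = c(1L, 1L, 1L, 1L, 1L, 1L, 0L)), meta)
  expect_identical(universal_core(m, meta), "all7")

  meta100 <- make_meta(0, 100, 0)
  m100 <- matrix(0L, 2, 100, dimnames = list(c("in91", "in90"), meta100$organism_id))
  m100["in91", 1:91] <- 1L
  m100["in90", 1:90] <- 1L
  tm <- trait_matrix(m100)
  expect_identical(near_universal(tm, 0.90), "in91")
  expect_identical(sort(near_universal(tm, 0)), c("in90", "in91"))

  set.seed(44)
  d <- random_dataset(40, 3, 4, 3, density = 0.8)
  for (th in c(0.3, 0.6, 0.9)) {
    expect_true(all(universal_core(d$matrix) %in% near_universal(d$matrix, th)))
  }
  # antitone in the threshold
  expect_true(all(near_universal(d$matrix, 0.8) %in% near_universal(d$matrix, 0.5)))
})

test_that("archaeal stem loss depresses spread in Archaea only", {
  f_medians <- function(rate, seed) {
    sim <- simulate_repertoires(scenario_params(
      n_organisms = c(A = 8, B = 20, E = 10), n_core = 40,
      n_specific = c(A = 0, B = 0, E = 0), n_hgt = 0,
      archaeal_loss_rate = rate, late_bacterial_loss_rate = 0, seed = seed))
    p <- spread_profiles(sim$matrix, sim$metadata)
    core <- p[p$trait_id %in% sim$truth$traits$trait_id, ]
    fA <- ifelse(is.na(core$f_A), 0, core$f_A)  # absent from A counts as 0 spread
    c(mean_A = mean(fA), median_B = median(core$f_B), median_E = median(core$f_E))
  }
  for (seed in 1:20) {
    none <- f_medians(0, seed)
    lost <- f_medians(0.4, seed)
    expect_lt(lost[["mean_A"]], none[["mean_A"]])
    expect_equal(lost[["median_B"]], none[["median_B"]])
    expect_equal(lost[["median_E"]], none[["median_E"]])
  }
})
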