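test_that("per-experiment depletion calls follow the strict -1.5 rule", {
  thr <- silac_thresholds()
  expect_equal(call_depletion(-2.0, -1.8, thr), "depleted")
  expect_equal(call_depletion(-2.0, -1.0, thr), "not_depleted")
  # the cutoff is a strict inequality: exactly -1.5 is not depleted
  expect_equal(call_depletion(-1.5, -1.5, thr), "not_depleted")
  expect_equal(call_depletion(NA, -2.0, thr), "incomplete")

  mean_thr <- silac_thresholds(combine_rule = "mean_of_orientations")
  expect_equal(call_depletion(-2.0, -1.2, mean_thr), "depleted") # mean -1.6
  expect_equal(call_depletion(-2.0, -1.0, mean_thr), "not_depleted")
})

test_that("label-bias flag uses a strict +/-0.5 WT/WT band", {
  thr <- silac_thresholds()
  expect_true(flag_label_bias(c(0.8, 0.1, -0.2), thr))
  # the boundary value -0.5 lies inside the accepted band
  expect_false(flag_label_bias(c(0.4, -0.5, 0.0), thr))
  expect_false(flag_label_bias(numeric(0), thr))
  expect_false(flag_label_bias(c(NA, NA), thr))
  m <- rbind(c(0.8, 0, 0), c(0.4, -0.5, 0), c(NA, NA, NA))
  expect_equal(unname(flag_label_bias(m, thr)), c(TRUE, FALSE, FALSE))
})

test_that("combined calls require min_experiments and no label bias", {
  sites <- toy_sites()
  calls <- silac_depletion_calls(sites, silac_thresholds())
  calls <- calls[match(sites$site_id, calls$site_id), ]
  # Atg13: depleted in experiments 1-2, clean controls
  expect_true(calls$combined_depleted[1])
  expect_equal(calls$n_depleted[1], 2)
  # Sorbs2: not depleted anywhere, and label-biased (control 0.9)
  expect_true(calls$label_biased[3])
  expect_false(calls$combined_depleted[3])

  # label bias excludes even a depleted site
  biased <- sites
  biased$control_exp2[1] <- 1.0
  calls2 <- silac_depletion_calls(biased, silac_thresholds())
  expect_false(calls2$combined_depleted[calls2$site_id == "Atg13_S355"])

  # raising min_experiments removes the 2-of-3 site
  calls3 <- silac_depletion_calls(sites,
                                  silac_thresholds(min_experiments = 3))
  expect_false(calls3$combined_depleted[calls3$site_id == "Atg13_S355"])
  expect_true(calls3$combined_depleted[calls3$site_id == "Prkab2_S38"])
})

test_that("depletion calls are monotone in threshold and min_experiments", {
  withr::with_seed(5, {
    n <- 400
    sites <- tibble::tibble(
      site_id = sprintf("s%03d", 1:n), gene = sprintf("g%03d", 1:n),
      ratio_fwd_exp1 = rnorm(n, -1, 1), ratio_rev_exp1 = rnorm(n, -1, 1),
      ratio_fwd_exp2 = rnorm(n, -1, 1), ratio_rev_exp2 = rnorm(n, -1, 1),
      ratio_fwd_exp3 = rnorm(n, -1, 1), ratio_rev_exp3 = rnorm(n, -1, 1)
    )
  })
  dep_set <- function(thr) {
    calls <- silac_depletion_calls(sites, thr)
    calls$site_id[calls$combined_depleted]
  }
  strict <- dep_set(silac_thresholds(depletion_log2 = -1.5))
  loose <- dep_set(silac_thresholds(depletion_log2 = -0.5))
  expect_true(all(strict %in% loose))
  more_exp <- dep_set(silac_thresholds(min_experiments = 2))
  expect_true(all(more_exp %in% strict))

  # combined set is contained in the union of per-experiment depleted sets
  calls <- silac_depletion_calls(sites, silac_thresholds())
  per_exp_union <- calls$site_id[
    calls$exp1 == "depleted" | calls$exp2 == "depleted" |
      calls$exp3 == "depleted"
  ]
  expect_true(all(strict %in% per_exp_union))
})

test_that("label-swap symmetry maps depletion onto enrichment", {
  withr::with_seed(6, {
    n <- 300
    sites <- tibble::tibble(
      site_id = sprintf("s%03d", 1:n), gene = sprintf("g%03d", 1:n),
      ratio_fwd_exp1 = rnorm(n, 0, 1.5), ratio_rev_exp1 = rnorm(n, 0, 1.5)
    )
  })
  swapped <- dplyr::mutate(sites,
    ratio_fwd_exp1 = -ratio_fwd_exp1, ratio_rev_exp1 = -ratio_rev_exp1)
  thr <- silac_thresholds()
  dep_swapped <- call_depletion(swapped$ratio_fwd_exp1,
                                swapped$ratio_rev_exp1, thr) == "depleted"
  enriched_orig <- sites$ratio_fwd_exp1 > -thr$depletion_log2 &
    sites$ratio_rev_exp1 > -thr$depletion_log2
  expect_equal(dep_swapped, enriched_orig)
})

test_that("protein-level-change flag requires enough sites mostly depleted", {
  calls <- tibble::tibble(
    site_id = sprintf("s%d", 1:8),
    gene = c(rep("Sorbs2", 4), rep("Atg13", 1), rep("Other", 3)),
    combined_depleted = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  flagged <- flag_protein_level_change(calls)
  expect_true(all(flagged$protein_level_flag[flagged$gene == "Sorbs2"]))
  # single depleted site never triggers the flag
  expect_false(any(flagged$protein_level_flag[flagged$gene == "Atg13"]))
  # 1/3 depleted is below the default fraction
  expect_false(any(flagged$protein_level_flag[flagged$gene == "Other"]))
})

test_that("planted protein-level confounders are flagged at >= 90%", {
  scr <- generate_screen(generator_config(n_proteins = 1500, seed = 21))
  calls <- flag_protein_level_change(
    silac_depletion_calls(scr$sites, silac_thresholds())
  )
  pl_sites <- scr$truth$site_id[scr$truth$class == "protein_level"]
  expect_gt(length(pl_sites), 0)
  hit <- calls$protein_level_flag[calls$site_id %in% pl_sites]
  expect_gte(mean(hit), 0.9)
})

test_that("scatter quadrants agree with depletion calls and direct counts", {
  thr <- silac_thresholds()
  sites <- tibble::tibble(
    site_id = c("a", "b", "c"), gene = c("a", "b", "c"),
    ratio_fwd_exp1 = c(-2, 2, 0), ratio_rev_exp1 = c(-2, 2, 0)
  )
  sc <- scatter_table(sites, 1, thr)
  expect_equal(sc$quadrant, c("lower_left", "upper_right", "centre"))

  withr::with_seed(7, {
    n <- 500
    sites <- tibble::tibble(
      site_id = sprintf("s%03d", 1:n), gene = sprintf("g%03d", 1:n),
      ratio_fwd_exp1 = rnorm(n, 0, 2), ratio_rev_exp1 = rnorm(n, 0, 2)
    )
  })
  sc <- scatter_table(sites, 1, thr)
  dep <- call_depletion(sites$ratio_fwd_exp1, sites$ratio_rev_exp1, thr)
  expect_equal(sc$quadrant == "lower_left", dep == "depleted")
  expect_equal(sum(sc$quadrant == "lower_left"),
               sum(sites$ratio_fwd_exp1 < -1.5 & sites$ratio_rev_exp1 < -1.5))
  expect_equal(sum(sc$quadrant == "upper_right"),
               sum(sites$ratio_fwd_exp1 > 1.5 & sites$ratio_rev_exp1 > 1.5))
})
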