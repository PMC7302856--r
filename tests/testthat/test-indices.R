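test_that("hand-similarity index evaluates its printed contrast", {
  expect_equal(hand_similarity_index(equal_rdm(3)), 0)
  # (T-CP + T-AP) - (H-CP + H-AP) = (2 + 2) - (1 + 1)
  expect_equal(hand_similarity_index(toy_rdm(hc = 1, ha = 1, ht = 9,
                                             ca = 9, ct = 2, at = 2)), 2)
  # tool-like geometry gives negative values
  expect_equal(hand_similarity_index(toy_rdm(hc = 3, ha = 3, ht = 9,
                                             ca = 9, ct = 1, at = 1)), -4)
  # symmetric in the two prosthesis conditions
  expect_equal(hand_similarity_index(toy_rdm(hc = 1, ha = 2, ht = 5,
                                             ca = 4, ct = 3, at = 7)),
               hand_similarity_index(toy_rdm(hc = 2, ha = 1, ht = 5,
                                             ca = 4, ct = 7, at = 3)))
})

test_that("hand-similarity is the negative of the tool-similarity contrast", {
  tool_similarity <- function(x) { # contrast with hand and tool terms swapped
    (rdm_entry(x, "hands", "cosmetic_prosthesis") +
       rdm_entry(x, "hands", "active_prosthesis")) -
      (rdm_entry(x, "tools", "cosmetic_prosthesis") +
         rdm_entry(x, "tools", "active_prosthesis"))
  }
  set.seed(11)
  for (i in 1:10) {
    v <- runif(6, 0, 5)
    r <- toy_rdm(v[1], v[2], v[3], v[4], v[5], v[6])
    expect_equal(hand_similarity_index(r), -tool_similarity(r))
  }
})

test_that("prosthesis-similarity index evaluates its printed contrast", {
  expect_equal(prosthesis_similarity_index(equal_rdm(5)), 0)
  # 3(H-CP + T-AP) - 2(H-AP + T-CP + AP-CP) = 3*4 - 2*5
  expect_equal(prosthesis_similarity_index(toy_rdm(hc = 2, ha = 2, ht = 9,
                                                   ca = 1, ct = 2, at = 2)), 2)
  # natural-category geometry scores strongly negative
  expect_equal(prosthesis_similarity_index(toy_rdm(hc = 1, ha = 3, ht = 9,
                                                   ca = 3, ct = 3, at = 1)), -12)
})

test_that("indices are linear and separate the two planted geometries", {
  set.seed(12)
  v <- runif(6, 0, 4)
  r1 <- toy_rdm(v[1], v[2], v[3], v[4], v[5], v[6])
  r3 <- toy_rdm(3 * v[1], 3 * v[2], 3 * v[3], 3 * v[4], 3 * v[5], 3 * v[6])
  expect_equal(hand_similarity_index(r3), 3 * hand_similarity_index(r1))
  expect_equal(prosthesis_similarity_index(r3),
               3 * prosthesis_similarity_index(r1))

  # cluster geometry beats natural-category geometry on the index
  ctl <- rdm(default_control_template()$target_rdm)
  usr <- rdm(default_user_template()$target_rdm)
  expect_gt(prosthesis_similarity_index(usr), prosthesis_similarity_index(ctl))
})

test_that("missing conditions are reported by name", {
  cn <- c("hands", "tools")
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(cn, cn))
  expect_error(hand_similarity_index(rdm(m)), "cosmetic_prosthesis")
})

test_that("hand-tool residualisation matches the closed-form OLS oracle", {
  # perfect fit: residuals all zero
  expect_equal(standardize_by_hand_tool(c(1, 2, 3), c(1, 2, 3)),
               c(0, 0, 0), ignore_attr = TRUE)

  # hand-solved normal equations: y = (2,4,6,9), x = (1,2,3,4)
  # slope = 11.5/5 = 2.3, intercept = -0.5, residuals (0.2, -0.1, -0.4, 0.3)
  res <- standardize_by_hand_tool(c(2, 4, 6, 9), c(1, 2, 3, 4))
  expect_equal(unname(res), c(0.2, -0.1, -0.4, 0.3), tolerance = 1e-10)
  expect_equal(sum(res), 0, tolerance = 1e-12)
  expect_equal(cor(res, c(1, 2, 3, 4)), 0, tolerance = 1e-10)

  # constant covariate: mean-centering fallback with a warning
  expect_warning(fb <- standardize_by_hand_tool(c(1, -1, 3), c(1, 1, 1)),
                 "mean-centering")
  expect_equal(unname(fb), c(0, -2, 2))

  # invariant to adding any multiple of the covariate
  set.seed(13)
  y <- rnorm(10); x <- rnorm(10)
  expect_equal(unname(standardize_by_hand_tool(y + 2.7 * x, x)),
               unname(standardize_by_hand_tool(y, x)), tolerance = 1e-10)

  expect_error(standardize_by_hand_tool(c(1, 2), c(1, 2)), "at least 3")
})

test_that("active-distance replacement touches exactly the three entries", {
  r1 <- toy_rdm(hc = 1, ha = 5, ht = 9, ca = 6, ct = 7, at = 2)
  r2 <- toy_rdm(hc = 1, ha = 3, ht = 9, ca = 2, ct = 7, at = 4)
  r3 <- toy_rdm(hc = 1, ha = 9, ht = 8, ca = 9, ct = 7, at = 9)
  rdms <- list(u1 = r1, u2 = r2, u3 = r3)

  expect_identical(replace_active_distances(rdms, character()), rdms)

  out <- replace_active_distances(rdms, "u3")
  expect_equal(rdm_entry(out$u3, "tools", "active_prosthesis"), mean(c(2, 4)))
  expect_equal(rdm_entry(out$u3, "hands", "active_prosthesis"), mean(c(5, 3)))
  expect_equal(rdm_entry(out$u3, "active_prosthesis", "cosmetic_prosthesis"),
               mean(c(6, 2)))
  # untouched entries, including hands-tools
  expect_equal(rdm_entry(out$u3, "hands", "tools"), 8)
  expect_equal(rdm_entry(out$u3, "hands", "cosmetic_prosthesis"), 1)
  expect_identical(out$u1, r1)

  excl <- replace_active_distances(rdms, "u3", variant = "exclude")
  expect_named(excl, c("u1", "u2"))

  expect_error(replace_active_distances(rdms, c("u1", "u2", "u3")),
               "no reference group")
})

test_that("own-prosthesis normalisation is the ratio to the control baseline", {
  ctrl <- list(toy_rdm(hc = 2, ha = 4, ht = 9, ca = 5, ct = 6, at = 3),
               toy_rdm(hc = 4, ha = 4, ht = 9, ca = 5, ct = 8, at = 3))
  # control means: cosmetic-hands = 3, cosmetic-tools = 7,
  #                active-hands = 4,  active-tools = 3

  user_eq <- toy_rdm(hc = 1, ha = 1, ht = 9, ca = 1, ct = 1, at = 1,
                     own_h = 3, own_t = 7)
  s <- own_prosthesis_normalized(user_eq, ctrl, own_type = "cosmetic")
  expect_equal(s$own_hand_normalized, 1)
  expect_equal(s$own_tool_normalized, 1)
  expect_equal(s$matched_control_condition, "cosmetic_prosthesis")

  user_2x <- toy_rdm(hc = 1, ha = 1, ht = 9, ca = 1, ct = 1, at = 1,
                     own_h = 6, own_t = 14)
  expect_equal(own_prosthesis_normalized(user_2x, ctrl,
                                         own_type = "cosmetic")$own_hand_normalized, 2)

  # matching rules: active own prosthesis normally matches the active
  # condition; a hand-like active one re-matches to cosmetic
  act <- own_prosthesis_normalized(user_eq, ctrl, own_type = "mechanical")
  expect_equal(act$matched_control_condition, "active_prosthesis")
  expect_equal(act$own_hand_normalized, 3 / 4)
  hl <- own_prosthesis_normalized(user_eq, ctrl, own_type = "mechanical",
                                  hand_like = TRUE, matching = "hand_likeness")
  expect_equal(hl$matched_control_condition, "cosmetic_prosthesis")

  # zero control baseline is an error
  ctrl0 <- list(toy_rdm(hc = 0, ha = 1, ht = 9, ca = 1, ct = 1, at = 1))
  expect_error(own_prosthesis_normalized(user_eq, ctrl0, own_type = "cosmetic"),
               "zero")
  # user without the own condition
  expect_error(own_prosthesis_normalized(equal_rdm(), ctrl,
                                         own_type = "cosmetic"),
               "own_prosthesis")
})

test_that("a planted own-prosthesis displacement is recovered at cohort level", {
  cfg <- sim_config(n_controls = 10, n_users = 14, n_runs = 3, n_voxels = 24,
                    n_residual_timepoints = 40, noise_variance = 0.5,
                    spatial_correlation_length = 0, seed = 77)
  ch <- simulate_cohort(cfg, include_own = TRUE, own_hand_scale = 1.5)
  rdms <- cohort_rdms(ch)
  user_ids <- ch$metadata$subject_id[ch$metadata$group == "user"]
  ctrl_ids <- ch$metadata$subject_id[ch$metadata$group == "control"]
  own <- own_prosthesis_scores(rdms[user_ids], rdms[ctrl_ids], ch$metadata)
  expect_gt(nrow(own), 3)
  tt <- one_sample_t_vs(own$own_hand_normalized, 1)
  expect_gt(tt$statistic, 0)
  expect_lt(tt$p_value, 0.05)
})

test_that("the tidy index table carries raw, covariate and residualised values", {
  cfg <- tiny_config(seed = 19)
  ch <- simulate_cohort(cfg, include_own = FALSE)
  rdms <- cohort_rdms(ch)
  idx <- compute_similarity_indices(rdms, ch$metadata)
  expect_equal(nrow(idx), nrow(ch$metadata))
  expect_equal(idx$hand_similarity_raw,
               vapply(rdms[idx$subject_id], hand_similarity_index, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(sum(idx$prosthesis_similarity_std), 0, tolerance = 1e-8)
  expect_equal(cor(idx$hand_similarity_std, idx$hand_tool_distance), 0,
               tolerance = 1e-8)
  # by-group residualisation: residuals sum to zero within each group
  idx_g <- compute_similarity_indices(rdms, ch$metadata, pooling = "by_group")
  sums <- tapply(idx_g$hand_similarity_std, idx_g$group, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-8)
})
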