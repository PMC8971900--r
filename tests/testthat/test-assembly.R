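test_that("neutral occupancy predictions behave like CDFs", {
  d <- 1e-4
  set.seed(77)
  p <- sort(runif(50, 1e-5, 0.5))
  for (Nm in c(50, 1000)) {
    f <- ncm_occupancy(p, Nm, d)
    expect_true(all(diff(f) >= 0))
    expect_true(all(diff(f)[f[-1] < 1 - 1e-9] > 0))  # strict until saturation
    expect_true(all(f >= 0 & f <= 1))
    fr <- ncm_occupancy_reads(p, Nm, 1 / d)
    expect_true(all(diff(fr) >= 0))
  }
  expect_equal(ncm_occupancy(0, 1000, d), 0)       # F(0) = 0 boundary
  expect_equal(ncm_occupancy_reads(0, 1000, 1e4), 0)
  # the two detection models agree when depth >> Nm
  pp <- c(1e-4, 1e-3, 1e-2)
  expect_equal(ncm_occupancy(pp, 50, 1e-5),
               ncm_occupancy_reads(pp, 50, 1e5), tolerance = 0.02)
})

test_that("fit_ncm recovers the migration parameter from neutral data", {
  prof <- default_profiles(n_tail = 164)   # 200 taxa
  tab <- simulate_neutral_assembly(
    simulation_config(n_samples = 60, N = 1000, m = 1, seed = 21,
                      depth_range = c(30000L, 30000L)),
    prof$saliva)
  fit <- fit_ncm(tab, detection = "reads", n_boot = 49, boot_seed = 21)
  expect_s3_class(fit, "ncm_fit")
  expect_lt(abs(fit$Nm - 1000) / 1000, 0.25)
  expect_gte(fit$r_squared, 0.8)
  expect_true(fit$Nm_lower <= fit$Nm_upper)
  pc <- partition_counts(fit)
  expect_equal(sum(pc$n), nrow(fit$taxa))
  expect_gte(pc$n[pc$partition == "fit"] / sum(pc$n), 0.8)
  expect_true(all(fit$taxa$lower <= fit$taxa$freq_pred + 1e-12))
  expect_true(all(fit$taxa$freq_pred <= fit$taxa$upper + 1e-12))
})

test_that("fit_ncm rejects degenerate inputs and flags constant occupancy", {
  tab <- toy_table()
  expect_error(fit_ncm(tab), ">= 10 samples")
  big <- feature_table(matrix(5L, 12, 3,
                              dimnames = list(paste0("s", 1:12),
                                              paste0("t", 1:3))))
  expect_error(fit_ncm(big), "fewer than 5 taxa")
  # all taxa everywhere: constant occupancy -> undefined R^2, reported poor
  allin <- feature_table(matrix(rpois(12 * 8, 50) + 1L, 12, 8,
                                dimnames = list(paste0("s", 1:12),
                                                paste0("t", 1:8))))
  expect_message(f <- fit_ncm(allin, n_boot = 0), "R\\^2 undefined")
  expect_true(is.na(f$r_squared))
  expect_true(all(f$taxa$freq_obs == 1))
})

test_that("a taxon forced into every sample at tiny abundance sits above", {
  set.seed(31)
  prof <- default_profiles(n_tail = 104)
  tab <- simulate_neutral_assembly(
    simulation_config(n_samples = 40, N = 500, m = 1, seed = 31,
                      depth_range = c(20000L, 20000L)),
    prof$saliva)
  forced <- matrix(2L, nrow(tab), 1, dimnames = list(rownames(tab), "forced"))
  fit <- fit_ncm(feature_table(cbind(tab, forced)), n_boot = 0)
  expect_equal(as.character(fit$taxa$partition[fit$taxa$taxon == "forced"]),
               "above")
})

test_that("tidy/glance/autoplot expose the fit", {
  prof <- default_profiles(n_tail = 64)
  tab <- simulate_neutral_assembly(
    simulation_config(n_samples = 20, N = 1000, m = 1, seed = 2,
                      depth_range = c(10000L, 10000L)),
    prof$saliva)
  fit <- fit_ncm(tab, n_boot = 0)
  td <- tidy(fit)
  expect_true(all(c("taxon", "p", "freq_obs", "freq_pred", "partition")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_taxa, nrow(td))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("null randomization preserves totals, richness and occupancy", {
  study <- small_study()
  sub <- study$table[1:8, colSums(study$table[1:8, ]) > 0]
  pa <- (sub > 0) * 1L
  nm <- vegan::nullmodel(pa, "curveball")
  sims <- stats::simulate(nm, nsim = 20, seed = 9)
  for (k in c(1, 10, 20)) {
    expect_equal(rowSums(sims[, , k]), rowSums(pa))   # sample richness
    expect_equal(colSums(sims[, , k]), colSums(pa))   # taxon occupancy
    refilled <- t(vapply(seq_len(nrow(sub)), function(i) {
      oralsite:::refill_abundance(sims[i, , k], rowSums(sub)[i],
                                  colSums(sub))
    }, integer(ncol(sub))))
    expect_equal(rowSums(refilled), unname(rowSums(sub)))  # totals
    expect_equal(rowSums(refilled > 0), unname(rowSums(pa)))
  }
})

test_that("null_model summary satisfies its identities", {
  study <- small_study()
  res <- null_model(study$table, study$metadata, n_null = 29, seed = 4)
  s <- glance(res)
  expect_equal(nrow(s), 2)
  expect_equal(s$ses_beta, (s$obs_beta - s$mean_null_beta) / s$sd_null_beta,
               tolerance = 1e-12)
  expect_true(all(s$obs_beta >= 0 & s$obs_beta <= 1))
  expect_true(all(s$mean_null_beta >= 0 & s$mean_null_beta <= 1))
  expect_true(all(s$ds >= 0 & s$ds <= 100))
  # gamma is the count of taxa with nonzero group totals
  for (h in s$group) {
    ids <- study$metadata$sample_id[study$metadata$habitat == h]
    expect_equal(s$gamma[s$group == h],
                 sum(colSums(study$table[ids, ]) > 0))
    expect_equal(s$obs_mean_alpha[s$group == h],
                 mean(rowSums(study$table[ids, ] > 0)))
  }
  expect_error(null_model(study$table[1:2, ], study$metadata),
               "fewer than 3")
})

test_that("deterministic strength has the right limits", {
  expect_equal(deterministic_strength(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # duplicated samples: observed 0, null positive -> full strength
  expect_equal(deterministic_strength(c(0, 0), c(0.4, 0.6)), 100)
  expect_warning(ds <- deterministic_strength(c(0, 0.4), c(0, 0.2)),
                 "skipped")
  expect_equal(ds, 50)
  expect_equal(deterministic_strength(0.8, 0.4), 50)
  expect_equal(deterministic_strength(0.2, 0.4), 50)
})

test_that("duplicated samples give DS = 100 through the null model", {
  study <- small_study()
  one <- study$table[3, colSums(study$table[3, , drop = FALSE]) > 0,
                     drop = FALSE]
  dup <- one[rep(1, 5), ]
  rownames(dup) <- paste0("d", 1:5)
  res <- null_model(feature_table(dup), n_null = 19, seed = 2)
  s <- glance(res)
  expect_equal(s$obs_beta, 0)
  expect_equal(s$ds, 100)
})

test_that("neutral assemblies score lower DS than habitat-filtered ones", {
  prof <- default_profiles(n_tail = 104)
  wins <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_samples = 12, N = 2000, m = 1, seed = s,
                             depth_range = c(8000L, 8000L))
    neu <- simulate_neutral_assembly(cfg, prof$saliva)
    fil <- simulate_filtered_assembly(cfg, prof$saliva, prof$mucosa,
                                      strength = 1)
    ds_n <- glance(null_model(neu, n_null = 29, seed = s))$ds
    ds_f <- glance(null_model(fil, n_null = 29, seed = s))$ds
    ds_n < ds_f
  })
  expect_gte(sum(wins), 9)
})
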