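test_that("alpha metrics match hand-computed values", {
  expect_equal(shannon(c(10, 10, 10, 10)), 2)
  expect_equal(shannon(42), 0)
  expect_equal(shannon(c(75, 25)), 0.8112781245, tolerance = 1e-9)
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1(c(1, 1)), 3)
  expect_equal(simpson(c(1, 1)), 0.5)
  expect_equal(simpson(7), 0)
  expect_equal(simpson(c(1, 1, 2)), 0.625)
  for (f in list(shannon, chao1, simpson)) {
    expect_error(f(c(0, 0, 0)), "all-zero")
    expect_error(f(c(-1, 2)), "negative")
  }
  # natural-log base option
  expect_equal(shannon(c(1, 1), base = exp(1)), log(2))
})

test_that("alpha_diversity returns one coherent row per sample", {
  tab <- toy_table()
  a <- alpha_diversity(tab)
  expect_equal(nrow(a), 3)
  expect_equal(a$richness, unname(rowSums(tab > 0)))
  expect_true(all(a$chao1 >= a$richness))
  expect_true(all(a$simpson >= 0 & a$simpson <= 1))
  expect_true(all(a$shannon >= 0))
  expect_equal(a$depth, unname(rowSums(tab)))
})

test_that("bray_curtis matches its formula and the distance axioms", {
  rel <- rbind(s1 = c(0.6, 0.4, 0), s2 = c(0.2, 0.4, 0.4), s3 = c(0.6, 0.4, 0))
  d <- bray_curtis(rel)
  expect_equal(d["s1", "s2"], 0.4)
  expect_equal(d["s1", "s3"], 0)          # identical rows
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(disj)["a", "b"], 1)  # disjoint supports
  expect_error(bray_curtis(rel[1, , drop = FALSE]), "2 samples")
})

test_that("alpha and beta metrics agree with brute force on random vectors", {
  set.seed(41)
  for (rep in 1:300) {
    x <- rpois(sample(2:12, 1), lambda = sample(c(0.5, 2, 20), 1))
    if (sum(x) == 0) x[1] <- 1
    expect_equal(shannon(x), brute_shannon(x), tolerance = 1e-12)
    expect_equal(chao1(x), brute_chao1(x), tolerance = 1e-12)
    expect_equal(simpson(x), brute_simpson(x), tolerance = 1e-12)
  }
  # cross-check against vegan as an independent implementation
  set.seed(42)
  m <- matrix(rpois(60, 5), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  m[1, ] <- m[1, ] + 1
  expect_equal(apply(m, 1, shannon, base = exp(1)),
               vegan::diversity(m, "shannon"), tolerance = 1e-12)
  expect_equal(apply(m, 1, simpson), vegan::diversity(m, "simpson"),
               tolerance = 1e-12)
  rel <- to_relative(feature_table(m))
  expect_equal(bray_curtis(rel),
               as.matrix(vegan::vegdist(rel, "bray")), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("shannon is maximised by the uniform composition", {
  # exhaustive enumeration of integer compositions at fixed richness
  for (k in 2:4) {
    total <- 12
    combos <- all_compositions(k, total)
    h <- apply(combos, 1, function(x) if (any(x == 0)) NA else shannon(x))
    expect_equal(unname(combos[which.max(h), ]), rep(total / k, k))
  }
})

test_that("nmds embeds exact low-dimensional configurations faithfully", {
  set.seed(7)
  pts <- matrix(rnorm(24), ncol = 2,
                dimnames = list(paste0("s", 1:12), NULL))
  dm <- as.matrix(dist(pts))
  ord <- nmds_ordination(dm, dims = 2, seed = 1)
  emb <- as.matrix(dist(as.matrix(ord$points[, c("nmds1", "nmds2")])))
  expect_gte(cor(dm[lower.tri(dm)], emb[lower.tri(emb)], method = "spearman"),
             0.99)
  expect_lt(ord$stress, 0.05)
  # degenerate all-zero distances collapse to a point with zero stress
  zero <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  ord0 <- nmds_ordination(zero)
  expect_equal(ord0$stress, 0)
  expect_true(all(as.matrix(ord0$points[, -1]) == 0))
})

test_that("paired-habitat ordination separates habitats", {
  study <- small_study()
  rel <- to_relative(collapse_taxa(study$table, study$taxonomy, "genus"))
  dm <- bray_curtis(rel)
  ord <- nmds_ordination(dm, seed = 2)
  pts <- as.matrix(ord$points[, c("nmds1", "nmds2")])
  rownames(pts) <- ord$points$sample_id
  hab <- study$metadata$habitat[match(rownames(pts),
                                      study$metadata$sample_id)]
  emb <- as.matrix(dist(pts))
  same <- outer(hab, hab, "==")
  diag(same) <- NA
  expect_lt(mean(emb[which(same)]), mean(emb[which(!same)]))
})

test_that("compare_groups runs a Welch test with per-level means and SEs", {
  md <- tibble::tibble(sample_id = paste0("s", 1:8),
                       individual_id = paste0("i", 1:8),
                       habitat = rep(c("saliva", "buccal_mucosa"), each = 4))
  v <- setNames(c(1, 2, 3, 4, 1, 2, 3, 4), md$sample_id)
  res <- compare_groups(v, md)
  expect_gt(res$p_value, 0.99)                  # identical groups
  expect_equal(res$mean1 - res$mean2, 0)
  expect_equal(res$se1, sd(1:4) / 2)            # SE = SD / sqrt(n)
  vv <- setNames(c(1, 2, 3, 10, 11, 12, 10.5, 11.5), md$sample_id)
  res2 <- compare_groups(vv, md)
  expect_lt(res2$p_value, 0.05)
  expect_error(compare_groups(v[1:5], md[1:5, ]), "2 samples per level")
  # three-value toy group definition check
  md3 <- tibble::tibble(sample_id = paste0("t", 1:6),
                        individual_id = paste0("j", 1:6),
                        habitat = rep(c("saliva", "buccal_mucosa"), each = 3))
  v3 <- setNames(c(2, 4, 9, 1, 1, 1), md3$sample_id)
  r3 <- compare_groups(v3, md3)
  expect_equal(r3$mean1, 5)
  expect_equal(r3$se1, sd(c(2, 4, 9)) / sqrt(3))
})

test_that("a planted Shannon shift is detected with high power", {
  set.seed(8)
  hits <- replicate(100, {
    md <- tibble::tibble(sample_id = paste0("s", 1:100),
                         individual_id = paste0("i", 1:100),
                         habitat = rep(habitat_levels(), each = 50))
    v <- setNames(c(rnorm(50, 0), rnorm(50, 3)), md$sample_id)  # 3 SD shift
    compare_groups(v, md)$p_value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("spearman_age reports per-habitat rank correlations", {
  md <- toy_metadata()
  md$age <- c(20, 20, 45, 45)
  md2 <- dplyr::bind_rows(md, dplyr::mutate(md,
    sample_id = paste0(sample_id, "b"), individual_id = paste0(individual_id, "b"),
    age = c(30, 30, 35, 35)))
  v <- setNames(md2$age + 0.001, md2$sample_id)   # perfectly increasing
  res <- spearman_age(v, md2)
  expect_equal(res$rho, c(1, 1))
  vd <- setNames(-md2$age, md2$sample_id)         # perfectly decreasing
  expect_equal(spearman_age(vd, md2)$rho, c(-1, -1))
  vc <- setNames(rep(1, nrow(md2)), md2$sample_id)
  expect_error(spearman_age(vc, md2), "constant")
})

test_that("independent age and diversity rarely correlate", {
  set.seed(12)
  hits <- replicate(100, {
    md <- tibble::tibble(sample_id = paste0("s", 1:50),
                         individual_id = paste0("i", 1:50),
                         habitat = "saliva", age = sample(20:50, 50, TRUE))
    v <- setNames(rnorm(50), md$sample_id)
    abs(spearman_age(v, md)$rho) < 0.3
  })
  expect_gte(mean(hits), 0.95)
})

test_that("differential abundance mirrors a dominant-taxa table", {
  study <- small_study()
  rel <- to_relative(collapse_taxa(study$table, study$taxonomy, "genus"))
  da <- differential_abundance(rel, study$metadata, top_n = 10)
  expect_equal(nrow(da), 10)
  expect_true(!is.unsorted(rev(da$overall_mean)))   # sorted descending
  expect_true(all(c("stars", "p_adj_bh") %in% names(da)))
  expect_true(da$p_value[da$taxon == "Streptococcus"] < 0.01)
  # identically distributed groups -> no real signal
  sal <- study$metadata$sample_id[study$metadata$habitat == "saliva"]
  md0 <- tibble::tibble(sample_id = sal,
                        individual_id = paste0("x", seq_along(sal)),
                        habitat = rep(habitat_levels(), length.out = length(sal)))
  da0 <- differential_abundance(rel[sal, ], md0, top_n = 5)
  expect_true(all(da0$p_value > 1e-4))
})
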