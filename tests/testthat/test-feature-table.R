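test_that("feature_table validates dimnames, duplicates and counts", {
  m <- matrix(1:4, 2, 2)
  expect_error(feature_table(m), "row names")
  dimnames(m) <- list(c("s1", "s1"), c("a", "b"))
  expect_error(feature_table(m), "duplicated sample id: s1")
  dimnames(m) <- list(c("s1", "s2"), c("a", "a"))
  expect_error(feature_table(m), "duplicated feature id: a")
  dimnames(m) <- list(c("s1", "s2"), c("a", "b"))
  m2 <- m; m2[1, 2] <- -1L
  expect_error(feature_table(m2), "sample 's1', feature 'b'")
  m3 <- matrix(c(1.5, 1, 2, 3), 2, 2, dimnames = dimnames(m))
  expect_error(feature_table(m3), "non-integer")
})

test_that("metadata validation enforces the closed habitat set and pairing", {
  md <- toy_metadata()
  expect_s3_class(validate_metadata(md), "tbl_df")
  bad <- md; bad$habitat[2] <- "tongue"
  expect_error(validate_metadata(bad), "tongue")
  dup <- md; dup$habitat[2] <- "saliva"
  expect_error(validate_metadata(dup), "more than one 'saliva'")
  dup2 <- md; dup2$sample_id[2] <- "s1"
  expect_error(validate_metadata(dup2), "duplicated sample id")
  expect_error(validate_metadata(md[, -2]), "individual_id")
})

test_that("file round trips are lossless for all three formats", {
  dir <- withr::local_tempdir()
  tab <- toy_table()
  write_feature_table(tab, file.path(dir, "ft.tsv"))
  expect_identical(read_feature_table(file.path(dir, "ft.tsv")), tab)

  tax <- toy_taxonomy(colnames(tab), genus = c("Streptococcus", "Veillonella",
                                               "Neisseria", "Rothia"))
  tax$species[2] <- NA  # unassigned rank must survive the round trip
  write_taxonomy(tax, file.path(dir, "tax.tsv"))
  expect_identical(read_taxonomy(file.path(dir, "tax.tsv")), validate_taxonomy(tax))

  md <- toy_metadata()
  write_metadata(md, file.path(dir, "md.tsv"))
  back <- read_metadata(file.path(dir, "md.tsv"))
  expect_equal(back$sample_id, md$sample_id)
  expect_equal(back$age, md$age)
})

test_that("reading rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("#OTU ID\ts1\ts2", "a\t1\t2", "a\t3\t4"),
             file.path(dir, "dup.tsv"))
  expect_error(read_feature_table(file.path(dir, "dup.tsv")),
               "duplicated feature id")
  writeLines(c("sample\ts1", "a\t1"), file.path(dir, "nohdr.tsv"))
  expect_error(read_feature_table(file.path(dir, "nohdr.tsv")), "#OTU ID")
  expect_error(read_feature_table(file.path(dir, "missing.tsv")), "no such file")
  writeLines(c("sample_id\tindividual_id\thabitat", "s1\ti1\ttongue"),
             file.path(dir, "md.tsv"))
  expect_error(read_metadata(file.path(dir, "md.tsv")), "tongue")
})

test_that("taxonomy reader strips rank prefixes and pads short lineages", {
  dir <- withr::local_tempdir()
  writeLines(c("Feature ID\tTaxon\tConfidence",
               "a\tk__Bacteria; p__Firmicutes; c__Bacilli\t0.99"),
             file.path(dir, "tax.tsv"))
  tax <- read_taxonomy(file.path(dir, "tax.tsv"))
  expect_equal(tax$kingdom, "Bacteria")
  expect_equal(tax$class, "Bacilli")
  expect_true(is.na(tax$genus))
})

test_that("remove_singletons drops exactly the total-count-1 features", {
  m <- feature_table(matrix(c(1L, 0L, 0L, 3L, 2L, 0L, 0L, 1L, 1L), 3,
                            dimnames = list(paste0("s", 1:3), c("a", "b", "c"))))
  # totals: a = 1 (singleton), b = 5, c = 2
  out <- remove_singletons(m)
  expect_identical(colnames(out), c("b", "c"))
  expect_identical(remove_singletons(out), out)  # no singletons -> identity
  allsing <- feature_table(matrix(c(1L, 0L, 0L, 1L), 2,
                                  dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_error(remove_singletons(allsing), "empty table")
})

test_that("rarefaction depth is floor(fraction x minimum total)", {
  mk <- function(tot1, tot2) {
    feature_table(matrix(as.integer(c(tot1 - 5, 5, tot2 - 7, 7)), 2,
                         byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("a", "b"))))
  }
  expect_equal(rarefaction_depth(mk(10000, 20000)), 9500)
  expect_equal(rarefaction_depth(mk(100, 300)), 95)
  expect_equal(rarefaction_depth(mk(50201, 199533)), 47690)
  expect_equal(rarefaction_depth(mk(100, 300), fraction = 0.5), 50)
  expect_error(rarefaction_depth(mk(100, 300)[0, , drop = FALSE]), "empty")
})

test_that("rarefy subsamples exactly to depth, reproducibly", {
  tab <- feature_table(matrix(c(5L, 5L, 10L, 0L), 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"), c("a", "b"))))
  out <- rarefy(tab, 10, seed = 1)
  expect_equal(unname(out["s1", ]), c(5, 5))   # depth equals total: identity
  expect_equal(unname(out["s2", ]), c(10, 0))
  out4 <- rarefy(tab, 4, seed = 3)
  expect_true(all(rowSums(out4) == 4))
  expect_equal(unname(out4["s2", ]), c(4, 0))  # single occupied taxon
  expect_true(all(out4 <= tab))
  expect_identical(rarefy(tab, 4, seed = 3), out4)  # seeded determinism
  expect_error(rarefy(tab, 0), "positive")
  big <- feature_table(matrix(c(100L, 100L, 3L, 2L), 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_warning(r <- rarefy(big, 50, seed = 1), "dropping 1 sample")
  expect_identical(rownames(r), "s1")
})

test_that("observed richness is monotone in rarefaction depth", {
  study <- small_study()
  tab <- study$table[1:4, ]
  rich <- sapply(c(200, 1000, 5000), function(d)
    rowSums(rarefy(tab, d, seed = 11) > 0))
  expect_true(all(diff(t(rich)) >= 0))
  expect_true(all(rich[, 3] <= rowSums(tab > 0)))
})

test_that("collapse sums counts by lineage prefix and conserves totals", {
  tab <- feature_table(matrix(c(3L, 4L, 2L, 1L, 0L, 5L), 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"),
                                              c("a1", "a2", "b1"))))
  tax <- toy_taxonomy(c("a1", "a2", "b1"),
                      genus = c("Streptococcus", "Streptococcus", "Rothia"))
  gen <- collapse_taxa(tab, tax, "genus")
  expect_equal(unname(gen[, "Streptococcus"]), c(7, 1))  # additivity
  expect_equal(rowSums(gen), rowSums(tab))               # conservation
  # species-resolved collapse is identity up to relabeling
  sp <- collapse_taxa(tab, tax, "species")
  expect_equal(unname(sp[, tax$species]), unname(tab[, tax$feature_id]))
  # feature missing from taxonomy pools into Unassigned (and conserves)
  expect_message(gen2 <- collapse_taxa(tab, tax[-3, ], "genus"), "Unassigned")
  expect_equal(unname(gen2[, "Unassigned"]), c(2, 5))
  expect_equal(rowSums(gen2), rowSums(tab))
  expect_error(collapse_taxa(tab, tax[-3, ], "genus", missing = "error"),
               "missing from taxonomy")
  # unassigned rank pools too
  tax$genus[3] <- NA
  gen3 <- collapse_taxa(tab, tax, "genus")
  expect_true("Unassigned" %in% colnames(gen3))
})

test_that("to_relative divides by sample totals and flags all-zero samples", {
  tab <- feature_table(matrix(c(2L, 2L, 10L, 0L), 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"), c("a", "b"))))
  rel <- to_relative(tab)
  expect_equal(unname(rel["s1", ]), c(0.5, 0.5))
  expect_equal(unname(rel["s2", ]), c(1, 0))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  zero <- feature_table(matrix(c(0L, 0L, 1L, 2L), 2, byrow = TRUE,
                               dimnames = list(c("sz", "s2"), c("a", "b"))))
  expect_error(to_relative(zero), "sz")
})
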