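# Readers/writers, QC filters and rarefaction.

test_that("ASV table round-trips through TSV in both orientations", {
  m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
              dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
  tab <- asv_table(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(tab, f)
  expect_equal(unclass(read_asv_table(f)), unclass(tab))
  write_asv_table(tab, f, orientation = "features_as_rows")
  expect_equal(unclass(read_asv_table(f, orientation = "features_as_rows")),
               unclass(tab))
  # the feature-oriented file carries a QIIME-style leading token
  expect_match(readLines(f, n = 1), "^#OTU ID")
})

test_that("malformed tables are rejected with the offending label", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s1"), c("a", "b")))
  expect_error(asv_table(m), "s1")
  m2 <- matrix(c(1, -2, 3, 4), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(asv_table(m2), "s2.*a|a.*s2")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ta\tb", "s1\t1\t2", "s1\t3\t4"), f)
  expect_error(read_asv_table(f), "s1")
})

test_that("sample metadata validates taxonomy and round-trips", {
  meta <- toy_meta(c("x1", "x2"), c("spA", "spB"), controls = "neg1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_info(meta, f)
  back <- read_sample_info(f)
  expect_equal(back$sample_id, meta$sample_id)
  expect_equal(back$is_control, meta$is_control)
  bad <- as.data.frame(meta)
  bad$host_species[1] <- ""
  expect_error(sample_info(bad), "x1")
})

test_that("newick io preserves topology and branch lengths", {
  tr <- read_newick(text = "((a:1,b:1):1,c:2);")
  expect_equal(length(tr$tip.label), 3L)
  expect_error(read_newick(text = "((a:1,a:1):1,c:2);"), "duplicate")
  set.seed(42)
  tr2 <- random_bl_tree(8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr2, f)
  back <- read_newick(f)
  expect_true(ape::all.equal.phylo(tr2, back, tolerance = 1e-9))
})

test_that("prune_and_rename keeps path lengths and applies the tip map", {
  set.seed(7)
  tr <- random_bl_tree(5)
  full <- ape::cophenetic.phylo(tr)
  keep <- c("t1", "t3", "t5")
  pruned <- prune_and_rename(tr, keep)
  expect_setequal(pruned$tip.label, keep)
  expect_equal(ape::cophenetic.phylo(pruned)[keep, keep], full[keep, keep],
               tolerance = 1e-12)
  # a study taxon represented by its closest available relative
  map <- tip_name_map("t2", "stand_in_taxon")
  renamed <- prune_and_rename(tr, c("t1", "stand_in_taxon"), map)
  expect_true("stand_in_taxon" %in% renamed$tip.label)
  expect_error(prune_and_rename(tr, c("t1", "nope")), "nope")
})

test_that("control-borne ASVs are removed everywhere, controls dropped", {
  m <- rbind(x1 = c(ctrl_only = 0L, shared = 5L, clean = 3L),
             x2 = c(2L, 1L, 4L),
             neg1 = c(7L, 2L, 0L))
  colnames(m) <- c("ctrl_only", "shared", "clean")
  meta <- toy_meta(c("x1", "x2"), c("spA", "spB"), controls = "neg1")
  out <- remove_control_asvs(asv_table(m), meta)
  expect_equal(rownames(out), c("x1", "x2"))
  expect_equal(colnames(out), "clean")
  expect_equal(unname(unclass(out)[, "clean"]), c(3L, 4L))
  # degenerate: every ASV contaminated
  m2 <- m[, c("ctrl_only", "shared")]
  expect_warning(out2 <- remove_control_asvs(asv_table(m2), meta), "all ASVs")
  expect_equal(ncol(out2), 0L)
  # no controls at all: warn, no-op
  meta_nc <- toy_meta(c("x1", "x2"), c("spA", "spB"))
  expect_warning(out3 <- remove_control_asvs(asv_table(m[1:2, ]), meta_nc),
                 "no control")
  expect_equal(unclass(out3), unclass(asv_table(m[1:2, ])))
})

test_that("minimum-depth filter keeps samples at or above the threshold", {
  m <- rbind(low = c(1000L, 999L), edge = c(1000L, 1000L), high = c(4000L, 1000L))
  colnames(m) <- c("a", "b")
  out <- filter_min_depth(asv_table(m), 2000)
  expect_equal(rownames(out), c("edge", "high"))
  expect_equal(rownames(filter_min_depth(asv_table(m), 1)), rownames(m))
  expect_equal(nrow(filter_min_depth(asv_table(m), 10^6)), 0L)
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(1)
  m <- random_count_table(6, 40, max_count = 400)
  m[1, ] <- 0L; m[1, 1:10] <- 200L           # row sum exactly 2000
  tab <- asv_table(m * 2L)
  tab <- asv_table(rbind(unclass(tab), shallow = c(5L, rep(0L, 39))))
  out <- rarefy(tab, 100, seed = 3)
  expect_false("shallow" %in% rownames(out))
  expect_true(all(rowSums(unclass(out)) == 100))
  expect_true(all(unclass(out) <= unclass(tab)[rownames(out), ]))
  # exact-depth sample passes through unchanged
  tab2 <- asv_table(m)
  out2 <- rarefy(tab2, 2000, seed = 3)
  expect_equal(unclass(out2)["s1", ], unclass(tab2)["s1", ])
  # reproducibility and seed sensitivity
  expect_identical(unclass(rarefy(tab, 100, seed = 3)), unclass(out))
  expect_false(identical(unclass(rarefy(tab, 100, seed = 4)), unclass(out)))
  expect_error(rarefy(tab, 0), "depth")
})

test_that("rarefaction draws are unbiased and order-independent", {
  row <- c(a = 120L, b = 60L, c = 20L)
  tab <- asv_table(matrix(row, 1, 3, dimnames = list("s1", names(row))))
  draws <- t(vapply(1:500, function(s) unclass(rarefy(tab, 50, seed = s))[1, ],
                    numeric(3)))
  expected <- 50 * row / sum(row)
  expect_equal(colMeans(draws), unname(expected), tolerance = 0.05,
               ignore_attr = TRUE)
  # per-sample seeds: permuting the row order leaves each sample's draw alone
  m <- random_count_table(5, 20, max_count = 100)
  t1 <- rarefy(asv_table(m), 30, seed = 9)
  t2 <- rarefy(asv_table(m[5:1, ]), 30, seed = 9)
  expect_equal(unclass(t2)[rownames(t1), ], unclass(t1), ignore_attr = TRUE)
})
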