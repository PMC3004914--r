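test_that("property matrix applies declared log transforms and drops incomplete drugs", {
  prof <- fixture_profiles()
  cols <- c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "UD", "Rev", "tau_off_s")
  logs <- c("Kr_uM", "Ki_kapp_uM", "IC50_uM", "SD", "tau_off_s")
  m <- build_matrix(prof, cols, logs)
  expect_equal(dim(m), c(35L, 7L))
  expect_equal(unname(m["FLX", "log_IC50_uM"]), log10(43.09), tolerance = 1e-12)
  expect_equal(unname(m["FLX", "UD"]), 1.14)

  holey <- prof; holey$tau_off_s[holey$drug_code == "MIA"] <- NA
  expect_warning(m2 <- build_matrix(holey, cols, logs), "MIA")
  expect_equal(nrow(m2), 34L)

  negd <- prof; negd$SD[negd$drug_code == "AMB"] <- -1
  expect_error(build_matrix(negd, cols, logs), "non-positive.*SD.*AMB")
  expect_equal(build_matrix(prof, cols, character())[, "IC50_uM"],
               stats::setNames(prof$IC50_uM, prof$drug_code))
})

test_that("z-scoring normalizes columns and is idempotent", {
  m <- build_matrix(fixture_profiles(), c("IC50_uM", "Rev", "UD"), "IC50_uM")
  z <- zscore(m)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(cbind(a = c(1, 1, 1), b = 1:3)), "constant")
  expect_error(zscore(m[1, , drop = FALSE]), "at least 2")
})

test_that("correlation matrix matches a brute-force covariance oracle", {
  x <- cbind(a = c(1.2, 3.4, 2.2, 5.1, 4.0),
             b = c(0.3, 1.1, 0.9, 2.0, 1.2),
             c = c(9.9, 4.1, 6.6, 1.2, 3.3))
  cm <- correlation_matrix(x)
  bf_r <- function(u, v) {
    du <- u - sum(u) / length(u); dv <- v - sum(v) / length(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(cm$r[i, j], if (i == j) 1 else bf_r(x[, i], x[, j]), tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
})

test_that("correlations are invariant to affine rescaling and flag significance", {
  set.seed(31)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("p", "q", "s")))
  x[, 2] <- x[, 1] * 0.9 + rnorm(20, sd = 0.2) # strongly correlated pair
  cm1 <- correlation_matrix(x)
  y <- x; y[, 1] <- 5 - 2 * y[, 1]             # affine map flips the sign only
  cm2 <- correlation_matrix(y)
  expect_equal(abs(cm2$r), abs(cm1$r), tolerance = 1e-12)
  expect_equal(cm1$flags["p", "q"], "**")
  # insufficient pairwise-complete cells are absent, not fabricated
  x[1:18, 3] <- NA
  cm3 <- correlation_matrix(x)
  expect_true(is.na(cm3$r["p", "s"]))
})

test_that("WPGMA linkage reproduces the hand-computed 1-D example", {
  m <- matrix(c(0, 1, 10, 12), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  tree <- hcluster(m, "wpgma")
  expect_equal(sort(tree$height), c(1, 2, 10.5))
  cut2 <- cut_tree(tree, height = 5)
  expect_equal(unname(cut2[c("a", "b")]), rep(cut2[["a"]], 2))
  expect_equal(unname(cut2[c("c", "d")]), rep(cut2[["c"]], 2))
  expect_true(cut2[["a"]] != cut2[["c"]])
  # identical rows merge first at distance zero
  m2 <- rbind(m, e = 0)
  expect_equal(min(hcluster(m2, "wpgma")$height), 0)
})

test_that("both linkage rules agree with brute-force agglomeration oracles", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(n * 3), ncol = 3)
    rownames(x) <- paste0("r", seq_len(n))
    expect_true(tree_agrees_with_oracle(hcluster(x, "wpgma"), bf_wpgma(x)))
    expect_true(tree_agrees_with_oracle(hcluster(x, "ward"), bf_ward(x)))
  }
})

test_that("linkage heights are monotone non-decreasing on Euclidean input", {
  set.seed(42)
  for (rep in 1:10) {
    x <- matrix(rnorm(7 * 4), ncol = 4)
    expect_true(!is.unsorted(hcluster(x, "wpgma")$height))
    expect_true(!is.unsorted(hcluster(x, "ward")$height))
  }
})

test_that("tree cutting and Newick export are consistent with the tree", {
  m <- zscore(build_matrix(fixture_profiles(), c("IC50_uM", "Rev", "UD"), "IC50_uM"))
  tree <- hcluster(m, "ward")
  expect_equal(length(unique(cut_tree(tree, n_clusters = 1))), 1L)
  expect_equal(length(unique(cut_tree(tree, n_clusters = nrow(m)))), nrow(m))
  expect_error(cut_tree(tree, n_clusters = nrow(m) + 1), "exceeds")
  nwk <- linkage_to_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(rownames(m) %in% ape::read.tree(text = nwk)$tip.label))
  expect_equal(nrow(merge_table(tree)), nrow(m) - 1L)
})

test_that("type classification reproduces the published group memberships", {
  cls <- classify_types(fixture_profiles())
  got <- stats::setNames(cls$type, cls$drug_code)
  type1 <- c("FLX", "SRT", "PRX", "AMI", "IMI", "DMI", "MPR", "HAL", "RIT")
  expect_true(all(got[type1] == "Type1"))
  expect_true(all(got[c("FLR", "LIF")] == "Type3"))
  expect_true(all(got[c("LID", "MEX", "AMB", "TOL")] == "Type2_UD"))
  expect_true(all(got[c("CBZ", "LTG", "DPH", "MEM", "VFX", "BPR", "DIC")] == "Type2_nonUD"))
  expect_equal(unname(got["NIS"]), "Type4") # intermediate potency/kinetics

  # a profile straddling the Type 1 and Type 2 boxes falls through to Type 4
  mid <- data.frame(drug_code = "MID", IC50_uM = 60, Rev = 0.9, UD = 1.3,
                    tau_on_s = 15, tau_off_s = 30, Ki_kapp_uM = 10)
  expect_equal(classify_types(mid)$type, "Type4")
})

test_that("radar export min-max scales each axis over the drug set", {
  prof <- fixture_profiles()
  rad <- export_radar(prof, c("IC50_uM", "Rev", "UD"), "IC50_uM")
  expect_equal(nrow(rad), 35L)
  for (cl in c("log_IC50_uM", "Rev", "UD")) {
    expect_equal(min(rad[[cl]]), 0)
    expect_equal(max(rad[[cl]]), 1)
  }
  cst <- data.frame(drug_code = c("A", "B"), v = c(2, 2), w = c(1, 3))
  expect_equal(export_radar(cst, c("v", "w"))$v, c(0.5, 0.5))
})
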