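# small deterministic profile set: 3 groups x 3 samples, 6 genes
demo_profiles <- function() {
  set.seed(33)
  base <- list(SCC = c(8, 1, 1, 5, 2, 2), Pap = c(1, 8, 1, 2, 5, 2),
               Ctrl = c(1, 1, 8, 2, 2, 5))
  prof <- do.call(cbind, lapply(names(base), function(g)
    sapply(1:3, function(i) base[[g]] + rnorm(6, sd = 0.3))))
  dimnames(prof) <- list(paste0("g", 1:6),
                         paste0(rep(c("SCC", "Pap", "Ctrl"), each = 3), "_", 1:3))
  sheet <- data.frame(sample_id = colnames(prof),
                      group = rep(c("SCC", "Pap", "Ctrl"), each = 3))
  list(prof = prof, sheet = sheet)
}

test_that("expression profiles preserve panel order and name absentees", {
  d <- demo_profiles()
  nm <- structure(list(norm = 2^d$prof - 1, log2 = d$prof,
                       size_factors = rep(1, 9), pseudocount = 1),
                  class = "norm_matrix")
  p <- expression_profile(nm, c("g3", "g1"))
  expect_equal(rownames(p), c("g3", "g1"))
  expect_equal(p["g1", ], d$prof["g1", ])
  expect_error(expression_profile(nm, c("g1", "gX")), "gX")
  pn <- expression_profile(nm, "g1", scale = "norm")
  expect_equal(pn["g1", ], (2^d$prof - 1)["g1", ])
})

test_that("centroids average the right samples, with LOO exclusion", {
  d <- demo_profiles()
  cent <- group_centroids(d$prof, d$sheet)
  expect_equal(cent[, "SCC"], rowMeans(d$prof[, 1:3]))
  # exclusion removes the sample from its own group only
  cex <- group_centroids(d$prof, d$sheet, exclude = "SCC_2")
  expect_equal(cex[, "SCC"], rowMeans(d$prof[, c(1, 3)]))
  expect_equal(cex[, "Pap"], cent[, "Pap"])
  # group of two: excluding one leaves the other
  two <- d$prof[, c(1, 2, 4, 5, 7, 8)]
  sheet2 <- d$sheet[c(1, 2, 4, 5, 7, 8), ]
  c2 <- group_centroids(two, sheet2, exclude = "SCC_1")
  expect_equal(c2[, "SCC"], two[, "SCC_2"])
})

test_that("leave-one-out correlations match a from-scratch oracle", {
  d <- demo_profiles()
  cors <- loo_correlations(d$prof, d$sheet)
  expect_equal(nrow(cors), 9L)
  for (i in seq_len(nrow(cors))) {
    sid <- cors$sample_id[i]
    x <- d$prof[, sid]
    for (g in c("SCC", "Pap", "Ctrl")) {
      own <- d$sheet$group[d$sheet$sample_id == sid]
      cent <- centroid_brute(d$prof, d$sheet$group, g,
                             if (g == own) sid else "none")
      expect_equal(cors[[paste0("r_", g)]][i], pearson_brute(x, cent),
                   tolerance = 1e-12)
    }
    # each sample correlates best with its own group's centroid here
    expect_equal(cors$true_group[i],
                 c("SCC", "Pap", "Ctrl")[which.max(
                   unlist(cors[i, c("r_SCC", "r_Pap", "r_Ctrl")]))])
  }
  small <- d$sheet[d$sheet$sample_id != "SCC_1", ]
  small$group[small$sample_id == "SCC_2"] <- "Solo"
  expect_error(loo_correlations(d$prof[, small$sample_id], small), ">= 2 samples")
})

test_that("correlation behaves like the product-moment definition", {
  expect_equal(cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(cor(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(14)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(length(x))
    expect_equal(cor(x, y), pearson_brute(x, y), tolerance = 1e-12)
    # invariance under positive affine transforms
    expect_equal(cor(2.5 * x + 3, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("diagonal scores are signed perpendicular distances", {
  cors <- data.frame(sample_id = c("a", "b"), true_group = c("SCC", "Pap"),
                     r_SCC = c(0.9, 0.5), r_Pap = c(0.5, 0.5), r_Ctrl = c(0.1, 0.9))
  attr(cors, "groups") <- c("SCC", "Pap", "Ctrl")
  sc <- diagonal_scores(cors)
  expect_equal(sc$d_scc_pap, c(0.4 / sqrt(2), 0))
  expect_equal(sc$d_pap_ctrl, c(0.4 / sqrt(2), -0.4 / sqrt(2)))
  # positive score on the first axis iff r_SCC > r_Pap; antisymmetry under swap
  swapped <- cors
  names(swapped)[3:4] <- c("r_Pap", "r_SCC")
  attr(swapped, "groups") <- c("SCC", "Pap", "Ctrl")
  expect_equal(diagonal_scores(swapped)$d_scc_pap, -sc$d_scc_pap)
})

test_that("cutoffs are the SD of a group's absolute distances, scaled by c", {
  sc <- data.frame(sample_id = paste0("s", 1:7),
                   true_group = c(rep("SCC", 3), rep("Pap", 2), rep("Ctrl", 2)),
                   d_scc_pap = c(0.1, 0.2, 0.3, -0.1, -0.3, 0, 0),
                   d_pap_ctrl = c(0, 0, 0, 0.2, 0.4, -0.1, -0.5))
  attr(sc, "groups") <- c("SCC", "Pap", "Ctrl")
  attr(sc, "axes") <- c("d_scc_pap", "d_pap_ctrl")
  cut <- determine_cutoffs(sc)
  expect_equal(cut$cutoffs$d_scc_pap[["positive"]], sd(c(0.1, 0.2, 0.3)))
  expect_equal(cut$cutoffs$d_scc_pap[["positive"]], 0.1)
  expect_equal(cut$cutoffs$d_scc_pap[["negative"]], sd(c(0.1, 0.3)))
  expect_equal(cut$cutoffs$d_pap_ctrl[["negative"]], sd(c(0.1, 0.5)))
  # homogeneity: doubling the scores doubles every threshold
  sc2 <- sc; sc2$d_scc_pap <- 2 * sc$d_scc_pap; sc2$d_pap_ctrl <- 2 * sc$d_pap_ctrl
  attr(sc2, "groups") <- attr(sc, "groups"); attr(sc2, "axes") <- attr(sc, "axes")
  cut2 <- determine_cutoffs(sc2)
  expect_equal(unlist(cut2$cutoffs), 2 * unlist(cut$cutoffs))
  # c = 0: every threshold zero, every prediction confident
  set.seed(44)
  cors0 <- data.frame(sample_id = paste0("s", 1:9),
                      true_group = rep(c("SCC", "Pap", "Ctrl"), 3),
                      r_SCC = runif(9, -1, 1), r_Pap = runif(9, -1, 1),
                      r_Ctrl = runif(9, -1, 1))
  attr(cors0, "groups") <- c("SCC", "Pap", "Ctrl")
  sc0 <- diagonal_scores(cors0)
  cut0 <- determine_cutoffs(sc0, c = 0)
  expect_true(all(unlist(cut0$cutoffs) == 0))
  expect_true(all(classify_samples(sc0, cut0)$confident))
})

test_that("argmax prediction agrees with exhaustive pairwise comparison", {
  set.seed(15)
  groups <- c("SCC", "Pap", "Ctrl")
  r <- matrix(runif(3 * 200, -1, 1), ncol = 3, dimnames = list(NULL, groups))
  r[sample(200, 20), 2] <- r[sample(200, 20), 1]  # inject ties
  sc <- data.frame(sample_id = paste0("s", 1:200),
                   true_group = sample(groups, 200, TRUE),
                   r_SCC = r[, 1], r_Pap = r[, 2], r_Ctrl = r[, 3])
  attr(sc, "groups") <- groups
  sc <- diagonal_scores(sc)
  got <- classify_samples(sc)$predicted
  # oracle: a group wins iff it loses no pairwise "higher correlation" duel,
  # ties resolved by the fixed priority order
  oracle <- apply(r, 1, function(v) {
    for (g in groups) {
      if (all(v[g] >= v[setdiff(groups, g)])) return(g)
    }
  })
  expect_equal(got, unname(oracle))
  # degenerate full tie: priority gives SCC, not confident at default cutoffs
  tie <- data.frame(sample_id = "t", true_group = "Pap",
                    r_SCC = 0.5, r_Pap = 0.5, r_Ctrl = 0.5)
  attr(tie, "groups") <- groups
  tie <- diagonal_scores(tie)
  cut <- list(cutoffs = list(d_scc_pap = c(positive = 0.2, negative = 0.2),
                             d_pap_ctrl = c(positive = 0.2, negative = 0.2)),
              multiplier = 1, groups = groups,
              axes = c("d_scc_pap", "d_pap_ctrl"))
  class(cut) <- "cutoff_set"
  out <- classify_samples(tie, cut)
  expect_equal(out$predicted, "SCC")
  expect_false(out$confident)
})
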