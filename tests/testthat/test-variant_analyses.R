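# Downstream statistics on variant score tables.

test_that("splice filter and transitive clustering", {
  cfg <- negmatch_config(seed = 2)
  variants <- data.frame(chrom = "c1",
                         pos = c(100L, 515L, 1000L, 1008L, 1016L, 5000L),
                         id = paste0("v", 1:6), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  splice <- data.frame(chrom = "c1", start = 499L, end = 500L)
  out <- filter_pathogenic_set(variants, splice, cfg)
  # v2 at 515 is 15 bp from the splice site: removed
  expect_false("v2" %in% out$id)
  expect_true("v1" %in% out$id)
  # v3,v4,v5 chain at gaps 8,8 (span 16): one group, one representative
  expect_equal(sum(out$pos %in% c(1000L, 1008L, 1016L)), 1L)
  # union-find oracle on the chain
  expect_true("v6" %in% out$id)
  # two variants 8 bp apart: exactly one retained
  two <- data.frame(chrom = "c1", pos = c(50L, 58L), id = c("a", "b"),
                    ref = "C", alt = "T", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_pathogenic_set(two, splice[0, ], cfg)), 1L)
})

test_that("matched negatives: distance rule, composition, determinism", {
  set.seed(10)
  # genome rich in all bases
  genome <- list(c1 = random_seq(10000, 55))
  pos <- c(3000L, 5000L, 7000L)
  ref <- vapply(pos, function(p) substr(genome$c1, p, p), "")
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  pth <- data.frame(chrom = "c1", pos = pos, id = paste0("p", 1:3),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  cfg <- negmatch_config(seed = 4)
  neg <- build_matched_negatives(pth, genome, cfg)
  expect_equal(nrow(neg), 3L)
  # composition preserved exactly: ref/alt multisets match
  expect_equal(sort(paste(neg$ref, neg$alt)), sort(paste(pth$ref,
                                                         pth$alt)))
  # each negative's ref base actually matches the genome
  for (i in seq_len(nrow(neg)))
    expect_equal(substr(genome$c1, neg$pos[i], neg$pos[i]), neg$ref[i])
  # distances within [1000 - cap, 1000 + cap]
  d <- abs(neg$pos - pth$pos[match(neg$matched_id, pth$id)])
  expect_true(all(d >= 1000 - cfg$search_cap & d <= 1000 + cfg$search_cap))
  # the chosen candidate minimizes |distance - 1000| (exhaustive oracle)
  for (i in seq_len(nrow(neg))) {
    p0 <- pth$pos[match(neg$matched_id[i], pth$id)]
    cand_err <- c()
    for (dir in c(-1, 1)) {
      anchor <- p0 + dir * 1000
      offs <- 0:cfg$search_cap
      for (off in offs) {
        for (p in unique(c(anchor + off, anchor - off))) {
          if (p < 1 || p > 10000) next
          if (substr(genome$c1, p, p) == neg$ref[i]) {
            cand_err <- c(cand_err, abs(abs(p - p0) - 1000))
            off <- NA
            break
          }
        }
        if (is.na(off)) break
      }
    }
    expect_equal(abs(d[i] - 1000), min(cand_err))
  }
  # determinism under the seed
  neg2 <- build_matched_negatives(pth, genome, cfg)
  expect_identical(neg, neg2)
  # exact match at +1000 is chosen when available
  g2 <- list(c1 = paste(rep("A", 5000), collapse = ""))
  p2 <- data.frame(chrom = "c1", pos = 2000L, id = "x", ref = "A",
                   alt = "T", stringsAsFactors = FALSE)
  n2 <- build_matched_negatives(p2, g2, cfg)
  expect_true(abs(n2$pos - 2000L) == 1000L)
})

test_that("classifier CV: oracle feature gives AUROC 1, permuted ~ 0.5", {
  set.seed(3)
  n <- 80
  labels <- rep(c(0, 1), each = n / 2)
  feats <- cbind(oracle = labels + rnorm(n, 0, 1e-6),
                 noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  cfg <- classifier_config(folds = 8, iterations = 3, n_trees = 25,
                           seed = 7)
  res <- classify_with_cv(feats, labels, cfg)
  expect_equal(res$auroc, rep(1, 3), tolerance = 0.01)
  # permuted labels: null behavior around 0.5 (mean over iterations;
  # single iterations fluctuate with n = 80)
  perm <- sample(labels)
  resp <- classify_with_cv(feats, perm,
                           classifier_config(folds = 8, iterations = 8,
                                             n_trees = 25, seed = 7))
  expect_lt(abs(mean(resp$auroc) - 0.5), 0.15)
  expect_lt(mean(resp$auroc), mean(res$auroc))
  # ROC starts at (0,0) and ends at (1,1)
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  expect_error(classify_with_cv(feats, rep(1, n), cfg), "single class")
  # separable classes beat permuted labels in every iteration
  expect_gt(min(res$auroc), max(resp$auroc))
})

test_that("each variant is out-of-fold exactly once per iteration", {
  # fold partition contract, checked through the pooled score vector:
  # every variant receives exactly one out-of-fold score
  set.seed(4)
  n <- 40
  labels <- rep(c(0, 1), n / 2)
  feats <- matrix(rnorm(n * 3), n)
  res <- classify_with_cv(feats, labels,
                          classifier_config(folds = 8, iterations = 1,
                                            n_trees = 10, seed = 1))
  expect_length(res$oof_scores, n)
  expect_true(all(is.finite(res$oof_scores)))
})

test_that("eQTL summarization is the arithmetic mean over genes", {
  expect_equal(unname(summarize_eqtl_effects(list(v1 = c(0.2, 0.4)))), 0.3)
  expect_equal(unname(summarize_eqtl_effects(list(v = 0.7))), 0.7)
  expect_true(is.na(summarize_eqtl_effects(list(v = numeric(0)))))
  set.seed(6)
  alpha <- lapply(1:20, function(i) rnorm(sample(1:5, 1)))
  got <- summarize_eqtl_effects(alpha)
  oracle <- vapply(alpha, function(a) sum(a) / length(a), 0)
  expect_equal(unname(got), oracle)
})

test_that("weight_scores formula", {
  expect_equal(weight_scores(-0.5, 10), 5.0)
  expect_equal(weight_scores(0.3, 10), 0.3)
  expect_equal(weight_scores(c(-2, -1, 0, 1), 1), c(2, 1, 0, 1))
  expect_error(weight_scores(1, 0.5), ">= 1")
})

test_that("proband/sibling MWU: worked example and identity case", {
  # {3,4,5} vs {1,2}: U = 6, exact two-sided p = 0.2 (enumeration)
  w <- wilcox.test(c(3, 4, 5), c(1, 2))
  expect_equal(unname(w$statistic), 6)
  expect_equal(w$p.value, 0.2)
  # through the full pipeline (scores positive so weighting is identity)
  pro <- matrix(c(3, 4, 5), ncol = 1, dimnames = list(NULL, "d1"))
  sib <- matrix(c(1, 2), ncol = 1, dimnames = list(NULL, "d1"))
  res <- proband_sibling_tests(pro, sib, denovo_config())
  expect_equal(res$p, 0.2)
  expect_equal(res$effect, mean(log(c(3, 4, 5) + 1)) -
                 mean(log(c(1, 2) + 1)))
  # identical multisets: effect 0, p = 1
  res0 <- proband_sibling_tests(pro, pro, denovo_config())
  expect_equal(res0$effect, 0)
  expect_gt(res0$p, 0.99)
})

test_that("BH null calibration across seeded replicates", {
  # iid null scores: the average fraction of datasets at q < 0.05 stays
  # at or below 0.05 (100 replicates x 8 datasets)
  frac <- vapply(1:100, function(s) {
    set.seed(s)
    pro <- matrix(rnorm(40 * 8), 40)
    sib <- matrix(rnorm(40 * 8), 40)
    res <- proband_sibling_tests(pro, sib, denovo_config())
    mean(res$q < 0.05)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("risk score binomial test and symmetry", {
  # 8 families, proband always higher: two-sided exact p = 2 * (1/2)^8
  df <- data.frame(family = rep(1:8, each = 2),
                   role = rep(c("proband", "sibling"), 8),
                   score = rep(c(2, 1), 8))
  rs <- individual_risk_score(df, denovo_config(negative_weight = 1))
  expect_equal(rs$successes, 8L)
  expect_equal(rs$p_value, 2 * (1 / 2)^8)
  expect_equal(rs$proband_fraction, 1)
  # all ties: zero informative families, p = 1
  dft <- df
  dft$score <- 1
  rst <- individual_risk_score(dft, denovo_config(negative_weight = 1))
  expect_equal(rst$n_informative, 0L)
  expect_equal(rst$p_value, 1)
  # label swap flips successes to the complement
  dfs <- df
  dfs$role <- rep(c("sibling", "proband"), 8)
  rss <- individual_risk_score(dfs, denovo_config(negative_weight = 1))
  expect_equal(rss$successes, 0L)
  expect_equal(rss$p_value, rs$p_value)   # symmetric two-sided test
  # missing member excluded with warning
  dfm <- rbind(df, data.frame(family = 9, role = "proband", score = 5))
  expect_warning(rsm <- individual_risk_score(dfm,
                                              denovo_config(negative_weight = 1)),
                 "missing")
  expect_equal(rsm$n_informative, 8L)
})

test_that("filter_tss_proximal distance rule", {
  tss <- data.frame(chrom = "c1", pos = c(1000L, 100000L))
  v <- data.frame(chrom = c("c1", "c1", "c2"),
                  pos = c(30000L, 60001L, 500L))
  keep <- filter_tss_proximal(v, tss, 50000L)
  expect_equal(keep, c(TRUE, TRUE, FALSE))
  keep2 <- filter_tss_proximal(v, tss, 20000L)
  expect_equal(keep2, c(FALSE, FALSE, FALSE))
})
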