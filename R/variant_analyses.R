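## Downstream statistical procedures on variant score tables:
## pathogenic-set filtering and matched-negative construction, cross-
## validated classification, eQTL effect summarization, and the
## proband/sibling de novo variant tests with per-individual risk scores.

#' Matched-negative construction configuration
#' @param target_offset distance (bp) negatives are shifted to (1000).
#' @param splice_exclusion variants closer than this to a splice site are
#'   removed (20).
#' @param cluster_radius variants within this distance are grouped and one
#'   representative kept (10).
#' @param search_cap maximum scan (bp) around each anchor for a matching
#'   reference base.
#' @param seed integer seed for representative sampling and tie-breaks.
#' @return a `negmatch_config` list.
#' @export
negmatch_config <- function(target_offset = 1000L, splice_exclusion = 20L,
                            cluster_radius = 10L, search_cap = 200L,
                            seed = 1L) {
  stopifnot(target_offset > 0, splice_exclusion > 0, cluster_radius > 0,
            search_cap > 0)
  structure(list(target_offset = as.integer(target_offset),
                 splice_exclusion = as.integer(splice_exclusion),
                 cluster_radius = as.integer(cluster_radius),
                 search_cap = as.integer(search_cap),
                 seed = as.integer(seed)),
            class = "negmatch_config")
}

#' Filter a pathogenic variant set
#'
#' Removes variants within `splice_exclusion` bp of any splice site, then
#' groups the survivors by transitive chaining of gaps at most
#' `cluster_radius` bp and keeps one seeded-random representative per
#' group, so retained variants function independently.
#'
#' @param variants data.frame with chrom, pos (1-based), id, ref, alt.
#' @param splice_sites data.frame of splice-site intervals (chrom, start,
#'   end; 0-based half-open).
#' @param config a [negmatch_config()].
#' @return filtered variant data.frame.
#' @export
filter_pathogenic_set <- function(variants, splice_sites,
                                  config = negmatch_config()) {
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(splice_sites) && nrow(splice_sites) > 0) {
    for (i in seq_len(nrow(variants))) {
      ss <- splice_sites[splice_sites$chrom == variants$chrom[i], ]
      if (nrow(ss) == 0) next
      pos0 <- variants$pos[i] - 1L
      d <- pmax(0L, pmax(ss$start - pos0, pos0 - (ss$end - 1L)))
      if (min(d) <= config$splice_exclusion) keep[i] <- FALSE
    }
  }
  v <- variants[keep, , drop = FALSE]
  if (nrow(v) == 0) return(v)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  # transitive chaining: a new group starts when the gap to the previous
  # variant exceeds cluster_radius
  gap_break <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
                   diff(v$pos) > config$cluster_radius)
  grp <- cumsum(gap_break)
  reps <- with_seed(derive_seed(config$seed, "cluster_rep"), {
    vapply(split(seq_len(nrow(v)), grp),
           function(idx) if (length(idx) == 1) idx else
             idx[sample(length(idx), 1)], 0L)
  })
  out <- v[sort(reps), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build matched negative variants
#'
#' For each pathogenic variant, considers anchors 1000 bp up- and
#' downstream, scans each anchor (up to `search_cap` bp) for the nearest
#' reference base equal to the variant's reference base, keeps the
#' candidate whose distance is closest to 1000 bp (seeded random
#' tie-break), and copies the alternative allele. Negatives therefore
#' match the positives' nucleotide composition exactly while controlling
#' for genomic region.
#'
#' @param pathogenic filtered variant data.frame.
#' @param genome named chromosome sequences.
#' @param config a [negmatch_config()].
#' @return data.frame of negatives with `matched_id` linking each to its
#'   positive; variants with no candidate within the cap are skipped with
#'   a warning.
#' @export
build_matched_negatives <- function(pathogenic, genome,
                                    config = negmatch_config()) {
  out <- list()
  with_seed(derive_seed(config$seed, "negatives"), {
    for (i in seq_len(nrow(pathogenic))) {
      v <- pathogenic[i, ]
      chrom_seq <- genome[[v$chrom]]
      n <- nchar(chrom_seq)
      pos0 <- v$pos - 1L
      best <- NULL
      for (dir in c(-1L, 1L)) {
        anchor <- pos0 + dir * config$target_offset
        cand <- NA_integer_
        # scan symmetric offsets around the anchor in order of |offset|
        for (off in 0:config$search_cap) {
          for (p in unique(c(anchor + off, anchor - off))) {
            if (p < 0 || p >= n) next
            if (substr(chrom_seq, p + 1L, p + 1L) == toupper(v$ref)) {
              cand <- p
              break
            }
          }
          if (!is.na(cand)) break
        }
        if (is.na(cand)) next
        err <- abs(abs(cand - pos0) - config$target_offset)
        if (is.null(best) || err < best$err) {
          best <- list(pos = cand, err = err)
        } else if (err == best$err && runif(1) < 0.5) {
          best <- list(pos = cand, err = err)
        }
      }
      if (is.null(best)) {
        warning("no matching reference base within cap for ", v$id)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = v$chrom, pos = best$pos + 1L,
        id = paste0(v$id, "_neg"), ref = v$ref, alt = v$alt,
        matched_id = v$id, stringsAsFactors = FALSE)
    }
  })
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), matched_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## ---- compact random forest ------------------------------------------
## No random-forest library ships with the runtime, so a small CART-based
## forest (Gini splits, bootstrap resampling, per-split feature
## subsampling) backs the cross-validation harness.

gini_best_split <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum_pos <- cumsum(ys)
  tot_pos <- cum_pos[n]
  valid <- which(xs[-n] < xs[-1])     # split between distinct values
  if (length(valid) == 0) return(NULL)
  nl <- valid
  nr <- n - nl
  pl <- cum_pos[valid] / nl
  pr <- (tot_pos - cum_pos[valid]) / nr
  gini <- nl / n * 2 * pl * (1 - pl) + nr / n * 2 * pr * (1 - pr)
  b <- which.min(gini)
  list(threshold = (xs[valid[b]] + xs[valid[b] + 1]) / 2,
       gini = gini[b])
}

grow_tree <- function(X, y, max_features, min_node = 5L, depth = 0L,
                      max_depth = 25L) {
  n <- length(y)
  p_hat <- mean(y)
  if (n < min_node || p_hat == 0 || p_hat == 1 || depth >= max_depth)
    return(list(leaf = TRUE, p = p_hat))
  feats <- sample(ncol(X), min(max_features, ncol(X)))
  best <- NULL
  for (f in feats) {
    sp <- gini_best_split(X[, f], y)
    if (!is.null(sp) && (is.null(best) || sp$gini < best$gini)) {
      best <- c(sp, feature = f)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = p_hat))
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], max_features,
                        min_node, depth + 1L, max_depth),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], max_features,
                         min_node, depth + 1L, max_depth))
}

predict_tree <- function(tree, X) {
  if (tree$leaf) return(rep(tree$p, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, tree$feature] <= tree$threshold
  if (any(left)) out[left] <- predict_tree(tree$left,
                                           X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(tree$right,
                                             X[!left, , drop = FALSE])
  out
}

#' Fit a compact random forest classifier
#'
#' Bootstrap-aggregated CART trees with Gini splits; the number of
#' features considered per split defaults to `log2` of the feature count.
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 label vector.
#' @param n_trees trees in the ensemble.
#' @param max_features features per split; default `max(1, floor(log2(p)))`.
#' @return a `crossreg_rf` model.
#' @export
fit_random_forest <- function(X, y, n_trees = 50L, max_features = NULL) {
  max_features <- max_features %||% max(1L, floor(log2(ncol(X))))
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample(nrow(X), nrow(X), replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], max_features)
  })
  structure(list(trees = trees, max_features = max_features),
            class = "crossreg_rf")
}

#' @rdname fit_random_forest
#' @param object a `crossreg_rf`.
#' @param newdata feature matrix to score.
#' @param ... unused.
#' @return predicted class-1 probabilities.
#' @export
predict.crossreg_rf <- function(object, newdata, ...) {
  preds <- vapply(object$trees,
                  function(tr) predict_tree(tr, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Area under the ROC curve
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return AUROC via the rank statistic.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop2("need both classes for AUROC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier cross-validation configuration
#' @param folds cross-validation folds (8).
#' @param iterations repeated CV iterations (200).
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(folds = 8L, iterations = 200L,
                              n_trees = 50L, seed = 1L) {
  stopifnot(folds >= 2, iterations >= 1)
  structure(list(folds = as.integer(folds),
                 iterations = as.integer(iterations),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Repeated cross-validated classification of variant classes
#'
#' Per iteration: a fresh seeded fold split, a random forest per fold,
#' out-of-fold scores pooled into one AUROC. Feature-set comparisons
#' should use [compare_auroc()] (Mann-Whitney U over iteration AUROCs).
#'
#' @param features variants x datasets score matrix (rows aligned with
#'   `labels`).
#' @param labels binary 0/1 vector (1 = pathogenic class).
#' @param config a [classifier_config()].
#' @return list with `auroc` (one value per iteration), `roc`
#'   (data.frame fpr/tpr from the first iteration's pooled scores), and
#'   `oof_scores` (first iteration's out-of-fold scores).
#' @export
classify_with_cv <- function(features, labels,
                             config = classifier_config()) {
  if (length(unique(labels)) < 2)
    stop2("labels contain a single class")
  n <- length(labels)
  aurocs <- numeric(config$iterations)
  roc <- NULL
  oof_first <- NULL
  for (it in seq_len(config$iterations)) {
    with_seed(derive_seed(config$seed, "cv", it), {
      fold <- sample(rep(seq_len(config$folds), length.out = n))
      oof <- numeric(n)
      for (f in seq_len(config$folds)) {
        tr <- fold != f
        rf <- fit_random_forest(features[tr, , drop = FALSE], labels[tr],
                                n_trees = config$n_trees)
        oof[!tr] <- predict(rf, features[!tr, , drop = FALSE])
      }
      aurocs[it] <- auroc(oof, labels)
      if (it == 1) {
        oof_first <- oof
        th <- sort(unique(c(-Inf, oof, Inf)), decreasing = TRUE)
        roc <- data.frame(
          fpr = vapply(th, function(t) mean(oof[labels == 0] >= t), 0),
          tpr = vapply(th, function(t) mean(oof[labels == 1] >= t), 0))
      }
    })
  }
  list(auroc = aurocs, roc = roc, oof_scores = oof_first)
}

#' Compare two classifiers' iteration AUROCs
#' @param auroc_a,auroc_b AUROC vectors from [classify_with_cv()].
#' @return two-sided Mann-Whitney U p-value.
#' @export
compare_auroc <- function(auroc_a, auroc_b) {
  wilcox.test(auroc_a, auroc_b)$p.value
}

## ---- eQTL summarization and de novo tests ---------------------------

#' Summarize a variant's eQTL effects across cis-genes
#'
#' The arithmetic mean of the per-gene marginal correlations over the
#' variant's tested gene set; empty sets yield NA (excluded downstream).
#'
#' @param alpha named list: per variant, the vector of per-gene marginal
#'   correlations.
#' @return named numeric vector of summarized effects.
#' @export
summarize_eqtl_effects <- function(alpha) {
  vapply(alpha, function(a) if (length(a) == 0) NA_real_ else mean(a),
         0)
}

#' Weight signed variant scores
#'
#' Negative predictions (disturbed active elements) carry more signal, so
#' they are scaled by `w` before the absolute value: `s >= 0 -> s`,
#' `s < 0 -> w * |s|`.
#'
#' @param scores signed numeric vector/matrix.
#' @param w negative-score weight (>= 1, default 10).
#' @return nonnegative scores of the same shape.
#' @export
weight_scores <- function(scores, w = 10) {
  if (w < 1) stop2("weight must be >= 1")
  ifelse(scores >= 0, scores, w * abs(scores))
}

#' De novo test configuration
#' @param tss_max_distance keep variants within this distance of a TSS
#'   (50 kb).
#' @param negative_weight scaling of negative scores (10).
#' @param fdr_level Benjamini-Hochberg threshold (0.05).
#' @param log_pseudocount pseudocount inside the effect-size log (1).
#' @return a `denovo_config` list.
#' @export
denovo_config <- function(tss_max_distance = 50000L, negative_weight = 10,
                          fdr_level = 0.05, log_pseudocount = 1) {
  stopifnot(negative_weight >= 1, fdr_level > 0, fdr_level < 1)
  structure(list(tss_max_distance = as.integer(tss_max_distance),
                 negative_weight = negative_weight,
                 fdr_level = fdr_level,
                 log_pseudocount = log_pseudocount),
            class = "denovo_config")
}

#' Filter variants to TSS-proximal positions
#' @param variants data.frame with chrom, pos (1-based).
#' @param tss data.frame with chrom, pos (0-based TSS positions).
#' @param max_distance maximum distance in bp.
#' @return logical keep vector.
#' @export
filter_tss_proximal <- function(variants, tss, max_distance = 50000L) {
  vapply(seq_len(nrow(variants)), function(i) {
    tp <- tss$pos[tss$chrom == variants$chrom[i]]
    length(tp) > 0 && min(abs(tp - (variants$pos[i] - 1L))) <= max_distance
  }, TRUE)
}

#' Proband versus sibling de novo variant tests
#'
#' Per dataset: signed scores are weighted ([weight_scores()]), the effect
#' size is the difference of mean natural-log scores (proband minus
#' sibling, with a pseudocount), the p-value a two-sided Mann-Whitney U
#' test, and q-values Benjamini-Hochberg across datasets (optionally
#' within assay families via `groups`).
#'
#' @param proband_scores,sibling_scores variants x datasets signed score
#'   matrices (pre-filtered to TSS-proximal variants).
#' @param config a [denovo_config()].
#' @param groups optional dataset grouping for within-family BH
#'   correction.
#' @return data.frame (dataset, effect, p, q).
#' @export
proband_sibling_tests <- function(proband_scores, sibling_scores,
                                  config = denovo_config(),
                                  groups = NULL) {
  datasets <- colnames(proband_scores) %||%
    paste0("ds", seq_len(ncol(proband_scores)))
  res <- lapply(seq_along(datasets), function(j) {
    ps <- weight_scores(proband_scores[, j], config$negative_weight)
    ss <- weight_scores(sibling_scores[, j], config$negative_weight)
    if (length(ps) == 0 || length(ss) == 0) return(NULL)
    lp <- log(ps + config$log_pseudocount)
    ls <- log(ss + config$log_pseudocount)
    p <- suppressWarnings(wilcox.test(ps, ss)$p.value)
    data.frame(dataset = datasets[j], effect = mean(lp) - mean(ls),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(groups)) {
    out$q <- p.adjust(out$p, method = "BH")
  } else {
    out$q <- NA_real_
    for (g in unique(groups)) {
      idx <- which(groups[match(out$dataset, datasets)] == g)
      out$q[idx] <- p.adjust(out$p[idx], method = "BH")
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-individual risk scores with a binomial family test
#'
#' Sums each individual's weighted variant scores for one dataset; a
#' family is a success when the proband's sum exceeds the sibling's. Tied
#' families are excluded; the two-sided exact binomial test uses null
#' probability one half.
#'
#' @param scores data.frame with columns family, role
#'   (`"proband"`/`"sibling"`), and score (signed, one row per variant).
#' @param config a [denovo_config()].
#' @return list with `individual` (family, role, risk_score),
#'   `successes`, `n_informative`, `proband_fraction`, and `p_value`.
#' @export
individual_risk_score <- function(scores, config = denovo_config()) {
  scores$w <- weight_scores(scores$score, config$negative_weight)
  agg <- stats::aggregate(w ~ family + role, data = scores, FUN = sum)
  fams <- unique(agg$family)
  succ <- 0L; ties <- 0L; kept <- 0L
  for (f in fams) {
    pr <- agg$w[agg$family == f & agg$role == "proband"]
    si <- agg$w[agg$family == f & agg$role == "sibling"]
    if (length(pr) != 1 || length(si) != 1) {
      warning("family ", f, " missing a member; excluded")
      next
    }
    if (pr == si) { ties <- ties + 1L; next }
    kept <- kept + 1L
    if (pr > si) succ <- succ + 1L
  }
  p <- if (kept == 0) 1 else binom.test(succ, kept, p = 0.5)$p.value
  list(individual = agg[, c("family", "role", "w")],
       successes = succ, n_informative = kept,
       proband_fraction = if (kept > 0) succ / kept else NA_real_,
       p_value = p)
}
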