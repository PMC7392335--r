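## Cross-species transfer evaluation.
##
## Observed and predicted activity matrices (rows = TSSs or genomic sites,
## columns = samples) are quantile normalized to align sample
## distributions, optionally log transformed (CAGE-like data), filtered to
## the most variable rows, optionally mean-normalized across samples, and
## compared by Pearson correlation per sample pair. Mean-normalization
## removes correlation driven by global cross-tissue activity, isolating
## tissue specificity.

#' Quantile normalize the columns of a matrix
#'
#' Every column receives the identical sorted value set — the per-rank
#' mean across columns — while within-column ranks are preserved. Ties are
#' resolved by mean rank.
#'
#' @param m numeric matrix with at least two columns.
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) stop2("quantile normalization needs >= 2 columns")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # average reference values for tied (fractional) ranks
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Center each row at zero across samples
#' @param m numeric matrix.
#' @return matrix with row means removed (rows sum to zero exactly).
#' @export
mean_center_rows <- function(m) {
  m - rowMeans(m)
}

#' Select the most variable rows
#'
#' Rows are ranked by cross-sample variance (on whatever scale the caller
#' has already transformed to) and the top fraction kept; ties break
#' deterministically by row label.
#'
#' @param m numeric matrix with unique rownames.
#' @param fraction fraction of rows to keep, in (0, 1].
#' @return row subset of `m`, original row order preserved.
#' @export
select_top_variable <- function(m, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop2("fraction must lie in (0, 1]")
  if (fraction == 1) return(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(max(1, floor(fraction * nrow(m))))])
  m[keep, , drop = FALSE]
}

#' Cross-species matched/mismatched correlation matrix
#'
#' Pipeline (order logged in the result): quantile normalize observed and
#' predicted jointly, optional `log1p` transform, top-variable row filter,
#' optional row mean-centering, then Pearson correlation of every
#' (observed sample, predicted sample) pair.
#'
#' @param observed,predicted matrices over a shared row universe (same
#'   rownames); columns are samples.
#' @param sample_pairs named character vector mapping observed column ->
#'   matched predicted column.
#' @param log_transform apply `log1p` (CAGE-like data).
#' @param top_fraction row fraction kept by variance.
#' @param mean_center remove per-row cross-sample means before
#'   correlating.
#' @return list with `cor` (observed x predicted correlation matrix),
#'   `matched` (logical matrix flagging matched pairs), and
#'   `pipeline` (character vector of applied steps).
#' @export
cross_species_correlation <- function(observed, predicted, sample_pairs,
                                      log_transform = TRUE,
                                      top_fraction = 0.5,
                                      mean_center = TRUE) {
  shared <- intersect(rownames(observed), rownames(predicted))
  if (length(shared) < 3)
    stop2("need at least 3 shared rows, got ", length(shared))
  obs <- observed[shared, , drop = FALSE]
  prd <- predicted[shared, , drop = FALSE]
  joint <- cbind(obs, prd)
  pipeline <- "quantile_normalize"
  joint <- quantile_normalize(joint)
  if (log_transform) {
    joint <- log1p(joint)
    pipeline <- c(pipeline, "log1p")
  }
  joint <- select_top_variable(joint, top_fraction)
  pipeline <- c(pipeline, sprintf("top_variable(%g)", top_fraction))
  if (mean_center) {
    joint <- mean_center_rows(joint)
    pipeline <- c(pipeline, "mean_center_rows")
  }
  obs <- joint[, seq_len(ncol(observed)), drop = FALSE]
  prd <- joint[, ncol(observed) + seq_len(ncol(predicted)), drop = FALSE]
  cc <- cor(obs, prd)
  matched <- matrix(FALSE, ncol(obs), ncol(prd),
                    dimnames = dimnames(cc))
  for (o in names(sample_pairs)) {
    if (o %in% rownames(matched) &&
        sample_pairs[[o]] %in% colnames(matched))
      matched[o, sample_pairs[[o]]] <- TRUE
  }
  list(cor = cc, matched = matched, pipeline = pipeline)
}

#' Activity matrix of TSS signal from a track or model predictions
#'
#' Helper assembling the rows x samples matrix for transfer evaluation:
#' for each TSS, the summed signal (observed per-bp track) or the
#' prediction bin value covering the TSS.
#'
#' @param tracks named list of per-bp tracks (datasets as samples).
#' @param tss data.frame with chrom, pos (0-based).
#' @param window bp summed around each TSS.
#' @return TSS x dataset matrix with rownames `chrom:pos`.
#' @export
tss_activity_matrix <- function(tracks, tss, window = 192L) {
  half <- window %/% 2L
  m <- matrix(0, nrow(tss), length(tracks),
              dimnames = list(paste0(tss$chrom, ":", tss$pos),
                              names(tracks)))
  for (d in seq_along(tracks)) {
    tr <- tracks[[d]]
    for (i in seq_len(nrow(tss))) {
      v <- tr[[tss$chrom[i]]]
      s <- max(1L, tss$pos[i] - half)
      e <- min(length(v), tss$pos[i] + half)
      m[i, d] <- sum(v[s:e])
    }
  }
  m
}

#' Gradient-based saliency scores for 128-bp segments
#'
#' Scores each post-tower segment representation by the inner product of
#' the gradient of the summed predictions (one dataset) with the segment's
#' representation vector. Peaks flag distal regulatory elements; the sign
#' separates enhancing (+) from repressing (-) influence.
#'
#' @param model a `seqnet`.
#' @param x one-hot 4 x L matrix.
#' @param genome_id head to use.
#' @param dataset column index of the dataset to explain.
#' @return numeric vector, one saliency score per post-tower segment.
#' @export
saliency_scores <- function(model, x, genome_id, dataset = 1L) {
  n_tower <- model$n_tower_layers
  tower_layers <- model$trunk[seq_len(n_tower)]
  rest_layers <- model$trunk[(n_tower + 1):length(model$trunk)]
  tw <- nn_forward(tower_layers, list(t(x)), training = FALSE)
  rep_mat <- tw$out[[1]]
  rs <- nn_forward(rest_layers, tw$out, training = FALSE)
  hd <- nn_forward(model$heads[[genome_id]], rs$out, training = FALSE)
  dpred <- matrix(0, nrow(hd$out[[1]]), ncol(hd$out[[1]]))
  dpred[, dataset] <- 1
  hb <- nn_backward(model$heads[[genome_id]], hd$caches, list(dpred))
  rb <- nn_backward(rest_layers, rs$caches, hb$dx)
  grad_rep <- rb$dx[[1]]
  rowSums(grad_rep * rep_mat)
}
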