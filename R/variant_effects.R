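## Allele-difference variant effect scores.
##
## For a biallelic SNV, predict signal over the surrounding window with the
## reference and with the alternative allele, subtract, and sum across the
## sequence: one signed score per dataset (sign convention alt - ref,
## recorded in the table metadata). Scores are averaged over the forward
## and reverse-complement sequence and small shifts.

# extract the L-window centered on a variant; returns list(seq, offset)
variant_window <- function(genome, chrom, pos1, L, shift = 0L) {
  n <- nchar(genome[[chrom]])
  start0 <- pos1 - 1L - L %/% 2L + shift
  if (start0 < 0 || start0 + L > n)
    stop2("window off contig for variant at ", chrom, ":", pos1)
  list(seq = substr(genome[[chrom]], start0 + 1L, start0 + L),
       var_at = pos1 - 1L - start0)  # 0-based within window
}

#' Score one variant by allele difference
#'
#' @param model a `seqnet`.
#' @param genome named chromosome sequences.
#' @param variant list/row with chrom, pos (1-based), ref, alt.
#' @param genome_id model head to use.
#' @param shift window shift in bp (used by the ensemble).
#' @param rc score on the reverse-complement strand.
#' @return named numeric vector of per-dataset signed scores (alt - ref).
#' @export
score_variant <- function(model, genome, variant, genome_id,
                          shift = 0L, rc = FALSE) {
  L <- model$config$seq_len
  win <- variant_window(genome, variant$chrom, variant$pos, L, shift)
  ref_here <- substr(win$seq, win$var_at + 1L, win$var_at + 1L)
  if (ref_here != toupper(variant$ref))
    stop2("reference mismatch at ", variant$chrom, ":", variant$pos,
          " (genome has ", ref_here, ", variant says ", variant$ref, ")")
  seq_alt <- win$seq
  substr(seq_alt, win$var_at + 1L, win$var_at + 1L) <- toupper(variant$alt)
  enc <- function(s) {
    x <- encode_sequence(s)
    if (rc) revcomp_onehot(x) else x
  }
  preds <- forward(model, list(enc(win$seq), enc(seq_alt)), genome_id)
  out <- colSums(preds[[2]]) - colSums(preds[[1]])
  names(out) <- colnames(preds[[1]]) %||%
    paste0("ds", seq_along(out))
  out
}

#' Ensemble-averaged variant score
#'
#' Arithmetic mean of [score_variant()] over the cross of strand
#' ({forward, reverse-complement} when `rc = TRUE`) and window shifts.
#'
#' @inheritParams score_variant
#' @param shifts symmetric set of shifts (default `c(-1, 0, 1)`).
#' @param rc include the reverse-complement passes.
#' @return named numeric vector of per-dataset scores.
#' @export
ensemble_scores <- function(model, genome, variant, genome_id,
                            shifts = c(-1L, 0L, 1L), rc = TRUE) {
  if (!isTRUE(all.equal(sort(shifts), sort(-shifts))))
    stop2("shifts must be symmetric around 0")
  rcs <- if (rc) c(FALSE, TRUE) else FALSE
  acc <- NULL
  n <- 0
  for (s in shifts) {
    for (r in rcs) {
      sc <- score_variant(model, genome, variant, genome_id,
                          shift = s, rc = r)
      acc <- if (is.null(acc)) sc else acc + sc
      n <- n + 1
    }
  }
  acc / n
}

#' Score a table of variants across all datasets
#'
#' @param model a `seqnet`.
#' @param genome named chromosome sequences.
#' @param variants data.frame with chrom, pos, id, ref, alt.
#' @param genome_id model head to use.
#' @param ensemble logical; use [ensemble_scores()] (default) or a single
#'   unshifted forward pass.
#' @param shifts shift set for the ensemble.
#' @return a `variant_score_table`: variants x datasets numeric matrix
#'   with metadata attributes (`genome_id`, `ensemble`, `sign`).
#' @export
score_variants <- function(model, genome, variants, genome_id,
                           ensemble = TRUE, shifts = c(-1L, 0L, 1L)) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$ref == v$alt) {
      n_tasks <- model$config$heads[[genome_id]]
      return(setNames(numeric(n_tasks), paste0("ds", seq_len(n_tasks))))
    }
    if (ensemble) ensemble_scores(model, genome, v, genome_id, shifts)
    else score_variant(model, genome, v, genome_id)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- variants$id
  structure(m, class = c("variant_score_table", class(m)),
            genome_id = genome_id, ensemble = ensemble,
            sign = "alt_minus_ref")
}

#' Export a score table as TSV (SLDP-compatible signed annotation)
#'
#' Long format: variant id, dataset, score. The sign convention
#' (alt - ref) travels in a header comment.
#'
#' @param scores a `variant_score_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_score_table <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sign=", attr(scores, "sign"),
                    " genome=", attr(scores, "genome_id")), con)
  df <- data.frame(variant = rep(rownames(scores), ncol(scores)),
                   dataset = rep(colnames(scores) %||%
                                   paste0("ds", seq_len(ncol(scores))),
                                 each = nrow(scores)),
                   score = as.vector(scores))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
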