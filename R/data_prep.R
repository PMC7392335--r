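## Coverage-track preprocessing and training-example construction.
##
## The fixed preprocessing order is: clip negatives to zero -> mask
## blacklist/unmappable regions to the track's 25th-percentile value ->
## average replicates -> bin to windows (sum) -> soft-clip the binned
## values at the per-source threshold.

#' Preprocessing configuration for one coverage dataset
#'
#' @param source one of `"CAGE"`, `"ENCODE"`, `"GEO"`, or `"custom"`;
#'   selects the default clip threshold (384 / 32 / 64).
#' @param clip_threshold soft-clip threshold `t_c`; overrides the source
#'   default when given.
#' @param mask_percentile percentile (0-100) whose value replaces signal in
#'   masked regions.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(source = c("CAGE", "ENCODE", "GEO", "custom"),
                              clip_threshold = NULL,
                              mask_percentile = 25) {
  source <- match.arg(source)
  tc <- clip_threshold %||%
    switch(source, CAGE = 384, ENCODE = 32, GEO = 64,
           custom = stop2("custom source requires clip_threshold"))
  if (tc <= 0) stop2("clip_threshold must be positive")
  if (mask_percentile < 0 || mask_percentile > 100)
    stop2("mask_percentile must lie in [0, 100]")
  structure(list(source = source, clip_threshold = tc,
                 mask_percentile = mask_percentile),
            class = "preprocess_config")
}

#' Soft clip of high signal values
#'
#' `f(x) = min(x, t_c + sqrt(max(0, x - t_c)))`: identity below the
#' threshold, square-root compression of the residual above it. Idempotent
#' and monotone nondecreasing.
#'
#' @param x numeric vector of signal values.
#' @param t_c clip threshold (positive).
#' @return soft-clipped values, same length.
#' @export
soft_clip <- function(x, t_c) {
  if (any(!is.finite(x))) stop2("soft_clip: non-finite input")
  pmin(x, t_c + sqrt(pmax(0, x - t_c)))
}

#' Clip negative signal values to zero
#' @param x numeric vector.
#' @return `pmax(x, 0)`.
#' @export
clip_negatives <- function(x) pmax(x, 0)

#' Replace signal in masked regions by a track percentile
#'
#' Blacklist, satellite-repeat and unmappable intervals collect artifactual
#' signal; their values are replaced by the track's genome-wide percentile
#' value (computed on negative-clipped values, before masking or
#' soft-clipping).
#'
#' @param track named list of per-chromosome numeric vectors.
#' @param regions data.frame of intervals (chrom, start, end; 0-based
#'   half-open) to mask.
#' @param percentile percentile in 0-100 (default 25).
#' @return masked track, same shape.
#' @export
mask_to_percentile <- function(track, regions, percentile = 25) {
  if (length(track) == 0 || sum(lengths(track)) == 0)
    stop2("mask_to_percentile: empty track")
  vals <- clip_negatives(unlist(track, use.names = FALSE))
  fill <- as.numeric(quantile(vals, percentile / 100, names = FALSE,
                              type = 7))
  if (nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      chrom <- regions$chrom[i]
      if (!chrom %in% names(track)) next
      n <- length(track[[chrom]])
      s <- max(0L, regions$start[i]); e <- min(n, regions$end[i])
      if (s < e) track[[chrom]][(s + 1L):e] <- fill
    }
  }
  track
}

#' Average replicate coverage tracks
#'
#' @param tracks list of tracks (each a named list of per-chromosome
#'   vectors) with identical chromosomes and lengths.
#' @return per-bp arithmetic mean track.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0) stop2("no tracks supplied")
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (!identical(names(tr), names(ref)) ||
        !identical(lengths(tr), lengths(ref)))
      stop2("replicate tracks differ in chromosomes or lengths")
  }
  out <- ref
  for (chrom in names(ref)) {
    acc <- ref[[chrom]]
    for (tr in tracks[-1]) acc <- acc + tr[[chrom]]
    out[[chrom]] <- acc / length(tracks)
  }
  out
}

#' Sum per-bp signal into fixed-width bins
#'
#' The bin statistic is the sum (a count-like quantity matching the Poisson
#' training loss); total signal is conserved.
#'
#' @param x numeric vector whose length is divisible by `width`.
#' @param width bin width in bp (default 128).
#' @return numeric vector of length `length(x) / width`.
#' @export
bin_signal <- function(x, width = 128) {
  n <- length(x)
  if (n %% width != 0)
    stop2("bin_signal: length ", n, " not divisible by width ", width)
  colSums(matrix(x, nrow = width))
}

#' Full preprocessing of one dataset's raw replicate tracks
#'
#' Applies the fixed order: clip negatives, mask to percentile, average
#' replicates. Binning and soft-clipping happen later, per training
#' interval, in [make_training_examples()].
#'
#' @param tracks list of replicate tracks (named per-chromosome lists).
#' @param mask_regions data.frame of blacklist/unmappable intervals (may
#'   have zero rows).
#' @param config a [preprocess_config()].
#' @return preprocessed per-bp track.
#' @export
preprocess_track <- function(tracks, mask_regions, config) {
  tracks <- lapply(tracks, function(tr) lapply(tr, clip_negatives))
  tracks <- lapply(tracks, mask_to_percentile, regions = mask_regions,
                   percentile = config$mask_percentile)
  average_replicates(tracks)
}

#' Tile training intervals across split territory
#'
#' Lays fixed-length model windows at a constant stride inside each
#' contiguous block of one split's territory. The default stride is
#' `L/2 + 63`: a 50 percent overlap shifted by 63 bp so that bin and
#' pooling boundaries also move between overlapping views of the same
#' locus. Windows never cross block (hence split) boundaries.
#'
#' @param blocks data.frame of contiguous split intervals (chrom, start,
#'   end; 0-based half-open).
#' @param L window length in bp (default 131072).
#' @param stride distance between window starts (default `L/2 + 63`).
#' @return data.frame of intervals (chrom, start, end).
#' @export
tile_training_intervals <- function(blocks, L = 131072L,
                                    stride = NULL) {
  stride <- as.integer(stride %||% (L / 2 + 63))
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    len <- blocks$end[i] - blocks$start[i]
    if (len < L) next
    n <- (len - L) %/% stride + 1L
    starts <- blocks$start[i] + stride * (seq_len(n) - 1L)
    out[[length(out) + 1L]] <- data.frame(
      chrom = blocks$chrom[i], start = starts, end = starts + L,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    warning("no contiguous block long enough for one training window")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' One-hot encode a DNA sequence
#'
#' Rows in fixed order A, C, G, T; `N` becomes 0.25 in every row so each
#' column still sums to one; case-insensitive.
#'
#' @param dna character scalar over A/C/G/T/N.
#' @return 4 x nchar(dna) numeric matrix with rownames A,C,G,T.
#' @export
encode_sequence <- function(dna) {
  bases <- str_bases(dna)
  idx <- match(bases, c("A", "C", "G", "T"))
  bad <- is.na(idx) & bases != "N"
  if (any(bad))
    stop2("encode_sequence: invalid character '", bases[which(bad)[1]],
          "' at position ", which(bad)[1])
  m <- matrix(0, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  known <- !is.na(idx)
  m[cbind(idx[known], which(known))] <- 1
  m[, !known] <- 0.25
  m
}

#' Reverse complement a one-hot encoded sequence
#' @param m 4 x L one-hot matrix from [encode_sequence()].
#' @return 4 x L matrix of the reverse complement.
#' @export
revcomp_onehot <- function(m) {
  out <- m[c("T", "G", "C", "A"), ncol(m):1, drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Build model-ready training examples for one genome
#'
#' For each interval: one-hot encodes the sequence and bins every
#' preprocessed dataset track into `width`-bp windows (sum), then
#' soft-clips the binned values at each dataset's threshold.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tracks named list of preprocessed per-bp tracks (one per
#'   dataset).
#' @param intervals data.frame from [tile_training_intervals()].
#' @param configs named list of [preprocess_config()] parallel to
#'   `tracks`.
#' @param genome_id genome label, e.g. `"A"`.
#' @param width bin width in bp.
#' @param split_label optional split name stored on each example.
#' @return list of `training_example` objects, each with fields `x`
#'   (4 x L), `y` (n_bins x n_datasets), `genome_id`, `chrom`, `start`,
#'   `end`, `split`.
#' @export
make_training_examples <- function(genome, tracks, intervals, configs,
                                   genome_id, width = 128L,
                                   split_label = NA_character_) {
  stopifnot(length(tracks) == length(configs))
  n_ds <- length(tracks)
  lapply(seq_len(nrow(intervals)), function(i) {
    chrom <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    seq_str <- substr(genome[[chrom]], s + 1L, e)
    y <- matrix(0, nrow = (e - s) %/% width, ncol = n_ds,
                dimnames = list(NULL, names(tracks)))
    for (d in seq_len(n_ds)) {
      binned <- bin_signal(tracks[[d]][[chrom]][(s + 1L):e], width)
      y[, d] <- soft_clip(binned, configs[[d]]$clip_threshold)
    }
    structure(list(x = encode_sequence(seq_str), y = y,
                   genome_id = genome_id, chrom = chrom,
                   start = s, end = e, split = split_label),
              class = "training_example")
  })
}

#' Write / read a training-example dataset container
#'
#' A simple chunked container: a JSON index plus one RDS chunk per batch of
#' examples, supporting streaming reads. Built at run time (never shipped).
#'
#' @param examples list of training examples.
#' @param path directory to create.
#' @param chunk_size examples per chunk.
#' @return `path` invisibly (write); list of examples (read).
#' @export
write_dataset <- function(examples, path, chunk_size = 16L) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(examples)
  chunks <- if (n > 0) split(seq_len(n), (seq_len(n) - 1L) %/% chunk_size)
            else list()
  for (j in seq_along(chunks)) {
    saveRDS(examples[chunks[[j]]],
            file.path(path, sprintf("chunk_%04d.rds", j)))
  }
  jsonlite::write_json(list(n_examples = n, n_chunks = length(chunks),
                            chunk_size = chunk_size),
                       file.path(path, "index.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @param batches optional integer vector of chunk indices to read
#'   (streaming); default all.
#' @export
read_dataset <- function(path, batches = NULL) {
  idx_path <- file.path(path, "index.json")
  if (!file.exists(idx_path)) stop2("corrupt container: missing index.json")
  idx <- jsonlite::read_json(idx_path)
  n_chunks <- idx$n_chunks
  batches <- batches %||% seq_len(n_chunks)
  out <- list()
  for (j in batches) {
    f <- file.path(path, sprintf("chunk_%04d.rds", j))
    if (!file.exists(f)) stop2("corrupt container: missing chunk offset ", j)
    out <- c(out, readRDS(f))
  }
  out
}
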