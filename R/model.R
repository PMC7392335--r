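## The residual dilated convolutional architecture.
##
## Tower: `tower_blocks` rounds of [conv (width 15 first, then 5) -> batch
## norm -> GELU -> max pool width 2], filters growing geometrically.
## Trunk: `dilated_blocks` residual blocks [GELU -> dilated conv width 3 ->
## BN -> GELU -> width-1 conv back to residual_filters -> BN -> dropout],
## each added to its input, dilation growing by `dilation_growth` per
## block. Final width-1 conv block, then one width-1 conv head per genome
## with a softplus link. All parameters are shared between genomes except
## the head weights.

#' Geometric convolution filter schedule
#'
#' Block `i` of the convolution tower uses
#' `round(init * growth^(i-1))` filters.
#'
#' @param init filters in the first block.
#' @param growth per-block growth factor (>= 1).
#' @param n_blocks number of tower blocks.
#' @return integer vector of length `n_blocks`.
#' @export
filter_schedule <- function(init = 288, growth = 1.1776, n_blocks = 7) {
  stopifnot(init >= 1, growth >= 1)
  as.integer(round(init * growth^(seq_len(n_blocks) - 1)))
}

#' Dilation-rate schedule of the residual stack
#' @param growth per-block dilation growth factor.
#' @param n_blocks number of residual blocks.
#' @return integer dilation rate per block, `max(1, round(growth^(i-1)))`.
#' @export
dilation_schedule <- function(growth = 1.5, n_blocks = 11) {
  pmax(1L, as.integer(round(growth^(seq_len(n_blocks) - 1))))
}

#' Model architecture configuration
#'
#' Defaults reproduce the full-scale architecture: 131,072-bp input, seven
#' tower blocks (288 filters growing by 1.1776x to 768), eleven dilated
#' residual blocks (384 dilated filters, 768 residual filters, dilation
#' growing 1.5x, dropout 0.3), a 1536-filter final block (dropout 0.05),
#' and per-genome softplus heads over 128-bp bins.
#'
#' @param seq_len input sequence length L (bp).
#' @param tower_blocks,init_filters,filter_growth,first_kernel,tower_kernel,pool_width
#'   convolution tower shape.
#' @param dilated_blocks,dilated_filters,residual_filters,dilation_growth,residual_dropout
#'   dilated residual stack shape.
#' @param final_filters,final_dropout final width-1 block.
#' @param heads named list/vector mapping genome id to number of output
#'   datasets (tasks).
#' @param bn_momentum,bn_eps batch-norm running-statistics momentum and
#'   variance epsilon (library defaults, recorded here).
#' @return a `model_config` object. `n_bins` and the per-block filter and
#'   dilation schedules are derived fields.
#' @export
model_config <- function(seq_len = 131072L, tower_blocks = 7L,
                         init_filters = 288L, filter_growth = 1.1776,
                         first_kernel = 15L, tower_kernel = 5L,
                         pool_width = 2L, dilated_blocks = 11L,
                         dilated_filters = 384L, residual_filters = 768L,
                         dilation_growth = 1.5, residual_dropout = 0.3,
                         final_filters = 1536L, final_dropout = 0.05,
                         heads = c(A = 5313L, B = 1643L),
                         bn_momentum = 0.99, bn_eps = 1e-3) {
  pool_total <- pool_width^tower_blocks
  if (seq_len %% pool_total != 0)
    stop2("seq_len must be divisible by pool_width^tower_blocks = ",
          pool_total)
  if (residual_dropout < 0 || residual_dropout >= 1 ||
      final_dropout < 0 || final_dropout >= 1)
    stop2("dropout probabilities must lie in [0, 1)")
  filters <- filter_schedule(init_filters, filter_growth, tower_blocks)
  if (filters[tower_blocks] != residual_filters)
    stop2("final tower filter count (", filters[tower_blocks],
          ") must equal residual_filters (", residual_filters,
          "); adjust init_filters/filter_growth")
  structure(list(seq_len = as.integer(seq_len),
                 tower_blocks = as.integer(tower_blocks),
                 init_filters = as.integer(init_filters),
                 filter_growth = filter_growth,
                 first_kernel = as.integer(first_kernel),
                 tower_kernel = as.integer(tower_kernel),
                 pool_width = as.integer(pool_width),
                 dilated_blocks = as.integer(dilated_blocks),
                 dilated_filters = as.integer(dilated_filters),
                 residual_filters = as.integer(residual_filters),
                 dilation_growth = dilation_growth,
                 residual_dropout = residual_dropout,
                 final_filters = as.integer(final_filters),
                 final_dropout = final_dropout,
                 heads = unlist(heads),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 filters = filters,
                 dilations = dilation_schedule(dilation_growth,
                                               dilated_blocks),
                 n_bins = as.integer(seq_len / pool_total)),
            class = "model_config")
}

#' Write / read a model config as JSON
#' @param config a [model_config()].
#' @param path JSON file.
#' @return `path` invisibly (write); a `model_config` (read).
#' @export
write_model_config <- function(config, path) {
  config$heads <- as.list(config$heads)  # keep genome names in JSON
  jsonlite::write_json(unclass(config)[c(
    "seq_len", "tower_blocks", "init_filters", "filter_growth",
    "first_kernel", "tower_kernel", "pool_width", "dilated_blocks",
    "dilated_filters", "residual_filters", "dilation_growth",
    "residual_dropout", "final_filters", "final_dropout", "heads",
    "bn_momentum", "bn_eps")], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_config, j)
}

#' Assemble the network
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `seqnet` model: shared trunk layers plus one head (width-1
#'   conv + softplus) per genome.
#' @export
build_model <- function(config, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    trunk <- list()
    c_in <- 4L
    for (i in seq_len(config$tower_blocks)) {
      k <- if (i == 1) config$first_kernel else config$tower_kernel
      c_out <- config$filters[i]
      trunk <- c(trunk, list(new_conv(c_in, c_out, k),
                             new_bn_gelu(c_out, config$bn_momentum,
                                         config$bn_eps),
                             new_pool()))
      c_in <- c_out
    }
    n_tower_layers <- length(trunk)
    for (i in seq_len(config$dilated_blocks)) {
      sub <- list(new_act(),
                  new_conv(config$residual_filters, config$dilated_filters,
                           3L, config$dilations[i]),
                  new_bn_gelu(config$dilated_filters, config$bn_momentum,
                              config$bn_eps),
                  new_conv(config$dilated_filters,
                           config$residual_filters, 1L),
                  new_bn(config$residual_filters, config$bn_momentum,
                         config$bn_eps),
                  new_dropout(config$residual_dropout))
      trunk <- c(trunk, list(new_residual(sub)))
    }
    trunk <- c(trunk, list(
      new_conv(config$residual_filters, config$final_filters, 1L),
      new_bn_gelu(config$final_filters, config$bn_momentum,
                  config$bn_eps),
      new_dropout(config$final_dropout)))
    heads <- lapply(config$heads, function(n_tasks) {
      list(new_conv(config$final_filters, as.integer(n_tasks), 1L),
           list(type = "softplus"))
    })
    structure(list(trunk = trunk, heads = heads, config = config,
                   n_tower_layers = n_tower_layers, seed = seed),
              class = "seqnet")
  })
}

#' Forward pass
#'
#' @param model a `seqnet` from [build_model()].
#' @param x one-hot matrix (4 x L, as from [encode_sequence()]) or a list
#'   of them (a batch).
#' @param genome_id which genome head to apply.
#' @param training logical; enables dropout and batch statistics.
#' @return `n_bins x n_tasks` prediction matrix (or a list of them),
#'   strictly positive. Inference mode is deterministic.
#' @export
forward <- function(model, x, genome_id, training = FALSE) {
  if (!genome_id %in% names(model$heads))
    stop2("unregistered genome_id '", genome_id, "'")
  single <- !is.list(x)
  xs <- if (single) list(t(x)) else lapply(x, t)
  tr <- nn_forward(model$trunk, xs, training)
  hd <- nn_forward(model$heads[[genome_id]], tr$out, training)
  if (single) hd$out[[1]] else hd$out
}

# forward keeping caches, for training steps
forward_full <- function(model, xs, genome_id, training = TRUE) {
  tr <- nn_forward(model$trunk, xs, training)
  hd <- nn_forward(model$heads[[genome_id]], tr$out, training)
  list(pred = hd$out, trunk_cache = tr, head_cache = hd)
}

#' Save / load a model checkpoint
#' @param model a `seqnet`.
#' @param path checkpoint file (RDS payload).
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Post-tower representation of a sequence
#'
#' The per-128-bp-segment embedding after the convolution tower and before
#' the dilated stack; the substrate of the saliency analysis.
#'
#' @param model a `seqnet`.
#' @param x one-hot matrix 4 x L.
#' @return `n_bins x residual_filters` matrix.
#' @export
tower_representation <- function(model, x) {
  tr <- nn_forward(model$trunk[seq_len(model$n_tower_layers)], list(t(x)),
                   training = FALSE)
  tr$out[[1]]
}
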