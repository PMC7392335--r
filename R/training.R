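## Joint two-genome optimization: Poisson loss on cropped center bins,
## reverse-complement / small-shift augmentation, genome-proportional
## batches, SGD with momentum, early stopping on validation loss, and
## per-genome fine-tuning.

#' Training configuration
#'
#' @param batch_size sequences per SGD batch.
#' @param lr,momentum SGD learning rate and momentum.
#' @param joint_patience epochs without validation improvement before the
#'   joint phase stops.
#' @param finetune_patience same for per-genome fine-tuning.
#' @param crop_keep number of center bins the loss is computed on;
#'   `NULL` means `round(7/8 * n_bins)`, preserving the full-scale
#'   1024 -> 896 ratio.
#' @param shift_max maximum sequence shift (bp) for augmentation; shifts
#'   require genome access at training time.
#' @param rc_augment cycle reverse-complement augmentation.
#' @param max_epochs hard epoch cap.
#' @param seed integer seed governing batching, augmentation phase, and
#'   dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 4L, lr = 0.005, momentum = 0.99,
                         joint_patience = 30L, finetune_patience = 10L,
                         crop_keep = NULL, shift_max = 3L,
                         rc_augment = TRUE, max_epochs = 1000L,
                         seed = 1L) {
  if (shift_max < 0) stop2("shift_max must be >= 0")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum,
                 joint_patience = as.integer(joint_patience),
                 finetune_patience = as.integer(finetune_patience),
                 crop_keep = crop_keep, shift_max = as.integer(shift_max),
                 rc_augment = rc_augment,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Poisson regression loss
#'
#' Mean over elements of `pred - target * log(pred)` (the negative Poisson
#' log likelihood up to the target-only term).
#'
#' @param pred strictly positive prediction matrix.
#' @param target nonnegative target matrix of the same shape.
#' @return scalar loss.
#' @export
poisson_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop2("shape mismatch")
  if (any(pred <= 0)) stop2("poisson_loss requires strictly positive pred")
  mean(pred - target * log(pred))
}

#' Crop a binned matrix to its center rows
#'
#' Training ignores the outermost bins, where sequence context beyond the
#' input is missing.
#'
#' @param m n_bins x n_tasks matrix.
#' @param keep number of center rows to keep; `nrow(m) - keep` must be
#'   even.
#' @return the center `keep` rows.
#' @export
crop_center <- function(m, keep) {
  drop_total <- nrow(m) - keep
  if (drop_total < 0 || drop_total %% 2 != 0)
    stop2("cannot crop ", nrow(m), " bins to ", keep,
          ": remainder must be even and nonnegative")
  if (drop_total == 0) return(m)
  side <- drop_total / 2
  m[(side + 1):(nrow(m) - side), , drop = FALSE]
}

default_crop_keep <- function(n_bins, crop_keep = NULL) {
  k <- crop_keep %||% round(7 / 8 * n_bins)
  if ((n_bins - k) %% 2 != 0) k <- k + 1
  as.integer(k)
}

#' Augment a training example
#'
#' Reverse complementation flips the one-hot sequence and reverses the
#' target bin order; shifting moves the sequence window along the genome
#' while targets stay fixed.
#'
#' @param example a `training_example`.
#' @param rc logical, reverse complement.
#' @param shift signed shift in bp (requires `genome`).
#' @param genome named chromosome sequences (for shifts only).
#' @return augmented `training_example`.
#' @export
augment_example <- function(example, rc = FALSE, shift = 0L,
                            genome = NULL) {
  if (shift != 0) {
    if (is.null(genome))
      stop2("sequence shifts require the genome")
    s <- example$start + shift
    e <- example$end + shift
    n <- nchar(genome[[example$chrom]])
    if (s < 0 || e > n)
      stop2("shift moves the window off the contig")
    example$x <- encode_sequence(substr(genome[[example$chrom]],
                                        s + 1L, e))
  }
  if (rc) {
    example$x <- revcomp_onehot(example$x)
    example$y <- example$y[nrow(example$y):1, , drop = FALSE]
  }
  example
}

#' Genome-proportional batch schedule
#'
#' Each batch is homogeneous in genome; the genome of every batch is drawn
#' independently with probability proportional to the genomes' example
#' counts.
#'
#' @param counts named vector of per-genome example counts.
#' @param n_batches schedule length to emit.
#' @param seed integer seed.
#' @return character vector of genome ids, length `n_batches`.
#' @export
sample_genome_batches <- function(counts, n_batches, seed = 1L) {
  if (any(counts < 0) || sum(counts) == 0)
    stop2("need nonnegative counts with at least one positive")
  with_seed(derive_seed(seed, "batches"), {
    sample(names(counts), n_batches, replace = TRUE,
           prob = counts / sum(counts))
  })
}

# one SGD step on a homogeneous batch; returns updated model/state/loss
train_step <- function(model, state, examples, genome_id, lr, momentum,
                       crop_keep) {
  xs <- lapply(examples, function(e) t(e$x))
  fw <- forward_full(model, xs, genome_id, training = TRUE)
  n_bins <- nrow(fw$pred[[1]])
  side <- (n_bins - crop_keep) / 2
  keep_rows <- (side + 1):(n_bins - side)
  n_elem <- length(examples) * crop_keep * ncol(fw$pred[[1]])
  loss <- 0
  dpreds <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    pred <- fw$pred[[i]]
    y <- examples[[i]]$y
    dp <- matrix(0, nrow(pred), ncol(pred))
    pk <- pred[keep_rows, , drop = FALSE]
    yk <- y[keep_rows, , drop = FALSE]
    loss <- loss + sum(pk - yk * log(pk))
    dp[keep_rows, ] <- (1 - yk / pk) / n_elem
    dpreds[[i]] <- dp
  }
  loss <- loss / n_elem
  if (!is.finite(loss))
    stop2("divergent loss (non-finite) on genome ", genome_id,
          "; reduce the learning rate")
  head_layers <- model$heads[[genome_id]]
  hb <- nn_backward(head_layers, fw$head_cache$caches, dpreds)
  tb <- nn_backward(model$trunk, fw$trunk_cache$caches, hb$dx)

  up_t <- sgd_update(model$trunk, tb$grads, state$trunk, lr, momentum)
  model$trunk <- bn_refresh(up_t$layers, fw$trunk_cache$caches)
  state$trunk <- up_t$state
  up_h <- sgd_update(head_layers, hb$grads,
                     state$heads[[genome_id]], lr, momentum)
  model$heads[[genome_id]] <- bn_refresh(up_h$layers,
                                         fw$head_cache$caches)
  state$heads[[genome_id]] <- up_h$state
  list(model = model, state = state, loss = loss)
}

# mean validation loss for one genome's example list
valid_loss <- function(model, examples, genome_id, crop_keep) {
  if (length(examples) == 0) return(NA_real_)
  losses <- vapply(examples, function(e) {
    pred <- forward(model, e$x, genome_id, training = FALSE)
    poisson_loss(crop_center(pred, crop_keep),
                 crop_center(e$y, crop_keep))
  }, 0)
  mean(losses)
}

# augmentation plan: cycle over rc x shift combinations with a per-example
# seeded phase offset
augment_plan <- function(n_examples, epoch, config, seed) {
  shifts <- seq(-config$shift_max, config$shift_max)
  rcs <- if (config$rc_augment) c(FALSE, TRUE) else FALSE
  combos <- expand.grid(shift = shifts, rc = rcs)
  offs <- with_seed(derive_seed(seed, "augphase"),
                    sample(nrow(combos), n_examples, replace = TRUE))
  idx <- ((offs + epoch - 1L) %% nrow(combos)) + 1L
  combos[idx, , drop = FALSE]
}

#' Train the model on one or two genomes
#'
#' Runs SGD with momentum on genome-homogeneous batches drawn
#' proportionally to example counts, cycling reverse-complement and shift
#' augmentations, computing the Poisson loss on the center bins. Training
#' stops when the (sampling-proportion weighted) validation loss has not
#' improved for `patience` epochs, and the weights achieving the minimum
#' validation loss are returned.
#'
#' @param model a `seqnet`.
#' @param train_sets named list (by genome id) of training-example lists.
#' @param valid_sets named list of validation-example lists.
#' @param config a [train_config()].
#' @param genomes optional named list of genome sequence vectors (enables
#'   shift augmentation).
#' @param patience overrides `config$joint_patience`.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best weights), `history` (per-epoch
#'   data.frame: epoch, genome, train_loss, valid_loss, weighted valid),
#'   and `best_epoch`.
#' @export
train_model <- function(model, train_sets, valid_sets, config = train_config(),
                        genomes = NULL, patience = NULL, verbose = FALSE) {
  genome_ids <- names(train_sets)
  if (any(lengths(train_sets) == 0))
    stop2("empty training set for genome ",
          paste(genome_ids[lengths(train_sets) == 0], collapse = ","))
  patience <- patience %||% config$joint_patience
  counts <- lengths(train_sets)
  props <- counts / sum(counts)
  n_bins <- nrow(train_sets[[1]][[1]]$y)
  crop_keep <- default_crop_keep(n_bins, config$crop_keep)

  state <- list(trunk = vector("list", length(model$trunk)),
                heads = lapply(model$heads, function(h)
                  vector("list", length(h))))
  best <- list(loss = Inf, model = model, epoch = 0L)
  history <- list()
  epochs_since_best <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    n_batches <- ceiling(sum(counts) / config$batch_size)
    schedule <- sample_genome_batches(counts, n_batches,
                                      derive_seed(config$seed, "sched",
                                                  epoch))
    queues <- lapply(genome_ids, function(g)
      with_seed(derive_seed(config$seed, "shuffle", epoch, g),
                sample(counts[[g]])))
    names(queues) <- genome_ids
    plans <- lapply(genome_ids, function(g)
      augment_plan(counts[[g]], epoch, config,
                   derive_seed(config$seed, g)))
    names(plans) <- genome_ids
    qpos <- setNames(rep(1L, length(genome_ids)), genome_ids)
    train_losses <- setNames(rep(0, length(genome_ids)), genome_ids)
    train_n <- setNames(rep(0L, length(genome_ids)), genome_ids)

    with_seed(derive_seed(config$seed, "dropout", epoch), {
      for (b in schedule) {
        take <- min(config$batch_size, counts[[b]])
        idx <- integer(take)
        for (j in seq_len(take)) {
          if (qpos[[b]] > counts[[b]]) qpos[[b]] <- 1L
          idx[j] <- queues[[b]][qpos[[b]]]
          qpos[[b]] <- qpos[[b]] + 1L
        }
        batch <- lapply(idx, function(i) {
          pl <- plans[[b]][i, ]
          ex <- train_sets[[b]][[i]]
          sh <- if (is.null(genomes)) 0L else pl$shift
          if (sh != 0) {
            # drop the shift at contig edges
            n <- nchar(genomes[[b]][[ex$chrom]])
            if (ex$start + sh < 0 || ex$end + sh > n) sh <- 0L
          }
          augment_example(ex, rc = pl$rc, shift = sh,
                          genome = genomes[[b]])
        })
        st <- train_step(model, state, batch, b, config$lr,
                         config$momentum, crop_keep)
        model <- st$model; state <- st$state
        train_losses[[b]] <- train_losses[[b]] + st$loss
        train_n[[b]] <- train_n[[b]] + 1L
      }
    })

    vloss <- vapply(genome_ids, function(g)
      valid_loss(model, valid_sets[[g]], g, crop_keep), 0)
    wvalid <- sum(props * vloss)
    for (g in genome_ids) {
      history[[length(history) + 1L]] <- data.frame(
        epoch = epoch, genome = g,
        train_loss = train_losses[[g]] / max(train_n[[g]], 1L),
        valid_loss = vloss[[g]], weighted_valid = wvalid)
    }
    if (verbose)
      message(sprintf("epoch %d: weighted valid loss %.5f", epoch, wvalid))

    if (wvalid < best$loss) {
      best <- list(loss = wvalid, model = model, epoch = epoch)
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
      if (epochs_since_best > patience) break
    }
  }
  list(model = best$model, history = do.call(rbind, history),
       best_epoch = best$epoch, best_valid = best$loss)
}

#' Fine-tune a jointly trained model on one genome
#'
#' Continues training on a single genome's data (trunk plus that genome's
#' head; the other head is untouched) with the shorter fine-tuning
#' patience, returning the best-validation weights. If the initial
#' validation loss is never beaten the entry model is returned.
#'
#' @param model a jointly trained `seqnet`.
#' @param genome_id genome to fine-tune on.
#' @param train_set,valid_set example lists for that genome.
#' @param config a [train_config()].
#' @param genomes optional genome sequences for shift augmentation.
#' @return list as from [train_model()].
#' @export
fine_tune <- function(model, genome_id, train_set, valid_set,
                      config = train_config(), genomes = NULL) {
  if (!genome_id %in% names(model$heads))
    stop2("unknown genome '", genome_id, "'")
  n_bins <- nrow(train_set[[1]]$y)
  crop_keep <- default_crop_keep(n_bins, config$crop_keep)
  entry_loss <- valid_loss(model, valid_set, genome_id, crop_keep)
  res <- train_model(model,
                     setNames(list(train_set), genome_id),
                     setNames(list(valid_set), genome_id),
                     config, genomes = genomes,
                     patience = config$finetune_patience)
  if (is.finite(entry_loss) && res$best_valid > entry_loss) {
    res$model <- model
    res$best_valid <- entry_loss
    res$best_epoch <- 0L
  }
  res
}

#' Evaluate per-dataset prediction accuracy
#'
#' Pearson correlation between predictions and targets over all cropped
#' bins of all test examples, per dataset.
#'
#' @param model a `seqnet`.
#' @param test_set list of training examples from the held-out split (one
#'   genome).
#' @param genome_id genome head to use.
#' @param crop_keep center bins scored; default `round(7/8 * n_bins)`.
#' @return data.frame (dataset, r); datasets with zero variance get NA.
#' @export
evaluate_model <- function(model, test_set, genome_id, crop_keep = NULL) {
  if (length(test_set) == 0) stop2("empty test set")
  n_bins <- nrow(test_set[[1]]$y)
  crop_keep <- default_crop_keep(n_bins, crop_keep)
  preds <- lapply(test_set, function(e)
    crop_center(forward(model, e$x, genome_id), crop_keep))
  targs <- lapply(test_set, function(e) crop_center(e$y, crop_keep))
  P <- do.call(rbind, preds)
  Y <- do.call(rbind, targs)
  r <- vapply(seq_len(ncol(Y)), function(j) {
    if (sd(Y[, j]) == 0 || sd(P[, j]) == 0) return(NA_real_)
    cor(P[, j], Y[, j])
  }, 0)
  data.frame(dataset = colnames(test_set[[1]]$y) %||%
               paste0("ds", seq_len(ncol(Y))),
             r = r, stringsAsFactors = FALSE)
}
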