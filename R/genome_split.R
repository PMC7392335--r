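## Leakage-free train/validation/test partitioning of two genomes.
##
## Each genome is tiled into fixed-size regions; regions from the two
## genomes are joined by an edge when they share more than `min_aligned`
## base pairs of aligning sequence; connected components of this bipartite
## graph are assigned to splits as indivisible units, so no holdout region
## has a training-set ortholog.

#' Split configuration
#'
#' @param tile_size region size in bp (default 1 Mb).
#' @param min_aligned minimum aligned bp (strict inequality) for an edge
#'   (default 100 kb).
#' @param valid_frac,test_frac target per-genome nucleotide fractions for
#'   the validation and test sets (default 0.12 each).
#' @param seed integer seed for tie-breaking.
#' @return a `split_config` list.
#' @export
split_config <- function(tile_size = 1000000L, min_aligned = 100000L,
                         valid_frac = 0.12, test_frac = 0.12, seed = 1L) {
  if (valid_frac + test_frac >= 1)
    stop2("valid_frac + test_frac must be < 1")
  if (min_aligned >= tile_size)
    stop2("min_aligned must be smaller than tile_size")
  structure(list(tile_size = as.integer(tile_size),
                 min_aligned = as.integer(min_aligned),
                 valid_frac = valid_frac, test_frac = test_frac,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Tile a genome into fixed-size regions
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param tile_size region size in bp.
#' @param genome_id genome label stored on each region.
#' @return data.frame with genome_id, chrom, start, end, region_index;
#'   regions tile each chromosome exactly, the last one possibly short.
#' @export
tile_genome <- function(chrom_sizes, tile_size = 1000000L,
                        genome_id = "A") {
  if (any(chrom_sizes < 0)) stop2("negative chromosome length")
  zero <- chrom_sizes == 0
  if (any(zero)) {
    warning("skipping zero-length chromosome(s): ",
            paste(names(chrom_sizes)[zero], collapse = ", "))
    chrom_sizes <- chrom_sizes[!zero]
  }
  out <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    starts <- seq(0L, len - 1L, by = tile_size)
    data.frame(genome_id = genome_id, chrom = chrom, start = starts,
               end = pmin(starts + tile_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$region_index <- seq_len(nrow(out)) - 1L
  out
}

# map alignment blocks onto region pairs; blocks spanning tile boundaries
# contribute aligned length proportionally to their overlap on genome A,
# then proportionally again on genome B
region_pair_aligned <- function(regions_a, regions_b, alignment) {
  pairs <- new.env(parent = emptyenv())
  lookup <- function(regions, chrom) {
    idx <- which(regions$chrom == chrom)
    if (length(idx) == 0) return(NULL)
    regions[idx, ]
  }
  for (i in seq_len(nrow(alignment))) {
    blk <- alignment[i, ]
    ra <- lookup(regions_a, blk$chromA)
    rb <- lookup(regions_b, blk$chromB)
    if (is.null(ra) || is.null(rb))
      stop2("alignment record ", i, " references unknown chromosome: ",
            blk$chromA, " / ", blk$chromB)
    spanA <- blk$endA - blk$startA
    spanB <- blk$endB - blk$startB
    ovA <- pmin(ra$end, blk$endA) - pmax(ra$start, blk$startA)
    for (ja in which(ovA > 0)) {
      fracA <- ovA[ja] / spanA
      # the A-overlap maps to a proportional window on B
      bs <- blk$startB + (pmax(ra$start[ja], blk$startA) - blk$startA) /
        spanA * spanB
      be <- bs + fracA * spanB
      ovB <- pmin(rb$end, be) - pmax(rb$start, bs)
      for (jb in which(ovB > 0)) {
        key <- paste(ra$region_index[ja], rb$region_index[jb])
        add <- blk$aligned_len * fracA * (ovB[jb] / (be - bs))
        pairs[[key]] <- (pairs[[key]] %||% 0) + add
      }
    }
  }
  keys <- ls(pairs)
  if (length(keys) == 0)
    return(data.frame(region_a = integer(), region_b = integer(),
                      aligned = numeric()))
  ab <- do.call(rbind, strsplit(keys, " "))
  data.frame(region_a = as.integer(ab[, 1]), region_b = as.integer(ab[, 2]),
             aligned = vapply(keys, function(k) pairs[[k]], 0),
             row.names = NULL)
}

#' Build the bipartite homology graph over genome regions
#'
#' @param regions_a,regions_b region tables from [tile_genome()] for the
#'   two genomes.
#' @param alignment alignment block data.frame (see [read_net_tsv()]).
#' @param min_aligned edge threshold: an edge requires strictly more than
#'   this many aligned bp between a region pair (summed over blocks).
#' @return a `homology_graph`: region tables plus an edge data.frame
#'   (region_a, region_b, aligned).
#' @export
build_homology_graph <- function(regions_a, regions_b, alignment,
                                 min_aligned = 100000L) {
  pa <- region_pair_aligned(regions_a, regions_b, alignment)
  edges <- pa[pa$aligned > min_aligned, , drop = FALSE]
  structure(list(regions_a = regions_a, regions_b = regions_b,
                 edges = edges, pair_aligned = pa,
                 min_aligned = min_aligned),
            class = "homology_graph")
}

#' Connected components of the homology graph
#'
#' Iterative breadth-first search over the bipartite graph. Region node
#' ids are `A<region_index>` / `B<region_index>`.
#'
#' @param graph a `homology_graph`.
#' @return integer vector of component ids named by node id.
#' @export
graph_components <- function(graph) {
  nodes <- c(paste0("A", graph$regions_a$region_index),
             paste0("B", graph$regions_b$region_index))
  adj <- new.env(parent = emptyenv())
  edge_push <- function(u, v) adj[[u]] <- c(adj[[u]] %||% character(), v)
  if (nrow(graph$edges) > 0) {
    for (i in seq_len(nrow(graph$edges))) {
      u <- paste0("A", graph$edges$region_a[i])
      v <- paste0("B", graph$edges$region_b[i])
      edge_push(u, v); edge_push(v, u)
    }
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (n in nodes) {
    if (!is.na(comp[[n]])) next
    cid <- cid + 1L
    queue <- n
    comp[[n]] <- cid
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in adj[[u]] %||% character()) {
        if (is.na(comp[[v]])) {
          comp[[v]] <- cid
          queue <- c(queue, v)
        }
      }
    }
  }
  comp
}

#' Partition homology-graph components into train/valid/test
#'
#' Components are sorted by total nucleotides (descending) and each is
#' assigned greedily to the split with the largest deficit below target,
#' where the deficit is averaged over genomes weighted by where the
#' component's nucleotides actually lie (train target =
#' 1 - valid - test); ties are broken by a seeded draw. All regions of a
#' component share one label, so no edge ever crosses splits.
#'
#' @param graph a `homology_graph`.
#' @param config a [split_config()].
#' @return data.frame of regions (both genomes) with a `split` column;
#'   attribute `fractions` holds the achieved per-genome nucleotide
#'   fractions.
#' @export
partition_components <- function(graph, config = split_config()) {
  comp <- graph_components(graph)
  regions <- rbind(graph$regions_a, graph$regions_b)
  node_id <- paste0(regions$genome_id, regions$region_index)
  regions$component <- comp[node_id]
  regions$nt <- regions$end - regions$start

  genome_total <- tapply(regions$nt, regions$genome_id, sum)
  comp_nt <- do.call(rbind, lapply(split(regions, regions$component),
    function(df) {
      data.frame(component = df$component[1],
                 nt_A = sum(df$nt[df$genome_id == "A"]),
                 nt_B = sum(df$nt[df$genome_id == "B"]),
                 nt = sum(df$nt))
    }))
  train_frac <- 1 - config$valid_frac - config$test_frac
  tot_A <- if ("A" %in% names(genome_total)) genome_total[["A"]] else 0
  tot_B <- if ("B" %in% names(genome_total)) genome_total[["B"]] else 0
  too_big <- (tot_A > 0 & comp_nt$nt_A / max(tot_A, 1) > train_frac) |
             (tot_B > 0 & comp_nt$nt_B / max(tot_B, 1) > train_frac)
  if (any(too_big))
    stop2("monolithic component: one connected component holds more than ",
          round(100 * train_frac), "% of a genome; relax min_aligned or ",
          "reduce tile_size")

  targets <- c(train = train_frac, valid = config$valid_frac,
               test = config$test_frac)
  assigned <- c(train = 0, valid = 0, test = 0)       # nt pooled
  assigned_g <- matrix(0, 2, 3, dimnames = list(c("A", "B"), names(targets)))
  comp_nt <- comp_nt[order(-comp_nt$nt, comp_nt$component), ]
  label <- setNames(character(nrow(comp_nt)), comp_nt$component)
  with_seed(derive_seed(config$seed, "partition"), {
    total <- sum(genome_total)
    for (i in seq_len(nrow(comp_nt))) {
      # deficit per split, weighted by the genome composition of this
      # component, so both genomes individually approach their targets
      wA <- comp_nt$nt_A[i] / comp_nt$nt[i]
      wB <- comp_nt$nt_B[i] / comp_nt$nt[i]
      defA <- targets - assigned_g["A", ] / max(tot_A, 1)
      defB <- targets - assigned_g["B", ] / max(tot_B, 1)
      deficit <- wA * defA + wB * defB
      best <- names(deficit)[deficit == max(deficit)]
      pick <- if (length(best) == 1) best else sample(best, 1)
      label[as.character(comp_nt$component[i])] <- pick
      assigned[pick] <- assigned[pick] + comp_nt$nt[i]
      assigned_g["A", pick] <- assigned_g["A", pick] + comp_nt$nt_A[i]
      assigned_g["B", pick] <- assigned_g["B", pick] + comp_nt$nt_B[i]
    }
  })
  regions$split <- unname(label[as.character(regions$component)])
  fr <- sweep(assigned_g, 1, pmax(c(tot_A, tot_B), 1), "/")
  attr(regions, "fractions") <- fr
  regions
}

#' Audit cross-split homology leakage
#'
#' Recomputes aligned bp between every region pair at threshold zero (all
#' blocks counted) and reports, per split pair, the aligned bp crossing
#' between splits and the fraction of validation/test nucleotides with a
#' training-set ortholog.
#'
#' @param assignment region table from [partition_components()].
#' @param alignment alignment block data.frame.
#' @param min_aligned threshold defining the supra-threshold view
#'   `cross_bp_supra` (region pairs with aligned bp strictly above it);
#'   the full `cross_bp` matrix always counts every aligned bp.
#' @return list with `cross_bp` (split-pair matrix of aligned bp at
#'   threshold 0), `cross_bp_supra` (same, restricted to supra-threshold
#'   region pairs), `holdout_train_ortholog_frac` (named vector for valid
#'   and test), and `total_aligned_bp`.
#' @export
audit_leakage <- function(assignment, alignment, min_aligned = 0) {
  ra <- assignment[assignment$genome_id == "A", ]
  rb <- assignment[assignment$genome_id == "B", ]
  pa <- region_pair_aligned(ra, rb, alignment)
  splits <- c("train", "valid", "test")
  cross <- matrix(0, 3, 3, dimnames = list(splits, splits))
  cross_supra <- cross
  sa <- setNames(ra$split, ra$region_index)
  sb <- setNames(rb$split, rb$region_index)
  if (nrow(pa) > 0) {
    for (i in seq_len(nrow(pa))) {
      u <- sa[[as.character(pa$region_a[i])]]
      v <- sb[[as.character(pa$region_b[i])]]
      cross[u, v] <- cross[u, v] + pa$aligned[i]
      if (pa$aligned[i] > min_aligned)
        cross_supra[u, v] <- cross_supra[u, v] + pa$aligned[i]
    }
  }
  holdout_frac <- c(valid = 0, test = 0)
  for (s in c("valid", "test")) {
    bad_a <- unique(pa$region_a[sb[as.character(pa$region_b)] == "train"])
    bad_b <- unique(pa$region_b[sa[as.character(pa$region_a)] == "train"])
    nt_bad <- sum(ra$nt[ra$split == s & ra$region_index %in% bad_a]) +
      sum(rb$nt[rb$split == s & rb$region_index %in% bad_b])
    nt_all <- sum(assignment$nt[assignment$split == s])
    holdout_frac[s] <- if (nt_all > 0) nt_bad / nt_all else 0
  }
  list(cross_bp = cross, cross_bp_supra = cross_supra,
       holdout_train_ortholog_frac = holdout_frac,
       total_aligned_bp = sum(pa$aligned))
}

#' Run the full split pipeline for a genome pair
#'
#' @param chrom_sizes_a,chrom_sizes_b named chromosome-length vectors.
#' @param alignment alignment block data.frame.
#' @param config a [split_config()].
#' @return the assignment table from [partition_components()] with the
#'   homology graph in `attr(, "graph")`.
#' @export
split_genomes <- function(chrom_sizes_a, chrom_sizes_b, alignment,
                          config = split_config()) {
  ra <- tile_genome(chrom_sizes_a, config$tile_size, "A")
  rb <- tile_genome(chrom_sizes_b, config$tile_size, "B")
  g <- build_homology_graph(ra, rb, alignment, config$min_aligned)
  out <- partition_components(g, config)
  attr(out, "graph") <- g
  out
}

#' Contiguous split territory as BED-style blocks
#'
#' Merges adjacent same-split regions of one genome into maximal
#' contiguous blocks, the input for [tile_training_intervals()].
#'
#' @param assignment region table from [partition_components()].
#' @param genome_id genome to extract.
#' @param split split label to extract.
#' @return data.frame (chrom, start, end).
#' @export
split_blocks <- function(assignment, genome_id, split) {
  df <- assignment[assignment$genome_id == genome_id &
                     assignment$split == split, ]
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$start), ]
  out <- list()
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, ]
    brk <- c(TRUE, d$start[-1] != d$end[-nrow(d)])
    grp <- cumsum(brk)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = tapply(d$start, grp, min),
      end = tapply(d$end, grp, max), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
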