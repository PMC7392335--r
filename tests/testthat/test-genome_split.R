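# Homology-aware genome splitting.

test_that("tile_genome ceiling arithmetic and zero-length handling", {
  r <- tile_genome(c(chr1 = 2500000L), 1000000L)
  expect_equal(nrow(r), 3L)
  expect_equal(r$end - r$start, c(1000000L, 1000000L, 500000L))
  expect_equal(nrow(tile_genome(c(chr1 = 1000000L), 1000000L)), 1L)
  r10 <- tile_genome(c(chr1 = 1e7), 1e6)
  expect_equal(nrow(r10), 10L)
  expect_true(all(r10$end - r10$start == 1e6))
  expect_warning(out <- tile_genome(c(a = 0L, b = 100L), 50L), "zero-length")
  expect_equal(unique(out$chrom), "b")
})

test_that("edge threshold is strict and sums blocks per region pair", {
  ra <- tile_genome(c(cA = 1000000L), 1000000L, "A")
  rb <- tile_genome(c(cB = 1000000L), 1000000L, "B")
  blk <- function(s, e, len) data.frame(chromA = "cA", startA = s,
                                        endA = e, chromB = "cB",
                                        startB = s, endB = e,
                                        strand = "+", aligned_len = len)
  # 150 kb: edge
  g <- build_homology_graph(ra, rb, blk(0L, 150000L, 150000L), 100000L)
  expect_equal(nrow(g$edges), 1L)
  # exactly 100 kb: NO edge (strict inequality)
  g <- build_homology_graph(ra, rb, blk(0L, 100000L, 100000L), 100000L)
  expect_equal(nrow(g$edges), 0L)
  # 60 kb + 50 kb summed over two blocks between the same pair: edge.
  # per-pair summation oracle: total aligned = 110,000 > 100,000
  two <- rbind(blk(0L, 60000L, 60000L), blk(500000L, 550000L, 50000L))
  g <- build_homology_graph(ra, rb, two, 100000L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$aligned, 110000)
  expect_error(build_homology_graph(ra, rb,
                                    blk(0L, 1000L, 1000L) |>
                                      transform(chromA = "nope"), 0L),
               "unknown chromosome")
})

test_that("boundary-spanning blocks split aligned length proportionally", {
  ra <- tile_genome(c(cA = 2000000L), 1000000L, "A")
  rb <- tile_genome(c(cB = 2000000L), 1000000L, "B")
  # block straddling the A tile boundary half/half
  aln <- data.frame(chromA = "cA", startA = 900000L, endA = 1100000L,
                    chromB = "cB", startB = 0L, endB = 200000L,
                    strand = "+", aligned_len = 200000L)
  pa <- crossreg:::region_pair_aligned(ra, rb, aln)
  expect_equal(sum(pa$aligned), 200000)        # total conserved
  a0 <- pa$aligned[pa$region_a == 0]
  a1 <- pa$aligned[pa$region_a == 1]
  expect_equal(sum(a0), 100000)
  expect_equal(sum(a1), 100000)
})

test_that("components equal a BFS oracle (igraph) on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    set.seed(seed)
    nA <- 30L; nB <- 30L
    ra <- data.frame(genome_id = "A", chrom = "cA",
                     start = (seq_len(nA) - 1L) * 100L,
                     end = seq_len(nA) * 100L,
                     region_index = seq_len(nA) - 1L)
    rb <- data.frame(genome_id = "B", chrom = "cB",
                     start = (seq_len(nB) - 1L) * 100L,
                     end = seq_len(nB) * 100L, region_index = nA +
                       seq_len(nB) - 1L)
    ne <- 25L
    edges <- data.frame(region_a = sample(ra$region_index, ne, TRUE),
                        region_b = sample(rb$region_index, ne, TRUE),
                        aligned = 1)
    g <- structure(list(regions_a = ra, regions_b = rb, edges = edges),
                   class = "homology_graph")
    comp <- graph_components(g)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = paste0("A", edges$region_a),
                 to = paste0("B", edges$region_b)),
      directed = FALSE,
      vertices = c(paste0("A", ra$region_index),
                   paste0("B", rb$region_index)))
    ic <- igraph::components(ig)$membership
    # same partition: components agree up to relabeling
    expect_equal(length(unique(comp)), length(unique(ic)))
    expect_true(all(tapply(ic[names(comp)], comp,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("partitioning matches a brute-force minimum-deviation search", {
  # three components of sizes {50, 30, 20}, targets 12%/12%
  ra <- data.frame(genome_id = "A", chrom = paste0("c", 1:3),
                   start = 0L, end = c(50L, 30L, 20L),
                   region_index = 0:2)
  rb <- data.frame(genome_id = character(), chrom = character(),
                   start = integer(), end = integer(),
                   region_index = integer(), stringsAsFactors = FALSE)
  g <- structure(list(regions_a = ra, regions_b = rb,
                      edges = data.frame(region_a = integer(),
                                         region_b = integer(),
                                         aligned = numeric())),
                 class = "homology_graph")
  cfg <- split_config(tile_size = 100L, min_aligned = 50L, seed = 9)
  asn <- partition_components(g, cfg)
  # brute force over 3^3 labelings: minimal L1 deviation from targets
  sizes <- c(50, 30, 20)
  labs <- c("train", "valid", "test")
  targets <- c(train = 0.76, valid = 0.12, test = 0.12)
  best_dev <- Inf
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    fr <- tapply(sizes, factor(labs[c(i, j, k)], levels = labs), sum)
    fr[is.na(fr)] <- 0
    best_dev <- min(best_dev, sum(abs(fr / 100 - targets)))
  }
  got <- tapply(asn$nt, factor(asn$split, levels = labs), sum)
  got[is.na(got)] <- 0
  expect_equal(sum(abs(got / 100 - targets)), best_dev)
})

test_that("all-in-one component raises the monolithic error", {
  ra <- tile_genome(c(cA = 3000000L), 1000000L, "A")
  rb <- tile_genome(c(cB = 4000000L), 1000000L, "B")
  rb$region_index <- rb$region_index + 3L
  # blocks offset by half a tile chain every region into one component
  aln <- do.call(rbind, lapply(0:2, function(i)
    data.frame(chromA = "cA", startA = i * 1000000L,
               endA = (i + 1) * 1000000L, chromB = "cB",
               startB = i * 1000000L + 500000L,
               endB = (i + 1) * 1000000L + 500000L,
               strand = "+", aligned_len = 1000000L)))
  g <- build_homology_graph(ra, rb, aln, 100000L)
  expect_error(partition_components(g, split_config()), "monolithic")
})

test_that("empty alignment partitions each genome independently near 12/12", {
  ra <- tile_genome(c(cA = 16000000L), 1000000L, "A")
  rb <- tile_genome(c(cB = 16000000L), 1000000L, "B")
  rb$region_index <- rb$region_index + nrow(ra)
  g <- build_homology_graph(ra, rb,
                            data.frame(chromA = character(),
                                       startA = integer(),
                                       endA = integer(),
                                       chromB = character(),
                                       startB = integer(),
                                       endB = integer(),
                                       strand = character(),
                                       aligned_len = integer()), 100000L)
  asn <- partition_components(g, split_config(seed = 2))
  fr <- attr(asn, "fractions")
  # within one tile (1/16 = 6.25 pp) of the 12% target for both genomes
  expect_true(all(abs(fr[, c("valid", "test")] - 0.12) <= 1 / 16))
})

test_that("no edge crosses split labels; assignment deterministic", {
  pair <- small_pair()
  sz <- function(g) setNames(nchar(pair$genomes[[g]]),
                             names(pair$genomes[[g]]))
  cfg <- split_config(tile_size = 2^15, min_aligned = 2^14, seed = 31)
  a1 <- split_genomes(sz("A"), sz("B"), pair$alignment, cfg)
  a2 <- split_genomes(sz("A"), sz("B"), pair$alignment, cfg)
  expect_identical(a1, a2)
  g <- attr(a1, "graph")
  sa <- setNames(a1$split[a1$genome_id == "A"],
                 a1$region_index[a1$genome_id == "A"])
  sb <- setNames(a1$split[a1$genome_id == "B"],
                 a1$region_index[a1$genome_id == "B"])
  if (nrow(g$edges) > 0) {
    expect_true(all(sa[as.character(g$edges$region_a)] ==
                      sb[as.character(g$edges$region_b)]))
  }
})

test_that("leakage audit: component splits clean, random splits leak", {
  pair <- small_pair()
  sz <- function(g) setNames(nchar(pair$genomes[[g]]),
                             names(pair$genomes[[g]]))
  cfg <- split_config(tile_size = 2^15, min_aligned = 2^14, seed = 8)
  asn <- split_genomes(sz("A"), sz("B"), pair$alignment, cfg)
  aud <- audit_leakage(asn, pair$alignment, min_aligned = cfg$min_aligned)
  off_diag <- aud$cross_bp_supra
  diag(off_diag) <- 0
  expect_equal(sum(off_diag), 0)
  # no alignment: all metrics zero
  aud0 <- audit_leakage(asn, pair$alignment[0, ])
  expect_equal(sum(aud0$cross_bp), 0)
  expect_equal(unname(aud0$holdout_train_ortholog_frac), c(0, 0))
  # a random non-component split on a shared_fraction=0.5 pair must leak
  set.seed(1)
  rnd <- asn
  rnd$split <- sample(c("train", "valid", "test"), nrow(rnd), TRUE)
  audr <- audit_leakage(rnd, pair$alignment)
  off <- audr$cross_bp
  diag(off) <- 0
  expect_gt(sum(off), 0)
})

test_that("chain-subset reader converts ungapped chains to net blocks", {
  chain <- c("chain 100 cA 1000 + 100 400 cB 1000 + 50 350 1",
             "100\t20\t10", "80", "")
  path <- tempfile()
  writeLines(chain, path)
  blocks <- read_chain_subset(path)
  expect_equal(nrow(blocks), 2L)
  expect_equal(blocks$startA, c(100L, 220L))
  expect_equal(blocks$startB, c(50L, 160L))
  expect_equal(blocks$aligned_len, c(100L, 80L))
})
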