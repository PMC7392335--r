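# The synthetic two-species benchmark generator.

test_that("grammar_spec validates its invariants", {
  g <- small_grammar()
  expect_s3_class(g, "grammar_spec")
  expect_true(all(vapply(g$motif_set, ncol, 1L) %in% 6:12))
  expect_true(all(is.finite(g$tissue_profiles)))
  expect_error(grammar_spec(distal_decay = 0), "distal_decay")
  expect_error(grammar_spec(substitution_rate = 0.5), "substitution_rate")
})

test_that("degenerate homology cases behave as stated", {
  g0 <- grammar_spec(seed = 3, substitution_rate = 0)
  dir1 <- tempfile(); dir2 <- tempfile()
  # full homology, no substitutions: identical genomes, alignment covers all
  p1 <- generate_species_pair(g0, n_chrom = 1, chrom_len = 2^16,
                              shared_fraction = 1, out_dir = dir1,
                              block_len = 2^14, seq_len = 4096)
  expect_equal(unname(p1$genomes$A), unname(p1$genomes$B))
  expect_equal(sum(p1$alignment$aligned_len), 2^16)
  # zero sharing: no alignment blocks
  p0 <- generate_species_pair(grammar_spec(seed = 3), n_chrom = 1,
                              chrom_len = 2^16, shared_fraction = 0,
                              out_dir = dir2, block_len = 2^14,
                              seq_len = 4096)
  expect_equal(nrow(p0$alignment), 0L)
  expect_equal(nrow(read_net_tsv(p0$paths$alignment)), 0L)
  # sizing error
  expect_error(generate_species_pair(g0, n_chrom = 1, chrom_len = 1000,
                                     shared_fraction = 1, seq_len = 4096),
               "4x")
})

test_that("same seed gives byte-identical outputs; coverage ~ shared_fraction", {
  g <- grammar_spec(seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- generate_species_pair(g, n_chrom = 1, chrom_len = 2^16,
                              shared_fraction = 0.5, out_dir = d1,
                              block_len = 2^14, seq_len = 4096)
  p2 <- generate_species_pair(g, n_chrom = 1, chrom_len = 2^16,
                              shared_fraction = 0.5, out_dir = d2,
                              block_len = 2^14, seq_len = 4096)
  for (f in c("genome_a", "genome_b", "alignment", "tss_a", "tss_b")) {
    expect_identical(readLines(p1$paths[[f]]), readLines(p2$paths[[f]]),
                     info = f)
  }
  # alignment covers shared_fraction of the genome within one block
  expect_lte(abs(sum(p1$alignment$aligned_len) - 0.5 * 2^16), 2^14)
  # every homologous block appears exactly once
  key <- paste(p1$alignment$chromA, p1$alignment$startA)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("tracks: zero activity -> background; homologs match at rate 0", {
  g0 <- grammar_spec(seed = 5, substitution_rate = 0,
                     tissue_profiles = matrix(0, 2, 6,
                       dimnames = list(c("t1", "t2"), paste0("m", 1:6))))
  p <- generate_species_pair(g0, n_chrom = 1, chrom_len = 2^16,
                             shared_fraction = 1, block_len = 2^14,
                             seq_len = 4096)
  p <- simulate_signal_tracks(p)
  # zero motif activity everywhere: tracks equal the background constant
  expect_equal(unique(p$truth_tracks$A$CAGE_t1$chrA1), g0$background)
  expect_equal(unique(p$truth_tracks$A$ACC_t2$chrA1), g0$background)
  # shared grammar + no substitutions: homologous truth identical
  g1 <- grammar_spec(seed = 5, substitution_rate = 0)
  p1 <- generate_species_pair(g1, n_chrom = 1, chrom_len = 2^16,
                              shared_fraction = 1, block_len = 2^14,
                              seq_len = 4096)
  p1 <- simulate_signal_tracks(p1)
  expect_equal(unname(p1$truth_tracks$A$CAGE_brain$chrA1),
               unname(p1$truth_tracks$B$CAGE_brain$chrB1))
  expect_error(simulate_signal_tracks(p1, tissues = "kidney"), "unknown")
})

test_that("planting a strong distal motif raises the TSS CAGE value", {
  # generative-formula oracle, evaluated directly on a constructed locus
  g <- small_grammar()
  pwm <- g$motif_set[[1]]
  cons <- paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)],
                collapse = "")
  base <- strrep("A", 40000)
  tss_pos <- 30000L
  el_far <- data.frame(chrom = "c", pos = 15000L, motif_id = 1L)  # 15 kb up
  seq_planted <- paste0(substr(base, 1, 15000), cons,
                        substr(base, 15001 + nchar(cons), 40000))
  act0 <- crossreg:::gen_tss_activity(base, el_far, tss_pos, g, "brain")
  act1 <- crossreg:::gen_tss_activity(seq_planted, el_far, tss_pos, g,
                                      "brain")
  # oracle: weight * rel(=1 for consensus) * exp(-d / decay)
  d <- abs(15000 + nchar(cons) %/% 2 - tss_pos)
  expected <- g$tissue_profiles["brain", 1] * exp(-d / g$distal_decay)
  expect_equal(act1, expected, tolerance = 1e-8)
  expect_gt(act1, act0)
  expect_gt(crossreg:::cage_peak_mass(act1), 0)
})

test_that("variant truth: classes, determinism, sign against regeneration", {
  pair <- small_pair()
  v1 <- simulate_variant_truth(pair, n_variants = 30, seed = 4)
  v2 <- simulate_variant_truth(pair, n_variants = 30, seed = 4,
                               write_path = tempfile(fileext = ".vcf"))
  expect_identical(v1[, c("chrom", "pos", "ref", "alt", "class")],
                   v2[, c("chrom", "pos", "ref", "alt", "class")])
  expect_setequal(unique(v1$class),
                  c("disrupting", "creating", "background"))
  # background variants are inert under the generative model
  bg <- v1$class == "background"
  expect_true(all(abs(v1$effect[bg, ]) < 1e-12))
  # ref matches the genome
  for (i in seq_len(nrow(v1))) {
    expect_equal(substr(pair$genomes$A[[v1$chrom[i]]], v1$pos[i],
                        v1$pos[i]), v1$ref[i])
  }
  # internal consistency: signs agree with re-running the generative model
  # on the mutated sequence (independent recomputation per variant)
  g <- pair$grammar
  el <- pair$elements$A; tss <- pair$tss$A
  idx <- which(!bg)
  for (i in idx) {
    chrom <- v1$chrom[i]
    seq_alt <- crossreg:::splice_seq(pair$genomes$A[[chrom]],
                                     v1$pos[i] - 1L, v1$alt[i])
    for (t in seq_along(g$tissues)) {
      eff <- v1$effect[i, t]
      if (abs(eff) < 1e-9) next
      elc <- el[el$chrom == chrom, ]
      tssc <- tss$pos[tss$chrom == chrom]
      alt_sig <- sum(crossreg:::gen_local_signal(seq_alt, elc, tssc, g,
                                                 g$tissues[t]))
      ref_sig <- sum(crossreg:::gen_local_signal(pair$genomes$A[[chrom]],
                                                 elc, tssc, g,
                                                 g$tissues[t]))
      expect_equal(sign(eff), sign(alt_sig - ref_sig), info = i)
    }
  }
  # VCF round trip carries the effects
  tab <- read_vcf_table(attr(v2, "vcf"))
  expect_equal(nrow(tab), nrow(v1))
  eff <- crossreg:::vcf_info_field(tab$info, "GEN_EFFECT")
  expect_false(anyNA(eff))
})
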