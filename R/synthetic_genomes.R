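## Synthetic two-species benchmark with a shared regulatory grammar.
##
## Two genomes share homologous blocks (copied sequence plus point
## substitutions) and a common motif lexicon. Tissue-specific CAGE-like
## tracks are sharply peaked at planted TSSs with magnitude driven by
## proximal and distal (<= 20 kb) motif contributions through a softplus
## link; accessibility-like tracks are broad plateaus over motif clusters.
## Variants are planted with known generative effect sizes, providing the
## ground truth that variant-effect scoring is audited against.

DISTAL_MAX <- 20000L
ACC_SCALE <- 0.05      # accessibility plateau height per unit motif weight
ACC_HALF_WIDTH <- 250L # plateau half-width in bp

#' Regulatory grammar specification for the synthetic benchmark
#'
#' @param n_motifs number of position-weight matrices in the lexicon.
#' @param motif_lens integer vector of candidate motif lengths (6-12 bp).
#' @param tissues character vector of tissue names.
#' @param distal_decay exponential length-scale (bp) of distal enhancer
#'   contributions.
#' @param substitution_rate per-bp substitution probability applied to
#'   homologous blocks of the second genome (in `[0, 0.5)`).
#' @param seed integer seed controlling the lexicon and all downstream
#'   generation.
#' @param motif_density expected planted motif instances per bp.
#' @param tss_spacing mean spacing (bp) between planted TSSs.
#' @param proximal_window distance (bp) within which a motif counts as
#'   proximal to a TSS.
#' @param background per-bp background signal level of all tracks.
#' @param cage_scale multiplier on CAGE peak mass (dynamic-range knob;
#'   CAGE spans orders of magnitude in real data).
#' @param consensus_prob probability mass on the consensus base in each
#'   PWM column.
#' @param promoter_len length (bp) of the core promoter element planted at
#'   every TSS. The promoter marks where a TSS sits (as core promoter
#'   elements do in real genomes) but carries no activity weight itself;
#'   CAGE magnitude comes from the surrounding tissue motifs.
#' @param tissue_profiles optional tissues x motifs matrix of signed
#'   activity weights; generated (block-diagonal-ish, tissue-specific) when
#'   `NULL`.
#' @return a `grammar_spec` object.
#' @export
grammar_spec <- function(n_motifs = 6, motif_lens = 6:12,
                         tissues = c("brain", "liver", "heart", "tcell"),
                         distal_decay = 5000, substitution_rate = 0.02,
                         seed = 1L, motif_density = 1 / 500,
                         tss_spacing = 6000, proximal_window = 1000,
                         background = 0.02, consensus_prob = 0.92,
                         cage_scale = 4, promoter_len = 8L,
                         tissue_profiles = NULL) {
  if (distal_decay <= 0) stop2("distal_decay must be > 0")
  if (substitution_rate < 0 || substitution_rate >= 0.5)
    stop2("substitution_rate must lie in [0, 0.5)")
  motifs <- with_seed(derive_seed(seed, "motifs"), {
    lapply(seq_len(n_motifs), function(i) {
      len <- sample(motif_lens, 1)
      cons <- sample(4, len, replace = TRUE)
      pwm <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = len,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pwm[cbind(cons, seq_len(len))] <- consensus_prob
      pwm
    })
  })
  if (is.null(tissue_profiles)) {
    tissue_profiles <- with_seed(derive_seed(seed, "profiles"), {
      tp <- matrix(rnorm(length(tissues) * n_motifs, 0, 0.3),
                   nrow = length(tissues),
                   dimnames = list(tissues, paste0("m", seq_len(n_motifs))))
      # each tissue owns a strong activating motif; remaining weights are
      # weak, giving well-separated tissue signatures
      for (t in seq_along(tissues)) {
        tp[t, (t - 1) %% n_motifs + 1] <- 4
      }
      tp
    })
  }
  if (any(!is.finite(tissue_profiles))) stop2("tissue weights must be finite")
  promoter <- with_seed(derive_seed(seed, "promoter"), {
    cons <- sample(4, promoter_len, replace = TRUE)
    pwm <- matrix(0.02, nrow = 4, ncol = promoter_len,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm[cbind(cons, seq_len(promoter_len))] <- 0.94
    pwm
  })
  structure(list(motif_set = motifs, promoter = promoter,
                 tissue_profiles = tissue_profiles,
                 tissues = rownames(tissue_profiles),
                 distal_decay = distal_decay,
                 substitution_rate = substitution_rate, seed = seed,
                 motif_density = motif_density, tss_spacing = tss_spacing,
                 proximal_window = proximal_window, background = background,
                 cage_scale = cage_scale),
            class = "grammar_spec")
}

# sample the bases of one motif instance from its PWM
sample_motif_bases <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(ncol(pwm)),
               function(j) sample(bases, 1, prob = pwm[, j]), ""),
        collapse = "")
}

# replace a substring of a chromosome (string form); pos0 is 0-based
splice_seq <- function(seq, pos0, replacement) {
  paste0(substr(seq, 1, pos0),
         replacement,
         substr(seq, pos0 + nchar(replacement) + 1, nchar(seq)))
}

# genome construction works on per-base character vectors (cheap in-place
# edits); chromosomes are collapsed to strings once finished
random_dna_vec <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# plant motif instances and TSSs in one segment of a base vector; positions
# are absolute 0-based.
#
# Placement is TSS-centric, emulating enhancer/promoter architecture: each
# TSS draws a random subset of motif types and receives several instances
# of each, mostly proximal with occasional distal (<= 15 kb) copies, so
# different TSSs have genuinely different motif compositions (hence
# tissue-specific activity). A sparse uniform background of instances is
# added on top. Uniform planting at fixed density makes every tissue's
# track nearly proportional to every other's, which defeats
# tissue-specificity analyses by construction.
plant_segment <- function(seq_vec, seg_start, seg_len, grammar) {
  n_motifs <- length(grammar$motif_set)
  max_len <- max(vapply(grammar$motif_set, ncol, 1L))
  n_tss <- max(1L, round(seg_len / grammar$tss_spacing))
  margin <- 60L
  tss_pos <- seg_start + sort(sample(seq(margin, seg_len - margin), n_tss))

  pos <- integer(0)
  motif_ids <- integer(0)
  add_inst <- function(p, id) {
    # clamp inside the segment, clear of the edges
    p <- min(max(p, seg_start + 1L), seg_start + seg_len - max_len - 1L)
    pos <<- c(pos, as.integer(p))
    motif_ids <<- c(motif_ids, id)
  }
  for (tp in tss_pos) {
    # each TSS is owned by one tissue: a tissue-pure proximal cluster of
    # its owning motif (as tissue-specific promoters carry their own
    # factors' sites), plus an occasional distal copy
    owner <- sample(n_motifs, 1)
    n_prox <- 2L + rpois(1, 1)
    for (j in seq_len(n_prox)) add_inst(tp + sample(-400:400, 1), owner)
    if (runif(1) < 0.5) {
      add_inst(tp + sample(c(-1, 1), 1) * sample(1000:15000, 1), owner)
    }
  }
  n_bg <- rpois(1, grammar$motif_density * seg_len * 0.1)
  if (n_bg > 0) {
    for (j in seq_len(n_bg)) {
      add_inst(seg_start + sample(seg_len - max_len - 1L, 1),
               sample(n_motifs, 1))
    }
  }
  ord <- order(pos)
  pos <- pos[ord]; motif_ids <- motif_ids[ord]
  for (i in seq_along(pos)) {
    bases <- strsplit(sample_motif_bases(
      grammar$motif_set[[motif_ids[i]]]), "")[[1]]
    seq_vec[(pos[i] + 1L):(pos[i] + length(bases))] <- bases
  }
  elements <- if (length(pos))
    data.frame(pos = pos, motif_id = motif_ids) else NULL

  # the core promoter element is planted last so every TSS keeps its
  # sequence signature (emulating real core promoters)
  plen <- ncol(grammar$promoter)
  for (tp in tss_pos) {
    bases <- strsplit(sample_motif_bases(grammar$promoter), "")[[1]]
    start <- tp - plen %/% 2L
    seq_vec[(start + 1L):(start + plen)] <- bases
  }
  list(seq = seq_vec, elements = elements, tss = data.frame(pos = tss_pos))
}

apply_substitutions_vec <- function(seq_vec, rate) {
  if (rate <= 0) return(seq_vec)
  n <- length(seq_vec)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq_vec)
  pos <- sample(n, k)
  alts <- vapply(seq_vec[pos],
                 function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  seq_vec[pos] <- alts
  seq_vec
}

#' Generate a homologous two-species genome pair
#'
#' Each chromosome is divided into segments of `block_len` bp; a fraction
#' `shared_fraction` of segments (chosen at random under the grammar seed)
#' are homologous: genome B receives genome A's segment sequence with
#' point substitutions at the grammar's rate, and both genomes carry the
#' same planted motif instances and TSSs there. Non-shared segments have
#' independent backgrounds, motifs, and TSSs. The emitted alignment covers
#' exactly the shared segments.
#'
#' @param grammar a [grammar_spec()].
#' @param n_chrom chromosomes per genome.
#' @param chrom_len chromosome length (bp); must be at least
#'   `4 * seq_len`.
#' @param shared_fraction fraction of each chromosome that is homologous,
#'   in `[0, 1]`.
#' @param out_dir directory where FASTA/BED/TSV files are written.
#' @param block_len homologous block size in bp.
#' @param seq_len model sequence length the benchmark must accommodate
#'   (sizing check only).
#' @return a `synthetic_pair` object with file paths, in-memory genomes,
#'   element and TSS tables, and the alignment block table.
#' @export
generate_species_pair <- function(grammar, n_chrom = 2,
                                  chrom_len = 2^18,
                                  shared_fraction = 0.5,
                                  out_dir = tempfile("synthpair"),
                                  block_len = 2^16,
                                  seq_len = 16384) {
  if (chrom_len < 4 * seq_len)
    stop2("chrom_len (", chrom_len, ") must be at least 4x the model ",
          "sequence length (", seq_len, ")")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop2("shared_fraction must lie in [0, 1]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genomes <- list(A = character(), B = character())
  elements <- list(A = NULL, B = NULL)
  tss <- list(A = NULL, B = NULL)
  aln <- NULL

  for (ci in seq_len(n_chrom)) {
    chromA <- paste0("chrA", ci)
    chromB <- paste0("chrB", ci)
    n_seg <- chrom_len %/% block_len
    n_shared <- round(shared_fraction * n_seg)
    res <- with_seed(derive_seed(grammar$seed, "pair", ci), {
      shared <- sort(sample(n_seg, n_shared))
      seqA <- random_dna_vec(chrom_len)
      seqB <- random_dna_vec(chrom_len)
      elA <- list(); elB <- list(); tssA <- list(); tssB <- list()
      aln_rows <- list()
      for (si in seq_len(n_seg)) {
        s0 <- (si - 1L) * block_len
        idx <- (s0 + 1L):(s0 + block_len)
        if (si %in% shared) {
          pl <- plant_segment(seqA, s0, block_len, grammar)
          seqA <- pl$seq
          seqB[idx] <- apply_substitutions_vec(seqA[idx],
                                               grammar$substitution_rate)
          elA[[si]] <- pl$elements; elB[[si]] <- pl$elements
          tssA[[si]] <- pl$tss; tssB[[si]] <- pl$tss
          aln_rows[[si]] <- data.frame(
            chromA = chromA, startA = s0, endA = s0 + block_len,
            chromB = chromB, startB = s0, endB = s0 + block_len,
            strand = "+", aligned_len = block_len,
            stringsAsFactors = FALSE)
        } else {
          plA <- plant_segment(seqA, s0, block_len, grammar)
          seqA <- plA$seq
          plB <- plant_segment(seqB, s0, block_len, grammar)
          seqB <- plB$seq
          elA[[si]] <- plA$elements; elB[[si]] <- plB$elements
          tssA[[si]] <- plA$tss; tssB[[si]] <- plB$tss
        }
      }
      list(seqA = paste(seqA, collapse = ""),
           seqB = paste(seqB, collapse = ""),
           elA = do.call(rbind, elA[!vapply(elA, is.null, TRUE)]),
           elB = do.call(rbind, elB[!vapply(elB, is.null, TRUE)]),
           tssA = do.call(rbind, tssA), tssB = do.call(rbind, tssB),
           aln = if (length(aln_rows)) do.call(rbind, aln_rows) else NULL)
    })
    genomes$A[chromA] <- res$seqA
    genomes$B[chromB] <- res$seqB
    add_chrom <- function(df, chrom) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      cbind(data.frame(chrom = chrom, stringsAsFactors = FALSE), df)
    }
    elements$A <- rbind(elements$A, add_chrom(res$elA, chromA))
    elements$B <- rbind(elements$B, add_chrom(res$elB, chromB))
    tss$A <- rbind(tss$A, add_chrom(res$tssA, chromA))
    tss$B <- rbind(tss$B, add_chrom(res$tssB, chromB))
    aln <- rbind(aln, res$aln)
  }
  if (is.null(aln)) {
    aln <- data.frame(chromA = character(), startA = integer(),
                      endA = integer(), chromB = character(),
                      startB = integer(), endB = integer(),
                      strand = character(), aligned_len = integer(),
                      stringsAsFactors = FALSE)
  }

  paths <- list(genome_a = file.path(out_dir, "genomeA.fa"),
                genome_b = file.path(out_dir, "genomeB.fa"),
                alignment = file.path(out_dir, "alignment.net.tsv"),
                tss_a = file.path(out_dir, "tssA.bed"),
                tss_b = file.path(out_dir, "tssB.bed"))
  write_genome_fasta(genomes$A, paths$genome_a)
  write_genome_fasta(genomes$B, paths$genome_b)
  write_net_tsv(aln, paths$alignment)
  for (g in c("A", "B")) {
    df <- tss[[g]]
    write_bed(data.frame(chrom = df$chrom, start = df$pos,
                         end = df$pos + 1L,
                         name = paste0("tss", g, seq_len(nrow(df)))),
              paths[[paste0("tss_", tolower(g))]])
  }

  structure(list(paths = paths, genomes = genomes, elements = elements,
                 tss = tss, alignment = aln, grammar = grammar,
                 block_len = block_len, chrom_len = chrom_len,
                 n_chrom = n_chrom, out_dir = out_dir,
                 truth_tracks = NULL),
            class = "synthetic_pair")
}

# relative match score of one planted instance against the actual sequence:
# log-odds vs uniform background, clipped at zero and scaled to [0, 1]
instance_rel_score <- function(chrom_seq, pos0, pwm) {
  len <- ncol(pwm)
  bases <- str_bases(substr(chrom_seq, pos0 + 1L, pos0 + len))
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(0)
  lo <- sum(log(pwm[cbind(idx, seq_len(len))] / 0.25))
  max_lo <- sum(log(apply(pwm, 2, max) / 0.25))
  max(0, lo) / max_lo
}

# generative TSS activity (pre-link) for one tissue on one chromosome
gen_tss_activity <- function(chrom_seq, el, tss_pos, grammar, tissue) {
  w <- grammar$tissue_profiles[tissue, ]
  act <- numeric(length(tss_pos))
  if (is.null(el) || nrow(el) == 0) return(act)
  rel <- vapply(seq_len(nrow(el)), function(i) {
    instance_rel_score(chrom_seq, el$pos[i],
                       grammar$motif_set[[el$motif_id[i]]])
  }, 0)
  centers <- el$pos +
    vapply(grammar$motif_set[el$motif_id], ncol, 1L) %/% 2L
  for (k in seq_along(tss_pos)) {
    d <- abs(centers - tss_pos[k])
    keep <- d <= DISTAL_MAX
    if (!any(keep)) next
    kern <- ifelse(d[keep] <= grammar$proximal_window, 1,
                   exp(-d[keep] / grammar$distal_decay))
    act[k] <- sum(w[el$motif_id[keep]] * rel[keep] * kern)
  }
  act
}

# CAGE peak mass through the softplus link, shifted so that zero activity
# yields zero planted mass (tracks then equal the background constant);
# cage_scale widens the dynamic range
cage_peak_mass <- function(activity, scale = 1) {
  scale * pmax(0, softplus(activity) - log(2))
}

#' Simulate tissue-specific truth signal tracks
#'
#' CAGE-like tracks: background constant plus a sharp 5-bp peak at each
#' planted TSS whose total mass is the shifted-softplus of the proximal
#' motif score plus exponentially decaying distal (<= 20 kb) motif scores.
#' Accessibility-like tracks: background plus broad plateaus (+-250 bp)
#' over motif instances with positive tissue weight. Matched tissues share
#' weights across species, so homologous loci carry matching truth signal
#' up to sequence divergence.
#'
#' @param pair a `synthetic_pair`.
#' @param grammar the [grammar_spec()] used to build the pair.
#' @param tissues tissue names (must exist in the grammar profiles).
#' @param write logical; also write wiggle files under the pair directory.
#' @return the pair with `$truth_tracks[[genome]][[dataset]]` filled in;
#'   dataset names are `CAGE_<tissue>` and `ACC_<tissue>`.
#' @export
simulate_signal_tracks <- function(pair, grammar = pair$grammar,
                                   tissues = grammar$tissues,
                                   write = FALSE) {
  unknown <- setdiff(tissues, rownames(grammar$tissue_profiles))
  if (length(unknown))
    stop2("unknown tissue name(s): ", paste(unknown, collapse = ", "))
  # triangular 48-bp peak (total mass 1) centered on the TSS
  peak_offs <- -23:24
  peak_kernel <- 24.5 - abs(peak_offs - 0.5)
  peak_kernel <- peak_kernel / sum(peak_kernel)
  acc_half_width <- ACC_HALF_WIDTH
  acc_scale <- ACC_SCALE
  tracks <- list(A = list(), B = list())
  for (g in c("A", "B")) {
    genome <- pair$genomes[[g]]
    for (tissue in tissues) {
      cage <- list(); acc <- list()
      for (chrom in names(genome)) {
        n <- nchar(genome[[chrom]])
        cage_v <- rep(grammar$background, n)
        acc_v <- rep(grammar$background, n)
        el <- pair$elements[[g]]
        el <- if (is.null(el)) NULL else el[el$chrom == chrom, ]
        tss_pos <- pair$tss[[g]]$pos[pair$tss[[g]]$chrom == chrom]
        act <- gen_tss_activity(genome[[chrom]], el, tss_pos, grammar,
                                tissue)
        mass <- cage_peak_mass(act, grammar$cage_scale %||% 1)
        for (k in seq_along(tss_pos)) {
          if (mass[k] <= 0) next
          idx <- tss_pos[k] + peak_offs + 1L  # 1-based index window
          ok <- idx >= 1 & idx <= n
          cage_v[idx[ok]] <- cage_v[idx[ok]] +
            mass[k] * peak_kernel[ok] / sum(peak_kernel[ok])
        }
        if (!is.null(el) && nrow(el) > 0) {
          w <- grammar$tissue_profiles[tissue, el$motif_id]
          rel <- vapply(seq_len(nrow(el)), function(i) {
            instance_rel_score(genome[[chrom]], el$pos[i],
                               grammar$motif_set[[el$motif_id[i]]])
          }, 0)
          h <- pmax(0, w) * rel * acc_scale
          for (i in seq_len(nrow(el))) {
            if (h[i] <= 0) next
            s <- max(1L, el$pos[i] - acc_half_width)
            e <- min(n, el$pos[i] + acc_half_width)
            acc_v[s:e] <- acc_v[s:e] + h[i]
          }
        }
        cage[[chrom]] <- cage_v
        acc[[chrom]] <- acc_v
      }
      tracks[[g]][[paste0("CAGE_", tissue)]] <- cage
      tracks[[g]][[paste0("ACC_", tissue)]] <- acc
    }
  }
  pair$truth_tracks <- tracks
  if (write) {
    for (g in c("A", "B")) {
      for (ds in names(tracks[[g]])) {
        write_wig(tracks[[g]][[ds]],
                  file.path(pair$out_dir, sprintf("track_%s_%s.wig", g, ds)))
      }
    }
  }
  pair
}

# total generative signal (CAGE + accessibility, all tissues or one) around
# a locus, recomputed from an arbitrary sequence; used for variant truth
gen_local_signal <- function(chrom_seq, el, tss_pos, grammar, tissue) {
  cage <- sum(cage_peak_mass(
    gen_tss_activity(chrom_seq, el, tss_pos, grammar, tissue),
    grammar$cage_scale %||% 1))
  acc <- 0
  if (!is.null(el) && nrow(el) > 0) {
    w <- grammar$tissue_profiles[tissue, el$motif_id]
    rel <- vapply(seq_len(nrow(el)), function(i) {
      instance_rel_score(chrom_seq, el$pos[i],
                         grammar$motif_set[[el$motif_id[i]]])
    }, 0)
    acc <- sum(pmax(0, w) * rel * ACC_SCALE * (2 * ACC_HALF_WIDTH + 1))
  }
  c(cage = cage, acc = acc)
}

#' Plant variants with known generative effect sizes
#'
#' Three strata: motif-disrupting (consensus base of a planted instance
#' changed to a low-probability base), motif-creating (a degraded planted
#' instance restored toward consensus), and background (far from all
#' planted elements). Each variant's per-tissue effect is the generative
#' track sum (CAGE peaks plus accessibility plateaus within 20 kb)
#' recomputed with the alternative allele minus the reference allele.
#'
#' @param pair a `synthetic_pair`.
#' @param n_variants total variants requested (split evenly over strata).
#' @param seed integer seed.
#' @param genome_id which genome to plant variants on (`"A"` or `"B"`).
#' @param write_path optional path for the VCF (defaults under the pair
#'   directory).
#' @return data.frame of variants (chrom, pos 1-based, id, ref, alt,
#'   class) with an `effect` matrix column (variants x tissues, CAGE+ACC
#'   sum) and the VCF path in `attr(, "vcf")`. INFO carries
#'   `GEN_EFFECT` (per-tissue, comma-separated) and `VCLASS`.
#' @export
simulate_variant_truth <- function(pair, n_variants = 60, seed = 1L,
                                   genome_id = "A", write_path = NULL) {
  grammar <- pair$grammar
  genome <- pair$genomes[[genome_id]]
  el_all <- pair$elements[[genome_id]]
  tss_all <- pair$tss[[genome_id]]
  tissues <- grammar$tissues
  bases4 <- c("A", "C", "G", "T")
  per_class <- ceiling(n_variants / 3)

  out <- with_seed(derive_seed(seed, "variants"), {
    rows <- list()
    add_row <- function(chrom, pos0, ref, alt, class) {
      rows[[length(rows) + 1]] <<- data.frame(
        chrom = chrom, pos = pos0 + 1L, ref = ref, alt = alt,
        class = class, stringsAsFactors = FALSE)
    }
    # motif-disrupting: hit a matching consensus position
    cand <- el_all[sample(nrow(el_all)), ]
    n_done <- 0
    for (i in seq_len(nrow(cand))) {
      if (n_done >= per_class) break
      pwm <- grammar$motif_set[[cand$motif_id[i]]]
      cons <- apply(pwm, 2, which.max)
      seq_b <- str_bases(substr(genome[[cand$chrom[i]]],
                                cand$pos[i] + 1L,
                                cand$pos[i] + ncol(pwm)))
      match_j <- which(seq_b == bases4[cons])
      if (length(match_j) == 0) next
      j <- match_j[sample(length(match_j), 1)]
      alt <- sample(setdiff(bases4, seq_b[j]), 1)
      add_row(cand$chrom[i], cand$pos[i] + j - 1L, seq_b[j], alt,
              "disrupting")
      n_done <- n_done + 1
    }
    # motif-creating: restore a mismatched position to consensus
    cand <- el_all[sample(nrow(el_all)), ]
    n_done <- 0
    for (i in seq_len(nrow(cand))) {
      if (n_done >= per_class) break
      pwm <- grammar$motif_set[[cand$motif_id[i]]]
      cons <- apply(pwm, 2, which.max)
      seq_b <- str_bases(substr(genome[[cand$chrom[i]]],
                                cand$pos[i] + 1L,
                                cand$pos[i] + ncol(pwm)))
      mism_j <- which(seq_b != bases4[cons])
      if (length(mism_j) == 0) next
      j <- mism_j[sample(length(mism_j), 1)]
      add_row(cand$chrom[i], cand$pos[i] + j - 1L, seq_b[j],
              bases4[cons[j]], "creating")
      n_done <- n_done + 1
    }
    # background: outside every planted element footprint (sequence only
    # enters the generative model through motif-instance match scores, so
    # clearance beyond the longest motif suffices for a zero effect)
    n_done <- 0
    tries <- 0
    clear <- max(vapply(grammar$motif_set, ncol, 1L)) + 5L
    while (n_done < n_variants - 2 * per_class && tries < 50 * n_variants) {
      tries <- tries + 1
      chrom <- sample(names(genome), 1)
      pos0 <- sample(nchar(genome[[chrom]]) - 2L, 1)
      near_el <- el_all$pos[el_all$chrom == chrom]
      if (length(near_el) && min(abs(near_el - pos0)) <= clear) next
      ref <- substr(genome[[chrom]], pos0 + 1L, pos0 + 1L)
      add_row(chrom, pos0, ref, sample(setdiff(bases4, ref), 1),
              "background")
      n_done <- n_done + 1
    }
    do.call(rbind, rows)
  })
  if (nrow(out) < n_variants)
    warning("requested ", n_variants, " variants, emitted ", nrow(out),
            " (motif instances exhausted)")
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out$id <- paste0("var", seq_len(nrow(out)))

  # generative effect: local signal with alt minus with ref, per tissue
  eff <- matrix(0, nrow(out), length(tissues),
                dimnames = list(out$id, tissues))
  for (i in seq_len(nrow(out))) {
    chrom <- out$chrom[i]; pos0 <- out$pos[i] - 1L
    lo <- pos0 - DISTAL_MAX - 100L; hi <- pos0 + DISTAL_MAX + 100L
    el <- el_all[el_all$chrom == chrom & el_all$pos >= lo &
                   el_all$pos <= hi, ]
    tss_pos <- tss_all$pos[tss_all$chrom == chrom &
                             tss_all$pos >= lo & tss_all$pos <= hi]
    seq_ref <- genome[[chrom]]
    seq_alt <- splice_seq(seq_ref, pos0, out$alt[i])
    for (t in seq_along(tissues)) {
      eff[i, t] <- sum(gen_local_signal(seq_alt, el, tss_pos, grammar,
                                        tissues[t])) -
        sum(gen_local_signal(seq_ref, el, tss_pos, grammar, tissues[t]))
    }
  }
  out$effect <- eff

  vcf_path <- write_path %||% file.path(pair$out_dir,
                                        paste0("variants_", genome_id,
                                               ".vcf"))
  info <- sprintf("GEN_EFFECT=%s;VCLASS=%s",
                  apply(eff, 1, function(r)
                    paste(formatC(r, format = "g", digits = 8),
                          collapse = ",")),
                  out$class)
  write_vcf(data.frame(chrom = out$chrom, pos = out$pos, id = out$id,
                       ref = out$ref, alt = out$alt, info = info,
                       stringsAsFactors = FALSE),
            vcf_path,
            info_header = c(
              paste0("##INFO=<ID=GEN_EFFECT,Number=.,Type=Float,",
                     "Description=\"Generative effect per tissue (",
                     paste(tissues, collapse = ","), ")\">"),
              paste0("##INFO=<ID=VCLASS,Number=1,Type=String,",
                     "Description=\"Variant stratum\">")))
  attr(out, "vcf") <- vcf_path
  out
}
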