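## Plain-text genomics IO.
## Coordinates are 0-based half-open everywhere inside the package; VCF
## positions are converted on ingest/export. FASTA goes through Biostrings.

#' Write a genome to FASTA
#' @param seqs named character vector or `DNAStringSet`, one entry per
#'   chromosome.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read/write BED intervals (0-based half-open)
#'
#' Only the first four columns (chrom, start, end, name) are used; `name`
#' is optional.
#' @param path BED file.
#' @param bed data.frame with columns chrom, start, end and optionally name.
#' @return data.frame (read) or `path` invisibly (write).
#' @export
read_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, fill = TRUE)
  if (nrow(df) == 0) return(empty)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(bed))
  write.table(bed[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes table
#' @param path two-column TSV (chrom, length).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Read/write alignment blocks in the simplified net dialect
#'
#' A whole-genome alignment distilled to a TSV with one block per line:
#' `chromA startA endA chromB startB endB strand alignedLen`, 0-based
#' half-open on both genomes. `alignedLen` is the number of aligned
#' (non-gap) base pairs within the block.
#'
#' @param path TSV file.
#' @param blocks data.frame with the eight columns above.
#' @return data.frame of blocks (read) or `path` invisibly (write).
#' @export
read_net_tsv <- function(path) {
  cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB",
            "strand", "aligned_len")
  first <- readLines(path, n = 1)
  header <- length(first) == 1 && startsWith(first, "chromA")
  df <- read.table(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), 8), cols))
  }
  names(df) <- cols
  for (f in c("startA", "endA", "startB", "endB", "aligned_len"))
    df[[f]] <- as.integer(df[[f]])
  df
}

#' @rdname read_net_tsv
#' @export
write_net_tsv <- function(blocks, path) {
  write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a UCSC chain file into simplified net blocks
#'
#' Supports the ungapped subset needed for real-file ingestion: each chain's
#' alignment lines are converted to blocks with `aligned_len` equal to the
#' ungapped segment sizes. Only `+` target strand chains are expected.
#'
#' @param path chain-format file.
#' @return data.frame in the simplified net layout (see [read_net_tsv()]).
#' @export
read_chain_subset <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "chain")) {
      f <- strsplit(ln, "\\s+")[[1]]
      tName <- f[3]; tStart <- as.integer(f[6])
      qName <- f[8]; qStrand <- f[10]; qStart <- as.integer(f[11])
      i <- i + 1
      tp <- tStart; qp <- qStart
      while (i <= length(lines) && nzchar(trimws(lines[i]))) {
        seg <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
        size <- seg[1]
        out[[length(out) + 1]] <- data.frame(
          chromA = tName, startA = tp, endA = tp + size,
          chromB = qName, startB = qp, endB = qp + size,
          strand = qStrand, aligned_len = size,
          stringsAsFactors = FALSE)
        dt <- if (length(seg) >= 3) seg[2] else 0L
        dq <- if (length(seg) >= 3) seg[3] else 0L
        tp <- tp + size + dt; qp <- qp + size + dq
        i <- i + 1
      }
    }
    i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(chromA = character(), startA = integer(),
                      endA = integer(), chromB = character(),
                      startB = integer(), endB = integer(),
                      strand = character(), aligned_len = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read/write per-bp coverage tracks as fixedStep wiggle
#'
#' One declaration line per chromosome (`fixedStep chrom=... start=1 step=1`)
#' followed by one value per base pair, the plain-text stand-in for BigWig.
#'
#' @param track named list of numeric vectors (one per chromosome).
#' @param path wiggle file.
#' @return named list of numeric vectors (read) or `path` invisibly (write).
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(formatC(track[[chrom]], format = "g", digits = 8), con)
  }
  invisible(path)
}

#' @rdname write_wig
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  decl <- grep("^fixedStep", lines)
  if (length(decl) == 0) stop2("no fixedStep declarations in ", path)
  bounds <- c(decl, length(lines) + 1L)
  out <- list()
  for (j in seq_along(decl)) {
    chrom <- sub(".*chrom=([^ ]+).*", "\\1", lines[decl[j]])
    vals <- as.numeric(lines[(decl[j] + 1L):(bounds[j + 1L] - 1L)])
    out[[chrom]] <- vals
  }
  out
}

#' Write variants to a minimal VCF 4.2 file
#'
#' @param variants data.frame with columns chrom, pos (1-based), id, ref,
#'   alt, and optionally info (pre-formatted INFO strings).
#' @param path output `.vcf`.
#' @param info_header character vector of extra `##INFO` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, info_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", info_header,
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    info <- variants$info %||% rep(".", nrow(variants))
    writeLines(paste(variants$chrom, variants$pos, variants$id,
                     variants$ref, variants$alt, ".", ".", info,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a (plain-text, biallelic SNV) VCF into a data.frame
#'
#' @param path `.vcf` file.
#' @return data.frame with chrom, pos, id, ref, alt, info.
#' @export
read_vcf_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      id = character(), ref = character(),
                      alt = character(), info = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[`, "", 1),
             pos = as.integer(vapply(f, `[`, "", 2)),
             id = vapply(f, `[`, "", 3),
             ref = vapply(f, `[`, "", 4),
             alt = vapply(f, `[`, "", 5),
             info = vapply(f, `[`, "", 8),
             stringsAsFactors = FALSE)
}

# pull one key's value out of an INFO string, NA when absent
vcf_info_field <- function(info, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  has <- grepl(pat, info)
  out <- rep(NA_character_, length(info))
  out[has] <- sub(paste0(".*", pat, ".*"), "\\2", info[has])
  out
}
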