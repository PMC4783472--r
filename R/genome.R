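#' Read a reference genome from FASTA
#'
#' Loads a (toy or real) genome into a `Biostrings::DNAStringSet`, normalizing
#' to uppercase and trimming FASTA descriptions to the first word.
#'
#' @param path path to an uncompressed or gzipped FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop_trio("no sequence in ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop_trio("duplicate chromosome names in ", path)
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

as_genome <- function(genome) {
  if (length(genome) == 0L) stop_trio("no sequence")
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop_trio("genome must be a DNAStringSet or a named character vector")
  }
  if (length(genome) == 0L || any(Biostrings::width(genome) < 1L)) {
    stop_trio("no sequence")
  }
  genome
}

#' Chromosome sizes of a genome
#'
#' @param genome a `DNAStringSet` or named character vector of sequences.
#' @return A tibble with columns `chrom` and `size` (bp).
#' @export
chrom_sizes <- function(genome) {
  genome <- as_genome(genome)
  tibble::tibble(chrom = names(genome), size = Biostrings::width(genome))
}

#' Simulate a random genome sequence
#'
#' Draws i.i.d. bases with a mild GC bias so that MspI sites (CCGG) occur at a
#' realistic density for digestion experiments on toy chromosomes.
#'
#' @param sizes named integer vector of chromosome lengths in bp.
#' @param gc GC fraction of the simulated sequence.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(sizes, gc = 0.5, seed = NULL) {
  if (is.null(names(sizes))) names(sizes) <- paste0("chr", seq_along(sizes))
  check_number(gc, "gc", min = 0)
  with_preserved_seed(seed, {
    seqs <- vapply(sizes, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' In-silico MspI digestion
#'
#' Scans each chromosome for MspI recognition sites (CCGG) and returns the
#' fragments between consecutive cut positions. MspI cuts C^CGG, so the cut
#' coordinate is one base into each CCGG occurrence; fragments before the first
#' and after the last cut of a chromosome are not returned (every reported
#' fragment is CCGG-flanked on both sides). CCGG never spans an N run, so N-rich
#' assemblies simply yield fewer sites.
#'
#' Coordinates are 0-based half-open; consecutive CCGG sites cannot overlap, so
#' every fragment is at least 4 bp.
#'
#' @param genome a `DNAStringSet` or named character vector.
#' @return A tibble with columns `frag_id`, `chrom`, `start`, `end`.
#' @export
digest_mspi <- function(genome) {
  genome <- as_genome(genome)
  frags <- purrr::map_dfr(names(genome), function(chr) {
    hits <- Biostrings::matchPattern("CCGG", genome[[chr]])
    # 1-based match start == 0-based cut coordinate (offset + 1 within CCGG)
    cuts <- BiocGenerics::start(hits)
    if (length(cuts) < 2L) {
      return(tibble::tibble(chrom = character(), start = integer(),
                            end = integer()))
    }
    tibble::tibble(chrom = chr,
                   start = as.integer(cuts[-length(cuts)]),
                   end = as.integer(cuts[-1L]))
  })
  frags$frag_id <- if (nrow(frags) > 0L) {
    sprintf("%s:%d-%d", frags$chrom, frags$start, frags$end)
  } else character(0)
  dplyr::select(frags, "frag_id", "chrom", "start", "end")
}

fragment_sequences <- function(fragments, genome) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(fragments)), function(i) {
    as.character(Biostrings::subseq(genome[[fragments$chrom[i]]],
                                    start = fragments$start[i] + 1L,
                                    end = fragments$end[i]))
  }, character(1))
}

#' Simulate paired end-reads from fragment ends
#'
#' RRBS reads come from the two ends of each MspI fragment. For each fragment
#' this produces the first `read_len` bases (forward read) and the reverse
#' complement of the last `read_len` bases (reverse read); reads are truncated
#' to the fragment length when the fragment is shorter than `read_len`.
#'
#' @param fragments tibble from [digest_mspi()].
#' @param genome the genome the fragments were digested from.
#' @param read_len simulated read length in bp (>= 1).
#' @return `fragments` with character columns `read_fwd` and `read_rev` added.
#' @export
simulate_end_reads <- function(fragments, genome, read_len = 36) {
  check_number(read_len, "read_len", min = 1)
  genome <- as_genome(genome)
  if (nrow(fragments) == 0L) {
    return(dplyr::mutate(fragments, read_fwd = character(0),
                         read_rev = character(0)))
  }
  seqs <- fragment_sequences(fragments, genome)
  len <- pmin(nchar(seqs), as.integer(read_len))
  fwd <- substr(seqs, 1L, len)
  last <- substr(seqs, nchar(seqs) - len + 1L, nchar(seqs))
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(last)))
  dplyr::mutate(fragments, read_fwd = fwd, read_rev = rev)
}

# C->T collapse used for bisulfite-space matching.
bisulfite_collapse <- function(x) chartr("C", "T", x)

#' Flag fragments whose end-reads map uniquely in bisulfite space
#'
#' Mimics alignment of the simulated end-reads: both the reads and both genome
#' strands are C-to-T collapsed (as a bisulfite aligner does), and a fragment is
#' unique only if each of its two end-reads occurs exactly once across all
#' positions of both collapsed strands. Matching is exact (no mismatches), which
#' is stricter than a real aligner; see the package vignette.
#'
#' @param fragments tibble with `read_fwd`/`read_rev` from
#'   [simulate_end_reads()].
#' @param genome the genome to match against.
#' @param read_len read length used to generate the end reads (informational).
#' @return `fragments` with a logical `is_unique` column added.
#' @export
flag_unique_fragments <- function(fragments, genome, read_len = 36) {
  genome <- as_genome(genome)
  if (nrow(fragments) == 0L) {
    return(dplyr::mutate(fragments, is_unique = logical(0)))
  }
  check_columns(fragments, c("read_fwd", "read_rev"), "fragments")
  fwd_strand <- bisulfite_collapse(as.character(genome))
  rev_strand <- bisulfite_collapse(as.character(
    Biostrings::reverseComplement(genome)))
  subjects <- Biostrings::DNAStringSet(c(fwd_strand, rev_strand))

  reads <- bisulfite_collapse(c(fragments$read_fwd, fragments$read_rev))
  counts <- count_occurrences(reads, subjects)
  n <- nrow(fragments)
  dplyr::mutate(fragments,
                is_unique = counts[seq_len(n)] == 1L &
                  counts[n + seq_len(n)] == 1L)
}

# Exact-match occurrence counts of each read across a set of subjects.
# Constant-width ACGT reads go through a PDict (fast preprocessed matching);
# the rest are counted individually.
count_occurrences <- function(reads, subjects) {
  counts <- integer(length(reads))
  widths <- nchar(reads)
  clean <- !grepl("[^ACGT]", reads)
  main_w <- if (any(clean)) as.integer(names(which.max(table(widths[clean])))) else NA_integer_
  use_pdict <- which(clean & widths == main_w)
  if (length(use_pdict) > 1L) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads[use_pdict]))
    m <- Biostrings::vcountPDict(pd, subjects)
    counts[use_pdict] <- as.integer(rowSums(m))
    rest <- setdiff(seq_along(reads), use_pdict)
  } else {
    rest <- seq_along(reads)
  }
  for (i in rest) {
    counts[i] <- sum(Biostrings::vcountPattern(reads[i], subjects,
                                               fixed = TRUE))
  }
  counts
}

#' Tile chromosomes into fixed-size genomic bins
#'
#' Bins tile each chromosome without overlap in chromosome order; the last bin
#' of a chromosome may be shorter. Coordinates are 0-based half-open.
#'
#' @param sizes a tibble with columns `chrom` and `size`, or a named vector.
#' @param bin_size bin width in bp (default 10 Mb, the resolution used for
#'   read-depth copy-number profiles).
#' @return A tibble with columns `bin_id`, `chrom`, `start`, `end`, `masked`.
#' @export
build_bins <- function(sizes, bin_size = 1e7) {
  check_number(bin_size, "bin_size", min = 1)
  if (!is.data.frame(sizes)) {
    sizes <- tibble::tibble(chrom = names(sizes), size = unname(sizes))
  }
  check_columns(sizes, c("chrom", "size"), "sizes")
  bins <- purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    starts <- seq(0, sizes$size[i] - 1, by = bin_size)
    tibble::tibble(chrom = sizes$chrom[i],
                   start = starts,
                   end = pmin(starts + bin_size, sizes$size[i]))
  })
  dplyr::mutate(bins,
                bin_id = sprintf("%s:%d", .data$chrom, as.integer(.data$start / 1e3)),
                masked = FALSE,
                .before = 1)
}

assign_to_bins <- function(chrom, pos, bins, what = "position") {
  bin_id <- rep(NA_character_, length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    b <- bins[bins$chrom == chr, ]
    if (nrow(b) == 0L) stop_trio("unknown chromosome in ", what, ": ", chr)
    b <- b[order(b$start), ]
    idx <- findInterval(pos[sel], b$start)
    bad <- idx < 1L | pos[sel] >= b$end[pmax(idx, 1L)]
    if (any(bad)) {
      stop_trio(what, " outside any bin: ", chr, ":",
                pos[sel][which(bad)[1]])
    }
    bin_id[sel] <- b$bin_id[idx]
  }
  bin_id
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to the bin containing its start coordinate, so
#' totals are conserved: counts sum to the number of (optionally unique)
#' fragments.
#'
#' @param fragments tibble from [digest_mspi()], optionally with `is_unique`.
#' @param bins tibble from [build_bins()].
#' @param unique_only count only fragments flagged unique.
#' @return `bins` with an integer `n_fragments` column.
#' @export
count_fragments_per_bin <- function(fragments, bins, unique_only = FALSE) {
  if (unique_only) {
    check_columns(fragments, "is_unique", "fragments")
    fragments <- dplyr::filter(fragments, .data$is_unique)
  }
  if (nrow(fragments) == 0L) {
    return(dplyr::mutate(bins, n_fragments = 0L))
  }
  fragments$bin_id <- assign_to_bins(fragments$chrom, fragments$start, bins,
                                     "fragment")
  counts <- dplyr::count(fragments, .data$bin_id, name = "n_fragments")
  out <- dplyr::left_join(bins, counts, by = "bin_id")
  dplyr::mutate(out, n_fragments = as.integer(tidyr::replace_na(.data$n_fragments, 0L)))
}
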