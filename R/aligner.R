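#' DUST low-complexity masking parameters
#'
#' @param window window size in bp (default 64).
#' @param level score threshold scaled by 10, i.e. a window is
#'   low-complexity when its triplet score exceeds `level / 10`
#'   (default 20).
#' @param linker masked intervals separated by at most this many bases are
#'   merged (default 1).
#' @return A list of class `dust_params`.
#' @export
dust_params <- function(window = 64L, level = 20L, linker = 1L) {
  stopifnot(window >= 3)
  structure(list(window = as.integer(window), level = as.integer(level),
                 linker = as.integer(linker)), class = "dust_params")
}

#' Mask low-complexity DNA (DUST)
#'
#' Every window of `window` bp is scored by its triplet composition,
#' S = sum over triplet types of c(c-1)/2, divided by (w - 3); positions
#' inside any window scoring above `level / 10` are lowercased, and masked
#' intervals separated by at most `linker` bases are merged. Only case
#' changes; length and content are preserved.
#'
#' @param seq DNA string(s) over A, C, G, T, N.
#' @param params a [dust_params()].
#' @return The masked string(s).
#' @export
dust_mask <- function(seq, params = dust_params()) {
  vapply(as.character(seq), function(s)
    cpp_dust_mask(s, params$window, params$level, params$linker), "",
    USE.NAMES = FALSE)
}

#' Spliced alignment of a probe against a genomic contig
#'
#' Finds chained local alignments allowing intron-scale gaps on the contig
#' axis only. For a protein probe the alignment is in translated space
#' (codon-granular on the contig); both contig orientations are tried and
#' the better one kept. Intron-scale gaps are free when flanked by the
#' canonical GT...AG dinucleotides and carry a small constant penalty
#' otherwise. The similarity score is identities over aligned probe
#' positions; probe coverage is the fraction of probe positions inside
#' alignment blocks.
#'
#' @param probe a one-row [seq_set()] (protein or DNA).
#' @param contig a one-row [seq_set()] (DNA).
#' @return A list of class `spliced_alignment`: `probe_id`, `contig_id`,
#'   `blocks` (matrix of half-open 0-based `probe_start`, `probe_end` in
#'   residues/bases and `contig_start`, `contig_end` in bp), `similarity`,
#'   `probe_coverage`, `aligned_length` (bp on contig), `strand`, and
#'   `contig_length`.
#' @export
splice_align <- function(probe, contig) {
  stopifnot(nrow(probe) == 1, nrow(contig) == 1,
            contig$alphabet == "dna")
  res <- cpp_splice_align(probe$seq, probe$alphabet == "protein", contig$seq)
  structure(list(probe_id = probe$id, contig_id = contig$id,
                 blocks = res$blocks, similarity = res$similarity,
                 probe_coverage = res$probe_coverage,
                 aligned_length = res$aligned_length,
                 identities = res$identities, strand = res$strand,
                 contig_length = nchar(contig$seq)),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s [%s]: similarity %.3f, probe coverage %.3f, %d bp in %d block(s)\n",
              x$probe_id, x$contig_id, x$strand, x$similarity,
              x$probe_coverage, x$aligned_length, nrow(x$blocks)))
  invisible(x)
}

#' Hit decision for a contig
#'
#' A contig is a hit when its length reaches `min_len`, the spliced
#' alignment similarity reaches `min_sim` and the alignment covers at
#' least `min_cov` of the probe.
#'
#' @param aln a [splice_align()] result.
#' @param contig_len contig length in bp (taken from `aln` when omitted).
#' @param min_len minimum contig length (default 200 bp).
#' @param min_sim minimum similarity score (default 0.5).
#' @param min_cov minimum probe coverage fraction (default 0.8).
#' @return `TRUE` or `FALSE`.
#' @export
is_hit <- function(aln, contig_len = aln$contig_length, min_len = 200L,
                   min_sim = 0.5, min_cov = 0.8) {
  contig_len >= min_len && aln$similarity >= min_sim &&
    aln$probe_coverage >= min_cov
}

#' Write a plain-text spliced-alignment report
#'
#' One stanza per contig: similarity, probe coverage, strand, and the
#' alignment blocks (1-based inclusive coordinates in the report).
#'
#' @param alignments list of [splice_align()] results.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_aln_report <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    writeLines(sprintf(">%s vs %s strand=%s similarity=%.4f coverage=%.4f aligned_bp=%d",
                       a$probe_id, a$contig_id, a$strand, a$similarity,
                       a$probe_coverage, a$aligned_length), con)
    if (nrow(a$blocks) > 0) {
      writeLines(sprintf("  block %d: probe %d..%d contig %d..%d",
                         seq_len(nrow(a$blocks)),
                         a$blocks[, 1] + 1L, a$blocks[, 2],
                         pmin(a$blocks[, 3], a$blocks[, 4]) + 1L,
                         pmax(a$blocks[, 3], a$blocks[, 4])), con)
    }
  }
  invisible(path)
}

#' Emit hit gene structures as GFF3 (blocks as exon features)
#'
#' @param alignments list of [splice_align()] results.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(alignments, path, source = "srwalk") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (a in alignments) {
    if (nrow(a$blocks) == 0) next
    lo <- pmin(a$blocks[, 3], a$blocks[, 4]) + 1L
    hi <- pmax(a$blocks[, 3], a$blocks[, 4])
    gid <- paste0(a$contig_id, ".", a$probe_id)
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t%.3f\t%s\t.\tID=%s",
                       a$contig_id, source, min(lo), max(hi), a$similarity,
                       a$strand, gid), con)
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       a$contig_id, source, lo, hi, a$strand, gid), con)
  }
  invisible(path)
}
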