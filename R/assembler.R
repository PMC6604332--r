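#' Build a de Bruijn graph from a read pool
#'
#' Nodes are canonical k-mers (the lexicographically smaller of a k-mer
#' and its reverse complement), so both strands are represented; k-mers
#' containing N are excluded. k must be odd so canonical orientation is
#' always well defined.
#'
#' @param reads character vector of DNA reads or a [seq_set()].
#' @param k odd k-mer size, 11..63.
#' @return An object of class `dbg_graph`.
#' @export
build_graph <- function(reads, k) {
  if (inherits(reads, "seq_set")) reads <- reads$seq
  ptr <- cpp_dbg_build(as.character(reads), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k)), class = "dbg_graph")
}

#' @export
print.dbg_graph <- function(x, ...) {
  st <- cpp_dbg_stats(x$ptr)
  cat(sprintf("de Bruijn graph: k=%d, %d node(s), %g k-mer occurrence(s)\n",
              st$k, st$n_nodes, st$n_occurrences))
  invisible(x)
}

#' Graph summary statistics (node count, k-mer occurrences)
#' @param graph a `dbg_graph`.
#' @return A list with `k`, `n_nodes` and `n_occurrences`.
#' @export
graph_stats <- function(graph) cpp_dbg_stats(graph$ptr)

#' Coverage of a single k-mer (either orientation)
#' @param graph a `dbg_graph`.
#' @param kmer a k-mer string.
#' @return The stored coverage count (0 if absent).
#' @export
graph_coverage <- function(graph, kmer) cpp_dbg_cov(graph$ptr, kmer)

#' All canonical k-mers of the graph (sorted; for small graphs/tests)
#' @param graph a `dbg_graph`.
#' @return Character vector of canonical k-mers.
#' @export
graph_kmers <- function(graph) cpp_dbg_kmers(graph$ptr)

#' Clean up a de Bruijn graph in place
#'
#' Dead-end paths shorter than `tip_len` with lower coverage than the
#' competing branch at their junction are removed; branches that diverge
#' at a junction and reconverge at the same node ("bubbles", including
#' multi-arm ones) are collapsed onto the highest-coverage arm when the
#' arm sequences are at least `bubble_identity` identical (gapped
#' identity, so 1 bp indel bubbles collapse too). Iterated to a fixpoint.
#'
#' @param graph a `dbg_graph` (modified in place).
#' @param tip_len maximum tip length in bp (default `2 * k`).
#' @param bubble_identity minimum arm identity for collapsing (default 0.9).
#' @param min_count optional k-mer coverage floor applied before the
#'   topological cleanup; the default of 1 keeps every k-mer. Pools with
#'   ample fold coverage benefit from 2: at percent-scale sequencing error
#'   rates, singleton k-mers are overwhelmingly errors.
#' @return The graph, invisibly.
#' @export
simplify_graph <- function(graph, tip_len = 2L * graph$k,
                           bubble_identity = 0.9, min_count = 1L) {
  cpp_dbg_simplify(graph$ptr, as.integer(tip_len), bubble_identity,
                   as.integer(min_count))
  invisible(graph)
}

#' Spell unitigs (maximal non-branching paths) of a graph
#'
#' Each unitig is reported in canonical orientation (the lexicographically
#' smaller of the sequence and its reverse complement); results shorter
#' than `min_len` are dropped and output is sorted by decreasing length,
#' then sequence, for determinism.
#'
#' @param graph a `dbg_graph`.
#' @param min_len minimum contig length in bp.
#' @param ids prefix for contig identifiers.
#' @return A [seq_set()] of contigs.
#' @export
unitigs <- function(graph, min_len = 200L, ids = "ctg") {
  seqs <- cpp_dbg_unitigs(graph$ptr, as.integer(min_len))
  if (length(seqs) == 0) return(seq_set(alphabet = "dna"))
  seq_set(id = sprintf("%s%05d", ids, seq_along(seqs)), seq = seqs,
          alphabet = "dna")
}

#' Assemble a read pool with a k-mer sweep and pick the best k
#'
#' The graph is built, simplified and unitigged once per k in `k_list`
#' (defaults 15, 25, 35, 45). Each assembly is scored by the total
#' spliced-alignment length of the probe against its contigs, and the
#' assembly with the greatest total wins; on ties the larger k is kept
#' (larger k resolves repeats better). The winning contigs are
#' low-complexity masked (DUST) for use as next-round queries; the
#' reported contigs keep their original case.
#'
#' @param reads read pool (character vector or [seq_set()]).
#' @param k_list odd k-mer sizes to sweep.
#' @param probe the probe record (one-row [seq_set()]), protein or DNA.
#' @param min_contig minimum contig length (bp) kept after assembly.
#' @param tip_len,bubble_identity graph cleanup parameters; `tip_len = NULL`
#'   uses `2 * k` per sweep value.
#' @param min_count k-mer coverage floor for the sweep (default 2;
#'   see [simplify_graph()]).
#' @param dust [dust_params()] used to mask next-round queries.
#' @param contig_prefix prefix for contig ids (round tag).
#' @return A list of class `assembly`: `k_used`, `contigs` ([seq_set()]),
#'   `metric` (total aligned bp), `alignments` (per-contig
#'   [splice_align()] results) and `queries` (masked contigs).
#' @export
assemble_sweep <- function(reads, k_list = c(15L, 25L, 35L, 45L), probe,
                           min_contig = 200L, tip_len = NULL,
                           bubble_identity = 0.9, min_count = 2L,
                           dust = dust_params(), contig_prefix = "ctg") {
  if (inherits(reads, "seq_set")) reads <- reads$seq
  stopifnot(length(k_list) > 0, all(k_list %% 2 == 1))
  best <- NULL
  for (k in sort(as.integer(k_list))) {
    g <- build_graph(reads, k)
    simplify_graph(g, tip_len = if (is.null(tip_len)) 2L * k else tip_len,
                   bubble_identity = bubble_identity, min_count = min_count)
    ctg <- unitigs(g, min_len = min_contig,
                   ids = sprintf("%s_k%d_", contig_prefix, k))
    rm(g)
    if (nrow(ctg) == 0) {
      cand <- list(k_used = k, contigs = ctg, metric = 0,
                   alignments = list())
    } else {
      alns <- lapply(seq_len(nrow(ctg)), function(i) {
        splice_align(probe, seq_record(ctg, i))
      })
      cand <- list(k_used = k, contigs = ctg,
                   metric = sweep_metric(alns, probe), alignments = alns)
    }
    # ties keep the larger k: sweep ascends, so >= replaces
    if (is.null(best) || cand$metric >= best$metric) best <- cand
  }
  best$queries <- if (nrow(best$contigs) > 0) {
    masked <- best$contigs
    masked$seq <- vapply(masked$seq, function(s)
      cpp_dust_mask(s, dust$window, dust$level, dust$linker), "",
      USE.NAMES = FALSE)
    masked
  } else best$contigs
  class(best) <- "assembly"
  best
}

# Sweep score of an assembly: the greatest spliced-alignment length any
# single contig achieves against the probe (bp on the contig). Scoring
# the longest alignment rather than a per-contig total keeps a fragmented
# assembly, whose pieces each align a little, from outscoring one whose
# single contig spans the probe -- the walk is after one contig covering
# the query.
sweep_metric <- function(alns, probe) {
  if (length(alns) == 0) return(0)
  max(vapply(alns, `[[`, numeric(1), "aligned_length"))
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: best k=%d, %d contig(s), metric=%d aligned bp\n",
              x$k_used, nrow(x$contigs), as.integer(x$metric)))
  invisible(x)
}
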