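# The standard synthetic study fixture: a 1 Mb genome with one planted
# 3-exon gene (~1.5 kb CDS), paired 70 bp reads at the requested fold
# coverage with the wgsim-style parameter defaults, and a protein probe
# diverged to ~85% identity.

paper_fixture <- function(coverage, seed_base, base_error = 0.02,
                          genome_len = 1000000L, tag = "fx") {
  gs <- gene_spec(pos = as.integer(genome_len / 2),
                  exon_lens = c(480L, 510L, 513L),
                  intron_lens = c(350L, 420L))
  sim <- make_genome(genome_len, genes = list(gs), seed = seed_base + 1L)
  probe <- diverge_probe(sim$genes[[1]], 0.85, seed = seed_base + 2L)$protein
  rd <- simulate_reads(sim, sim_params(coverage = coverage,
                                       base_error = base_error,
                                       seed = seed_base + 3L),
                       out_prefix = file.path(tempdir(),
                                              paste0(tag, "_", seed_base)))
  gene <- sim$genes[[1]]
  list(sim = sim, gene = gene, probe = probe,
       body = substr(sim$genome$seq, gene$gene_start, gene$gene_end),
       library = list(file1 = rd$file1, file2 = rd$file2,
                      insert_size = 340L),
       r1 = rd$r1, r2 = rd$r2)
}

# BLAST-style percent identity of a contig against the truth gene body:
# best local alignment in either orientation.
identity_to_body <- function(contig, body) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(contig),
                                      Biostrings::DNAString(body),
                                      type = "local")
  pa2 <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(contig)),
    Biostrings::DNAString(body), type = "local")
  if (Biostrings::score(pa2) > Biostrings::score(pa)) pa <- pa2
  Biostrings::pid(pa)
}

# the walk's best candidate: a hit contig when one exists, otherwise the
# contig with the greatest spliced-alignment length to the probe
best_candidate <- function(res) {
  if (nrow(res$hit_contigs) > 0) return(res$hit_contigs$seq[1])
  if (nrow(res$all_contigs) == 0) return(NA_character_)
  al <- vapply(res$alignments, `[[`, numeric(1), "aligned_length")
  res$all_contigs$seq[which.max(al)]
}
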