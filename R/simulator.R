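#' Read-simulation parameters
#'
#' Defaults emulate a wgsim-style protocol: 70 bp paired reads, insert
#' size 340 +/- 50 bp, per-base sequencing substitution error 0.02,
#' haplotype mutation rate 0 with 10% of mutations as 1 bp indels (so no
#' indels at the default mutation rate).
#'
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd insert-size distribution (bp); fragment
#'   lengths are normal, truncated at `2 * read_len`.
#' @param base_error per-base sequencing substitution rate.
#' @param mutation_rate per-base haplotype mutation rate.
#' @param indel_fraction fraction of mutations realized as 1 bp indels.
#' @param coverage fold coverage of the genome.
#' @param seed integer seed; all outputs are reproducible per seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(read_len = 70L, insert_mean = 340, insert_sd = 50,
                       base_error = 0.02, mutation_rate = 0,
                       indel_fraction = 0.10, coverage = 20, seed = 1L) {
  stopifnot(base_error >= 0, base_error <= 1, mutation_rate >= 0,
            mutation_rate <= 1, indel_fraction >= 0, indel_fraction <= 1,
            read_len <= insert_mean)
  structure(list(read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 base_error = base_error, mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction, coverage = coverage,
                 seed = as.integer(seed)), class = "sim_params")
}

# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a gene to plant in a synthetic genome
#'
#' Exon lengths must be multiples of 3: introns are inserted at codon
#' boundaries so that the exon concatenation translates cleanly.
#'
#' @param pos 1-based genome position of the gene start.
#' @param exon_lens exon lengths in bp (each a multiple of 3; the total is
#'   the CDS length and must accommodate a start and a stop codon).
#' @param intron_lens intron lengths in bp (one fewer than exons, each at
#'   least 8 bp for the GT...AG signals).
#' @param strand `"+"` or `"-"`.
#' @param id gene identifier.
#' @return A list of class `gene_spec`.
#' @export
gene_spec <- function(pos, exon_lens, intron_lens = integer(), strand = "+",
                      id = "gene1") {
  stopifnot(all(exon_lens %% 3 == 0), all(exon_lens > 0),
            length(intron_lens) == length(exon_lens) - 1,
            all(intron_lens >= 8), strand %in% c("+", "-"),
            sum(exon_lens) >= 9)
  structure(list(pos = as.integer(pos), exon_lens = as.integer(exon_lens),
                 intron_lens = as.integer(intron_lens), strand = strand,
                 id = id), class = "gene_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  ok <- setdiff(codons, STOP_CODONS)
  sample(ok, n, replace = TRUE)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Generate a synthetic genome with planted multi-exon genes
#'
#' The background is uniform random DNA; each gene's CDS is random
#' non-stop codons opening with ATG and closing with a stop codon, split
#' over its exons, with GT...AG introns between them. Deterministic per
#' seed. A truth table (gene coordinates, exon coordinates, CDS, protein)
#' is returned alongside the sequence.
#'
#' @param length genome length in bp.
#' @param genes list of [gene_spec()]s (must not overlap).
#' @param seed integer seed.
#' @param id sequence identifier.
#' @return A list of class `sim_genome`: `genome` (one-row [seq_set()]),
#'   `genes` (list of planted genes with `gene_start`, `gene_end`,
#'   `exons` matrix, `strand`, `cds`, `protein`) and `truth`
#'   (a data.frame).
#' @export
make_genome <- function(length, genes = list(), seed = 1L, id = "synth1") {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  with_seed(seed, {
    seq <- random_dna_chr(length)
    planted <- list()
    occupied <- NULL
    for (g in genes) {
      cds_len <- sum(g$exon_lens)
      n_codons <- cds_len / 3
      codons <- random_codons(n_codons)
      codons[1] <- "ATG"
      codons[n_codons] <- sample(STOP_CODONS, 1)
      cds <- paste(codons, collapse = "")
      introns <- vapply(g$intron_lens, function(n)
        paste0("GT", random_dna_chr(n - 4L), "AG"), "")
      pieces <- character(0)
      exon_starts_local <- integer(0)
      off <- 0L
      cpos <- 1L
      for (i in seq_along(g$exon_lens)) {
        exon_starts_local <- c(exon_starts_local, off + 1L)
        pieces <- c(pieces, substr(cds, cpos, cpos + g$exon_lens[i] - 1L))
        cpos <- cpos + g$exon_lens[i]
        off <- off + g$exon_lens[i]
        if (i < length(g$exon_lens)) {
          pieces <- c(pieces, introns[i])
          off <- off + g$intron_lens[i]
        }
      }
      gene_seq <- paste(pieces, collapse = "")
      glen <- nchar(gene_seq)
      gstart <- g$pos
      gend <- g$pos + glen - 1L
      if (gend > length) stop("gene '", g$id, "' does not fit in the genome")
      iv <- c(gstart, gend)
      if (!is.null(occupied) &&
          any(occupied[, 1] <= iv[2] & occupied[, 2] >= iv[1])) {
        stop("gene '", g$id, "' overlaps a previously planted gene")
      }
      occupied <- rbind(occupied, iv)
      exons_fwd <- cbind(start = gstart + exon_starts_local - 1L,
                         end = gstart + exon_starts_local + g$exon_lens - 2L)
      if (g$strand == "-") {
        gene_seq <- revcomp_chr(gene_seq)
        exons <- cbind(start = gstart + gend - exons_fwd[, "end"],
                       end = gstart + gend - exons_fwd[, "start"])
        exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
      } else {
        exons <- exons_fwd
      }
      substr(seq, gstart, gend) <- gene_seq
      protein <- translate_cds(cds)
      protein <- sub("\\*$", "", protein)
      if (grepl("\\*", protein)) stop("internal stop codon in planted gene")
      planted[[g$id]] <- list(id = g$id, gene_start = gstart,
                              gene_end = gend, strand = g$strand,
                              exons = exons, cds = cds, protein = protein)
    }
    truth <- do.call(rbind, lapply(planted, function(p) {
      data.frame(gene = p$id, start = p$gene_start, end = p$gene_end,
                 strand = p$strand,
                 exon_starts = paste(p$exons[, "start"], collapse = ","),
                 exon_ends = paste(p$exons[, "end"], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    structure(list(genome = seq_set(id = id, seq = seq, alphabet = "dna"),
                   genes = planted, truth = truth),
              class = "sim_genome")
  })
}

#' Derive a diverged homologous probe from a planted gene
#'
#' Amino-acid substitutions are applied to reach the target protein
#' identity (within about two percentage points); the cDNA is mutated
#' with a synonymous bias to a correlated nucleotide identity. No stop
#' codons are ever introduced.
#'
#' @param gene a planted gene from [make_genome()].
#' @param target_protein_identity target identity in `[0.5, 1]`.
#' @param seed integer seed.
#' @return A list with `protein` and `cdna` (one-row [seq_set()]s).
#' @export
diverge_probe <- function(gene, target_protein_identity = 0.85, seed = 1L) {
  stopifnot(target_protein_identity >= 0.5, target_protein_identity <= 1)
  with_seed(seed, {
    aas <- strsplit(gene$protein, "")[[1]]
    n <- length(aas)
    codons <- substring(gene$cds, seq(1, nchar(gene$cds) - 3, 3),
                        seq(3, nchar(gene$cds) - 3 + 2, 3))
    codons <- codons[seq_len(n)] # drop the stop codon
    n_sub <- round((1 - target_protein_identity) * n)
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    gc <- Biostrings::GENETIC_CODE
    syn <- split(names(gc), unname(gc))
    if (n_sub > 0) {
      pos <- sample(2:n, n_sub) # never touch the initiator Met
      for (p in pos) {
        new_aa <- sample(setdiff(alphabet, aas[p]), 1)
        aas[p] <- new_aa
        codons[p] <- sample(syn[[new_aa]], 1)
      }
    }
    # synonymous churn elsewhere, correlating the nucleotide identity
    keep <- setdiff(seq_len(n), if (n_sub > 0) pos else integer())
    for (p in keep) {
      if (runif(1) < 0.3) {
        alt <- setdiff(syn[[aas[p]]], codons[p])
        if (length(alt) > 0) codons[p] <- sample(alt, 1)
      }
    }
    protein <- paste(aas, collapse = "")
    cdna <- paste(codons, collapse = "")
    list(protein = seq_set(id = paste0(gene$id, "_probe_prot"),
                           seq = protein, alphabet = "protein"),
         cdna = seq_set(id = paste0(gene$id, "_probe_cdna"), seq = cdna,
                        alphabet = "dna"))
  })
}

#' Simulate a paired-end read library
#'
#' N = floor(genome_length * coverage / (read_len * 2)) fragments are
#' drawn with uniform starts and truncated-normal lengths; mate 1 is read
#' forward from the fragment start and mate 2 reverse-complement from the
#' fragment end. Read names carry the true fragment coordinates
#' (`sim_<start>_<end>_<i>`, 1-based inclusive). Deterministic per seed.
#'
#' @param genome a one-row [seq_set()] or DNA string.
#' @param params a [sim_params()].
#' @param out_prefix if non-`NULL`, mate files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written and a library spec returned.
#' @return A list with `r1`, `r2` ([seq_set()]s), `n_pairs`, and (when
#'   written) `file1`, `file2`, `insert_size`.
#' @export
simulate_reads <- function(genome, params = sim_params(), out_prefix = NULL) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  gseq <- if (inherits(genome, "data.frame")) genome$seq[1] else
    as.character(genome)
  L <- nchar(gseq)
  if (params$coverage <= 0) stop("coverage must be positive")
  if (L <= params$insert_mean + 4 * params$insert_sd) {
    stop("genome too short for the insert-size distribution")
  }
  n <- floor(L * params$coverage / (params$read_len * 2))
  sim <- cpp_simulate_pairs(gseq, n, params$read_len, params$insert_mean,
                            params$insert_sd, params$base_error,
                            params$mutation_rate, params$indel_fraction,
                            params$seed)
  qual <- strrep("I", params$read_len)
  r1 <- seq_set(id = sim$id, seq = sim$seq1, qual = qual, alphabet = "dna")
  r2 <- seq_set(id = sim$id, seq = sim$seq2, qual = qual, alphabet = "dna")
  out <- list(r1 = r1, r2 = r2, n_pairs = n)
  if (!is.null(out_prefix)) {
    f1 <- paste0(out_prefix, "_1.fastq")
    f2 <- paste0(out_prefix, "_2.fastq")
    write_fastq(r1, f1)
    write_fastq(r2, f2)
    out$file1 <- f1
    out$file2 <- f2
    out$insert_size <- params$insert_mean
  }
  out
}

#' Write the truth table of a synthetic genome
#'
#' @param sim a `sim_genome` from [make_genome()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse true fragment coordinates from simulated read names
#'
#' @param ids read names of the form `sim_<start>_<end>_<i>`.
#' @return A data.frame with `start`, `end` (1-based inclusive fragment
#'   coordinates) and `pair` index.
#' @export
read_truth_coords <- function(ids) {
  m <- regmatches(ids, regexec("^sim_(\\d+)_(\\d+)_(\\d+)$", ids))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("not a simulated read name: ", ids[which(bad)[1]])
  data.frame(start = as.integer(vapply(m, `[[`, "", 2)),
             end = as.integer(vapply(m, `[[`, "", 3)),
             pair = as.integer(vapply(m, `[[`, "", 4)))
}
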