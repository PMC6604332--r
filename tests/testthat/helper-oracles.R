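# Independent oracles used to validate the fast implementations. These are
# deliberately written with different machinery (plain R string ops and
# Biostrings) than the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

canonical_seq <- function(s) {
  r <- rc(s)
  if (s <= r) s else r
}

# Does `read` share an exact common substring of length >= m with any of
# `queries`, on either strand? (Window enumeration + fixed grepl.)
oracle_dna_match <- function(read, queries, m) {
  queries <- toupper(queries)
  for (s in c(read, rc(read))) {
    if (nchar(s) < m) next
    wins <- substring(s, 1:(nchar(s) - m + 1), m:nchar(s))
    for (w in wins) if (any(grepl(w, queries, fixed = TRUE))) return(TRUE)
  }
  FALSE
}

# Six-frame translations of a read, split at stops and ambiguous residues.
oracle_translations <- function(read) {
  out <- character()
  for (s in c(read, rc(read))) {
    for (f in 0:2) {
      n <- nchar(s) - f
      n <- n - n %% 3
      if (n < 3) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1, f + n)),
        if.fuzzy.codon = "X"))
      out <- c(out, strsplit(aa, "[*X]")[[1]])
    }
  }
  out[nchar(out) > 0]
}

# Does the read share an exact >= m aa substring with the protein probe in
# any reading frame?
oracle_prot_match <- function(read, probe, m) {
  for (t in oracle_translations(read)) {
    if (nchar(t) < m) next
    wins <- substring(t, 1:(nchar(t) - m + 1), m:nchar(t))
    for (w in wins) if (grepl(w, probe, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# Greedy overlap-merge assembler: repeatedly merge the pair of sequences
# (either orientation) with the longest exact suffix/prefix overlap of at
# least min_ov bases.
oracle_overlap <- function(a, b) {
  max_ov <- 0
  for (o in seq_len(min(nchar(a), nchar(b)) - 1)) {
    if (substr(a, nchar(a) - o + 1, nchar(a)) == substr(b, 1, o)) max_ov <- o
  }
  max_ov
}

oracle_merge_assemble <- function(reads, min_ov) {
  seqs <- unique(toupper(reads))
  repeat {
    best <- NULL
    n <- length(seqs)
    if (n < 2) break
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (ai in c(seqs[[i]], rc(seqs[[i]]))) for (bi in c(seqs[[j]], rc(seqs[[j]]))) {
        ov <- oracle_overlap(ai, bi)
        if (ov >= min_ov && (is.null(best) || ov > best$ov)) {
          best <- list(i = i, j = j, ov = ov,
                       merged = paste0(ai, substr(bi, ov + 1, nchar(bi))))
        }
      }
    }
    if (is.null(best)) break
    seqs <- c(seqs[-c(best$i, best$j)], best$merged)
  }
  sort(unname(vapply(seqs, canonical_seq, "")))
}

# Exhaustive DUST oracle: score every window of length min(window, n)
# directly from a triplet table; mask positions of windows scoring above
# level/10; merge masked intervals separated by <= linker.
oracle_dust <- function(seq, window = 64, level = 20, linker = 1) {
  n <- nchar(seq)
  w <- min(window, n)
  if (w < 4) return(seq)
  up <- toupper(seq)
  masked <- logical(n)
  for (i in 1:(n - w + 1)) {
    win <- substr(up, i, i + w - 1)
    trips <- substring(win, 1:(w - 2), 3:w)
    trips <- trips[!grepl("[^ACGT]", trips)]
    cnt <- table(trips)
    score <- sum(cnt * (cnt - 1) / 2) / (w - 3)
    if (score > level / 10) masked[i:(i + w - 1)] <- TRUE
  }
  # merge intervals within linker
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      if (iv[k, 1] - iv[k - 1, 2] - 1 <= linker) masked[iv[k - 1, 2]:iv[k, 1]] <- TRUE
    }
  }
  ch <- strsplit(seq, "")[[1]]
  ch[masked] <- tolower(ch[masked])
  paste(ch, collapse = "")
}

# write a seq_set to a temporary FASTA/FASTQ and return the path
tmp_fasta <- function(records, dir = tempdir()) {
  f <- tempfile("seqs_", tmpdir = dir, fileext = ".fasta")
  write_sequences(records, f)
  f
}

tmp_fastq <- function(ids, seqs, quals = NULL, dir = tempdir()) {
  f <- tempfile("reads_", tmpdir = dir, fileext = ".fastq")
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), f)
  f
}

# small indexed store over explicit read sequences (single- or paired-end)
make_store <- function(seqs1, seqs2 = NULL, split_size = 500000L,
                       ids1 = sprintf("r%03d", seq_along(seqs1)),
                       ids2 = ids1, with_prot = TRUE) {
  f1 <- tmp_fastq(ids1, seqs1)
  lib <- list(file1 = f1)
  if (!is.null(seqs2)) lib$file2 <- tmp_fastq(ids2, seqs2)
  store <- preprocess(list(lib), split_size = split_size,
                      prep_dir = tempfile("prep_"))
  build_index(store, with_prot = with_prot)
}

# random codon CDS (no internal stops) and its protein
random_cds <- function(n_codons) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  ok <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cds <- paste(c("ATG", sample(ok, n_codons - 1, replace = TRUE)),
               collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  list(cds = cds, protein = prot)
}
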