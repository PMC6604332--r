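test_that("preprocessing splits reads into ceiling(n/size) chunks", {
  set.seed(11)
  seqs <- vapply(rep(70, 12), random_dna, "")
  f <- tmp_fastq(sprintf("r%02d", 1:12), seqs)
  store <- preprocess(list(list(file1 = f)), split_size = 5L,
                      prep_dir = tempfile())
  expect_equal(nrow(store$chunks), 3L)
  expect_equal(store$chunks$n, c(5L, 5L, 2L))
  expect_equal(store$chunks$base, c(0L, 5L, 10L))
})

test_that("paired files of unequal length are rejected", {
  set.seed(12)
  f1 <- tmp_fastq(sprintf("p%d", 1:10), vapply(rep(70, 10), random_dna, ""))
  f2 <- tmp_fastq(sprintf("p%d", 1:9), vapply(rep(70, 9), random_dna, ""))
  expect_error(preprocess(list(list(file1 = f1, file2 = f2)),
                          prep_dir = tempfile()),
               "unequal")
})

test_that("rerunning on the same inputs reuses persisted chunks", {
  set.seed(13)
  f <- tmp_fastq(sprintf("r%02d", 1:8), vapply(rep(70, 8), random_dna, ""))
  prep <- tempfile()
  s1 <- preprocess(list(list(file1 = f)), split_size = 4L, prep_dir = prep)
  chunk_files <- file.path(prep, s1$chunks$file)
  mt <- file.mtime(chunk_files)
  Sys.sleep(1.2)
  s2 <- preprocess(list(list(file1 = f)), split_size = 4L, prep_dir = prep)
  expect_equal(s2$chunks$chunk_id, s1$chunks$chunk_id)
  expect_equal(file.mtime(chunk_files), mt) # not rewritten
})

test_that("DNA postings cover both strands (L - k + 1 per strand)", {
  idx <- chunk_index("ACGTACGTACGTACG", k_dna = 12L, k_prot = 4L)
  expect_equal(index_posting_count(idx, "dna"), 8) # 4 forward + 4 reverse
  p <- kmer_postings(idx, "ACGTACGTACGT", "dna")
  expect_true(all(p$read == 1))
  expect_setequal(p$strand, c("+", "-"))
})

test_that("protein postings slide over frame translations", {
  # frame +1 of ATG GCT ATG GCA CCT AAA is MAMAPK
  idx <- chunk_index("ATGGCTATGGCACCTAAA", k_dna = 11L, k_prot = 4L)
  for (km in c("MAMA", "AMAP", "MAPK")) {
    p <- kmer_postings(idx, km, "prot")
    expect_true(any(p$frame == 1L), info = km)
  }
  expect_equal(kmer_postings(idx, "MAMA", "prot")$offset[1], 0L)
})

test_that("no protein posting spans an in-frame stop codon", {
  # frame +1: M K * K L M A V (stop after 2 residues)
  read <- paste0("ATGAAA", "TGA", "AAACTTATGGCTGTT")
  idx <- chunk_index(read, k_dna = 11L, k_prot = 4L)
  expect_equal(nrow(kmer_postings(idx, "MKKL", "prot")), 0L)
  p <- kmer_postings(idx, "KLMA", "prot")
  expect_true(any(p$frame == 1L)) # after the stop, windows resume
})

test_that("index postings verify against direct substring lookup", {
  set.seed(14)
  reads <- vapply(rep(70, 30), random_dna, "")
  idx <- chunk_index(reads, k_dna = 15L, k_prot = 5L)
  for (space in c("dna", "prot")) {
    total <- index_posting_count(idx, space)
    for (j in sample(total, 100)) {
      p <- index_posting_at(idx, j, space)
      if (space == "dna") {
        s <- if (p$strand == "+") reads[p$read] else rc(reads[p$read])
        expect_equal(substr(s, p$offset + 1, p$offset + 15), p$kmer)
      } else {
        s <- if (p$frame > 0) reads[p$read] else rc(reads[p$read])
        f <- abs(p$frame)
        n <- nchar(s) - f + 1
        n <- n - n %% 3
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(s, f, f + n - 1)),
          if.fuzzy.codon = "X"))
        expect_equal(substr(aa, p$offset + 1, p$offset + 5), p$kmer)
      }
    }
  }
})

test_that("a query containing an exact 30-mer of a read recruits it", {
  set.seed(15)
  reads <- vapply(rep(70, 20), random_dna, "")
  store <- make_store(reads)
  query <- seq_set(id = "q", seq = paste0(random_dna(50),
                                          substr(reads[7], 20, 49),
                                          random_dna(50)),
                   alphabet = "dna")
  hits <- find_matching_reads(store, query)
  expect_true(7L %in% hits)
})

test_that("matcher equals brute-force common-substring search (DNA)", {
  set.seed(16)
  reads <- vapply(rep(70, 60), random_dna, "")
  # plant shared substrings of assorted lengths and strands
  contig <- random_dna(400)
  for (i in 1:12) {
    len <- sample(25:45, 1)
    frag <- substr(contig, i * 30, i * 30 + len - 1)
    if (i %% 2 == 0) frag <- rc(frag)
    pos <- sample(70 - len, 1)
    substr(reads[i], pos, pos + len - 1) <- frag
  }
  store <- make_store(reads, with_prot = FALSE)
  queries <- seq_set(id = "c", seq = contig, alphabet = "dna")
  got <- find_matching_reads(store, queries, min_match_dna = 30L)
  want <- which(vapply(reads, oracle_dna_match, NA, queries = contig, m = 30))
  expect_equal(got, as.integer(want))
})

test_that("matcher equals brute-force six-frame search (protein)", {
  set.seed(17)
  probe_aa <- random_cds(60)$protein
  reads <- vapply(rep(70, 40), random_dna, "")
  # residues 10..19 of the probe encoded in frame -2 of read 3, plus a
  # few other planted frames
  enc <- function(aa) {
    gc <- Biostrings::GENETIC_CODE
    paste(vapply(strsplit(aa, "")[[1]],
                 function(a) sample(names(gc)[gc == a], 1), ""),
          collapse = "")
  }
  plant <- function(read, aa, frame) {
    nt <- enc(aa)
    if (frame < 0) nt <- rc(nt)
    pos <- abs(frame) + 3
    substr(read, pos, pos + nchar(nt) - 1) <- nt
    read
  }
  reads[3] <- plant(reads[3], substr(probe_aa, 10, 19), -2L)
  reads[8] <- plant(reads[8], substr(probe_aa, 25, 36), 1L)
  reads[12] <- plant(reads[12], substr(probe_aa, 40, 48), 3L) # only 9 aa
  store <- make_store(reads)
  probe <- seq_set(id = "p", seq = probe_aa, alphabet = "protein")
  got <- find_matching_reads(store, probe, min_match_prot = 10L)
  want <- which(vapply(reads, oracle_prot_match, NA, probe = probe_aa, m = 10))
  expect_true(3L %in% got)
  expect_equal(got, as.integer(want))
})

test_that("lowercase-masked query regions contribute no seeds", {
  set.seed(18)
  reads <- vapply(rep(70, 10), random_dna, "")
  shared <- substr(reads[4], 10, 49) # 40 bp shared with read 4
  store <- make_store(reads, with_prot = FALSE)
  q_masked <- seq_set(id = "qm", seq = paste0(random_dna(30),
                                              tolower(shared),
                                              random_dna(30)),
                      alphabet = "dna")
  expect_false(4L %in% find_matching_reads(store, q_masked))
  # a seed outside the masked region may extend across it
  q_half <- q_masked
  q_half$seq <- paste0(random_dna(30), tolower(substr(shared, 1, 20)),
                       substr(shared, 21, 40), random_dna(30))
  expect_true(4L %in% find_matching_reads(store, q_half))
})

test_that("min_match below the index k is a configuration error", {
  store <- make_store(vapply(rep(70, 3), random_dna, ""))
  q <- seq_set(id = "q", seq = random_dna(100), alphabet = "dna")
  expect_error(find_matching_reads(store, q, min_match_dna = 10L),
               "min_match")
})

test_that("complete_pairs closes mates, is idempotent and monotone", {
  set.seed(19)
  s1 <- vapply(rep(70, 6), random_dna, "")
  s2 <- vapply(rep(70, 6), random_dna, "")
  store <- make_store(s1, s2)
  # found = mate 1 of pair 5 only (global id 5)
  out <- complete_pairs(store, 5L)
  expect_equal(out, c(5L, 11L))
  expect_equal(complete_pairs(store, out), out) # idempotent
  out2 <- complete_pairs(store, c(2L, 5L))
  expect_true(all(out %in% out2)) # monotone
  # single-end store is unaffected
  sngl <- make_store(s1)
  expect_equal(complete_pairs(sngl, 3L), 3L)
})
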