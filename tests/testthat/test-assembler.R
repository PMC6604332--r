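test_that("graph building counts canonical k-mers from both strands", {
  set.seed(21)
  r <- random_dna(50)
  g <- build_graph(r, 15L)
  st <- graph_stats(g)
  expect_equal(st$n_occurrences, 36) # L - k + 1
  kms <- graph_kmers(g)
  expect_true(all(vapply(kms, function(km) graph_coverage(g, km), 0) == 1))

  # adding the exact reverse complement doubles coverage, same nodes
  g2 <- build_graph(c(r, rc(r)), 15L)
  expect_equal(graph_kmers(g2), kms)
  expect_true(all(vapply(kms, function(km) graph_coverage(g2, km), 0) == 2))
})

test_that("a homopolymer collapses to a single self-looping node", {
  g <- build_graph(strrep("A", 20), 15L)
  expect_equal(graph_stats(g)$n_nodes, 1)
  expect_equal(graph_coverage(g, strrep("A", 15)), 6)
})

test_that("k-mers containing N are excluded and short reads give empty graphs", {
  g <- build_graph(paste0(strrep("ACGTC", 3), "N", strrep("GGACT", 3)), 31L)
  expect_equal(graph_stats(g)$n_nodes, 0)
  expect_equal(nrow(unitigs(g, min_len = 1L)), 0L)
  expect_error(build_graph("ACGT", 14L), "odd")
})

test_that("simplify leaves a branch-free linear graph unchanged", {
  set.seed(22)
  r <- random_dna(300)
  g <- build_graph(r, 15L)
  n0 <- graph_stats(g)$n_nodes
  simplify_graph(g)
  expect_equal(graph_stats(g)$n_nodes, n0)
  expect_equal(unitigs(g, 1L)$seq, canonical_seq(r))
})

test_that("low-coverage end-mismatch tips are clipped", {
  set.seed(23)
  r <- random_dna(70)
  bad <- r
  substr(bad, 68, 68) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, 68, 68))[1]
  g <- build_graph(c(rep(r, 10), bad), 15L)
  expect_gt(length(unitigs(g, 1L)$seq), 1L)
  simplify_graph(g)
  expect_equal(unitigs(g, 1L)$seq, canonical_seq(r))
})

test_that("a single-SNP bubble collapses to the majority path", {
  set.seed(24)
  tmpl <- random_dna(200)
  v <- tmpl
  substr(v, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tmpl, 100, 100))[1]
  starts <- seq(1, 131, by = 10)
  reads <- c(rep(substring(tmpl, starts, starts + 69), 9),
             substring(v, starts, starts + 69))
  g <- build_graph(reads, 15L)
  simplify_graph(g)
  expect_equal(unitigs(g, 1L)$seq, canonical_seq(tmpl))
})

test_that("unitigs equal a brute-force overlap-merge oracle", {
  reads <- c("ACGTACGTGGATCCA", "CGTGGATCCATTGCA")
  g <- build_graph(reads, 11L)
  got <- unitigs(g, min_len = 1L)$seq
  expect_equal(sort(got), oracle_merge_assemble(reads, min_ov = 10))
  expect_equal(got, canonical_seq("ACGTACGTGGATCCATTGCA"))

  # a larger random fixture: tile a template into overlapping reads
  set.seed(25)
  tmpl <- random_dna(400)
  starts <- seq(1, 331, by = 20)
  reads2 <- substring(tmpl, starts, starts + 69)
  reads2[c(3, 7)] <- vapply(reads2[c(3, 7)], rc, "") # orientation-mixed
  g2 <- build_graph(reads2, 21L)
  expect_equal(sort(unitigs(g2, 1L)$seq),
               oracle_merge_assemble(reads2, min_ov = 20))
})

test_that("contigs below min_len are dropped", {
  set.seed(26)
  g <- build_graph(random_dna(199), 15L)
  expect_equal(nrow(unitigs(g, min_len = 200L)), 0L)
  expect_equal(nchar(unitigs(g, min_len = 1L)$seq), 199L)
})

test_that("unitig output is deterministic and sorted", {
  set.seed(27)
  reads <- vapply(rep(70, 40), random_dna, "")
  u1 <- unitigs(build_graph(reads, 15L), 1L)$seq
  u2 <- unitigs(build_graph(sample(reads), 15L), 1L)$seq
  expect_identical(u1, u2)
  len <- nchar(u1)
  expect_true(all(diff(len) <= 0))
})

test_that("every contig k-mer occurs in the read pool", {
  set.seed(28)
  tmpl <- random_dna(500)
  starts <- seq(1, 431, by = 7)
  reads <- substring(tmpl, starts, starts + 69)
  g <- build_graph(reads, 21L)
  simplify_graph(g)
  ctg <- unitigs(g, 1L)$seq[1]
  g0 <- build_graph(reads, 21L) # unsimplified
  wins <- substring(ctg, 1:20, 21:40) # spot-check 20 k-mers
  expect_true(all(vapply(wins, function(w) graph_coverage(g0, w), 0) >= 1))
})

test_that("the sweep selects the only k that yields contigs", {
  set.seed(29)
  tmpl <- random_dna(300)
  starts <- seq(1, 281, by = 2)
  reads <- substring(tmpl, starts, starts + 19) # 20 bp reads: k=25+ empty
  probe <- seq_set(id = "p", seq = tmpl, alphabet = "dna")
  asm <- assemble_sweep(reads, k_list = c(15L, 25L), probe = probe,
                        min_contig = 200L, min_count = 1L)
  expect_equal(asm$k_used, 15L)
  expect_gt(asm$metric, 0)
})

test_that("metric ties go to the larger k", {
  set.seed(30)
  tmpl <- random_dna(400)
  starts <- seq(1, 331, by = 3)
  reads <- substring(tmpl, starts, starts + 69)
  probe <- seq_set(id = "p", seq = tmpl, alphabet = "dna")
  # error-free tiled reads reconstruct the template at every k
  asm <- assemble_sweep(reads, k_list = c(25L, 35L), probe = probe,
                        min_contig = 200L, min_count = 1L)
  expect_equal(asm$k_used, 35L)
})

test_that("the sweep prefers the k with the longer spliced alignment", {
  set.seed(31)
  # a repeated 20-mer fragments k=15 assemblies but not k=35
  rep20 <- random_dna(20)
  tmpl <- paste0(random_dna(150), rep20, random_dna(150), rep20,
                 random_dna(150))
  starts <- seq(1, nchar(tmpl) - 69, by = 3)
  reads <- substring(tmpl, starts, starts + 69)
  probe <- seq_set(id = "p", seq = tmpl, alphabet = "dna")
  asm <- assemble_sweep(reads, k_list = c(15L, 35L), probe = probe,
                        min_contig = 100L, min_count = 1L)
  expect_equal(asm$k_used, 35L)
  expect_equal(nrow(asm$contigs), 1L)
})

test_that("all k empty gives an empty assembly with metric 0", {
  probe <- seq_set(id = "p", seq = random_dna(100), alphabet = "dna")
  asm <- assemble_sweep(c("ACGTAGG", "CCTGAAC"), k_list = c(15L, 25L),
                        probe = probe)
  expect_equal(nrow(asm$contigs), 0L)
  expect_equal(asm$metric, 0)
})

test_that("winning contigs are DUST-masked for querying, not in reports", {
  set.seed(32)
  # aperiodic low-complexity stretch (two-letter alphabet), so the DUST
  # score is high but the k-mers stay unique
  lc <- paste(sample(c("A", "C"), 80, replace = TRUE), collapse = "")
  tmpl <- paste0(random_dna(150), lc, random_dna(150))
  starts <- seq(1, nchar(tmpl) - 69, by = 3)
  reads <- substring(tmpl, starts, starts + 69)
  probe <- seq_set(id = "p", seq = tmpl, alphabet = "dna")
  asm <- assemble_sweep(reads, k_list = c(25L), probe = probe,
                        min_contig = 200L, min_count = 1L)
  expect_false(any(grepl("[a-z]", asm$contigs$seq)))
  expect_true(any(grepl("[a-z]", asm$queries$seq)))
})

test_that("error-free tiled reads at deep coverage reconstruct the template", {
  set.seed(33)
  tmpl <- random_dna(2000)
  starts <- unique(c(seq(1, 1931, by = 3), 1931L)) # ~23X, ends included
  reads <- substring(tmpl, starts, starts + 69)
  g <- build_graph(reads, 25L)
  simplify_graph(g)
  u <- unitigs(g, min_len = 200L)
  expect_equal(nrow(u), 1L)
  expect_equal(u$seq, canonical_seq(tmpl))
})
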