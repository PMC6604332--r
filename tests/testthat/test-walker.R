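# Most tests here drive the state machine directly on small constructed
# stores; the full recursion is exercised end-to-end in test-acceptance.R.

tile_reads <- function(tmpl, step = 4, len = 70) {
  starts <- seq(1, nchar(tmpl) - len + 1, by = step)
  substring(tmpl, starts, starts + len - 1)
}

test_that("before the assembly start round, found reads are the queries", {
  set.seed(51)
  tmpl <- random_dna(600)
  reads <- tile_reads(tmpl)
  store <- make_store(reads, with_prot = FALSE)
  probe <- seq_set(id = "p", seq = substr(tmpl, 200, 400), alphabet = "dna")
  params <- walk_params(assembly_start_round = 3L)
  st <- walk_init(probe, params)
  st <- run_round(st, store, params)
  expect_true(st$query_is_reads)
  expect_null(st$last_assembly)
  expect_gt(length(st$found), 0)
  st <- run_round(st, store, params)
  expect_true(st$query_is_reads)
  expect_null(st$last_assembly)
  st <- run_round(st, store, params)
  expect_false(is.null(st$last_assembly)) # round 3 assembles
})

test_that("a round recruiting nothing leaves found unchanged and stops", {
  set.seed(52)
  store <- make_store(tile_reads(random_dna(500)), with_prot = FALSE)
  probe <- seq_set(id = "p", seq = random_dna(300), alphabet = "dna")
  params <- walk_params()
  st <- walk_init(probe, params)
  st <- run_round(st, store, params)
  expect_equal(length(st$found), 0L)
  expect_equal(st$new_read_count, 0L)
  st <- check_stop(st, params)
  expect_equal(st$stop, "no_new_reads")
})

test_that("found pool is non-decreasing and mate-closed across rounds", {
  set.seed(53)
  tmpl <- random_dna(3000)
  n <- 300
  starts <- sample(nchar(tmpl) - 209, n, replace = TRUE)
  s1 <- substring(tmpl, starts, starts + 69)
  s2 <- vapply(substring(tmpl, starts + 140, starts + 209), rc, "")
  store <- make_store(s1, s2)
  probe <- seq_set(id = "p", seq = substr(tmpl, 1400, 1600),
                   alphabet = "dna")
  params <- walk_params(max_rounds = 4L)
  st <- walk_init(probe, params)
  prev <- integer()
  for (i in 1:4) {
    if (!is.null(st$stop)) break
    st <- run_round(st, store, params)
    expect_true(all(prev %in% st$found))
    expect_equal(st$found, complete_pairs(store, st$found))
    prev <- st$found
    st <- check_stop(st, params)
  }
  expect_equal(nrow(st$history), max(st$history$round))
})

test_that("cleaning culls contigs without probe matches plus their reads", {
  set.seed(54)
  locus <- random_dna(800)
  junk <- random_dna(800)
  probe <- seq_set(id = "p", seq = substr(locus, 300, 500),
                   alphabet = "dna")
  reads <- c(tile_reads(locus, step = 10), tile_reads(junk, step = 10))
  store <- make_store(reads, with_prot = FALSE)
  params <- walk_params()
  st <- walk_init(probe, params)
  st$found <- seq_along(reads)
  asm <- assemble_sweep(reads, k_list = 25L, probe = probe,
                        min_contig = 200L, min_count = 1L)
  expect_equal(nrow(asm$contigs), 2L) # locus + junk contig
  st$last_assembly <- asm
  st$query_set <- asm$queries
  st$round <- 4L
  st2 <- clean_round(st, store, params)
  expect_equal(nrow(st2$last_assembly$contigs), 1L)
  expect_true(grepl(substr(locus, 350, 380),
                    toupper(st2$last_assembly$contigs$seq[1]), fixed = TRUE))
  # reads exclusive to the junk contig are gone, locus reads survive
  expect_lt(length(st2$found), length(reads))
  expect_true(all(st2$found <= length(tile_reads(locus, step = 10))))
})

test_that("cleaning with all contigs matching removes nothing", {
  set.seed(55)
  locus <- random_dna(700)
  probe <- seq_set(id = "p", seq = substr(locus, 200, 450),
                   alphabet = "dna")
  reads <- tile_reads(locus, step = 8)
  store <- make_store(reads, with_prot = FALSE)
  params <- walk_params()
  st <- walk_init(probe, params)
  st$found <- seq_along(reads)
  st$last_assembly <- assemble_sweep(reads, k_list = 25L, probe = probe,
                                     min_contig = 200L, min_count = 1L)
  st$round <- 4L
  st2 <- clean_round(st, store, params)
  expect_equal(nrow(st2$last_assembly$contigs),
               nrow(st$last_assembly$contigs))
  expect_equal(st2$found, st$found)
})

test_that("cleaning cadence is every four rounds or above the contig limit", {
  params <- walk_params()
  st <- walk_init(seq_set(id = "p", seq = "ACGTACGTACGT",
                          alphabet = "dna"), params)
  fake_asm <- function(n) {
    list(contigs = data.frame(id = sprintf("c%d", seq_len(n))))
  }
  st$round <- 2L
  st$last_assembly <- fake_asm(500L)
  expect_false(cleaning_due(st, params))
  st$last_assembly <- fake_asm(501L)
  expect_true(cleaning_due(st, params)) # early trigger
  st$round <- 4L
  st$last_assembly <- fake_asm(3L)
  expect_true(cleaning_due(st, params))
  st$round <- 5L
  expect_false(cleaning_due(st, params))
})

long_contig_fixture <- function(seed = 56) {
  set.seed(seed)
  region <- random_dna(1400)
  reads <- tile_reads(region, step = 4)
  store <- make_store(reads, with_prot = FALSE)
  list(region = region, reads = reads, store = store,
       params = walk_params(max_contig = 1000L, min_contig = 200L),
       probe = seq_set(id = "p", seq = substr(region, 600, 800),
                       alphabet = "dna"))
}

test_that("over-long contigs are trimmed symmetrically and retired as queries", {
  fx <- long_contig_fixture()
  st <- walk_init(fx$probe, fx$params)
  long_seq <- substr(fx$region, 101, 1300) # 1200 bp > max 1000
  short_seq <- substr(fx$region, 200, 1198) # 999 bp: under the cap
  ctg <- seq_set(id = c("big", "small"), seq = c(long_seq, short_seq),
                 alphabet = "dna")
  st$last_assembly <- list(contigs = ctg, alignments = list(NULL, NULL),
                           queries = ctg, k_used = 25L, metric = 0)
  st$query_set <- ctg
  st$round <- 1L
  st2 <- handle_long_contigs(st, fx$store, fx$params)
  expect_equal(nrow(st2$candidate_long), 1L)
  # symmetric trim: excess 200, 100 off each end
  expect_equal(st2$candidate_long$seq, substr(long_seq, 101, 1100))
  expect_equal(nchar(st2$candidate_long$seq), 1000L)
  expect_equal(st2$query_set$id, "small") # long contig removed as query
})

test_that("reassembled candidates are promoted and their reads retired", {
  fx <- long_contig_fixture()
  st <- walk_init(fx$probe, fx$params)
  st$found <- seq_along(fx$reads)
  cand <- seq_set(id = "cand", seq = substr(fx$region, 201, 1200),
                  alphabet = "dna")
  st$candidate_long <- cand
  bigger <- seq_set(id = "big2", seq = substr(fx$region, 150, 1250),
                    alphabet = "dna") # 1101 bp >= max, contains cand
  st$last_assembly <- list(contigs = bigger, alignments = list(NULL),
                           queries = bigger, k_used = 25L, metric = 0)
  st$query_set <- bigger
  st$round <- 2L
  st2 <- handle_long_contigs(st, fx$store, fx$params)
  expect_equal(st2$permanent_long$seq, cand$seq)
  expect_gt(length(st2$retired), 0)
  expect_true(all(st2$retired %in% st2$found))
  # permanent contigs never re-enter the query set
  expect_false(any(st2$query_set$seq == cand$seq))
})

hit_assembly <- function(probe, contig_seq) {
  ctg <- seq_set(id = "hitctg", seq = contig_seq, alphabet = "dna")
  list(contigs = ctg, queries = ctg, k_used = 25L, metric = 1,
       alignments = list(splice_align(probe, ctg)))
}

test_that("stopping criteria fire in the documented order", {
  set.seed(57)
  cdna <- random_dna(600)
  probe <- seq_set(id = "p", seq = cdna, alphabet = "dna")
  contig <- paste0(random_dna(100), cdna, random_dna(100))
  params <- walk_params(max_rounds = 6L)

  st <- walk_init(probe, params)
  st$round <- 2L
  st$new_read_count <- 10L
  st$last_assembly <- hit_assembly(probe, contig)
  expect_equal(check_stop(st, params)$stop, "hit")

  st$last_assembly <- NULL
  st$new_read_count <- 0L
  expect_equal(check_stop(st, params)$stop, "no_new_reads")

  st$new_read_count <- 5L
  st$round <- 6L
  expect_equal(check_stop(st, params)$stop, "max_rounds")

  # all contigs at or beyond the maximum length
  st$round <- 3L
  long <- seq_set(id = "l", seq = random_dna(10000), alphabet = "dna")
  st$last_assembly <- list(contigs = long, queries = long, k_used = 25L,
                           metric = 0,
                           alignments = list(splice_align(probe, long)))
  expect_equal(check_stop(st, params)$stop, "all_long")
})

test_that("force_max_rounds ignores hits until the round cap", {
  set.seed(58)
  cdna <- random_dna(600)
  probe <- seq_set(id = "p", seq = cdna, alphabet = "dna")
  params <- walk_params(max_rounds = 10L, force_max_rounds = TRUE)
  st <- walk_init(probe, params)
  st$round <- 3L
  st$new_read_count <- 4L
  st$last_assembly <- hit_assembly(probe, paste0(random_dna(80), cdna))
  st <- check_stop(st, params)
  expect_null(st$stop)
  st$round <- 10L
  expect_equal(check_stop(st, params)$stop, "max_rounds")
  expect_error(walk_params(force_max_rounds = TRUE, extra_rounds = 2L))
})

test_that("extra_rounds arms a countdown at the first hit", {
  set.seed(59)
  cdna <- random_dna(600)
  probe <- seq_set(id = "p", seq = cdna, alphabet = "dna")
  params <- walk_params(max_rounds = 10L, extra_rounds = 2L)
  st <- walk_init(probe, params)
  st$new_read_count <- 4L
  st$last_assembly <- hit_assembly(probe, paste0(cdna, random_dna(50)))
  st$round <- 3L
  st <- check_stop(st, params)
  expect_null(st$stop)
  expect_equal(st$hit_round, 3L)
  st$round <- 4L
  st <- check_stop(st, params)
  expect_null(st$stop)
  st$round <- 5L
  st <- check_stop(st, params)
  expect_equal(st$stop, "hit")
})

test_that("finalize splits all_contigs and hit_contigs and writes reports", {
  set.seed(60)
  cdna <- random_dna(600)
  probe <- seq_set(id = "p", seq = cdna, alphabet = "dna")
  params <- walk_params()
  st <- walk_init(probe, params)
  ctg <- seq_set(id = c("hit1", "dom1", "tiny"),
                 seq = c(paste0(random_dna(60), cdna, random_dna(60)),
                         paste0(random_dna(200),
                                substr(cdna, 100, 320), # a shared domain
                                random_dna(300)),
                         random_dna(150)), # below min_contig
                 alphabet = "dna")
  st$last_assembly <- list(contigs = ctg, queries = ctg, k_used = 25L,
                           metric = 1,
                           alignments = lapply(seq_len(3), function(i)
                             splice_align(probe, ctg[i, , drop = FALSE])))
  st$permanent_long <- seq_set(id = "perm1", seq = random_dna(10000),
                               alphabet = "dna")
  st$stop <- "hit"
  out <- tempfile()
  res <- finalize(st, params, out_dir = out)
  expect_equal(nrow(res$all_contigs), 3L) # hit1, dom1, perm1; tiny dropped
  expect_equal(res$hit_contigs$id, "hit1")
  expect_true(res$success)
  expect_true(file.exists(file.path(out, "all_contigs.fasta")))
  written <- load_sequences(file.path(out, "hit_contigs.fasta"))
  expect_equal(written$seq, res$hit_contigs$seq)
  aln <- readLines(file.path(out, "output.aln"))
  # report covers every all_contigs entry with nonzero coverage
  expect_true(any(grepl("vs hit1", aln)))
  expect_true(any(grepl("vs dom1", aln)))
})

test_that("a walk ending with nothing reports empty outputs and failure", {
  probe <- seq_set(id = "p", seq = "ACGTACGTACGTACGTACGT", alphabet = "dna")
  params <- walk_params()
  st <- walk_init(probe, params)
  st$stop <- "no_new_reads"
  res <- finalize(st, params)
  expect_equal(nrow(res$all_contigs), 0L)
  expect_equal(nrow(res$hit_contigs), 0L)
  expect_false(res$success)
})

test_that("permanent long contigs stay byte-identical through the walk", {
  fx <- long_contig_fixture(seed = 61)
  st <- walk_init(fx$probe, fx$params)
  st$found <- seq_along(fx$reads)
  perm <- seq_set(id = "perm", seq = substr(fx$region, 301, 1300),
                  alphabet = "dna")
  st$permanent_long <- perm
  for (i in 1:2) {
    st <- run_round(st, fx$store, fx$params)
    st <- handle_long_contigs(st, fx$store, fx$params)
    if (cleaning_due(st, fx$params)) st <- clean_round(st, fx$store, fx$params)
    expect_identical(st$permanent_long$seq[1], perm$seq)
    st <- check_stop(st, fx$params)
    if (!is.null(st$stop)) break
  }
  st$stop <- st$stop %||% "max_rounds"
  res <- finalize(st, fx$params)
  expect_true(perm$seq %in% res$all_contigs$seq)
})
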