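#' Walk parameters
#'
#' Defaults follow the standard workflow configuration: contigs shorter
#' than 200 bp are dropped, contigs beyond 10,000 bp are retired, a hit
#' requires spliced-alignment similarity >= 0.5 covering >= 0.8 of the
#' probe, cleaning runs every 4 rounds (or immediately above 500 contigs),
#' and the assembler sweeps k = 15, 25, 35, 45.
#'
#' @param max_rounds maximum number of recursion rounds.
#' @param min_contig minimum reported contig length (bp).
#' @param max_contig maximum contig length (bp) before retirement.
#' @param min_similarity minimum spliced-alignment similarity for a hit.
#' @param min_query_coverage minimum probe coverage fraction for a hit.
#' @param clean_period cleaning cadence in rounds.
#' @param contig_limit contig count that triggers an early clean.
#' @param k_list assembler k-mer sweep values (odd).
#' @param assembly_start_round first round that assembles found reads into
#'   contigs; before it, the found reads themselves serve as queries.
#' @param force_max_rounds ignore the hit criterion and run all rounds.
#' @param extra_rounds extra rounds to complete after the first hit.
#' @param split_size reads per preprocessing chunk.
#' @param min_match_dna minimum exact DNA match (nt) for read recruitment.
#' @param min_match_prot minimum exact translated match (aa).
#' @param k_dna,k_prot read-index k-mer sizes.
#' @param tip_len,bubble_identity graph cleanup parameters (`NULL` tip_len
#'   means `2 * k` per sweep value).
#' @param dust [dust_params()] for query masking.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(max_rounds = 10L, min_contig = 200L,
                        max_contig = 10000L, min_similarity = 0.5,
                        min_query_coverage = 0.8, clean_period = 4L,
                        contig_limit = 500L, k_list = c(15L, 25L, 35L, 45L),
                        assembly_start_round = 1L, force_max_rounds = FALSE,
                        extra_rounds = 0L, split_size = 500000L,
                        min_match_dna = 30L, min_match_prot = 10L,
                        k_dna = 15L, k_prot = 5L, tip_len = NULL,
                        bubble_identity = 0.9, dust = dust_params()) {
  stopifnot(max_contig > min_contig,
            min_similarity >= 0, min_similarity <= 1,
            min_query_coverage >= 0, min_query_coverage <= 1,
            all(k_list %% 2 == 1))
  if (force_max_rounds && extra_rounds > 0) {
    stop("force_max_rounds cannot be combined with extra_rounds")
  }
  structure(list(max_rounds = as.integer(max_rounds),
                 min_contig = as.integer(min_contig),
                 max_contig = as.integer(max_contig),
                 min_similarity = min_similarity,
                 min_query_coverage = min_query_coverage,
                 clean_period = as.integer(clean_period),
                 contig_limit = as.integer(contig_limit),
                 k_list = as.integer(k_list),
                 assembly_start_round = as.integer(assembly_start_round),
                 force_max_rounds = isTRUE(force_max_rounds),
                 extra_rounds = as.integer(extra_rounds),
                 split_size = as.integer(split_size),
                 min_match_dna = as.integer(min_match_dna),
                 min_match_prot = as.integer(min_match_prot),
                 k_dna = as.integer(k_dna), k_prot = as.integer(k_prot),
                 tip_len = tip_len, bubble_identity = bubble_identity,
                 dust = dust),
            class = "walk_params")
}

#' Initialize a walk state
#'
#' @param probe one-row [seq_set()] (protein or DNA probe).
#' @param params a [walk_params()].
#' @return A list of class `walk_state`.
#' @export
walk_init <- function(probe, params = walk_params()) {
  stopifnot(nrow(probe) == 1)
  empty <- seq_set(alphabet = "dna")
  structure(list(round = 0L, probe = probe, query_set = probe,
                 query_is_reads = FALSE, found = integer(),
                 retired = integer(), new_read_count = NA_integer_,
                 candidate_long = empty, permanent_long = empty,
                 last_assembly = NULL, stop = NULL, hit_round = NA_integer_,
                 history = NULL),
            class = "walk_state")
}

#' Execute one recursion round
#'
#' Recruits reads matching the current query set, closes the set under
#' mate inclusion, and (from `assembly_start_round` on) reassembles the
#' whole found pool, the winning masked contigs becoming the next query
#' set. Before `assembly_start_round` the found reads themselves are the
#' next queries.
#'
#' @param state a `walk_state`.
#' @param store an indexed `read_store`.
#' @param params a [walk_params()].
#' @return The updated state.
#' @export
run_round <- function(state, store, params = walk_params()) {
  stopifnot(is.null(state$stop))
  r <- state$round + 1L
  matches <- find_matching_reads(store, state$query_set,
                                 min_match_dna = params$min_match_dna,
                                 min_match_prot = params$min_match_prot)
  new <- complete_pairs(store, matches)
  truly_new <- setdiff(new, state$found)
  state$found <- sort(unique(c(state$found, new)))
  state$new_read_count <- length(truly_new)

  if (r >= params$assembly_start_round) {
    pool <- setdiff(state$found, state$retired)
    asm <- assemble_sweep(read_seqs(store, pool), k_list = params$k_list,
                          probe = state$probe,
                          min_contig = params$min_contig,
                          tip_len = params$tip_len,
                          bubble_identity = params$bubble_identity,
                          dust = params$dust,
                          contig_prefix = sprintf("r%d", r))
    state$last_assembly <- asm
    if (nrow(asm$contigs) > 0) {
      state$query_is_reads <- FALSE
      state$query_set <- asm$queries
    } else {
      # no contig survived the length filter: fall back to querying with
      # the found reads themselves so sparse early rounds can still walk
      state$query_set <- seq_set(
        id = sprintf("read%08d", state$found),
        seq = read_seqs(store, state$found), alphabet = "dna")
      state$query_is_reads <- TRUE
    }
  } else {
    state$query_set <- seq_set(
      id = sprintf("read%08d", state$found),
      seq = read_seqs(store, state$found), alphabet = "dna")
    state$query_is_reads <- TRUE
  }
  state$round <- r
  state <- append_history(state)
  state
}

append_history <- function(state) {
  asm <- state$last_assembly
  best_cov <- 0; best_sim <- 0; best_k <- NA_integer_; nctg <- 0L
  if (!is.null(asm)) {
    nctg <- nrow(asm$contigs)
    best_k <- asm$k_used
    if (length(asm$alignments) > 0) {
      best_cov <- max(vapply(asm$alignments, `[[`, numeric(1),
                             "probe_coverage"))
      best_sim <- max(vapply(asm$alignments, `[[`, numeric(1), "similarity"))
    }
  }
  row <- data.frame(round = state$round, reads_found = length(state$found),
                    new_reads = state$new_read_count, contigs = nctg,
                    best_k = best_k, best_coverage = best_cov,
                    best_similarity = best_sim, stringsAsFactors = FALSE)
  state$history <- rbind(state$history, row)
  state
}

#' Is a cleaning round due?
#'
#' Cleaning triggers every `clean_period` rounds, or immediately when the
#' current contig count exceeds `contig_limit`.
#'
#' @inheritParams run_round
#' @return `TRUE` or `FALSE`.
#' @export
cleaning_due <- function(state, params = walk_params()) {
  nctg <- if (is.null(state$last_assembly)) 0L else
    nrow(state$last_assembly$contigs)
  (state$round > 0 && state$round %% params$clean_period == 0L) ||
    nctg > params$contig_limit
}

#' Cull non-matching contigs and reads
#'
#' Contigs without at least a partial match to the original probe (same
#' matcher as recruitment, with the minimum match length halved) are
#' discarded; found reads that match none of the surviving contigs (nor a
#' permanent long contig) are then discarded, and mate closure is
#' re-applied.
#'
#' @inheritParams run_round
#' @return The updated state.
#' @export
clean_round <- function(state, store, params = walk_params()) {
  asm <- state$last_assembly
  if (is.null(asm) || nrow(asm$contigs) == 0) return(state)
  half_dna <- max(params$k_dna, params$min_match_dna %/% 2L)
  half_prot <- max(params$k_prot, params$min_match_prot %/% 2L)
  is_prot <- state$probe$alphabet == "protein"
  cidx <- chunk_index(toupper(asm$contigs$seq), k_dna = params$k_dna,
                      k_prot = params$k_prot, with_prot = is_prot)
  keep <- cpp_chunk_search(cidx$ptr, state$probe$seq, state$probe$alphabet,
                           half_dna, half_prot)
  if (length(keep) < nrow(asm$contigs)) {
    asm$contigs <- asm$contigs[keep, , drop = FALSE]
    asm$alignments <- asm$alignments[keep]
    asm$queries <- asm$queries[keep, , drop = FALSE]
    state$last_assembly <- asm
    if (!state$query_is_reads) {
      state$query_set <- if (nrow(asm$queries) > 0) asm$queries else
        state$probe
    }
    if (nrow(asm$contigs) == 0) {
      # all contigs culled: keep the probe as query so the walk can re-seed
      state$query_set <- state$probe
    }
  }
  targets <- c(toupper(asm$contigs$seq), toupper(state$permanent_long$seq))
  if (length(targets) == 0 || length(state$found) == 0) return(state)
  ridx <- chunk_index(read_seqs(store, state$found), k_dna = params$k_dna,
                      k_prot = params$k_prot, with_prot = FALSE)
  kept <- cpp_chunk_search(ridx$ptr, targets, rep("dna", length(targets)),
                           params$min_match_dna, params$min_match_prot)
  state$found <- complete_pairs(store, state$found[kept])
  state$retired <- intersect(state$retired, state$found)
  state
}

#' Retire over-long contigs
#'
#' Contigs longer than `max_contig` are removed from the query set and a
#' symmetrically trimmed copy (excess/2 off each end, the extra base off
#' the tail for odd excess) becomes a candidate long contig. A candidate
#' whose sequence is reassembled in the next round (contained, in either
#' orientation, in a new contig of at least `max_contig` bp) is promoted
#' to a permanent long contig; reads matching permanent long contigs are
#' removed from the assembly pool and the permanent contigs never serve
#' as queries again, but are included in the final output.
#'
#' @inheritParams run_round
#' @return The updated state.
#' @export
handle_long_contigs <- function(state, store, params = walk_params()) {
  asm <- state$last_assembly
  if (is.null(asm) || nrow(asm$contigs) == 0) return(state)
  len <- nchar(asm$contigs$seq)

  # promotion of last round's candidates against this round's long contigs
  if (nrow(state$candidate_long) > 0) {
    targets <- toupper(asm$contigs$seq[len >= params$max_contig])
    promoted <- vapply(seq_len(nrow(state$candidate_long)), function(i) {
      s <- toupper(state$candidate_long$seq[i])
      any(vapply(targets, function(t)
        grepl(s, t, fixed = TRUE) || grepl(revcomp_chr(s), t, fixed = TRUE),
        NA))
    }, NA)
    if (any(promoted)) {
      promo <- state$candidate_long[promoted, , drop = FALSE]
      state$permanent_long <- rbind(state$permanent_long, promo)
      pool <- setdiff(state$found, state$retired)
      if (length(pool) > 0) {
        ridx <- chunk_index(read_seqs(store, pool), k_dna = params$k_dna,
                            k_prot = params$k_prot, with_prot = FALSE)
        hit <- cpp_chunk_search(ridx$ptr, toupper(promo$seq),
                                rep("dna", nrow(promo)),
                                params$min_match_dna, params$min_match_prot)
        state$retired <- sort(unique(c(state$retired, pool[hit])))
      }
    }
  }

  # retire this round's over-long contigs from the query set
  long <- len > params$max_contig
  if (any(long)) {
    trimmed <- asm$contigs[long, , drop = FALSE]
    excess <- nchar(trimmed$seq) - params$max_contig
    head_off <- excess %/% 2L
    trimmed$seq <- substr(trimmed$seq, head_off + 1L,
                          head_off + params$max_contig)
    trimmed$id <- paste0(trimmed$id, "_trim")
    state$candidate_long <- trimmed
    keep_ids <- asm$contigs$id[!long]
    state$query_set <- state$query_set[state$query_set$id %in% keep_ids, ,
                                       drop = FALSE]
    if (nrow(state$query_set) == 0 && !state$query_is_reads &&
        !all(long)) {
      state$query_set <- state$probe
    }
  } else {
    state$candidate_long <- seq_set(alphabet = "dna")
  }
  state
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Evaluate the stopping criteria
#'
#' In order: (1) a hit contig exists (ignored under `force_max_rounds`;
#' with `extra_rounds > 0` the first hit arms a countdown instead);
#' (2) the round recruited no new reads; (3) the round cap is reached;
#' (4) every assembled contig reached the maximum length.
#'
#' @inheritParams run_round
#' @return The state, with `stop` possibly set to one of `"hit"`,
#'   `"no_new_reads"`, `"max_rounds"`, `"all_long"`.
#' @export
check_stop <- function(state, params = walk_params()) {
  asm <- state$last_assembly
  hit <- FALSE
  if (!is.null(asm) && length(asm$alignments) > 0) {
    hit <- any(vapply(seq_along(asm$alignments), function(i) {
      is_hit(asm$alignments[[i]], nchar(asm$contigs$seq[i]),
             min_len = params$min_contig, min_sim = params$min_similarity,
             min_cov = params$min_query_coverage)
    }, NA))
  }
  if (hit && !params$force_max_rounds) {
    if (params$extra_rounds == 0L) {
      state$stop <- "hit"
      return(state)
    }
    if (is.na(state$hit_round)) state$hit_round <- state$round
  }
  if (!is.na(state$hit_round) &&
      state$round >= state$hit_round + params$extra_rounds) {
    state$stop <- "hit"
    return(state)
  }
  if (isTRUE(state$new_read_count == 0L)) {
    state$stop <- "no_new_reads"
    return(state)
  }
  cap <- params$max_rounds +
    if (!is.na(state$hit_round)) params$extra_rounds else 0L
  if (state$round >= cap) {
    state$stop <- "max_rounds"
    return(state)
  }
  if (!is.null(asm) && nrow(asm$contigs) > 0 &&
      all(nchar(asm$contigs$seq) >= params$max_contig)) {
    state$stop <- "all_long"
  }
  state
}

#' Produce the final outputs of a walk
#'
#' `all_contigs` holds the final-round contigs of at least `min_contig` bp
#' plus any permanent long contigs; `hit_contigs` is the subset passing
#' [is_hit()]; the alignment report covers every `all_contigs` entry with
#' nonzero probe coverage.
#'
#' @param state a stopped `walk_state`.
#' @param params a [walk_params()].
#' @param out_dir if non-`NULL`, `all_contigs.fasta`, `hit_contigs.fasta`,
#'   `output.aln`, `output.gff3` and `history.tsv` are written there.
#' @return A list of class `walk_result`: `all_contigs`, `hit_contigs`
#'   ([seq_set()]s), `alignments`, `history`, `stop`, `success`.
#' @export
finalize <- function(state, params = walk_params(), out_dir = NULL) {
  stopifnot(!is.null(state$stop))
  asm <- state$last_assembly
  contigs <- if (is.null(asm)) seq_set(alphabet = "dna") else asm$contigs
  alns <- if (is.null(asm)) list() else asm$alignments
  keep <- nchar(contigs$seq) >= params$min_contig
  contigs <- contigs[keep, , drop = FALSE]
  alns <- alns[keep]
  if (nrow(state$permanent_long) > 0) {
    contigs <- rbind(contigs, state$permanent_long)
    alns <- c(alns, lapply(seq_len(nrow(state$permanent_long)), function(i) {
      splice_align(state$probe, seq_record(state$permanent_long, i))
    }))
  }
  hit <- vapply(seq_along(alns), function(i) {
    is_hit(alns[[i]], nchar(contigs$seq[i]), min_len = params$min_contig,
           min_sim = params$min_similarity,
           min_cov = params$min_query_coverage)
  }, NA)
  if (length(hit) == 0) hit <- logical()
  res <- structure(list(all_contigs = contigs,
                        hit_contigs = contigs[hit, , drop = FALSE],
                        alignments = alns, history = state$history,
                        stop = state$stop, success = any(hit)),
                   class = "walk_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sequences(res$all_contigs, file.path(out_dir, "all_contigs.fasta"))
    write_sequences(res$hit_contigs, file.path(out_dir, "hit_contigs.fasta"))
    nz <- Filter(function(a) a$probe_coverage > 0, alns)
    write_aln_report(nz, file.path(out_dir, "output.aln"))
    write_gff3(Filter(function(a) nrow(a$blocks) > 0, alns),
               file.path(out_dir, "output.gff3"))
    if (!is.null(res$history)) {
      write.table(res$history, file.path(out_dir, "history.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("walk finished (stop=%s): %d contig(s), %d hit(s)\n",
              x$stop, nrow(x$all_contigs), nrow(x$hit_contigs)))
  invisible(x)
}

#' Run a complete in silico chromosome walk
#'
#' Drives the full recursion: preprocessing/indexing (unless an indexed
#' store is supplied), rounds of read recruitment and reassembly,
#' long-contig retirement, periodic cleaning, stopping criteria, and
#' final output.
#'
#' @param probe a one-row [seq_set()] or path to a FASTA file with the
#'   probe (protein or DNA).
#' @param libraries library specifications (see [preprocess()]); ignored
#'   when `store` is given.
#' @param store an indexed `read_store` to reuse.
#' @param params a [walk_params()].
#' @param out_dir optional output directory (see [finalize()]).
#' @param prep_dir preprocessing directory (default: a session temporary
#'   directory).
#' @param verbose print a per-round progress line.
#' @return A `walk_result` (see [finalize()]).
#' @export
sr_walk <- function(probe, libraries = NULL, store = NULL,
                    params = walk_params(), out_dir = NULL,
                    prep_dir = NULL, verbose = FALSE) {
  if (is.character(probe)) probe <- load_sequences(probe)
  probe <- seq_record(probe, 1L)
  if (is.null(store)) {
    if (is.null(prep_dir)) prep_dir <- tempfile("srwalk_prep_")
    store <- preprocess(libraries, split_size = params$split_size,
                        prep_dir = prep_dir)
  }
  if (is.null(store$indexes)) {
    store <- build_index(store, k_dna = params$k_dna, k_prot = params$k_prot,
                         with_prot = probe$alphabet == "protein")
  }
  state <- walk_init(probe, params)
  while (is.null(state$stop)) {
    state <- run_round(state, store, params)
    state <- handle_long_contigs(state, store, params)
    if (cleaning_due(state, params)) {
      state <- clean_round(state, store, params)
    }
    state <- check_stop(state, params)
    if (verbose) {
      h <- tail(state$history, 1)
      message(sprintf(
        "round %d: %d reads (+%d), %d contig(s), best k=%s, cov=%.2f, sim=%.2f%s",
        h$round, h$reads_found, h$new_reads, h$contigs,
        ifelse(is.na(h$best_k), "-", h$best_k), h$best_coverage,
        h$best_similarity,
        if (!is.null(state$stop)) paste0(" [stop=", state$stop, "]") else ""))
    }
  }
  finalize(state, params, out_dir = out_dir)
}
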