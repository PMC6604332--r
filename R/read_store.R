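#' Preprocess read libraries into persisted chunks
#'
#' Reads are loaded (FASTA or FASTQ), uppercased, stripped of qualities and
#' split into chunks which are persisted as FASTA files plus a plain-text
#' manifest, so a rerun on the same inputs can skip this step. For a
#' paired-end library the two mate files must hold the same number of
#' reads in matched order; a chunk then stores a block of mate-1 reads
#' followed by the corresponding block of mate-2 reads, holding at most
#' `split_size` reads in total.
#'
#' @param library_specs a list of library specifications; each is a list
#'   with `file1`, optional `file2` (paired) and optional `insert_size`.
#'   A plain character vector is taken as single-end libraries.
#' @param split_size maximum reads per chunk (default 500000).
#' @param prep_dir directory for the persisted chunks and manifest.
#' @param force re-run preprocessing even if a matching manifest exists.
#' @return A `read_store` object (not yet indexed; see [build_index()]).
#' @export
preprocess <- function(library_specs, split_size = 500000L, prep_dir,
                       force = FALSE) {
  specs <- normalize_library_specs(library_specs)
  dir.create(prep_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(prep_dir, "manifest.tsv")
  if (!force && file.exists(manifest_path)) {
    store <- try(load_read_store(prep_dir), silent = TRUE)
    if (!inherits(store, "try-error") &&
        manifest_matches(store, specs, split_size)) {
      return(store)
    }
  }
  chunks <- NULL
  lib_rows <- NULL
  base <- 0L
  chunk_id <- 0L
  for (li in seq_along(specs)) {
    sp <- specs[[li]]
    r1 <- load_sequences(sp$file1)
    if (any(r1$alphabet != "dna")) stop("reads must be DNA: ", sp$file1)
    paired <- !is.null(sp$file2)
    if (paired) {
      r2 <- load_sequences(sp$file2)
      if (nrow(r1) != nrow(r2)) {
        stop("paired files have unequal read counts (", nrow(r1), " vs ",
             nrow(r2), "): ", sp$file1, ", ", sp$file2)
      }
      per <- max(1L, split_size %/% 2L)
    } else {
      per <- max(1L, as.integer(split_size))
    }
    n_units <- nrow(r1)
    n_chunks <- max(1L, as.integer(ceiling(n_units / per)))
    for (ci in seq_len(n_chunks)) {
      lo <- (ci - 1L) * per + 1L
      hi <- min(ci * per, n_units)
      if (lo > hi) break
      if (paired) {
        recs <- rbind(r1[lo:hi, , drop = FALSE], r2[lo:hi, , drop = FALSE])
        m <- hi - lo + 1L
      } else {
        recs <- r1[lo:hi, , drop = FALSE]
        m <- 0L
      }
      recs$seq <- toupper(recs$seq)
      recs$qual <- NA_character_
      fn <- sprintf("chunk_%04d.fasta", chunk_id)
      write_sequences(recs, file.path(prep_dir, fn))
      chunks <- rbind(chunks, data.frame(
        library = li, chunk_id = chunk_id, file = fn, n = nrow(recs),
        m = m, base = base, stringsAsFactors = FALSE))
      base <- base + nrow(recs)
      chunk_id <- chunk_id + 1L
    }
    lib_rows <- rbind(lib_rows, data.frame(
      library = li, file1 = normalizePath(sp$file1),
      file2 = if (paired) normalizePath(sp$file2) else NA_character_,
      insert_size = if (is.null(sp$insert_size)) NA_integer_ else
        as.integer(sp$insert_size),
      size1 = file.size(sp$file1),
      size2 = if (paired) file.size(sp$file2) else NA_real_,
      stringsAsFactors = FALSE))
  }
  store <- structure(list(prep_dir = normalizePath(prep_dir),
                          split_size = as.integer(split_size),
                          libraries = lib_rows, chunks = chunks,
                          indexes = NULL, k_dna = NA_integer_,
                          k_prot = NA_integer_, with_prot = FALSE),
                     class = "read_store")
  save_manifest(store)
  store
}

normalize_library_specs <- function(library_specs) {
  if (is.character(library_specs)) {
    library_specs <- lapply(library_specs, function(f) list(file1 = f))
  }
  if (!is.null(library_specs$file1)) library_specs <- list(library_specs)
  lapply(library_specs, function(sp) {
    stopifnot(!is.null(sp$file1))
    if (!file.exists(sp$file1)) stop("file not found: ", sp$file1)
    if (!is.null(sp$file2) && !file.exists(sp$file2)) {
      stop("file not found: ", sp$file2)
    }
    sp
  })
}

save_manifest <- function(store) {
  path <- file.path(store$prep_dir, "manifest.tsv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# srwalk read-store manifest; split_size=",
                    store$split_size), con)
  writeLines("## libraries", con)
  write.table(store$libraries, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines("## chunks", con)
  write.table(store$chunks, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a persisted read store from its preprocessing directory
#'
#' @param prep_dir directory previously populated by [preprocess()].
#' @return A `read_store` (not indexed).
#' @export
load_read_store <- function(prep_dir) {
  path <- file.path(prep_dir, "manifest.tsv")
  if (!file.exists(path)) stop("no manifest in ", prep_dir)
  lines <- readLines(path)
  split_size <- as.integer(sub(".*split_size=", "", lines[1]))
  li <- which(lines == "## libraries")
  ci <- which(lines == "## chunks")
  libs <- read.delim(text = lines[(li + 1):(ci - 1)], stringsAsFactors = FALSE)
  chunks <- read.delim(text = lines[(ci + 1):length(lines)],
                       stringsAsFactors = FALSE)
  missing <- !file.exists(file.path(prep_dir, chunks$file))
  if (any(missing)) stop("chunk file missing: ", chunks$file[which(missing)[1]])
  structure(list(prep_dir = normalizePath(prep_dir), split_size = split_size,
                 libraries = libs, chunks = chunks, indexes = NULL,
                 k_dna = NA_integer_, k_prot = NA_integer_,
                 with_prot = FALSE),
            class = "read_store")
}

manifest_matches <- function(store, specs, split_size) {
  if (store$split_size != split_size) return(FALSE)
  if (nrow(store$libraries) != length(specs)) return(FALSE)
  for (li in seq_along(specs)) {
    sp <- specs[[li]]
    row <- store$libraries[li, ]
    if (normalizePath(sp$file1) != row$file1) return(FALSE)
    if (!identical(file.size(sp$file1), row$size1)) return(FALSE)
    paired <- !is.null(sp$file2)
    if (paired != !is.na(row$file2)) return(FALSE)
    if (paired && normalizePath(sp$file2) != row$file2) return(FALSE)
    if (paired && !identical(file.size(sp$file2), row$size2)) return(FALSE)
  }
  TRUE
}

#' Build k-mer indexes over the chunks of a read store
#'
#' Each chunk is indexed with exact k-mer postings: DNA postings on both
#' strands, and (when `with_prot`) translated postings over all six
#' frames, with translations broken at stop codons and ambiguous codons so
#' that no k-mer spans them.
#'
#' @param store a `read_store` from [preprocess()] or [load_read_store()].
#' @param k_dna DNA index k-mer size (>= 11).
#' @param k_prot protein index k-mer size in amino acids (>= 4).
#' @param with_prot build the translated-space postings (needed for
#'   protein probes).
#' @return The store with per-chunk indexes attached.
#' @export
build_index <- function(store, k_dna = 15L, k_prot = 5L, with_prot = TRUE) {
  stopifnot(inherits(store, "read_store"), k_dna >= 11, k_prot >= 4)
  store$indexes <- lapply(seq_len(nrow(store$chunks)), function(i) {
    recs <- load_sequences(file.path(store$prep_dir, store$chunks$file[i]))
    chunk_index(recs$seq, k_dna = k_dna, k_prot = k_prot,
                with_prot = with_prot)
  })
  store$k_dna <- as.integer(k_dna)
  store$k_prot <- as.integer(k_prot)
  store$with_prot <- with_prot
  store
}

#' Low-level k-mer index over a set of sequences
#'
#' @param seqs character vector of DNA sequences.
#' @inheritParams build_index
#' @return An object of class `kmer_index`.
#' @export
chunk_index <- function(seqs, k_dna = 15L, k_prot = 5L, with_prot = TRUE) {
  stopifnot(k_dna >= 11, k_dna <= 31, k_prot >= 4, k_prot <= 12)
  ptr <- cpp_chunk_index(as.character(seqs), as.integer(k_dna),
                         as.integer(k_prot), isTRUE(with_prot))
  structure(list(ptr = ptr, k_dna = as.integer(k_dna),
                 k_prot = as.integer(k_prot), with_prot = isTRUE(with_prot),
                 n = length(seqs)),
            class = "kmer_index")
}

#' Postings of one exact k-mer
#'
#' @param index a `kmer_index`.
#' @param kmer the k-mer (length `k_dna` for DNA space, `k_prot` for
#'   translated space).
#' @param space `"dna"` or `"prot"`.
#' @return A data.frame with `read` (1-based ordinal), `offset` (0-based,
#'   within the read for `strand == "+"`, within its reverse complement
#'   for `"-"`; in amino acids within the frame translation for protein
#'   space) and `strand` (`"+"`/`"-"`) or `frame` (1, 2, 3, -1, -2, -3).
#' @export
kmer_postings <- function(index, kmer, space = c("dna", "prot")) {
  space <- match.arg(space)
  df <- cpp_index_postings(index$ptr, as.character(kmer), space)
  if (space == "dna") {
    df$strand <- ifelse(df$code == 0, "+", "-")
  } else {
    df$frame <- c(1L, 2L, 3L, -1L, -2L, -3L)[df$code + 1L]
  }
  df$code <- NULL
  df
}

index_posting_count <- function(index, space = c("dna", "prot")) {
  space <- match.arg(space)
  cnt <- cpp_index_counts(index$ptr)
  if (space == "dna") cnt$dna else cnt$prot
}

index_posting_at <- function(index, j, space = c("dna", "prot")) {
  space <- match.arg(space)
  p <- cpp_index_posting_at(index$ptr, as.numeric(j), space)
  if (space == "dna") {
    p$strand <- if (p$code == 0) "+" else "-"
  } else {
    p$frame <- c(1L, 2L, 3L, -1L, -2L, -3L)[p$code + 1L]
  }
  p
}

#' Find reads matching a set of query sequences
#'
#' A read matches when it shares at least one exact common substring of
#' length `min_match` with some query: in DNA space (either strand) for
#' DNA queries, in translated space (any of the six frames) for protein
#' queries. Lowercase (masked) query positions contribute no seeds, but
#' a match seeded elsewhere may extend across them.
#'
#' @param store an indexed `read_store` (see [build_index()]).
#' @param queries a [seq_set()] of DNA contigs and/or a protein probe.
#' @param min_match_dna minimum exact match length in nucleotides.
#' @param min_match_prot minimum exact match length in amino acids.
#' @return Sorted vector of matching global read ids.
#' @export
find_matching_reads <- function(store, queries, min_match_dna = 30L,
                                min_match_prot = 10L) {
  stopifnot(inherits(store, "read_store"), nrow(queries) > 0)
  if (is.null(store$indexes)) stop("store is not indexed; call build_index()")
  if (min_match_dna < store$k_dna || min_match_prot < store$k_prot) {
    stop("min_match must be at least the index k-mer size")
  }
  out <- integer()
  for (i in seq_len(nrow(store$chunks))) {
    hits <- cpp_chunk_search(store$indexes[[i]]$ptr, queries$seq,
                             queries$alphabet, as.integer(min_match_dna),
                             as.integer(min_match_prot))
    out <- c(out, hits + store$chunks$base[i])
  }
  sort(unique(out))
}

#' Close a read set under mate inclusion
#'
#' For paired-end libraries both members of a pair are retained when
#' either mate matched; single-end reads are unaffected. Idempotent and
#' monotone.
#'
#' @param store a `read_store`.
#' @param found integer vector of global read ids.
#' @return Sorted superset of `found` closed under mate inclusion.
#' @export
complete_pairs <- function(store, found) {
  if (length(found) == 0) return(integer())
  ch <- store$chunks
  ci <- findInterval(found - 1L, ch$base)
  local <- found - ch$base[ci]
  m <- ch$m[ci]
  mate <- ifelse(m > 0L, ifelse(local <= m, found + m, found - m), NA_integer_)
  sort(unique(c(found, mate[!is.na(mate)])))
}

#' Fetch read sequences by global id
#' @param store an indexed `read_store`.
#' @param ids global read ids.
#' @return Character vector of read sequences.
#' @export
read_seqs <- function(store, ids) {
  if (is.null(store$indexes)) stop("store is not indexed; call build_index()")
  if (length(ids) == 0) return(character())
  ch <- store$chunks
  ci <- findInterval(ids - 1L, ch$base)
  out <- character(length(ids))
  for (i in unique(ci)) {
    sel <- ci == i
    out[sel] <- cpp_chunk_seqs(store$indexes[[i]]$ptr,
                               as.integer(ids[sel] - ch$base[i]))
  }
  out
}

#' @export
print.read_store <- function(x, ...) {
  cat("read_store:", nrow(x$chunks), "chunk(s),",
      sum(x$chunks$n), "reads,",
      if (is.null(x$indexes)) "not indexed" else
        sprintf("indexed (k_dna=%d, k_prot=%d)", x$k_dna, x$k_prot), "\n")
  invisible(x)
}
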