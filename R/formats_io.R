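#' Sequence record collections
#'
#' A `seq_set` is a plain `data.frame` with one row per sequence and
#' columns `id`, `desc`, `seq`, `qual` (NA when absent) and `alphabet`
#' (`"dna"` or `"protein"`). Case is significant: lowercase bases mark
#' masked (low-complexity) regions and survive serialization.
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param qual optional per-base quality strings (Phred+33); must match
#'   sequence lengths where not `NA`.
#' @param alphabet `"dna"`, `"protein"`, or `"auto"` to guess per record.
#' @param desc optional descriptions (text after the first whitespace of a
#'   FASTA header).
#' @return A `data.frame` of class `seq_set`.
#' @export
seq_set <- function(id = character(), seq = character(), qual = NA_character_,
                    alphabet = "auto", desc = NA_character_) {
  id <- as.character(id)
  seq <- as.character(seq)
  stopifnot(length(id) == length(seq))
  n <- length(id)
  qual <- rep_len(as.character(qual), n)
  desc <- rep_len(as.character(desc), n)
  alphabet <- rep_len(alphabet, n)
  auto <- alphabet == "auto"
  if (any(auto)) alphabet[auto] <- ifelse(guess_dna(seq[auto]), "dna", "protein")
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) {
    stop("quality length differs from sequence length for record '",
         id[which(bad)[1]], "'")
  }
  validate_alphabet(seq, alphabet, id)
  out <- data.frame(id = id, desc = desc, seq = seq, qual = qual,
                    alphabet = alphabet, stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

guess_dna <- function(seq) {
  !grepl("[^ACGTNacgtn]", seq)
}

validate_alphabet <- function(seq, alphabet, id) {
  dna_bad <- alphabet == "dna" & grepl("[^ACGTNacgtn]", seq)
  if (any(dna_bad)) {
    stop("record '", id[which(dna_bad)[1]], "' contains non-DNA characters")
  }
  prot_bad <- alphabet == "protein" &
    grepl("[^ACDEFGHIKLMNPQRSTVWYXBZUacdefghiklmnpqrstvwyxbzu*]", seq)
  if (any(prot_bad)) {
    stop("record '", id[which(prot_bad)[1]], "' contains non-amino-acid characters")
  }
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Identifiers terminate at the first whitespace of the header; the
#' remainder is kept as the record description. FASTQ qualities are
#' retained (Phred+33 assumed). Sequence case is preserved, so lowercase
#' masking round-trips. An empty file yields an empty collection.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"` (guessed from the extension when
#'   omitted).
#' @param alphabet `"auto"`, `"dna"` or `"protein"`.
#' @return A [seq_set()].
#' @export
load_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           alphabet = "auto") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fastq") {
    validate_fastq(path)
    x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    if (length(x) == 0) qual <- character()
  } else {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  seq_set(id = id, seq = as.character(x), qual = qual, alphabet = alphabet,
          desc = desc)
}

# Structural check of a four-line-record FASTQ file; the downstream
# parser pads short quality strings silently, so lengths are verified
# here, with the offending line reported.
validate_fastq <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0) return(invisible(TRUE))
  if (length(ln) %% 4 != 0) {
    stop("FASTQ parse error in '", path, "': truncated record at line ",
         (length(ln) %/% 4) * 4 + 1)
  }
  heads <- ln[seq(1, length(ln), by = 4)]
  if (any(substr(heads, 1, 1) != "@")) {
    i <- which(substr(heads, 1, 1) != "@")[1]
    stop("FASTQ parse error in '", path, "': expected '@' at line ",
         (i - 1) * 4 + 1)
  }
  nseq <- nchar(ln[seq(2, length(ln), by = 4)])
  nq <- nchar(ln[seq(4, length(ln), by = 4)])
  if (any(nseq != nq)) {
    i <- which(nseq != nq)[1]
    stop("FASTQ parse error in '", path, "': quality length (", nq[i],
         ") differs from sequence length (", nseq[i], ") at line ",
         (i - 1) * 4 + 4)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' Sequences are wrapped at 80 columns. Case is preserved so that
#' lowercase (masked) regions survive a round-trip through
#' [load_sequences()].
#'
#' @param records a [seq_set()].
#' @param path output file path.
#' @param format only `"fasta"`.
#' @return The path, invisibly.
#' @export
write_sequences <- function(records, path, format = "fasta") {
  stopifnot(identical(format, "fasta"), !is.null(records))
  nm <- ifelse(is.na(records$desc) | records$desc == "", records$id,
               paste(records$id, records$desc))
  x <- Biostrings::BStringSet(setNames(as.character(records$seq), nm))
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Write sequences to FASTQ (constant qualities substituted where absent)
#' @noRd
write_fastq <- function(records, path, default_qual = "I") {
  qual <- ifelse(is.na(records$qual),
                 vapply(nchar(records$seq), function(n)
                   strrep(default_qual, n), ""),
                 records$qual)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", nrow(x), "record(s)\n")
  if (nrow(x) > 0) {
    show <- head(x, 6)
    cat(sprintf("  %-20s %8s  %s\n", show$id, nchar(show$seq),
                substr(show$seq, 1, 40)), sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

# single-record accessor used throughout the walker
seq_record <- function(set, i = 1L) {
  stopifnot(nrow(set) >= i)
  set[i, , drop = FALSE]
}
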