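#' DNA molecules with explicit topology
#'
#' `dna_seq()` is the basic substrate of the cloning simulator: an upper-case
#' ACGT string plus a topology flag. Circular molecules have a defined origin
#' for storage but every search operation in the package is
#' rotation-invariant, so the origin carries no meaning beyond display.
#'
#' Ambiguity codes are rejected at construction: the simulator models designed
#' molecules, for which an ambiguous base is always an upstream error.
#'
#' @param seq character scalar over A/C/G/T (case-insensitive on input).
#' @param id sequence identifier.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `dna_seq` with fields `id`, `seq`, `topology`.
#' @examples
#' x <- dna_seq("acgtACGT", id = "demo")
#' seq_length(x)
#' @export
dna_seq <- function(seq, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    tk_stop("`seq` must be a single character string", "bad_sequence")
  seq <- toupper(seq)
  if (nchar(seq) == 0L)
    tk_stop("empty sequence", "bad_sequence")
  if (grepl("[^ACGT]", seq))
    tk_stop(sprintf("sequence '%s' contains characters outside A/C/G/T", id), "bad_sequence")
  structure(list(id = as.character(id), seq = seq, topology = topology),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$seq)
  prev <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<dna_seq> %s | %d bp | %s\n  %s\n", x$id, n, x$topology, prev))
  invisible(x)
}

#' @rdname dna_seq
#' @param x a `dna_seq` or character scalar.
#' @export
seq_length <- function(x) nchar(as_dna_string(x))

#' @export
is_dna_seq <- function(x) inherits(x, "dna_seq")

# accept either a dna_seq or a bare string wherever convenient
as_dna_string <- function(x) {
  if (is_dna_seq(x)) x$seq else if (is.character(x) && length(x) == 1L) toupper(x)
  else tk_stop("expected a dna_seq or character scalar", "bad_sequence")
}

#' Reverse complement of a DNA string
#'
#' @param x `dna_seq` or character scalar.
#' @return Same type as the input (a `dna_seq` input keeps id/topology).
#' @export
revcomp <- function(x) {
  # plain string implementation: called in tight loops where the S4 overhead
  # of a DNAString round trip dominates
  rc <- function(s) chartr("ACGTacgt", "TGCAtgca",
                           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  if (is_dna_seq(x)) {
    x$seq <- rc(x$seq)
    x
  } else rc(toupper(x))
}

#' Translate a DNA string (standard genetic code)
#'
#' Translation proceeds codon by codon from the first base; trailing partial
#' codons are dropped. Stop codons become `*` unless `to_stop = TRUE`, in which
#' case translation ends before the first stop.
#'
#' @param x `dna_seq` or character scalar; length need not be a multiple of 3.
#' @param to_stop stop at (and exclude) the first stop codon.
#' @return Amino-acid string.
#' @export
translate_dna <- function(x, to_stop = FALSE) {
  s <- as_dna_string(x)
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                                           no.init.codon = TRUE))
  if (to_stop) sub("\\*.*$", "", aa) else aa
}

#' Read / write DNA FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O that return/accept `dna_seq`
#' objects. All sequences are read as linear and upper-cased; writing wraps at
#' 60 columns.
#'
#' @param path file path.
#' @param topology topology assigned to all records read.
#' @return `read_fasta_dna`: named list of `dna_seq`.
#' @export
read_fasta_dna <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    dna_seq(as.character(set[[i]]), id = names(set)[i], topology = topology))
  names(out) <- names(set)
  out
}

#' @rdname read_fasta_dna
#' @param seqs a `dna_seq` or list of them.
#' @export
write_fasta_dna <- function(seqs, path) {
  if (is_dna_seq(seqs)) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# rotate a circular sequence string so position `new_origin` becomes position 1
rotate_string <- function(s, new_origin) {
  n <- nchar(s)
  k <- ((new_origin - 1L) %% n)
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

# all plus-strand match positions of `pattern`; for circular subjects matches
# spanning the origin are found by scanning the doubled string truncated so no
# match is counted twice. Positions are 1-based starts in [1, L].
find_pattern <- function(x, pattern, circular = NULL) {
  s <- as_dna_string(x)
  if (is.null(circular)) circular <- is_dna_seq(x) && x$topology == "circular"
  L <- nchar(s)
  k <- nchar(pattern)
  if (k > L) return(integer(0))
  subject <- if (circular && k > 1L) paste0(s, substr(s, 1L, k - 1L)) else s
  pos <- str_find_all(subject, pattern)
  pos[pos <= L]
}
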