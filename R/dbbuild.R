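# Build an MS search database from assembled transcripts: six-frame ORF
# finding, best-hit annotation from alignment tabular output, longest
# representative per transcript group, FASTA emission.

#' Find open reading frames in a transcript
#'
#' Scans all six frames for maximal ORFs. Within each stop-to-stop segment
#' the ORF runs from the first ATG (or from the segment start when
#' `require_atg = FALSE`) to the stop; segments hitting the transcript end
#' without a stop are reported only when `include_partial = TRUE`.
#' Coordinates are 1-based inclusive nucleotide positions on the plus strand,
#' covering the coding codons (the stop codon is excluded, so the span is
#' 3 x protein length). Frames are +1/+2/+3 and -1/-2/-3 on the reverse
#' complement.
#'
#' @param x a `dna_seq`, character sequence, or `transcript_record`.
#' @param min_aa minimum protein length in residues (default 100).
#' @param require_atg require an ATG start (default TRUE).
#' @param include_partial keep ORFs lacking a terminal stop codon.
#' @param id transcript id used in the output (defaults to the input's id).
#' @return data.frame `orf_id`, `transcript_id`, `frame`, `start`, `end`,
#'   `protein`, sorted by protein length descending (ties: frame, start).
#' @export
find_orfs <- function(x, min_aa = 100L, require_atg = TRUE,
                      include_partial = FALSE, id = NULL) {
  if (inherits(x, "transcript_record")) {
    if (is.null(id)) id <- x$transcript_id
    s <- x$seq
  } else {
    s <- as_dna_string(x)
    if (is.null(id)) id <- if (is_dna_seq(x)) x$id else "transcript"
  }
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    t <- if (strand == "+") s else revcomp(s)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      aa <- translate_dna(substr(t, off + 1L, off + 3L * n_codons))
      segs <- orf_segments(aa, require_atg, include_partial)
      for (seg in segs) {
        prot <- substr(aa, seg$from, seg$to)
        if (nchar(prot) < min_aa) next
        nt_from <- off + (seg$from - 1L) * 3L + 1L   # on strand t
        nt_to <- off + seg$to * 3L
        if (strand == "+") {
          start <- nt_from; end <- nt_to
        } else {
          start <- L - nt_to + 1L; end <- L - nt_from + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id,
          frame = paste0(strand, off + 1L),
          start = start, end = end, protein = prot,
          has_stop = seg$has_stop, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(orf_id = character(0), transcript_id = character(0),
                      frame = character(0), start = integer(0), end = integer(0),
                      protein = character(0), has_stop = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-nchar(out$protein), out$frame, out$start), , drop = FALSE]
  out$orf_id <- sprintf("%s.p%d", out$transcript_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("orf_id", "transcript_id", "frame", "start", "end", "protein", "has_stop")]
}

# segments of an aa string (with '*' stops): list of (from, to, has_stop)
# in 1-based aa coordinates, ORF = first ATG (M) .. residue before stop
orf_segments <- function(aa, require_atg, include_partial) {
  n <- nchar(aa)
  chars <- strsplit(aa, "")[[1]]
  stops <- which(chars == "*")
  seg_starts <- c(1L, stops + 1L)
  seg_ends <- c(stops - 1L, n)
  out <- list()
  for (i in seq_along(seg_starts)) {
    a <- seg_starts[i]; b <- seg_ends[i]
    if (a > b) next
    has_stop <- i <= length(stops)
    if (!has_stop && !include_partial) next
    if (require_atg) {
      ms <- which(chars[a:b] == "M")
      if (!length(ms)) next
      a <- a + ms[1L] - 1L
    }
    out[[length(out) + 1L]] <- list(from = a, to = b, has_stop = has_stop)
  }
  out
}

#' Transcript records
#'
#' @param transcript_id unique transcript id; the assembly group id defaults
#'   to the id with a trailing isoform suffix (`_i<n>`) removed, emulating
#'   Trinity-style component grouping, and can be overridden.
#' @param seq DNA string.
#' @param group_id transcript-group ("gene") id.
#' @return Object of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, seq, group_id = NULL) {
  if (is.null(group_id)) group_id <- transcript_group(transcript_id)
  if (!nzchar(group_id)) tk_stop("group_id must be non-empty", "bad_transcript")
  structure(list(transcript_id = transcript_id, group_id = group_id,
                 seq = toupper(as_dna_string(seq))),
            class = "transcript_record")
}

#' @rdname transcript_record
#' @param pattern regex removed from transcript ids to obtain the group id.
#' @export
transcript_group <- function(transcript_id, pattern = "_i[0-9]+$") {
  sub(pattern, "", transcript_id)
}

#' Read a 12-column alignment tabular file (BLAST outfmt 6 dialect)
#'
#' Comment lines (`#`) are tolerated. Malformed rows are skipped with a
#' warning and their count is recorded in the `n_skipped` attribute.
#'
#' @param path file path.
#' @return data.frame with the standard columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cols <- c("query_id", "subject_id", "pct_identity", "align_len", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end", "e_value", "bit_score")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 12L
  rows <- lapply(parts[ok], function(p) {
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (any(is.na(num))) return(NULL)
    data.frame(query_id = p[1], subject_id = p[2], t(num), stringsAsFactors = FALSE)
  })
  bad <- sum(!ok) + sum(vapply(rows, is.null, logical(1)))
  rows <- Filter(Negate(is.null), rows)
  if (bad > 0)
    tk_warn(sprintf("skipped %d malformed alignment row(s) in %s", bad, path),
            "malformed_hits")
  out <- if (length(rows)) do.call(rbind, rows)
         else as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
  names(out) <- cols
  e_neg <- out$e_value < 0
  if (any(e_neg)) {
    tk_warn(sprintf("skipped %d row(s) with negative e-value", sum(e_neg)),
            "malformed_hits")
    out <- out[!e_neg, , drop = FALSE]
  }
  attr(out, "n_skipped") <- bad
  out
}

#' Annotate ORFs from alignment hits
#'
#' Hits above the e-value cutoff are discarded; for each ORF the surviving
#' hit with the lowest e-value supplies the protein name, separately and
#' independently per species. Ties are broken by higher bit score, then
#' lexicographically smaller subject id, so the result is invariant to input
#' row order.
#'
#' @param orfs data.frame from [find_orfs()] (columns `orf_id`,
#'   `transcript_id`, `protein`).
#' @param hits data.frame in [read_blast_tab()] layout plus a
#'   `subject_species` column, or one derivable via `species_map`.
#' @param e_cutoff e-value cutoff (default 1e-10).
#' @param species_map named character vector mapping subject-id prefixes to
#'   species (e.g. `c(GG = "chicken", HS = "human")`); used when
#'   `hits$subject_species` is absent.
#' @param group_pattern passed to [transcript_group()] for the group id.
#' @return data.frame `id`, `protein`, `name_chicken`, `name_human`,
#'   `group_id` (one row per ORF; names NA without a passing hit).
#' @export
annotate_orfs <- function(orfs, hits, e_cutoff = 1e-10,
                          species_map = c(GG = "chicken", HS = "human"),
                          group_pattern = "_i[0-9]+$") {
  if (!nrow(orfs)) {
    return(data.frame(id = character(0), protein = character(0),
                      name_chicken = character(0), name_human = character(0),
                      group_id = character(0), stringsAsFactors = FALSE))
  }
  if (nrow(hits) && !"subject_species" %in% names(hits)) {
    prefix <- sub("_.*$", "", hits$subject_id)
    hits$subject_species <- unname(species_map[prefix])
  }
  if (nrow(hits)) {
    unresolved <- !hits$query_id %in% orfs$orf_id
    if (any(unresolved))
      tk_warn(sprintf("%d hit(s) reference unknown ORF ids and were ignored",
                      sum(unresolved)), "unresolved_hits")
    hits <- hits[!unresolved & hits$e_value <= e_cutoff &
                   !is.na(hits$subject_species), , drop = FALSE]
  }
  best_name <- function(q, species) {
    h <- hits[hits$query_id == q & hits$subject_species == species, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h <- h[order(h$e_value, -h$bit_score, h$subject_id), , drop = FALSE]
    h$subject_id[1L]
  }
  out <- data.frame(id = orfs$orf_id, protein = orfs$protein,
                    name_chicken = vapply(orfs$orf_id, best_name, character(1),
                                          species = "chicken"),
                    name_human = vapply(orfs$orf_id, best_name, character(1),
                                        species = "human"),
                    group_id = transcript_group(orfs$transcript_id, group_pattern),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Longest representative per transcript group
#'
#' Keeps exactly one protein per group: the longest (in amino acids of the
#' chosen ORF — the final data set is a protein database), ties broken by
#' lexicographically smaller id. Input order is irrelevant.
#'
#' @param annotated data.frame from [annotate_orfs()] (needs `id`, `protein`,
#'   `group_id`).
#' @return Subset of `annotated`, one row per distinct group, sorted by group.
#' @export
select_representatives <- function(annotated) {
  if (!nrow(annotated)) return(annotated)
  o <- order(annotated$group_id, -nchar(annotated$protein), annotated$id)
  sorted <- annotated[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the protein search database FASTA
#'
#' Headers are `id | chicken name | human name | group` with `-` for missing
#' annotations. Configured extra entries (the quantification peptide by
#' default; the TEV protease and any user sequences can be supplied) are
#' appended after the transcript-derived set. Re-running on identical input
#' is byte-identical.
#'
#' @param proteins data.frame from [select_representatives()] (or
#'   [annotate_orfs()]).
#' @param path output FASTA path.
#' @param extras named character vector of extra amino-acid entries.
#' @return Invisibly, a summary list: `n_total`, `n_transcript_derived`,
#'   `n_without_chicken`, `n_extras`.
#' @export
build_fasta_db <- function(proteins, path,
                           extras = c(Quant_peptide = "LAADITSLYK")) {
  ids <- c(proteins$id, names(extras))
  if (anyDuplicated(ids))
    tk_stop("duplicate ids in database", "duplicate_ids")
  dash <- function(x) ifelse(is.na(x) | !nzchar(x), "-", x)
  headers <- character(0)
  seqs <- character(0)
  if (nrow(proteins)) {
    headers <- sprintf("%s | %s | %s | %s", proteins$id,
                       dash(proteins$name_chicken), dash(proteins$name_human),
                       dash(proteins$group_id))
    seqs <- proteins$protein
  }
  if (length(extras)) {
    headers <- c(headers, sprintf("%s | - | - | extra", names(extras)))
    seqs <- c(seqs, unname(extras))
  }
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  summary <- list(n_total = length(seqs),
                  n_transcript_derived = nrow(proteins),
                  n_without_chicken = if (nrow(proteins))
                    sum(is.na(proteins$name_chicken)) else 0L,
                  n_extras = length(extras))
  invisible(summary)
}
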