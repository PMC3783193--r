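#' Restriction enzymes
#'
#' Enzymes carry top- and bottom-strand cut offsets within their recognition
#' sequence (e.g. NotI = GC^GGCCGC with the bottom strand cut after position
#' 6, leaving a 4-nt 5' extension). Cohesive-end compatibility downstream is
#' exact sequence equality of the single-stranded extensions.
#'
#' A small table of common single-site linearization enzymes ships with the
#' package (`enzyme_table()`, from `extdata/enzymes.tsv`).
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (>= 6 nt here; palindromes typical).
#' @param cut_top 0-based offset of the top-strand cut within `recognition`.
#' @param cut_bottom 0-based offset of the bottom-strand cut (measured along
#'   the top strand). `cut_bottom > cut_top` gives a 5' extension,
#'   equality gives blunt ends.
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 6L)
    tk_stop("recognition sequence must be at least 6 nt", "bad_enzyme")
  if (grepl("[^ACGT]", recognition))
    tk_stop("recognition must be over A/C/G/T", "bad_enzyme")
  cut_top <- as.integer(cut_top); cut_bottom <- as.integer(cut_bottom)
  k <- nchar(recognition)
  if (cut_top < 0L || cut_top > k || cut_bottom < 0L || cut_bottom > k)
    tk_stop("cut offsets must lie within [0, recognition length]", "bad_enzyme")
  if (cut_bottom < cut_top)
    tk_stop("3' extensions are not modelled; require cut_bottom >= cut_top", "bad_enzyme")
  structure(list(name = name, recognition = recognition,
                 cut_top = cut_top, cut_bottom = cut_bottom),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s %s^%s (overhang %d nt)\n", x$name,
              substr(x$recognition, 1, x$cut_top),
              substr(x$recognition, x$cut_top + 1, nchar(x$recognition)),
              x$cut_bottom - x$cut_top))
  invisible(x)
}

#' @rdname restriction_enzyme
#' @export
enzyme_table <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "tagkit", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname restriction_enzyme
#' @param x an enzyme name, or a `restriction_enzyme` passed through unchanged.
#' @export
get_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) return(x)
  tab <- enzyme_table()
  i <- match(x, tab$name)
  if (is.na(i)) tk_stop(sprintf("unknown enzyme '%s'", x), "bad_enzyme")
  restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_top[i], tab$cut_bottom[i])
}

#' Find restriction sites
#'
#' Returns all 1-based start positions of the recognition sequence on the
#' given molecule (both strands when the recognition is non-palindromic; for a
#' palindrome the two strands coincide). On circular molecules sites spanning
#' the origin are found.
#'
#' @param x a `dna_seq`.
#' @param enzyme enzyme name or `restriction_enzyme`.
#' @return Sorted integer vector of site start positions (possibly empty).
#' @examples
#' find_sites(dna_seq("AAGCGGCCGCTT"), "NotI")  # site starts at position 3
#' @export
find_sites <- function(x, enzyme) {
  enzyme <- get_enzyme(enzyme)
  pos <- find_pattern(x, enzyme$recognition)
  rc <- revcomp(enzyme$recognition)
  if (rc != enzyme$recognition) pos <- c(pos, find_pattern(x, rc))
  sort(unique(pos))
}
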