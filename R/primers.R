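#' PCR primers
#'
#' A primer is a 3' annealing region (perfect match to the template, >= 15 nt)
#' plus an optional 5' overhang, the carrier of restriction sites and SLIC
#' homology in the construct designs. The melting temperature of the annealing
#' region is computed at construction.
#'
#' @param anneal 3' template-binding region (>= 15 nt).
#' @param overhang 5' overhang (may be empty).
#' @param name primer name.
#' @return Object of class `tk_primer` with fields `name`, `anneal`,
#'   `overhang`, `tm_c`.
#' @export
primer <- function(anneal, overhang = "", name = "primer") {
  anneal <- toupper(anneal)
  overhang <- toupper(overhang)
  if (nchar(anneal) < 15L)
    tk_stop("annealing region must be at least 15 nt", "bad_primer")
  if (grepl("[^ACGT]", paste0(overhang, anneal)))
    tk_stop("primer must be over A/C/G/T", "bad_primer")
  p <- structure(list(name = name, anneal = anneal, overhang = overhang, tm_c = NA_real_),
                 class = "tk_primer")
  p$tm_c <- compute_tm(p)
  p
}

#' @export
print.tk_primer <- function(x, ...) {
  cat(sprintf("<primer> %s | %s%s%s | Tm %.1f C\n", x$name,
              tolower(x$overhang), if (nchar(x$overhang)) "/" else "", x$anneal, x$tm_c))
  invisible(x)
}

#' @rdname primer
#' @param p a `tk_primer`.
#' @export
primer_sequence <- function(p) paste0(p$overhang, p$anneal)

# Unified nearest-neighbour parameters (Allawi & SantaLucia 1997):
# dH kcal/mol, dS cal/(mol K), dimers 5'->3' on the top strand.
.nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# initiation terms per terminal base pair
.nn_init_dh <- c(GC = 0.1, AT = 2.3)
.nn_init_ds <- c(GC = -2.8, AT = 4.1)

# full 16-dimer lookup: a dimer absent from the unified table is scored as
# its reverse complement (the table is strand-symmetric)
.nn_expand <- local({
  rc2 <- function(d) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(d, "")[[1]]), collapse = ""))
  b <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(b, b, paste0))
  key <- ifelse(all16 %in% names(.nn_dh), all16, vapply(all16, rc2, character(1)))
  list(dh = stats::setNames(.nn_dh[key], all16),
       ds = stats::setNames(.nn_ds[key], all16))
})
.nn_dh_full <- .nn_expand$dh
.nn_ds_full <- .nn_expand$ds

#' Nearest-neighbour melting temperature
#'
#' Two-state nearest-neighbour model with the unified parameter set
#' (Allawi & SantaLucia 1997), entropic monovalent-salt correction
#' 0.368·(N−1)·ln[Na+] and the standard non-self-complementary concentration
#' term R·ln(CT/4). Defaults model a typical PCR: 50 mM monovalent salt,
#' 500 nM total primer. Deterministic; Tm is invariant under reverse
#' complement because the parameter table is strand-symmetric.
#'
#' @param x a `tk_primer` (its annealing region is used) or a character
#'   sequence.
#' @param na_mM monovalent cation concentration (mM).
#' @param primer_nM total primer concentration CT (nM).
#' @return Melting temperature in degrees Celsius.
#' @export
compute_tm <- function(x, na_mM = 50, primer_nM = 500) {
  s <- if (inherits(x, "tk_primer")) x$anneal else toupper(x)
  if (nchar(s) < 2L) tk_stop("sequence too short for a duplex", "bad_primer")
  if (grepl("[^ACGT]", s)) tk_stop("sequence must be over A/C/G/T", "bad_primer")
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  dimers <- paste0(chars[-n], chars[-1L])
  dh <- sum(.nn_dh_full[dimers])
  ds <- sum(.nn_ds_full[dimers])
  term <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  dh <- dh + .nn_init_dh[term(chars[1L])] + .nn_init_dh[term(chars[n])]
  ds <- ds + .nn_init_ds[term(chars[1L])] + .nn_init_ds[term(chars[n])]
  ds_salt <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  unname(1000 * dh / (ds_salt + 1.987 * log(ct / 4)) - 273.15)
}

# deterministic anneal-length tuner for primers at a FIXED template position:
# grow the annealing region over `lengths` aiming for Tm inside
# [target - band, target + band]; if several lengths land in the band the
# shortest wins, ties broken by fewer A/T among the three 3'-terminal bases.
# If the band is unreachable the closest-Tm length is used (the position is
# dictated by the design, so a primer must be returned).
tune_anneal <- function(get_anneal, lengths = 18:32, target = 60, band = 3) {
  cand <- lapply(lengths, function(l) {
    a <- get_anneal(l)
    if (is.null(a) || nchar(a) < l) return(NULL)
    list(len = l, anneal = a, tm = compute_tm(a),
         at3 = sum(strsplit(substr(a, l - 2L, l), "")[[1]] %in% c("A", "T")))
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) tk_stop("no feasible annealing length", "bad_primer")
  dev <- vapply(cand, function(c) abs(c$tm - target), numeric(1))
  in_band <- dev <= band
  if (any(in_band)) {
    pool <- cand[in_band]
    o <- order(vapply(pool, `[[`, numeric(1), "len"),
               vapply(pool, `[[`, numeric(1), "at3"))
  } else {
    pool <- cand
    o <- order(dev, vapply(pool, `[[`, numeric(1), "len"))
  }
  c(pool[[o[1L]]], list(in_band = any(in_band)))
}
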