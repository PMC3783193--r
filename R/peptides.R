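# Peptide-level sequence operations for the tag system: TEV cleavage, tryptic
# digestion, monoisotopic masses and stable-isotope label shifts.

# monoisotopic atomic masses (CODATA/AME values, Da)
.atom_mass <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
# heavy-isotope monoisotopic masses
.isotope_mass <- c(`13C` = 13.0033548378, `15N` = 15.0001088984,
                   `2H` = 2.0141017780, `18O` = 17.9991604)
.isotope_light <- c(`13C` = "C", `15N` = "N", `2H` = "H", `18O` = "O")

# residue elemental composition (residue = amino acid minus water), C H N O S
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

.water_mass <- 2 * .atom_mass[["H"]] + .atom_mass[["O"]]
.proton_mass <- 1.00727646688

residue_mass <- function(res) {
  f <- .residue_formula[[res]]
  if (is.null(f)) tk_stop(sprintf("unknown residue '%s'", res), "bad_residue")
  sum(f * .atom_mass[c("C", "H", "N", "O", "S")])
}

#' Peptides with modifications
#'
#' A peptide is a string over the 20 canonical residues plus a (possibly
#' empty) list of modifications, each a `(position, mass shift, label)`
#' triple. Heavy-isotope internal standards are expressed as modifications
#' whose shift comes from [heavy_label_shift()].
#'
#' @param sequence amino-acid string (canonical residues only).
#' @param mods list of `list(pos =, shift =, label =)` entries.
#' @return Object of class `tk_peptide`.
#' @export
peptide <- function(sequence, mods = list()) {
  sequence <- toupper(sequence)
  if (!nchar(sequence) || grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
    tk_stop("peptide must be non-empty over the 20 canonical residues", "bad_residue")
  for (m in mods) {
    if (m$pos < 1L || m$pos > nchar(sequence))
      tk_stop("modification position outside peptide", "bad_modification")
    if (!is.finite(m$shift))
      tk_stop("modification mass shift must be finite", "bad_modification")
  }
  structure(list(sequence = sequence, mods = mods), class = "tk_peptide")
}

#' @export
print.tk_peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d aa%s) %.4f Da\n", x$sequence, nchar(x$sequence),
              if (length(x$mods)) sprintf(", %d mods", length(x$mods)) else "",
              monoisotopic_mass(x)))
  invisible(x)
}

#' TEV protease cleavage
#'
#' Cuts after the Q of every occurrence of the recognition motif (canonical
#' ENLYFQ) that is followed by one of the accepted P1' residues (G or S),
#' i.e. ENLYFQ|G and ENLYFQ|S. Fragments concatenate to the input; a protein
#' without a site is returned whole.
#'
#' @param protein amino-acid string.
#' @param motif recognition motif ending in the P1 residue.
#' @param p1prime accepted residues immediately after the cut.
#' @return Character vector of fragments, N- to C-terminal.
#' @export
tev_cleave <- function(protein, motif = "ENLYFQ", p1prime = c("G", "S")) {
  protein <- toupper(protein)
  k <- nchar(motif)
  hits <- str_find_all(protein, motif)
  cuts <- integer(0)
  for (h in hits) {
    nxt <- substr(protein, h + k, h + k)
    if (nxt %in% p1prime) cuts <- c(cuts, h + k - 1L)  # cut after this position
  }
  split_after(protein, cuts)
}

split_after <- function(s, cuts) {
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 1L & cuts < nchar(s)]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(s))
  substring(s, starts, ends)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal of K or R except when the next residue is P (the
#' classical Keil rule). With `missed = 0` the peptides partition the input;
#' with `missed = m` all concatenations of up to `m + 1` adjacent fully
#' cleaved peptides are additionally returned, in N-terminal order.
#'
#' @param protein amino-acid string.
#' @param missed maximum number of missed cleavages.
#' @return Character vector of peptide sequences.
#' @export
tryptic_digest <- function(protein, missed = 0L) {
  protein <- toupper(protein)
  if (missed < 0L) tk_stop("`missed` must be >= 0", "bad_argument")
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n & chars[cuts + 1L] != "P"]
  base <- split_after(protein, cuts)
  if (missed == 0L) return(base)
  out <- character(0)
  nb <- length(base)
  for (i in seq_len(nb)) {
    for (m in 0:min(missed, nb - i)) {
      out <- c(out, paste(base[i:(i + m)], collapse = ""))
    }
  }
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses (from elemental composition and
#' monoisotopic atomic masses) plus one water, plus any modification shifts.
#'
#' @param x a [peptide()] or plain amino-acid string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("G")  # glycine: 75.0320 Da
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- peptide(x)
  res <- strsplit(x$sequence, "")[[1]]
  m <- sum(vapply(res, residue_mass, numeric(1))) + .water_mass
  if (length(x$mods)) m <- m + sum(vapply(x$mods, `[[`, numeric(1), "shift"))
  unname(m)
}

#' Peptide m/z for low charge states
#'
#' @param x a [peptide()] or amino-acid string.
#' @param charges charge states to report.
#' @return Named numeric vector of m/z values.
#' @export
peptide_mz <- function(x, charges = 1:3) {
  m <- monoisotopic_mass(x)
  stats::setNames((m + charges * .proton_mass) / charges, paste0("z", charges))
}

#' Stable-isotope label mass shift
#'
#' Exact monoisotopic shift for substituting heavy isotopes into one residue,
#' e.g. Lys(13C6; 15N2) = 6·(13.0033548 − 12) + 2·(15.0001089 − 14.0030740)
#' = +8.0142 Da — the "+8 Da" heavy-lysine internal standard. The requested
#' atom counts are checked against the residue's elemental composition.
#'
#' @param residue single-letter residue code.
#' @param label isotope specification, either a string like `"13C6;15N2"`
#'   (separators `;`, `,` or space) or a named vector like
#'   `c("13C" = 6, "15N" = 2)`. Empty label gives 0.
#' @return Mass shift in Da.
#' @export
heavy_label_shift <- function(residue, label) {
  counts <- parse_isotope_label(label)
  if (!length(counts)) return(0)
  f <- .residue_formula[[toupper(residue)]]
  if (is.null(f)) tk_stop(sprintf("unknown residue '%s'", residue), "bad_residue")
  names(f) <- c("C", "H", "N", "O", "S")
  shift <- 0
  for (iso in names(counts)) {
    if (!iso %in% names(.isotope_mass))
      tk_stop(sprintf("unknown isotope '%s'", iso), "bad_label")
    elem <- .isotope_light[[iso]]
    if (counts[[iso]] > f[[elem]])
      tk_stop(sprintf("residue %s has only %d %s atoms (%d requested)",
                      residue, f[[elem]], elem, counts[[iso]]), "bad_label")
    shift <- shift + counts[[iso]] * (.isotope_mass[[iso]] - .atom_mass[[elem]])
  }
  shift
}

parse_isotope_label <- function(label) {
  if (is.numeric(label)) {
    return(label[label > 0])
  }
  if (!is.character(label) || !nzchar(trimws(paste(label, collapse = ""))))
    return(numeric(0))
  parts <- unlist(strsplit(label, "[;,[:space:]]+"))
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([0-9]+)([A-Za-z]+)([0-9]*)$", parts))
  out <- numeric(0)
  for (g in m) {
    if (length(g) != 4L)
      tk_stop(sprintf("cannot parse isotope label '%s'", paste(parts, collapse = ";")),
              "bad_label")
    iso <- paste0(g[2], toupper(g[3]))
    n <- if (nzchar(g[4])) as.numeric(g[4]) else 1
    out[iso] <- (if (iso %in% names(out)) out[iso] else 0) + n
  }
  out
}

#' Tag architecture of the C-terminal quantification tags
#'
#' The tag appended to a bait protein consists of an 11-residue
#' quantification remnant (default KLAADITSLYK) that stays on the bait after
#' TEV elution, the TEV recognition site, and a reporter moiety (protein A,
#' FLAG or EGFP) that leaves with the protease cut.
#'
#' @param quant_remnant residues left on the bait C-terminus after TEV
#'   cleavage; tryptic digestion releases the quantification peptide from it.
#' @param tev_site TEV recognition motif (P6..P1).
#' @param reporter reporter name, one of ProtA/FLAG/EGFP (free text allowed).
#' @return Object of class `tag_architecture`.
#' @export
tag_architecture <- function(quant_remnant = "KLAADITSLYK", tev_site = "ENLYFQ",
                             reporter = c("EGFP", "ProtA", "FLAG")) {
  reporter <- if (is.character(reporter) && length(reporter) > 1) match.arg(reporter)
              else as.character(reporter)
  structure(list(quant_remnant = toupper(quant_remnant),
                 tev_site = toupper(tev_site), reporter = reporter),
            class = "tag_architecture")
}

#' Extract the quantification peptide from a tagged fusion
#'
#' Applies TEV cleavage, takes the bait-side fragment (the one ending in
#' quant remnant + TEV site), digests it with trypsin (0 missed cleavages)
#' and returns the peptide released in 1:1 stoichiometry with the bait: the
#' digest product whose C-terminus abuts the TEV site. If the bait sequence
#' itself contains another copy of that peptide, a "non-unique quant peptide"
#' warning is raised, because spiked-standard quantification then
#' over-counts.
#'
#' @param arch a [tag_architecture()].
#' @param fusion full fusion protein sequence (bait + tag).
#' @return A [peptide()] (default architecture: LAADITSLYK, 10 residues).
#' @export
extract_quant_peptide <- function(arch, fusion) {
  stopifnot(inherits(arch, "tag_architecture"))
  fusion <- toupper(fusion)
  bait_suffix <- paste0(arch$quant_remnant, arch$tev_site)
  frags <- tev_cleave(fusion, motif = arch$tev_site)
  is_bait <- vapply(frags, function(f) endsWith(f, bait_suffix), logical(1))
  if (!any(is_bait))
    tk_stop("fusion does not contain the tag architecture (quant remnant + TEV site)",
            "tag_not_found")
  bait <- frags[[which(is_bait)[1L]]]
  peps <- tryptic_digest(bait, missed = 0L)
  # the quantification peptide ends exactly where the TEV site begins
  ends <- cumsum(nchar(peps))
  target_end <- nchar(bait) - nchar(arch$tev_site)
  hit <- which(ends == target_end)
  if (!length(hit))
    tk_stop("no tryptic peptide ends at the TEV site boundary", "tag_not_found")
  quant <- peps[hit[1L]]
  # stoichiometry check across the whole fusion digest
  all_peps <- unlist(lapply(tev_cleave(fusion, motif = arch$tev_site), tryptic_digest))
  n_copies <- sum(all_peps == quant)
  if (n_copies != 1L)
    tk_warn(sprintf("quantification peptide '%s' occurs %d times per fusion: non-unique quant peptide",
                    quant, n_copies), "nonunique_quant")
  peptide(quant)
}

#' Write a peptide table (TSV)
#'
#' One row per peptide: sequence, modification summary, monoisotopic mass and
#' m/z for charges 1-3.
#'
#' @param peptides list of [peptide()] objects or character vector.
#' @param path output path.
#' @export
write_peptide_table <- function(peptides, path) {
  if (is.character(peptides)) peptides <- lapply(peptides, peptide)
  rows <- lapply(peptides, function(p) {
    mz <- peptide_mz(p)
    data.frame(sequence = p$sequence,
               mods = if (length(p$mods))
                 paste(vapply(p$mods, function(m)
                   sprintf("%d:%s(%+.4f)", m$pos, m$label, m$shift), character(1)),
                   collapse = ";") else "",
               mono_mass = round(monoisotopic_mass(p), 4),
               mz1 = round(mz[[1]], 4), mz2 = round(mz[[2]], 4), mz3 = round(mz[[3]], 4))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
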