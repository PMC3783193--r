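# Quantification-peptide absolute quantification: heavy/light ratio -> fmol
# in the eluate -> protein copies per cell, with calibration-linearity check.

.avogadro <- 6.02214076e23

#' Amount of bait peptide in the eluate
#'
#' The light (endogenous) to heavy (spiked standard) peak-volume ratio times
#' the spiked amount gives the absolute amount of quantification peptide —
#' and hence bait protein, given 1:1 stoichiometry — in the eluate.
#'
#' @param light_volume,heavy_volume peak volumes (arbitrary units >= 0).
#' @param spike_fmol amount of heavy standard spiked (default 500 fmol,
#'   i.e. 0.5 pmol).
#' @return Amount in fmol (vectorized).
#' @export
eluate_fmol <- function(light_volume, heavy_volume, spike_fmol = 500) {
  if (any(light_volume < 0) || any(heavy_volume < 0))
    tk_stop("peak volumes must be >= 0", "bad_measurement")
  if (any(spike_fmol <= 0))
    tk_stop("spike amount must be positive", "bad_measurement")
  if (any(heavy_volume == 0))
    tk_stop("heavy peak volume is 0: no internal standard detected", "no_standard")
  (light_volume / heavy_volume) * spike_fmol
}

#' Protein copies per cell
#'
#' `copies = fmol * 1e-15 * N_A / (n_cells * coip_yield)`. The reported value
#' is rounded to `sig_digits` significant figures (1 by default, the
#' precision at which copy numbers in this kind of experiment are honest);
#' the raw value is always returned alongside.
#'
#' @param fmol amount in the eluate (fmol).
#' @param n_cells number of input cells.
#' @param coip_yield purification yield as a fraction in (0, 1].
#' @param sig_digits significant figures for the reported value.
#' @return data.frame with `copies_raw` and `copies_reported` (vectorized).
#' @examples
#' copies_per_cell(69, 4e7, 0.5)  # ~2078 raw, reported 2000
#' @export
copies_per_cell <- function(fmol, n_cells, coip_yield = 0.5, sig_digits = 1L) {
  if (any(n_cells < 1)) tk_stop("n_cells must be >= 1", "bad_measurement")
  if (any(coip_yield <= 0) || any(coip_yield > 1))
    tk_stop("coip_yield must be in (0, 1]", "bad_measurement")
  raw <- fmol * 1e-15 * .avogadro / (n_cells * coip_yield)
  data.frame(copies_raw = raw, copies_reported = signif(raw, sig_digits))
}

#' Calibration linearity check
#'
#' Ordinary least squares of peak volume on concentration; the series is
#' flagged linear when r-squared meets the threshold. Used to confirm that
#' the standard behaves linearly over the working range (the reference
#' instrument was linear from 250 pM to 250 nM).
#'
#' @param concentration strictly increasing concentrations (>= 3 points).
#' @param volume peak volumes.
#' @param r2_threshold minimum r-squared to call the range linear.
#' @return List with `slope`, `intercept`, `r_squared`, `linear_range`.
#' @export
check_linearity <- function(concentration, volume, r2_threshold = 0.99) {
  if (length(concentration) != length(volume))
    tk_stop("concentration and volume lengths differ", "bad_measurement")
  if (anyDuplicated(concentration))
    tk_stop("duplicate concentrations in calibration series", "bad_measurement")
  if (length(concentration) < 3L)
    tk_stop("need at least 3 calibration points for r-squared", "bad_measurement")
  fit <- stats::lm(volume ~ concentration)
  ss_tot <- sum((volume - mean(volume))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, linear_range = r2 >= r2_threshold)
}

#' Absolute quantification of a measurement table
#'
#' Input: one row per (protein, replicate) with light/heavy peak volumes,
#' spike amount, cell input. Per protein the eluate amount is computed per
#' replicate and summarized as mean +/- sample SD; copies per cell come from
#' the mean.
#'
#' @param measurements data.frame with columns `protein`, `replicate`,
#'   `light_volume`, `heavy_volume`, `spike_fmol`, `n_cells`.
#' @param coip_yield assumed purification yield (default 0.5).
#' @param sig_digits significant figures for reported copies.
#' @return data.frame: `protein`, `n_replicates`, `fmol_mean`, `fmol_sd`,
#'   `copies_raw`, `copies_reported`.
#' @export
absquant_table <- function(measurements, coip_yield = 0.5, sig_digits = 1L) {
  need <- c("protein", "replicate", "light_volume", "heavy_volume",
            "spike_fmol", "n_cells")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    tk_stop(sprintf("measurement table lacks column(s): %s",
                    paste(missing, collapse = ", ")), "bad_measurement")
  out <- lapply(split(measurements, measurements$protein), function(d) {
    fmol <- eluate_fmol(d$light_volume, d$heavy_volume, d$spike_fmol)
    n_cells <- unique(d$n_cells)
    if (length(n_cells) != 1L)
      tk_stop(sprintf("protein '%s' has replicates with different n_cells",
                      d$protein[1]), "bad_measurement")
    cp <- copies_per_cell(mean(fmol), n_cells, coip_yield, sig_digits)
    data.frame(protein = d$protein[1], n_replicates = nrow(d),
               fmol_mean = mean(fmol),
               fmol_sd = if (nrow(d) > 1) stats::sd(fmol) else NA_real_,
               copies_raw = cp$copies_raw, copies_reported = cp$copies_reported,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write absolute-quantification TSVs
#'
#' @param path TSV path.
#' @return `read_quant_measurements`: data.frame in the layout
#'   [absquant_table()] expects.
#' @export
read_quant_measurements <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_quant_measurements
#' @param x a measurement or result data.frame.
#' @export
write_quant_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
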