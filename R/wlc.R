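#' Extensible worm-like chain parameters
#'
#' Bundle the polymer-elasticity parameters for one DNA species (double- or
#' single-stranded). Extension per monomer at force `F` follows the
#' Marko-Siggia interpolation with an additive enthalpic stretch term,
#' `xi(F) = h * (1 - 1/2 sqrt(kT / (F P)) + F / S)`.
#'
#' @param persistence_nm Persistence length P in nm.
#' @param contour_nm Contour length per monomer h, in nm per bp (dsDNA) or
#'   nm per nt (ssDNA).
#' @param stretch_pN Stretch modulus S in pN.
#' @param kT_pNnm Thermal energy in pN nm. Default 4.11 (298 K).
#' @return An object of class `wlc_params`.
#' @seealso [wlc_dsdna()], [wlc_ssdna()], [monomer_extension()]
#' @export
wlc_params <- function(persistence_nm, contour_nm, stretch_pN, kT_pNnm = 4.11) {
  vals <- c(persistence_nm = persistence_nm, contour_nm = contour_nm,
            stretch_pN = stretch_pN, kT_pNnm = kT_pNnm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all worm-like chain parameters must be strictly positive")
  structure(as.list(vals), class = "wlc_params")
}

#' @rdname wlc_params
#' @details `wlc_dsdna()` and `wlc_ssdna()` return the default parameter sets
#'   for B-form dsDNA (P = 50 nm, h = 0.34 nm/bp, S = 1000 pN) and ssDNA
#'   (P = 1.0 nm, h = 0.59 nm/nt, S = 1000 pN).
#' @export
wlc_dsdna <- function(kT_pNnm = 4.11) wlc_params(50, 0.34, 1000, kT_pNnm)

#' @rdname wlc_params
#' @export
wlc_ssdna <- function(kT_pNnm = 4.11) wlc_params(1.0, 0.59, 1000, kT_pNnm)

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("worm-like chain: P = %g nm, h = %g nm, S = %g pN, kT = %g pN nm\n",
              x$persistence_nm, x$contour_nm, x$stretch_pN, x$kT_pNnm))
  invisible(x)
}

#' Hairpin construct geometry
#'
#' Monomer counts for the hairpin tether: dsDNA handles, ssDNA loading site,
#' hairpin stem, and loop. The fully open hairpin exposes
#' `loading_site_nt + 2 * stem_bp + loop_nt` nucleotides of ssDNA, since each
#' unwound base pair releases two nucleotides.
#'
#' @param handle_bp dsDNA handle length in bp (both handles combined).
#' @param loading_site_nt ssDNA loading-site length in nt.
#' @param stem_bp hairpin stem length in bp.
#' @param loop_nt loop length in nt.
#' @return An object of class `construct_geometry`.
#' @export
construct_geometry <- function(handle_bp = 3050, loading_site_nt = 10,
                               stem_bp = 89, loop_nt = 4) {
  counts <- c(handle_bp, loading_site_nt, stem_bp, loop_nt)
  if (any(counts < 0)) stop("monomer counts must be non-negative")
  structure(list(handle_bp = handle_bp, loading_site_nt = loading_site_nt,
                 stem_bp = stem_bp, loop_nt = loop_nt,
                 open_ss_nt = loading_site_nt + 2L * stem_bp + loop_nt),
            class = "construct_geometry")
}

#' Extension of one monomer at a given force
#'
#' Evaluates the extensible worm-like chain interpolation for the extension
#' of a single bp (dsDNA) or nt (ssDNA) at force `force`.
#'
#' @param force Force in pN; strictly positive (vectorized).
#' @param params A [wlc_params()] object.
#' @return Extension in nm per monomer.
#' @examples
#' monomer_extension(12, wlc_ssdna())  # ~0.424 nm/nt
#' @export
monomer_extension <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(force)) || any(force <= 0))
    stop("force must be strictly positive")
  params$contour_nm *
    (1 - 0.5 * sqrt(params$kT_pNnm / (force * params$persistence_nm)) +
       force / params$stretch_pN)
}

#' End-to-end extension of a mixed ds/ss DNA construct
#'
#' Additive extension `n_ds * xi_ds(F) + n_ss * xi_ss(F)`.
#'
#' @param force Force in pN.
#' @param n_ds Number of dsDNA base pairs.
#' @param n_ss Number of ssDNA nucleotides.
#' @param ds_params,ss_params Worm-like chain parameter sets.
#' @return Extension in nm.
#' @export
construct_extension <- function(force, n_ds, n_ss,
                                ds_params = wlc_dsdna(), ss_params = wlc_ssdna()) {
  if (any(n_ds < 0) || any(n_ss < 0)) stop("monomer counts must be non-negative")
  n_ds * monomer_extension(force, ds_params) +
    n_ss * monomer_extension(force, ss_params)
}

#' Convert an extension change to base pairs unwound
#'
#' Each unwound base pair releases two nucleotides of ssDNA, so
#' `n_unwound = delta_x / (2 * xi_ss(F))`. The result is real-valued;
#' discretization belongs to step detection.
#'
#' @param delta_x Change in tether extension in nm.
#' @param force Force in pN.
#' @param ss_params ssDNA worm-like chain parameters.
#' @return Base pairs unwound (real-valued).
#' @seealso [extension_for_bp()] for the inverse.
#' @export
bp_unwound <- function(delta_x, force, ss_params = wlc_ssdna()) {
  delta_x / (2 * monomer_extension(force, ss_params))
}

#' Extension change for a number of base pairs unwound
#'
#' Inverse of [bp_unwound()]: `delta_x = n * 2 * xi_ss(F)`.
#'
#' @param n Base pairs unwound.
#' @param force Force in pN.
#' @param ss_params ssDNA worm-like chain parameters.
#' @return Extension change in nm.
#' @export
extension_for_bp <- function(n, force, ss_params = wlc_ssdna()) {
  n * 2 * monomer_extension(force, ss_params)
}
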