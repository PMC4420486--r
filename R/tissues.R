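#' Tissue electrical properties for electroporation modelling
#'
#' Each tissue is described by four quantities: the reversible
#' electroporation threshold `E0` (V/cm), the irreversible threshold `E1`
#' (V/cm), and the conductivities before (`sigma0`, S/m) and after
#' (`sigma1`, S/m) electroporation. Between `E0` and `E1` the conductivity
#' ramps continuously from `sigma0` to `sigma1` as the local field
#' magnitude increases (see [conductivity()]).
#'
#' @param name Tissue label (character scalar).
#' @param E0,E1 Reversible / irreversible electroporation thresholds in V/cm.
#' @param sigma0,sigma1 Pre- / post-electroporation conductivity in S/m.
#' @return An object of class `tissue_properties`.
#' @examples
#' tissue_properties("liver", E0 = 350, E1 = 700, sigma0 = 0.04, sigma1 = 0.12)
#' @export
tissue_properties <- function(name, E0, E1, sigma0, sigma1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(E0) && is.finite(E1) && E0 > 0 && E1 > E0))
    stop("tissue thresholds must satisfy 0 < E0 < E1 (got E0=", E0,
         ", E1=", E1, ")")
  if (!(is.finite(sigma0) && is.finite(sigma1) && sigma0 > 0 && sigma1 >= sigma0))
    stop("conductivities must satisfy 0 < sigma0 <= sigma1 (got sigma0=",
         sigma0, ", sigma1=", sigma1, ")")
  structure(
    list(name = name, E0 = E0, E1 = E1, sigma0 = sigma0, sigma1 = sigma1),
    class = "tissue_properties"
  )
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<tissue %s>  E0=%g V/cm  E1=%g V/cm  sigma0=%g S/m  sigma1=%g S/m\n",
              x$name, x$E0, x$E1, x$sigma0, x$sigma1))
  invisible(x)
}

#' Built-in tissue property table
#'
#' Default electroporation thresholds and conductivities for the four
#' tissues of the liver/vessel model: liver parenchyma, tumor, vessel wall
#' and blood. Thresholds for liver and tumor come from in vivo
#' measurements reported in the electroporation literature; vessel wall
#' and blood values are extrapolated from measurements on similar tissues
#' (muscle for the wall, cell suspensions for blood).
#'
#' @param overrides Optional named list of per-tissue overrides, e.g.
#'   `list(liver = list(sigma0 = 0.05))`. Unknown tissue or field names
#'   are an error.
#' @return Named list of [tissue_properties()] objects with entries
#'   `liver`, `tumor`, `vessel_wall`, `blood`.
#' @examples
#' tt <- builtin_tissue_table()
#' tt$liver$sigma1 / tt$liver$sigma0   # 3-fold conductivity increase
#' @export
builtin_tissue_table <- function(overrides = NULL) {
  tab <- list(
    liver       = list(E0 = 350, E1 = 700,  sigma0 = 0.04, sigma1 = 0.12),
    tumor       = list(E0 = 400, E1 = 800,  sigma0 = 0.2,  sigma1 = 0.7),
    vessel_wall = list(E0 = 400, E1 = 800,  sigma0 = 0.26, sigma1 = 0.78),
    blood       = list(E0 = 400, E1 = 1100, sigma0 = 0.7,  sigma1 = 1.05)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (tis in names(overrides)) {
      if (!tis %in% names(tab))
        stop("unknown tissue in overrides: ", tis)
      ov <- overrides[[tis]]
      bad <- setdiff(names(ov), c("E0", "E1", "sigma0", "sigma1"))
      if (length(bad))
        stop("unknown tissue property: ", paste(bad, collapse = ", "))
      tab[[tis]][names(ov)] <- ov
    }
  }
  out <- lapply(names(tab), function(n) do.call(tissue_properties, c(list(name = n), tab[[n]])))
  names(out) <- names(tab)
  out
}

#' Field-dependent tissue conductivity
#'
#' Conductivity as a smooth, monotone non-decreasing function of the local
#' electric field magnitude: `sigma0` below the reversible threshold `E0`,
#' `sigma1` above the irreversible threshold `E1`, and a cubic Hermite
#' smoothstep ramp in between (zero slope at both ends, so the curve is
#' C1-continuous everywhere). This emulates the smoothed-Heaviside
#' conductivity increase observed during tissue electroporation.
#'
#' @param E Electric field magnitude(s) in V/cm; vectorized.
#' @param tissue A [tissue_properties()] object.
#' @return Conductivity in S/m, same length as `E`.
#' @examples
#' liver <- builtin_tissue_table()$liver
#' conductivity(c(0, 350, 525, 700, 1000), liver)
#' @export
conductivity <- function(E, tissue) {
  stopifnot(inherits(tissue, "tissue_properties"))
  if (any(E < 0, na.rm = TRUE)) stop("field magnitude E must be >= 0")
  t <- (E - tissue$E0) / (tissue$E1 - tissue$E0)
  t <- pmin(pmax(t, 0), 1)
  s <- t * t * (3 - 2 * t)  # cubic smoothstep
  tissue$sigma0 + (tissue$sigma1 - tissue$sigma0) * s
}

# Conversion between the interface unit (V/cm) and SI (V/m).
V_PER_CM_TO_V_PER_M <- 100
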