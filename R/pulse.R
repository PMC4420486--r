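#' Build the electrode-pair pulse plan
#'
#' Expands the two optimization variables -- the voltage between
#' neighboring (outer) electrode pairs, `U_outer`, and the diagonal
#' voltage, `U_diag` -- into the ordered list of pair drives. For layouts
#' with a central electrode the diagonal voltage is applied between the
#' center and each surrounding electrode; for the 4-electrode box it is
#' applied between the two non-neighbor (opposite-corner) pairs. Neighbor
#' pairs around the ring are driven first, then the diagonal pairs.
#'
#' @param electrodes An `electrode_set` from [place_electrodes()].
#' @param U_outer Voltage between neighboring outer pairs (V).
#' @param U_diag Diagonal voltage (V).
#' @return A data.frame of class `pulse_plan` with columns `anode`,
#'   `cathode`, `voltage`, `kind`.
#' @examples
#' sc <- build_simplified_scene(10, spacing = 2, padding = 4)
#' el <- place_electrodes(sc, "ECT", 4)
#' make_pulse_plan(el, 600, 1000)
#' @export
make_pulse_plan <- function(electrodes, U_outer, U_diag) {
  stopifnot(U_outer > 0, U_diag > 0)
  roles <- vapply(electrodes, function(e) e$role, "")
  ids <- vapply(electrodes, function(e) e$id, 1L)
  outer_ids <- ids[roles == "outer"]
  center_id <- ids[roles == "center"]
  m <- length(outer_ids)
  if (!(m %in% c(4L, 6L)) || length(center_id) > 1L)
    stop("unknown electrode layout: ", m, " outer + ", length(center_id),
         " center electrodes")
  nb <- data.frame(anode = outer_ids, cathode = outer_ids[c(2:m, 1)],
                   voltage = U_outer, kind = "outer")
  if (length(center_id) == 1L) {
    dg <- data.frame(anode = center_id, cathode = outer_ids,
                     voltage = U_diag, kind = "diagonal")
  } else {
    if (m != 4L)
      stop("layout without a center electrode must have 4 outer electrodes")
    dg <- data.frame(anode = outer_ids[c(1L, 2L)], cathode = outer_ids[c(3L, 4L)],
                     voltage = U_diag, kind = "diagonal")
  }
  plan <- rbind(nb, dg)
  if (any(plan$anode == plan$cathode)) stop("drive with identical electrodes")
  class(plan) <- c("pulse_plan", "data.frame")
  plan
}
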