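#' Default length-mass allometry table
#'
#' Per-order coefficients of the power law `dry_mass_mg = a * length_mm^b`
#' used to convert invertebrate body lengths into inferred dry mass. The
#' table ships with a generic arthropod row (`order = "all"`) used as a
#' fallback for orders without their own entry. The shipped coefficients
#' are ordinary literature-style values for temperate arthropods and are
#' intended as replaceable defaults: supply your own table to
#' [length_to_dry_mass()] or [aggregate_daily()] for taxon-calibrated work.
#'
#' @return A data.frame with columns `order`, `a` (mg mm^-b) and `b`
#'   (dimensionless), one row per taxonomic order plus the `"all"` fallback.
#' @export
#' @examples
#' default_allometry()
default_allometry <- function() {
  data.frame(
    order = c("all", "Araneae", "Coleoptera", "Diptera", "Hymenoptera",
              "Hemiptera", "Acari", "Collembola", "Lepidoptera",
              "Orthoptera", "Trichoptera"),
    a = c(0.0305, 0.0500, 0.0312, 0.0400, 0.0220,
          0.0230, 0.0500, 0.0500, 0.0030,
          0.0300, 0.0056),
    b = c(2.62, 2.74, 2.91, 2.26, 2.57,
          2.86, 2.26, 2.20, 2.88,
          2.55, 2.84),
    stringsAsFactors = FALSE
  )
}

#' Convert body length to inferred dry mass
#'
#' Applies the taxon-specific power law `a * length^b`. Orders absent from
#' the table fall back to the generic `"all"` row.
#'
#' @param length_mm Numeric vector of body lengths in mm; must be > 0.
#' @param order Character vector of taxonomic orders, recycled against
#'   `length_mm`.
#' @param table Allometry table as returned by [default_allometry()];
#'   must contain an `"all"` row if any order is missing from it.
#' @return Numeric vector of inferred dry masses in mg.
#' @export
#' @examples
#' length_to_dry_mass(3, "Diptera")
#' length_to_dry_mass(c(2, 5), "Araneae")
length_to_dry_mass <- function(length_mm, order, table = default_allometry()) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("length_mm must be positive and finite")
  }
  stopifnot(is.data.frame(table), all(c("order", "a", "b") %in% names(table)))
  if (any(table$a <= 0) || any(table$b <= 0)) {
    stop("allometry coefficients must be positive")
  }
  n <- max(length(length_mm), length(order))
  length_mm <- rep_len(length_mm, n)
  order <- rep_len(as.character(order), n)
  idx <- match(order, table$order)
  if (anyNA(idx)) {
    fb <- match("all", table$order)
    if (is.na(fb)) stop("order(s) not in allometry table and no 'all' fallback row: ",
                        paste(unique(order[is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- fb
  }
  table$a[idx] * length_mm^table$b[idx]
}
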