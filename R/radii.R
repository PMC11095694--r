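## van der Waals radius assignment. Two bundled editable tables under
## inst/extdata: "bondi" (all-atom Bondi radii, the default) and "united"
## (heavier radii absorbing implicit hydrogens, for heavy-atom-only
## geometry). The choice of set is a documented, swappable configuration.

load_radius_table <- function(radius_set) {
  if (is.data.frame(radius_set)) {
    if (!all(c("element", "radius") %in% names(radius_set)))
      stopf("a custom radius table needs columns 'element' and 'radius'")
    tab <- radius_set
  } else {
    path <- system.file("extdata", paste0("vdw_radii_", radius_set, ".tsv"),
                        package = "lcpaccess")
    if (!nzchar(path)) stopf("unknown bundled radius set '%s'", radius_set)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
  }
  stats::setNames(tab$radius, toupper(tab$element))
}

#' Assign van der Waals radii
#'
#' Fills the per-atom `radius` column from a named radius table. All
#' tunnel and pocket geometry requires radii to be assigned first.
#'
#' @param structure a `mol_structure`.
#' @param radius_set `"bondi"` (default), `"united"`, or a data.frame with
#'   columns `element` and `radius` (Angstrom).
#' @param default fallback radius (Angstrom) for elements missing from the
#'   table; if `NULL` (default) missing elements raise an error.
#' @return the structure with every atom's `radius` set (> 0).
#' @export
assign_radii <- function(structure, radius_set = "bondi", default = NULL) {
  tab <- load_radius_table(radius_set)
  elem <- toupper(structure$atoms$element)
  r <- unname(tab[elem])
  if (anyNA(r)) {
    missing_elems <- sort(unique(elem[is.na(r)]))
    if (is.null(default))
      stopf("no radius for element(s): %s (supply a table entry or a default)",
            paste(missing_elems, collapse = ", "))
    r[is.na(r)] <- default
  }
  structure$atoms$radius <- r
  structure
}
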