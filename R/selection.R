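## Atom-selection mini-language.
##
## Grammar:
##   expr    := term ("or" term)*
##   term    := factor ("and" factor)*
##   factor  := "not" factor | "(" expr ")" | primary
##   primary := "element" SYM+ | "name" NAME+ | "resname" NAME+
##            | "resnum" RANGES | "chain" ID+
##            | "all" | "water" | "backbone" | "hydrogen" | "heavy" | "hetero"
## RANGES are integers, "a-b" spans, or comma-separated lists thereof.

WATER_NAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SPC", "SOL")
BACKBONE_NAMES <- c("N", "CA", "C", "O")

sel_tokenize <- function(expression) {
  x <- gsub("\\(", " ( ", gsub("\\)", " ) ", expression))
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

parse_resnum_values <- function(values) {
  out <- integer(0)
  for (v in unlist(strsplit(values, ","))) {
    v <- trimws(v)
    if (!nzchar(v)) next
    if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
      m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      out <- c(out, as.integer(m[2]):as.integer(m[3]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stopf("selection syntax error: bad residue range '%s'", v)
  }
  out
}

#' Select atoms by expression
#'
#' Evaluates a small boolean selection language over an atom table.
#' Fields: `element`, `name`, `resname`, `resnum` (ranges like `29-49`),
#' `chain`; convenience sets `all`, `water`, `backbone`, `hydrogen`,
#' `heavy`, `hetero`; combined with `and`, `or`, `not` and parentheses.
#'
#' @param structure a `mol_structure`.
#' @param expression selection string, e.g. `"chain A and not water"`.
#' @return sorted integer vector of atom indices (possibly empty).
#' @examples
#' s <- build_polyisoprene(2)$structure
#' length(select_atoms(s, "element C"))
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  toks <- sel_tokenize(expression)
  if (!length(toks)) stopf("selection syntax error: empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  keywords <- c("and", "or", "not", "(", ")",
                "element", "name", "resname", "resnum", "chain",
                "all", "water", "backbone", "hydrogen", "heavy", "hetero")
  is_value <- function(t) !is.na(t) && !(tolower(t) %in% keywords)

  parse_primary <- function() {
    t <- advance()
    if (is.na(t)) stopf("selection syntax error: unexpected end of expression")
    kw <- tolower(t)
    take_values <- function(field) {
      vals <- character(0)
      while (is_value(peek())) vals <- c(vals, advance())
      if (!length(vals)) stopf("selection syntax error: '%s' needs at least one value", field)
      vals
    }
    switch(kw,
      "all" = rep(TRUE, nrow(a)),
      "water" = a$resname %in% WATER_NAMES,
      "backbone" = a$name %in% BACKBONE_NAMES & !(a$resname %in% WATER_NAMES),
      "hydrogen" = a$element == "H",
      "heavy" = a$element != "H",
      "hetero" = a$type == "HETATM",
      "element" = toupper(a$element) %in% toupper(take_values("element")),
      "name" = toupper(a$name) %in% toupper(take_values("name")),
      "resname" = toupper(a$resname) %in% toupper(take_values("resname")),
      "chain" = a$chain %in% take_values("chain"),
      "resnum" = a$resnum %in% parse_resnum_values(take_values("resnum")),
      stopf("selection syntax error at token '%s'", t))
  }
  parse_factor <- function() {
    if (identical(tolower(peek()), "not")) { advance(); return(!parse_factor()) }
    if (identical(peek(), "(")) {
      advance()
      v <- parse_expr()
      if (!identical(peek(), ")")) stopf("selection syntax error: missing ')'")
      advance()
      return(v)
    }
    parse_primary()
  }
  parse_term <- function() {
    v <- parse_factor()
    while (identical(tolower(peek()), "and")) { advance(); v <- v & parse_factor() }
    v
  }
  parse_expr <- function() {
    v <- parse_term()
    while (identical(tolower(peek()), "or")) { advance(); v <- v | parse_term() }
    v
  }
  mask <- parse_expr()
  if (!is.na(peek())) stopf("selection syntax error at token '%s'", peek())
  which(mask)
}

#' Remove residues by name
#'
#' Strips co-crystallized species (e.g. waters, imidazole, diols) from a
#' structure; absent names are a no-op. Bond indices are remapped.
#'
#' @param structure a `mol_structure`.
#' @param residue_names character vector of residue names to remove.
#' @return the stripped `mol_structure`.
#' @export
strip_species <- function(structure, residue_names) {
  if (!length(residue_names)) return(structure)
  keep <- !(structure$atoms$resname %in% residue_names)
  subset_structure(structure, which(keep))
}

#' Subset a structure by atom indices
#' @param structure a `mol_structure`.
#' @param indices integer atom indices to keep (in order).
#' @return the sub-structure, with bonds remapped (bonds crossing the cut dropped).
#' @export
subset_structure <- function(structure, indices) {
  atoms <- structure$atoms[indices, , drop = FALSE]
  bonds <- structure$bonds
  if (!is.null(bonds)) {
    remap <- integer(n_atoms(structure))
    remap[indices] <- seq_along(indices)
    ok <- bonds[, 1] %in% indices & bonds[, 2] %in% indices
    bonds <- if (any(ok)) cbind(remap[bonds[ok, 1]], remap[bonds[ok, 2]]) else NULL
  }
  molecular_structure(atoms, bonds)
}
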