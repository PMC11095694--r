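## Idealized cis-1,4-polyisoprene builder.
##
## The repeat unit is -CH2-C(CH3)=CH-CH2- (C1 C2 C3 C4 backbone, C5 the
## methyl on C2), hydrogen-capped at both ends, giving C(5n)H(8n+2); at
## n = 10 this is the C50H82 substrate model. Double bonds C2=C3 are built
## cis (chain-continuation substituents on the same side) and are numbered
## 1..n starting from the dimethyl terminus (the end where C2 carries two
## methyl groups, R-CH=C(CH3)2).

BOND_CC_SINGLE <- 1.54
BOND_CC_DOUBLE <- 1.34
BOND_CH <- 1.09
ANGLE_SP3 <- 109.5
ANGLE_SP2 <- 120

## Place atom D bonded to C given chain A-B-C, bond length |CD|, angle
## B-C-D and torsion A-B-C-D (degrees). Standard NeRF construction.
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(C - B)
  n <- unit(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + cbind(bc, m, n) %*% d
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an idealized cis-1,4-polyisoprene n-mer
#'
#' Constructs a hydrogen-capped cis-1,4-polyisoprene chain with idealized
#' geometry (C-C 1.54 A, C=C 1.34 A, sp2 angles 120 deg, sp3 angles
#' 109.5 deg), cis across every C=C, in an extended conformation. All
#' single-bond backbone torsions default to trans (180 deg), which yields a
#' straight, clash-free chain (the in-plane turns of the cis kink cancel
#' within each repeat); any torsion can be overridden to build folded test
#' poses.
#'
#' @param n monomer count (>= 1); n = 10 gives the C50H82 substrate model.
#' @param torsion_overrides optional data.frame with columns `unit`
#'   (1..n), `bond` (one of `"a"` C4'-C1, `"b"` C1-C2, `"c"` C2=C3,
#'   `"d"` C3-C4) and `angle` (degrees), replacing the default torsion.
#' @return a `polymer_model`: list with `monomer_count`, `structure`
#'   (`mol_structure`, residue name IPR, one residue per monomer),
#'   `double_bonds` (n x 2 atom-index matrix, numbered from the dimethyl
#'   terminus), `terminus_atoms` (indices of the two terminal carbons).
#' @examples
#' m <- build_polyisoprene(10)
#' table(m$structure$atoms$element)  # 50 C, 82 H
#' @export
build_polyisoprene <- function(n, torsion_overrides = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stopf("monomer count n must be a positive integer")
  n <- as.integer(n)

  tor_default <- function(unit, bond) {
    ov <- torsion_overrides
    if (!is.null(ov)) {
      hit <- which(ov$unit == unit & ov$bond == bond)
      if (length(hit)) return(ov$angle[hit[1]])
    }
    switch(bond,
           a = 180,   # C4(i-1)-C1(i)
           b = 180,   # C1-C2
           c = 0,     # C2=C3, cis
           d = 180)   # C3-C4
  }

  pos <- list(); name <- character(0); elem <- character(0); resn <- integer(0)
  bonds <- NULL
  add <- function(p, nm, el, unit, bond_to = NULL) {
    pos[[length(pos) + 1L]] <<- as.numeric(p)
    name[length(name) + 1L] <<- nm
    elem[length(elem) + 1L] <<- el
    resn[length(resn) + 1L] <<- unit
    i <- length(pos)
    if (!is.null(bond_to)) bonds <<- rbind(bonds, c(bond_to, i))
    i
  }
  idx <- function(nm, unit) which(name == nm & resn == unit)

  c1 <- c2 <- c3 <- c4 <- integer(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      c1[1] <- add(c(0, 0, 0), "C1", "C", 1)
      c2[1] <- add(c(BOND_CC_SINGLE, 0, 0), "C2", "C", 1, c1[1])
      c3[1] <- add(place_atom(c(0, 1, 0), pos[[c1[1]]], pos[[c2[1]]],
                              BOND_CC_DOUBLE, ANGLE_SP2, tor_default(1, "b") + 0) ,
                   "C3", "C", 1, c2[1])
    } else {
      ## C1(i) off C4(i-1); its torsion is bond "d" of the previous unit
      c1[i] <- add(place_atom(pos[[c2[i - 1]]], pos[[c3[i - 1]]], pos[[c4[i - 1]]],
                              BOND_CC_SINGLE, ANGLE_SP3, tor_default(i - 1, "d")),
                   "C1", "C", i, c4[i - 1])
      c2[i] <- add(place_atom(pos[[c3[i - 1]]], pos[[c4[i - 1]]], pos[[c1[i]]],
                              BOND_CC_SINGLE, ANGLE_SP3, tor_default(i, "a")),
                   "C2", "C", i, c1[i])
      c3[i] <- add(place_atom(pos[[c4[i - 1]]], pos[[c1[i]]], pos[[c2[i]]],
                              BOND_CC_DOUBLE, ANGLE_SP2, tor_default(i, "b")),
                   "C3", "C", i, c2[i])
    }
    c4[i] <- add(place_atom(pos[[c1[i]]], pos[[c2[i]]], pos[[c3[i]]],
                            BOND_CC_SINGLE, ANGLE_SP2, tor_default(i, "c")),
                 "C4", "C", i, c3[i])
    ## methyl carbon on C2, anti to C4 across the double bond
    c5 <- add(place_atom(pos[[c4[i]]], pos[[c3[i]]], pos[[c2[i]]],
                         BOND_CC_SINGLE, ANGLE_SP2, 180), "C5", "C", i, c2[i])
    ## hydrogens -------------------------------------------------------
    ## C1: CH2 (CH3 on unit 1); H torsions offset from the heavy substituent
    href <- if (i == 1) c(60, 180, 300) else c(60, -60)
    for (k in seq_along(href))
      add(place_atom(pos[[c3[i]]], pos[[c2[i]]], pos[[c1[i]]], BOND_CH,
                     ANGLE_SP3, href[k]), paste0("H1", k), "H", i, c1[i])
    ## C3: vinylic H, opposite side from C4
    add(place_atom(pos[[c1[i]]], pos[[c2[i]]], pos[[c3[i]]], BOND_CH,
                   ANGLE_SP2, 180), "H3", "H", i, c3[i])
    ## C4: CH2 (CH3 on unit n); offsets from the continuation torsion
    td <- tor_default(i, "d")
    hq <- if (i == n) c(td, td + 120, td - 120) else c(td + 120, td - 120)
    for (k in seq_along(hq))
      add(place_atom(pos[[c2[i]]], pos[[c3[i]]], pos[[c4[i]]], BOND_CH,
                     ANGLE_SP3, hq[k]), paste0("H4", k), "H", i, c4[i])
    ## C5 methyl
    for (k in 1:3)
      add(place_atom(pos[[c3[i]]], pos[[c2[i]]], pos[[c5]], BOND_CH,
                     ANGLE_SP3, c(60, 180, 300)[k]), paste0("H5", k), "H", i, c5)
  }

  xyz <- do.call(rbind, pos)
  s <- molecular_structure(data.frame(
    name = name, element = elem, resname = "IPR", resnum = resn, chain = "L",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
    bonds = bonds)
  model <- structure(list(
    monomer_count = n,
    structure = s,
    double_bonds = cbind(c2, c3),
    terminus_atoms = c(c1[1], c4[n])), class = "polymer_model")
  clash <- min_nonbonded_distance(model)
  if (clash < 1.0)
    stopf("built geometry has a non-bonded clash (%.2f A); adjust torsions", clash)
  model
}

## Minimum distance over atom pairs not directly bonded.
min_nonbonded_distance <- function(model) {
  xyz <- coords(model$structure)
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  b <- model$structure$bonds
  d[b] <- Inf; d[b[, 2:1]] <- Inf
  min(d)
}

#' @export
print.polymer_model <- function(x, ...) {
  el <- table(x$structure$atoms$element)
  cat(sprintf("cis-1,4-polyisoprene %d-mer: C%dH%d, %d double bonds\n",
              x$monomer_count, el["C"], el["H"], nrow(x$double_bonds)))
  invisible(x)
}

#' Maximum chain width of an extended polymer
#'
#' Width is the maximum heavy-atom extent perpendicular to the principal
#' axis of the chain, plus a 1.1 Angstrom allowance for hydrogens.
#'
#' @param model a `polymer_model` (or any `mol_structure`) in an extended
#'   conformation.
#' @param h_allowance hydrogen allowance added to the heavy-atom extent
#'   (Angstrom; default 1.1).
#' @return width in Angstrom.
#' @export
chain_width <- function(model, h_allowance = 1.1) {
  s <- if (inherits(model, "polymer_model")) model$structure else model
  heavy <- which(s$atoms$element != "H")
  xyz <- coords(s)[heavy, , drop = FALSE]
  if (nrow(xyz) == 1) {
    r <- s$atoms$radius[heavy]
    if (is.na(r)) r <- load_radius_table("bondi")[toupper(s$atoms$element[heavy])]
    return(unname(2 * r))
  }
  if (nrow(xyz) < 3) stopf("chain axis undefined for fewer than 3 heavy atoms")
  ctr <- sweep(xyz, 2, colMeans(xyz))
  axis <- svd(ctr)$v[, 1]
  perp <- ctr - outer(as.vector(ctr %*% axis), axis)
  max(stats::dist(perp)) + h_allowance
}

#' Cleavage products of a polyisoprene chain
#'
#' Oxidative cleavage at double bond k of an n-mer destroys that bond's
#' C=C and yields two oligomers retaining k-1 and n-k intact double bonds
#' (bond numbering from the dimethyl terminus). Cleaving a central bond of
#' the 10-mer (k = 5 or 6) gives oligomers of 4 and 5 isoprene units.
#'
#' @param n monomer (= double bond) count.
#' @param k cleaved bond number, 1..n.
#' @return integer vector of the two intact-double-bond counts,
#'   `c(dimethyl_side = k - 1, far_side = n - k)`.
#' @export
cleavage_products <- function(n, k) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stopf("n must be a positive integer")
  if (!is.numeric(k) || k < 1 || k > n || k != round(k))
    stopf("cleaved bond number k must be in 1..n")
  c(dimethyl_side = as.integer(k - 1), far_side = as.integer(n - k))
}
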