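#' Registry mapping heterogroup residue codes to cofactor kinds
#'
#' Default assignments follow wwPDB chemical-component conventions: `HEM`
#' (b-type heme), `HEC` (c-type heme), `FES` ([2Fe2S]), `SF4` ([4Fe4S]),
#' `F3S` ([3Fe4S]), `FAD`, `NAP`/`NDP` (NADP). The registry is deliberately
#' user-overridable: b- versus c-type heme assignment by residue code is only
#' as reliable as the depositor's labels (structure-prediction models in
#' particular are known to mislabel heme types), so curated reassignments can
#' be injected here.
#'
#' @param overrides named character vector of `code = kind` entries added to
#'   (or replacing entries of) the defaults.
#' @return named character vector mapping residue codes to kinds.
#' @examples
#' cofactor_registry(c(HEM = "heme_c"))  # treat HEM groups as c-type
#' @export
cofactor_registry <- function(overrides = NULL) {
  reg <- c(HEM = "heme_b", HEC = "heme_c", FES = "fe2s2", SF4 = "fe4s4",
           F3S = "fe3s4", FAD = "FAD", NAP = "NADP", NDP = "NADP")
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named character vector")
    reg[names(overrides)] <- overrides
  }
  reg
}

cofactor_kinds <- function() {
  c("heme_b", "heme_c", "fe2s2", "fe4s4", "fe3s4", "FAD", "NADP")
}

#' Parse a PDB coordinate file into an atom table
#'
#' Reads ATOM and HETATM records (first MODEL only) and returns one row per
#' atom. Alternate locations are resolved by keeping the highest-occupancy
#' altloc of each atom (ties go to the first encountered). Element symbols
#' missing from the element column are recovered from the atom name.
#'
#' @param file path to a PDB file.
#' @return data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `chain`, `residue_seq`, `x`, `y`, `z`, `is_hydrogen`.
#' @export
parse_structure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records found in ", file)
  bad <- which(rec & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad) > 0L)
    stop(sprintf("malformed coordinate record at line %d of %s", bad[1], file))

  pdb <- tryCatch(
    bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", file, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  ele <- at$elesy
  miss <- is.na(ele) | ele == ""
  if (any(miss))
    ele[miss] <- suppressWarnings(bio3d::atom2ele(at$elety[miss]))
  at$elesy <- toupper(trimws(ele))

  # altloc: keep the highest-occupancy conformer of each atom; tie -> first
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- rep(TRUE, nrow(at))
  dupd <- key %in% key[duplicated(key)]
  if (any(dupd)) {
    for (k in unique(key[dupd])) {
      rows <- which(key == k)
      best <- rows[which.max(occ[rows])]   # which.max: first maximum wins
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]

  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    stop("non-finite coordinates in ", file)
  data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = at$elesy,
    residue_name = trimws(at$resid),
    chain = at$chain,
    residue_seq = at$resno,
    x = at$x, y = at$y, z = at$z,
    is_hydrogen = at$elesy %in% c("H", "D"),
    stringsAsFactors = FALSE)
}

#' Extract redox cofactors from an atom table
#'
#' Groups heterogroup atoms into cofactor instances by (chain, residue
#' number, residue name) for every residue code present in the registry.
#' Hydrogens are excluded from instance atom lists; heme instances must
#' contain at least one iron. Unrecognized heterogroup codes (other than
#' water) are ignored with a message.
#'
#' @param atoms atom table from [parse_structure()].
#' @param registry residue-code mapping from [cofactor_registry()].
#' @return list of `cofactor_instance` objects, each a list with `kind`,
#'   `label` (`CODE_<chain><resno>`), and `atoms` (heavy-atom rows).
#' @export
identify_cofactors <- function(atoms, registry = cofactor_registry()) {
  known_aa <- c(bio3d::aa.table$aa3, "HOH", "WAT", "DOD")
  het <- atoms[!(atoms$residue_name %in% known_aa), , drop = FALSE]
  is_cof <- het$residue_name %in% names(registry)
  ignored <- unique(het$residue_name[!is_cof])
  if (length(ignored) > 0L)
    message("ignoring unrecognized heterogroup(s): ",
            paste(ignored, collapse = ", "))
  cof <- het[is_cof, , drop = FALSE]
  if (nrow(cof) == 0L) return(list())
  key <- paste(cof$chain, cof$residue_seq, cof$residue_name, sep = "|")
  out <- lapply(unique(key), function(k) {
    rows <- cof[key == k, , drop = FALSE]
    heavy <- rows[!rows$is_hydrogen, , drop = FALSE]
    if (nrow(heavy) == 0L) return(NULL)
    kind <- unname(registry[heavy$residue_name[1]])
    if (kind %in% c("heme_b", "heme_c") &&
        !any(heavy$element == "FE"))
      stop(sprintf("heme group %s contains no iron atom", k))
    structure(list(
      kind = kind,
      label = sprintf("%s_%s%d", heavy$residue_name[1], heavy$chain[1],
                      heavy$residue_seq[1]),
      atoms = heavy), class = "cofactor_instance")
  })
  Filter(Negate(is.null), out)
}

#' @export
print.cofactor_instance <- function(x, ...) {
  cat(sprintf("<cofactor %s: %s, %d heavy atoms>\n",
              x$label, x$kind, nrow(x$atoms)))
  invisible(x)
}

# atom names of the conjugated (pi/redox-active) core per cofactor kind;
# used by the optional "conjugated" edge mode. Moser-Dutton practice often
# restricts the tunneling edge to these atoms: the porphyrin macrocycle plus
# iron for hemes, the isoalloxazine ring system for FAD, the nicotinamide
# ring and amide for NADP. Iron-sulfur clusters are their own conjugated
# core, so no restriction applies.
conjugated_atom_names <- function(kind) {
  porphyrin <- c("FE",
                 "NA", "NB", "NC", "ND",
                 "C1A", "C2A", "C3A", "C4A",
                 "C1B", "C2B", "C3B", "C4B",
                 "C1C", "C2C", "C3C", "C4C",
                 "C1D", "C2D", "C3D", "C4D",
                 "CHA", "CHB", "CHC", "CHD")
  switch(kind,
         heme_b = ,
         heme_c = porphyrin,
         FAD = c("N1", "C2", "O2", "N3", "C4", "O4", "C4X", "N5",
                 "C5X", "C6", "C7", "C7M", "C8", "C8M", "C9", "C9A",
                 "N10", "C10"),
         NADP = c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N",
                  "C7N", "O7N", "N7N"),
         NULL)
}

cofactor_coords <- function(cof, mode = "all") {
  at <- cof$atoms
  if (mode == "conjugated") {
    sel <- conjugated_atom_names(cof$kind)
    if (!is.null(sel)) {
      sub <- at[at$name %in% sel, , drop = FALSE]
      if (nrow(sub) > 0L) at <- sub
    }
  }
  as.matrix(at[, c("x", "y", "z")])
}

#' Minimum edge-to-edge distance between two cofactors
#'
#' The standard electron-tunneling metric: the minimum Euclidean distance
#' over all pairs of heavy atoms of the two groups. With
#' `mode = "conjugated"` the atom sets are restricted to the conjugated
#' cores (see the package vignette); substituents such as heme propionates
#' and the FAD/NADP tails are then excluded. For iron-sulfur clusters the
#' two modes coincide.
#'
#' @param a,b `cofactor_instance` objects (distinct).
#' @param mode `"all"` (default, all heavy atoms) or `"conjugated"`.
#' @return distance in Angstrom. Symmetric in its arguments.
#' @export
edge_to_edge <- function(a, b, mode = c("all", "conjugated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "cofactor_instance"),
            inherits(b, "cofactor_instance"))
  if (identical(a$label, b$label))
    stop("edge_to_edge requires two distinct cofactors")
  xa <- cofactor_coords(a, mode)
  xb <- cofactor_coords(b, mode)
  if (nrow(xa) == 0L || nrow(xb) == 0L)
    stop("cofactor with empty atom list")
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}

#' All-pairs edge-to-edge distance matrix
#'
#' @param cofactors list of `cofactor_instance` (length >= 2).
#' @param mode passed to [edge_to_edge()].
#' @return symmetric matrix of distances (Angstrom) with cofactor labels as
#'   dimnames; the diagonal is `NA` (self-distance undefined).
#' @export
distance_matrix <- function(cofactors, mode = c("all", "conjugated")) {
  mode <- match.arg(mode)
  n <- length(cofactors)
  if (n < 2L) stop("need at least 2 cofactors")
  labs <- vapply(cofactors, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("cofactor labels must be unique")
  D <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- edge_to_edge(cofactors[[i]], cofactors[[j]], mode)
  D
}
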