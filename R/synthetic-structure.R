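# Rigid local-coordinate templates for toy cofactor fixtures. Geometries are
# plausible (Fe-S ~2.2-2.3 A, porphyrin N at 2.0 A from Fe) but deliberately
# schematic: fixtures exercise distance/graph logic, not chemistry.
cofactor_templates <- function() {
  tpl <- list()

  tpl$fe2s2 <- data.frame(
    name = c("FE1", "FE2", "S1", "S2"),
    element = c("FE", "FE", "S", "S"),
    x = c(-1.35, 1.35, 0, 0),
    y = c(0, 0, 1.74, -1.74),
    z = 0, stringsAsFactors = FALSE)

  cube <- expand.grid(x = c(-1.35, 1.35), y = c(-1.35, 1.35),
                      z = c(-1.35, 1.35))
  par_even <- with(cube, (x > 0) + (y > 0) + (z > 0)) %% 2 == 0
  fe <- cube[par_even, ]; s <- cube[!par_even, ]
  tpl$fe4s4 <- data.frame(
    name = c(paste0("FE", 1:4), paste0("S", 1:4)),
    element = c(rep("FE", 4), rep("S", 4)),
    rbind(fe, s), stringsAsFactors = FALSE)

  tpl$fe3s4 <- tpl$fe4s4[-4, ]   # remove one iron vertex
  tpl$fe3s4$name <- c(paste0("FE", 1:3), paste0("S", 1:4))

  ring_angle <- function(deg) deg * pi / 180
  porph <- function() {
    ang_n <- ring_angle(c(0, 90, 180, 270))
    ang_meso <- ring_angle(c(45, 135, 225, 315))
    ang_a <- ring_angle(c(20, 70, 110, 160, 200, 250, 290, 340))
    data.frame(
      name = c("FE", "NA", "NB", "NC", "ND",
               "CHA", "CHB", "CHC", "CHD",
               "C1A", "C4A", "C1B", "C4B", "C1C", "C4C", "C1D", "C4D",
               "CGA", "O1A", "O2A", "CGD", "O1D", "O2D"),
      element = c("FE", rep("N", 4), rep("C", 12),
                  "C", "O", "O", "C", "O", "O"),
      x = c(0, 2.0 * cos(ang_n), 3.4 * cos(ang_meso), 3.1 * cos(ang_a),
            4.9, 5.9, 4.9, -4.9, -5.9, -4.9),
      y = c(0, 2.0 * sin(ang_n), 3.4 * sin(ang_meso), 3.1 * sin(ang_a),
            -2.5, -2.9, -3.6, -2.5, -2.9, -3.6),
      z = c(rep(0, 17), 0.6, 1.2, 0.2, 0.6, 1.2, 0.2),
      stringsAsFactors = FALSE)
  }
  tpl$heme_b <- porph()
  tpl$heme_c <- porph()

  hexagon <- function(r, z = 0) {
    a <- ring_angle(seq(0, 300, by = 60))
    cbind(x = r * cos(a), y = r * sin(a), z = z)
  }
  iso <- hexagon(1.4)
  tpl$FAD <- data.frame(
    name = c("N1", "C2", "O2", "N3", "C4", "O4",
             "C4X", "N5", "C5X", "C9A", "N10", "C10",
             "C6", "C7", "C7M", "C8", "C8M", "C9",
             "PA", "O1A", "O2A"),
    element = c("N", "C", "O", "N", "C", "O",
                "C", "N", "C", "C", "N", "C",
                "C", "C", "C", "C", "C", "C",
                "P", "O", "O"),
    x = c(iso[, 1], iso[, 1] + 2.4, iso[, 1] + 4.8, 8.5, 9.3, 8.5),
    y = c(iso[, 2], iso[, 2], iso[, 2], 0, 0.8, -0.8),
    z = 0, stringsAsFactors = FALSE)

  nic <- hexagon(1.4)
  tpl$NADP <- data.frame(
    name = c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N",
             "C7N", "O7N", "N7N", "PN", "O1N", "O2N"),
    element = c("N", "C", "C", "C", "C", "C", "C", "O", "N", "P", "O", "O"),
    x = c(nic[, 1], 2.6, 3.2, 3.2, -6.0, -6.8, -6.0),
    y = c(nic[, 2], 1.2, 2.3, 0.2, 0, 0.8, -0.8),
    z = 0, stringsAsFactors = FALSE)

  tpl
}

kind_to_code <- function(kind) {
  c(heme_b = "HEM", heme_c = "HEC", fe2s2 = "FES", fe4s4 = "SF4",
    fe3s4 = "F3S", FAD = "FAD", NADP = "NAP")[kind]
}

#' Write a toy PDB structure containing cofactor heterogroups
#'
#' Places rigid template cofactors at prescribed centroids and writes them
#' as HETATM records with canonical residue codes (HEM, HEC, FES, SF4, F3S,
#' FAD, NAP). The resulting file is a fixture for the geometry pipeline:
#' distances between fixtures are controlled by construction, so distance
#' matrices, graphs and pathways can be checked against known answers.
#'
#' @param layout data.frame with columns `kind` (registry kind names such as
#'   `"fe2s2"`, or residue codes such as `"FES"`), `x`, `y`, `z` (centroid,
#'   Angstrom). One cofactor per row; templates are centered on their
#'   centroid before placement.
#' @param file output PDB path.
#' @return `file`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' make_toy_structure(data.frame(kind = c("fe2s2", "fe2s2"),
#'                               x = c(0, 12), y = 0, z = 0), f)
#' length(identify_cofactors(parse_structure(f)))
#' @export
make_toy_structure <- function(layout, file) {
  need <- c("kind", "x", "y", "z")
  if (!all(need %in% names(layout)))
    stop("layout must have columns: ", paste(need, collapse = ", "))
  tpl <- cofactor_templates()
  kinds <- as.character(layout$kind)
  # accept residue codes as aliases for kind names
  codes <- kind_to_code(cofactor_kinds())
  alias <- stats::setNames(cofactor_kinds(), codes)
  kinds <- ifelse(kinds %in% names(alias), alias[kinds], kinds)
  unknown <- setdiff(kinds, cofactor_kinds())
  if (length(unknown) > 0L)
    stop("unknown cofactor kind(s): ", paste(unknown, collapse = ", "))

  rows <- list()
  for (i in seq_along(kinds)) {
    t <- tpl[[kinds[i]]]
    centered <- scale(as.matrix(t[, c("x", "y", "z")]), scale = FALSE)
    t$x <- centered[, 1] + layout$x[i]
    t$y <- centered[, 2] + layout$y[i]
    t$z <- centered[, 3] + layout$z[i]
    t$resid <- unname(kind_to_code(kinds[i]))
    t$resno <- i
    rows[[i]] <- t
  }
  all <- do.call(rbind, rows)
  n <- nrow(all)
  xyz <- as.numeric(t(as.matrix(all[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = file, xyz = xyz,
                   type = rep("HETATM", n),
                   resno = all$resno, resid = all$resid,
                   eleno = seq_len(n), elety = all$name,
                   chain = rep("A", n), o = rep(1, n), b = rep(0, n),
                   elesy = all$element)
  invisible(file)
}
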