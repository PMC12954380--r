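#' Define a redox couple
#'
#' The currency of the bifurcation ledger: a named half-reaction with its
#' midpoint potential in mV vs SHE.
#'
#' @param name label, unique within a scheme.
#' @param Em_mV midpoint potential, mV vs SHE (finite).
#' @param source free-text provenance.
#' @return object of class `redox_couple`.
#' @examples
#' redox_couple("MK-7", -70, "membrane menaquinone pool")
#' @export
redox_couple <- function(name, Em_mV, source = "") {
  if (!is.finite(Em_mV)) stop("Em_mV must be finite")
  structure(list(name = name, Em = as.numeric(Em_mV), source = source),
            class = "redox_couple")
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf("<redox couple %s: E0' = %+g mV vs SHE>\n", x$name, x$Em))
  invisible(x)
}

as_em <- function(x) {
  if (inherits(x, "redox_couple")) return(x$Em)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) return(as.numeric(x))
  stop("expected a redox_couple or a single finite potential in mV")
}

#' Driving force of an electron transfer
#'
#' `acceptor Em - donor Em`, in mV; positive when the transfer is downhill
#' (thermodynamically favorable).
#'
#' @param donor,acceptor `redox_couple` objects or potentials in mV vs SHE.
#' @return driving force, mV.
#' @examples
#' driving_force(-70, 380)  # menaquinol electron to the nitrite/NO couple
#' @export
driving_force <- function(donor, acceptor) {
  as_em(acceptor) - as_em(donor)
}

#' Uphill energy requirement of an electron transfer
#'
#' `donor Em - acceptor Em`, in mV; positive when the transfer runs against
#' the potential gradient. Identically `-driving_force(donor, acceptor)`.
#'
#' @inheritParams driving_force
#' @return requirement, mV.
#' @examples
#' uphill_requirement(-70, -320)  # menaquinol electron up to NAD(P)+
#' @export
uphill_requirement <- function(donor, acceptor) {
  as_em(donor) - as_em(acceptor)
}

#' Quinol-symmetric estimate of the positive-side heme b potential
#'
#' In Rieske/cytochrome b complexes the potentials of the Rieske cluster and
#' the positive-side heme b (the two first acceptors of the bifurcated
#' electron pair) tend to sit symmetrically around the quinone potential.
#' Given measured quinone and Rieske potentials, the implied heme b_P
#' potential is the mirror image: `2*Em(quinone) - Em(rieske)`.
#'
#' @param quinone,rieske `redox_couple` objects or potentials in mV vs SHE.
#' @return estimated b_P potential, mV vs SHE.
#' @examples
#' estimate_bp(-70, 335)  # -475 mV
#' @export
estimate_bp <- function(quinone, rieske) {
  2 * as_em(quinone) - as_em(rieske)
}

#' Negative-side heme b potential from the b_P/b_N trend
#'
#' Across characterized Rieske/cytochrome b complexes the negative-side heme
#' sits roughly 130 mV above the positive-side heme; this applies that
#' offset.
#'
#' @param bp_Em b_P potential, mV vs SHE.
#' @param offset b_P to b_N potential difference, mV (default +130).
#' @return estimated b_N potential, mV vs SHE.
#' @examples
#' estimate_bn(-475)  # -345 mV
#' @export
estimate_bn <- function(bp_Em, offset = 130) {
  as_em(bp_Em) + offset
}

#' Assemble an electron-bifurcation scheme
#'
#' Names the four couples of a bifurcating quinol-oxidizing complex: the
#' quinone pool, the Rieske cluster (entry of the favorable branch), the
#' terminal acceptor of the high-potential branch, and the terminal acceptor
#' of the low-potential branch (e.g. NAD(P)+ when the complex is proposed to
#' generate NAD(P)H).
#'
#' @param quinone,rieske,high_branch_acceptor,low_branch_acceptor
#'   `redox_couple` objects.
#' @param bp_offset_to_bn b_P to b_N trend offset, mV.
#' @return object of class `bifurcation_scheme`.
#' @export
bifurcation_scheme <- function(quinone, rieske, high_branch_acceptor,
                               low_branch_acceptor,
                               bp_offset_to_bn = 130) {
  roles <- list(quinone = quinone, rieske = rieske,
                high_branch_acceptor = high_branch_acceptor,
                low_branch_acceptor = low_branch_acceptor)
  for (r in names(roles))
    if (!inherits(roles[[r]], "redox_couple"))
      stop(r, " must be a redox_couple")
  if (!is.finite(bp_offset_to_bn)) stop("bp_offset_to_bn must be finite")
  nm <- vapply(roles, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("couple names must be unique within a scheme")
  structure(c(roles, list(bp_offset_to_bn = bp_offset_to_bn)),
            class = "bifurcation_scheme")
}

#' Redox-potential feasibility of a bifurcation scheme
#'
#' Pure potential bookkeeping of the proposed coupling: the energy released
#' by sending one quinol electron down the high-potential branch
#' (`favorable_mV`), the energy demanded by pushing the other electron up to
#' the low-potential acceptor (`required_mV`), and their balance
#' (`net_mV = favorable - required`). The scheme is feasible, on standard
#' redox potentials alone, when the balance is non-negative. Estimates of
#' the b_P and b_N heme potentials ([estimate_bp()], [estimate_bn()]) are
#' filled in alongside. Proton-motive-force contributions are deliberately
#' not modeled.
#'
#' @param scheme a [bifurcation_scheme()].
#' @return object of class `energetics_report`: list with `favorable_mV`,
#'   `required_mV`, `net_mV`, `bp_estimate_mV`, `bn_estimate_mV`,
#'   `feasible`, and the input `scheme`.
#' @examples
#' sch <- bifurcation_scheme(
#'   quinone = redox_couple("MK-7", -70),
#'   rieske = redox_couple("Rieske", 335),
#'   high_branch_acceptor = redox_couple("nitrite/NO", 380),
#'   low_branch_acceptor = redox_couple("NAD(P)", -320))
#' assess_scheme(sch)
#' @export
assess_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "bifurcation_scheme"))
  fav <- driving_force(scheme$quinone, scheme$high_branch_acceptor)
  req <- uphill_requirement(scheme$quinone, scheme$low_branch_acceptor)
  bp <- estimate_bp(scheme$quinone, scheme$rieske)
  structure(list(
    favorable_mV = fav,
    required_mV = req,
    net_mV = fav - req,
    bp_estimate_mV = bp,
    bn_estimate_mV = estimate_bn(bp, scheme$bp_offset_to_bn),
    feasible = (fav - req) >= 0,
    scheme = scheme
  ), class = "energetics_report")
}

#' @export
print.energetics_report <- function(x, ...) {
  s <- x$scheme
  cat("Electron-bifurcation energetics (mV vs SHE)\n")
  cat(sprintf("  quinol electron -> %-14s : %+g - (%+g) = %+g mV released\n",
              s$high_branch_acceptor$name, s$high_branch_acceptor$Em,
              s$quinone$Em, x$favorable_mV))
  cat(sprintf("  quinol electron -> %-14s : %+g - (%+g) = %+g mV required\n",
              s$low_branch_acceptor$name, s$quinone$Em,
              s$low_branch_acceptor$Em, x$required_mV))
  cat(sprintf("  net balance                       : %+g mV (%s)\n",
              x$net_mV,
              if (x$feasible) "feasible" else "not feasible"))
  cat(sprintf("  heme b_P (quinol-symmetric vs %s) : %+g mV\n",
              s$rieske$name, x$bp_estimate_mV))
  cat(sprintf("  heme b_N (b_P %+g mV trend)       : %+g mV\n",
              s$bp_offset_to_bn, x$bn_estimate_mV))
  invisible(x)
}

#' Convert a potential difference to a molar Gibbs energy
#'
#' `dG = -n * F * dE`; a positive potential difference for a transferred
#' electron releases energy (negative dG).
#'
#' @param delta_mV potential difference, mV.
#' @param n_electrons number of electrons transferred.
#' @return Gibbs energy, kJ/mol.
#' @examples
#' potential_to_energy(450)  # about -43.4 kJ/mol
#' @export
potential_to_energy <- function(delta_mV, n_electrons = 1) {
  -n_electrons * 96485.34 * (delta_mV / 1000) / 1000
}

#' Reference redox couples for the anammox bifurcation ledger
#'
#' The couples used throughout the package examples: the menaquinone-7 pool
#' (E0' about -70 mV), NAD(P)+/NAD(P)H (-320 mV), nitrite/NO (+380 mV), and
#' the two measured Rieske-domain midpoints of the NAD(P)-reductase-bearing
#' complexes of *Kuenenia stuttgartiensis* (+303 and +335 mV).
#'
#' @return data.frame with columns `name`, `Em_mV`, `source`.
#' @export
anammox_couples <- function() {
  path <- system.file("extdata", "redox_couples.csv", package = "rieske",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a redox-couples table
#'
#' CSV with columns `name`, `Em_mV`, `source` (optional).
#'
#' @param file path.
#' @return named list of [redox_couple()] objects.
#' @export
read_couples <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("name", "Em_mV") %in% names(df)))
    stop("couples table needs columns name, Em_mV")
  if (anyDuplicated(df$name)) stop("couple names must be unique")
  src <- if ("source" %in% names(df)) df$source else rep("", nrow(df))
  stats::setNames(
    lapply(seq_len(nrow(df)),
           function(i) redox_couple(df$name[i], df$Em_mV[i], src[i])),
    df$name)
}
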