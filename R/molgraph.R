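# Molecular graph and conformer containers. The graph is the identity object:
# atoms carry element / formal charge / optional stereo flag, bonds carry an
# order in {1, 2, 3, ar}. One connected molecule per graph.

#' @importFrom stats rnorm runif setNames sd qnorm pnorm dist
#' @importFrom utils head write.csv read.csv
NULL

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

.BOND_ORDERS <- c("1", "2", "3", "ar")

#' Atomic number of an element symbol
#'
#' @param element character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- match(element, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  z
}

#' Construct a molecular graph
#'
#' The labeled graph that defines molecular identity: element symbols, formal
#' charges, optional per-atom stereo flags, and bonds with orders in
#' `{1, 2, 3, ar}` (`ar` = aromatic, SDF order code 4). The graph must be a
#' single connected molecule.
#'
#' @param elements character vector of element symbols.
#' @param bonds data frame with integer columns `a1`, `a2` (1-based atom
#'   indices) and character column `order` (one of `"1"`, `"2"`, `"3"`,
#'   `"ar"`); numeric orders are accepted and converted.
#' @param charges integer vector of formal charges (default all zero).
#' @param stereo optional character vector of per-atom stereo flags (`NA` =
#'   unset); participates in the canonical key only when any flag is set.
#' @param title record title carried through SDF I/O.
#' @return object of class `molecular_graph`.
#' @export
molecular_graph <- function(elements, bonds, charges = NULL, stereo = NULL,
                            title = "") {
  n <- length(elements)
  if (n < 1L) stop("a molecular graph needs at least one atom")
  atomic_number(elements) # validates symbols
  if (is.null(charges)) charges <- integer(n)
  if (length(charges) != n) stop("charges length must equal atom count")
  if (is.null(stereo)) stereo <- rep(NA_character_, n)
  if (length(stereo) != n) stop("stereo length must equal atom count")

  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                        order = as.character(bonds$order),
                        stringsAsFactors = FALSE)
  }
  if (nrow(bonds) > 0L) {
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n)) {
      stop("bond atom index out of range")
    }
    if (any(bonds$a1 == bonds$a2)) stop("self-bond not allowed")
    bonds$order[bonds$order == "4"] <- "ar"
    if (!all(bonds$order %in% .BOND_ORDERS)) {
      stop("bond order must be one of 1, 2, 3, ar")
    }
    key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }

  g <- structure(
    list(
      atoms = data.frame(element = as.character(elements),
                         charge = as.integer(charges),
                         stereo = as.character(stereo),
                         stringsAsFactors = FALSE),
      bonds = bonds,
      title = as.character(title)
    ),
    class = "molecular_graph"
  )
  if (!graph_is_connected(g)) {
    stop("graph is disconnected: one molecule per record")
  }
  g
}

#' Number of atoms in a molecular graph
#' @param graph a `molecular_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(graph) nrow(graph$atoms)

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d atoms, %d bonds\n",
              if (nzchar(x$title)) x$title else "(untitled)",
              n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

# igraph view of the molecular graph (undirected, vertices 1..n)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$bonds[, c("a1", "a2"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(graph)))
  )
}

graph_is_connected <- function(graph) {
  n <- n_atoms(graph)
  if (n == 1L) return(TRUE)
  if (nrow(graph$bonds) == 0L) return(FALSE)
  igraph::is_connected(as_igraph(graph))
}

# adjacency list: neighbors of each atom
graph_neighbors <- function(graph) {
  n <- n_atoms(graph)
  nb <- vector("list", n)
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b$a1[k]]] <- c(nb[[b$a1[k]]], b$a2[k])
    nb[[b$a2[k]]] <- c(nb[[b$a2[k]]], b$a1[k])
  }
  nb
}

graph_degrees <- function(graph) {
  tabulate(c(graph$bonds$a1, graph$bonds$a2), nbins = n_atoms(graph))
}

#' Construct a conformer
#'
#' One 3-D geometry of a molecular graph with its energy.
#'
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param energy energy in kcal/mol; may be non-finite only if `allow_nonfinite`.
#' @param source source label: `"QM"` or a force-field identifier.
#' @param allow_nonfinite allow a non-finite energy (flagged downstream).
#' @return object of class `conformer`.
#' @export
conformer <- function(coords, energy, source = "QM", allow_nonfinite = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("NaN/Inf coordinates forbidden")
  }
  energy <- as.numeric(energy)
  if (length(energy) != 1L) stop("energy must be a single number")
  if (!allow_nonfinite && !is.finite(energy)) stop("non-finite energy")
  structure(list(coords = unname(coords), energy = energy,
                 source = as.character(source)),
            class = "conformer")
}

#' Hartree to kcal/mol conversion constant
#'
#' Provided for upstream convenience when SDF energy tags are in hartree;
#' never applied implicitly by any reader.
#' @export
HARTREE_TO_KCAL <- 627.509474

#' Construct a structure record
#'
#' One QM-optimized conformer plus its per-force-field minimized conformers.
#' All conformers share the graph's atom ordering.
#'
#' @param graph `molecular_graph` of the QM-optimized geometry (the identity
#'   carrier).
#' @param qm QM `conformer`.
#' @param ff_results named list of `conformer` objects, one per force field.
#' @return object of class `structure_record`.
#' @export
structure_record <- function(graph, qm, ff_results = list()) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(qm, "conformer"))
  n <- n_atoms(graph)
  if (nrow(qm$coords) != n) stop("QM conformer atom count mismatch")
  for (nm in names(ff_results)) {
    if (nrow(ff_results[[nm]]$coords) != n) {
      stop("FF conformer atom count mismatch for ", nm)
    }
  }
  structure(list(graph = graph, qm = qm, ff_results = ff_results),
            class = "structure_record")
}
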