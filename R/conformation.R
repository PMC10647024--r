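#' Create a molecular conformation
#'
#' A conformation couples an ordered element list with Cartesian coordinates
#' in Angstrom, plus the metadata the analysis pipeline tracks: atom names,
#' net charge (used for charge-stratified reporting) and a role tag saying
#' whether the geometry is the receptor-bound pose, a generated conformer,
#' an optimized geometry, or an external reference.
#'
#' @param elements Character vector of chemical symbols, one per atom.
#' @param coords Numeric N x 3 matrix of positions in Angstrom.
#' @param atom_names Optional character vector of atom labels.
#' @param net_charge Integer net charge in elementary charges (default 0).
#' @param role One of `"bound"`, `"generated"`, `"optimized"`, `"reference"`.
#' @return An object of class `"conformation"`.
#' @examples
#' water <- conformation(c("O", "H", "H"),
#'                       rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' water
#' @export
conformation <- function(elements, coords,
                         atom_names = NULL, net_charge = 0L,
                         role = c("bound", "generated", "optimized", "reference")) {
  role <- match.arg(role)
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  if (length(elements) < 1L)
    err_shape("a conformation needs at least one atom")
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    err_shape("coords must be an N x 3 matrix")
  if (nrow(coords) != length(elements))
    err_shape(sprintf("coordinate rows (%d) do not match element count (%d)",
                      nrow(coords), length(elements)))
  if (!all(is.finite(coords)))
    err_shape("coordinates must be finite")
  bad <- setdiff(unique(elements), names(ELEMENT_MASSES))
  if (length(bad))
    err_shape(sprintf("not valid chemical symbols: %s", paste(bad, collapse = ", ")))
  if (!is.null(atom_names)) {
    atom_names <- as.character(atom_names)
    if (length(atom_names) != length(elements))
      err_shape("atom_names length must match element count")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = elements, coords = coords,
                 atom_names = atom_names,
                 net_charge = as.integer(net_charge), role = role),
            class = "conformation")
}

# Symbols the package recognizes; masses are only used for sanity checks and
# the heavy-atom filter (anything that is not H).
ELEMENT_MASSES <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d atoms (%s), net charge %+d, role '%s'\n",
              length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    sort(table(x$elements), decreasing = TRUE),
                    sep = "", collapse = " "),
              x$net_charge, x$role))
  invisible(x)
}

#' @export
as.matrix.conformation <- function(x, ...) x$coords

n_atoms <- function(conf) length(conf$elements)

# Replace coordinates, keeping all metadata; optionally retag the role.
set_coords <- function(conf, coords, role = conf$role) {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  conf$coords <- coords
  conf$role <- role
  conf
}

translate_conformation <- function(conf, shift) {
  set_coords(conf, sweep(conf$coords, 2L, shift, "+"))
}
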