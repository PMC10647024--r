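#' Read molecular structures
#'
#' Reads one or more structures from mol2, SDF (V2000) or xyz files.
#' mol2 records are parsed with bio3d (multi-record files are split on the
#' molecule delimiter and parsed record by record); SDF files are parsed
#' with ChemmineR; xyz is a bare geometry table and yields conformations
#' without bonds - operations that need connectivity raise an explicit
#' error for xyz-sourced records. Coordinates are always Angstrom.
#'
#' @param path File path.
#' @param format `"mol2"`, `"sdf"` or `"xyz"`; default inferred from the
#'   file extension.
#' @return List of records, each with `name`, `conformation` and `graph`
#'   (`NULL` for xyz; use [require_bonds()] where connectivity is needed).
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) err_parse(path, 0L, "file does not exist")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("mol2", "sdf", "xyz"))
  switch(format,
         mol2 = read_mol2_multi(path),
         sdf = read_sdf_multi(path),
         xyz = read_xyz_multi(path))
}

mol2_element_from_type <- function(ty, name) {
  el <- sub("\\..*$", "", ty)
  ifelse(el %in% names(ELEMENT_MASSES), el,
         sub("[0-9'].*$", "", name))
}

read_mol2_multi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) err_parse(path, 1L, "empty file")
  starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
  if (!length(starts)) err_parse(path, 1L, "no @<TRIPOS>MOLECULE record")
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp))
    writeLines(lines[starts[k]:ends[k]], tmp)
    m <- tryCatch(suppressWarnings(bio3d::read.mol2(tmp)),
                  error = function(e) err_parse(path, starts[k], conditionMessage(e)))
    at <- m$atom
    if (is.null(at) || !nrow(at)) err_parse(path, starts[k], "record has no atoms")
    coords <- cbind(as.numeric(at$x), as.numeric(at$y), as.numeric(at$z))
    if (any(!is.finite(coords))) err_parse(path, starts[k], "non-numeric coordinates")
    elements <- mol2_element_from_type(as.character(at$elety), as.character(at$elena))
    charge <- suppressWarnings(as.numeric(at$charge))
    net <- if (all(is.finite(charge))) as.integer(round(sum(charge))) else 0L
    bonds <- if (!is.null(m$bond) && nrow(m$bond))
      cbind(as.integer(m$bond$origin), as.integer(m$bond$target))
    else matrix(integer(0), ncol = 2L)
    graph <- mol_graph(elements, bonds, atom_names = as.character(at$elena))
    list(name = if (nzchar(m$name)) m$name else sprintf("mol%d", k),
         graph = graph,
         conformation = conformation(elements, coords,
                                     atom_names = as.character(at$elena),
                                     net_charge = net, role = "reference"))
  })
}

read_sdf_multi <- function(path) {
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e) err_parse(path, 1L, conditionMessage(e)))
  if (!length(sdfs)) err_parse(path, 1L, "no SDF records")
  lapply(seq_along(sdfs), function(k) {
    s <- sdfs[[k]]
    ab <- ChemmineR::atomblock(s)
    bb <- ChemmineR::bondblock(s)
    if (!nrow(ab)) err_parse(path, k, "record has no atoms")
    elements <- sub("_.*$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    bonds <- if (!is.null(bb) && nrow(bb))
      cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    else matrix(integer(0), ncol = 2L)
    hdr <- ChemmineR::header(s)
    list(name = if (nzchar(hdr[[1L]])) hdr[[1L]] else sprintf("mol%d", k),
         graph = mol_graph(elements, bonds),
         conformation = conformation(elements, coords, role = "reference"))
  })
}

read_xyz_multi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) err_parse(path, 1L, "empty file")
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) err_parse(path, i, "expected an atom count")
    if (i + 1L + n > length(lines)) err_parse(path, i, "truncated xyz block")
    name <- trimws(lines[i + 1L])
    body <- do.call(rbind, strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+"))
    if (ncol(body) < 4L) err_parse(path, i + 2L, "xyz rows need element + 3 coordinates")
    coords <- matrix(as.numeric(body[, 2:4]), ncol = 3L)
    if (any(!is.finite(coords))) err_parse(path, i + 2L, "non-numeric coordinates")
    cf <- conformation(body[, 1L], coords, role = "reference")
    rec <- list(name = if (nzchar(name)) name else sprintf("mol%d", length(out) + 1L),
                graph = NULL, conformation = cf)
    rec$source_format <- "xyz"
    rec$path <- path
    out[[length(out) + 1L]] <- rec
    i <- i + 2L + n
  }
  if (!length(out)) err_parse(path, 1L, "no xyz blocks found")
  out
}

#' @rdname read_structure
#' @param record A record returned by [read_structure()].
#' @export
require_bonds <- function(record) {
  if (is.null(record$graph))
    err_bonds_unavailable(if (is.null(record$path)) "structure" else record$path)
  record$graph
}

#' Write molecular structures
#'
#' Writes a list of structure records (as returned by [read_structure()],
#' or assembled as `list(name=, graph=, conformation=)`) to mol2 (via
#' bio3d), SDF (via ChemmineR) or xyz. Multi-record output goes to a
#' single file.
#'
#' @param records A single record or list of records.
#' @param path Output file path.
#' @param format `"mol2"`, `"sdf"` or `"xyz"`; default inferred from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(records, path, format = NULL) {
  if (!is.null(records$conformation)) records <- list(records)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("mol2", "sdf", "xyz"))
  switch(format,
         mol2 = write_mol2_multi(records, path),
         sdf = write_sdf_multi(records, path),
         xyz = write_xyz_multi(records, path))
  invisible(path)
}

as_bio3d_mol2 <- function(rec) {
  cf <- rec$conformation
  g <- rec$graph
  n <- n_atoms(cf)
  nb <- if (is.null(g)) 0L else nrow(g$bonds)
  names <- if (!is.null(cf$atom_names)) cf$atom_names
           else paste0(cf$elements, seq_len(n))
  atom <- data.frame(eleno = seq_len(n), elena = names,
                     x = cf$coords[, 1L], y = cf$coords[, 2L],
                     z = cf$coords[, 3L], elety = cf$elements,
                     resno = 1L, resid = "LIG1",
                     charge = 0, statbit = "",
                     stringsAsFactors = FALSE)
  bond <- if (nb) data.frame(id = seq_len(nb), origin = g$bonds[, 1L],
                             target = g$bonds[, 2L], type = "1",
                             stringsAsFactors = FALSE)
          else data.frame(id = integer(0), origin = integer(0),
                          target = integer(0), type = character(0))
  structure(list(atom = atom, bond = bond, substructure = NULL,
                 xyz = bio3d::as.xyz(as.numeric(t(cf$coords))),
                 info = c(n, nb, 1L, 0L, 0L),
                 name = if (is.null(rec$name)) "LIG" else rec$name),
            class = "mol2")
}

write_mol2_multi <- function(records, path) {
  if (file.exists(path)) unlink(path)
  for (k in seq_along(records)) {
    bio3d::write.mol2(as_bio3d_mol2(records[[k]]), file = path,
                      append = (k > 1L))
  }
}

write_sdf_multi <- function(records, path) {
  sdfs <- lapply(records, function(rec) {
    cf <- rec$conformation
    g <- rec$graph
    n <- n_atoms(cf)
    nb <- if (is.null(g)) 0L else nrow(g$bonds)
    header <- c(Molecule_Name = if (is.null(rec$name)) "LIG" else rec$name,
                Source = "confstrain", Comment = "",
                Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                      n, nb))
    ab <- cbind(C1 = cf$coords[, 1L], C2 = cf$coords[, 2L],
                C3 = cf$coords[, 3L], C5 = 0, C6 = 0, C7 = 0, C8 = 0,
                C9 = 0, C10 = 0, C11 = 0, C12 = 0, C13 = 0, C14 = 0,
                C15 = 0, C16 = 0)
    rownames(ab) <- paste(cf$elements, seq_len(n), sep = "_")
    bb <- if (nb) cbind(C1 = g$bonds[, 1L], C2 = g$bonds[, 2L],
                        C3 = rep(1L, nb), C4 = rep(0L, nb),
                        C5 = rep(0L, nb), C6 = rep(0L, nb), C7 = rep(0L, nb))
          else matrix(integer(0), 0L, 7L,
                      dimnames = list(NULL, paste0("C", 1:7)))
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = header, atomblock = ab, bondblock = bb,
                 datablock = character(0))
  })
  names(sdfs) <- vapply(seq_along(sdfs), function(k) sprintf("CMP%d", k), "")
  set <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")),
                      SDF = sdfs, ID = names(sdfs))
  ChemmineR::write.SDF(set, file = path)
}

write_xyz_multi <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    cf <- rec$conformation
    writeLines(c(as.character(n_atoms(cf)),
                 if (is.null(rec$name)) "" else rec$name,
                 sprintf("%-2s %14.8f %14.8f %14.8f", cf$elements,
                         cf$coords[, 1L], cf$coords[, 2L], cf$coords[, 3L])),
               con)
  }
}

# ---- JSON-lines ensemble ledger ------------------------------------------

#' Read and write ensemble-record ledgers
#'
#' The per-ligand analysis ledger is JSON-lines: one
#' `"ensemble_record"` per line with all scalar fields plus the member
#' energies. Writing is deterministic (fixed field order, full floating
#' precision), so identical analyses produce byte-identical ledgers.
#'
#' @param records List of `"ensemble_record"` objects.
#' @param path Ledger file path.
#' @return `write_ledger()` returns `path` invisibly; `read_ledger()`
#'   returns a list of `"ensemble_record"` objects.
#' @export
write_ledger <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(ligand_id = r$ligand_id, e_active = r$e_active,
                          member_energies = r$member_energies,
                          e_min = r$e_min, e_global = r$e_global,
                          e_max = r$e_max, n_conformers = r$n_conformers,
                          scenario = r$scenario, delta_e = r$delta_e,
                          atom_count = r$atom_count,
                          net_charge = r$net_charge,
                          rmsd_bound = r$rmsd_bound,
                          rmsd_members = r$rmsd_members),
                     auto_unbox = TRUE, digits = I(17), null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    ensemble_record(ligand_id = x$ligand_id, e_active = x$e_active,
                    member_energies = x$member_energies,
                    atom_count = x$atom_count, net_charge = x$net_charge,
                    rmsd_bound = if (is.null(x$rmsd_bound)) NA_real_ else x$rmsd_bound,
                    rmsd_members = x$rmsd_members)
  })
}
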