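# V2000 SDF reader/writer for conformer ensembles. Identity comes from the
# explicit bond table and M CHG lines, never perceived from coordinates.
# Energies are carried in a data tag (default <ENERGY_KCAL>) in kcal/mol.

#' Read a conformer ensemble from a V2000 SDF file
#'
#' One (graph, conformer) pair per SDF record, in file order. Record titles,
#' formal charges (`M  CHG`) and bond orders (4 is read as aromatic) are taken
#' from the connection table. The named data tag must be present in every
#' record and parse as a decimal energy in kcal/mol.
#'
#' @param path path to an SDF file.
#' @param energy_tag name of the data tag holding the energy (default
#'   `"ENERGY_KCAL"`).
#' @param source source label stored on each conformer (e.g. `"QM"` or a
#'   force-field id).
#' @return list of entries, each `list(graph = molecular_graph,
#'   conformer = conformer)`.
#' @export
read_conformer_sdf <- function(path, energy_tag = "ENERGY_KCAL",
                               source = "QM") {
  lines <- readLines(path, warn = FALSE)
  # split on records terminated by $$$$
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) stop("no SDF records ($$$$ terminator) in ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    rec <- lines[starts[r]:(ends[r] - 1L)]
    out[[r]] <- tryCatch(
      parse_sdf_record(rec, energy_tag = energy_tag, source = source),
      error = function(e) {
        stop(sprintf("SDF record %d of %s: %s", r, path, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  out
}

parse_sdf_record <- function(rec, energy_tag, source) {
  if (length(rec) < 4L) stop("truncated record header")
  title <- rec[1L]
  counts <- rec[4L]
  if (!grepl("V2000", counts)) stop("not a V2000 connection table")
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) {
    stop("malformed counts line")
  }
  if (length(rec) < 4L + natoms + nbonds) stop("truncated connection table")

  atom_lines <- rec[5L:(4L + natoms)]
  x <- as.numeric(substr(atom_lines, 1L, 10L))
  y <- as.numeric(substr(atom_lines, 11L, 20L))
  z <- as.numeric(substr(atom_lines, 21L, 30L))
  el <- trimws(substr(atom_lines, 32L, 34L))
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("malformed atom block")

  if (nbonds > 0L) {
    bond_lines <- rec[(5L + natoms):(4L + natoms + nbonds)]
    a1 <- as.integer(substr(bond_lines, 1L, 3L))
    a2 <- as.integer(substr(bond_lines, 4L, 6L))
    bo <- trimws(substr(bond_lines, 7L, 9L))
    if (anyNA(a1) || anyNA(a2)) stop("malformed bond block")
    bonds <- data.frame(a1 = a1, a2 = a2, order = bo,
                        stringsAsFactors = FALSE)
  } else {
    bonds <- NULL
  }

  charges <- integer(natoms)
  tail_lines <- rec[(5L + natoms + nbonds):length(rec)]
  for (ln in tail_lines[startsWith(tail_lines, "M  CHG")]) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))),
                                "\\s+")[[1]])
    nchg <- flds[1L]
    for (k in seq_len(nchg)) {
      charges[flds[2L * k]] <- flds[2L * k + 1L]
    }
  }

  graph <- molecular_graph(elements = el, bonds = bonds, charges = charges,
                           title = title)

  # data items: "> ... <TAG>" then value line(s) until blank
  energy <- NULL
  tag_re <- paste0("<", energy_tag, ">")
  hit <- which(startsWith(tail_lines, ">") & grepl(tag_re, tail_lines,
                                                   fixed = TRUE))
  if (length(hit) >= 1L && hit[1L] < length(tail_lines)) {
    val <- trimws(tail_lines[hit[1L] + 1L])
    energy <- suppressWarnings(as.numeric(val))
  }
  if (is.null(energy) || is.na(energy)) {
    stop(sprintf("missing or unparseable energy tag <%s>", energy_tag))
  }

  list(graph = graph,
       conformer = conformer(cbind(x, y, z), energy, source = source))
}

#' Write a conformer ensemble to a V2000 SDF file
#'
#' Inverse of [read_conformer_sdf()]: coordinates are printed at the format's
#' `%10.4f` precision, aromatic bonds as order 4, formal charges as `M  CHG`
#' lines, and each record carries the energy under `energy_tag`.
#'
#' @param entries list of `list(graph =, conformer =)` pairs.
#' @param path output path.
#' @param energy_tag data tag name for the energy.
#' @return `path`, invisibly.
#' @export
write_conformer_sdf <- function(entries, path, energy_tag = "ENERGY_KCAL") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (e in entries) {
    writeLines(format_sdf_record(e$graph, e$conformer, energy_tag), con)
  }
  invisible(path)
}

format_sdf_record <- function(graph, conf, energy_tag) {
  n <- n_atoms(graph)
  b <- graph$bonds
  lines <- c(
    graph$title, "  ffbench", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b))
  )
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              conf$coords[i, 1L], conf$coords[i, 2L],
                              conf$coords[i, 3L], graph$atoms$element[i]))
  }
  if (nrow(b) > 0L) {
    code <- match(b$order, .BOND_ORDERS) # "ar" is SDF code 4
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$a1, b$a2, code))
  }
  chg <- which(graph$atoms$charge != 0L)
  if (length(chg) > 0L) {
    # at most 8 atom/charge pairs per M CHG line
    for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf("%4d%4d", grp, graph$atoms$charge[grp]),
               collapse = "")
      ))
    }
  }
  lines <- c(lines, "M  END",
             sprintf(">  <%s>", energy_tag),
             format_energy(conf$energy), "",
             "$$$$")
  lines
}

# decimal text for an energy: stable, round-trips through as.numeric
format_energy <- function(e) {
  if (!is.finite(e)) return(as.character(e))
  formatC(e, format = "g", digits = 17)
}
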