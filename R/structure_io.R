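# PQR structure I/O.  PQR is the PDB-like whitespace-separated format
# carrying per-atom partial charge and radius in the occupancy/B columns:
#   ATOM  serial  name  resName  resSeq  x y z  charge  radius
# (the chain column is optional; whitespace-separated fields are accepted,
# which covers files written by pdb2pqr and by UHBD preparation tools).

#' Read a PQR structure file
#'
#' @param path file path or character lines.
#' @param role_map optional named character vector assigning role tags from
#'   atom names, e.g. `c(P1 = "P1", C3 = "C3", C4 = "C4", C5 = "C5")`
#'   (name = role, value = atom name as it appears in the file).
#' @param phosphate_names atom names flagged as phosphates (default `"P"`
#'   plus any name starting with `"P"` followed by a digit).
#' @param leaflet_rule how to assign leaflets: `"z_sign"` uses the sign of
#'   the atom z relative to the structure's mean z; or a numeric vector.
#' @return an atom tibble in this package's structure layout.
#' @export
read_pqr <- function(path, role_map = NULL, phosphate_names = NULL,
                     leaflet_rule = "z_sign") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) abort("no ATOM/HETATM records in the PQR source.")
  toks <- strsplit(trimws(lines), "\\s+")
  n_tok <- lengths(toks)
  if (any(n_tok < 10L))
    abort("PQR record with fewer than 10 whitespace-separated fields.")
  # fields counted from the end are robust to an optional chain column:
  # last two are charge and radius, the three before are x, y, z
  get_rev <- function(k) vapply(toks, function(t) t[length(t) - k], "")
  name <- vapply(toks, `[[`, "", 3)
  x <- as.numeric(get_rev(4)); y <- as.numeric(get_rev(3))
  z <- as.numeric(get_rev(2))
  charge <- as.numeric(get_rev(1)); radius <- as.numeric(get_rev(0))
  if (anyNA(c(x, y, z, charge, radius)))
    abort("non-numeric coordinate/charge/radius field in PQR source.")
  resseq <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 5)))
  if (anyNA(resseq)) resseq <- seq_along(name)
  role <- rep(NA_character_, length(name))
  if (!is.null(role_map))
    for (r in names(role_map)) role[name == role_map[[r]]] <- r
  if (is.null(phosphate_names)) {
    is_ph <- name == "P" | grepl("^P[0-9]", name)
  } else {
    is_ph <- name %in% phosphate_names
  }
  leaflet <- if (is.numeric(leaflet_rule)) as.integer(leaflet_rule)
             else ifelse(z >= mean(z), 1L, -1L)
  tibble::tibble(atom = name, role = role, lipid = resseq,
                 leaflet = leaflet, is_phosphate = is_ph,
                 x = x, y = y, z = z, charge = charge, radius = radius)
}

#' Write a structure as PQR
#'
#' @param structure atom tibble (see [generate_bilayer()]).
#' @param path optional output file.
#' @param resname residue name to stamp on every record.
#' @return invisibly, the character lines.
#' @export
write_pqr <- function(structure, path = NULL, resname = "LIP") {
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %5d    %8.3f%8.3f%8.3f %8.4f %7.4f",
    seq_len(nrow(structure)), substr(structure$atom, 1, 4), resname,
    structure$lipid, structure$x, structure$y, structure$z,
    structure$charge, structure$radius)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
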