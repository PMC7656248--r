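# Trajectory and table I/O.
#
# Supported trajectory formats are text-only: multi-model PDB (MODEL /
# ENDMDL blocks, CRYST1 for the box, coordinates in Angstrom) and XYZ with
# a sidecar box file (one edge triple per frame, same unit as the
# coordinates). Everything is normalised to nm on read.

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records of the first model. Waters are detected by
#' residue name (HOH/WAT/SOL), the metal by residue name or element in the
#' lanthanide set; anything with an unrecognisable element is classified as
#' peptide with a warning.
#'
#' @param path PDB file.
#' @return An `ln_topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  lines <- first_model_lines(lines)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  serial <- as.integer(substr(rec, 7, 11))
  if (anyDuplicated(serial)) stop("duplicate atom serial numbers in ", path)
  name <- trimws(substr(rec, 13, 16))
  resname <- trimws(substr(rec, 18, 20))
  resid <- as.integer(substr(rec, 23, 26))
  element <- trimws(substr(rec, 77, 78))
  blank <- !nzchar(element)
  if (any(blank)) element[blank] <- guess_element(name[blank], resname[blank])
  known <- toupper(element) %in% c(toupper(LN_SYMBOLS),
                                   "H", "C", "N", "O", "S", "P", "NA", "CL")
  if (any(!known)) {
    warning("unknown element(s) ", paste(unique(element[!known]), collapse = ", "),
            "; classified as peptide")
  }
  topology(name, resname, resid, element)
}

first_model_lines <- function(lines) {
  m_start <- grep("^MODEL", lines)
  if (length(m_start) == 0) return(lines)
  m_end <- grep("^ENDMDL", lines)
  if (length(m_end) == 0) stop("MODEL without ENDMDL")
  lines[seq(m_start[1], m_end[1])]
}

parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  c(as.numeric(substr(cl[1], 7, 15)),
    as.numeric(substr(cl[1], 16, 24)),
    as.numeric(substr(cl[1], 25, 33)))
}

#' Read a trajectory
#'
#' @param path Multi-model PDB or XYZ file.
#' @param top The matching `ln_topology` (atom count is checked per frame).
#' @param unit Coordinate unit of the file: `"A"` (Angstrom) or `"nm"`.
#'   PDB files are Angstrom by convention and default to `"A"`; XYZ
#'   defaults to `"nm"`.
#' @param format `"pdb"` or `"xyz"`; inferred from the file extension when
#'   missing.
#' @param box_path For XYZ input, the sidecar box file (one whitespace
#'   separated edge triple per frame, same unit as the coordinates).
#'   Defaults to `paste0(path, ".box")`. A missing box is an error, never a
#'   silent infinite box.
#' @return An `ln_traj` with coordinates and box in nm.
#' @export
read_trajectory <- function(path, top, unit = NULL, format = NULL,
                            box_path = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  if (format == "pdb") {
    if (is.null(unit)) unit <- "A"
    read_trajectory_pdb(path, top, unit)
  } else {
    if (is.null(unit)) unit <- "nm"
    if (is.null(box_path)) box_path <- paste0(path, ".box")
    read_trajectory_xyz(path, top, unit, box_path)
  }
}

unit_to_nm <- function(unit) {
  switch(match.arg(unit, c("nm", "A")), nm = 1, A = 0.1)
}

read_trajectory_pdb <- function(path, top, unit) {
  scale <- unit_to_nm(unit)
  lines <- readLines(path)
  box_A <- parse_cryst1(lines)
  if (is.null(box_A)) stop("no CRYST1 record in ", path, "; box is required")
  m_start <- grep("^MODEL", lines)
  if (length(m_start) == 0) {
    blocks <- list(lines)
  } else {
    m_end <- grep("^ENDMDL", lines)
    if (length(m_end) != length(m_start)) stop("unbalanced MODEL/ENDMDL")
    blocks <- Map(function(a, b) lines[a:b], m_start, m_end)
  }
  nf <- length(blocks)
  na <- nrow(top)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    rec <- blocks[[f]][grepl("^(ATOM  |HETATM)", blocks[[f]])]
    if (length(rec) != na) {
      stop("frame ", f, " has ", length(rec), " atoms; topology expects ", na)
    }
    coords[f, , 1] <- as.numeric(substr(rec, 31, 38))
    coords[f, , 2] <- as.numeric(substr(rec, 39, 46))
    coords[f, , 3] <- as.numeric(substr(rec, 47, 54))
  }
  trajectory(coords * scale, box_A * scale)
}

read_trajectory_xyz <- function(path, top, unit, box_path) {
  scale <- unit_to_nm(unit)
  lines <- readLines(path)
  na <- nrow(top)
  per <- na + 2L
  if (length(lines) %% per != 0) {
    stop("XYZ file length is not a multiple of ", per, " lines")
  }
  nf <- length(lines) %/% per
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    off <- (f - 1L) * per
    cnt <- suppressWarnings(as.integer(trimws(lines[off + 1L])))
    if (is.na(cnt) || cnt != na) {
      stop("frame ", f, " declares ", lines[off + 1L], " atoms; expected ", na)
    }
    flds <- do.call(rbind, strsplit(trimws(lines[off + 2L + seq_len(na)]), "\\s+"))
    coords[f, , ] <- apply(flds[, 2:4, drop = FALSE], 2, as.numeric)
  }
  if (!file.exists(box_path)) {
    stop("no box sidecar file at ", box_path, "; box is required")
  }
  box <- as.matrix(utils::read.table(box_path))
  if (nrow(box) == 1) box <- box[rep(1, nf), , drop = FALSE]
  if (nrow(box) != nf || ncol(box) != 3) {
    stop("box sidecar must have one edge triple per frame")
  }
  trajectory(coords * scale, box * scale)
}

#' Write a trajectory
#'
#' @param traj An `ln_traj` (nm).
#' @param top The matching `ln_topology`.
#' @param path Output file.
#' @param format `"pdb"` (multi-model, Angstrom, CRYST1 box) or `"xyz"`
#'   (nm, sidecar box file at `paste0(path, ".box")`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, top, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  check_traj_topology(traj, top)
  if (format == "pdb") write_trajectory_pdb(traj, top, path)
  else write_trajectory_xyz(traj, top, path)
  invisible(path)
}

write_trajectory_pdb <- function(traj, top, path) {
  nf <- n_frames(traj)
  hetatm <- top$class != "peptide"
  out <- character(0)
  box_A <- traj$box[1, ] * 10
  out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                        box_A[1], box_A[2], box_A[3], 90, 90, 90))
  name4 <- ifelse(nchar(top$name) < 4,
                  sprintf(" %-3s", top$name), sprintf("%-4s", top$name))
  for (f in seq_len(nf)) {
    xyz_A <- traj$coords[f, , , drop = TRUE] * 10
    xyz_A <- matrix(xyz_A, nrow(top), 3)
    rec <- sprintf("%-6s%5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(hetatm, "HETATM", "ATOM"),
                   ((top$index - 1L) %% 99999L) + 1L, name4, top$resname,
                   top$resid %% 10000L, xyz_A[, 1], xyz_A[, 2], xyz_A[, 3],
                   1, 0, substr(top$element, 1, 2))
    out <- c(out, sprintf("MODEL     %4d", f), rec, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
}

write_trajectory_xyz <- function(traj, top, path) {
  nf <- n_frames(traj)
  na <- nrow(top)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(na), sprintf("frame %d t= %g ps", f, traj$times[f]),
                 sprintf("%-4s %12.6f %12.6f %12.6f", top$element,
                         traj$coords[f, , 1], traj$coords[f, , 2],
                         traj$coords[f, , 3])), con)
  }
  utils::write.table(traj$box, paste0(path, ".box"), row.names = FALSE,
                     col.names = FALSE)
}

#' Write/read a result table as CSV
#'
#' Plain CSV writers used by every analysis stage and the pipeline; the
#' reader returns a data.frame with `stringsAsFactors = FALSE`.
#'
#' @param x A data.frame.
#' @param path Output (or input) file.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_result_csv
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
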