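# PDB v3.3 input/output. ATOM/HETATM records are parsed by fixed columns;
# trajectories are multi-model PDB files, one MODEL/ENDMDL block per frame,
# with frame times carried in "REMARK 250 TIME_PS" records so that a
# write/read cycle round-trips both coordinates (to the format's 0.001 A
# precision) and time stamps.

.parse_atom_lines <- function(lines, lineno, chain = NULL, altloc_keep = "A") {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad) == 0L) bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed ATOM record at line ", lineno[bad[1]],
           ": bad ", what, " field '", trimws(s[bad[1]]), "'")
    }
    v
  }
  field <- function(a, b) substr(lines, a, b)
  name <- trimws(field(13, 16))
  alt <- field(17, 17)
  resname <- trimws(field(18, 20))
  ch <- field(22, 22)
  resid <- num(field(23, 26), "residue number")
  x <- num(field(31, 38), "x")
  y <- num(field(39, 46), "y")
  z <- num(field(47, 54), "z")
  elem <- toupper(trimws(field(77, 78)))

  keep <- alt %in% c(" ", "", altloc_keep)
  if (!is.null(chain)) keep <- keep & ch == chain
  unknown <- keep & !(elem %in% names(.element_masses))
  if (any(unknown)) {
    elem[unknown] <- .element_from_name(name[unknown])
    warning(sum(unknown), " atom record(s) lacked a recognised element ",
            "symbol in columns 77-78; element inferred from the atom name",
            call. = FALSE)
  }
  data.frame(name = name[keep], element = elem[keep],
             resid = as.integer(resid[keep]), resname = resname[keep],
             chain = ch[keep], x = x[keep], y = y[keep], z = z[keep],
             stringsAsFactors = FALSE)
}

.split_models <- function(lines) {
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_model)) {
    return(list(seq_along(lines)))
  }
  starts <- which(is_model)
  ends <- which(is_end)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(k) seq(starts[k] + 1L, ends[k] - 1L))
}

#' Read a Structure from a PDB file
#'
#' Parses ATOM records of a PDB v3.3 file. Multi-model files return the
#' requested model only. The element is taken from columns 77-78 and, when
#' that field is blank or unrecognised, inferred from the atom name (with a
#' warning). Masses come from the packaged element-mass table.
#'
#' @param path path to a PDB file.
#' @param model model number to extract from a multi-model file (default: the
#'   first model).
#' @param chain chain id to read; the default `NULL` keeps only the first
#'   chain in the file (single-chain monomer convention). Use `chain = NA`
#'   to read all chains. Alternate locations other than ' '/'A' are always
#'   dropped.
#' @return a [structure_new()] `Structure`.
#' @export
read_pdb <- function(path, model = NULL, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- trimws(sub("^TITLE\\s*", "", lines[startsWith(lines, "TITLE")][1]))
  if (is.na(title)) title <- basename(path)
  blocks <- .split_models(lines)
  if (is.null(model)) model <- 1L
  if (model < 1L || model > length(blocks)) {
    stop("requested model ", model, " but file has ", length(blocks),
         " model(s)")
  }
  idx <- blocks[[model]]
  sel <- idx[startsWith(lines[idx], "ATOM") | startsWith(lines[idx], "HETATM")]
  if (length(sel) == 0L) stop("no ATOM records found in ", path)
  want <- if (is.null(chain) || (length(chain) == 1L && is.na(chain))) {
    NULL
  } else {
    chain
  }
  atoms <- .parse_atom_lines(lines[sel], sel, chain = want)
  if (is.null(chain) && nrow(atoms) > 0L) {
    atoms <- atoms[atoms$chain == atoms$chain[1L], , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no atoms left after chain/altloc filtering")
  structure_new(atoms, title = title)
}

.format_atom_line <- function(i, at) {
  elem <- at$element[i]
  name <- at$name[i]
  # short names start in column 14 unless they begin with a digit or are
  # 4 characters long
  fname <- if (nchar(name) >= 4L || grepl("^[0-9]", name)) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, fname, " ", substr(at$resname[i], 1, 3), at$chain[i],
          at$resid[i] %% 10000L, at$x[i], at$y[i], at$z[i], 1.0, 0.0,
          substr(elem, 1, 2))
}

.atom_block <- function(at) {
  vapply(seq_len(nrow(at)), .format_atom_line, character(1), at = at)
}

#' Write a Structure to a PDB file
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "Structure"))
  lines <- c(sprintf("TITLE     %s", structure$title),
             .atom_block(structure$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; the frame time in ps is stored in a
#' `REMARK 250 TIME_PS` record preceding each MODEL so that
#' [read_trajectory()] round-trips coordinates (to 0.001 A) and time stamps.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  if (length(traj$frames) == 0L) stop("trajectory has no frames")
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", traj$title), con)
  for (k in seq_along(traj$frames)) {
    at$x <- traj$frames[[k]][, 1]
    at$y <- traj$frames[[k]][, 2]
    at$z <- traj$frames[[k]][, 3]
    writeLines(c(sprintf("REMARK 250 TIME_PS %.6f", traj$times[k]),
                 sprintf("MODEL     %4d", k),
                 .atom_block(at),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Frame times are recovered from `REMARK 250 TIME_PS` records when present;
#' otherwise frames are stamped 1, 2, ... ps.
#'
#' @param path path to a multi-model PDB file.
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- trimws(sub("^TITLE\\s*", "", lines[startsWith(lines, "TITLE")][1]))
  if (is.na(title)) title <- basename(path)
  blocks <- .split_models(lines)
  times <- grep("^REMARK 250 TIME_PS", lines, value = TRUE)
  frames <- vector("list", length(blocks))
  atoms <- NULL
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    sel <- idx[startsWith(lines[idx], "ATOM") |
                 startsWith(lines[idx], "HETATM")]
    at <- .parse_atom_lines(lines[sel], sel)
    if (is.null(atoms)) atoms <- at
    if (nrow(at) != nrow(atoms)) {
      stop("model ", k, " has ", nrow(at), " atoms; expected ", nrow(atoms))
    }
    frames[[k]] <- as.matrix(at[, c("x", "y", "z")])
  }
  tvals <- if (length(times) == length(frames)) {
    as.numeric(sub("^REMARK 250 TIME_PS\\s*", "", times))
  } else {
    seq_along(frames)
  }
  trajectory_new(atoms, frames, tvals, title = title)
}
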