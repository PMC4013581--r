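# Segment annotation tables: named secondary-structure elements (helices,
# strands, sheet groups, loops) given as closed 1-based residue intervals.
# The packaged defaults describe the open and closed conformers of Mad2, the
# two-state spindle-checkpoint protein the default analyses are set up for;
# segment tables for other proteins load from a plain-text config.

.seg_names <- list(
  aA = "αA", aB = "αB", aC = "αC",
  b1 = "β1", b2 = "β2", b3 = "β3", b4 = "β4",
  b5 = "β5", b6 = "β6", b7 = "β7", b8 = "β8",
  b8p = "β8′", b8pp = "β8″",
  b78 = "β7/8", b645 = "β6/4/5",
  b8pp8p = "β8″/8′",
  loop5C = "β5-αC loop"
)

#' Create a segment table
#'
#' @param entries list of entries, each a list with elements `name` (unique
#'   string), `class` (one of `"helix"`, `"strand"`, `"sheet-group"`,
#'   `"loop"`) and `ranges` (list of length-2 integer vectors, closed 1-based
#'   residue intervals).
#' @return an object of class `SegmentTable`.
#' @export
segment_table <- function(entries) {
  classes <- c("helix", "strand", "sheet-group", "loop")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("segment names must be unique")
  for (e in entries) {
    if (!e$class %in% classes) {
      stop("unknown segment class '", e$class, "' for segment '", e$name, "'")
    }
    if (length(e$ranges) == 0L) stop("segment '", e$name, "' has no ranges")
    for (r in e$ranges) {
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
        stop("bad range for segment '", e$name, "'")
      }
    }
  }
  names(entries) <- nms
  class(entries) <- "SegmentTable"
  entries
}

#' @export
print.SegmentTable <- function(x, ...) {
  cat("SegmentTable with", length(x), "segments\n")
  for (e in x) {
    rng <- paste(vapply(e$ranges, function(r) paste(r, collapse = "-"),
                        character(1)), collapse = ",")
    cat(sprintf("  %-14s %-12s %s\n", e$name, e$class, rng))
  }
  invisible(x)
}

#' Residues covered by a segment
#'
#' @param segments a `SegmentTable`.
#' @param name segment name.
#' @return sorted integer vector of residue indices.
#' @export
segment_residues <- function(segments, name) {
  stopifnot(inherits(segments, "SegmentTable"))
  e <- segments[[name]]
  if (is.null(e)) stop("unknown segment '", name, "'")
  sort(unique(unlist(lapply(e$ranges, function(r) seq(r[1], r[2])))))
}

.entry <- function(name, class, ...) {
  list(name = name, class = class, ranges = list(...))
}

#' Packaged segment tables for the open and closed conformers
#'
#' Residue ranges of the secondary-structure elements of the two native Mad2
#' folds: three alpha helices, the beta strands, the composite sheet groups
#' used in the mass-center-distance and network analyses, and the beta5-alphaC
#' loop (defined as the inter-element gap 106-121 between the end of beta5
#' and the start of alphaC). The closed-state table has no beta1 strand: in
#' the closed fold the N-terminal strand is absorbed into the extended alphaA
#' helix (12-37).
#'
#' @param state `"open"` or `"closed"`.
#' @return a `SegmentTable`.
#' @export
default_segments <- function(state = c("open", "closed")) {
  state <- match.arg(state)
  s <- .seg_names
  common <- list(
    .entry(s$aB, "helix", c(61L, 75L)),
    .entry(s$aC, "helix", c(122L, 142L)),
    .entry(s$b2, "strand", c(43L, 49L)),
    .entry(s$b3, "strand", c(53L, 58L)),
    .entry(s$b4, "strand", c(81L, 90L)),
    .entry(s$b5, "strand", c(97L, 105L)),
    .entry(s$b6, "strand", c(150L, 160L)),
    .entry(s$b645, "sheet-group", c(150L, 160L), c(81L, 90L), c(97L, 105L)),
    .entry(s$loop5C, "loop", c(106L, 121L))
  )
  if (state == "open") {
    segment_table(c(list(
      .entry(s$aA, "helix", c(18L, 37L)),
      .entry(s$b1, "strand", c(11L, 13L)),
      .entry(s$b7, "strand", c(170L, 174L)),
      .entry(s$b8, "strand", c(184L, 191L)),
      .entry(s$b78, "sheet-group", c(170L, 174L), c(184L, 191L))
    ), common))
  } else {
    segment_table(c(list(
      .entry(s$aA, "helix", c(12L, 37L)),
      .entry(s$b8p, "strand", c(177L, 188L)),
      .entry(s$b8pp, "strand", c(190L, 200L)),
      .entry(s$b8pp8p, "sheet-group", c(190L, 200L), c(177L, 188L))
    ), common))
  }
}

#' Read a segment table from a plain-text config
#'
#' One line per segment: `name <TAB> class <TAB> ranges` where ranges is a
#' comma-separated list of `start-end` intervals. Blank lines and lines
#' starting with `#` are skipped.
#'
#' @param path path to the config file.
#' @return a `SegmentTable`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- lapply(seq_along(lines), function(k) {
    parts <- strsplit(lines[k], "\t")[[1]]
    if (length(parts) != 3L) {
      stop("segment config line ", k, " needs 3 tab-separated fields")
    }
    ranges <- lapply(strsplit(parts[3], ",")[[1]], function(rs) {
      ab <- as.integer(strsplit(trimws(rs), "-")[[1]])
      if (length(ab) != 2L || anyNA(ab)) {
        stop("bad range '", rs, "' on segment config line ", k)
      }
      ab
    })
    list(name = parts[1], class = parts[2], ranges = ranges)
  })
  segment_table(entries)
}

#' Write a segment table to a plain-text config
#'
#' @param segments a `SegmentTable`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "SegmentTable"))
  lines <- vapply(segments, function(e) {
    rng <- paste(vapply(e$ranges, function(r) paste(r, collapse = "-"),
                        character(1)), collapse = ",")
    paste(e$name, e$class, rng, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
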