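# Correlated-segment network: nodes are annotated segments, an inter-residue
# "edge" exists where |C(i,j)| meets a threshold, and the segment-pair weight
# is the number of such edges (so drawn line widths are proportional to the
# sum of edges connecting two segments). Signed sub-networks are available
# via the `sign` argument.

#' Build a correlated-segment network from a DCCM
#'
#' An edge between residues i in segment A and j in segment B exists when
#' `|C(i,j)| >= threshold` (or the signed variants); the weight of the A-B
#' network edge is the count of such residue pairs, and the mean |C| over
#' the A x B block is reported alongside.
#'
#' @param dccm a `DCCM` (row/column names are residue indices).
#' @param segments a `SegmentTable`; every segment residue must be covered
#'   by the DCCM.
#' @param threshold correlation magnitude threshold in [0, 1].
#' @param sign `"abs"` (default: use |C|), `"positive"` (C >= threshold) or
#'   `"negative"` (C <= -threshold).
#' @return an object of class `SegmentNetwork`: list with `nodes`
#'   (data.frame name, n_residues), `edges` (data.frame seg_a, seg_b,
#'   n_edges, mean_abs_C), `threshold`, `sign`.
#' @export
build_segment_network <- function(dccm, segments, threshold = 0.5,
                                  sign = c("abs", "positive", "negative")) {
  stopifnot(inherits(dccm, "DCCM"), inherits(segments, "SegmentTable"))
  sign <- match.arg(sign)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  resids <- as.integer(rownames(dccm))
  seg_names <- names(segments)
  seg_idx <- lapply(seg_names, function(nm) {
    rr <- segment_residues(segments, nm)
    miss <- setdiff(rr, resids)
    if (length(miss)) {
      stop("segment '", nm, "' has residues not covered by the DCCM: ",
           paste(utils::head(miss, 5), collapse = ","))
    }
    match(rr, resids)
  })
  names(seg_idx) <- seg_names
  nodes <- data.frame(name = seg_names,
                      n_residues = vapply(seg_idx, length, integer(1)),
                      stringsAsFactors = FALSE)
  M <- unclass(dccm)
  edges <- list()
  for (i in seq_along(seg_names)) {
    for (j in seq_along(seg_names)) {
      if (j <= i) next
      block <- M[seg_idx[[i]], seg_idx[[j]], drop = FALSE]
      # ignore residues the two segments share (self-correlation)
      shared <- intersect(seg_idx[[i]], seg_idx[[j]])
      if (length(shared)) {
        block[match(shared, seg_idx[[i]]), match(shared, seg_idx[[j]])] <- NA
      }
      hit <- switch(sign,
                    abs = abs(block) >= threshold,
                    positive = block >= threshold,
                    negative = block <= -threshold)
      n_edges <- sum(hit, na.rm = TRUE)
      if (n_edges > 0L) {
        edges[[length(edges) + 1L]] <- data.frame(
          seg_a = seg_names[i], seg_b = seg_names[j], n_edges = n_edges,
          mean_abs_C = mean(abs(block), na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(seg_a = character(), seg_b = character(),
               n_edges = integer(), mean_abs_C = numeric())
  obj <- list(nodes = nodes, edges = edges, threshold = threshold,
              sign = sign)
  class(obj) <- "SegmentNetwork"
  obj
}

#' @export
print.SegmentNetwork <- function(x, ...) {
  cat("SegmentNetwork:", nrow(x$nodes), "segments,", nrow(x$edges),
      "edges (threshold", x$threshold, ", mode", x$sign, ")\n")
  if (nrow(x$edges)) print.data.frame(x$edges, row.names = FALSE)
  invisible(x)
}

#' Shortest communication path between two segments
#'
#' Shortest path by hop count through the segment network; ties are broken
#' by the larger minimum edge weight along the path, then lexicographically.
#' Returns `NULL` when the segments are disconnected.
#'
#' @param network a `SegmentNetwork`.
#' @param source,sink segment names.
#' @return character vector of segment names from source to sink, or `NULL`.
#' @export
path_exists <- function(network, source, sink) {
  stopifnot(inherits(network, "SegmentNetwork"))
  nms <- network$nodes$name
  if (!source %in% nms) stop("unknown segment '", source, "'")
  if (!sink %in% nms) stop("unknown segment '", sink, "'")
  if (source == sink) return(source)
  e <- network$edges
  if (nrow(e) == 0L) return(NULL)
  wgt <- function(a, b) {
    hit <- (e$seg_a == a & e$seg_b == b) | (e$seg_a == b & e$seg_b == a)
    if (any(hit)) e$n_edges[which(hit)[1]] else NA_real_
  }
  adj <- lapply(nms, function(a) nms[!is.na(vapply(nms, wgt, numeric(1),
                                                   a = a)) & nms != a])
  names(adj) <- nms
  # BFS for shortest hop count
  dist <- stats::setNames(rep(Inf, length(nms)), nms)
  dist[source] <- 0
  frontier <- source
  while (length(frontier) && !is.finite(dist[sink])) {
    nxt <- character()
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (!is.finite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[sink])) return(NULL)
  # enumerate all shortest paths backward through the BFS layers
  paths <- list(sink)
  repeat {
    done <- all(vapply(paths, function(p) p[1] == source, logical(1)))
    if (done) break
    newp <- list()
    for (p in paths) {
      head_ <- p[1]
      if (head_ == source) {
        newp[[length(newp) + 1L]] <- p
        next
      }
      preds <- adj[[head_]][dist[adj[[head_]]] == dist[head_] - 1]
      for (q in preds) newp[[length(newp) + 1L]] <- c(q, p)
    }
    paths <- newp
  }
  score <- vapply(paths, function(p) {
    min(vapply(seq_len(length(p) - 1L),
               function(k) wgt(p[k], p[k + 1L]), numeric(1)))
  }, numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1L) {
    keys <- vapply(paths[best], paste, character(1), collapse = "\r")
    best <- best[order(keys)][1]
  }
  paths[[best[1]]]
}

#' Write a segment network as tab-separated edges and as DOT
#'
#' @param network a `SegmentNetwork`.
#' @param path output path for the edge list (`seg_a`, `seg_b`, `n_edges`,
#'   `mean_abs_C`).
#' @param dot_path optional path for a Graphviz DOT rendering (edge
#'   penwidths proportional to the intersegment edge counts).
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, dot_path = NULL) {
  stopifnot(inherits(network, "SegmentNetwork"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dot_path)) {
    e <- network$edges
    wmax <- if (nrow(e)) max(e$n_edges) else 1
    lines <- c("graph segments {",
               sprintf('  "%s";', network$nodes$name),
               if (nrow(e)) sprintf('  "%s" -- "%s" [penwidth=%.2f, label="%d"];',
                                    e$seg_a, e$seg_b,
                                    0.5 + 4.5 * e$n_edges / wmax, e$n_edges),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(path)
}
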