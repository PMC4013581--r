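make_dccm <- function(M, resids = seq_len(nrow(M))) {
  dimnames(M) <- list(resids, resids)
  structure(M, class = c("DCCM", "matrix"), n_frames = 100L,
            selection = seq_len(nrow(M)), fit = TRUE)
}

two_block_dccm <- function(cross = 0.9) {
  M <- diag(10)
  M[1:5, 6:10] <- cross
  M[6:10, 1:5] <- cross
  make_dccm(M)
}

two_block_segments <- segment_table(list(
  list(name = "segA", class = "sheet-group", ranges = list(c(1L, 5L))),
  list(name = "segB", class = "sheet-group", ranges = list(c(6L, 10L)))))

test_that("edge weights count threshold-passing residue pairs", {
  net <- build_segment_network(two_block_dccm(0.9), two_block_segments,
                               threshold = 0.5)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$n_edges, 25L)   # 5 x 5 counting oracle
  expect_equal(net$edges$mean_abs_C, 0.9, tolerance = 1e-12)
  expect_equal(net$nodes$n_residues, c(5L, 5L))
})

test_that("thresholds are validated and identity DCCMs give empty networks", {
  expect_error(build_segment_network(two_block_dccm(), two_block_segments,
                                     threshold = 1.0 + 1e-9), "threshold")
  expect_error(build_segment_network(two_block_dccm(), two_block_segments,
                                     threshold = -0.1), "threshold")
  net <- build_segment_network(make_dccm(diag(10)), two_block_segments,
                               threshold = 0.2)
  expect_equal(nrow(net$edges), 0L)
  # segment residues must be covered by the matrix
  segs_out <- segment_table(list(
    list(name = "far", class = "strand", ranges = list(c(90L, 95L)))))
  expect_error(build_segment_network(two_block_dccm(), segs_out, 0.5),
               "not covered")
})

test_that("raising the threshold never adds edges", {
  set.seed(42)
  M <- matrix(runif(400, -1, 1), 20, 20)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  segs <- segment_table(lapply(1:4, function(k) {
    list(name = paste0("s", k), class = "strand",
         ranges = list(c(5L * k - 4L, 5L * k)))
  }))
  prev <- Inf
  for (c_ in c(0.3, 0.5, 0.7)) {
    net <- build_segment_network(make_dccm(M), segs, threshold = c_)
    total <- sum(net$edges$n_edges)
    expect_lte(total, prev)
    prev <- total
  }
})

test_that("planted segment-level correlations are recovered exactly at c = 0.5", {
  tr <- make_correlated_trajectory(
    20, 400, seed = 43,
    blocks = list(list(a = 1:4, b = 9:12, sign = 1),
                  list(a = 15:17, b = 18:20, sign = -1)))
  C <- compute_dccm(tr, fit = FALSE)
  segs <- segment_table(list(
    list(name = "b1a", class = "strand", ranges = list(c(1L, 4L))),
    list(name = "gap", class = "loop", ranges = list(c(5L, 8L))),
    list(name = "b1b", class = "strand", ranges = list(c(9L, 12L))),
    list(name = "lpA", class = "strand", ranges = list(c(15L, 17L))),
    list(name = "lpB", class = "strand", ranges = list(c(18L, 20L)))))
  net <- build_segment_network(C, segs, threshold = 0.5)
  got <- sort(paste(net$edges$seg_a, net$edges$seg_b))
  # exactly the planted couplings (plus nothing), regardless of sign
  expect_setequal(got, c("b1a b1b", "lpA lpB"))
})

test_that("shortest communication paths follow hop count with weight tie-breaks", {
  chain <- list(nodes = data.frame(name = c("β1", "loop", "sheet")),
                edges = data.frame(seg_a = c("β1", "loop"),
                                   seg_b = c("loop", "sheet"),
                                   n_edges = c(4L, 7L),
                                   mean_abs_C = c(0.7, 0.8)),
                threshold = 0.5, sign = "abs")
  class(chain) <- "SegmentNetwork"
  expect_equal(path_exists(chain, "β1", "sheet"), c("β1", "loop", "sheet"))

  disco <- chain
  disco$edges <- disco$edges[1, ]
  expect_null(path_exists(disco, "β1", "sheet"))
  expect_error(path_exists(chain, "β1", "nope"), "unknown segment")

  # a direct edge beats any 2-hop path
  direct <- chain
  direct$edges <- rbind(direct$edges,
                        data.frame(seg_a = "β1", seg_b = "sheet",
                                   n_edges = 1L, mean_abs_C = 0.51))
  expect_equal(path_exists(direct, "β1", "sheet"), c("β1", "sheet"))

  # hop ties resolve toward the larger minimum edge weight
  square <- list(nodes = data.frame(name = c("a", "p", "q", "z")),
                 edges = data.frame(seg_a = c("a", "p", "a", "q"),
                                    seg_b = c("p", "z", "q", "z"),
                                    n_edges = c(2L, 2L, 9L, 8L),
                                    mean_abs_C = 0.8),
                 threshold = 0.5, sign = "abs")
  class(square) <- "SegmentNetwork"
  expect_equal(path_exists(square, "a", "z"), c("a", "q", "z"))
})

test_that("network files carry the edge list and DOT rendering", {
  net <- build_segment_network(two_block_dccm(0.9), two_block_segments, 0.5)
  f <- withr::local_tempfile()
  fdot <- withr::local_tempfile(fileext = ".dot")
  write_network(net, f, dot_path = fdot)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$n_edges, 25L)
  dot <- readLines(fdot)
  expect_true(any(grepl("segA.*segB", dot)))
})
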